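#' Worked-example data for the Europe-geography word sets
#'
#' Bundles the small printed data that accompany the method's worked
#' example for the word *London* within the set \{London, Moscow,
#' Paris, north, south, east, west, Germany, Poland, Russia\}:
#'
#' * `table1`: the published per-word values for London — the combined
#'   WordNet similarities (`language`) and the conditional probability
#'   estimates from one single-trial classification (`brain`), both
#'   named vectors in the canonical word order.  Note the exact tie
#'   between `south` and `west` in the brain column.
#' * `connection_language_london`, `connection_brain_london`: the two
#'   published 10x10 connection matrices for London (the brain one comes
#'   from a later, different classification run than `table1$brain`).
#' * `word_sets`: the four 10-word classification sets (three city
#'   names, three country names, the four relative directions).
#' * `trial_counts`: per-word trial frequencies over the 48-sentence,
#'   10-block design (640 trials in total for the first word set).
#'
#' @return a list with elements `table1`, `connection_language_london`,
#'   `connection_brain_london`, `word_sets`, `trial_counts`.
#' @examples
#' fx <- geography_fixtures()
#' sum(fx$trial_counts[as.character(fx$word_sets[[1]])])  # 640
#' @export
geography_fixtures <- function() {
  canon <- word_set(c("London", "Moscow", "Paris", "north", "south",
                      "east", "west", "Germany", "Poland", "Russia"))
  lab <- as.character(canon)

  language <- c(London = 1.000, Moscow = 0.396, Paris = 0.466,
                north = 0.106, south = 0.103, east = 0.076,
                west = 0.078, Germany = 0.322, Poland = 0.299,
                Russia = 0.303)[lab]
  brain <- c(London = 0.275, Moscow = 0.108, Paris = 0.133,
             north = 0.042, south = 0.000, east = 0.008,
             west = 0.000, Germany = 0.075, Poland = 0.025,
             Russia = 0.033)[lab]

  conn_lang <- matrix(c(
    # L  M  P  n  s  e  w Ge Po Ru
      0, 0, 0, 0, 0, 0, 0, 0, 0, 0,  # London
      1, 0, 1, 0, 0, 0, 0, 0, 0, 0,  # Moscow
      1, 0, 0, 0, 0, 0, 0, 0, 0, 0,  # Paris
      1, 1, 1, 0, 0, 0, 0, 1, 1, 1,  # north
      1, 1, 1, 1, 0, 0, 0, 1, 1, 1,  # south
      1, 1, 1, 1, 1, 0, 1, 1, 1, 1,  # east
      1, 1, 1, 1, 1, 0, 0, 1, 1, 1,  # west
      1, 1, 1, 0, 0, 0, 0, 0, 0, 0,  # Germany
      1, 1, 1, 0, 0, 0, 0, 1, 0, 1,  # Poland
      1, 1, 1, 0, 0, 0, 0, 1, 0, 0   # Russia
  ), 10L, 10L, byrow = TRUE, dimnames = list(lab, lab))

  conn_brain <- matrix(c(
    # L  M  P  n  s  e  w Ge Po Ru
      0, 0, 0, 0, 0, 0, 0, 0, 0, 0,  # London
      1, 0, 0, 0, 0, 0, 0, 0, 0, 0,  # Moscow
      1, 1, 0, 0, 0, 0, 0, 0, 0, 0,  # Paris
      1, 1, 1, 0, 0, 0, 0, 1, 0, 0,  # north
      1, 1, 1, 1, 0, 1, 1, 1, 1, 1,  # south
      1, 1, 1, 1, 0, 0, 1, 1, 1, 1,  # east
      1, 1, 1, 1, 0, 0, 0, 1, 1, 0,  # west
      1, 1, 1, 0, 0, 0, 0, 0, 0, 0,  # Germany
      1, 1, 1, 0, 0, 0, 0, 1, 0, 0,  # Poland
      1, 1, 1, 1, 0, 0, 0, 1, 1, 0   # Russia
  ), 10L, 10L, byrow = TRUE, dimnames = list(lab, lab))

  word_sets <- list(
    canon,
    word_set(c("Paris", "Vienna", "Athens", "north", "south", "east",
               "west", "Italy", "Spain", "Austria")),
    word_set(c("Berlin", "Rome", "Warsaw", "north", "south", "east",
               "west", "France", "Greece", "Poland")),
    word_set(c("Madrid", "Rome", "Vienna", "north", "south", "east",
               "west", "Spain", "Italy", "Austria"))
  )

  trial_counts <- c(Berlin = 70L, London = 80L, Moscow = 90L, Paris = 80L,
                    Rome = 80L, Warsaw = 80L, Madrid = 70L, Vienna = 40L,
                    Athens = 50L, France = 40L, Germany = 40L, Italy = 40L,
                    Poland = 40L, Russia = 50L, Austria = 40L, Greece = 40L,
                    Spain = 50L, north = 60L, south = 70L, east = 60L,
                    west = 70L)

  list(table1 = list(language = language, brain = brain),
       connection_language_london = conn_lang,
       connection_brain_london = conn_brain,
       word_sets = word_sets,
       trial_counts = trial_counts)
}
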