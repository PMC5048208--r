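#' Convert a probability to odds
#'
#' The pretest odds of an event with probability `p` are `p / (1 - p)`.
#' This is the first step of the odds-ratio form of Bayes' rule: pretest
#' odds are multiplied by diagnostic likelihood ratios to give post-test
#' odds.
#'
#' @param p Numeric vector of probabilities in `[0, 1)`.
#' @return Numeric vector of odds, `p / (1 - p)`.
#' @seealso [odds_to_probability()] for the inverse transform.
#' @examples
#' probability_to_odds(0.28)   # 0.3888889
#' probability_to_odds(0.5)    # even odds
#' @export
probability_to_odds <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  if (any(p == 1, na.rm = TRUE)) stop("p = 1 gives infinite odds")
  p / (1 - p)
}

#' Convert odds to a probability
#'
#' Inverse of [probability_to_odds()]: `o / (1 + o)`. Used to transform
#' post-test odds back to a post-test probability after likelihood-ratio
#' updates.
#'
#' @param o Numeric vector of non-negative odds.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' odds_to_probability(1)          # 0.5
#' odds_to_probability(0.3888889)  # 0.28
#' @export
odds_to_probability <- function(o) {
  if (!is.numeric(o)) stop("'o' must be numeric")
  if (any(o < 0, na.rm = TRUE)) stop("odds must be non-negative")
  ifelse(is.infinite(o), 1, o / (1 + o))
}
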