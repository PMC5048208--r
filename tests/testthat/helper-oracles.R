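# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUROC by exhaustive case-control pair counting (ties score 1/2).
brute_auroc <- function(values, outcome, direction = "high_is_risk") {
  s <- if (direction == "high_is_risk") values else -values
  case <- s[outcome == 1]
  ctrl <- s[outcome == 0]
  tot <- 0
  for (x in case) for (y in ctrl)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case) * length(ctrl))
}

# Maximum Youden J by direct enumeration of every candidate cut. The
# degenerate all-positive / all-negative cuts have J = 0 exactly, so no
# exclusion is needed for the maximum to be well-defined.
brute_youden_max <- function(values, outcome, direction = "high_is_risk") {
  cuts <- c(-Inf, sort(unique(values)), Inf)
  case <- values[outcome == 1]
  ctrl <- values[outcome == 0]
  best <- -Inf
  for (t in cuts) {
    if (direction == "high_is_risk") {
      sens <- mean(case > t); spec <- mean(ctrl <= t)
    } else {
      sens <- mean(case <= t); spec <- mean(ctrl > t)
    }
    best <- max(best, sens + spec - 1)
  }
  best
}

# Posterior by direct class-conditional probability products (naive Bayes),
# without any odds arithmetic.
brute_posterior <- function(calls, sens, spec, prior) {
  pc <- prior
  qc <- 1 - prior
  for (i in seq_along(calls)) {
    if (calls[i] == 1) {
      pc <- pc * sens[i]
      qc <- qc * (1 - spec[i])
    } else {
      pc <- pc * (1 - sens[i])
      qc <- qc * spec[i]
    }
  }
  pc / (pc + qc)
}

# Small random cohort with deliberate ties; guarantees both classes.
random_tied_cohort <- function(n) {
  repeat {
    y <- stats::rbinom(n, 1, 0.4)
    if (sum(y) >= 1 && sum(1 - y) >= 1) break
  }
  x <- sample(1:6, n, replace = TRUE) + ifelse(y == 1, sample(0:2, n, TRUE), 0)
  list(x = as.numeric(x), y = y)
}

# Published per-predictor operating characteristics (percent scale) and the
# likelihood ratios printed alongside them.
published_lr_table <- function() {
  data.frame(
    name = c("drug_use", "panss_positive", "panss_negative", "panss_general",
             "gaf", "nervonic_acid", "total_omega3"),
    sens_pct = c(72.73, 81.82, 72.73, 72.73, 90.91, 90.91, 81.82),
    spec_pct = c(72.41, 65.52, 68.97, 75.86, 51.72, 53.57, 67.86),
    lr_pos = c(2.64, 2.37, 2.34, 3.01, 1.88, 1.96, 2.55),
    lr_neg = c(0.38, 0.28, 0.40, 0.36, 0.18, 0.17, 0.27),
    stringsAsFactors = FALSE)
}

uhr_groups <- function(spec = uhr_cohort_spec()) {
  gl <- vapply(spec$predictors, `[[`, character(1), "group")
  split(names(spec$predictors), factor(gl, levels = unique(gl)))
}

uhr_directions <- function(spec = uhr_cohort_spec()) {
  vapply(spec$predictors, `[[`, character(1), "direction")
}
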