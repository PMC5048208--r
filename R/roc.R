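# Empirical ROC machinery: curves over observed cuts, DeLong variance and
# correlated-AUROC comparison, Youden-optimal thresholds.

.check_outcome <- function(outcome) {
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0, 1))) stop("'outcome' must be coded 0/1")
  if (sum(outcome == 1) == 0) stop("degenerate outcome: no cases (outcome == 1)")
  if (sum(outcome == 0) == 0) stop("degenerate outcome: no controls (outcome == 0)")
  outcome
}

# Placement values for the Mann-Whitney kernel (ties count 1/2).
# s is oriented so that higher values indicate risk.
.placements <- function(s, outcome) {
  case <- s[outcome == 1]
  ctrl <- s[outcome == 0]
  m <- length(case)
  n <- length(ctrl)
  r_all <- rank(c(case, ctrl), ties.method = "average")
  r_case <- rank(case, ties.method = "average")
  r_ctrl <- rank(ctrl, ties.method = "average")
  # for case i: #{ctrl < x_i} + 0.5 #{ctrl == x_i} = R_i - r_i
  v10 <- (r_all[seq_len(m)] - r_case) / n
  # for control j: #{case > y_j} + 0.5 #{case == y_j} = m - (R_j - r_j)
  v01 <- (m - (r_all[m + seq_len(n)] - r_ctrl)) / m
  # sum-of-midranks form: exact half-integer arithmetic, so the AUROC is
  # bit-identical to exhaustive pair counting
  auroc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auroc = auroc, m = m, n = n)
}

#' Empirical ROC curve with DeLong variance
#'
#' Computes the empirical ROC of a predictor against a binary outcome over
#' all distinct observed values as candidate cuts (plus infinite endpoints),
#' the AUROC as the tie-corrected Mann-Whitney statistic, its DeLong
#' standard error, and a two-sided test against the chance value 0.5.
#'
#' The calling convention follows the direction of abnormality: for
#' `direction = "high_is_risk"` a subject is called positive when
#' `value > t`; for `"low_is_risk"` when `value <= t`.
#'
#' @param values Numeric predictor vector (no missing values; filter first).
#' @param outcome Binary outcome vector (1 = event), same length.
#' @param direction `"high_is_risk"` (default) or `"low_is_risk"`.
#' @return An object of class `"roc_curve"`: a list with `points` (data frame
#'   of `threshold`, `sensitivity`, `specificity`, ordered by increasing
#'   specificity), `auroc`, `auroc_se`, `p_vs_chance`, `direction`,
#'   `n_cases`, `n_controls`, and the data (`values`, `outcome`) for paired
#'   comparisons.
#' @seealso [youden_optimal()], [auroc_test()], [delong_compare()]
#' @examples
#' set.seed(1)
#' y <- rbinom(60, 1, 0.3)
#' x <- rnorm(60, mean = y)
#' r <- roc_curve(x, y)
#' r$auroc
#' @export
roc_curve <- function(values, outcome,
                      direction = c("high_is_risk", "low_is_risk")) {
  direction <- match.arg(direction)
  outcome <- .check_outcome(outcome)
  if (length(values) != length(outcome))
    stop("'values' and 'outcome' lengths differ")
  if (anyNA(values) || anyNA(outcome))
    stop("missing values are not allowed; filter before calling roc_curve()")

  s <- if (direction == "high_is_risk") values else -values
  pl <- .placements(s, outcome)

  cuts <- c(-Inf, sort(unique(values)), Inf)
  case <- values[outcome == 1]
  ctrl <- values[outcome == 0]
  if (direction == "high_is_risk") {
    sens <- vapply(cuts, function(t) mean(case > t), numeric(1))
    spec <- vapply(cuts, function(t) mean(ctrl <= t), numeric(1))
  } else {
    sens <- vapply(cuts, function(t) mean(case <= t), numeric(1))
    spec <- vapply(cuts, function(t) mean(ctrl > t), numeric(1))
  }
  pts <- data.frame(threshold = cuts, sensitivity = sens, specificity = spec)
  pts <- pts[!duplicated(pts[, c("sensitivity", "specificity")]), ]
  pts <- pts[order(pts$specificity, -pts$sensitivity), ]
  rownames(pts) <- NULL

  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- if (is.finite(v)) sqrt(max(v, 0)) else NA_real_
  if (is.na(se)) {
    # fewer than 2 cases or 2 controls: variance is undefined
    p <- NA_real_
    zero_var <- FALSE
  } else if (se == 0) {
    p <- if (pl$auroc == 0.5) 1 else 0
    zero_var <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs((pl$auroc - 0.5) / se))
    zero_var <- FALSE
  }

  structure(list(points = pts, auroc = pl$auroc, auroc_se = se,
                 p_vs_chance = p, zero_variance = zero_var,
                 direction = direction,
                 n_cases = pl$m, n_controls = pl$n,
                 values = values, outcome = outcome,
                 placements = pl),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, digits = 4, ...) {
  cat("Empirical ROC curve (", x$n_cases, " cases, ", x$n_controls,
      " controls, direction: ", x$direction, ")\n", sep = "")
  cat("  AUROC =", format(x$auroc, digits = digits),
      " (DeLong SE =", format(x$auroc_se, digits = digits), ")\n")
  cat("  two-sided P vs AUROC 0.5:", format.pval(x$p_vs_chance, digits = digits), "\n")
  invisible(x)
}

#' Test an AUROC against chance
#'
#' Two-sided test of the null AUROC = 0.5. The default uses the normal
#' approximation `z = (AUROC - 0.5) / SE` with the DeLong variance; an exact
#' Monte-Carlo permutation test (permuting outcome labels) is available for
#' very small samples.
#'
#' @param roc A [roc_curve()] object (needs at least 2 cases and 2 controls
#'   for a meaningful DeLong variance).
#' @param method `"delong"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations for `method = "permutation"`.
#' @return A list with `statistic` (z, or NA for permutation), `p_value`,
#'   `auroc`, `method`, and `zero_variance` (TRUE when the DeLong variance
#'   degenerates to 0, in which case the p-value is a limiting value and a
#'   warning is issued).
#' @export
auroc_test <- function(roc, method = c("delong", "permutation"),
                       n_perm = 2000) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "roc_curve"))
  if (method == "delong") {
    if (roc$zero_variance)
      warning("zero DeLong variance (perfect or constant classifier); ",
              "p-value is a limiting value")
    z <- if (roc$zero_variance) NA_real_ else (roc$auroc - 0.5) / roc$auroc_se
    out <- list(statistic = z, p_value = roc$p_vs_chance, auroc = roc$auroc,
                method = "delong", zero_variance = roc$zero_variance)
  } else {
    s <- if (roc$direction == "high_is_risk") roc$values else -roc$values
    obs <- abs(roc$auroc - 0.5)
    y <- roc$outcome
    hits <- vapply(seq_len(n_perm), function(i) {
      abs(.placements(s, sample(y))$auroc - 0.5) >= obs - 1e-12
    }, logical(1))
    out <- list(statistic = NA_real_, p_value = (sum(hits) + 1) / (n_perm + 1),
                auroc = roc$auroc, method = "permutation",
                zero_variance = roc$zero_variance)
  }
  out
}

#' Youden-optimal operating point
#'
#' Selects the cut maximizing Youden's J = sensitivity + specificity - 1
#' over the ROC operating points, excluding the two degenerate endpoints
#' (all-positive and all-negative calls) unless every interior point has
#' J <= 0. Ties are broken in favour of higher sensitivity (a missed event
#' is costlier than a false alarm), then in favour of the less extreme
#' threshold (closest to the median observed value).
#'
#' @param roc A [roc_curve()] object.
#' @return An object of class `"youden"`: list with `threshold`, `j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pts <- roc$points
  degen <- (pts$sensitivity == 1 & pts$specificity == 0) |
           (pts$sensitivity == 0 & pts$specificity == 1)
  interior <- pts[!degen, , drop = FALSE]
  j_all <- function(d) d$sensitivity + d$specificity - 1
  cand <- if (nrow(interior) > 0 && any(j_all(interior) > 0)) interior else pts
  j <- j_all(cand)
  best <- cand[j >= max(j) - 1e-12, , drop = FALSE]
  if (nrow(best) > 1)
    best <- best[best$sensitivity >= max(best$sensitivity) - 1e-12, , drop = FALSE]
  if (nrow(best) > 1) {
    med <- stats::median(roc$values)
    best <- best[which.min(abs(best$threshold - med)), , drop = FALSE]
  }
  structure(list(threshold = best$threshold[1],
                 j = best$sensitivity[1] + best$specificity[1] - 1,
                 sensitivity = best$sensitivity[1],
                 specificity = best$specificity[1]),
            class = "youden")
}

#' @export
print.youden <- function(x, digits = 4, ...) {
  cat("Youden-optimal cut: threshold =", format(x$threshold, digits = digits),
      " J =", format(x$j, digits = digits),
      " (sens =", format(x$sensitivity, digits = digits),
      ", spec =", format(x$specificity, digits = digits), ")\n")
  invisible(x)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Compares the AUROCs of two predictors measured on the same subjects using
#' the DeLong covariance of the paired placement values.
#'
#' @param roc_a,roc_b [roc_curve()] objects computed on the same subjects
#'   (identical outcome vectors in the same order).
#' @return A list of class `"delong_test"` with `delta_auroc`
#'   (AUROC a - AUROC b), `se`, `z`, `p_value`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_curve"), inherits(roc_b, "roc_curve"))
  if (length(roc_a$outcome) != length(roc_b$outcome) ||
      any(roc_a$outcome != roc_b$outcome))
    stop("ROC curves must be computed on the same subjects (paired outcomes)")
  a <- roc_a$placements
  b <- roc_b$placements
  m <- a$m; n <- a$n
  var_a <- stats::var(a$v10) / m + stats::var(a$v01) / n
  var_b <- stats::var(b$v10) / m + stats::var(b$v01) / n
  cov_ab <- stats::cov(a$v10, b$v10) / m + stats::cov(a$v01, b$v01) / n
  delta <- a$auroc - b$auroc
  v <- var_a + var_b - 2 * cov_ab
  if (v <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    se <- 0
  } else {
    se <- sqrt(v)
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(delta_auroc = delta, se = se, z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, digits = 4, ...) {
  cat("DeLong paired AUROC comparison\n")
  cat("  delta AUROC =", format(x$delta_auroc, digits = digits),
      " SE =", format(x$se, digits = digits),
      " z =", format(x$z, digits = digits),
      " P =", format.pval(x$p_value, digits = digits), "\n")
  invisible(x)
}

#' Export ROC operating points
#'
#' Writes the operating points of a ROC curve as a CSV file.
#'
#' @param roc A [roc_curve()] object.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(roc$points)
}
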