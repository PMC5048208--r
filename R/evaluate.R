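# Combined-model evaluation: ROC over posterior probabilities, predictive
# values at a given prevalence, BCa bootstrap of sensitivity at fixed
# specificity, and paired model comparison.

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Standard identities:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#'
#' @param sensitivity,specificity,prevalence Probabilities (vectorized).
#' @return List with `ppv` and `npv`.
#' @examples
#' ppv_npv(0.7273, 0.9643, 0.28)
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  list(ppv = sensitivity * prevalence /
         (sensitivity * prevalence + (1 - specificity) * (1 - prevalence)),
       npv = specificity * (1 - prevalence) /
         (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence))
}

#' Evaluate a set of posterior probabilities against outcomes
#'
#' Computes the ROC of the posterior scores (higher = riskier), the
#' Youden-optimal probability threshold, sensitivity and specificity at
#' that threshold, and PPV/NPV at the supplied prevalence.
#'
#' @param posteriors Numeric vector of post-test probabilities in `[0, 1]`.
#' @param outcome Binary outcome vector (1 = event).
#' @param prevalence Prevalence used for the predictive values; defaults to
#'   the observed outcome rate.
#' @return An object of class `"lrbayes_eval"`: list with `roc`
#'   ([roc_curve()]), `threshold` (probability cut), `sensitivity`,
#'   `specificity`, `youden_j`, `ppv`, `npv`, `prevalence`, `auroc`,
#'   `auroc_se`, `auroc_ci` (95%, normal approximation), `p_value`.
#' @export
evaluate_posteriors <- function(posteriors, outcome, prevalence = NULL) {
  if (any(posteriors < 0 | posteriors > 1, na.rm = TRUE))
    stop("posteriors must lie in [0, 1]")
  outcome <- .check_outcome(outcome)
  if (is.null(prevalence)) prevalence <- mean(outcome)
  if (length(unique(posteriors)) == 1)
    warning("degenerate posteriors (all equal); AUROC is 0.5")
  roc <- roc_curve(posteriors, outcome, direction = "high_is_risk")
  yj <- youden_optimal(roc)
  pv <- ppv_npv(yj$sensitivity, yj$specificity, prevalence)
  ci <- pmin(pmax(roc$auroc + c(-1, 1) * stats::qnorm(0.975) * roc$auroc_se,
                  0), 1)
  structure(list(roc = roc, threshold = yj$threshold,
                 sensitivity = yj$sensitivity, specificity = yj$specificity,
                 youden_j = yj$j, ppv = pv$ppv, npv = pv$npv,
                 prevalence = prevalence, auroc = roc$auroc,
                 auroc_se = roc$auroc_se, auroc_ci = ci,
                 p_value = roc$p_vs_chance),
            class = "lrbayes_eval")
}

#' @export
print.lrbayes_eval <- function(x, digits = 4, ...) {
  cat("Model evaluation (prevalence ", format(x$prevalence, digits = digits),
      ")\n", sep = "")
  cat("  AUROC =", format(x$auroc, digits = digits),
      " (SE ", format(x$auroc_se, digits = digits),
      ", 95% CI ", format(x$auroc_ci[1], digits = digits), "-",
      format(x$auroc_ci[2], digits = digits),
      ", P ", format.pval(x$p_value, digits = digits), ")\n", sep = "")
  cat("  Youden threshold probability >", format(x$threshold, digits = digits),
      ": sens =", format(x$sensitivity, digits = digits),
      " spec =", format(x$specificity, digits = digits), "\n")
  cat("  PPV =", format(x$ppv, digits = digits),
      " NPV =", format(x$npv, digits = digits), "\n")
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' Operating point chosen conservatively: the ROC point with the smallest
#' attainable specificity that is at least `fixed_specificity` (calls are
#' `score > t`); returns the sensitivity there.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param outcome Binary outcome vector.
#' @param fixed_specificity Target specificity in `[0, 1]`.
#' @return Sensitivity at the selected operating point.
#' @export
sens_at_spec <- function(scores, outcome, fixed_specificity) {
  case <- scores[outcome == 1]
  ctrl <- sort(scores[outcome == 0])
  m <- length(ctrl)
  if (m == 0 || length(case) == 0) return(NA_real_)
  k <- ceiling(fixed_specificity * m - 1e-9)
  if (k <= 0) return(mean(case > -Inf))
  t <- ctrl[k]
  mean(case > t)
}

# Order-statistic interpolation on the normal-quantile scale (the usual
# bootstrap-CI convention).
.quantile_norm_interp <- function(t, alpha) {
  t <- sort(t)
  R <- length(t)
  vapply(alpha, function(a) {
    rk <- (R + 1) * a
    if (rk <= 1) return(t[1])
    if (rk >= R) return(t[R])
    k <- floor(rk)
    if (t[k] == t[k + 1]) return(t[k])
    g <- (stats::qnorm(a) - stats::qnorm(k / (R + 1))) /
      (stats::qnorm((k + 1) / (R + 1)) - stats::qnorm(k / (R + 1)))
    t[k] + g * (t[k + 1] - t[k])
  }, numeric(1))
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Computes a BCa confidence interval from a point estimate, bootstrap
#' replicates and jackknife leave-one-out values. The bias-correction
#' constant uses the proportion of replicates below the point estimate
#' (ties counted half, which keeps the correction meaningful for discrete
#' statistics); the acceleration comes from the skewness of the jackknife
#' values. Falls back to the percentile interval with a warning when the
#' bias correction is undefined (all replicates on one side of the
#' estimate).
#'
#' @param t0 Point estimate on the original data.
#' @param t_star Numeric vector of bootstrap replicate statistics.
#' @param jack Numeric vector of jackknife leave-one-out statistics.
#' @param conf Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `z0`, `acceleration`, and
#'   `method_used` (`"bca"` or `"percentile"`).
#' @export
bca_interval <- function(t0, t_star, jack, conf = 0.95) {
  alpha <- (1 - conf) / 2
  B <- length(t_star)
  pb <- (sum(t_star < t0) + 0.5 * sum(t_star == t0)) / B
  if (pb <= 0 || pb >= 1) {
    warning("bias correction undefined (all bootstrap replicates on one ",
            "side of the estimate); falling back to percentile interval")
    q <- .quantile_norm_interp(t_star, c(alpha, 1 - alpha))
    return(list(lower = q[1], upper = q[2], z0 = NA_real_,
                acceleration = NA_real_, method_used = "percentile"))
  }
  z0 <- stats::qnorm(pb)
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zl <- z0 + stats::qnorm(alpha)
  zu <- z0 + stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + zl / (1 - a * zl))
  a2 <- stats::pnorm(z0 + zu / (1 - a * zu))
  q <- .quantile_norm_interp(t_star, c(a1, a2))
  list(lower = q[1], upper = q[2], z0 = z0, acceleration = a,
       method_used = "bca")
}

#' Bootstrap confidence interval for sensitivity at fixed specificity
#'
#' Case-resampling bootstrap (subjects resampled with replacement,
#' unstratified by default) of [sens_at_spec()], with a BCa interval by
#' default. Replicates that land on a single outcome class are redrawn, up
#' to a capped number of retries per replicate.
#'
#' @param scores Risk scores (e.g. posterior probabilities).
#' @param outcome Binary outcome vector.
#' @param fixed_specificity Specificity at which sensitivity is read off.
#' @param n_iterations Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fully determines all draws.
#' @param method `"bca"` (default) or `"percentile"`.
#' @param stratified Resample within outcome classes instead of over the
#'   full case set.
#' @param conf Confidence level (default 0.95).
#' @param max_retries Redraw cap per replicate for single-class resamples.
#' @return An object of class `"bootstrap_ci"`: list with `statistic`,
#'   `estimate`, `lower`, `upper`, `conf`, `n_iterations`, `method`
#'   (requested), `method_used`, `seed`, `n_redraws`, and the replicate
#'   vector `t_star`.
#' @export
bootstrap_sens_at_spec <- function(scores, outcome, fixed_specificity,
                                   n_iterations = 1000, seed = NULL,
                                   method = c("bca", "percentile"),
                                   stratified = FALSE, conf = 0.95,
                                   max_retries = 100) {
  method <- match.arg(method)
  outcome <- .check_outcome(outcome)
  n <- length(scores)
  if (length(outcome) != n) stop("length mismatch")
  t0 <- sens_at_spec(scores, outcome, fixed_specificity)
  if (is.na(t0)) stop("fixed specificity not attainable on the observed data")
  if (!is.null(seed)) set.seed(seed)

  idx_case <- which(outcome == 1)
  idx_ctrl <- which(outcome == 0)
  n_redraws <- 0
  t_star <- numeric(n_iterations)
  for (b in seq_len(n_iterations)) {
    if (stratified) {
      idx <- c(sample(idx_case, length(idx_case), replace = TRUE),
               sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    } else {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0
      while (length(unique(outcome[idx])) < 2) {
        tries <- tries + 1
        n_redraws <- n_redraws + 1
        if (tries > max_retries)
          stop("exceeded redraw cap: resamples keep landing on one class")
        idx <- sample.int(n, n, replace = TRUE)
      }
    }
    t_star[b] <- sens_at_spec(scores[idx], outcome[idx], fixed_specificity)
  }
  if (n_redraws > 0)
    warning(n_redraws, " single-class resample(s) redrawn")

  jack <- vapply(seq_len(n), function(i)
    sens_at_spec(scores[-i], outcome[-i], fixed_specificity), numeric(1))
  jack <- jack[!is.na(jack)]

  if (method == "bca") {
    ci <- bca_interval(t0, t_star, jack, conf = conf)
  } else {
    alpha <- (1 - conf) / 2
    q <- .quantile_norm_interp(t_star, c(alpha, 1 - alpha))
    ci <- list(lower = q[1], upper = q[2], z0 = NA_real_,
               acceleration = NA_real_, method_used = "percentile")
  }
  structure(list(statistic = "sensitivity_at_fixed_specificity",
                 fixed_specificity = fixed_specificity,
                 estimate = t0, lower = ci$lower, upper = ci$upper,
                 conf = conf, n_iterations = n_iterations,
                 method = method, method_used = ci$method_used,
                 z0 = ci$z0, acceleration = ci$acceleration,
                 seed = seed, n_redraws = n_redraws, t_star = t_star),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, digits = 4, ...) {
  cat("Bootstrap CI (", x$method_used, ", ", x$n_iterations,
      " iterations) for ", x$statistic, "\n", sep = "")
  cat("  estimate =", format(x$estimate, digits = digits),
      sprintf(" %d%% CI [%s, %s]\n", round(100 * x$conf),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits)))
  invisible(x)
}

#' Paired comparison of two evaluated models
#'
#' DeLong test of the difference in AUROC between two models evaluated on
#' the same subjects; delegates to [delong_compare()].
#'
#' @param eval_a,eval_b [evaluate_posteriors()] objects computed on the
#'   same subjects.
#' @return A `"delong_test"` list: `delta_auroc`, `se`, `z`, `p_value`.
#' @export
compare_models <- function(eval_a, eval_b) {
  stopifnot(inherits(eval_a, "lrbayes_eval"), inherits(eval_b, "lrbayes_eval"))
  delong_compare(eval_a$roc, eval_b$roc)
}

#' Write an evaluation summary as JSON
#'
#' Mirrors the usual ROC-statistics table columns: threshold probability,
#' AUROC, sensitivity, specificity, SE, 95% CI, p-value, PPV/NPV and
#' prevalence.
#'
#' @param eval An [evaluate_posteriors()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_evaluation <- function(eval, path) {
  stopifnot(inherits(eval, "lrbayes_eval"))
  x <- list(threshold_probability = eval$threshold, auroc = eval$auroc,
            sensitivity = eval$sensitivity, specificity = eval$specificity,
            auroc_se = eval$auroc_se,
            auroc_ci_lower = eval$auroc_ci[1],
            auroc_ci_upper = eval$auroc_ci[2],
            p_value = eval$p_value, ppv = eval$ppv, npv = eval$npv,
            prevalence = eval$prevalence)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
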