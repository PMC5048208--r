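# Dichotomization and diagnostic performance: confusion counts,
# sensitivity/specificity and the likelihood ratios that drive the
# odds-ratio Bayes chain.

#' Predictor specification
#'
#' Describes how a single predictor enters the model: its assessment group,
#' whether it is binary or continuous, its direction of abnormality, and the
#' dichotomization threshold. Binary predictors always use threshold 1 with
#' the convention that value 1 is a positive call.
#'
#' @param name Predictor name (column name in the cohort data).
#' @param group Assessment group label, e.g. `"historical"`, `"clinical"`,
#'   `"biomarker"`.
#' @param kind `"binary"` or `"continuous"`.
#' @param direction `"high_is_risk"` (positive call when value > threshold)
#'   or `"low_is_risk"` (positive call when value <= threshold).
#' @param threshold Dichotomization cut (ignored for binary predictors,
#'   which are fixed at 1).
#' @return An object of class `"predictor_spec"`.
#' @export
predictor_spec <- function(name, group,
                           kind = c("continuous", "binary"),
                           direction = c("high_is_risk", "low_is_risk"),
                           threshold = NA_real_) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind == "binary") threshold <- 1
  structure(list(name = as.character(name), group = as.character(group),
                 kind = kind, direction = direction,
                 threshold = as.numeric(threshold)),
            class = "predictor_spec")
}

#' Dichotomize a predictor at its threshold
#'
#' Converts raw predictor values to binary calls. Continuous predictors are
#' called positive when `value > threshold` (`high_is_risk`) or
#' `value <= threshold` (`low_is_risk`), matching the printed inequality
#' conventions of ROC cutoff tables. Binary predictors must already be coded
#' 0/1 and are passed through unchanged.
#'
#' @param values Numeric vector (NAs propagate to NA calls).
#' @param spec A [predictor_spec()].
#' @return Integer vector of calls (1 = positive) with NAs preserved.
#' @examples
#' gaf <- predictor_spec("gaf", "clinical", "continuous", "low_is_risk", 60)
#' dichotomize(c(55, 60, 61), gaf)  # 1 1 0
#' @export
dichotomize <- function(values, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (spec$kind == "binary") {
    ok <- is.na(values) | values %in% c(0, 1)
    if (!all(ok))
      stop("binary predictor '", spec$name, "' has values other than 0/1")
    return(as.integer(values))
  }
  if (is.na(spec$threshold))
    stop("continuous predictor '", spec$name, "' has no threshold")
  if (spec$direction == "high_is_risk")
    as.integer(values > spec$threshold)
  else
    as.integer(values <= spec$threshold)
}

#' Diagnostic performance of binary calls
#'
#' Cross-tabulates calls against the outcome and derives sensitivity,
#' specificity, Youden's J and the diagnostic likelihood ratios
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`.
#'
#' When specificity is exactly 1, `LR+` is infinite. The default
#' `zero_cell = "infinite"` reports `Inf` with a flag; `"haldane"` instead
#' adds 0.5 to all four confusion cells before computing rates (and is never
#' the default because it perturbs reproduction of printed tables).
#'
#' @param calls Binary call vector (1 = positive).
#' @param outcome Binary outcome vector (1 = event).
#' @param zero_cell `"infinite"` or `"haldane"`.
#' @return An object of class `"diag_perf"`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `lr_pos`, `lr_neg`, `youden_j`,
#'   `lr_pos_infinite` flag and the `zero_cell` policy used.
#' @seealso [likelihood_ratios()] to derive LRs directly from rates.
#' @export
diag_performance <- function(calls, outcome,
                             zero_cell = c("infinite", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  outcome <- .check_outcome(outcome)
  if (length(calls) != length(outcome)) stop("length mismatch")
  if (anyNA(calls) || anyNA(outcome)) stop("missing values not allowed")
  if (!all(calls %in% c(0, 1))) stop("'calls' must be coded 0/1")

  tp <- sum(calls == 1 & outcome == 1)
  fp <- sum(calls == 1 & outcome == 0)
  tn <- sum(calls == 0 & outcome == 0)
  fn <- sum(calls == 0 & outcome == 1)

  if (zero_cell == "haldane" && (fp == 0 || tn == 0 || tp == 0 || fn == 0)) {
    sens <- (tp + 0.5) / (tp + fn + 1)
    spec <- (tn + 0.5) / (tn + fp + 1)
  } else {
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
  }
  lr <- likelihood_ratios(sens, spec)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
                 lr_pos_infinite = is.infinite(lr$lr_pos),
                 youden_j = sens + spec - 1,
                 zero_cell = zero_cell),
            class = "diag_perf")
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `LR+ = sensitivity / (1 - specificity)`;
#' `LR- = (1 - sensitivity) / specificity`. A test with both LRs equal to 1
#' carries no information; `LR+ > 10` or `LR- < 0.1` is conventionally
#' strong evidence to rule a diagnosis in or out.
#'
#' @param sensitivity,specificity Probabilities (vectorized).
#' @return List with numeric `lr_pos` and `lr_neg` (`lr_pos` is `Inf` at
#'   specificity 1).
#' @examples
#' likelihood_ratios(0.7273, 0.7241)  # LR+ 2.64, LR- 0.38
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  list(lr_pos = ifelse(specificity == 1 & sensitivity > 0, Inf,
                       sensitivity / (1 - specificity)),
       lr_neg = (1 - sensitivity) / specificity)
}

#' @export
print.diag_perf <- function(x, digits = 4, ...) {
  cat("Diagnostic performance (", x$tp + x$fn, " events, ",
      x$tn + x$fp, " non-events)\n", sep = "")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat("  sensitivity =", format(x$sensitivity, digits = digits),
      " specificity =", format(x$specificity, digits = digits),
      " J =", format(x$youden_j, digits = digits), "\n")
  cat("  LR+ =", format(x$lr_pos, digits = digits),
      " LR- =", format(x$lr_neg, digits = digits), "\n")
  invisible(x)
}
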