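# Synthetic cohort generation with known ground truth.
#
# Continuous predictors use equal-SD class-conditional Gaussians whose means
# are solved analytically so that dichotomizing at the stated threshold
# yields the target sensitivity (cases) and specificity (non-cases). Binary
# predictors use class-conditional Bernoulli draws with positivity rates
# target_sensitivity (cases) and 1 - target_specificity (non-cases).

#' Generating specification for one synthetic predictor
#'
#' @param name Predictor name.
#' @param group Assessment group (`"historical"`, `"clinical"`,
#'   `"biomarker"`).
#' @param kind `"continuous"` or `"binary"`.
#' @param direction `"high_is_risk"` or `"low_is_risk"` (for
#'   `low_is_risk`, case-class values concentrate below the threshold).
#' @param target_sensitivity,target_specificity Operating characteristics
#'   that must hold when the generated values are dichotomized at
#'   `threshold`; both strictly inside (0, 1).
#' @param threshold The cut at which the targets hold (binary predictors are
#'   fixed at 1: value 1 is a positive call).
#' @param class_sd Common within-class SD for continuous predictors.
#' @return An object of class `"gen_predictor"`.
#' @details For a continuous predictor the targets must satisfy
#'   `target_sensitivity + target_specificity >= 1`; otherwise the implied
#'   case mean falls on the wrong side of the threshold (the cut would not
#'   be monotone in the stated direction) and the spec is rejected.
#' @export
gen_predictor <- function(name, group,
                          kind = c("continuous", "binary"),
                          direction = c("high_is_risk", "low_is_risk"),
                          target_sensitivity, target_specificity,
                          threshold = NA_real_, class_sd = 1) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  se <- target_sensitivity; sp <- target_specificity
  if (se <= 0 || se >= 1 || sp <= 0 || sp >= 1)
    stop("targets must lie strictly inside (0, 1)")
  if (kind == "continuous") {
    if (is.na(threshold)) stop("continuous predictor '", name,
                               "' needs a threshold")
    if (class_sd <= 0) stop("class_sd must be positive")
    if (se + sp < 1)
      stop("infeasible targets for '", name, "': sensitivity ",
           se, " + specificity ", sp, " < 1 would require a cut that is ",
           "not monotone in the stated direction of abnormality")
  } else {
    threshold <- 1
  }
  structure(list(name = as.character(name), group = as.character(group),
                 kind = kind, direction = direction,
                 target_sensitivity = se, target_specificity = sp,
                 threshold = as.numeric(threshold),
                 class_sd = as.numeric(class_sd)),
            class = "gen_predictor")
}

# Class-conditional means that place the target tail masses at the cut.
.solve_means <- function(p) {
  t <- p$threshold; sd <- p$class_sd
  if (p$direction == "high_is_risk") {
    # P(X > t | case) = sens ; P(X <= t | control) = spec
    list(case = t + sd * stats::qnorm(p$target_sensitivity),
         control = t - sd * stats::qnorm(p$target_specificity))
  } else {
    # P(X <= t | case) = sens ; P(X > t | control) = spec
    list(case = t - sd * stats::qnorm(p$target_sensitivity),
         control = t + sd * stats::qnorm(p$target_specificity))
  }
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prevalence Outcome prevalence, strictly inside (0, 1); outcomes
#'   are independent Bernoulli draws at this rate.
#' @param predictors List of [gen_predictor()] objects (at least one).
#' @param dependence Within-class equicorrelation of the latent Gaussian
#'   copula shared by all predictors, in `[0, 1)`. 0 (the default) gives
#'   conditional independence given the outcome — the assumption the
#'   likelihood-ratio chain relies on.
#' @param missing_rate Per-cell probability of a missing predictor value
#'   (missing completely at random); default 0.
#' @param seed Optional integer seed stored with the spec and used by
#'   [simulate_cohort()] unless overridden.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects, prevalence, predictors,
                        dependence = 0, missing_rate = 0, seed = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  if (length(predictors) < 1) stop("at least one predictor is required")
  if (!all(vapply(predictors, inherits, logical(1), "gen_predictor")))
    stop("'predictors' must be a list of gen_predictor objects")
  nm <- vapply(predictors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate predictor names")
  if (dependence < 0 || dependence >= 1)
    stop("dependence must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  names(predictors) <- nm
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence = prevalence, predictors = predictors,
                 dependence = dependence, missing_rate = missing_rate,
                 seed = seed),
            class = "cohort_spec")
}

#' Default ultra-high-risk cohort specification
#'
#' A pure function returning the reference synthetic-cohort configuration:
#' 40 subjects, 28% one-year transition prevalence, and seven informative
#' predictors in three assessment groups — any history of drug use
#' (historical, binary); PANSS positive, negative and general subscale
#' scores and GAF (clinical, continuous); nervonic acid and total omega-3
#' erythrocyte-membrane fatty acids (biomarker, continuous, low values
#' abnormal). Target sensitivities/specificities and thresholds are the
#' published operating characteristics of these predictors in a UHR cohort;
#' within-class SDs are set at plausible instrument scales (they only fix
#' units — the operating characteristics are scale-invariant).
#'
#' @return A [cohort_spec()] with 7 predictors in 3 groups.
#' @export
uhr_cohort_spec <- function() {
  preds <- list(
    gen_predictor("drug_use", "historical", "binary", "high_is_risk",
                  0.7273, 0.7241),
    gen_predictor("panss_positive", "clinical", "continuous", "high_is_risk",
                  0.8182, 0.6552, threshold = 14, class_sd = 4),
    gen_predictor("panss_negative", "clinical", "continuous", "high_is_risk",
                  0.7273, 0.6897, threshold = 12, class_sd = 4),
    gen_predictor("panss_general", "clinical", "continuous", "high_is_risk",
                  0.7273, 0.7586, threshold = 31, class_sd = 8),
    gen_predictor("gaf", "clinical", "continuous", "low_is_risk",
                  0.9091, 0.5172, threshold = 60, class_sd = 10),
    gen_predictor("nervonic_acid", "biomarker", "continuous", "low_is_risk",
                  0.9091, 0.5357, threshold = 0.2902, class_sd = 0.06),
    gen_predictor("total_omega3", "biomarker", "continuous", "low_is_risk",
                  0.8182, 0.6786, threshold = 5.0727, class_sd = 1.2))
  cohort_spec(n_subjects = 40, prevalence = 0.28, predictors = preds)
}

#' Simulate a cohort from a specification
#'
#' Draws outcomes at the specified prevalence and predictor values from the
#' class-conditional model of each [gen_predictor()]. With
#' `dependence > 0`, all predictors share a latent equicorrelated Gaussian
#' factor within each outcome class (a Gaussian copula), oriented so that
#' abnormality is positively associated across predictors; marginal
#' operating characteristics are unaffected.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (overrides `spec$seed`); the same seed
#'   reproduces the cohort bit-for-bit.
#' @return A `data.frame` of class `c("cohort", "data.frame")` with columns
#'   `subject_id`, `transition` (0/1) and one column per predictor; the
#'   generating spec is attached as attribute `"spec"`.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  rho <- spec$dependence
  outcome <- stats::rbinom(n, 1, spec$prevalence)

  w <- stats::rnorm(n)  # shared latent factor (used when rho > 0)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    transition = outcome)
  for (p in spec$predictors) {
    e <- stats::rnorm(n)
    z <- sqrt(rho) * w + sqrt(1 - rho) * e
    if (p$kind == "continuous") {
      mu <- .solve_means(p)
      mu_i <- ifelse(outcome == 1, mu$case, mu$control)
      sgn <- if (p$direction == "high_is_risk") 1 else -1
      val <- mu_i + sgn * p$class_sd * z
    } else {
      rate <- ifelse(outcome == 1, p$target_sensitivity,
                     1 - p$target_specificity)
      val <- as.numeric(z > stats::qnorm(1 - rate))
    }
    out[[p$name]] <- val
  }
  if (spec$missing_rate > 0) {
    for (p in spec$predictors) {
      drop <- stats::runif(n) < spec$missing_rate
      out[[p$name]][drop] <- NA
    }
  }
  attr(out, "spec") <- spec
  class(out) <- c("cohort", "data.frame")
  out
}

#' Read/write cohorts as CSV
#'
#' Cohort files are plain CSV with a header row, one subject per row, the
#' outcome in a column named `transition` coded 0/1, and missing cells
#' empty.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns the path invisibly; `read_cohort` returns
#'   a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), "transition" %in% names(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (!"transition" %in% names(x))
    stop("cohort file has no 'transition' column")
  class(x) <- c("cohort", "data.frame")
  x
}

#' Read/write a cohort specification as a YAML config
#'
#' Flat keys (`n_subjects`, `prevalence`, `dependence`, `missing_rate`,
#' `seed`) plus a `predictors` list; round-trips losslessly.
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec` returns the path invisibly;
#'   `read_cohort_spec` returns a [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$predictors <- lapply(unname(x$predictors), unclass)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  preds <- lapply(x$predictors, function(p)
    gen_predictor(p$name, p$group, p$kind, p$direction,
                  p$target_sensitivity, p$target_specificity,
                  threshold = p$threshold %||% NA_real_,
                  class_sd = p$class_sd %||% 1))
  cohort_spec(x$n_subjects, x$prevalence, preds,
              dependence = x$dependence %||% 0,
              missing_rate = x$missing_rate %||% 0,
              seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
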