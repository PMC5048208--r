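# Staged likelihood-ratio model: the odds-ratio form of Bayes' rule.
#
# Pretest odds are multiplied, assessment group by assessment group, by the
# positive or negative likelihood ratio of each dichotomized predictor
# (LR+ for a positive call, LR- for a negative call), then transformed back
# to a post-test probability. Validity of the chaining rests on conditional
# independence of the predictors given the outcome (naive Bayes).

#' Fit a staged likelihood-ratio risk model
#'
#' Implements the three-stage construction: (1) screen each candidate
#' predictor by testing its AUROC against 0.5 (DeLong) and retain those with
#' `p < alpha`; (2) choose a Youden-optimal threshold for each retained
#' continuous predictor (unless a fixed threshold is supplied); (3) compute
#' sensitivity, specificity and likelihood ratios at those thresholds and
#' assemble the retained predictors into ordered assessment groups for
#' sequential Bayes updating.
#'
#' @param formula Model formula, `outcome ~ predictor1 + predictor2 + ...`;
#'   the outcome must be coded 0/1 (1 = event).
#' @param data Data frame holding the outcome and predictor columns (e.g. a
#'   [simulate_cohort()] result). Missing predictor values are allowed:
#'   screening and threshold selection use the complete cases of each
#'   predictor; per-case posteriors exclude subjects missing any retained
#'   predictor (see `missing` in [predict.lrbayes()]).
#' @param groups Named list giving the assessment-stage order, e.g.
#'   `list(historical = "drug_use", clinical = c("panss_positive", "gaf"))`.
#'   Defaults to a single stage containing all predictors. The final
#'   posterior does not depend on the ordering (products commute); only the
#'   stepwise trajectories do.
#' @param directions Named character vector mapping predictor names to
#'   `"high_is_risk"` or `"low_is_risk"`; unnamed predictors default to
#'   `"high_is_risk"`.
#' @param thresholds Optional named numeric vector of fixed dichotomization
#'   cuts; predictors not named here (and not binary) get Youden-optimal
#'   cuts. Binary (0/1) predictors are detected automatically and fixed at
#'   threshold 1.
#' @param alpha Retention level for the AUROC-vs-chance screen (default
#'   0.05).
#' @param pretest Pretest probability of the outcome; defaults to the
#'   observed outcome rate in `data`. Override it to transport the model to
#'   a population with a different base rate.
#' @param zero_cell Zero-cell policy passed to [diag_performance()].
#' @return An object of class `"lrbayes"`; see Details.
#' @details The returned object contains `performance` (per-predictor data
#'   frame with AUROC, p-value, threshold, confusion counts, sensitivity,
#'   specificity, LR+, LR-, Youden J), `dropped` (screened-out candidates
#'   with their p-values), `groups`, `specs` ([predictor_spec()] list),
#'   `pretest`, fitted `posteriors` and `trajectories` for the analyzed
#'   subjects, and `excluded` (subjects dropped for missing data).
#'   Likelihood ratios are carried at full precision; rounding happens only
#'   in printed output.
#' @seealso [predict.lrbayes()], [evaluate_posteriors()], [uhr_model()]
#' @examples
#' cohort <- simulate_cohort(uhr_cohort_spec(), seed = 7)
#' fit <- lrbayes(transition ~ drug_use + panss_positive + gaf,
#'                data = cohort,
#'                groups = list(historical = "drug_use",
#'                              clinical = c("panss_positive", "gaf")),
#'                directions = c(gaf = "low_is_risk"))
#' fit
#' @export
lrbayes <- function(formula, data, groups = NULL, directions = NULL,
                    thresholds = NULL, alpha = 0.05, pretest = NULL,
                    zero_cell = c("infinite", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  outcome_name <- all.vars(formula[[2]])
  vars <- attr(stats::terms(formula, data = data), "term.labels")
  y <- data[[outcome_name]]
  if (anyNA(y)) stop("missing outcome values are not supported")
  y <- .check_outcome(y)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  # alpha = 1 disables the screen (every candidate with p < 1 is retained)
  if (is.null(pretest)) pretest <- mean(y)
  if (pretest <= 0 || pretest >= 1)
    stop("pretest probability must lie strictly inside (0, 1)")

  # stage structure defaults to a single group over all candidates
  if (is.null(groups)) groups <- list(all = vars)
  gv <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(gv)) stop("a predictor appears in more than one group")
  if (!all(gv %in% vars))
    stop("group members not in formula: ",
         paste(setdiff(gv, vars), collapse = ", "))
  if (!all(vars %in% gv))
    stop("predictors missing from 'groups': ",
         paste(setdiff(vars, gv), collapse = ", "))

  dir_of <- function(v) {
    d <- if (!is.null(directions) && v %in% names(directions))
      directions[[v]] else "high_is_risk"
    match.arg(d, c("high_is_risk", "low_is_risk"))
  }
  grp_of <- function(v) names(groups)[vapply(groups, function(g) v %in% g,
                                             logical(1))][1]

  screen <- vector("list", length(vars))
  names(screen) <- vars
  for (v in vars) {
    x <- data[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 4) stop("predictor '", v, "' has fewer than 4 observed values")
    is_binary <- all(x[ok] %in% c(0, 1))
    roc <- roc_curve(x[ok], y[ok], direction = dir_of(v))
    screen[[v]] <- list(roc = roc, binary = is_binary, n = sum(ok))
  }
  pvals <- vapply(screen, function(s) s$roc$p_vs_chance, numeric(1))
  keep <- names(pvals)[pvals < alpha]
  if (length(keep) == 0)
    stop("no predictor passed the AUROC screen at alpha = ", alpha,
         "; candidate p-values: ",
         paste(sprintf("%s=%.4g", names(pvals), pvals), collapse = ", "))

  specs <- list()
  perf_rows <- list()
  for (v in keep) {
    s <- screen[[v]]
    kind <- if (s$binary) "binary" else "continuous"
    thr <- if (s$binary) 1
           else if (!is.null(thresholds) && v %in% names(thresholds))
             thresholds[[v]]
           else youden_optimal(s$roc)$threshold
    sp <- predictor_spec(v, grp_of(v), kind, dir_of(v), thr)
    ok <- !is.na(data[[v]])
    calls <- dichotomize(data[[v]][ok], sp)
    perf <- diag_performance(calls, y[ok], zero_cell = zero_cell)
    specs[[v]] <- sp
    perf_rows[[v]] <- data.frame(
      name = v, group = sp$group, kind = kind, direction = sp$direction,
      n = s$n, threshold = thr, auroc = s$roc$auroc,
      auroc_se = s$roc$auroc_se, p_value = s$roc$p_vs_chance,
      tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn,
      sensitivity = perf$sensitivity, specificity = perf$specificity,
      lr_pos = perf$lr_pos, lr_neg = perf$lr_neg,
      youden_j = perf$youden_j, stringsAsFactors = FALSE)
  }
  performance <- do.call(rbind, perf_rows)
  rownames(performance) <- NULL
  dropped <- data.frame(
    name = setdiff(vars, keep),
    auroc = vapply(setdiff(vars, keep),
                   function(v) screen[[v]]$roc$auroc, numeric(1)),
    p_value = pvals[setdiff(vars, keep)], row.names = NULL,
    stringsAsFactors = FALSE)
  groups_kept <- lapply(groups, function(g) g[g %in% keep])
  groups_kept <- groups_kept[vapply(groups_kept, length, integer(1)) > 0]

  obj <- structure(list(performance = performance, dropped = dropped,
                        groups = groups_kept, specs = specs,
                        pretest = pretest, alpha = alpha,
                        zero_cell = zero_cell,
                        outcome_name = outcome_name, call = cl),
                   class = "lrbayes")
  pr <- predict(obj, newdata = data, type = "trajectory")
  obj$trajectories <- pr
  obj$posteriors <- .final_from_trajectories(pr)
  obj$outcome <- y
  obj$excluded <- unique(pr$subject_id[pr$excluded])
  obj
}

#' Construct a likelihood-ratio model from known operating characteristics
#'
#' Builds an `"lrbayes"` model directly from per-predictor sensitivity and
#' specificity (e.g. published values), bypassing fitting. Likelihood
#' ratios are derived at full precision via [likelihood_ratios()].
#'
#' @param predictors Data frame with columns `name`, `group`, `kind`,
#'   `direction`, `threshold`, `sensitivity`, `specificity` (one row per
#'   predictor; group order of first appearance defines the stage order).
#' @param pretest Pretest probability of the outcome.
#' @return An object of class `"lrbayes"` (without fitted data components).
#' @export
lrbayes_model <- function(predictors, pretest) {
  req <- c("name", "group", "kind", "direction", "threshold",
           "sensitivity", "specificity")
  if (!all(req %in% names(predictors)))
    stop("'predictors' needs columns: ", paste(req, collapse = ", "))
  if (pretest <= 0 || pretest >= 1)
    stop("pretest probability must lie strictly inside (0, 1)")
  lr <- likelihood_ratios(predictors$sensitivity, predictors$specificity)
  performance <- cbind(predictors,
                       data.frame(lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
                                  youden_j = predictors$sensitivity +
                                             predictors$specificity - 1))
  specs <- lapply(seq_len(nrow(predictors)), function(i)
    predictor_spec(predictors$name[i], predictors$group[i],
                   predictors$kind[i], predictors$direction[i],
                   predictors$threshold[i]))
  names(specs) <- predictors$name
  groups <- split(predictors$name,
                  factor(predictors$group, levels = unique(predictors$group)))
  structure(list(performance = performance,
                 dropped = data.frame(name = character(0),
                                      auroc = numeric(0),
                                      p_value = numeric(0)),
                 groups = as.list(groups), specs = specs,
                 pretest = pretest, alpha = NA_real_,
                 zero_cell = "infinite",
                 outcome_name = "transition", call = match.call()),
            class = "lrbayes")
}

#' Reference ultra-high-risk transition model
#'
#' The staged model with the seven published predictors at their reported
#' sensitivities/specificities ([uhr_cohort_spec()]), full-precision
#' likelihood ratios, stage order historical -> clinical -> biomarker, and
#' pretest probability 0.28.
#'
#' @return An `"lrbayes"` model object.
#' @export
uhr_model <- function() {
  sp <- uhr_cohort_spec()
  tab <- do.call(rbind, lapply(sp$predictors, function(p)
    data.frame(name = p$name, group = p$group, kind = p$kind,
               direction = p$direction, threshold = p$threshold,
               sensitivity = p$target_sensitivity,
               specificity = p$target_specificity,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  lrbayes_model(tab, pretest = sp$prevalence)
}

# Stage-by-stage odds updating for a matrix of calls (subjects x model
# predictors; entries 0/1/NA). Returns a list with the probability matrix
# (stages x subjects) and the exclusion mask.
.chain_posteriors <- function(calls, model, missing = c("exclude", "skip")) {
  missing <- match.arg(missing)
  nm <- model$performance$name
  calls <- calls[, nm, drop = FALSE]
  n <- nrow(calls)
  lrp <- model$performance$lr_pos
  lrn <- model$performance$lr_neg
  names(lrp) <- names(lrn) <- nm

  excluded <- if (missing == "exclude") apply(is.na(calls), 1, any)
              else rep(FALSE, n)
  odds <- rep(probability_to_odds(model$pretest), n)
  stages <- names(model$groups)
  prob <- matrix(NA_real_, nrow = length(stages) + 1, ncol = n,
                 dimnames = list(c("pretest", stages), NULL))
  prob["pretest", ] <- model$pretest
  for (g in stages) {
    for (v in model$groups[[g]]) {
      cv <- calls[, v]
      upd <- ifelse(is.na(cv), 1, ifelse(cv == 1, lrp[v], lrn[v]))
      odds <- odds * upd
    }
    prob[g, ] <- odds_to_probability(odds)
  }
  prob[, excluded] <- NA_real_
  list(prob = prob, excluded = excluded, stages = c("pretest", stages))
}

.final_from_trajectories <- function(tr) {
  last <- tr[tr$stage == tr$stage[nrow(tr)], ]
  stats::setNames(last$probability, last$subject_id)
}

#' Posterior trajectory for a single case
#'
#' Applies the odds-ratio Bayes chain to one subject's dichotomized calls:
#' starting from the pretest odds, each assessment group multiplies in LR+
#' for every positive call and LR- for every negative call, and the running
#' odds are converted back to a probability after each group.
#'
#' @param calls Named vector or list of calls (0, 1 or NA) covering the
#'   model's predictors.
#' @param model An `"lrbayes"` object.
#' @param missing `"exclude"` (default; any missing required call marks the
#'   case excluded, mirroring whole-case exclusion) or `"skip"` (a missing
#'   call contributes no update).
#' @return A data frame of class `"case_trajectory"` with columns `stage`
#'   and `probability`, beginning with the pretest row; attributes
#'   `final_probability` and `excluded`.
#' @examples
#' m <- uhr_model()
#' tr <- case_posterior(c(drug_use = 1, panss_positive = 1,
#'                        panss_negative = 0, panss_general = 1, gaf = 1,
#'                        nervonic_acid = 1, total_omega3 = 0), m)
#' tr
#' @export
case_posterior <- function(calls, model, missing = c("exclude", "skip")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "lrbayes"))
  calls <- unlist(calls)
  nm <- model$performance$name
  unknown <- setdiff(names(calls), nm)
  if (length(unknown) > 0)
    stop("unknown predictor name(s): ", paste(unknown, collapse = ", "))
  full <- stats::setNames(rep(NA_real_, length(nm)), nm)
  full[names(calls)] <- as.numeric(calls)
  ch <- .chain_posteriors(matrix(full, nrow = 1,
                                 dimnames = list(NULL, nm)),
                          model, missing = missing)
  out <- data.frame(stage = ch$stages, probability = unname(ch$prob[, 1]))
  rownames(out) <- NULL
  attr(out, "final_probability") <- unname(ch$prob[nrow(ch$prob), 1])
  attr(out, "excluded") <- ch$excluded[1]
  class(out) <- c("case_trajectory", "data.frame")
  out
}

#' Posterior probabilities from pre-dichotomized calls
#'
#' Runs the odds-ratio Bayes chain directly on a matrix (or data frame) of
#' 0/1 calls, one row per subject. Use this instead of
#' [predict.lrbayes()] when the data already hold binary calls for
#' continuous predictors (e.g. output of [simulate.lrbayes()]), since
#' `predict()` would re-dichotomize raw values at the model thresholds.
#'
#' @param calls Matrix or data frame of calls (0, 1 or NA) with the model's
#'   predictor names as columns.
#' @param model An `"lrbayes"` object.
#' @param missing Missing-call policy, see [case_posterior()].
#' @return Numeric vector of final post-test probabilities (NA for excluded
#'   subjects).
#' @export
posterior_from_calls <- function(calls, model,
                                 missing = c("exclude", "skip")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "lrbayes"))
  nm <- model$performance$name
  calls <- as.matrix(as.data.frame(calls)[, nm, drop = FALSE])
  if (!all(calls %in% c(0, 1, NA)))
    stop("'calls' must contain only 0, 1 or NA")
  ch <- .chain_posteriors(calls, model, missing = missing)
  unname(ch$prob[nrow(ch$prob), ])
}

#' Predict post-test probabilities for new subjects
#'
#' Dichotomizes each model predictor at its fitted threshold and runs the
#' odds-ratio Bayes chain for every row of `newdata`.
#'
#' @param object An `"lrbayes"` model.
#' @param newdata Data frame with the model's predictor columns (raw
#'   values; dichotomization is applied internally).
#' @param type `"response"` (final post-test probability), `"odds"` (final
#'   post-test odds), `"calls"` (the dichotomized call matrix), or
#'   `"trajectory"` (long data frame: `subject_id`, `stage`,
#'   `probability`, `excluded`).
#' @param missing Missing-call policy, see [case_posterior()].
#' @param ... Unused.
#' @return See `type`. Excluded subjects yield `NA` probabilities.
#' @export
predict.lrbayes <- function(object, newdata, type = c("response", "odds",
                                                      "calls", "trajectory"),
                            missing = c("exclude", "skip"), ...) {
  type <- match.arg(type)
  missing <- match.arg(missing)
  nm <- object$performance$name
  absent <- setdiff(nm, names(newdata))
  if (length(absent) > 0)
    stop("newdata lacks predictor column(s): ", paste(absent, collapse = ", "))
  calls <- sapply(nm, function(v) dichotomize(newdata[[v]], object$specs[[v]]))
  calls <- matrix(as.numeric(calls), ncol = length(nm),
                  dimnames = list(NULL, nm))
  if (type == "calls") return(calls)
  ch <- .chain_posteriors(calls, object, missing = missing)
  final <- ch$prob[nrow(ch$prob), ]
  ids <- if ("subject_id" %in% names(newdata)) newdata$subject_id
         else sprintf("S%03d", seq_len(nrow(newdata)))
  if (type == "response") return(stats::setNames(final, ids))
  if (type == "odds")
    return(stats::setNames(ifelse(final == 1, Inf, final / (1 - final)), ids))
  out <- data.frame(
    subject_id = rep(ids, each = length(ch$stages)),
    stage = factor(rep(ch$stages, times = length(ids)), levels = ch$stages),
    probability = as.vector(ch$prob),
    excluded = rep(ch$excluded, each = length(ch$stages)))
  out
}

#' @export
fitted.lrbayes <- function(object, ...) object$posteriors

#' @export
residuals.lrbayes <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  if (is.null(object$posteriors))
    stop("model carries no fitted data (built from published rates?)")
  p <- object$posteriors
  r <- object$outcome - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' @export
coef.lrbayes <- function(object, ...) {
  m <- as.matrix(object$performance[, c("lr_pos", "lr_neg")])
  rownames(m) <- object$performance$name
  m
}

#' Simulate call patterns and outcomes from a fitted model
#'
#' Draws new subjects from the model's own generative view: outcome from
#' the pretest probability, then each predictor's call from its
#' class-conditional positivity rate (sensitivity in cases,
#' 1 - specificity in non-cases), independently given the outcome.
#'
#' @param object An `"lrbayes"` model.
#' @param nsim Number of simulated cohorts.
#' @param seed Optional integer seed.
#' @param n Subjects per cohort (default 40).
#' @param ... Unused.
#' @return A list of `nsim` data frames with column `transition` and one
#'   0/1 call column per model predictor.
#' @export
simulate.lrbayes <- function(object, nsim = 1, seed = NULL, n = 40, ...) {
  if (!is.null(seed)) set.seed(seed)
  perf <- object$performance
  lapply(seq_len(nsim), function(i) {
    y <- stats::rbinom(n, 1, object$pretest)
    out <- data.frame(transition = y)
    for (j in seq_len(nrow(perf))) {
      rate <- ifelse(y == 1, perf$sensitivity[j], 1 - perf$specificity[j])
      out[[perf$name[j]]] <- stats::rbinom(n, 1, rate)
    }
    out
  })
}

#' @export
print.lrbayes <- function(x, digits = 3, ...) {
  cat("Staged likelihood-ratio model (odds-ratio form of Bayes' rule)\n")
  cat("Pretest probability:", format(x$pretest, digits = digits),
      " (pretest odds ", format(probability_to_odds(x$pretest),
                                digits = digits), ")\n", sep = "")
  cat("Assessment stages: ",
      paste(sprintf("%s [%s]", names(x$groups),
                    vapply(x$groups, paste, character(1), collapse = ", ")),
            collapse = " -> "), "\n")
  tab <- x$performance[, c("name", "group", "threshold", "sensitivity",
                           "specificity", "lr_pos", "lr_neg")]
  tab[-(1:2)] <- lapply(tab[-(1:2)], round, digits = digits)
  print(tab, row.names = FALSE)
  if (nrow(x$dropped) > 0)
    cat("Dropped by AUROC screen:", paste(x$dropped$name, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.lrbayes <- function(object, ...) {
  out <- list(model = object,
              n_predictors = nrow(object$performance),
              n_excluded = length(object$excluded))
  if (!is.null(object$posteriors)) {
    ok <- !is.na(object$posteriors)
    if (sum(object$outcome[ok] == 1) > 0 && sum(object$outcome[ok] == 0) > 0) {
      ev <- evaluate_posteriors(object$posteriors[ok], object$outcome[ok])
      out$evaluation <- ev
    }
  }
  class(out) <- "summary.lrbayes"
  out
}

#' @export
print.summary.lrbayes <- function(x, digits = 3, ...) {
  print(x$model, digits = digits)
  if (!is.null(x$evaluation)) {
    cat("\nIn-sample evaluation of combined posteriors:\n")
    print(x$evaluation, digits = digits)
  }
  if (x$n_excluded > 0)
    cat("Subjects excluded for missing data:", x$n_excluded, "\n")
  invisible(x)
}

#' Plot stepwise probability trajectories
#'
#' One panel per outcome class showing each case's probability of the event
#' after successive assessment stages, with an optional model-threshold
#' line — the standard way to visualise where each new mode of assessment
#' moves individual cases.
#'
#' @param x An `"lrbayes"` model fitted to data.
#' @param threshold Optional probability threshold drawn as a horizontal
#'   dashed line.
#' @param ... Passed to [plot_trajectories()].
#' @return Invisibly, the trajectory data frame.
#' @export
plot.lrbayes <- function(x, threshold = NULL, ...) {
  if (is.null(x$trajectories))
    stop("model carries no fitted trajectories")
  plot_trajectories(x$trajectories, outcome = x$outcome,
                    threshold = threshold, ...)
}

#' Read/write a fitted model as a YAML config
#'
#' Serializes predictor names, groups, directions, thresholds, operating
#' characteristics, likelihood ratios and the pretest probability in a
#' human-readable form that round-trips losslessly into a predictive model.
#'
#' @param model An `"lrbayes"` object.
#' @param path File path.
#' @return `write_lrbayes` returns the path invisibly; `read_lrbayes`
#'   returns an `"lrbayes"` model (without fitted data components).
#' @export
write_lrbayes <- function(model, path) {
  stopifnot(inherits(model, "lrbayes"))
  perf <- model$performance
  x <- list(pretest_probability = model$pretest,
            groups = lapply(model$groups, as.list),
            predictors = lapply(seq_len(nrow(perf)), function(i)
              list(name = perf$name[i], group = perf$group[i],
                   kind = perf$kind[i], direction = perf$direction[i],
                   threshold = perf$threshold[i],
                   sensitivity = perf$sensitivity[i],
                   specificity = perf$specificity[i])))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_lrbayes
#' @export
read_lrbayes <- function(path) {
  x <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(x$predictors, function(p)
    data.frame(name = p$name, group = p$group, kind = p$kind,
               direction = p$direction, threshold = p$threshold,
               sensitivity = p$sensitivity, specificity = p$specificity,
               stringsAsFactors = FALSE)))
  m <- lrbayes_model(tab, pretest = x$pretest_probability)
  m$groups <- lapply(x$groups, unlist)
  m
}

#' Export trajectories as long-format CSV
#'
#' @param trajectories Trajectory data frame from
#'   `predict(..., type = "trajectory")` or `model$trajectories`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories[, c("subject_id", "stage", "probability")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
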