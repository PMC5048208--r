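# End-to-end driver: cohort in, screened predictors, likelihood-ratio
# tables, per-group and combined-model evaluations, trajectories and plots
# out. All randomness flows through one seed.

#' Run the full staged-model pipeline
#'
#' Executes predictor screening, dichotomization, likelihood-ratio
#' estimation, sequential Bayes combination and model evaluation for every
#' non-empty combination of assessment groups, writing all artifacts to an
#' output directory.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{cohort}{Path to a cohort CSV ([read_cohort()]) — or}
#'     \item{synthetic}{A [cohort_spec()] object or path to a spec YAML;
#'       exactly one of `cohort`/`synthetic` must be given.}
#'     \item{groups}{Named list of assessment groups in stage order.}
#'     \item{directions}{Named list/vector of predictor directions.}
#'     \item{alpha}{AUROC-screen level (default 0.05).}
#'     \item{pretest}{Optional pretest-probability override.}
#'     \item{bootstrap}{Optional list: `n_iterations` (default 1000).}
#'     \item{outdir}{Output directory (created if needed).}
#'     \item{seed}{Integer seed for cohort simulation and bootstrap.}
#'   }
#' @return Invisibly, a list with the fitted model, the per-combination
#'   evaluations, the exclusion list and the paths of written artifacts:
#'   `roc_screen.csv`, `likelihood_ratios.csv`, `model_evaluation.csv`
#'   (+ one JSON per group combination), `trajectories.csv`,
#'   `trajectories.pdf`, `model.yaml`, `bootstrap.json`, `run_log.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_cohort <- !is.null(config$cohort)
  has_synth <- !is.null(config$synthetic)
  if (has_cohort == has_synth)
    stop("config must name exactly one cohort source ('cohort' or 'synthetic')")
  if (is.null(config$outdir)) stop("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05

  if (has_cohort) {
    cohort <- read_cohort(config$cohort)
  } else {
    spec <- config$synthetic
    if (is.character(spec)) spec <- read_cohort_spec(spec)
    cohort <- simulate_cohort(spec, seed = seed)
  }
  groups <- config$groups
  if (is.null(groups)) {
    if (!has_cohort) {
      spec <- attr(cohort, "spec")
      gl <- vapply(spec$predictors, `[[`, character(1), "group")
      groups <- split(names(spec$predictors), factor(gl, levels = unique(gl)))
    } else stop("config$groups is required for CSV cohorts")
  }
  directions <- config$directions
  if (is.null(directions) && !has_cohort) {
    spec <- attr(cohort, "spec")
    directions <- vapply(spec$predictors, `[[`, character(1), "direction")
  }
  vars <- unlist(groups, use.names = FALSE)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))

  fml <- stats::as.formula(paste("transition ~", paste(vars, collapse = " + ")))
  fit <- lrbayes(fml, cohort, groups = groups,
                 directions = unlist(directions), alpha = alpha,
                 pretest = config$pretest)

  paths <- list()

  # Table-1-style ROC screen over every candidate (retained or not)
  screen <- do.call(rbind, lapply(vars, function(v) {
    ok <- !is.na(cohort[[v]])
    d <- if (!is.null(directions) && v %in% names(unlist(directions)))
      unlist(directions)[[v]] else "high_is_risk"
    roc <- roc_curve(cohort[[v]][ok], cohort$transition[ok], direction = d)
    yj <- youden_optimal(roc)
    grp <- names(groups)[vapply(groups, function(g) v %in% g, logical(1))][1]
    data.frame(group = grp, variable = v, n = sum(ok),
               youden_index = yj$j, threshold = yj$threshold,
               auroc = roc$auroc, p_value = roc$p_vs_chance,
               retained = roc$p_vs_chance < alpha)
  }))
  paths$roc_screen <- file.path(outdir, "roc_screen.csv")
  utils::write.csv(screen, paths$roc_screen, row.names = FALSE)

  # Table-2-style LR export: full precision plus rounded display columns
  perf <- fit$performance
  lr_tab <- data.frame(
    group = perf$group, variable = perf$name,
    sensitivity = perf$sensitivity, specificity = perf$specificity,
    lr_pos = perf$lr_pos, lr_neg = perf$lr_neg,
    display_sensitivity_pct = round(100 * perf$sensitivity, 2),
    display_specificity_pct = round(100 * perf$specificity, 2),
    display_lr_pos = round(perf$lr_pos, 2),
    display_lr_neg = round(perf$lr_neg, 2))
  paths$likelihood_ratios <- file.path(outdir, "likelihood_ratios.csv")
  utils::write.csv(lr_tab, paths$likelihood_ratios, row.names = FALSE)

  # every non-empty combination of assessment groups
  gnames <- names(fit$groups)
  combos <- unlist(lapply(seq_along(gnames), function(k)
    utils::combn(gnames, k, simplify = FALSE)), recursive = FALSE)
  evals <- list()
  eval_rows <- list()
  for (cmb in combos) {
    label <- paste(cmb, collapse = "+")
    sub <- perf[perf$group %in% cmb,
                c("name", "group", "kind", "direction", "threshold",
                  "sensitivity", "specificity")]
    m <- lrbayes_model(sub, pretest = fit$pretest)
    m$groups <- fit$groups[cmb]
    post <- predict(m, cohort, type = "response")
    ok <- !is.na(post)
    ev <- evaluate_posteriors(post[ok], cohort$transition[ok],
                              prevalence = fit$pretest)
    evals[[label]] <- ev
    jpath <- file.path(outdir, paste0("evaluation_",
                                      gsub("[^A-Za-z0-9]+", "_", label),
                                      ".json"))
    write_evaluation(ev, jpath)
    eval_rows[[label]] <- data.frame(
      model = label, threshold_probability = ev$threshold,
      auroc = ev$auroc, sensitivity = ev$sensitivity,
      specificity = ev$specificity, se = ev$auroc_se,
      ci_lower = ev$auroc_ci[1], ci_upper = ev$auroc_ci[2],
      p_value = ev$p_value, ppv = ev$ppv, npv = ev$npv,
      n = sum(ok))
  }
  paths$model_evaluation <- file.path(outdir, "model_evaluation.csv")
  utils::write.csv(do.call(rbind, eval_rows), paths$model_evaluation,
                   row.names = FALSE)

  # trajectories (full model) + probability plots split by outcome
  traj <- fit$trajectories
  paths$trajectories <- file.path(outdir, "trajectories.csv")
  write_trajectories(traj, paths$trajectories)
  full_label <- paste(gnames, collapse = "+")
  paths$plot <- file.path(outdir, "trajectories.pdf")
  grDevices::pdf(paths$plot, width = 10, height = 5)
  plot_trajectories(traj, outcome = fit$outcome,
                    threshold = evals[[full_label]]$threshold)
  grDevices::dev.off()

  paths$model <- file.path(outdir, "model.yaml")
  write_lrbayes(fit, paths$model)

  # internal validation: sensitivity at the full model's Youden specificity
  nb <- (config$bootstrap %||% list())$n_iterations %||% 1000
  full_ev <- evals[[full_label]]
  post_full <- fit$posteriors
  okf <- !is.na(post_full)
  bs <- bootstrap_sens_at_spec(post_full[okf], fit$outcome[okf],
                               fixed_specificity = full_ev$specificity,
                               n_iterations = nb, seed = seed)
  paths$bootstrap <- file.path(outdir, "bootstrap.json")
  jsonlite::write_json(
    list(statistic = bs$statistic,
         fixed_specificity = bs$fixed_specificity,
         estimate = bs$estimate, lower = bs$lower, upper = bs$upper,
         conf = bs$conf, n_iterations = bs$n_iterations,
         method_used = bs$method_used, seed = seed),
    paths$bootstrap, auto_unbox = TRUE, digits = NA)

  excluded <- fit$excluded
  paths$log <- file.path(outdir, "run_log.txt")
  writeLines(c(
    paste0("lrbayes pipeline run"),
    paste0("package version: ",
           as.character(utils::packageVersion("lrbayes"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", seed),
    paste0("alpha: ", alpha),
    paste0("subjects: ", nrow(cohort)),
    paste0("pretest probability: ", fit$pretest),
    paste0("retained predictors: ",
           paste(fit$performance$name, collapse = ", ")),
    paste0("dropped predictors: ",
           if (nrow(fit$dropped)) paste(fit$dropped$name, collapse = ", ")
           else "none"),
    paste0("excluded subjects (missing data): ",
           if (length(excluded)) paste(excluded, collapse = ", ")
           else "none")),
    paths$log)

  invisible(list(fit = fit, evaluations = evals, excluded = excluded,
                 cohort = cohort, paths = paths))
}

#' Plot stepwise probability trajectories by outcome class
#'
#' Draws one panel per outcome class (event / no event); each line follows
#' one case's probability of the event across assessment stages. Excluded
#' cases (missing data) are omitted. An optional model threshold is shown
#' as a horizontal dashed line.
#'
#' @param trajectories Long trajectory data frame (`subject_id`, `stage`,
#'   `probability`, optionally `excluded`).
#' @param outcome Binary outcome vector, one entry per subject in the order
#'   subjects first appear in `trajectories`.
#' @param threshold Optional probability threshold to draw.
#' @param main Title prefix.
#' @return Invisibly, the trajectory data frame used.
#' @export
plot_trajectories <- function(trajectories, outcome, threshold = NULL,
                              main = "Probability of transition") {
  if (nrow(trajectories) == 0) stop("empty trajectory set")
  ids <- unique(trajectories$subject_id)
  names(outcome) <- ids
  if ("excluded" %in% names(trajectories)) {
    drop <- unique(trajectories$subject_id[trajectories$excluded])
    trajectories <- trajectories[!trajectories$subject_id %in% drop, ]
    ids <- setdiff(ids, drop)
  }
  stages <- unique(as.character(trajectories$stage))
  prob <- matrix(trajectories$probability, nrow = length(stages))
  colnames(prob) <- ids
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (cls in c(0, 1)) {
    sel <- ids[outcome[ids] == cls]
    ttl <- paste0(main, " (",
                  if (cls == 1) "transitioned" else "not transitioned", ")")
    graphics::matplot(seq_along(stages),
                      prob[, sel, drop = FALSE], type = "b", pch = 16,
                      lty = 1, col = grDevices::adjustcolor(
                        if (cls == 1) "firebrick" else "steelblue", 0.6),
                      ylim = c(0, 1), xaxt = "n", xlab = "Assessment stage",
                      ylab = "Probability", main = ttl)
    graphics::axis(1, at = seq_along(stages), labels = stages)
    if (!is.null(threshold))
      graphics::abline(h = threshold, lty = 2, col = "grey30")
  }
  invisible(trajectories)
}
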