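test_that("chained posterior equals direct naive-Bayes computation", {
  m <- uhr_model()
  perf <- m$performance
  nm <- perf$name
  # every one of the 2^7 call patterns
  grid <- expand.grid(rep(list(0:1), 7))
  names(grid) <- nm
  for (i in seq_len(nrow(grid))) {
    calls <- as.numeric(grid[i, ])
    names(calls) <- nm
    tr <- case_posterior(calls, m)
    want <- brute_posterior(calls, perf$sensitivity, perf$specificity, 0.28)
    expect_equal(attr(tr, "final_probability"), want, tolerance = 1e-12)
  }
})

test_that("extreme call patterns land where the LR products say", {
  m <- uhr_model()
  nm <- m$performance$name
  neg <- attr(case_posterior(setNames(rep(0, 7), nm), m), "final_probability")
  pos <- attr(case_posterior(setNames(rep(1, 7), nm), m), "final_probability")
  expect_lt(neg, 0.01)
  expect_gt(pos, 0.99)
})

test_that("stage ordering changes trajectories but not the final posterior", {
  m <- uhr_model()
  nm <- m$performance$name
  set.seed(14)
  for (i in 1:20) {
    calls <- setNames(rbinom(7, 1, 0.5), nm)
    base <- attr(case_posterior(calls, m), "final_probability")
    m2 <- m
    m2$groups <- m$groups[sample(names(m$groups))]
    m2$groups <- lapply(m2$groups, sample)
    tr2 <- case_posterior(calls, m2)
    expect_equal(attr(tr2, "final_probability"), base, tolerance = 1e-15)
  }
})

test_that("flipping any single call to positive strictly raises the posterior", {
  m <- uhr_model()
  nm <- m$performance$name
  set.seed(15)
  for (i in 1:10) {
    calls <- setNames(rbinom(7, 1, 0.5), nm)
    base <- attr(case_posterior(calls, m), "final_probability")
    for (v in nm[calls == 0]) {
      up <- calls
      up[v] <- 1
      expect_gt(attr(case_posterior(up, m), "final_probability"), base)
    }
  }
})

test_that("an empty model returns the prior and unknown predictors error", {
  empty <- data.frame(name = character(0), group = character(0),
                      kind = character(0), direction = character(0),
                      threshold = numeric(0), sensitivity = numeric(0),
                      specificity = numeric(0))
  m0 <- lrbayes_model(empty, pretest = 0.28)
  tr <- case_posterior(numeric(0), m0)
  expect_equal(attr(tr, "final_probability"), 0.28)
  m <- uhr_model()
  expect_error(case_posterior(c(not_a_predictor = 1), m), "unknown predictor")
})

test_that("trajectories start at the pretest value and stay within [0,1]", {
  m <- uhr_model()
  nm <- m$performance$name
  tr <- case_posterior(setNames(c(1, 0, 1, 0, 1, 0, 1), nm), m)
  expect_equal(tr$probability[tr$stage == "pretest"], 0.28)
  expect_identical(as.character(tr$stage),
                   c("pretest", "historical", "clinical", "biomarker"))
  expect_true(all(tr$probability >= 0 & tr$probability <= 1))
  # each stage's probability is the previous odds times the stage LR product
  perf <- m$performance
  calls <- setNames(c(1, 0, 1, 0, 1, 0, 1), nm)
  o <- 0.28 / 0.72
  for (g in names(m$groups)) {
    for (v in m$groups[[g]]) {
      o <- o * if (calls[v] == 1) perf$lr_pos[perf$name == v]
               else perf$lr_neg[perf$name == v]
    }
    expect_equal(tr$probability[tr$stage == g], o / (1 + o), tolerance = 1e-12)
  }
})

test_that("missing-data policies: whole-case exclusion versus skip", {
  m <- uhr_model()
  nm <- m$performance$name
  calls <- setNames(c(1, NA, 1, 0, 1, 0, 1), nm)
  tr_ex <- case_posterior(calls, m, missing = "exclude")
  expect_true(attr(tr_ex, "excluded"))
  expect_true(all(is.na(tr_ex$probability)))
  tr_sk <- case_posterior(calls, m, missing = "skip")
  expect_false(attr(tr_sk, "excluded"))
  # skipping equals treating the missing predictor's LR as 1
  complete <- calls
  complete[is.na(complete)] <- 0
  perf <- m$performance
  o <- 0.28 / 0.72
  for (v in nm) {
    if (is.na(calls[v])) next
    o <- o * if (calls[v] == 1) perf$lr_pos[perf$name == v]
             else perf$lr_neg[perf$name == v]
  }
  expect_equal(attr(tr_sk, "final_probability"), o / (1 + o),
               tolerance = 1e-12)
})

test_that("fitting recovers the population Youden thresholds at large n", {
  sp <- uhr_cohort_spec()
  sp$n_subjects <- 10000L
  co <- simulate_cohort(sp, seed = 77)
  fml <- stats::as.formula(paste("transition ~",
                                 paste(names(sp$predictors), collapse = "+")))
  fit <- lrbayes(fml, co, groups = uhr_groups(sp),
                 directions = uhr_directions(sp))
  expect_setequal(fit$performance$name, names(sp$predictors))
  # for equal-SD Gaussian classes the population J-optimum is the mid-mean
  # point; the planted cut only coincides with it when sens = spec
  est <- setNames(fit$performance$threshold, fit$performance$name)
  for (p in sp$predictors) {
    if (p$kind != "continuous") next
    mu <- lrbayes:::.solve_means(p)
    opt <- (mu$case + mu$control) / 2
    expect_lt(abs(est[p$name] - opt), 0.2 * p$class_sd)
  }
  # pretest defaults to the cohort outcome rate
  expect_equal(fit$pretest, mean(co$transition))
})

test_that("a candidate list containing only noise raises an informative error", {
  set.seed(16)
  co <- data.frame(transition = rbinom(60, 1, 0.3), noise = rnorm(60))
  while (sum(co$transition) < 2) co$transition <- rbinom(60, 1, 0.3)
  p <- roc_curve(co$noise, co$transition)$p_vs_chance
  if (p < 0.05) {
    co$noise <- seq_len(60) %% 2  # fall back to a provably null predictor
  }
  expect_error(lrbayes(transition ~ noise, co), "AUROC screen")
})

test_that("posteriors are calibrated under conditional independence", {
  # generate from the model's own class-conditional call probabilities and
  # check the mean outcome within posterior bins (naive-Bayes consistency)
  m <- uhr_model()
  sim <- simulate(m, nsim = 1, seed = 18, n = 100000)[[1]]
  post <- posterior_from_calls(sim, m)
  bins <- round(post, 10)
  for (b in unique(bins)) {
    sel <- bins == b
    if (sum(sel) < 2000) next
    se <- sqrt(b * (1 - b) / sum(sel))
    expect_lt(abs(mean(sim$transition[sel]) - b), 4 * se + 0.005)
  }
})

test_that("model round-trips through its YAML serialization", {
  m <- uhr_model()
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_lrbayes(m, f)
  m2 <- read_lrbayes(f)
  expect_equal(m2$performance$lr_pos, m$performance$lr_pos)
  expect_equal(m2$performance$lr_neg, m$performance$lr_neg)
  expect_equal(m2$pretest, m$pretest)
  expect_identical(lapply(m2$groups, as.character),
                   lapply(m$groups, as.character))
  nd <- simulate(m, nsim = 1, seed = 19, n = 50)[[1]]
  expect_equal(posterior_from_calls(nd, m2), posterior_from_calls(nd, m))
})

test_that("coef, fitted, residuals and summary behave on a fitted model", {
  sp <- uhr_cohort_spec()
  sp$n_subjects <- 300L
  co <- simulate_cohort(sp, seed = 20)
  fml <- stats::as.formula(paste("transition ~",
                                 paste(names(sp$predictors), collapse = "+")))
  fit <- lrbayes(fml, co, groups = uhr_groups(sp),
                 directions = uhr_directions(sp))
  cf <- coef(fit)
  expect_identical(colnames(cf), c("lr_pos", "lr_neg"))
  expect_true(all(cf[, "lr_pos"] > 1 & cf[, "lr_neg"] < 1))
  expect_equal(length(fitted(fit)), 300)
  expect_equal(unname(residuals(fit)), unname(co$transition - fitted(fit)))
  s <- summary(fit)
  expect_s3_class(s, "summary.lrbayes")
  expect_output(print(s), "AUROC")
})
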