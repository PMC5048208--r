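test_that("predictive values satisfy the closed-form identities on a grid", {
  for (se in c(0.1, 0.5, 0.7273, 0.95)) {
    for (sp in c(0.2, 0.6, 0.9643, 0.99)) {
      for (pr in c(0.01, 0.28, 0.5, 0.9)) {
        pv <- ppv_npv(se, sp, pr)
        expect_identical(pv$ppv,
                         se * pr / (se * pr + (1 - sp) * (1 - pr)))
        expect_identical(pv$npv,
                         sp * (1 - pr) / (sp * (1 - pr) + (1 - se) * pr))
      }
    }
  }
  # published full-model operating point at the sample prevalence
  pv <- ppv_npv(0.7273, 0.9643, 0.28)
  expect_equal(pv$ppv, 0.8879, tolerance = 1e-4)
  expect_equal(pv$npv, 0.9009, tolerance = 1e-4)
})

test_that("base-rate limits drive PPV to 0 and NPV to 1", {
  pv <- ppv_npv(0.8, 0.9, 1e-9)
  expect_lt(pv$ppv, 1e-6)
  expect_gt(pv$npv, 1 - 1e-6)
})

test_that("a perfect posterior model evaluates perfectly", {
  y <- rep(c(1, 0), each = 8)
  ev <- evaluate_posteriors(as.numeric(y), y)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$ppv, 1)
  expect_equal(ev$npv, 1)
})

test_that("degenerate posteriors warn and fall to chance", {
  y <- rep(c(1, 0), each = 5)
  expect_warning(ev <- evaluate_posteriors(rep(0.28, 10), y), "degenerate")
  expect_equal(ev$auroc, 0.5)
})

test_that("sensitivity at fixed specificity uses the conservative rule", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0, 0)
  # controls sorted: 0.1 0.2 0.3 0.7; spec 0.5 needs 2 controls below the
  # cut -> t = 0.2, attained spec 0.5, all three cases above
  expect_equal(sens_at_spec(scores, y, 0.5), 1)
  # spec 0.75 -> t = 0.3 (3 of 4 controls <= t), all cases above
  expect_equal(sens_at_spec(scores, y, 0.75), 1)
  # spec 0.8 is not attainable below 1 -> t = 0.7, case 0.4 drops out
  expect_equal(sens_at_spec(scores, y, 0.8), 2 / 3)
  # spec 1 -> t = 0.7, case 0.4 drops out
  expect_equal(sens_at_spec(scores, y, 1), 2 / 3)
  # spec 0 -> everything called positive
  expect_equal(sens_at_spec(scores, y, 0), 1)
})

test_that("perfectly separating posteriors give a degenerate [1, 1] interval", {
  y <- rep(c(1, 0), each = 10)
  scores <- ifelse(y == 1, 0.9, 0.1)
  ci <- suppressWarnings(
    bootstrap_sens_at_spec(scores, y, 0.9, n_iterations = 200, seed = 1))
  expect_equal(ci$estimate, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
})

test_that("the BCa machinery agrees with boot's implementation", {
  skip_if_not_installed("boot")
  set.seed(33)
  x <- rexp(60)  # skewed so bias correction and acceleration both engage
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ci_boot <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- bca_interval(mean(x), as.vector(bt$t), jack)
  expect_equal(mine$lower, ci_boot[1], tolerance = 1e-6)
  expect_equal(mine$upper, ci_boot[2], tolerance = 1e-6)
  expect_equal(mine$method_used, "bca")
})

test_that("percentile and BCa intervals agree for a symmetric statistic", {
  p <- gen_predictor("x", "g", "continuous", "high_is_risk",
                     0.75, 0.75, threshold = 0, class_sd = 1)
  co <- simulate_cohort(cohort_spec(400, 0.5, list(p)), seed = 34)
  b1 <- bootstrap_sens_at_spec(co$x, co$transition, 0.75,
                               n_iterations = 1000, seed = 35,
                               method = "bca")
  b2 <- bootstrap_sens_at_spec(co$x, co$transition, 0.75,
                               n_iterations = 1000, seed = 35,
                               method = "percentile")
  expect_lt(abs(b1$lower - b2$lower), 0.02)
  expect_lt(abs(b1$upper - b2$upper), 0.02)
})

test_that("interval width shrinks from small to large cohorts", {
  m <- uhr_model()
  sp <- uhr_cohort_spec()
  co40 <- simulate_cohort(sp, seed = 36)
  post40 <- predict(m, co40, type = "response")
  ci40 <- suppressWarnings(
    bootstrap_sens_at_spec(post40, co40$transition, 0.9643,
                           n_iterations = 1000, seed = 37))
  expect_gt(ci40$upper - ci40$lower, 0.3)

  sp$n_subjects <- 4000L
  co4k <- simulate_cohort(sp, seed = 38)
  post4k <- predict(m, co4k, type = "response")
  ci4k <- bootstrap_sens_at_spec(post4k, co4k$transition, 0.9643,
                                 n_iterations = 1000, seed = 39)
  expect_lt(ci4k$upper - ci4k$lower, 0.1)
})

test_that("stratified resampling and the redraw guard both work", {
  set.seed(40)
  y <- c(rep(1, 2), rep(0, 10))  # single-class resamples are likely
  scores <- rnorm(12, mean = y)
  expect_warning(
    ci <- bootstrap_sens_at_spec(scores, y, 0.7, n_iterations = 200,
                                 seed = 41),
    "redrawn")
  expect_gt(ci$n_redraws, 0)
  cs <- bootstrap_sens_at_spec(scores, y, 0.7, n_iterations = 200,
                               seed = 42, stratified = TRUE)
  expect_equal(cs$n_redraws, 0)
  # the full draw sequence is determined by the seed alone
  ci2 <- suppressWarnings(
    bootstrap_sens_at_spec(scores, y, 0.7, n_iterations = 200, seed = 41))
  expect_identical(ci$t_star, ci2$t_star)
})

test_that("paired model comparison is antisymmetric and null on itself", {
  m <- uhr_model()
  sp <- uhr_cohort_spec()
  sp$n_subjects <- 200L
  co <- simulate_cohort(sp, seed = 43)
  post_full <- predict(m, co, type = "response")
  perf <- m$performance
  hist_tab <- perf[perf$group == "historical",
                   c("name", "group", "kind", "direction", "threshold",
                     "sensitivity", "specificity")]
  m_hist <- lrbayes_model(hist_tab, pretest = 0.28)
  post_hist <- predict(m_hist, co, type = "response")
  ev_f <- evaluate_posteriors(post_full, co$transition)
  ev_h <- evaluate_posteriors(post_hist, co$transition)
  self <- compare_models(ev_f, ev_f)
  expect_equal(self$delta_auroc, 0)
  expect_equal(self$p_value, 1)
  ab <- compare_models(ev_f, ev_h)
  ba <- compare_models(ev_h, ev_f)
  expect_equal(ab$delta_auroc, -ba$delta_auroc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("the combined model dominates the historical-only model", {
  m <- uhr_model()
  perf <- m$performance
  hist_tab <- perf[perf$group == "historical",
                   c("name", "group", "kind", "direction", "threshold",
                     "sensitivity", "specificity")]
  m_hist <- lrbayes_model(hist_tab, pretest = 0.28)
  sp <- uhr_cohort_spec()
  sp$n_subjects <- 500L
  set.seed(44)
  wins <- replicate(50, {
    co <- simulate_cohort(sp)
    a <- roc_curve(predict(m, co, type = "response"), co$transition)$auroc
    b <- roc_curve(predict(m_hist, co, type = "response"),
                   co$transition)$auroc
    a > b
  })
  expect_gte(mean(wins), 0.99)
})

test_that("evaluation summaries serialize as JSON", {
  y <- rep(c(1, 0), c(6, 14))
  set.seed(45)
  post <- plogis(rnorm(20, mean = 2 * y - 1))
  ev <- evaluate_posteriors(post, y)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_evaluation(ev, f)
  x <- jsonlite::read_json(f)
  expect_equal(x$auroc, ev$auroc)
  expect_equal(x$threshold_probability, ev$threshold)
  expect_equal(x$ppv, ev$ppv)
})
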