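test_that("concordance index matches its definition on constructed cases", {
  # higher score = higher risk = earlier event
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(concordance_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0.0)
  expect_error(concordance_index(c(1, 2), c(5, 5), c(0, 0)),
    class = "crlmrad_metric_error")
  set.seed(3)
  for (i in 1:10) {
    n <- 50
    sc <- sample(rnorm(40), n, replace = TRUE)  # force some score ties
    tt <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(outer(tt, tt, `<`) & ev == 1) == 0) next
    expect_equal(concordance_index(sc, tt, ev), oracle_cindex(sc, tt, ev),
      tolerance = 1e-12)
  }
})

test_that("AUC is the tie-aware rank statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "crlmrad_metric_error")
  set.seed(4)
  sc <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
  lab <- rbinom(30, 1, 0.5)
  if (length(unique(lab)) == 2) {
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("landmark dichotomization handles all censoring patterns", {
  lab <- dichotomize_outcome(c(12, 40, 10, 18, 17), c(1, 0, 0, 1, 0), 18)
  expect_equal(as.character(lab),
    c("positive", "negative", "excluded", "positive", "excluded"))
  # censored beyond the horizon is a definite negative
  expect_equal(as.character(dichotomize_outcome(40, 0, 36)), "negative")
  # event after the horizon: event-free at the landmark
  expect_equal(as.character(dichotomize_outcome(40, 1, 36)), "negative")
})

test_that("stratified holdout has the published size and matched event ratio", {
  set.seed(10)
  ev <- rbinom(241, 1, 0.6)
  plan <- stratified_holdout(ev, fraction = 0.15, n_runs = 10, seed = 3)
  expect_length(plan$holdout, 36)  # round(0.15 * 241)
  expect_lte(abs(mean(ev[plan$holdout]) - mean(ev)),
    1 / length(plan$holdout) + 1e-9)
  plan2 <- stratified_holdout(ev, fraction = 0.15, n_runs = 10, seed = 3)
  expect_identical(plan, plan2)
  expect_error(stratified_holdout(c(1, 0, 0, 0), fraction = 0.5),
    class = "crlmrad_split_error")
})

test_that("score classifiers behave like nested logistic models", {
  set.seed(6)
  sc <- c(rnorm(40, 2), rnorm(40, -2))
  lab <- factor(rep(c("positive", "negative"), each = 40),
    levels = c("positive", "negative", "excluded"))
  cls <- fit_score_classifier(sc, lab)
  p <- predict(cls, data.frame(score = sc))
  expect_true(all(p > 0 & p < 1))
  expect_equal(roc_auc(p, lab), 1.0)
  # constant score: intercept-only fit, chance-level AUC
  cls0 <- fit_score_classifier(rep(1, 80), lab)
  expect_equal(roc_auc(predict(cls0, data.frame(score = rep(1, 80))), lab), 0.5)
  # constant CRS column adds nothing to the 1-feature model
  sc2 <- rnorm(80)
  c1 <- fit_score_classifier(sc2, lab)
  c2 <- fit_score_classifier(sc2, lab, crs = rep(1, 80))
  nd <- data.frame(score = sc2, crs = 1)
  expect_equal(predict(c1, nd), predict(c2, nd), tolerance = 1e-6)
  expect_error(fit_score_classifier(sc2, rep("positive", 80)),
    class = "crlmrad_fit_error")
})

test_that("direct classifiers are sane baselines", {
  set.seed(9)
  n <- 200
  x <- data.frame(matrix(rnorm(n * 4), n, 4))
  lab <- rbinom(n, 1, 0.5)  # independent of the features
  tr <- seq_len(120); ho <- 121:n
  for (kind in c("logistic", "random_forest")) {
    cls <- fit_direct_classifier(x[tr, ], lab[tr], kind = kind, seed = 2)
    auc <- roc_auc(predict(cls, x[ho, ]), lab[ho])
    null_sd <- sd(replicate(200, roc_auc(runif(length(ho)), lab[ho])))
    expect_lt(abs(auc - 0.5), 3 * null_sd + 0.02)
  }
  # duplicating rows does not move the logistic decision boundary
  xs <- data.frame(a = rnorm(60))
  ys <- as.integer(xs$a + rnorm(60, 0, 0.5) > 0)
  c1 <- fit_direct_classifier(xs, ys, kind = "logistic")
  c2 <- fit_direct_classifier(rbind(xs, xs), c(ys, ys), kind = "logistic")
  expect_equal(coef(c1$fit), coef(c2$fit), tolerance = 1e-6)
  # a single stump forest splits on the only informative binary feature
  xb <- data.frame(good = rep(c(0, 1), each = 20), bad = runif(40))
  yb <- xb$good
  cf <- fit_direct_classifier(xb, yb, kind = "random_forest", n_trees = 1,
    seed = 1, replace = FALSE, sample.fraction = 1, mtry = 2)
  expect_equal(ranger::treeInfo(cf$fit, 1)$splitvarName[1], "good")
})

test_that("percentile bootstrap is exact for constants and reproducible", {
  ci <- bootstrap_ci(mean, rep(3.5, 20), n_boot = 100, seed = 1)
  expect_equal(unname(ci[1]), 3.5)
  expect_equal(unname(ci[2]), 3.5)
  set.seed(2)
  x <- rnorm(60)
  a <- bootstrap_ci(mean, x, n_boot = 500, seed = 7)
  b <- bootstrap_ci(mean, x, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a[1], attr(a, "point"))
  expect_gte(a[2], attr(a, "point"))
  # degenerate resamples are redrawn and counted
  dat <- c(rep(NA_real_, 2), rnorm(10))
  ci2 <- bootstrap_ci(function(v) if (anyNA(v)) NA_real_ else mean(v), dat,
    n_boot = 50, seed = 3)
  expect_gt(attr(ci2, "n_degenerate"), 0)
})

test_that("the experiment report keeps books straight and never leaks", {
  co <- generate_cohort(synthetic_config(n_patients = 120, seed = 5))
  cfg <- experiment_config(outcomes = "ttr", strategies = "largest_only",
    models = "rsf", with_crs = FALSE, n_runs = 2, n_boot = 100, seed = 2)
  rep1 <- run_experiment(co, cfg)
  cell <- subset(rep1$runs, model == "rsf" & metric == "cindex")
  expect_equal(nrow(cell), 2)  # exactly one indexed value per run
  expect_true(all(rep1$summary$estimate >= 0 & rep1$summary$estimate <= 1,
    na.rm = TRUE))
  ok <- !is.na(rep1$summary$estimate) & rep1$summary$n_complete > 1
  expect_true(all(rep1$summary$ci_lo[ok] <= rep1$summary$estimate[ok] + 1e-9))
  expect_true(all(rep1$summary$ci_hi[ok] >= rep1$summary$estimate[ok] - 1e-9))
  # leakage audit: holdout disjoint from every training subsample
  plan <- rep1$plans$ttr
  for (idx in plan$runs) expect_length(intersect(plan$holdout, idx), 0)
  # identical config + seed reproduces the report byte for byte
  rep2 <- run_experiment(co, cfg)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_eval_report(rep1, d1); write_eval_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "eval_report.csv")),
    readLines(file.path(d2, "eval_report.csv")))
})
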