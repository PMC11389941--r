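test_that("Cox partial loss matches hand and brute-force evaluation", {
  # two subjects, both events, equal scores: (log 2 + log 1) / 2
  expect_equal(cox_partial_loss(c(0, 0), c(1, 2), c(1, 1)), log(2) / 2,
    tolerance = 1e-12)
  # location invariance
  set.seed(2)
  s <- rnorm(20); tt <- rexp(20); ev <- rbinom(20, 1, 0.7); ev[1] <- 1
  expect_equal(cox_partial_loss(s, tt, ev),
    cox_partial_loss(s + 13.7, tt, ev), tolerance = 1e-10)
  # perfectly ordered, widely separated scores: loss tends to zero
  tt3 <- c(1, 2, 3)
  expect_lt(cox_partial_loss(c(300, 200, 100), tt3, c(1, 1, 1)), 1e-10)
  expect_error(cox_partial_loss(s, tt, rep(0, 20)),
    class = "crlmrad_estimation_error")
})

test_that("loss gradient agrees with numerical differentiation", {
  set.seed(5)
  n <- 12
  s <- rnorm(n); tt <- round(rexp(n), 1); ev <- rbinom(n, 1, 0.6); ev[3] <- 1
  g <- crlmrad:::cox_loss_grad(s, tt, ev)$grad
  eps <- 1e-6
  for (i in c(1, 4, 9)) {
    sp <- s; sp[i] <- sp[i] + eps
    sm <- s; sm[i] <- sm[i] - eps
    num <- (cox_partial_loss(sp, tt, ev) - cox_partial_loss(sm, tt, ev)) /
      (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("network parameter count follows the architecture arithmetic", {
  set.seed(1)
  x <- matrix(rnorm(60 * 10), 60, 10)
  colnames(x) <- sprintf("v%02d", 1:10)
  tt <- rexp(60); ev <- rbinom(60, 1, 0.7); ev[1] <- 1
  fit <- fit_neural_surv(x, tt, ev,
    neural_surv_config(max_epochs = 5, patience = 5, seed = 1))
  np <- n_params(fit)
  expect_equal(unname(np["affine"]), 10 * 4 + 4 + 4 * 4 + 4 + 4 * 1 + 1)
  expect_equal(unname(np["batchnorm"]), 2 * (4 + 4))
})

test_that("zero learning rate leaves the initialization untouched", {
  set.seed(1)
  x <- matrix(rnorm(50 * 4), 50, 4)
  colnames(x) <- sprintf("v%d", 1:4)
  tt <- rexp(50); ev <- rbinom(50, 1, 0.8); ev[1] <- 1
  fit <- fit_neural_surv(x, tt, ev, neural_surv_config(learning_rate = 0,
    max_epochs = 50, patience = 50, seed = 9))
  ref <- local({
    set.seed(9)
    crlmrad:::init_net_params(4, c(4, 4))
  })
  # validation split consumes RNG before init inside the fit, so compare by
  # optimizer effect instead: weights after lr = 0 training equal weights
  # after a 1-epoch lr = 0 run (both are whatever init produced)
  fit1 <- fit_neural_surv(x, tt, ev, neural_surv_config(learning_rate = 0,
    max_epochs = 1, patience = 1, seed = 9))
  expect_equal(fit$params, fit1$params, tolerance = 1e-15)
  expect_false(isTRUE(all.equal(fit$params, ref)))  # sanity: seeds differ by stage
})

test_that("training improves the loss and scoring is deterministic", {
  set.seed(30)
  n <- 150
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  tt <- rexp(n, 0.1 * exp(1.2 * x[, 1]))
  ev <- rep(1L, n)
  fit <- fit_neural_surv(x, tt, ev, neural_surv_config(max_epochs = 4000,
    patience = 4000, seed = 2))
  expect_lte(fit$history$best_loss, fit$history$val_loss[1])
  r1 <- predict_risk(fit, x)
  r2 <- predict_risk(fit, x)
  expect_identical(r1, r2)  # evaluation mode: dropout off
  expect_true(all(is.finite(r1)))
  expect_error(predict_risk(fit, x[, 1:2]), class = "crlmrad_scoring_error")
  expect_error(predict_risk(fit, x[0, , drop = FALSE]),
    class = "crlmrad_scoring_error")
})

test_that("network learns a strong feature beyond the permutation null", {
  set.seed(55)
  n <- 250
  x <- matrix(rnorm(n * 4), n, 4)
  colnames(x) <- sprintf("v%d", 1:4)
  lp <- 1.5 * x[, 1]
  tt <- rexp(n, 0.05 * exp(lp))
  ev <- rbinom(n, 1, 0.85)
  ho <- sample(n, 50); tr <- setdiff(seq_len(n), ho)
  fit <- fit_neural_surv(x[tr, ], tt[tr], ev[tr],
    neural_surv_config(seed = 3))
  r <- predict_risk(fit, x[ho, ])
  ci <- concordance_index(r, tt[ho], ev[ho])
  null_ci <- replicate(200, concordance_index(sample(r), tt[ho], ev[ho]))
  expect_gt(ci, 0.5 + 3 * sd(null_ci))
})

test_that("survival forest splits on the separating feature and ranks by hazard", {
  # one binary feature that perfectly separates early events from late ones;
  # the log-rank statistic is maximal for that split and zero in expectation
  # for the junk feature
  set.seed(1)
  x <- data.frame(sep = rep(c(1, 0), each = 4), junk = runif(8))
  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1, 8)
  fit <- fit_rsf(x, tt, ev, n_trees = 1, min_leaf = 1, mtry = 2, seed = 4,
    replace = FALSE, sample.fraction = 1)
  info <- ranger::treeInfo(fit$engine, 1)
  expect_equal(info$splitvarName[1], "sep")
  risk <- predict_risk(fit, x)
  expect_true(all(risk[1:4] > risk[5:8]))
  expect_error(fit_rsf(x, tt, ev, min_leaf = 10), class = "crlmrad_param_error")
})

test_that("forest predictions are invariant to monotone feature transforms", {
  set.seed(8)
  n <- 120
  x <- data.frame(a = rnorm(n), b = runif(n))
  tt <- rexp(n, 0.1 * exp(x$a)); ev <- rbinom(n, 1, 0.8); ev[1] <- 1
  # full-sample trees: with bootstrapping an out-of-bag point can fall
  # between two in-bag neighbours, where the split threshold is convention
  f1 <- fit_rsf(x, tt, ev, n_trees = 20, seed = 6, replace = FALSE,
    sample.fraction = 1)
  x2 <- data.frame(a = exp(x$a), b = x$b)  # strictly monotone in a
  f2 <- fit_rsf(x2, tt, ev, n_trees = 20, seed = 6, replace = FALSE,
    sample.fraction = 1)
  expect_equal(predict_risk(f1, x), predict_risk(f2, x2), tolerance = 1e-10)
})

test_that("out-of-bag style forest performance on pure noise is near chance", {
  set.seed(12)
  n <- 160
  x <- data.frame(matrix(rnorm(n * 5), n, 5))
  tt <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.7); ev[1] <- 1
  tr <- seq_len(110); ho <- 111:n
  fit <- fit_rsf(x[tr, ], tt[tr], ev[tr], n_trees = 100, seed = 2)
  ci <- concordance_index(predict_risk(fit, x[ho, ]), tt[ho], ev[ho])
  expect_lt(abs(ci - 0.5), 0.12)
})

test_that("CRS concatenation appends one audited column", {
  x <- data.frame(f1 = 1:3, f2 = 4:6)
  out <- attach_crs(x, c("low", "high", "low"))
  expect_equal(ncol(out), 3)
  expect_equal(out$crs, c(0L, 1L, 0L))
  expect_equal(attr(out, "crs_encoding"), "binary")
  raw <- attach_crs(x, c(0, 3, 5), encoding = "raw")
  expect_equal(raw$crs, c(0L, 3L, 5L))
  # raw integer scores dichotomize under the binary default
  bin <- attach_crs(x, c(0, 3, 5))
  expect_equal(bin$crs, c(0L, 1L, 1L))
  expect_error(attach_crs(x, c("low", NA, "high")),
    class = "crlmrad_profile_error")
})
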