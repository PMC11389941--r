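#' Negative Cox partial log-likelihood
#'
#' Breslow-ties negative partial log-likelihood of a vector of risk scores,
#' averaged over events.  This is the training objective of the neural
#' survival model; it is invariant to adding a constant to all scores.
#'
#' @param scores per-subject risk scores (higher = higher hazard).
#' @param time,event right-censored outcome; at least one event required.
#' @return a single non-negative number.
#' @export
cox_partial_loss <- function(scores, time, event) {
  cox_loss_grad(scores, time, event)$loss
}

# Precomputed risk-set structure: sort order and tie-group bounds are fixed
# by (time, event), so they are built once per dataset and reused each epoch.
cox_structure <- function(time, event) {
  n_events <- sum(event)
  assert_that(n_events >= 1, "partial likelihood undefined without events",
    class = "crlmrad_estimation_error")
  ord <- order(time)
  tt <- time[ord]
  pos <- seq_along(tt)
  first_of_val <- pos[!duplicated(tt)]
  grp <- cumsum(!duplicated(tt))
  g_start <- first_of_val[grp]
  last_of_val <- rev(pos)[!duplicated(rev(tt))]
  g_end <- rev(last_of_val)[grp]
  list(ord = ord, dd = event[ord], g_start = g_start, g_end = g_end,
    n_events = n_events)
}

cox_loss_grad_pre <- function(scores, st) {
  s <- as.numeric(scores) - max(scores)  # location invariance + stability
  ss <- s[st$ord]
  es <- exp(ss)
  rcs <- rev(cumsum(rev(es)))
  S <- rcs[st$g_start]  # risk-set sum for each subject's time
  loss <- -sum(st$dd * (ss - log(S))) / st$n_events
  ch <- cumsum(st$dd / S)
  grad_sorted <- -(st$dd - es * ch[st$g_end]) / st$n_events
  grad <- numeric(length(s))
  grad[st$ord] <- grad_sorted
  list(loss = loss, grad = grad)
}

# loss and gradient wrt the scores, both Breslow / event-averaged
cox_loss_grad <- function(scores, time, event) {
  cox_loss_grad_pre(scores, cox_structure(time, event))
}

#' Configuration for the compact neural Cox survival model
#'
#' The backbone is two consecutive blocks of a 4-node fully connected layer,
#' batch normalization, ReLU, and dropout 0.1, followed by a linear risk
#' output, trained full-batch with Adam on the Cox partial-likelihood loss.
#' Training stops at the lowest loss on an internal validation split.
#'
#' @param block_widths widths of the fully connected blocks.
#' @param dropout dropout probability in [0, 1).
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum full-batch epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param seed integer seed (initialization, dropout, validation split).
#' @return object of class `crlm_neural_config`.
#' @export
neural_surv_config <- function(block_widths = c(4L, 4L), dropout = 0.1,
                               learning_rate = 1e-5, max_epochs = 30000L,
                               patience = 3000L, val_fraction = 0.15,
                               seed = 1L) {
  assert_that(all(block_widths >= 1), "block widths must be >= 1",
    class = "crlmrad_config_error")
  assert_that(is_prob(dropout) && dropout < 1, "dropout must be in [0,1)",
    class = "crlmrad_config_error")
  assert_that(learning_rate >= 0, "learning_rate must be >= 0",
    class = "crlmrad_config_error")
  assert_that(is_prob(val_fraction) && val_fraction < 1,
    "val_fraction must be in [0,1)", class = "crlmrad_config_error")
  structure(
    list(block_widths = as.integer(block_widths), dropout = dropout,
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), val_fraction = val_fraction,
      seed = as.integer(seed)),
    class = "crlm_neural_config"
  )
}

init_net_params <- function(d_in, widths) {
  sizes <- c(d_in, widths, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  gamma <- vector("list", L - 1L); beta <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
      sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  for (l in seq_len(L - 1L)) {
    gamma[[l]] <- rep(1, sizes[l + 1])
    beta[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, gamma = gamma, beta = beta)
}

net_forward <- function(params, x, dropout, training, run_stats,
                        bn_eps = 1e-5, bn_momentum = 0.1) {
  L <- length(params$W)
  n <- nrow(x)
  a <- x
  cache <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    z <- a %*% params$W[[l]]
    z <- z + rep(params$b[[l]], each = n)
    if (training) {
      mu <- colMeans(z)
      zc <- z - rep(mu, each = n)
      v <- colMeans(zc * zc)
      if (isTRUE(run_stats$fresh)) {
        # first batch: adopt the batch statistics outright so evaluation-mode
        # scores are meaningful from the start
        run_stats$mean[[l]] <- mu
        run_stats$var[[l]] <- v
      } else {
        run_stats$mean[[l]] <- (1 - bn_momentum) * run_stats$mean[[l]] +
          bn_momentum * mu
        run_stats$var[[l]] <- (1 - bn_momentum) * run_stats$var[[l]] +
          bn_momentum * v
      }
    } else {
      mu <- run_stats$mean[[l]]
      v <- run_stats$var[[l]]
      zc <- z - rep(mu, each = n)
    }
    xhat <- zc * rep(1 / sqrt(v + bn_eps), each = n)
    bn <- xhat * rep(params$gamma[[l]], each = n) +
      rep(params$beta[[l]], each = n)
    act <- pmax(bn, 0)
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(act), 1, 1 - dropout) /
        (1 - dropout), n, ncol(act))
      out <- act * mask
    } else {
      mask <- NULL
      out <- act
    }
    cache[[l]] <- list(a_in = a, z = z, mu = mu, v = v, xhat = xhat,
      bn = bn, act = act, mask = mask)
    a <- out
  }
  if (training) run_stats$fresh <- FALSE
  s <- as.numeric(a %*% params$W[[L]]) + params$b[[L]]
  list(scores = s, cache = cache, a_last = a, run_stats = run_stats)
}

net_backward <- function(params, fw, dscores, dropout, bn_eps = 1e-5) {
  L <- length(params$W)
  n <- length(dscores)
  grads <- list(W = vector("list", L), b = vector("list", L),
    gamma = vector("list", L - 1L), beta = vector("list", L - 1L))
  ds <- matrix(dscores, n, 1)
  grads$W[[L]] <- crossprod(fw$a_last, ds)
  grads$b[[L]] <- colSums(ds)
  da <- ds %*% t(params$W[[L]])
  for (l in rev(seq_len(L - 1L))) {
    cc <- fw$cache[[l]]
    if (!is.null(cc$mask)) da <- da * cc$mask
    da <- da * (cc$bn > 0)  # ReLU
    grads$gamma[[l]] <- colSums(da * cc$xhat)
    grads$beta[[l]] <- colSums(da)
    dxhat <- sweep(da, 2, params$gamma[[l]], `*`)
    inv_sd <- 1 / sqrt(cc$v + bn_eps)
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * cc$xhat)
    dz <- sweep(
      n * dxhat - matrix(sum_dxhat, n, length(sum_dxhat), byrow = TRUE) -
        cc$xhat * matrix(sum_dxhat_xhat, n, length(sum_dxhat_xhat),
          byrow = TRUE),
      2, inv_sd / n, `*`)
    grads$W[[l]] <- crossprod(cc$a_in, dz)
    grads$b[[l]] <- colSums(dz)
    da <- dz %*% t(params$W[[l]])
  }
  grads
}

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (grp in c("W", "b", "gamma", "beta")) {
    for (l in seq_along(params[[grp]])) {
      g <- grads[[grp]][[l]]
      state$m[[grp]][[l]] <- beta1 * state$m[[grp]][[l]] + (1 - beta1) * g
      state$v[[grp]][[l]] <- beta2 * state$v[[grp]][[l]] + (1 - beta2) * g^2
      mhat <- state$m[[grp]][[l]] / (1 - beta1^state$t)
      vhat <- state$v[[grp]][[l]] / (1 - beta2^state$t)
      params[[grp]][[l]] <- params[[grp]][[l]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Fit the compact neural Cox survival model
#'
#' Standardizes the inputs with training-set mean/SD (frozen for later
#' scoring), splits off a validation fraction stratified by event status,
#' and trains the two-block network full-batch with Adam on
#' [cox_partial_loss()].  The returned model carries the weights snapshot at
#' the lowest validation loss.
#'
#' @param x training features (matrix or data frame, named columns).
#' @param time,event training outcome.
#' @param config a `crlm_neural_config`.
#' @return object of class `crlm_deepsurv` with elements `params`,
#'   `run_stats`, `center`, `scale`, `feature_names`, `config`, `history`.
#' @export
fit_neural_surv <- function(x, time, event, config = neural_surv_config()) {
  assert_that(inherits(config, "crlm_neural_config"),
    "config must come from neural_surv_config()", class = "crlmrad_config_error")
  x <- as.matrix(x)
  assert_that(sum(event) >= 1, "need at least one event",
    class = "crlmrad_estimation_error")
  n <- nrow(x)
  set.seed(config$seed)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)

  # validation split stratified on the event flag; redraw if eventless
  n_val <- max(2L, round(config$val_fraction * n))
  val_idx <- NULL
  if (config$val_fraction > 0) {
    for (try in 1:25) {
      ev <- which(event == 1); ce <- which(event == 0)
      nv_ev <- min(length(ev), max(1L, round(config$val_fraction * length(ev))))
      cand <- c(sample(ev, nv_ev), sample(ce, min(length(ce),
        n_val - nv_ev)))
      if (sum(event[cand]) >= 1 && sum(event[-cand]) >= 1) {
        val_idx <- cand
        break
      }
    }
    assert_that(!is.null(val_idx),
      "could not draw a validation split containing events",
      class = "crlmrad_estimation_error")
  }
  fit_idx <- if (is.null(val_idx)) seq_len(n) else setdiff(seq_len(n), val_idx)

  params <- init_net_params(ncol(x), config$block_widths)
  nb <- length(config$block_widths)
  run_stats <- list(
    mean = lapply(config$block_widths, function(w) numeric(w)),
    var = lapply(config$block_widths, function(w) rep(1, w)),
    fresh = TRUE
  )
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, run_stats = run_stats,
    epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  xf <- xs[fit_idx, , drop = FALSE]
  tf <- time[fit_idx]; ef <- event[fit_idx]
  fit_struct <- cox_structure(tf, ef)
  val_struct <- if (!is.null(val_idx)) {
    cox_structure(time[val_idx], event[val_idx])
  }
  for (epoch in seq_len(config$max_epochs)) {
    fw <- net_forward(params, xf, config$dropout, training = TRUE, run_stats)
    run_stats <- fw$run_stats
    lg <- cox_loss_grad_pre(fw$scores, fit_struct)
    grads <- net_backward(params, fw, lg$grad, config$dropout)
    upd <- adam_step(params, grads, state, config$learning_rate)
    params <- upd$params
    state <- upd$state
    if (is.null(val_idx)) {
      monitor <- lg$loss
    } else {
      vs <- net_forward(params, xs[val_idx, , drop = FALSE], 0,
        training = FALSE, run_stats)$scores
      monitor <- cox_loss_grad_pre(vs, val_struct)$loss
    }
    history <- c(history, monitor)
    if (monitor < best$loss - 1e-10) {
      best <- list(loss = monitor, params = params, run_stats = run_stats,
        epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(
    list(params = best$params, run_stats = best$run_stats,
      center = center, scale = scale,
      feature_names = colnames(x), config = config,
      history = list(val_loss = history, best_epoch = best$epoch,
        best_loss = best$loss, n_epochs = length(history))),
    class = c("crlm_deepsurv", "crlm_survmodel")
  )
}

#' @exportS3Method base::print
print.crlm_deepsurv <- function(x, ...) {
  cat(sprintf(
    "Neural Cox model: %d inputs -> [%s] -> 1; stopped at epoch %d (val loss %.4f)\n",
    length(x$feature_names),
    paste(x$config$block_widths, collapse = ","),
    x$history$best_epoch, x$history$best_loss))
  invisible(x)
}

#' Number of trainable affine parameters of a neural Cox model
#'
#' Counts weights and biases of the fully connected layers (batch-norm scale
#' and shift parameters are reported separately).
#'
#' @param model a `crlm_deepsurv`.
#' @return named numeric vector with `affine` and `batchnorm` counts.
#' @export
n_params <- function(model) {
  affine <- sum(vapply(model$params$W, length, numeric(1))) +
    sum(vapply(model$params$b, length, numeric(1)))
  bn <- sum(vapply(model$params$gamma, length, numeric(1))) +
    sum(vapply(model$params$beta, length, numeric(1)))
  c(affine = affine, batchnorm = bn)
}

#' Fit a random survival forest
#'
#' Bootstrap ensemble of survival trees with log-rank splitting over sampled
#' feature subsets (via the `ranger` engine); a patient's risk score is the
#' ensemble cumulative hazard summed over the unique event times, so higher
#' scores mean higher predicted hazard.
#'
#' @param x training features (data frame or matrix).
#' @param time,event training outcome.
#' @param n_trees number of trees (default 200).
#' @param min_leaf minimal terminal-node size (default 5).
#' @param mtry features tried per split (default `ceiling(sqrt(d))`).
#' @param seed integer seed.
#' @param ... further arguments passed to [ranger::ranger()] (e.g.
#'   `max.depth`, `replace`, `sample.fraction`).
#' @return object of class `crlm_rsf`.
#' @export
fit_rsf <- function(x, time, event, n_trees = 200L, min_leaf = 5L,
                    mtry = NULL, seed = 1L, ...) {
  x <- as.data.frame(x, check.names = FALSE)
  assert_that(min_leaf <= nrow(x), "min_leaf larger than the sample",
    class = "crlmrad_param_error")
  assert_that(sum(event) >= 1, "need at least one event",
    class = "crlmrad_estimation_error")
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(x))))
  df <- data.frame(..time = time, ..status = event, x, check.names = FALSE)
  fit <- ranger::ranger(
    formula = survival::Surv(..time, ..status) ~ .,
    data = df, num.trees = n_trees, mtry = mtry,
    min.node.size = min_leaf, splitrule = "logrank", seed = seed,
    num.threads = 1, ...
  )
  structure(
    list(engine = fit, feature_names = colnames(x), seed = seed),
    class = c("crlm_rsf", "crlm_survmodel")
  )
}

#' @exportS3Method base::print
print.crlm_rsf <- function(x, ...) {
  cat(sprintf("Random survival forest: %d trees, %d features\n",
    x$engine$num.trees, length(x$feature_names)))
  invisible(x)
}

#' Predict per-patient risk scores
#'
#' Higher scores mean higher predicted hazard.  The neural model runs in
#' evaluation mode (dropout off, frozen batch-norm statistics), so repeated
#' calls are identical; the forest returns the ensemble-mean cumulative
#' hazard summed over the unique event times.
#'
#' @param model a fitted `crlm_deepsurv` or `crlm_rsf`.
#' @param features data frame/matrix with the training feature columns.
#' @return numeric vector of risk scores.
#' @export
predict_risk <- function(model, features) {
  UseMethod("predict_risk")
}

check_features <- function(model, features) {
  features <- as.data.frame(features, check.names = FALSE)
  assert_that(nrow(features) >= 1, "empty feature input",
    class = "crlmrad_scoring_error")
  missing_f <- setdiff(model$feature_names, colnames(features))
  if (length(missing_f)) {
    stop_crlmrad(sprintf("feature(s) missing from input: %s",
      paste(missing_f, collapse = ", ")), "crlmrad_scoring_error")
  }
  features[, model$feature_names, drop = FALSE]
}

#' @export
predict_risk.crlm_deepsurv <- function(model, features) {
  x <- as.matrix(check_features(model, features))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  net_forward(model$params, xs, 0, training = FALSE,
    model$run_stats)$scores
}

#' @export
predict_risk.crlm_rsf <- function(model, features) {
  x <- check_features(model, features)
  pr <- stats::predict(model$engine, data = x, num.threads = 1)
  rowSums(pr$chf)
}

#' @export
predict.crlm_deepsurv <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' @export
predict.crlm_rsf <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Append the clinical risk score to a feature table
#'
#' @param features data frame/matrix of patient-level features.
#' @param crs per-patient CRS: `"low"`/`"high"`, logical high flags, or raw
#'   integer scores 0-5.
#' @param encoding `"binary"` (default: high = 1) or `"raw"` (integer 0-5;
#'   requires raw scores).
#' @return data frame with one extra `crs` column; the encoding used is
#'   recorded in the `crs_encoding` attribute.
#' @export
attach_crs <- function(features, crs, encoding = c("binary", "raw")) {
  encoding <- match.arg(encoding)
  features <- as.data.frame(features, check.names = FALSE)
  assert_that(length(crs) == nrow(features) && !anyNA(crs),
    "CRS required for every patient", class = "crlmrad_profile_error")
  col <- if (encoding == "binary") {
    if (is.character(crs)) {
      assert_that(all(crs %in% c("low", "high")),
        "character CRS must be 'low'/'high'", class = "crlmrad_profile_error")
      as.integer(crs == "high")
    } else if (is.logical(crs)) {
      as.integer(crs)
    } else {
      as.integer(dichotomize_crs(crs) == "high")
    }
  } else {
    assert_that(is.numeric(crs) && all(crs %in% 0:5),
      "raw encoding needs integer scores 0-5", class = "crlmrad_profile_error")
    as.integer(crs)
  }
  out <- cbind(features, crs = col)
  attr(out, "crs_encoding") <- encoding
  out
}
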