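# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementations they check.

oracle_cindex <- function(scores, time, event) {
  num <- 0
  den <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  num <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) num <- num + 1
      if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / (length(pos) * length(neg))
}

oracle_cox_loss <- function(scores, time, event) {
  total <- 0
  for (i in which(event == 1)) {
    risk_set <- which(time >= time[i])
    total <- total - (scores[i] - log(sum(exp(scores[risk_set]))))
  }
  total / sum(event)
}

# Newton-Raphson solver for the unpenalized Cox model (Breslow ties),
# independent of both survival::coxph and glmnet.
oracle_newton_cox <- function(x, time, event, iter = 60) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(iter)) {
    eta <- as.numeric(x %*% beta)
    w <- exp(eta)
    grad <- rep(0, p)
    hess <- matrix(0, p, p)
    for (t_ev in unique(time[event == 1])) {
      d_t <- sum(event == 1 & time == t_ev)
      rs <- which(time >= t_ev)
      s0 <- sum(w[rs])
      s1 <- colSums(x[rs, , drop = FALSE] * w[rs])
      s2 <- matrix(0, p, p)
      for (i in rs) s2 <- s2 + w[i] * tcrossprod(x[i, ])
      xbar <- s1 / s0
      for (i in which(event == 1 & time == t_ev)) grad <- grad + x[i, ] - xbar
      hess <- hess - d_t * (s2 / s0 - tcrossprod(xbar))
    }
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# 13 antipodal-unique unit offsets, enumerated independently
oracle_offsets <- local({
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      offs[[length(offs) + 1]] <- c(dx, dy, dz)
    }
  }
  offs
})

oracle_glcm <- function(bins, mask, n_bins) {
  d <- dim(bins)
  acc <- NULL
  n_dir <- 0
  for (off in oracle_offsets) {
    counts <- matrix(0, n_bins, n_bins)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (mask[i, j, k] != 1) next
      for (sgn in c(1, -1)) {
        ii <- i + sgn * off[1]; jj <- j + sgn * off[2]; kk <- k + sgn * off[3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        if (mask[ii, jj, kk] != 1) next
        counts[bins[i, j, k], bins[ii, jj, kk]] <-
          counts[bins[i, j, k], bins[ii, jj, kk]] + 1
      }
    }
    if (sum(counts) == 0) next
    p <- counts / sum(counts)
    lev <- seq_len(n_bins)
    px <- rowSums(p)
    mu <- sum(lev * px)
    sdv <- sqrt(sum((lev - mu)^2 * px))
    contrast <- 0; corr_num <- 0; ent <- 0; ener <- 0; homog <- 0
    for (a in lev) for (b in lev) {
      contrast <- contrast + p[a, b] * (a - b)^2
      corr_num <- corr_num + (a - mu) * (b - mu) * p[a, b]
      if (p[a, b] > 0) ent <- ent - p[a, b] * log2(p[a, b])
      ener <- ener + p[a, b]^2
      homog <- homog + p[a, b] / (1 + abs(a - b))
    }
    f <- c(contrast = contrast,
      correlation = if (sdv > 0) corr_num / sdv^2 else 1,
      joint_entropy = ent, energy = ener, homogeneity = homog)
    acc <- if (is.null(acc)) f else acc + f
    n_dir <- n_dir + 1
  }
  acc / n_dir
}

oracle_glrlm <- function(bins, mask, n_bins) {
  d <- dim(bins)
  nvox <- sum(mask == 1)
  acc <- NULL
  for (off in oracle_offsets) {
    # enumerate maximal lines: start voxels whose predecessor is off-grid
    runs <- list()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      prev <- c(i, j, k) - off
      inside <- all(prev >= 1) && all(prev <= d)
      if (inside) next
      # walk the line
      cur <- c(i, j, k)
      run_lev <- NA; run_len <- 0
      while (all(cur >= 1) && all(cur <= d)) {
        v <- if (mask[cur[1], cur[2], cur[3]] == 1) bins[cur[1], cur[2], cur[3]] else NA
        if (!is.na(v) && !is.na(run_lev) && v == run_lev) {
          run_len <- run_len + 1
        } else {
          if (!is.na(run_lev)) runs[[length(runs) + 1]] <- c(run_lev, run_len)
          run_lev <- v
          run_len <- if (is.na(v)) 0 else 1
        }
        cur <- cur + off
      }
      if (!is.na(run_lev)) runs[[length(runs) + 1]] <- c(run_lev, run_len)
    }
    rmat <- do.call(rbind, runs)
    nr <- nrow(rmat)
    sre <- sum(1 / rmat[, 2]^2) / nr
    lre <- sum(rmat[, 2]^2) / nr
    rln <- sum(table(rmat[, 2])^2) / nr
    gln <- sum(table(rmat[, 1])^2) / nr
    rp <- nr / nvox
    f <- c(short_run_emphasis = sre, long_run_emphasis = lre,
      run_length_nonuniformity = rln, gray_level_nonuniformity = gln,
      run_percentage = rp)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(oracle_offsets)
}

# exhaustive greedy MRMR recomputation with its own MI estimator
oracle_mrmr <- function(x, target, k) {
  disc <- function(v) {
    if (max(v) == min(v)) return(rep(1, length(v)))
    qs <- unique(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    findInterval(v, qs, left.open = TRUE) + 1
  }
  mi <- function(a, b) {
    tab <- table(a, b)
    p <- tab / sum(tab)
    out <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        out <- out + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
      }
    }
    out
  }
  dx <- lapply(seq_len(ncol(x)), function(j) disc(x[, j]))
  rel <- sapply(dx, function(d) mi(d, target))
  sel <- integer(0)
  rem <- seq_len(ncol(x))
  while (length(sel) < k && length(rem) > 0) {
    if (length(sel) == 0) {
      score <- rel[rem]
    } else {
      score <- sapply(rem, function(j) {
        rel[j] - mean(sapply(sel, function(s) mi(dx[[j]], dx[[s]])))
      })
    }
    pick <- rem[which.max(score)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  colnames(x)[sel]
}

# small survival datasets with ties for exactness checks
random_surv_data <- function(n, censor_frac = 0.3, tie_prob = 0.3) {
  time <- round(rexp(n, 0.1), digits = if (runif(1) < tie_prob) 0 else 3)
  time[time <= 0] <- 0.5
  event <- rbinom(n, 1, 1 - censor_frac)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  list(time = time, event = event)
}

make_profile <- function(node = FALSE, dfi = 24, n_crlm = 1, size = 3,
                         cea = 50) {
  list(node_positive_primary = node, disease_free_interval_months = dfi,
    n_crlm = n_crlm, largest_crlm_cm = size, cea_ng_ml = cea)
}
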