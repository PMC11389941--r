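# Quartile discretization used for mutual-information estimates; constant
# columns collapse to a single bin (zero information).
discretize_quartiles <- function(x) {
  qs <- unique(stats::quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE,
    type = 7))
  if (length(qs) == 0 || max(x) == min(x)) return(rep(1L, length(x)))
  findInterval(x, qs, left.open = TRUE) + 1L
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  expected <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / expected[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy MRMR with the difference (MID) criterion: the first feature
#' maximizes mutual information with the target; each next feature maximizes
#' relevance minus the mean mutual information with the already-selected set.
#' Features are discretized into quartiles; the target (the event indicator
#' by default) is used as-is.  Ties break by input column order, so the
#' ranking is deterministic.
#'
#' @param x numeric matrix or data frame of features (columns named).
#' @param target discrete relevance target, one value per row.
#' @param k number of features to rank.
#' @return character vector of ranked feature names, length `min(k, ncol(x))`.
#' @export
mrmr_select <- function(x, target, k = 50L) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 1, "need at least one feature")
  assert_that(length(target) == nrow(x), "target must match rows")
  assert_that(!anyNA(target), "target must be defined for every row")
  p <- ncol(x)
  k <- min(as.integer(k), p)
  disc <- lapply(seq_len(p), function(j) discretize_quartiles(x[, j]))
  relevance <- vapply(disc, function(d) mutual_information(d, target),
    numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red <- matrix(NA_real_, p, p)  # pairwise MI cache, filled lazily
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- relevance
    } else {
      mean_red <- vapply(remaining, function(j) {
        vals <- vapply(selected, function(s) {
          if (is.na(red[j, s])) {
            red[j, s] <<- red[s, j] <<- mutual_information(disc[[j]], disc[[s]])
          }
          red[j, s]
        }, numeric(1))
        mean(vals)
      }, numeric(1))
      score <- relevance[remaining] - mean_red
    }
    if (step == 1L) {
      pick <- remaining[which.max(score[remaining])]
    } else {
      pick <- remaining[which.max(score)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
  }
  colnames(x)[selected]
}

#' Univariate Cox concordance filter
#'
#' Fits a one-covariate Cox proportional-hazards model (Breslow ties) per
#' feature on the training data and keeps the feature iff the Harrell
#' concordance of its fitted risk score on the same data exceeds the
#' threshold.  Features whose fit fails or returns a non-finite coefficient
#' are dropped with a warning.
#'
#' @param x numeric matrix or data frame of features.
#' @param time,event survival outcome (months, 1 = event).
#' @param threshold concordance threshold (default 0.53).
#' @return character vector of surviving feature names.
#' @export
univariate_cox_filter <- function(x, time, event, threshold = 0.53) {
  x <- as.matrix(x)
  assert_that(sum(event) >= 1, "need at least one event",
    class = "crlmrad_estimation_error")
  keep <- character(0)
  for (j in seq_len(ncol(x))) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(time, event) ~ x[, j], ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      warning(sprintf("univariate Cox fit failed for '%s'; feature dropped",
        colnames(x)[j]))
      next
    }
    risk <- as.numeric(stats::coef(fit)) * x[, j]
    ci <- concordance_index(risk, time, event)
    if (ci > threshold) keep <- c(keep, colnames(x)[j])
  }
  keep
}

new_signature <- function(terms, provenance = list()) {
  structure(list(terms = terms, provenance = provenance),
    class = "crlm_signature")
}

#' @exportS3Method base::print
print.crlm_signature <- function(x, ...) {
  cat(sprintf("Radiomics signature with %d term(s)\n", nrow(x$terms)))
  if (nrow(x$terms)) {
    print(x$terms, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.crlm_signature <- function(object, ...) {
  stats::setNames(object$terms$coefficient, object$terms$feature)
}

#' Lasso-penalized Cox signature
#'
#' L1-penalized Cox partial likelihood over a decreasing penalty path
#' (features standardized internally; coefficients reported on the original
#' scale).  By default the penalty is chosen by 5-fold cross-validated
#' partial likelihood; a fixed `penalty` (possibly 0 for an unpenalized fit)
#' can be supplied instead.  The non-zero coefficients form the signature.
#'
#' @param x numeric matrix or data frame (>= 1 column).
#' @param time,event survival outcome; at least one event required.
#' @param penalty optional fixed lambda; `NULL` (default) selects by CV.
#' @param nfolds folds for the CV path.
#' @param lambda_choice `"min"` (default) or `"1se"`.
#' @return a `crlm_signature` whose provenance records the lambda used and
#'   the active-set sizes along the computed path.
#' @export
lasso_cox <- function(x, time, event, penalty = NULL, nfolds = 5L,
                      lambda_choice = c("min", "1se")) {
  lambda_choice <- match.arg(lambda_choice)
  x <- as.matrix(x)
  assert_that(sum(event) >= 1, "all records censored: cannot fit",
    class = "crlmrad_estimation_error")
  y <- survival::Surv(time, event)
  if (ncol(x) == 1L) {
    # glmnet needs >= 2 columns; a single candidate gets an unpenalized fit
    fit <- survival::coxph(y ~ x, ties = "breslow")
    beta <- as.numeric(stats::coef(fit))
    terms <- if (is.finite(beta) && beta != 0) {
      data.frame(feature = colnames(x), coefficient = beta,
        stringsAsFactors = FALSE)
    } else {
      data.frame(feature = character(0), coefficient = numeric(0))
    }
    return(new_signature(terms, list(lambda = 0, path_df = NA_integer_)))
  }
  if (is.null(penalty)) {
    cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = nfolds,
      standardize = TRUE)
    lambda <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
    path_df <- fit$df
  } else {
    lambda <- penalty
    fit <- glmnet::glmnet(x, y, family = "cox", standardize = TRUE,
      lambda = if (penalty == 0) c(0.01, 0) else penalty,
      thresh = 1e-14, maxit = 1e6)
    path_df <- fit$df
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  names(beta) <- colnames(x)
  nz <- which(beta != 0)
  terms <- data.frame(feature = names(beta)[nz], coefficient = beta[nz],
    stringsAsFactors = FALSE, row.names = NULL)
  new_signature(terms, list(lambda = lambda, path_df = path_df))
}

#' Score a patient with a signature
#'
#' Linear combination `sum(coefficient * feature value)`; an empty signature
#' scores 0 for everyone.
#'
#' @param signature a `crlm_signature`.
#' @param features named numeric vector, or a data frame/matrix with one row
#'   per patient and named columns.
#' @return numeric score(s).
#' @export
signature_score <- function(signature, features) {
  assert_that(inherits(signature, "crlm_signature"),
    "signature must be a crlm_signature")
  if (nrow(signature$terms) == 0) {
    n <- if (is.null(dim(features))) 1L else nrow(features)
    return(rep(0, n))
  }
  want <- signature$terms$feature
  if (is.null(dim(features))) {
    missing_f <- setdiff(want, names(features))
    if (length(missing_f)) {
      stop_crlmrad(sprintf("feature(s) missing from input: %s",
        paste(missing_f, collapse = ", ")), "crlmrad_scoring_error")
    }
    return(sum(signature$terms$coefficient * as.numeric(features[want])))
  }
  missing_f <- setdiff(want, colnames(features))
  if (length(missing_f)) {
    stop_crlmrad(sprintf("feature(s) missing from input: %s",
      paste(missing_f, collapse = ", ")), "crlmrad_scoring_error")
  }
  as.numeric(as.matrix(features[, want, drop = FALSE]) %*%
    signature$terms$coefficient)
}

#' Repeated subsampled selection cascade
#'
#' Runs the full cascade (random 85% subsample of the training set, MRMR
#' top-k, univariate Cox concordance filter, cross-validated Lasso-Cox)
#' `n_runs` times, recording which features are selected with which
#' coefficients on each run.  The consensus signature keeps features selected
#' in at least `consensus_fraction` of the runs, with the mean coefficient
#' over the runs where each was selected.  Subsamples whose events all
#' vanish are redrawn (and counted).  Only training data may be passed in;
#' the holdout set stays outside this function by construction.
#'
#' @param x training feature matrix/data frame.
#' @param time,event training outcome.
#' @param n_runs number of subsampled runs (default 100).
#' @param subsample subsample fraction (default 0.85).
#' @param k MRMR rank cutoff (default 50).
#' @param cox_threshold univariate concordance threshold (default 0.53).
#' @param consensus_fraction minimum selection fraction for the consensus
#'   signature (default 0.5).
#' @param seed base seed; run r uses `seed + r`.
#' @return object of class `crlm_selection_trace`: list with `trace`
#'   (data frame: run, feature, coefficient), `counts` (per-feature selection
#'   counts), `signature` (consensus `crlm_signature`), `n_runs`, `redraws`.
#' @export
repeated_signature <- function(x, time, event, n_runs = 100L,
                               subsample = 0.85, k = 50L,
                               cox_threshold = 0.53,
                               consensus_fraction = 0.5,
                               seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  assert_that(is_prob(subsample) && subsample > 0, "subsample must be in (0,1]")
  trace <- vector("list", n_runs)
  redraws <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    repeat {
      idx <- sample.int(n, size = max(2L, floor(subsample * n)))
      if (sum(event[idx]) >= 1) break
      redraws <- redraws + 1L
      assert_that(redraws < 50L, "could not draw a subsample with events",
        class = "crlmrad_estimation_error")
    }
    sig <- run_cascade(x[idx, , drop = FALSE], time[idx], event[idx],
      k = k, cox_threshold = cox_threshold)
    if (nrow(sig$terms)) {
      trace[[r]] <- data.frame(run = r, sig$terms, stringsAsFactors = FALSE)
    }
  }
  trace <- if (all(vapply(trace, is.null, logical(1)))) {
    data.frame(run = integer(0), feature = character(0),
      coefficient = numeric(0))
  } else {
    do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  }
  counts <- table(factor(trace$feature, levels = colnames(x)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  keep <- names(counts)[counts >= consensus_fraction * n_runs]
  terms <- if (length(keep)) {
    data.frame(
      feature = keep,
      coefficient = vapply(keep, function(f) {
        mean(trace$coefficient[trace$feature == f])
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(feature = character(0), coefficient = numeric(0))
  }
  structure(
    list(
      trace = trace, counts = counts,
      signature = new_signature(terms,
        list(n_runs = n_runs, subsample = subsample, seed = seed,
          consensus_fraction = consensus_fraction)),
      n_runs = n_runs, redraws = redraws
    ),
    class = "crlm_selection_trace"
  )
}

# One pass of the selection cascade on a (sub)sample.
run_cascade <- function(x, time, event, k = 50L, cox_threshold = 0.53) {
  ranked <- mrmr_select(x, event, k = k)
  surv <- univariate_cox_filter(x[, ranked, drop = FALSE], time, event,
    threshold = cox_threshold)
  if (length(surv) == 0) {
    return(new_signature(
      data.frame(feature = character(0), coefficient = numeric(0))))
  }
  lasso_cox(x[, surv, drop = FALSE], time, event)
}

#' @exportS3Method base::print
print.crlm_selection_trace <- function(x, ...) {
  cat(sprintf(
    "Selection trace: %d runs, %d features ever selected, %d redraw(s)\n",
    x$n_runs, sum(x$counts > 0), x$redraws))
  cat(sprintf("Consensus signature: %d term(s)\n", nrow(x$signature$terms)))
  invisible(x)
}

#' Serialize a selection trace
#'
#' Writes the per-run coefficients as CSV and a JSON summary (counts and the
#' consensus signature with provenance).
#'
#' @param trace a `crlm_selection_trace`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_selection_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trace$trace, file.path(dir, "selection_trace.csv"),
    row.names = FALSE)
  jsonlite::write_json(
    list(
      counts = as.list(trace$counts[trace$counts > 0]),
      signature = stats::setNames(
        as.list(trace$signature$terms$coefficient),
        trace$signature$terms$feature),
      provenance = trace$signature$provenance
    ),
    file.path(dir, "signature.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
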