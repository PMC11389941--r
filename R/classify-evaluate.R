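#' Harrell's concordance index
#'
#' Censoring-aware rank concordance between risk scores and outcome: a pair
#' is comparable iff the strictly earlier time is an event; a comparable pair
#' is concordant when the earlier-event subject has the higher score, and
#' tied scores earn half credit.
#'
#' @param scores per-subject risk scores (higher = higher risk).
#' @param time,event right-censored outcome.
#' @return number in [0, 1].
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  assert_that(length(time) == n && length(event) == n,
    "scores/time/event lengths differ")
  earlier <- outer(time, time, `<`) & (event == 1)  # row i earlier event
  n_comp <- sum(earlier)
  assert_that(n_comp > 0, "no comparable pairs",
    class = "crlmrad_metric_error")
  sdiff <- outer(scores, scores, `-`)
  concordant <- sum(earlier & sdiff > 0)
  tied <- sum(earlier & sdiff == 0)
  (concordant + 0.5 * tied) / n_comp
}

#' ROC area under the curve
#'
#' Rank statistic (Mann-Whitney normalization) with half credit for tied
#' scores.
#'
#' @param scores predicted scores or probabilities.
#' @param labels binary labels: logical, 0/1, or `"positive"`/`"negative"`.
#' @return number in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "positive"
  } else {
    as.logical(labels)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  assert_that(n_pos > 0 && n_neg > 0, "need both classes",
    class = "crlmrad_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Landmark dichotomization of survival outcomes
#'
#' Positive: event at or before the horizon.  Negative: observation
#' (event-free) reaching the horizon.  Censored strictly before the horizon:
#' excluded (status indeterminate).
#'
#' @param time,event right-censored outcome.
#' @param horizon_months landmark horizon (> 0); 18 months is the usual
#'   recurrence landmark, 36 months the survival landmark.
#' @return factor with levels `positive`, `negative`, `excluded`.
#' @export
dichotomize_outcome <- function(time, event, horizon_months) {
  assert_that(horizon_months > 0, "horizon must be > 0")
  lab <- ifelse(event == 1 & time <= horizon_months, "positive",
    ifelse(time >= horizon_months, "negative", "excluded"))
  factor(lab, levels = c("positive", "negative", "excluded"))
}

#' Stratified holdout and repeated-subsample plan
#'
#' Draws a holdout set of `round(fraction * n)` subjects with the event
#' proportion matched by stratified sampling on the event flag, then draws
#' `n_runs` random subsamples of `subsample` of the remaining training set
#' (redrawing any eventless subsample).  Holdout indices never appear in any
#' training subsample, by construction.
#'
#' @param event per-subject event flags for the outcome under study.
#' @param fraction holdout fraction (default 0.15).
#' @param n_runs number of training subsamples.
#' @param subsample subsample fraction of the training set (default 0.85).
#' @param seed integer seed.
#' @return object of class `crlm_split_plan`: list with `holdout`, `train`,
#'   `runs` (list of index vectors into the cohort), `seed`.
#' @export
stratified_holdout <- function(event, fraction = 0.15, n_runs = 100L,
                               subsample = 0.85, seed = 1L) {
  n <- length(event)
  ev <- which(event == 1)
  ce <- which(event == 0)
  assert_that(length(ev) >= 2 && length(ce) >= 2,
    "need at least 2 events and 2 censored records to stratify",
    class = "crlmrad_split_error")
  set.seed(seed)
  n_hold <- round(fraction * n)
  assert_that(n_hold >= 1 && n_hold < n, "holdout fraction out of range",
    class = "crlmrad_split_error")
  n_hold_ev <- min(length(ev) - 1L, max(1L, round(fraction * length(ev))))
  n_hold_ce <- min(length(ce) - 1L, max(0L, n_hold - n_hold_ev))
  holdout <- sort(c(sample(ev, n_hold_ev), sample(ce, n_hold_ce)))
  train <- setdiff(seq_len(n), holdout)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + 1000L + r)
    repeat {
      idx <- sort(sample(train, max(2L, floor(subsample * length(train)))))
      if (sum(event[idx]) >= 1) break
    }
    runs[[r]] <- idx
  }
  structure(
    list(holdout = holdout, train = train, runs = runs, seed = seed,
      fraction = fraction, subsample = subsample),
    class = "crlm_split_plan"
  )
}

#' @exportS3Method base::print
print.crlm_split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d train / %d holdout, %d subsampled runs\n",
    length(x$train), length(x$holdout), length(x$runs)))
  invisible(x)
}

# runtime leakage audit
assert_no_leakage <- function(plan) {
  for (idx in plan$runs) {
    if (length(intersect(plan$holdout, idx)) > 0) {
      stop_crlmrad("holdout indices leaked into a training subsample",
        "crlmrad_leakage_error")
    }
  }
  invisible(TRUE)
}

#' Logistic classifier on survival scores
#'
#' Logistic regression on one (score) or two (score + CRS) inputs, used as
#' the second stage that turns survival risk scores into landmark-horizon
#' class probabilities.
#'
#' @param scores training risk scores.
#' @param labels factor from [dichotomize_outcome()] (excluded rows are
#'   dropped) or binary labels.
#' @param crs optional second input column (e.g. dichotomized CRS).
#' @return object of class `crlm_score_classifier`.
#' @export
fit_score_classifier <- function(scores, labels, crs = NULL) {
  df <- data.frame(score = as.numeric(scores))
  if (!is.null(crs)) df$crs <- as.numeric(crs)
  y <- if (is.factor(labels) || is.character(labels)) {
    keep <- as.character(labels) != "excluded"
    df <- df[keep, , drop = FALSE]
    as.integer(as.character(labels)[keep] == "positive")
  } else {
    as.integer(labels)
  }
  assert_that(length(unique(y)) == 2, "need both classes to fit",
    class = "crlmrad_fit_error")
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
    data = cbind(df, y = y)))
  structure(list(fit = fit, uses_crs = !is.null(crs)),
    class = "crlm_score_classifier")
}

#' @export
predict.crlm_score_classifier <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newdata = newdata,
    type = "response"))
}

#' Direct classifier on selected radiomic features
#'
#' Baseline that classifies the landmark outcome straight from the
#' cascade-selected feature columns, by logistic regression or a probability
#' random forest.
#'
#' @param x feature data frame/matrix.
#' @param labels as in [fit_score_classifier()].
#' @param kind `"logistic"` or `"random_forest"`.
#' @param n_trees,seed random-forest settings.
#' @param ... further arguments passed to [ranger::ranger()] for the
#'   random-forest kind.
#' @return object of class `crlm_direct_classifier`.
#' @export
fit_direct_classifier <- function(x, labels, kind = c("logistic",
                                  "random_forest"), n_trees = 200L,
                                  seed = 1L, ...) {
  kind <- match.arg(kind)
  x <- as.data.frame(x, check.names = FALSE)
  if (is.factor(labels) || is.character(labels)) {
    keep <- as.character(labels) != "excluded"
    x <- x[keep, , drop = FALSE]
    y <- as.integer(as.character(labels)[keep] == "positive")
  } else {
    y <- as.integer(labels)
  }
  assert_that(length(unique(y)) == 2, "need both classes to fit",
    class = "crlmrad_fit_error")
  fit <- if (kind == "logistic") {
    suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
      data = cbind(x, y = y)))
  } else {
    ranger::ranger(y = factor(y), x = x, num.trees = n_trees,
      probability = TRUE, seed = seed, num.threads = 1, ...)
  }
  structure(list(fit = fit, kind = kind, feature_names = colnames(x)),
    class = "crlm_direct_classifier")
}

#' @export
predict.crlm_direct_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  if (object$kind == "logistic") {
    as.numeric(stats::predict(object$fit, newdata = newdata,
      type = "response"))
  } else {
    stats::predict(object$fit,
      data = newdata[, object$feature_names, drop = FALSE],
      num.threads = 1)$predictions[, "1"]
  }
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the evaluation records with replacement `n_boot` times and takes
#' the percentile interval of the metric.  Degenerate resamples (metric
#' undefined) are redrawn and counted.
#'
#' @param metric_fn function of one resampled data object returning a scalar
#'   (may error / return `NA` on degenerate resamples).
#' @param data vector or data frame of paired evaluation records.
#' @param n_boot bootstrap iterations (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(lower, upper)` with attributes `n_degenerate` and
#'   `point` (the metric on the observed data).
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 2000L, level = 0.95,
                         seed = 1L) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  assert_that(n >= 2, "need at least 2 records",
    class = "crlmrad_metric_error")
  take <- function(d, idx) if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  set.seed(seed)
  stat <- numeric(n_boot)
  degenerate <- 0L
  max_tries <- 10L * n_boot
  i <- 1L
  tries <- 0L
  while (i <= n_boot) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_crlmrad("bootstrap failed: resamples persistently degenerate",
        "crlmrad_metric_error")
    }
    v <- tryCatch(metric_fn(take(data, sample.int(n, n, replace = TRUE))),
      error = function(e) NA_real_)
    if (is.na(v)) {
      degenerate <- degenerate + 1L
      next
    }
    stat[i] <- v
    i <- i + 1L
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  point <- tryCatch(metric_fn(data), error = function(e) NA_real_)
  structure(ci, n_degenerate = degenerate, point = point)
}

#' Experiment configuration
#'
#' Defaults reproduce the full design: all seven aggregation strategies, both
#' outcomes (TTR landmark 18 months, DSS landmark 36 months), both survival
#' models with and without CRS, 100 runs of 85% training subsamples around a
#' 15% stratified holdout, and 2000-iteration bootstrap intervals.  Tests and
#' examples scale `n_runs`, `strategies` and `models` down.
#'
#' @param outcomes subset of `c("ttr", "dss")`.
#' @param strategies subset of [aggregation_strategies()].
#' @param models subset of `c("rsf", "deepsurv")`.
#' @param with_crs logical vector of CRS-concatenation settings to evaluate.
#' @param n_runs,subsample,holdout_fraction split design.
#' @param horizons named list of landmark horizons in months.
#' @param n_boot bootstrap iterations for the report intervals.
#' @param k,cox_threshold cascade settings (MRMR rank cutoff, univariate
#'   concordance threshold).
#' @param rsf_trees,rsf_min_leaf forest settings.
#' @param neural a `crlm_neural_config` (its seed is re-derived per run).
#' @param direct_baselines also fit logistic/random-forest classifiers
#'   directly on the selected features.
#' @param seed global seed.
#' @return object of class `crlm_experiment_config`.
#' @export
experiment_config <- function(outcomes = c("ttr", "dss"),
                              strategies = aggregation_strategies(),
                              models = c("rsf", "deepsurv"),
                              with_crs = c(FALSE, TRUE),
                              n_runs = 100L, subsample = 0.85,
                              holdout_fraction = 0.15,
                              horizons = list(ttr = 18, dss = 36),
                              n_boot = 2000L,
                              k = 50L, cox_threshold = 0.53,
                              rsf_trees = 200L, rsf_min_leaf = 5L,
                              neural = neural_surv_config(),
                              direct_baselines = FALSE,
                              seed = 1L) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  strategies <- match.arg(strategies, aggregation_strategies(),
    several.ok = TRUE)
  models <- match.arg(models, c("rsf", "deepsurv"), several.ok = TRUE)
  assert_that(is_prob(holdout_fraction) && holdout_fraction > 0 &&
    holdout_fraction < 1, "holdout_fraction must be in (0,1)",
    class = "crlmrad_config_error")
  assert_that(is_prob(cox_threshold), "cox_threshold must be in [0,1]",
    class = "crlmrad_config_error")
  structure(
    list(outcomes = outcomes, strategies = strategies, models = models,
      with_crs = with_crs, n_runs = as.integer(n_runs),
      subsample = subsample, holdout_fraction = holdout_fraction,
      horizons = horizons, n_boot = as.integer(n_boot), k = as.integer(k),
      cox_threshold = cox_threshold, rsf_trees = as.integer(rsf_trees),
      rsf_min_leaf = as.integer(rsf_min_leaf), neural = neural,
      direct_baselines = direct_baselines, seed = as.integer(seed)),
    class = "crlm_experiment_config"
  )
}

#' Run the full repeated-split evaluation experiment
#'
#' For each outcome: draws one stratified holdout; then, for every
#' aggregation strategy and training subsample, runs the selection cascade,
#' fits the requested survival models on the selected features (with and/or
#' without CRS), scores the holdout, and records the holdout concordance
#' index of each risk score plus the landmark-classification AUC of logistic
#' models on the signature and survival scores.  Any stage failure marks
#' that run's cell incomplete instead of aborting.  Point estimates are
#' means over runs; intervals are percentile bootstraps over the per-run
#' holdout metrics.
#'
#' @param cohort a `crlm_cohort` (or a list with compatible `patients` and
#'   `lesions` tables).
#' @param config a `crlm_experiment_config`.
#' @return object of class `crlm_eval_report`: list with `summary` (long
#'   data frame: outcome, strategy, model, crs_flag, metric, estimate,
#'   ci_lo, ci_hi, n_runs, n_complete), `runs` (per-run metric values) and
#'   `plans`.
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  assert_that(inherits(config, "crlm_experiment_config"),
    "config must come from experiment_config()", class = "crlmrad_config_error")
  patients <- cohort$patients
  lesions <- cohort$lesions
  n <- nrow(patients)
  crs_high <- as.integer(patients$crs_high %||%
    (dichotomize_crs(patients$crs) == "high"))
  rows <- list()
  plans <- list()
  for (outcome in config$outcomes) {
    time <- patients[[paste0(outcome, "_months")]]
    event <- patients[[paste0(outcome, "_event")]]
    horizon <- config$horizons[[outcome]]
    plan <- stratified_holdout(event, config$holdout_fraction,
      n_runs = config$n_runs, subsample = config$subsample,
      seed = config$seed)
    assert_no_leakage(plan)
    plans[[outcome]] <- plan
    ho <- plan$holdout
    ho_labels <- dichotomize_outcome(time[ho], event[ho], horizon)
    # CRS-alone baselines (identical across runs and strategies)
    crs_ci <- tryCatch(concordance_index(crs_high[ho], time[ho], event[ho]),
      error = function(e) NA_real_)
    crs_auc <- tryCatch(roc_auc(crs_high[ho][ho_labels != "excluded"],
      ho_labels[ho_labels != "excluded"]), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = outcome, strategy = "none", model = "crs",
      crs_flag = TRUE, metric = c("cindex", "auc"), run = NA_integer_,
      value = c(crs_ci, crs_auc), stringsAsFactors = FALSE)
    for (strategy in config$strategies) {
      agg <- aggregate_cohort(lesions, strategy)
      agg <- agg[match(patients$patient_id, agg$patient_id), , drop = FALSE]
      X <- agg[, setdiff(names(agg), "patient_id"), drop = FALSE]
      for (r in seq_len(config$n_runs)) {
        idx <- plan$runs[[r]]
        run_seed <- config$seed + 7919L * r
        res <- evaluate_one_run(X, time, event, idx, ho, ho_labels,
          horizon, crs_high, config, run_seed)
        if (nrow(res)) {
          res$outcome <- outcome
          res$strategy <- strategy
          res$run <- r
          rows[[length(rows) + 1L]] <- res[, c("outcome", "strategy",
            "model", "crs_flag", "metric", "run", "value")]
        }
      }
    }
  }
  runs_df <- do.call(rbind, rows)
  rownames(runs_df) <- NULL
  summary_df <- summarize_runs(runs_df, config)
  structure(
    list(summary = summary_df, runs = runs_df, plans = plans,
      config = config),
    class = "crlm_eval_report"
  )
}

# one training subsample: cascade + models + classification metrics
evaluate_one_run <- function(X, time, event, idx, ho, ho_labels, horizon,
                             crs_high, config, run_seed) {
  out <- list()
  tr_labels <- dichotomize_outcome(time[idx], event[idx], horizon)
  add <- function(model, crs_flag, metric, value) {
    out[[length(out) + 1L]] <<- data.frame(model = model,
      crs_flag = crs_flag, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  set.seed(run_seed)
  sig <- tryCatch(
    run_cascade(X[idx, , drop = FALSE], time[idx], event[idx],
      k = config$k, cox_threshold = config$cox_threshold),
    error = function(e) NULL)
  selected <- if (is.null(sig)) character(0) else sig$terms$feature
  lab_keep <- ho_labels != "excluded"
  if (!is.null(sig) && length(selected)) {
    sc_tr <- signature_score(sig, X[idx, , drop = FALSE])
    sc_ho <- signature_score(sig, X[ho, , drop = FALSE])
    add("signature", FALSE, "cindex", tryCatch(
      concordance_index(sc_ho, time[ho], event[ho]),
      error = function(e) NA_real_))
    # classification stage: logistic on training scores, applied to holdout
    for (use_crs in unique(config$with_crs)) {
      cls <- tryCatch(
        fit_score_classifier(sc_tr, tr_labels,
          crs = if (use_crs) crs_high[idx] else NULL),
        error = function(e) NULL)
      if (is.null(cls)) {
        add("signature", use_crs, "auc", NA_real_)
        next
      }
      nd <- data.frame(score = sc_ho)
      if (use_crs) nd$crs <- crs_high[ho]
      p <- predict(cls, nd)
      add("signature", use_crs, "auc", tryCatch(
        roc_auc(p[lab_keep], ho_labels[lab_keep]),
        error = function(e) NA_real_))
    }
  } else {
    add("signature", FALSE, "cindex", NA_real_)
    for (use_crs in unique(config$with_crs)) {
      add("signature", use_crs, "auc", NA_real_)
    }
  }
  if (length(selected)) {
    for (model in config$models) {
      for (use_crs in config$with_crs) {
        Xtr <- X[idx, selected, drop = FALSE]
        Xho <- X[ho, selected, drop = FALSE]
        if (use_crs) {
          Xtr <- attach_crs(Xtr, crs_high[idx] == 1L)
          Xho <- attach_crs(Xho, crs_high[ho] == 1L)
        }
        fit <- tryCatch(
          if (model == "rsf") {
            fit_rsf(Xtr, time[idx], event[idx],
              n_trees = config$rsf_trees, min_leaf = config$rsf_min_leaf,
              seed = run_seed)
          } else {
            cfg <- config$neural
            cfg$seed <- run_seed
            fit_neural_surv(Xtr, time[idx], event[idx], cfg)
          },
          error = function(e) NULL)
        if (is.null(fit)) {
          add(model, use_crs, "cindex", NA_real_)
          next
        }
        risk_ho <- predict_risk(fit, Xho)
        add(model, use_crs, "cindex", tryCatch(
          concordance_index(risk_ho, time[ho], event[ho]),
          error = function(e) NA_real_))
        if (model == "deepsurv") {
          # classification on the DeepSurv score
          risk_tr <- predict_risk(fit, Xtr)
          cls <- tryCatch(fit_score_classifier(risk_tr, tr_labels),
            error = function(e) NULL)
          auc <- if (is.null(cls)) NA_real_ else tryCatch(
            roc_auc(predict(cls, data.frame(score = risk_ho))[lab_keep],
              ho_labels[lab_keep]),
            error = function(e) NA_real_)
          add("deepsurv_score", use_crs, "auc", auc)
        }
      }
    }
    if (isTRUE(config$direct_baselines)) {
      for (kind in c("logistic", "random_forest")) {
        cls <- tryCatch(
          fit_direct_classifier(X[idx, selected, drop = FALSE], tr_labels,
            kind = kind, seed = run_seed),
          error = function(e) NULL)
        auc <- if (is.null(cls)) NA_real_ else tryCatch(
          roc_auc(predict(cls, X[ho, selected, drop = FALSE])[lab_keep],
            ho_labels[lab_keep]),
          error = function(e) NA_real_)
        add(paste0("direct_", kind), FALSE, "auc", auc)
      }
    }
  } else {
    for (model in config$models) {
      for (use_crs in config$with_crs) add(model, use_crs, "cindex", NA_real_)
    }
  }
  do.call(rbind, out)
}

summarize_runs <- function(runs_df, config) {
  keys <- unique(runs_df[, c("outcome", "strategy", "model", "crs_flag",
    "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    kk <- keys[i, ]
    sel <- runs_df$outcome == kk$outcome & runs_df$strategy == kk$strategy &
      runs_df$model == kk$model & runs_df$crs_flag == kk$crs_flag &
      runs_df$metric == kk$metric
    v <- runs_df$value[sel]
    ok <- v[!is.na(v)]
    if (length(ok) == 0) {
      est <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else if (length(ok) == 1) {
      est <- ok; lo <- ok; hi <- ok
    } else {
      est <- mean(ok)
      ci <- bootstrap_ci(mean, ok, n_boot = config$n_boot,
        seed = config$seed)
      lo <- ci[1]; hi <- ci[2]
    }
    data.frame(kk, estimate = est, ci_lo = lo, ci_hi = hi,
      n_runs = sum(sel), n_complete = length(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @exportS3Method base::print
print.crlm_eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation report: %d cells over %d run(s)\n",
    nrow(x$summary), x$config$n_runs))
  df <- x$summary
  df$estimate <- round(df$estimate, digits)
  df$ci_lo <- round(df$ci_lo, digits)
  df$ci_hi <- round(df$ci_hi, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Long-format CSV of the summary plus a JSON copy with the configuration.
#'
#' @param report a `crlm_eval_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "eval_report.csv"),
    row.names = FALSE)
  cfg <- report$config
  cfg$neural <- unclass(cfg$neural)
  jsonlite::write_json(
    list(summary = report$summary, config = unclass(cfg)),
    file.path(dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
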