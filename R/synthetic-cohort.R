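#' Configuration for the synthetic CRLM cohort generator
#'
#' Defines the statistical structure of a simulated colorectal-liver-metastasis
#' cohort: per-lesion radiomics-like features in equicorrelated Gaussian
#' blocks, log-normal lesion volumes, clinical fields spanning the Fong score
#' range, and right-censored time-to-recurrence (TTR) and disease-specific
#' survival (DSS) outcomes drawn from an exponential proportional-hazards
#' model.  The informative features are planted in the *largest* lesion of
#' each patient, so aggregation strategies that privilege the largest lesion
#' can recover the signal while smallest-lesion aggregation cannot.
#'
#' @param n_patients number of patients (>= 1).
#' @param lesion_count_law list with `lambda`: lesions per patient are
#'   `1 + Poisson(lambda)` so every patient has at least one lesion; the
#'   default `lambda = 2` gives a mean of 3 lesions.
#' @param n_features number of per-lesion features.
#' @param n_informative number of features that enter the hazard.
#' @param true_betas log-hazard coefficients per standard deviation for the
#'   informative features (recycled to length `n_informative`).
#' @param crs_beta log-hazard coefficient for the dichotomized clinical risk
#'   score (high = 1).
#' @param baseline_hazard constant baseline hazard rate in 1/month.
#' @param censor_law list with `horizon` (administrative censoring horizon in
#'   months, may be `Inf`) and `rate` (rate of an independent exponential
#'   random-censoring time; 0 disables random censoring).
#' @param correlation within-block feature correlation in [0, 1); features are
#'   grouped in blocks of `block_size`.
#' @param block_size features per correlation block.
#' @param dss_hazard_ratio multiplier applied to `baseline_hazard` for the DSS
#'   outcome (death is rarer than recurrence).
#' @param volume_meanlog,volume_sdlog log-normal parameters for lesion volume
#'   in mm^3.
#' @param seed integer seed; the whole cohort is reproducible from it.
#'
#' @return an object of class `crlm_synth_config`.
#' @export
synthetic_config <- function(n_patients = 300L,
                             lesion_count_law = list(lambda = 2),
                             n_features = 60L,
                             n_informative = 3L,
                             true_betas = 0.7,
                             crs_beta = 0.4,
                             baseline_hazard = 0.02,
                             censor_law = list(horizon = 84, rate = 0.006),
                             correlation = 0.3,
                             block_size = 10L,
                             dss_hazard_ratio = 0.5,
                             volume_meanlog = log(9000),
                             volume_sdlog = 1.1,
                             seed = 1L) {
  assert_that(is_count(n_patients), "n_patients must be a positive integer",
    class = "crlmrad_config_error")
  assert_that(is_count(n_features) && is_count(n_informative),
    "feature counts must be positive integers", class = "crlmrad_config_error")
  assert_that(n_informative <= n_features,
    "n_informative must not exceed n_features", class = "crlmrad_config_error")
  assert_that(is.numeric(baseline_hazard) && baseline_hazard > 0,
    "baseline_hazard must be > 0", class = "crlmrad_config_error")
  assert_that(is.numeric(lesion_count_law$lambda) && lesion_count_law$lambda >= 0,
    "lesion_count_law$lambda must be >= 0", class = "crlmrad_config_error")
  assert_that(is.numeric(correlation) && correlation >= 0 && correlation < 1,
    "correlation must be in [0, 1)", class = "crlmrad_config_error")
  assert_that(is.numeric(censor_law$horizon) && censor_law$horizon > 0,
    "censor horizon must be > 0", class = "crlmrad_config_error")
  assert_that(is.numeric(censor_law$rate) && censor_law$rate >= 0,
    "censor rate must be >= 0", class = "crlmrad_config_error")
  true_betas <- rep_len(as.numeric(true_betas), n_informative)
  structure(
    list(
      n_patients = as.integer(n_patients),
      lesion_count_law = lesion_count_law,
      n_features = as.integer(n_features),
      n_informative = as.integer(n_informative),
      true_betas = true_betas,
      crs_beta = crs_beta,
      baseline_hazard = baseline_hazard,
      censor_law = censor_law,
      correlation = correlation,
      block_size = as.integer(block_size),
      dss_hazard_ratio = dss_hazard_ratio,
      volume_meanlog = volume_meanlog,
      volume_sdlog = volume_sdlog,
      seed = as.integer(seed)
    ),
    class = "crlm_synth_config"
  )
}

#' Feature names used by the synthetic generator
#'
#' Informative features carry the reserved prefix `inf_`, noise features the
#' prefix `noise_`, so selection modules can be scored for recovery.
#'
#' @param config a `crlm_synth_config`.
#' @return character vector of length `n_features`.
#' @export
synthetic_feature_names <- function(config) {
  c(
    sprintf("inf_%02d", seq_len(config$n_informative)),
    sprintf("noise_%03d", seq_len(config$n_features - config$n_informative))
  )
}

# Draw an (n x p) matrix of equicorrelated-block standard Gaussians.
draw_block_features <- function(n, p, rho, block_size) {
  blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
  x <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    for (idx in blocks) {
      shared <- stats::rnorm(n)
      x[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * x[, idx, drop = FALSE]
    }
  }
  x
}

#' Generate a synthetic CRLM cohort
#'
#' Draws patients with 1+ lesions each, per-lesion feature vectors and
#' volumes, clinical fields for the Fong score, and censored TTR/DSS outcomes
#' from an exponential proportional-hazards model.  The hazard linear
#' predictor is `sum(beta_j * x_j)` over the informative features of the
#' patient's largest lesion, plus `crs_beta` times the dichotomized clinical
#' risk score (high = 1).
#'
#' @param config a `crlm_synth_config` from [synthetic_config()].
#' @return an object of class `crlm_cohort`: a list with elements
#'   `patients` (one row per patient: clinical fields, `crs`, `crs_high`,
#'   `ttr_months`, `ttr_event`, `dss_months`, `dss_event`), `lesions`
#'   (one row per lesion: `patient_id`, `lesion_id`, `volume_mm3` and the
#'   feature columns), `config`, and a `latent` table of generation-time
#'   truths (linear predictor, latent event and censoring times) used only by
#'   diagnostics and tests.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "crlm_synth_config"),
    "config must be created by synthetic_config()", class = "crlmrad_config_error")
  set.seed(config$seed)
  n <- config$n_patients
  fnames <- synthetic_feature_names(config)
  m <- 1L + stats::rpois(n, config$lesion_count_law$lambda)
  patient_id <- sprintf("P%04d", seq_len(n))

  lesion_rows <- vector("list", n)
  lp_feat <- numeric(n)
  largest_cm <- numeric(n)
  for (i in seq_len(n)) {
    x <- draw_block_features(m[i], config$n_features, config$correlation,
      config$block_size)
    colnames(x) <- fnames
    vol <- stats::rlnorm(m[i], config$volume_meanlog, config$volume_sdlog)
    largest <- which.max(vol)
    lp_feat[i] <- sum(config$true_betas *
      x[largest, seq_len(config$n_informative)])
    largest_cm[i] <- (6 * max(vol) / pi)^(1 / 3) / 10  # equivalent sphere diameter, cm
    lesion_rows[[i]] <- data.frame(
      patient_id = patient_id[i],
      lesion_id = sprintf("L%02d", seq_len(m[i])),
      volume_mm3 = vol,
      x,
      stringsAsFactors = FALSE
    )
  }
  lesions <- do.call(rbind, lesion_rows)
  rownames(lesions) <- NULL

  # Clinical profile: marginals chosen so the Fong score concentrates on 2-3.
  node_positive <- stats::rbinom(n, 1, 0.6) == 1
  dfi <- stats::rexp(n, 1 / 15)
  cea <- stats::rlnorm(n, log(15), 1.8)
  profile <- data.frame(
    patient_id = patient_id,
    node_positive_primary = node_positive,
    disease_free_interval_months = dfi,
    n_crlm = m,
    largest_crlm_cm = largest_cm,
    cea_ng_ml = cea,
    stringsAsFactors = FALSE
  )
  crs <- vapply(seq_len(n), function(i) fong_crs(profile[i, ]), integer(1))
  crs_high <- crs >= 3L
  lp <- lp_feat + config$crs_beta * as.numeric(crs_high)

  draw_outcome <- function(hazard) {
    latent <- stats::rexp(n, 1) / (hazard * exp(lp))
    cens <- if (config$censor_law$rate > 0) {
      stats::rexp(n, config$censor_law$rate)
    } else {
      rep(Inf, n)
    }
    cens <- pmin(cens, config$censor_law$horizon)
    list(
      time = pmin(latent, cens),
      event = as.integer(latent <= cens),
      latent = latent,
      cens = cens
    )
  }
  ttr <- draw_outcome(config$baseline_hazard)
  dss <- draw_outcome(config$baseline_hazard * config$dss_hazard_ratio)

  patients <- cbind(
    profile,
    data.frame(
      crs = crs,
      crs_high = crs_high,
      ttr_months = ttr$time, ttr_event = ttr$event,
      dss_months = dss$time, dss_event = dss$event
    )
  )
  latent <- data.frame(
    patient_id = patient_id,
    linear_predictor = lp,
    ttr_latent = ttr$latent, ttr_censor = ttr$cens,
    dss_latent = dss$latent, dss_censor = dss$cens
  )
  structure(
    list(patients = patients, lesions = lesions, config = config,
      latent = latent),
    class = "crlm_cohort"
  )
}

#' @exportS3Method base::print
print.crlm_cohort <- function(x, ...) {
  cat("Synthetic CRLM cohort\n")
  n_feat <- x$config$n_features %||% (ncol(x$lesions) - 3L)
  cat(sprintf("  patients: %d   lesions: %d   features/lesion: %d\n",
    nrow(x$patients), nrow(x$lesions), n_feat))
  cat(sprintf("  TTR events: %d (%.0f%%)   DSS events: %d (%.0f%%)\n",
    sum(x$patients$ttr_event), 100 * mean(x$patients$ttr_event),
    sum(x$patients$dss_event), 100 * mean(x$patients$dss_event)))
  invisible(x)
}

#' Extract one patient's bundle from a cohort
#'
#' @param cohort a `crlm_cohort`.
#' @param patient_id patient identifier.
#' @return list with `lesions` (data frame), `clinical` (one-row data frame)
#'   and `patient_id`.
#' @export
patient_bundle <- function(cohort, patient_id) {
  assert_that(inherits(cohort, "crlm_cohort"), "cohort must be a crlm_cohort")
  assert_that(patient_id %in% cohort$patients$patient_id,
    sprintf("unknown patient_id '%s'", patient_id))
  list(
    patient_id = patient_id,
    lesions = cohort$lesions[cohort$lesions$patient_id == patient_id, ,
      drop = FALSE],
    clinical = cohort$patients[cohort$patients$patient_id == patient_id, ,
      drop = FALSE]
  )
}

#' Exact hazard linear predictor used at generation time
#'
#' Recomputes, from a patient bundle, the linear predictor that drove that
#' patient's simulated event times: the informative features of the largest
#' lesion weighted by `true_betas`, plus `crs_beta` for a high clinical risk
#' score.  Serves as the oracle risk score in parameter-recovery tests.
#'
#' @param bundle a patient bundle from [patient_bundle()].
#' @param config the `crlm_synth_config` the cohort was generated under.
#' @return the linear predictor (a single number).
#' @export
true_linear_predictor <- function(bundle, config) {
  assert_that(inherits(config, "crlm_synth_config"),
    "config must be a crlm_synth_config", class = "crlmrad_config_error")
  fnames <- synthetic_feature_names(config)
  inf <- fnames[seq_len(config$n_informative)]
  if (!all(inf %in% names(bundle$lesions))) {
    stop_crlmrad("bundle does not carry this config's informative features",
      "crlmrad_mismatch_error")
  }
  les <- bundle$lesions
  largest <- order(-les$volume_mm3, les$lesion_id)[1L]
  lp <- sum(config$true_betas * as.numeric(les[largest, inf]))
  crs_high <- bundle$clinical$crs_high %||%
    (fong_crs(bundle$clinical) >= 3L)
  lp + config$crs_beta * as.numeric(crs_high)
}

#' Write a cohort to plain-text tables
#'
#' Writes `lesions.csv`, `patients.csv` and a JSON sidecar of the generation
#' parameters into `dir`.
#'
#' @param cohort a `crlm_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "crlm_cohort"), "cohort must be a crlm_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"),
    row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
    row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
    file.path(dir, "generation_params.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
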