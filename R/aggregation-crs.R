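#' Available multi-lesion aggregation strategies
#'
#' @return character vector of the seven strategy ids.
#' @export
aggregation_strategies <- function() {
  c("largest_only", "smallest_only", "unweighted_average",
    "weighted_average", "weighted_average_top3",
    "largest_plus_count", "largest_plus_total_volume")
}

#' Assign geometric/texture roles to feature names
#'
#' Aggregation sums geometric features over lesions and averages texture
#' features.  By default shape-family features and the appended burden
#' features (`n_lesions`, `total_volume_mm3`, `volume_mm3`) are geometric and
#' every intensity/texture family (first-order included) is texture; the map
#' is overridable.
#'
#' @param feature_names character vector.
#' @param overrides optional named character vector/list mapping feature names
#'   to `"geometric"` or `"texture"`.
#' @return named character vector with values `"geometric"` or `"texture"`.
#' @export
feature_roles <- function(feature_names, overrides = NULL) {
  roles <- ifelse(
    grepl("(^|__)shape__", feature_names) |
      feature_names %in% c("volume_mm3", "n_lesions", "total_volume_mm3"),
    "geometric", "texture")
  names(roles) <- feature_names
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), feature_names)
    if (length(unknown)) {
      stop_crlmrad(sprintf("role override for unknown feature(s): %s",
        paste(unknown, collapse = ", ")), "crlmrad_taxonomy_error")
    }
    bad <- !overrides %in% c("geometric", "texture")
    assert_that(!any(bad), "roles must be 'geometric' or 'texture'",
      class = "crlmrad_taxonomy_error")
    roles[names(overrides)] <- overrides
  }
  roles
}

# order lesions by decreasing volume, ties broken by lexicographic lesion_id
lesion_order <- function(lesions) {
  order(-lesions$volume_mm3, as.character(lesions$lesion_id))
}

#' Aggregate per-lesion features to one patient-level vector
#'
#' Implements the seven aggregation strategies: copy the largest (or
#' smallest) lesion; average across lesions (unweighted, volume-ratio
#' weighted, or volume-ratio weighted over the three largest); or copy the
#' largest lesion and append a tumor-burden feature (`n_lesions` or
#' `total_volume_mm3`).  In every multi-lesion strategy geometric features
#' are summed over the included lesions while texture features are averaged
#' (with the strategy's volume-ratio weights, renormalized over the included
#' lesions, where applicable).
#'
#' @param lesions data frame with `patient_id`, `lesion_id`, `volume_mm3` and
#'   feature columns, all rows belonging to one patient.
#' @param strategy one of [aggregation_strategies()].
#' @param roles named role vector from [feature_roles()]; computed from the
#'   column names when `NULL`.
#' @return named numeric patient-level feature vector (burden features
#'   appended where the strategy defines them).
#' @export
aggregate_lesions <- function(lesions, strategy = "largest_only",
                              roles = NULL) {
  strategy <- match.arg(strategy, aggregation_strategies())
  assert_that(nrow(lesions) >= 1, "need at least one lesion")
  meta <- c("patient_id", "lesion_id", "volume_mm3")
  fnames <- setdiff(names(lesions), meta)
  if (is.null(roles)) {
    roles <- feature_roles(fnames)
  } else {
    unknown <- setdiff(fnames, names(roles))
    if (length(unknown)) {
      stop_crlmrad(sprintf("no role declared for feature(s): %s",
        paste(utils::head(unknown, 5), collapse = ", ")),
        "crlmrad_taxonomy_error")
    }
  }
  x <- as.matrix(lesions[, fnames, drop = FALSE])
  vol <- lesions$volume_mm3
  ord <- lesion_order(lesions)
  single <- function(i) stats::setNames(as.numeric(x[i, ]), fnames)
  combine <- function(idx, weights = NULL) {
    xi <- x[idx, , drop = FALSE]
    if (is.null(weights)) {
      w <- rep(1 / length(idx), length(idx))
    } else {
      w <- weights / sum(weights)
    }
    is_geo <- roles[fnames] == "geometric"
    out <- numeric(length(fnames))
    out[is_geo] <- colSums(xi[, is_geo, drop = FALSE])
    out[!is_geo] <- as.numeric(crossprod(xi[, !is_geo, drop = FALSE], w))
    stats::setNames(out, fnames)
  }
  switch(strategy,
    largest_only = single(ord[1]),
    smallest_only = single(ord[length(ord)]),
    unweighted_average = combine(seq_len(nrow(x))),
    weighted_average = combine(seq_len(nrow(x)), weights = vol),
    weighted_average_top3 = {
      idx <- ord[seq_len(min(3L, length(ord)))]
      combine(idx, weights = vol[idx])
    },
    largest_plus_count = c(single(ord[1]), n_lesions = nrow(lesions)),
    largest_plus_total_volume = c(single(ord[1]),
      total_volume_mm3 = sum(vol))
  )
}

#' Build a patient-level feature table for one strategy
#'
#' Applies [aggregate_lesions()] per patient over a cohort lesion table.
#'
#' @param lesions lesion table (data frame, many patients).
#' @param strategy one of [aggregation_strategies()].
#' @param roles optional role map.
#' @return data frame with `patient_id` and patient-level feature columns,
#'   plus a `strategy` attribute.
#' @export
aggregate_cohort <- function(lesions, strategy = "largest_only",
                             roles = NULL) {
  strategy <- match.arg(strategy, aggregation_strategies())
  ids <- unique(lesions$patient_id)
  rows <- lapply(ids, function(pid) {
    v <- aggregate_lesions(
      lesions[lesions$patient_id == pid, , drop = FALSE], strategy, roles)
    data.frame(patient_id = pid, as.list(v), check.names = FALSE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  out
}

#' Fong clinical risk score
#'
#' One point for each of: node-positive primary cancer; disease-free interval
#' from primary to CRLM diagnosis under 12 months; more than one CRLM;
#' largest CRLM over 5 cm; preoperative CEA over 200 ng/mL.  All inequalities
#' are strict, so boundary values (exactly 12 months, exactly 5 cm, exactly
#' 200 ng/mL) score no point.
#'
#' @param profile list or one-row data frame with `node_positive_primary`,
#'   `disease_free_interval_months`, `n_crlm`, `largest_crlm_cm`,
#'   `cea_ng_ml`.
#' @return integer score in 0..5.
#' @export
fong_crs <- function(profile) {
  need <- c("node_positive_primary", "disease_free_interval_months",
    "n_crlm", "largest_crlm_cm", "cea_ng_ml")
  missing_f <- need[!vapply(need, function(f) {
    !is.null(profile[[f]]) && !is.na(profile[[f]])
  }, logical(1))]
  assert_that(length(missing_f) == 0,
    sprintf("clinical profile incomplete: %s", paste(missing_f, collapse = ", ")),
    class = "crlmrad_profile_error")
  as.integer(
    isTRUE(as.logical(profile$node_positive_primary)) +
      (profile$disease_free_interval_months < 12) +
      (profile$n_crlm > 1) +
      (profile$largest_crlm_cm > 5) +
      (profile$cea_ng_ml > 200)
  )
}

#' Dichotomize the Fong score
#'
#' Scores 0-2 are low risk, 3-5 high risk.
#'
#' @param score integer in 0..5.
#' @return `"low"` or `"high"`.
#' @export
dichotomize_crs <- function(score) {
  assert_that(all(score %in% 0:5), "CRS must be an integer in 0..5",
    class = "crlmrad_domain_error")
  ifelse(score <= 2, "low", "high")
}
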