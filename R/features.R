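#' First-order intensity statistics
#'
#' Computes intensity statistics over the in-mask voxels: mean, median,
#' population variance, skewness (`m3 / m2^1.5`), kurtosis (`m4 / m2^2`,
#' Pearson convention, 3 for a Gaussian), energy (sum of squares), minimum,
#' maximum, range, and base-2 Shannon entropy of the fixed-bin-width
#' discretized histogram (occupied bins).  Skewness and kurtosis of a
#' constant region are defined as 0.
#'
#' @param values numeric vector of in-mask intensities (already clipped).
#' @param config a `crlm_preprocess_config` (supplies the discretization for
#'   the entropy).
#' @return named numeric vector.
#' @export
first_order_features <- function(values, config = preprocess_config()) {
  assert_that(length(values) >= 1, "need at least one in-mask voxel",
    class = "crlmrad_degenerate_error")
  v <- as.numeric(values)
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  bins <- discretize(v, config)
  p <- tabulate(bins, attr(bins, "n_bins")) / n
  p <- p[p > 0]
  c(
    mean = mu,
    median = stats::median(v),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(v^2),
    minimum = min(v),
    maximum = max(v),
    range = max(v) - min(v),
    entropy = -sum(p * log2(p))
  )
}

# Exposed-face count per axis pair: faces between an in-mask voxel and an
# out-of-mask (or out-of-grid) neighbour.
surface_area_faces <- function(mask, spacing) {
  d <- dim(mask)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
    spacing[1] * spacing[2])
  for (a in 1:3) {
    n <- dim(pad)[a]
    lo <- switch(a, pad[-n, , ], pad[, -n, ], pad[, , -n])
    hi <- switch(a, pad[-1, , ], pad[, -1, ], pad[, , -1])
    area <- area + sum(lo != hi) * face_area[a]
  }
  area
}

#' Shape features of a binary lesion mask
#'
#' Voxel-count volume, exposed-face surface area, surface-to-volume ratio,
#' maximum 3-D diameter (largest center-to-center distance between surface
#' voxels; 0 for a single voxel), and sphericity
#' `pi^(1/3) * (6V)^(2/3) / A`.
#'
#' @param mask binary 3-D array (or `crlm_volume`); nonzero = lesion.
#' @param spacing_mm voxel spacing (taken from the volume if available).
#' @return named numeric vector.
#' @export
shape_features <- function(mask, spacing_mm = attr(mask, "spacing_mm")) {
  assert_that(!is.null(spacing_mm), "spacing_mm required")
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  m <- array(as.integer(mask > 0), dim = dim(mask))
  nvox <- sum(m)
  assert_that(nvox > 0, "mask is empty", class = "crlmrad_degenerate_error")
  vol <- nvox * prod(spacing_mm)
  area <- surface_area_faces(m, spacing_mm)
  # surface voxels: at least one exposed face
  idx <- which(m == 1L, arr.ind = TRUE)
  on_surface <- vapply(seq_len(nrow(idx)), function(r) {
    p <- idx[r, ]
    for (a in 1:3) for (s in c(-1L, 1L)) {
      q <- p
      q[a] <- q[a] + s
      if (q[a] < 1L || q[a] > dim(m)[a] || m[q[1], q[2], q[3]] == 0L) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  surf <- idx[on_surface, , drop = FALSE]
  max_diam <- if (nrow(surf) < 2) 0 else {
    pts <- sweep(surf, 2, spacing_mm, `*`)
    max(stats::dist(pts))
  }
  c(
    volume_mm3 = vol,
    surface_area_mm2 = area,
    surface_to_volume_ratio = area / vol,
    max_diameter_3d_mm = max_diam,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  )
}

# Shift-based extraction of in-mask neighbour pairs for one offset.
offset_pairs <- function(bins, mask, off) {
  d <- dim(bins)
  rng <- function(a) {
    lo <- max(1L, 1L - off[a])
    hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(NULL)
    seq.int(lo, hi)
  }
  rx <- rng(1); ry <- rng(2); rz <- rng(3)
  if (is.null(rx) || is.null(ry) || is.null(rz)) {
    return(list(a = integer(0), b = integer(0)))
  }
  a_bin <- bins[rx, ry, rz, drop = FALSE]
  b_bin <- bins[rx + off[1], ry + off[2], rz + off[3], drop = FALSE]
  a_in <- mask[rx, ry, rz, drop = FALSE] == 1L
  b_in <- mask[rx + off[1], ry + off[2], rz + off[3], drop = FALSE] == 1L
  keep <- a_in & b_in
  list(a = a_bin[keep], b = b_bin[keep])
}

glcm_from_counts <- function(counts) {
  p <- counts / sum(counts)
  n <- nrow(p)
  lev <- seq_len(n)
  px <- rowSums(p)
  mu_x <- sum(lev * px)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  ij <- outer(lev, lev, function(i, j) i - j)
  corr <- if (sd_x > 0) {
    sum(outer(lev - mu_x, lev - mu_x) * p) / sd_x^2
  } else {
    1
  }
  pe <- p[p > 0]
  c(
    contrast = sum(p * ij^2),
    correlation = corr,
    joint_entropy = -sum(pe * log2(pe)),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(ij)))
  )
}

#' Gray-level co-occurrence matrix features
#'
#' Accumulates a symmetric GLCM at distance 1 over the 13 unique 3-D
#' directions, restricted to in-mask voxel pairs; each direction's matrix is
#' normalized and its features computed, then features are averaged over the
#' directions that contain at least one pair.  Returns contrast, correlation
#' (1 for a degenerate single-level region), joint entropy (base 2), energy
#' (angular second moment), and homogeneity (inverse difference).
#'
#' @param bins integer 3-D array of bin labels (from [discretize()]).
#' @param mask binary 3-D array, same dimensions.
#' @param n_bins number of gray levels (defaults to the `n_bins` attribute of
#'   `bins`, else `max(bins)`).
#' @return named numeric vector.
#' @export
glcm_features <- function(bins, mask, n_bins = attr(bins, "n_bins")) {
  m <- array(as.integer(mask > 0), dim = dim(mask))
  assert_that(sum(m) >= 2, "need at least 2 in-mask voxels",
    class = "crlmrad_degenerate_error")
  if (is.null(n_bins)) n_bins <- max(bins)
  b <- array(as.integer(bins), dim = dim(bins))
  offs <- direction_offsets_13()
  acc <- NULL
  n_dir <- 0L
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(b, m, offs[r, ])
    if (length(pr$a) == 0) next
    k <- (pr$a - 1L) * n_bins + pr$b
    counts <- matrix(tabulate(k, n_bins * n_bins), n_bins, n_bins, byrow = TRUE)
    counts <- counts + t(counts)  # symmetric accumulation
    f <- glcm_from_counts(counts)
    acc <- if (is.null(acc)) f else acc + f
    n_dir <- n_dir + 1L
  }
  assert_that(n_dir > 0, "no in-mask voxel pairs in any direction",
    class = "crlmrad_degenerate_error")
  acc / n_dir
}

# Enumerate in-mask runs along one direction; returns data frame of
# (level, length) counts.
runs_one_direction <- function(bins, mask, off) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  a0 <- which(off != 0)[1]
  t_pos <- idx[, a0] * sign(off[a0])
  line_key <- idx - outer(t_pos, off)
  key_id <- paste(line_key[, 1], line_key[, 2], line_key[, 3], sep = ",")
  ord <- order(key_id, t_pos)
  key_o <- key_id[ord]
  t_o <- t_pos[ord]
  lev_o <- bins[idx][ord]
  n <- length(ord)
  if (n == 0) return(data.frame(level = integer(0), len = integer(0)))
  new_run <- c(TRUE, key_o[-1] != key_o[-n] | diff(t_o) != 1L |
    lev_o[-1] != lev_o[-n])
  run_id <- cumsum(new_run)
  data.frame(
    level = lev_o[new_run],
    len = as.integer(tabulate(run_id))
  )
}

glrlm_from_runs <- function(runs, n_voxels) {
  nr <- nrow(runs)
  counts <- stats::aggregate(cnt ~ level + len,
    data = cbind(runs, cnt = 1), FUN = sum)
  c(
    short_run_emphasis = sum(counts$cnt / counts$len^2) / nr,
    long_run_emphasis = sum(counts$cnt * counts$len^2) / nr,
    run_length_nonuniformity =
      sum(tapply(counts$cnt, counts$len, sum)^2) / nr,
    gray_level_nonuniformity =
      sum(tapply(counts$cnt, counts$level, sum)^2) / nr,
    run_percentage = nr / n_voxels
  )
}

#' Gray-level run-length matrix features
#'
#' Builds run-length matrices over in-mask runs along each of the 13 unique
#' 3-D directions (out-of-mask voxels break runs) and averages the feature
#' values over directions.  Returns short-run emphasis, long-run emphasis,
#' run-length non-uniformity, gray-level non-uniformity, and run percentage.
#'
#' @inheritParams glcm_features
#' @return named numeric vector.
#' @export
glrlm_features <- function(bins, mask, n_bins = attr(bins, "n_bins")) {
  m <- array(as.integer(mask > 0), dim = dim(mask))
  assert_that(sum(m) >= 2, "need at least 2 in-mask voxels",
    class = "crlmrad_degenerate_error")
  b <- array(as.integer(bins), dim = dim(bins))
  offs <- direction_offsets_13()
  nvox <- sum(m)
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    runs <- runs_one_direction(b, m, offs[r, ])
    f <- glrlm_from_runs(runs, nvox)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(offs)
}

texture_feature_names <- c(
  "contrast", "correlation", "joint_entropy", "energy", "homogeneity"
)
glrlm_feature_names <- c(
  "short_run_emphasis", "long_run_emphasis", "run_length_nonuniformity",
  "gray_level_nonuniformity", "run_percentage"
)
firstorder_feature_names <- c(
  "mean", "median", "variance", "skewness", "kurtosis", "energy",
  "minimum", "maximum", "range", "entropy"
)
shape_feature_names <- c(
  "volume_mm3", "surface_area_mm2", "surface_to_volume_ratio",
  "max_diameter_3d_mm", "sphericity"
)

channel_names <- function(config) {
  c("original",
    if (length(config$log_sigmas_mm)) {
      sprintf("log_sigma_%g_mm", config$log_sigmas_mm)
    })
}

#' Deterministic catalog of natively computed feature names
#'
#' Per intensity channel (original plus one per LoG sigma): 10 first-order,
#' 5 GLCM and 5 GLRLM features; plus 5 channel-independent shape features.
#'
#' @param config a `crlm_preprocess_config`.
#' @return character vector of `channel__family__statistic` names (shape
#'   features are named `shape__statistic`).
#' @export
feature_catalog <- function(config = preprocess_config()) {
  per_channel <- function(ch) {
    c(paste(ch, "firstorder", firstorder_feature_names, sep = "__"),
      paste(ch, "glcm", texture_feature_names, sep = "__"),
      paste(ch, "glrlm", glrlm_feature_names, sep = "__"))
  }
  c(paste("shape", shape_feature_names, sep = "__"),
    unlist(lapply(channel_names(config), per_channel), use.names = FALSE))
}

#' Extract all native features for one lesion
#'
#' Runs [preprocess()], computes shape features on the resampled mask, and
#' first-order/GLCM/GLRLM features on the clipped original channel and on
#' each Laplacian-of-Gaussian channel.  Each channel is discretized with the
#' same clip-window/bin-width rule.  Lesions reduced to a single voxel after
#' resampling get shape and first-order features with texture features set to
#' `NA` (with a warning).
#'
#' @param image,mask `crlm_volume`s.
#' @param config a `crlm_preprocess_config`.
#' @param patient_id,lesion_id identifiers carried into the record.
#' @return object of class `crlm_lesion_record`: list with `patient_id`,
#'   `lesion_id`, `volume_mm3` and a named `features` vector following
#'   [feature_catalog()].
#' @export
extract_lesion <- function(image, mask, config = preprocess_config(),
                           patient_id = "P0001", lesion_id = "L01") {
  pp <- preprocess(image, mask, config)
  msk <- array(as.integer(pp$mask > 0), dim = dim(pp$mask))
  sp <- spacing_of(pp$mask)
  shape <- shape_features(msk, sp)
  feats <- stats::setNames(
    rep(NA_real_, length(feature_catalog(config))), feature_catalog(config))
  feats[paste("shape", names(shape), sep = "__")] <- shape
  degenerate <- sum(msk) < 2
  if (degenerate) {
    warning("lesion has < 2 voxels after resampling; texture features set NA")
  }
  for (ch in channel_names(config)) {
    chan_vol <- if (ch == "original") {
      pp$image
    } else {
      sigma <- as.numeric(sub("^log_sigma_([0-9.]+)_mm$", "\\1", ch))
      log_filter(pp$image, sigma)
    }
    vals <- as.numeric(chan_vol)[msk == 1L]
    # LoG outputs are re-clipped into the analysis window before binning so
    # that one discretization rule covers every channel
    vals_clipped <- pmin(pmax(vals, config$clip_lo_hu), config$clip_hi_hu)
    fo <- first_order_features(vals_clipped, config)
    feats[paste(ch, "firstorder", names(fo), sep = "__")] <- fo
    if (!degenerate) {
      bins_arr <- array(discretize(
        pmin(pmax(as.numeric(chan_vol), config$clip_lo_hu), config$clip_hi_hu),
        config), dim = dim(chan_vol))
      nb <- attr(discretize(0, config), "n_bins")
      glcm <- glcm_features(bins_arr, msk, n_bins = nb)
      glrlm <- glrlm_features(bins_arr, msk, n_bins = nb)
      feats[paste(ch, "glcm", names(glcm), sep = "__")] <- glcm
      feats[paste(ch, "glrlm", names(glrlm), sep = "__")] <- glrlm
    }
  }
  structure(
    list(patient_id = patient_id, lesion_id = lesion_id,
      volume_mm3 = unname(shape["volume_mm3"]), features = feats),
    class = "crlm_lesion_record"
  )
}

#' @exportS3Method base::print
print.crlm_lesion_record <- function(x, ...) {
  cat(sprintf("Lesion %s/%s: volume %.1f mm3, %d features\n",
    x$patient_id, x$lesion_id, x$volume_mm3, length(x$features)))
  invisible(x)
}

#' Combine lesion records into a lesion table
#'
#' @param records list of `crlm_lesion_record`s.
#' @return data frame with `patient_id`, `lesion_id`, `volume_mm3` and one
#'   column per feature.
#' @export
lesion_table <- function(records) {
  assert_that(length(records) > 0, "no lesion records")
  rows <- lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, lesion_id = r$lesion_id,
      volume_mm3 = r$volume_mm3, as.list(r$features), check.names = FALSE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ingest an externally computed per-lesion feature table
#'
#' Accepts CSV/TSV tables in the package schema (`patient_id`, `lesion_id`,
#' `volume_mm3`, then numeric feature columns), e.g. full-catalog tables
#' computed by an external radiomics engine.  Validates keys, volumes and
#' numeric cells with row-level diagnostics.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param expected_features optional character vector; under `strict = TRUE`
#'   any feature column outside this set is an error, under lenient mode a
#'   warning (columns pass through either way when lenient).
#' @param strict enforce the expected feature set (default `FALSE`).
#' @return validated lesion table (data frame).
#' @export
ingest_feature_table <- function(path, expected_features = NULL,
                                 strict = FALSE) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
    class = "crlmrad_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
    stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "lesion_id", "volume_mm3")
  missing_cols <- setdiff(required, names(tab))
  if ("volume_mm3" %in% missing_cols) {
    stop_crlmrad("feature table lacks a volume_mm3 column",
      "crlmrad_schema_error")
  }
  assert_that(length(missing_cols) == 0,
    sprintf("missing required columns: %s", paste(missing_cols, collapse = ", ")),
    class = "crlmrad_schema_error")
  key <- paste(tab$patient_id, tab$lesion_id, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop_crlmrad(sprintf("duplicate lesion key(s): %s",
      paste(unique(dup), collapse = ", ")), "crlmrad_integrity_error")
  }
  feat_cols <- setdiff(names(tab), required)
  if (!is.null(expected_features)) {
    unknown <- setdiff(feat_cols, expected_features)
    if (length(unknown)) {
      msg <- sprintf("unknown feature column(s): %s",
        paste(unknown, collapse = ", "))
      if (strict) stop_crlmrad(msg, "crlmrad_schema_error") else warning(msg)
    }
  }
  for (col in c("volume_mm3", feat_cols)) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_crlmrad(sprintf(
        "non-numeric or missing values in column '%s' (rows %s)",
        col, paste(utils::head(bad, 5), collapse = ", ")),
        "crlmrad_schema_error")
    }
    tab[[col]] <- v
  }
  assert_that(all(tab$volume_mm3 > 0), "volumes must be positive",
    class = "crlmrad_schema_error")
  tab
}
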