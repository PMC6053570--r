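## Feature-table data model: samples x features intensity matrix with
## per-feature retention time (minutes) and m/z (Daltons), identified by
## "<rt>_<mz>" labels, e.g. "2.41_343.82".

#' Construct a feature table
#'
#' A feature table couples a non-negative intensity matrix (samples in rows,
#' metabolic features in columns) with per-feature retention time and m/z.
#' Feature identifiers follow the `"<rt>_<mz>"` convention used for
#' untargeted LC-MS fingerprints, so `"2.41_343.82"` is the feature eluting
#' at 2.41 min with mass 343.82 Da.
#'
#' @param intensities numeric matrix, samples x features, all values >= 0.
#'   Row names are sample ids; column names are feature ids (`"<rt>_<mz>"`).
#' @param features optional data.frame with columns `feature_id`, `rt`, `mz`;
#'   parsed from the column names when omitted.
#' @return An object of class `feature_table` with elements `intensities`,
#'   `features`, `sample_ids`, `feature_ids`.
#' @export
feature_table <- function(intensities, features = NULL) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) == 0L) stopf("no features")
  if (is.null(rownames(intensities))) stopf("intensity matrix needs sample ids as row names")
  if (is.null(colnames(intensities))) stopf("intensity matrix needs feature ids as column names")
  if (anyDuplicated(rownames(intensities))) stopf("duplicate sample ids")
  if (anyDuplicated(colnames(intensities))) stopf("duplicate feature ids")
  if (anyNA(intensities)) stopf("missing intensities are not allowed")
  if (any(intensities < 0)) stopf("negative intensity found (min = %g)", min(intensities))
  if (is.null(features)) {
    parsed <- parse_feature_id(colnames(intensities))
    features <- data.frame(feature_id = colnames(intensities),
                           rt = parsed$rt, mz = parsed$mz,
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("feature_id", "rt", "mz") %in% names(features)))
    features <- features[match(colnames(intensities), features$feature_id), , drop = FALSE]
    if (anyNA(features$feature_id)) stopf("features table does not cover all columns")
  }
  rownames(features) <- NULL
  structure(list(intensities = intensities,
                 features = features,
                 sample_ids = rownames(intensities),
                 feature_ids = colnames(intensities)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  rt range: %.3f-%.3f min; m/z range: %.2f-%.2f Da\n",
              min(x$features$rt), max(x$features$rt),
              min(x$features$mz), max(x$features$mz)))
  zero <- mean(x$intensities == 0)
  cat(sprintf("  zero intensities: %.1f%%\n", 100 * zero))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Compose a feature identifier from retention time and m/z
#'
#' @param rt retention time in minutes (finite, positive).
#' @param mz mass-to-charge in Daltons (finite, positive).
#' @param digits decimal precision used for both components (default 4,
#'   trailing zeros dropped so `make_feature_id(2.41, 343.82)` is
#'   `"2.41_343.82"`).
#' @return Character vector of `"<rt>_<mz>"` identifiers; round-trips through
#'   [parse_feature_id()] for inputs with at most `digits` decimals.
#' @export
make_feature_id <- function(rt, mz, digits = 4) {
  if (any(!is.finite(rt)) || any(!is.finite(mz))) stopf("rt and mz must be finite")
  if (any(rt <= 0) || any(mz <= 0)) stopf("rt and mz must be positive")
  fmt <- function(x) {
    vapply(x, function(v) format(round(v, digits), scientific = FALSE,
                                 trim = TRUE, drop0trailing = TRUE),
           character(1))
  }
  paste0(fmt(rt), "_", fmt(mz))
}

#' Parse `"<rt>_<mz>"` feature identifiers
#'
#' @param id character vector of identifiers.
#' @return A list with numeric vectors `rt` and `mz`.
#' @export
parse_feature_id <- function(id) {
  parts <- strsplit(as.character(id), "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  rt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- bad | !is.finite(rt) | !is.finite(mz)
  if (any(bad)) stopf("unparseable feature id(s): %s",
                      paste(utils::head(id[bad], 5), collapse = ", "))
  list(rt = rt, mz = mz)
}

#' Normalize each sample to a common total intensity
#'
#' Scales every sample (row) so its summed feature intensity equals
#' `target_sum`, the usual total-marker-intensity normalization for
#' untargeted LC-MS fingerprints. Zeros are preserved exactly.
#'
#' @param x a [feature_table()].
#' @param target_sum row total after scaling (default 10000).
#' @return A normalized `feature_table`.
#' @export
normalize_total_intensity <- function(x, target_sum = 10000) {
  stopifnot(inherits(x, "feature_table"), target_sum > 0)
  tot <- rowSums(x$intensities)
  if (any(tot <= 0)) {
    stopf("all-zero sample(s): %s",
          paste(utils::head(x$sample_ids[tot <= 0], 5), collapse = ", "))
  }
  x$intensities <- x$intensities * (target_sum / tot)
  x
}

#' Filter features by relative standard deviation across pooled-QC injections
#'
#' For each feature, RSD = 100 * sd / mean over the QC injections. Features
#' whose QC RSD exceeds `threshold_pct`, or whose QC mean is zero (RSD
#' undefined), are removed; this is the standard pooled-QC repeatability
#' filter for untargeted biomarker data.
#'
#' @param x a [feature_table()] (typically already normalized).
#' @param qc_sample_ids ids of the QC rows (>= 2 required).
#' @param threshold_pct removal threshold in percent (default 30).
#' @return A list: `table` (filtered `feature_table`, all samples kept),
#'   `removed` (data.frame `feature_id`, `rsd_pct`), `rsd` (named vector of
#'   per-feature RSDs, `NA` where undefined).
#' @export
qc_rsd_filter <- function(x, qc_sample_ids, threshold_pct = 30) {
  stopifnot(inherits(x, "feature_table"))
  qc_sample_ids <- as.character(qc_sample_ids)
  missing <- setdiff(qc_sample_ids, x$sample_ids)
  if (length(missing)) stopf("QC sample(s) absent from table: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  if (length(qc_sample_ids) < 2L) stopf("need at least 2 QC samples to compute an RSD")
  q <- x$intensities[qc_sample_ids, , drop = FALSE]
  m <- colMeans(q)
  s <- apply(q, 2L, sd)  # sample (n-1) standard deviation
  rsd <- ifelse(m > 0, 100 * s / m, NA_real_)
  drop <- is.na(rsd) | rsd > threshold_pct
  removed <- data.frame(feature_id = x$feature_ids[drop],
                        rsd_pct = rsd[drop], row.names = NULL,
                        stringsAsFactors = FALSE)
  if (all(drop)) stopf("no features survive the QC RSD filter")
  keep <- !drop
  x$intensities <- x$intensities[, keep, drop = FALSE]
  x$features <- x$features[keep, , drop = FALSE]
  rownames(x$features) <- NULL
  x$feature_ids <- x$feature_ids[keep]
  list(table = x, removed = removed, rsd = setNames(rsd, colnames(q)))
}

## biological-sample key: one leaf = one plant x leaf_status combination
leaf_key <- function(md) paste(md$plant_id, md$leaf_status, sep = "_")

#' Average triplicate injections into one row per biological sample
#'
#' Collapses injection replicates of each leaf (plant x leaf status) to their
#' arithmetic mean. QC and conditioning rows are excluded from the output.
#'
#' @param x a [feature_table()].
#' @param metadata sample metadata (see [read_feature_table()]); must contain
#'   `sample_id`, `role`, `plant_id`, `leaf_status`, `injection_replicate`.
#' @return A list: `table` (collapsed `feature_table`, sample ids
#'   `"<plant_id>_<leaf_status>"`), `metadata` (one row per leaf, injection
#'   and batch columns dropped).
#' @export
average_replicates <- function(x, metadata) {
  stopifnot(inherits(x, "feature_table"))
  md <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stopf("sample(s) without metadata")
  bio <- md$role == "biological"
  if (!any(bio)) stopf("no biological samples")
  key <- leaf_key(md[bio, , drop = FALSE])
  mat <- x$intensities[bio, , drop = FALSE]
  groups <- split(seq_len(nrow(mat)), key)
  if (any(lengths(groups) == 0L)) stopf("empty replicate group")
  means <- t(vapply(groups, function(i) colMeans(mat[i, , drop = FALSE]),
                    numeric(ncol(mat))))
  colnames(means) <- x$feature_ids
  out_md <- md[bio, , drop = FALSE][!duplicated(key), , drop = FALSE]
  out_md <- out_md[match(rownames(means), leaf_key(out_md)), , drop = FALSE]
  out_md$sample_id <- rownames(means)
  out_md$injection_replicate <- NULL
  out_md$batch <- NULL
  rownames(out_md) <- NULL
  list(table = feature_table(means, x$features), metadata = out_md)
}

#' Within-plant paired differences (undamaged minus damaged leaf)
#'
#' Reduces the paired-leaf design to one row per plant by subtracting the
#' damaged leaf's feature intensities from the undamaged leaf's
#' (M_U - M_D), removing plant-level variation. The leaf-area difference
#' (undamaged minus damaged, cm^2) and the damaged leaf's herbivory damage
#' percentage are carried along as plant-level predictors.
#'
#' @param x an averaged [feature_table()] (one row per leaf, from
#'   [average_replicates()]).
#' @param metadata the matching per-leaf metadata.
#' @return An object of class `paired_difference`: `diff_intensities`
#'   (plants x features, may be negative), `plant_ids`, `diff_leaf_area`,
#'   `damage_pct`, `feature_ids`.
#' @export
paired_difference <- function(x, metadata) {
  stopifnot(inherits(x, "feature_table"))
  md <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stopf("sample(s) without metadata")
  plants <- unique(md$plant_id)
  iu <- match(paste(plants, "undamaged", sep = "_"), leaf_key(md))
  id <- match(paste(plants, "damaged", sep = "_"), leaf_key(md))
  if (anyNA(iu) || anyNA(id)) {
    miss <- plants[is.na(iu) | is.na(id)]
    stopf("plant(s) missing a pair member: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  d <- x$intensities[iu, , drop = FALSE] - x$intensities[id, , drop = FALSE]
  rownames(d) <- plants
  structure(list(diff_intensities = d,
                 plant_ids = plants,
                 diff_leaf_area = md$leaf_area[iu] - md$leaf_area[id],
                 damage_pct = md$damage_pct[id],
                 feature_ids = x$feature_ids),
            class = "paired_difference")
}

#' @export
print.paired_difference <- function(x, ...) {
  cat(sprintf("paired_difference: %d plants x %d features (M_U - M_D)\n",
              length(x$plant_ids), length(x$feature_ids)))
  invisible(x)
}
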