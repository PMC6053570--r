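## Delimiter-separated text I/O for feature tables, metadata and reports.
## Wide orientation, UTF-8, "." decimal separator throughout.

ROLE_LEVELS      <- c("biological", "qc", "conditioning")
REGION_LEVELS    <- c("western_jutland", "eastern_jutland", "islands")
HABITAT_LEVELS   <- c("agricultural", "forest", "manicured_park", "meadow")
LIGHT_LEVELS     <- c("full_sun", "part_shade", "shade")
PHENOLOGY_LEVELS <- c("vegetative", "immature_flowers", "flowering")
LEAF_LEVELS      <- c("undamaged", "damaged")

validate_metadata <- function(md) {
  need <- c("sample_id", "role")
  miss <- setdiff(need, names(md))
  if (length(miss)) stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample ids in metadata")
  md$role <- check_vocab(md$role, ROLE_LEVELS, "role")
  bio <- md$role == "biological"
  if ("region" %in% names(md)) md$region[bio] <- check_vocab(md$region[bio], REGION_LEVELS, "region")
  if ("habitat" %in% names(md)) md$habitat[bio] <- check_vocab(md$habitat[bio], HABITAT_LEVELS, "habitat")
  if ("light" %in% names(md)) md$light[bio] <- check_vocab(md$light[bio], LIGHT_LEVELS, "light")
  if ("phenology" %in% names(md)) md$phenology[bio] <- check_vocab(md$phenology[bio], PHENOLOGY_LEVELS, "phenology")
  if ("leaf_status" %in% names(md)) {
    md$leaf_status[bio] <- check_vocab(md$leaf_status[bio], LEAF_LEVELS, "leaf_status")
    dup <- stats::aggregate(list(n = md$sample_id[bio]),
                            by = list(plant_id = md$plant_id[bio],
                                      leaf_status = md$leaf_status[bio],
                                      rep = md$injection_replicate[bio] %||% 1),
                            FUN = length)
    if (any(dup$n > 1L)) stopf("a plant has more than one leaf per leaf_status")
  }
  if ("damage_pct" %in% names(md)) {
    dp <- md$damage_pct[bio]
    if (any(dp < 0 | dp > 100, na.rm = TRUE)) stopf("damage_pct outside [0, 100]")
    if ("leaf_status" %in% names(md)) {
      und <- bio & md$leaf_status == "undamaged"
      if (any(md$damage_pct[und] != 0, na.rm = TRUE))
        stopf("undamaged leaves must have damage_pct = 0")
    }
  }
  md
}

#' Read a wide feature table with its sample metadata
#'
#' The feature table is delimiter-separated text with sample ids in the first
#' column and `"<rt>_<mz>"` feature ids in the header. Metadata is joined by
#' `sample_id` and validated against the controlled vocabularies (role,
#' region, habitat, light, phenology, leaf status).
#'
#' @param path path to the feature-intensity table.
#' @param metadata_path path to the sample-metadata table.
#' @param sep field delimiter (default `","`).
#' @return A list with elements `table` (a [feature_table()]) and `metadata`
#'   (a validated data.frame).
#' @export
read_feature_table <- function(path, metadata_path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stopf("no features")
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  tab <- feature_table(mat)
  md <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  md <- validate_metadata(md)
  uses <- tab$sample_ids[!tab$sample_ids %in% md$sample_id]
  if (length(uses)) stopf("sample(s) without metadata: %s",
                          paste(utils::head(uses, 5), collapse = ", "))
  list(table = tab, metadata = md)
}

#' Write a feature table (and optionally metadata) as delimited text
#'
#' @param x a [feature_table()].
#' @param path output path for the intensity table.
#' @param metadata optional metadata data.frame.
#' @param metadata_path output path for the metadata (required with
#'   `metadata`).
#' @param sep field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(x, path, metadata = NULL, metadata_path = NULL,
                                sep = ",") {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(sample_id = x$sample_ids, x$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(metadata)) {
    if (is.null(metadata_path)) stopf("metadata_path required when writing metadata")
    utils::write.table(metadata, metadata_path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
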