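## Targeted screening: match known standards to unfiltered features by
## retention-time / m-z windows and test damaged vs undamaged intensities.

#' Read a target-compound definition table
#'
#' Delimiter-separated text with columns `compound`, `rt` (minutes), `mz`
#' (Daltons) and optional per-compound `rt_tol` / `mz_tol` windows.
#'
#' @param path input path.
#' @param sep field delimiter (default `","`).
#' @param rt_tol,mz_tol default windows applied where the file has none.
#' @return A data.frame of target definitions.
#' @export
read_targets <- function(path, sep = ",", rt_tol = 0.20, mz_tol = 0.05) {
  t <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("compound", "rt", "mz")
  miss <- setdiff(need, names(t))
  if (length(miss)) stopf("targets table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(t$rt_tol)) t$rt_tol <- rt_tol
  if (is.null(t$mz_tol)) t$mz_tol <- mz_tol
  if (any(t$rt_tol <= 0) || any(t$mz_tol <= 0)) stopf("tolerances must be > 0")
  t
}

#' Match target compounds to features by retention-time and mass windows
#'
#' A feature matches a target when `|rt - expected| <= rt_tol` and
#' `|mz - expected| <= mz_tol`. All matches are reported, ranked per
#' compound by the combined normalized distance
#' `sqrt((drt/rt_tol)^2 + (dmz/mz_tol)^2)`.
#'
#' @param x an (unfiltered) [feature_table()].
#' @param targets a target definition data.frame (see [read_targets()]).
#' @return A data.frame with one row per (compound, matched feature):
#'   `compound`, `feature_id`, `d_rt`, `d_mz`, `distance`, `rank`;
#'   compounds without a match appear once with `feature_id = NA`.
#' @export
match_targets <- function(x, targets) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(targets$rt_tol)) targets$rt_tol <- 0.20
  if (is.null(targets$mz_tol)) targets$mz_tol <- 0.05
  if (any(targets$rt_tol <= 0) || any(targets$mz_tol <= 0))
    stopf("tolerances must be > 0")
  out <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    d_rt <- abs(x$features$rt - t$rt)
    d_mz <- abs(x$features$mz - t$mz)
    hit <- d_rt <= t$rt_tol & d_mz <= t$mz_tol
    if (!any(hit)) {
      return(data.frame(compound = t$compound, feature_id = NA_character_,
                        d_rt = NA_real_, d_mz = NA_real_,
                        distance = NA_real_, rank = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    dist <- sqrt((d_rt[hit] / t$rt_tol)^2 + (d_mz[hit] / t$mz_tol)^2)
    o <- order(dist)
    data.frame(compound = t$compound,
               feature_id = x$feature_ids[hit][o],
               d_rt = d_rt[hit][o], d_mz = d_mz[hit][o],
               distance = dist[o], rank = seq_along(o),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sided Mann-Whitney U test
#'
#' Wilcoxon rank-sum with tie correction; the exact distribution is used
#' when both groups have at most 8 observations and no ties occur.
#'
#' @param a,b numeric value vectors (both non-empty).
#' @return A list: `U` (statistic for group `a`), `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Screen target compounds and test damaged vs undamaged intensities
#'
#' Matches each target in the unfiltered table, then — for compounds with a
#' match — compares the closest matching feature's per-leaf averaged
#' intensity between damaged and undamaged leaves with an (unpaired)
#' Mann-Whitney U test. A paired Wilcoxon signed-rank alternative over
#' within-plant pairs is available.
#'
#' @param x an unfiltered [feature_table()] (injection-level rows).
#' @param metadata the matching injection-level metadata.
#' @param targets a target definition table.
#' @param paired use a within-plant paired signed-rank test instead.
#' @return A data.frame with one row per compound: `compound`, `detected`,
#'   `feature_id`, `U` (or `V` when paired), `p`.
#' @export
screen_targets <- function(x, metadata, targets, paired = FALSE) {
  matches <- match_targets(x, targets)
  avg <- average_replicates(x, metadata)
  md <- avg$metadata
  out <- lapply(unique(matches$compound), function(cmp) {
    m <- matches[matches$compound == cmp & !is.na(matches$feature_id), , drop = FALSE]
    if (nrow(m) == 0L) {
      return(data.frame(compound = cmp, detected = FALSE,
                        feature_id = NA_character_, U = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    fid <- m$feature_id[1L]  # closest match
    y <- avg$table$intensities[, fid]
    und <- y[md$leaf_status == "undamaged"]
    dam <- y[md$leaf_status == "damaged"]
    if (paired) {
      plants <- unique(md$plant_id)
      u <- y[match(paste0(plants, "_undamaged"), avg$table$sample_ids)]
      d <- y[match(paste0(plants, "_damaged"), avg$table$sample_ids)]
      wt <- suppressWarnings(wilcox.test(u, d, paired = TRUE))
      return(data.frame(compound = cmp, detected = TRUE, feature_id = fid,
                        U = unname(wt$statistic), p = wt$p.value,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(und, dam)
    data.frame(compound = cmp, detected = TRUE, feature_id = fid,
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
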