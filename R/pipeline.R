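## End-to-end orchestration: normalize -> QC filter -> average replicates ->
## paired differences -> spatial predictors -> ordination -> variation
## partitioning -> per-factor conditional log-normal analyses -> network ->
## targeted screen, with derived per-stage seeds and a run report.

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts (`NULL` for none).
#' @param target_sum total-intensity normalization target.
#' @param qc_rsd_threshold QC RSD removal threshold (percent).
#' @param factors explanatory variables analysed with the conditional
#'   log-normal model (default: all eight).
#' @param n_perm permutations for variation-partitioning tests.
#' @param nmds_restarts random restarts for the ordination.
#' @param network_threshold Spearman rho edge threshold (default the 0.372
#'   p < 0.01 convention; `NULL` recomputes via [critical_rho()] from the
#'   sample count and `network_alpha`).
#' @param network_alpha alpha used when recomputing the threshold.
#' @param q_cutoff FDR significance cutoff for reporting, post hoc testing
#'   and network node selection.
#' @param run_posthoc run Tukey post hoc contrasts on significant features
#'   of categorical factors.
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, target_sum = 10000,
                            qc_rsd_threshold = 30,
                            factors = CLN_FACTORS,
                            n_perm = 999, nmds_restarts = 20,
                            network_threshold = 0.372, network_alpha = 0.01,
                            q_cutoff = 0.20, run_posthoc = FALSE, seed = 1L) {
  factors <- match.arg(factors, CLN_FACTORS, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a feature table + metadata (or a synthetic
#' study), deterministic given the master seed, and returns a run report;
#' artifacts are written under `config$out_dir` when set.
#'
#' @param x a `folmet_study` from [generate_study()], or a list with
#'   elements `table` (unfiltered injection-level [feature_table()]) and
#'   `metadata` as returned by [read_feature_table()].
#' @param config a [pipeline_config()].
#' @param targets optional target definition table for the targeted screen.
#' @return An object of class `run_report` (see Details), with the filtered,
#'   averaged table and intermediate results attached.
#'
#' @details The report carries: feature counts before/after QC filtering;
#' NMDS stress; variation-partitioning fractions and permutation F/p for the
#' soil/region/phenology model (per-plant means) and the leaf-area/damage
#' paired-difference model; the per-factor significance tallies and
#' significant-feature lists with their overlap (Venn) counts; co-occurrence
#' network node/edge/component counts; and the targeted-screen table.
#' @export
run_pipeline <- function(x, config = pipeline_config(), targets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  md <- x$metadata
  stage <- function(name) derive_seed(config$seed, name)

  ## -- preprocess --------------------------------------------------------
  norm <- normalize_total_intensity(x$table, config$target_sum)
  qc_ids <- md$sample_id[md$role == "qc"]
  filt <- qc_rsd_filter(norm, qc_ids, config$qc_rsd_threshold)
  avg <- average_replicates(filt$table, md)
  leaf_md <- avg$metadata
  paired <- paired_difference(avg$table, leaf_md)

  ## -- spatial predictors ------------------------------------------------
  sites <- unique(leaf_md[, c("population", "latitude", "longitude")])
  site_d <- euclidean_distance(sites, labels = sites$population)
  axes <- pcnm_axes(site_d)

  ## -- ordination --------------------------------------------------------
  bc <- bray_curtis(avg$table)
  ord <- nmds(bc, k = 2, restarts = config$nmds_restarts,
              seed = stage("nmds"))

  ## -- variation partitioning -------------------------------------------
  ## soil / region / phenology on per-plant means of the averaged leaves
  plant_ids <- unique(leaf_md$plant_id)
  pm <- t(vapply(plant_ids, function(p)
    colMeans(avg$table$intensities[leaf_md$plant_id == p, , drop = FALSE]),
    numeric(ncol(avg$table$intensities))))
  pmd <- leaf_md[match(plant_ids, leaf_md$plant_id), , drop = FALSE]
  vp_main <- varpart_blocks(
    pm,
    blocks = list(soil = pmd[, c("soil_ph", "soil_ec", "soil_cn")],
                  region = pmd[, "region", drop = FALSE],
                  phenology = pmd[, "phenology", drop = FALSE]),
    n_perm = config$n_perm, seed = stage("varpart_main"))
  ## leaf area / damage on the paired-difference table
  vp_paired <- varpart_blocks(
    paired$diff_intensities,
    blocks = list(leaf_area = data.frame(diff_leaf_area = paired$diff_leaf_area),
                  damage = data.frame(damage_pct = paired$damage_pct)),
    n_perm = config$n_perm, seed = stage("varpart_paired"))

  ## -- conditional log-normal analyses ------------------------------------
  cln <- lapply(config$factors, function(f)
    cln_analysis(avg$table, leaf_md, f, pcnm = axes))
  names(cln) <- config$factors
  tallies <- do.call(rbind, lapply(cln, significance_tallies))
  rownames(tallies) <- NULL
  sig_sets <- lapply(cln, function(r)
    r$feature_id[!is.na(r$q) & r$q < config$q_cutoff])
  venn <- if (sum(lengths(sig_sets) > 0) >= 2L)
    overlap_sets(sig_sets[lengths(sig_sets) > 0]) else NULL

  posthoc <- NULL
  if (config$run_posthoc) {
    cat_factors <- intersect(config$factors,
                             c("region", "habitat", "light", "phenology",
                               "leaf_status"))
    posthoc <- do.call(rbind, lapply(cat_factors, function(f) {
      ids <- sig_sets[[f]]
      if (length(ids) == 0L) return(NULL)
      cbind(factor = f,
            tukey_posthoc(avg$table, leaf_md, f, ids, pcnm = axes))
    }))
  }

  ## -- co-occurrence network ---------------------------------------------
  net <- NULL; profiles <- NULL
  node_set <- sig_sets[["region"]] %||% character(0)
  if (length(node_set) >= 2L) {
    sp <- spearman_matrix(avg$table$intensities[, node_set, drop = FALSE])
    thr <- config$network_threshold %||%
      critical_rho(nrow(avg$table$intensities), config$network_alpha)
    net <- build_network(sp, threshold = thr)
    profiles <- region_profiles(avg$table, leaf_md, node_set)
  }

  ## -- targeted screen ----------------------------------------------------
  screen <- if (!is.null(targets)) screen_targets(x$table, md, targets)

  report <- structure(list(
    seed = config$seed,
    n_injections = nrow(x$table$intensities),
    n_leaves = nrow(avg$table$intensities),
    n_plants = length(plant_ids),
    features_before = ncol(x$table$intensities),
    features_after = ncol(filt$table$intensities),
    removed_features = filt$removed,
    nmds_stress = ord$stress,
    varpart_main = vp_main, varpart_paired = vp_paired,
    tallies = tallies, significant = sig_sets, venn = venn,
    posthoc = posthoc,
    network = net, network_profiles = profiles,
    targeted = screen,
    cln = cln, ordination = ord, pcnm = axes,
    table = avg$table, metadata = leaf_md, paired = paired,
    config = config), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d)\n", x$seed))
  cat(sprintf("  %d injections -> %d leaves over %d plants\n",
              x$n_injections, x$n_leaves, x$n_plants))
  cat(sprintf("  QC RSD filter: %d -> %d features\n",
              x$features_before, x$features_after))
  cat(sprintf("  NMDS stress: %.4f\n", x$nmds_stress))
  cat("  variation partitioning (adjusted fractions):\n")
  print(round(x$varpart_main$fractions, 3))
  cat("  significance tallies:\n")
  print(x$tallies)
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d nodes, %d edges\n",
                nrow(x$network$nodes), nrow(x$network$edges)))
  }
  if (!is.null(x$targeted)) {
    cat(sprintf("  targeted screen: %d of %d compounds detected\n",
                sum(x$targeted$detected), nrow(x$targeted)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_feature_table(report$table, fp("filtered_averaged_table.csv"),
                      metadata = report$metadata,
                      metadata_path = fp("leaf_metadata.csv"))
  utils::write.table(report$removed_features, fp("qc_removed_features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample_id = rownames(report$ordination$points),
                                report$ordination$points),
                     fp("nmds_scores.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(fraction = names(report$varpart_main$fractions),
                                adj_r2 = unname(report$varpart_main$fractions)),
                     fp("varpart_main_fractions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$tallies, fp("significance_tallies.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (f in names(report$cln)) {
    utils::write.table(report$cln[[f]], fp(sprintf("cln_%s.tsv", f)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$network)) {
    write_network_graphml(report$network, report$network_profiles,
                          fp("cooc_network.graphml"),
                          edgelist_path = fp("cooc_edges.tsv"))
  }
  if (!is.null(report$targeted)) {
    utils::write.table(report$targeted, fp("targeted_screen.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  ## audit trail: full parameter set of the run
  cfg <- report$config
  cfg_lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(format(cfg[[k]]), collapse = ", ")),
    character(1))
  writeLines(cfg_lines, fp("run_parameters.txt"))
  invisible(out_dir)
}

#' Venn overlap counts of per-factor significant feature sets
#'
#' Counts every intersection cell (exclusive regions of the Venn diagram)
#' over two or more feature lists, plus the union size.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return A list: `cells` (named counts, names like `"region&soil_ph"` for
#'   the cell of features significant for exactly those sets), `union`
#'   (total unique features), `membership` (feature x set logical matrix).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2L) stopf("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be named")
  all_f <- unique(unlist(sets))
  mem <- vapply(sets, function(s) all_f %in% s, logical(length(all_f)))
  mem <- matrix(mem, nrow = length(all_f),
                dimnames = list(all_f, names(sets)))
  key <- apply(mem, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  cells <- table(key)
  list(cells = setNames(as.integer(cells), names(cells)),
       union = length(all_f), membership = mem)
}
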