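## shared fixtures: studies are generated once per session and memoized,
## so several test files can reuse the same default-design study

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.study_cache[[key]])) assign(key, fn(), .study_cache)
  .study_cache[[key]]
}

default_study <- function(seed = 1) {
  cached(paste0("study_", seed), function() generate_study(sim_config(), seed = seed))
}

## normalize -> QC filter -> average for a study; returns table, metadata, filter
prep_study <- function(st) {
  cached(paste0("prep_", st$seed), function() {
    md <- st$metadata
    qf <- qc_rsd_filter(normalize_total_intensity(st$table),
                        md$sample_id[md$role == "qc"])
    avg <- average_replicates(qf$table, md)
    list(table = avg$table, metadata = avg$metadata, filter = qf)
  })
}

## reduced feature count for unit tests that fit models per feature
small_config <- function(...) {
  args <- list(n_features = 60, n_rsd_violators = 20,
               n_region_features = 9, n_ph_features = 4,
               n_habitat_features = 2, n_leafarea_features = 2)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
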