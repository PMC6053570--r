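## Synthetic-study generator: emulates a 15-population, paired-leaf,
## triplicate-injection untargeted LC-MS design with planted ground truth
## (region / soil-pH / habitat / leaf-area effects, QC-RSD violators), so
## every downstream stage can be validated against known truth.

#' The default population frame: 15 Danish sites in 3 geographic regions
#'
#' Site names, coordinates (decimal degrees), region, habitat type and light
#' level for the fifteen sampled populations. Regions split 3 (western
#' Jutland) / 6 (eastern Jutland) / 6 (islands).
#'
#' @return A data.frame with columns `population`, `code`, `latitude`,
#'   `longitude`, `region`, `habitat`, `light`.
#' @export
default_populations <- function() {
  df <- data.frame(
    population = c("Aalborg", "Falster", "Grenaa", "Hannerupskov", "Langeland",
                   "Nørre Nissum", "Nyråd", "Øjesø",
                   "Randers", "Ringkøbing", "Ringkøbing Ejstrup",
                   "Silkeborg", "Slæbæk", "Slagelse", "Vissenbjerg"),
    code = c("Aalborg", "Falster", "Grenaa", "Hannerupskov", "Langeland",
             "NorreNissum", "Nyrad", "Ojeso", "Randers", "Ringkobing",
             "RingkobingEjstrup", "Silkeborg", "Slaebaek", "Slagelse",
             "Vissenbjerg"),
    latitude = c(57.08, 54.80, 56.41, 55.59, 54.92, 56.55, 55.01, 56.29,
                 56.47, 56.10, 56.18, 56.23, 55.11, 55.43, 55.38),
    longitude = c(9.91, 12.09, 10.92, 9.72, 10.71, 8.42, 11.96, 10.61,
                  10.02, 8.23, 8.28, 9.67, 10.57, 11.46, 10.13),
    region = c("eastern_jutland", "islands", "eastern_jutland",
               "eastern_jutland", "islands", "western_jutland", "islands",
               "eastern_jutland", "eastern_jutland", "western_jutland",
               "western_jutland", "eastern_jutland", "islands", "islands",
               "islands"),
    habitat = c("meadow", "forest", "manicured_park", "forest", "agricultural",
                "agricultural", "forest", "forest", "manicured_park", "meadow",
                "agricultural", "manicured_park", "forest", "agricultural",
                "meadow"),
    light = c("full_sun", "shade", "full_sun", "shade", "full_sun", "full_sun",
              "part_shade", "part_shade", "full_sun", "full_sun", "full_sun",
              "full_sun", "shade", "full_sun", "part_shade"),
    stringsAsFactors = FALSE)
  df
}

#' Configuration for the synthetic-study generator
#'
#' Defaults mirror the emulated field design: 15 populations in 3 regions,
#' 3 plants per population, an undamaged and a damaged leaf per plant,
#' triplicate injections, 48 usable pooled-QC injections (plus 8 column-
#' conditioning injections that are excluded from filtering), 541 features of
#' which 344 are planted QC-RSD violators so the 30% filter retains 197.
#' Planted effect sets are sized like the study outcome they emulate
#' (30 region, 8 soil-pH, 4 habitat, 3 leaf-area features).
#'
#' @param n_plants plants per population.
#' @param n_injections injection replicates per leaf.
#' @param n_qc usable pooled-QC injections.
#' @param n_conditioning column-conditioning QC injections (excluded from
#'   RSD filtering).
#' @param n_features unfiltered feature count.
#' @param n_rsd_violators features planted with unstable injection noise.
#' @param rsd_violator_cv technical CV of violator features (fraction).
#' @param tech_cv injection-level technical CV of stable features (fraction).
#' @param baseline_logmean,baseline_logsd distribution of per-feature
#'   baseline log-intensities.
#' @param resid_logsd leaf-level residual SD on the log scale.
#' @param re_sd_population,re_sd_plant random-intercept SDs (log scale).
#' @param pi_common,pi_rare presence-probability ranges for common and
#'   low-prevalence features.
#' @param rare_fraction fraction of features drawn from `pi_rare`.
#' @param n_region_features,delta_region region-specific features (split into
#'   three disjoint per-region blocks) and their log-fold elevation.
#' @param n_ph_features,ph_beta soil-pH features and their linear/quadratic
#'   coefficients on centred pH.
#' @param ph_center centring constant for pH effects.
#' @param n_habitat_features,delta_habitat habitat features (elevated in
#'   forest) and their log shift.
#' @param n_leafarea_features,leafarea_slope leaf-area features and their
#'   slope on centred log leaf area.
#' @param region_ph_means,soil_ph_sd per-region soil pH means and SD.
#' @param ec_spearman,cn_spearman target Spearman correlations of soil EC and
#'   C:N with pH.
#' @param populations population frame (see [default_populations()]).
#' @param seed default seed used by [generate_study()].
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_plants = 3, n_injections = 3, n_qc = 48,
                       n_conditioning = 8, n_features = 541,
                       n_rsd_violators = 344, rsd_violator_cv = 0.8,
                       tech_cv = 0.10, baseline_logmean = 4,
                       baseline_logsd = 1, resid_logsd = 0.5,
                       re_sd_population = 0.3, re_sd_plant = 0.3,
                       pi_common = c(0.65, 0.98), pi_rare = c(0.10, 0.35),
                       rare_fraction = 0.12,
                       n_region_features = 30, delta_region = 2,
                       n_ph_features = 8, ph_beta = c(0.5, -0.4),
                       ph_center = 6.3,
                       n_habitat_features = 4, delta_habitat = 1.5,
                       n_leafarea_features = 3, leafarea_slope = 0.8,
                       region_ph_means = c(western_jutland = 5.5,
                                           eastern_jutland = 6.4,
                                           islands = 6.7),
                       soil_ph_sd = 0.6,
                       ec_spearman = 0.49, cn_spearman = 0.39,
                       populations = default_populations(), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_plants > 0, n_injections > 0, n_qc >= 2, n_features > 0,
            n_rsd_violators >= 0, n_rsd_violators < n_features,
            rare_fraction >= 0, rare_fraction < 1,
            all(pi_common > 0), all(pi_common <= 1), all(pi_rare > 0))
  n_eff <- n_region_features + n_ph_features + n_habitat_features +
    n_leafarea_features
  if (n_eff > n_features - n_rsd_violators) {
    stopf("effect features (%d) exceed the non-violator feature count (%d)",
          n_eff, n_features - n_rsd_violators)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d populations x %d plants x 2 leaves x ",
                     "%d injections; %d features (%d RSD violators)\n"),
              nrow(x$populations), x$n_plants, x$n_injections,
              x$n_features, x$n_rsd_violators))
  cat(sprintf("  planted effects: %d region, %d pH, %d habitat, %d leaf-area\n",
              x$n_region_features, x$n_ph_features, x$n_habitat_features,
              x$n_leafarea_features))
  invisible(x)
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

## monotone latent: EC/CN share a normal-score component with pH so that
## Spearman correlation hits the target (bivariate-normal rank identity);
## the noise is orthogonalized against the scores in-sample, pinning the
## realized Pearson correlation at the target rather than only in expectation
latent_with_spearman <- function(ph, rho_s) {
  n <- length(ph)
  u <- stats::qnorm((rank(ph, ties.method = "average") - 0.5) / n)
  u <- (u - mean(u)) / sd(u)
  r <- 2 * sin(pi * rho_s / 6)
  z <- rnorm(n)
  z <- z - u * sum(z * u) / sum(u^2) - mean(z)
  z <- z / sd(z)
  r * u + sqrt(1 - r^2) * z
}

#' Generate a synthetic study with planted ground truth
#'
#' Draws an unfiltered feature table (biological injections, pooled-QC
#' injections and conditioning injections), the matching sample metadata and
#' a per-feature ground-truth table. Intensities follow a two-part model:
#' per-leaf presence `Z ~ Bernoulli(pi_f)` and, conditional on presence,
#' `exp(eta + eps)` where `eta` holds the feature baseline, planted fixed
#' effects and population/plant random intercepts, and `eps` is leaf-level
#' log-normal noise. Injections multiply the leaf value by mean-one
#' log-normal technical noise with the configured CV; QC injections multiply
#' the pooled mean of all leaves by the same per-feature noise. The output is
#' deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `folmet_study`: `table` (unfiltered
#'   [feature_table()]), `metadata`, `truth` (per-feature flags and effect
#'   sizes), `config`, `seed`.
#' @export
generate_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- config
  pops <- cfg$populations
  n_pop <- nrow(pops)
  nf <- cfg$n_features

  ## ---- features: rt / m-z / identifiers -------------------------------
  repeat {
    rt <- round(runif(nf, 0.35, 6.70), 4)
    mz <- round(runif(nf, 100, 1000), 4)
    fid <- make_feature_id(rt, mz)
    if (!anyDuplicated(fid)) break
  }

  ## presence probability: mostly common features, a low-prevalence tail
  rare <- runif(nf) < cfg$rare_fraction
  pi_f <- ifelse(rare,
                 runif(nf, cfg$pi_rare[1], cfg$pi_rare[2]),
                 runif(nf, cfg$pi_common[1], cfg$pi_common[2]))
  baseline <- rnorm(nf, cfg$baseline_logmean, cfg$baseline_logsd)

  ## planted effect sets: disjoint, common features only, never violators
  affected <- rep("none", nf)
  common_idx <- which(!rare)
  n_eff <- cfg$n_region_features + cfg$n_ph_features +
    cfg$n_habitat_features + cfg$n_leafarea_features
  eff_idx <- sample(common_idx, n_eff)
  take <- function(n) {
    out <- eff_idx[seq_len(n)]
    eff_idx <<- eff_idx[-seq_len(n)]
    out
  }
  region_idx  <- take(cfg$n_region_features)
  ph_idx      <- take(cfg$n_ph_features)
  habitat_idx <- take(cfg$n_habitat_features)
  la_idx      <- take(cfg$n_leafarea_features)
  affected[region_idx] <- "region"
  affected[ph_idx] <- "ph"
  affected[habitat_idx] <- "habitat"
  affected[la_idx] <- "leaf_area"
  ## region features: three disjoint blocks, each elevated in one region
  region_block <- rep(NA_character_, nf)
  blocks <- split(region_idx,
                  rep(REGION_LEVELS, length.out = length(region_idx),
                      each = max(1L, length(region_idx) %/% 3L))[
                        seq_along(region_idx)])
  for (r in names(blocks)) region_block[blocks[[r]]] <- r

  ## violators: any non-effect feature can be unstable
  viol_pool <- setdiff(seq_len(nf), which(affected != "none"))
  violators <- sort(sample(viol_pool, cfg$n_rsd_violators))
  tech_sd <- rep(cv_to_sdlog(cfg$tech_cv), nf)
  tech_sd[violators] <- cv_to_sdlog(cfg$rsd_violator_cv)

  ## ---- sampling design -------------------------------------------------
  plants <- expand.grid(plant = seq_len(cfg$n_plants), pop = seq_len(n_pop))
  plants <- plants[order(plants$pop, plants$plant), ]
  n_plant <- nrow(plants)
  plant_id <- sprintf("%s_p%d", pops$code[plants$pop], plants$plant)
  ## soil: one sample adjacent to each plant
  ph <- rnorm(n_plant, cfg$region_ph_means[pops$region[plants$pop]],
              cfg$soil_ph_sd)
  ph <- pmin(pmax(ph, 4.0), 8.5)
  ec <- 150 * exp(0.5 * latent_with_spearman(ph, cfg$ec_spearman))
  cn <- 15 * exp(0.25 * latent_with_spearman(ph, cfg$cn_spearman))
  phenology <- sample(PHENOLOGY_LEVELS, n_plant, replace = TRUE,
                      prob = c(0.3, 0.4, 0.3))

  leaves <- data.frame(
    plant = rep(seq_len(n_plant), each = 2L),
    leaf_status = rep(LEAF_LEVELS, n_plant),
    stringsAsFactors = FALSE)
  n_leaf <- nrow(leaves)
  leaves$leaf_area <- rlnorm(n_leaf, log(35), 0.45)
  leaves$damage_pct <- ifelse(leaves$leaf_status == "damaged",
                              runif(n_leaf, 1, 30), 0)
  leaves$damage_area <- leaves$leaf_area * leaves$damage_pct / 100
  leaves$pop <- plants$pop[leaves$plant]
  leaves$region <- pops$region[leaves$pop]
  leaves$habitat <- pops$habitat[leaves$pop]
  leaves$light <- pops$light[leaves$pop]

  ## ---- leaf-level intensity model -------------------------------------
  eta <- matrix(baseline, n_leaf, nf, byrow = TRUE)
  b_pop <- matrix(rnorm(n_pop * nf, 0, cfg$re_sd_population), n_pop, nf)
  b_plant <- matrix(rnorm(n_plant * nf, 0, cfg$re_sd_plant), n_plant, nf)
  eta <- eta + b_pop[leaves$pop, , drop = FALSE] +
    b_plant[leaves$plant, , drop = FALSE]
  for (r in names(blocks)) {
    in_r <- leaves$region == r
    eta[in_r, blocks[[r]]] <- eta[in_r, blocks[[r]]] + cfg$delta_region
  }
  if (length(ph_idx)) {
    ph_c <- ph[leaves$plant] - cfg$ph_center
    eta[, ph_idx] <- eta[, ph_idx] +
      outer(ph_c, rep(cfg$ph_beta[1], length(ph_idx))) +
      outer(ph_c^2, rep(cfg$ph_beta[2], length(ph_idx)))
  }
  if (length(habitat_idx)) {
    in_h <- leaves$habitat == "forest"
    eta[in_h, habitat_idx] <- eta[in_h, habitat_idx] + cfg$delta_habitat
  }
  if (length(la_idx)) {
    la_c <- log(leaves$leaf_area) - log(35)
    eta[, la_idx] <- eta[, la_idx] +
      outer(la_c, rep(cfg$leafarea_slope, length(la_idx)))
  }
  eps <- matrix(rnorm(n_leaf * nf, 0, cfg$resid_logsd), n_leaf, nf)
  present <- matrix(rbinom(n_leaf * nf, 1L, rep(pi_f, each = n_leaf)),
                    n_leaf, nf)
  leaf_val <- present * exp(eta + eps)

  ## ---- injections ------------------------------------------------------
  n_inj <- cfg$n_injections
  inj <- leaves[rep(seq_len(n_leaf), each = n_inj), , drop = FALSE]
  inj$replicate <- rep(seq_len(n_inj), n_leaf)
  n_row <- nrow(inj)
  tech <- matrix(rnorm(n_row * nf, 0, 1), n_row, nf)
  tech <- sweep(tech, 2L, tech_sd, `*`)
  tech <- sweep(tech, 2L, tech_sd^2 / 2, `-`)  # mean-one multiplier
  bio_mat <- leaf_val[rep(seq_len(n_leaf), each = n_inj), , drop = FALSE] *
    exp(tech)
  bio_ids <- sprintf("%s_%s_r%d", plant_id[inj$plant],
                     ifelse(inj$leaf_status == "undamaged", "U", "D"),
                     inj$replicate)
  rownames(bio_mat) <- bio_ids

  ## QC: pooled mean of all leaves plus per-feature technical noise
  pooled <- colMeans(leaf_val)
  n_qc_all <- cfg$n_qc + cfg$n_conditioning
  qtech <- matrix(rnorm(n_qc_all * nf, 0, 1), n_qc_all, nf)
  qtech <- sweep(qtech, 2L, tech_sd, `*`)
  qtech <- sweep(qtech, 2L, tech_sd^2 / 2, `-`)
  qc_mat <- matrix(pooled, n_qc_all, nf, byrow = TRUE) * exp(qtech)
  qc_ids <- c(sprintf("QC_%02d", seq_len(cfg$n_qc)),
              if (cfg$n_conditioning > 0)
                sprintf("COND_%02d", seq_len(cfg$n_conditioning)))
  rownames(qc_mat) <- qc_ids

  mat <- rbind(bio_mat, qc_mat)
  colnames(mat) <- fid
  tab <- feature_table(mat, data.frame(feature_id = fid, rt = rt, mz = mz,
                                       stringsAsFactors = FALSE))

  ## ---- metadata --------------------------------------------------------
  batch <- ifelse(inj$replicate == 1L, "b1",
                  ifelse(inj$replicate == 3L, "b2",
                         ifelse(inj$leaf %% 2L == 0L, "b1", "b2")))
  md_bio <- data.frame(
    sample_id = bio_ids, role = "biological",
    population = pops$population[inj$pop],
    region = inj$region, habitat = inj$habitat, light = inj$light,
    phenology = phenology[inj$plant],
    plant_id = plant_id[inj$plant], leaf_status = inj$leaf_status,
    leaf_area = inj$leaf_area, damage_area = inj$damage_area,
    damage_pct = inj$damage_pct,
    soil_ph = ph[inj$plant], soil_ec = ec[inj$plant], soil_cn = cn[inj$plant],
    latitude = pops$latitude[inj$pop], longitude = pops$longitude[inj$pop],
    injection_replicate = inj$replicate, batch = batch,
    stringsAsFactors = FALSE)
  md_qc <- data.frame(
    sample_id = qc_ids,
    role = rep(c("qc", "conditioning"), c(cfg$n_qc, cfg$n_conditioning)),
    population = NA, region = NA, habitat = NA, light = NA, phenology = NA,
    plant_id = NA, leaf_status = NA, leaf_area = NA, damage_area = NA,
    damage_pct = NA, soil_ph = NA, soil_ec = NA, soil_cn = NA,
    latitude = NA, longitude = NA,
    injection_replicate = seq_len(n_qc_all),
    batch = rep(c("b1", "b2"), length.out = n_qc_all),
    stringsAsFactors = FALSE)
  metadata <- validate_metadata(rbind(md_bio, md_qc))

  truth <- data.frame(
    feature_id = fid, rt = rt, mz = mz,
    affected_by = affected, region_block = region_block,
    effect_size = ifelse(affected == "region", cfg$delta_region,
                  ifelse(affected == "habitat", cfg$delta_habitat,
                  ifelse(affected == "leaf_area", cfg$leafarea_slope,
                         NA_real_))),
    ph_b1 = ifelse(affected == "ph", cfg$ph_beta[1], NA_real_),
    ph_b2 = ifelse(affected == "ph", cfg$ph_beta[2], NA_real_),
    rsd_violator = seq_len(nf) %in% violators,
    pi = pi_f, tech_cv = sqrt(exp(tech_sd^2) - 1),
    stringsAsFactors = FALSE)

  structure(list(table = tab, metadata = metadata, truth = truth,
                 config = cfg, seed = seed),
            class = "folmet_study")
}

#' @export
print.folmet_study <- function(x, ...) {
  n_bio <- sum(x$metadata$role == "biological")
  cat(sprintf("folmet_study (seed %d): %d biological + %d QC + %d conditioning injections, %d features\n",
              x$seed, n_bio, sum(x$metadata$role == "qc"),
              sum(x$metadata$role == "conditioning"), ncol(x$table$intensities)))
  cat(sprintf("  planted: %d region, %d pH, %d habitat, %d leaf-area features; %d RSD violators\n",
              sum(x$truth$affected_by == "region"),
              sum(x$truth$affected_by == "ph"),
              sum(x$truth$affected_by == "habitat"),
              sum(x$truth$affected_by == "leaf_area"),
              sum(x$truth$rsd_violator)))
  invisible(x)
}

#' Generate a null synthetic study (no planted effects)
#'
#' Identical to [generate_study()] but with all effect sets empty; used for
#' type-I-error and FDR-control simulations.
#'
#' @inheritParams generate_study
#' @return A `folmet_study` whose ground truth lists zero affected features.
#' @export
generate_null_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$n_region_features <- 0L
  cfg$n_ph_features <- 0L
  cfg$n_habitat_features <- 0L
  cfg$n_leafarea_features <- 0L
  generate_study(cfg, seed = seed)
}

#' Build a demonstration target list from a synthetic study
#'
#' Picks `n_present` stable features from the study's unfiltered table as
#' "known standards" (their true rt and m/z become the target definitions)
#' and invents `n_absent` targets whose windows contain no feature, mirroring
#' a targeted screen in which some standards are below detection. Compound
#' names are placeholders for iridoid/phenylethanoid glycoside standards.
#'
#' @param study a `folmet_study`.
#' @param n_present,n_absent counts of detectable and undetectable targets.
#' @param rt_tol,mz_tol matching windows (minutes, Daltons).
#' @param seed integer seed.
#' @return A data.frame with columns `compound`, `rt`, `mz`, `rt_tol`,
#'   `mz_tol`, and a logical `planted_present` flag.
#' @export
demo_targets <- function(study, n_present = 6, n_absent = 4,
                         rt_tol = 0.20, mz_tol = 0.05, seed = study$seed) {
  stopifnot(inherits(study, "folmet_study"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "targets"))
  tr <- study$truth
  pool <- which(!tr$rsd_violator & tr$pi > 0.6)
  sel <- sample(pool, n_present)
  absent <- matrix(NA_real_, n_absent, 2)
  k <- 0L
  while (k < n_absent) {
    cand_rt <- round(runif(1, 0.35, 6.70), 4)
    cand_mz <- round(runif(1, 100, 1000), 4)
    if (all(abs(tr$rt - cand_rt) > rt_tol | abs(tr$mz - cand_mz) > mz_tol)) {
      k <- k + 1L
      absent[k, ] <- c(cand_rt, cand_mz)
    }
  }
  data.frame(
    compound = sprintf("standard_%02d", seq_len(n_present + n_absent)),
    rt = c(tr$rt[sel], absent[, 1]),
    mz = c(tr$mz[sel], absent[, 2]),
    rt_tol = rt_tol, mz_tol = mz_tol,
    planted_present = rep(c(TRUE, FALSE), c(n_present, n_absent)),
    stringsAsFactors = FALSE)
}
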