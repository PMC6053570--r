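## The conditional log-normal (two-part hurdle) per-feature model.
##
## Untargeted feature intensities are non-negative with many exact zeros
## (feature absent or below detection). Each feature is modelled in two
## parts: a binary presence/absence submodel (logistic) and a log-normal
## submodel for the strictly positive intensities, both containing the
## factor of interest plus standing covariates (log leaf area; soil pH on a
## quadratic scale) and population / plant-within-population random
## intercepts where estimable. Because the likelihood factorizes, the
## likelihood-ratio statistics of the two parts add, as do their degrees of
## freedom, giving one combined chi-square test per feature and factor.

CLN_FACTORS <- c("region", "distance", "habitat", "light", "phenology",
                 "leaf_status", "soil_ph", "leaf_area")

## model term labels for each factor of interest
factor_terms <- function(factor) {
  switch(factor,
         region = "region", habitat = "habitat", light = "light",
         phenology = "phenology", leaf_status = "leaf_status",
         distance = c("pcnm1", "pcnm2"),
         soil_ph = c("ph_c", "I(ph_c^2)"),
         leaf_area = "log_la",
         stopf("unknown factor '%s' (expected one of: %s)", factor,
               paste(CLN_FACTORS, collapse = ", ")))
}

## standing covariates, dropping whichever the factor itself supplies
covariate_rhs <- function(factor) {
  cov <- c(if (factor != "leaf_area") "log_la",
           if (factor != "soil_ph") c("ph_c", "I(ph_c^2)"))
  if (length(cov)) paste(cov, collapse = " + ") else NULL
}

#' Specification of one conditional log-normal analysis
#'
#' @param factor the explanatory variable of interest; one of `"region"`,
#'   `"distance"` (two PCNM axes), `"habitat"`, `"light"`, `"phenology"`,
#'   `"leaf_status"` (herbivory), `"soil_ph"` (linear + quadratic),
#'   `"leaf_area"` (log scale).
#' @param method how the two parts are tested and combined.
#'   `"f_fisher"` (default): the positive part is a REML mixed fit tested
#'   with a joint Satterthwaite F for the factor's coefficients, the binary
#'   part with its likelihood-ratio chi-square, and the two p-values are
#'   combined by Fisher's method. `"lr_additive"`: both parts are ML fits
#'   compared to factor-free reductions, log-likelihood differences and df
#'   add across parts, and the combined statistic is referred to a
#'   chi-square ([combined_lr_test()]). The default is chosen for null
#'   calibration: with 15 populations the additive chi-square is
#'   anticonservative for between-population factors, while the
#'   Satterthwaite F tracks the effective degrees of freedom.
#' @param min_level_positives minimum positive observations required in
#'   every level of a categorical factor (default 2).
#' @param min_total_positives minimum positive observations overall
#'   (default 5).
#' @param binary_engine `"auto"` (random-intercept logistic with fallbacks),
#'   `"glm"` (plain logistic), or `"none"` (skip the binary part).
#' @param sep_coef_limit absolute logistic coefficient beyond which complete
#'   separation is declared and the binary contribution dropped.
#' @return An object of class `cln_spec`.
#' @export
cln_spec <- function(factor, method = c("f_fisher", "lr_additive"),
                     min_level_positives = 2, min_total_positives = 5,
                     binary_engine = c("auto", "glm", "none"),
                     sep_coef_limit = 15) {
  factor <- match.arg(factor, CLN_FACTORS)
  structure(list(factor = factor,
                 method = match.arg(method),
                 factor_terms = factor_terms(factor),
                 factor_rhs = paste(factor_terms(factor), collapse = " + "),
                 covariate_rhs = covariate_rhs(factor),
                 min_level_positives = min_level_positives,
                 min_total_positives = min_total_positives,
                 binary_engine = match.arg(binary_engine),
                 sep_coef_limit = sep_coef_limit),
            class = "cln_spec")
}

#' Build the per-sample design frame for conditional log-normal modelling
#'
#' Derives the modelling covariates from per-leaf metadata: factor-coded
#' design variables, centred soil pH (`ph_c`), log leaf area (`log_la`) and
#' the first two PCNM axes computed from the population coordinates (one
#' site per population) unless supplied.
#'
#' @param metadata per-leaf metadata (after [average_replicates()]).
#' @param pcnm optional [pcnm_axes()] with row labels matching populations.
#' @param ph_center centring constant for soil pH (default: sample mean).
#' @return A data.frame aligned with `metadata` rows.
#' @export
cln_design <- function(metadata, pcnm = NULL, ph_center = NULL) {
  md <- metadata
  if (is.null(pcnm)) {
    sites <- unique(md[, c("population", "latitude", "longitude")])
    d <- euclidean_distance(sites, labels = sites$population)
    pcnm <- pcnm_axes(d)
  }
  ax <- pcnm$vectors
  i <- match(md$population, rownames(ax))
  if (anyNA(i)) stopf("PCNM axes lack population(s): %s",
                      paste(unique(md$population[is.na(i)]), collapse = ", "))
  ctr <- ph_center %||% mean(md$soil_ph)
  data.frame(
    population = factor(md$population),
    plant_id = factor(md$plant_id),
    region = factor(md$region, levels = sort(unique(md$region))),
    habitat = factor(md$habitat), light = factor(md$light),
    phenology = factor(md$phenology), leaf_status = factor(md$leaf_status),
    log_la = log(md$leaf_area),
    ph_c = md$soil_ph - ctr,
    pcnm1 = ax[i, 1L], pcnm2 = if (ncol(ax) >= 2L) ax[i, 2L] else 0,
    stringsAsFactors = TRUE)
}

#' Eligibility of a feature for conditional log-normal testing
#'
#' A feature qualifies when it has at least `min_total_positives` positive
#' observations overall and, for a categorical factor, at least
#' `min_level_positives` positives within every factor level; all-zero
#' features never qualify. All-positive features qualify with a degenerate
#' (skipped) binary part.
#'
#' @param y per-sample intensities of one feature.
#' @param spec a [cln_spec()].
#' @param design the [cln_design()] frame.
#' @return A list: `eligible` (logical), `reason` (`"ok"`,
#'   `"all_zero"`, `"insufficient_positives"`, `"level_without_positives"`),
#'   `n_pos`, `all_positive`.
#' @export
cln_eligibility <- function(y, spec, design) {
  pos <- y > 0
  n_pos <- sum(pos)
  if (n_pos == 0L)
    return(list(eligible = FALSE, reason = "all_zero", n_pos = 0L,
                all_positive = FALSE))
  if (n_pos < spec$min_total_positives)
    return(list(eligible = FALSE, reason = "insufficient_positives",
                n_pos = n_pos, all_positive = FALSE))
  fv <- switch(spec$factor,
               region = design$region, habitat = design$habitat,
               light = design$light, phenology = design$phenology,
               leaf_status = design$leaf_status, NULL)
  if (!is.null(fv)) {
    counts <- tapply(pos, fv, sum)
    if (any(is.na(counts)) || any(counts < spec$min_level_positives))
      return(list(eligible = FALSE, reason = "level_without_positives",
                  n_pos = n_pos, all_positive = all(pos)))
  }
  list(eligible = TRUE, reason = "ok", n_pos = n_pos, all_positive = all(pos))
}

lmer_ctrl <- function() lme4::lmerControl(
  calc.derivs = FALSE, check.conv.singular = "ignore",
  check.conv.grad = "ignore", check.conv.hess = "ignore")

glmer_ctrl <- function() lme4::glmerControl(
  calc.derivs = FALSE, check.conv.singular = "ignore",
  check.conv.grad = "ignore", check.conv.hess = "ignore")

## random-effect ladder for the positive part: plant within population,
## population only, then no grouping (plain least squares)
POS_RE_LADDER <- c("(1 | population) + (1 | plant_id)", "(1 | population)", "")

## positive part, additive-LR flavour: ML mixed fits of the full and
## factor-free models, walking down the random-effect ladder together
fit_positive_lrt <- function(dat, spec) {
  rhs_full <- paste(c(spec$factor_rhs, spec$covariate_rhs), collapse = " + ")
  rhs_red <- spec$covariate_rhs %||% "1"
  for (re in POS_RE_LADDER) {
    fits <- tryCatch({
      if (nzchar(re)) {
        f <- function(rhs) lme4::lmer(
          stats::as.formula(paste0("log_y ~ ", rhs, " + ", re)),
          data = dat, REML = FALSE, control = lmer_ctrl())
        list(full = f(rhs_full), red = f(rhs_red), engine = "lmer")
      } else {
        f <- function(rhs) stats::lm(
          stats::as.formula(paste0("log_y ~ ", rhs)), data = dat)
        list(full = f(rhs_full), red = f(rhs_red), engine = "lm")
      }
    }, error = function(e) NULL)
    if (!is.null(fits)) break
  }
  llf <- logLik(fits$full); llr <- logLik(fits$red)
  df <- attr(llf, "df") - attr(llr, "df")
  lr <- max(0, 2 * (as.numeric(llf) - as.numeric(llr)))
  list(p = if (df >= 1) pchisq(lr, df, lower.tail = FALSE) else NA_real_,
       stat = lr, df = df, ll_full = as.numeric(llf),
       ll_red = as.numeric(llr), engine = fits$engine,
       fit_full = fits$full, data = dat)
}

## between-within (containment) bound on the denominator df: a factor
## varying at the population (or plant) level is tested against the
## corresponding between-group stratum, never against leaf-level residual
## df. This guards the Satterthwaite approximation when a random-effect
## variance is estimated at the zero boundary (common with 15 populations),
## which would otherwise hand the test far too many denominator df.
den_df_bound <- function(dat, spec, num_df) {
  npop <- length(unique(dat$population))
  nplant <- length(unique(dat$plant_id))
  switch(spec$factor,
         region = , distance = , habitat = , light =
           max(1, npop - num_df - 1),
         soil_ph = , phenology =
           max(1, nplant - npop - num_df),
         Inf)  # leaf-level factors: residual-level df is appropriate
}

## positive part, default flavour: one REML mixed fit, joint Satterthwaite
## F for the factor's coefficients (lmerTest::contest) with the
## between-within bound applied; exact partial F under the least-squares
## fallback
fit_positive_f <- function(dat, spec) {
  rhs_full <- paste(c(spec$factor_rhs, spec$covariate_rhs), collapse = " + ")
  for (re in POS_RE_LADDER) {
    if (nzchar(re)) {
      res <- tryCatch({
        fit <- lmerTest::lmer(
          stats::as.formula(paste0("log_y ~ ", rhs_full, " + ", re)),
          data = dat, REML = TRUE, control = lmer_ctrl())
        X <- lme4::getME(fit, "X")
        tl <- attr(stats::terms(fit, fixed.only = TRUE), "term.labels")
        idx <- which(attr(X, "assign") %in% which(tl %in% spec$factor_terms))
        if (length(idx) == 0L) stop("factor constant among positives")
        L <- diag(length(lme4::fixef(fit)))[idx, , drop = FALSE]
        ct <- lmerTest::contest(fit, L, joint = TRUE)
        if (!is.finite(ct[["Pr(>F)"]])) stop("Satterthwaite failed")
        den <- min(ct[["DenDF"]], den_df_bound(dat, spec, ct[["NumDF"]]))
        list(p = stats::pf(ct[["F value"]], ct[["NumDF"]], den,
                           lower.tail = FALSE),
             stat = ct[["F value"]], df = ct[["NumDF"]], den_df = den,
             engine = "lmer", fit_full = fit, data = dat)
      }, error = function(e) NULL)
      if (!is.null(res)) return(res)
    } else {
      rhs_red <- spec$covariate_rhs %||% "1"
      full <- stats::lm(stats::as.formula(paste0("log_y ~ ", rhs_full)), dat)
      red <- stats::lm(stats::as.formula(paste0("log_y ~ ", rhs_red)), dat)
      an <- stats::anova(red, full)
      den <- min(an[["Res.Df"]][2L],
                 den_df_bound(dat, spec, an[["Df"]][2L]))
      return(list(p = stats::pf(an[["F"]][2L], an[["Df"]][2L], den,
                                lower.tail = FALSE),
                  stat = an[["F"]][2L], df = an[["Df"]][2L], den_df = den,
                  engine = "lm", fit_full = full, data = dat))
    }
  }
}

fit_positive_part <- function(y, design, spec) {
  dat <- design[y > 0, , drop = FALSE]
  dat$log_y <- log(y[y > 0])
  dat <- droplevels(dat)
  if (spec$method == "f_fisher") fit_positive_f(dat, spec)
  else fit_positive_lrt(dat, spec)
}

## binary part: presence/absence logistic submodel with a fallback ladder --
## population random intercept, then fixed population effects (only when not
## aliased with the factor), then no grouping. Complete separation drops the
## binary contribution (df from the positive part only).
fit_binary_part <- function(y, design, spec) {
  z <- as.numeric(y > 0)
  none <- list(ll_full = 0, ll_red = 0, df = 0L, engine = "none", flag = "")
  if (all(z == 1) || spec$binary_engine == "none") return(none)
  dat <- design
  dat$z <- z
  rhs_full <- paste(c(spec$factor_rhs, spec$covariate_rhs), collapse = " + ")
  rhs_red <- spec$covariate_rhs %||% "1"
  pair <- NULL
  if (spec$binary_engine == "auto") {
    pair <- tryCatch({
      fml <- function(rhs) stats::as.formula(paste0("z ~ ", rhs, " + (1 | population)"))
      full <- suppressMessages(lme4::glmer(fml(rhs_full), data = dat,
                                           family = stats::binomial(),
                                           nAGQ = 0, control = glmer_ctrl()))
      red <- suppressMessages(lme4::glmer(fml(rhs_red), data = dat,
                                          family = stats::binomial(),
                                          nAGQ = 0, control = glmer_ctrl()))
      list(full = full, red = red, engine = "glmer",
           coefs = lme4::fixef(full))
    }, error = function(e) NULL)
    if (is.null(pair)) {
      ## fixed population effects, unless aliased with the factor terms
      mm <- model.matrix(stats::as.formula(paste0("~ ", rhs_full)), dat)
      mm2 <- cbind(mm, model.matrix(~ population, dat)[, -1L, drop = FALSE])
      if (qr(mm2)$rank == ncol(mm2)) {
        pair <- tryCatch({
          full <- stats::glm(stats::as.formula(
            paste0("z ~ ", rhs_full, " + population")), dat, family = stats::binomial())
          red <- stats::glm(stats::as.formula(
            paste0("z ~ ", rhs_red, " + population")), dat, family = stats::binomial())
          list(full = full, red = red, engine = "glm_pop", coefs = coef(full))
        }, error = function(e) NULL)
      }
    }
  }
  if (is.null(pair)) {
    pair <- tryCatch({
      full <- stats::glm(stats::as.formula(paste0("z ~ ", rhs_full)), dat,
                         family = stats::binomial())
      red <- stats::glm(stats::as.formula(paste0("z ~ ", rhs_red)), dat,
                        family = stats::binomial())
      list(full = full, red = red, engine = "glm", coefs = coef(full))
    }, error = function(e) NULL)
  }
  if (is.null(pair)) return(modifyList(none, list(flag = "binary_unfit")))
  if (any(abs(pair$coefs) > spec$sep_coef_limit, na.rm = TRUE))
    return(modifyList(none, list(flag = "binary_separation")))
  llf <- logLik(pair$full); llr <- logLik(pair$red)
  df <- attr(llf, "df") - attr(llr, "df")
  if (df <= 0L) return(modifyList(none, list(flag = "binary_degenerate")))
  list(ll_full = as.numeric(llf), ll_red = as.numeric(llr), df = df,
       engine = pair$engine, flag = "")
}

#' Combine part-wise likelihood-ratio contributions into one chi-square test
#'
#' The factorized two-part likelihood makes log-likelihood differences
#' additive across the binary and positive parts: `LR = 2 * sum(delta_ll)`,
#' `df = sum(df_parts)`, upper-tail chi-square p-value. Small negative LR
#' values (numerical noise) are clamped to zero; larger ones are flagged.
#'
#' @param delta_ll per-part log-likelihood differences (full minus reduced).
#' @param df per-part added parameter counts.
#' @param tol tolerance below which a negative LR is treated as zero.
#' @return A list: `lr`, `df`, `p`, `flag` (`""` or `"negative_lr"`).
#' @export
combined_lr_test <- function(delta_ll, df, tol = 1e-6) {
  lr <- 2 * sum(delta_ll)
  df <- sum(df)
  flag <- ""
  if (lr < 0) {
    if (lr < -tol) flag <- "negative_lr"
    lr <- 0
  }
  p <- if (df >= 1L) pchisq(lr, df, lower.tail = FALSE) else NA_real_
  list(lr = lr, df = df, p = p, flag = flag)
}

#' Combine independent p-values by Fisher's method
#'
#' `X = -2 sum(log p) ~ chi-square(2k)` under the joint null; a single
#' p-value passes through unchanged.
#'
#' @param p vector of p-values (NA dropped).
#' @return A list: `stat`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(list(stat = NA_real_, df = 0L, p = NA_real_))
  if (length(p) == 1L) return(list(stat = -2 * log(max(p, 1e-300)),
                                   df = 2L, p = p))
  x <- -2 * sum(log(pmax(p, 1e-300)))
  list(stat = x, df = 2L * length(p),
       p = pchisq(x, 2L * length(p), lower.tail = FALSE))
}

#' Fit the conditional log-normal model for one feature
#'
#' @param y per-sample intensities of one (eligible) feature.
#' @param design the [cln_design()] frame.
#' @param spec a [cln_spec()].
#' @return A list with `binary` and `positive` part summaries (statistics,
#'   df, p, engine), the combined `test` (stat, df, p, flag) built per
#'   `spec$method`, and `n_pos`.
#' @export
fit_cln <- function(y, design, spec) {
  stopifnot(inherits(spec, "cln_spec"), length(y) == nrow(design))
  pos <- fit_positive_part(y, design, spec)
  bin <- fit_binary_part(y, design, spec)
  bin$p <- if (bin$df >= 1L)
    pchisq(max(0, 2 * (bin$ll_full - bin$ll_red)), bin$df,
           lower.tail = FALSE) else NA_real_
  if (spec$method == "f_fisher") {
    test <- fisher_combine(c(pos$p, bin$p))
    test$flag <- ""
  } else {
    test <- combined_lr_test(
      delta_ll = c(bin$ll_full - bin$ll_red, pos$ll_full - pos$ll_red),
      df = c(bin$df, pos$df))
    test$stat <- test$lr
  }
  if (nzchar(bin$flag)) test$flag <- paste(c(test$flag[nzchar(test$flag)],
                                             bin$flag), collapse = ";")
  list(binary = bin, positive = pos, test = test, n_pos = sum(y > 0))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j>=i} p_(j) m / j`,
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return q-values in the original order.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")  # m = number of tested features
  q
}

#' Per-feature conditional log-normal analysis of one explanatory variable
#'
#' Runs eligibility screening, the two-part fit and the combined
#' likelihood-ratio test for every feature in the table, then adjusts the
#' p-values with [fdr_bh()].
#'
#' @param x an averaged [feature_table()] (one row per leaf).
#' @param metadata the matching per-leaf metadata.
#' @param factor explanatory variable (see [cln_spec()]).
#' @param spec optional [cln_spec()]; defaults to `cln_spec(factor)`.
#' @param pcnm optional [pcnm_axes()] passed to [cln_design()].
#' @return An object of class `cln_result`: a data.frame with one row per
#'   feature (`feature_id`, `eligible`, `reason`, `n_pos`, `df_binary`,
#'   `df_positive`, `p_binary`, `p_positive`, `stat`, `df`, `p`, `q`,
#'   `binary_engine`, `positive_engine`, `flag`), with the factor and spec
#'   attached as attributes.
#' @export
cln_analysis <- function(x, metadata, factor, spec = NULL, pcnm = NULL) {
  stopifnot(inherits(x, "feature_table"))
  spec <- spec %||% cln_spec(factor)
  md <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stopf("sample(s) without metadata")
  design <- cln_design(md, pcnm = pcnm)
  nfeat <- ncol(x$intensities)
  res <- data.frame(
    feature_id = x$feature_ids, eligible = FALSE, reason = "",
    n_pos = 0L, df_binary = NA_integer_, df_positive = NA_integer_,
    p_binary = NA_real_, p_positive = NA_real_,
    stat = NA_real_, df = NA_integer_, p = NA_real_, q = NA_real_,
    binary_engine = NA_character_, positive_engine = NA_character_,
    flag = "", stringsAsFactors = FALSE)
  for (j in seq_len(nfeat)) {
    y <- x$intensities[, j]
    el <- cln_eligibility(y, spec, design)
    res$eligible[j] <- el$eligible
    res$reason[j] <- el$reason
    res$n_pos[j] <- el$n_pos
    if (!el$eligible) next
    fit <- tryCatch(suppressWarnings(suppressMessages(fit_cln(y, design, spec))),
                    error = function(e) NULL)
    if (is.null(fit)) {
      res$eligible[j] <- FALSE
      res$reason[j] <- "unfit"
      next
    }
    res$df_binary[j] <- fit$binary$df
    res$df_positive[j] <- fit$positive$df
    res$p_binary[j] <- fit$binary$p
    res$p_positive[j] <- fit$positive$p
    res$stat[j] <- fit$test$stat
    res$df[j] <- fit$test$df
    res$p[j] <- fit$test$p
    res$binary_engine[j] <- fit$binary$engine
    res$positive_engine[j] <- fit$positive$engine
    res$flag[j] <- fit$test$flag %||% ""
  }
  res$q <- fdr_bh(res$p)
  structure(res, class = c("cln_result", "data.frame"),
            factor = spec$factor, spec = spec)
}

#' Significance tallies of a conditional log-normal analysis
#'
#' One summary row per analysis: features used, and counts significant at
#' `q < 0.20 / 0.10 / 0.05` and raw `p < 0.001 / 0.01 / 0.05`.
#'
#' @param res a [cln_analysis()] result.
#' @return A one-row data.frame.
#' @export
significance_tallies <- function(res) {
  stopifnot(inherits(res, "cln_result"))
  tested <- !is.na(res$p)
  data.frame(
    factor = attr(res, "factor"),
    n_used = sum(tested),
    q_lt_0.20 = sum(res$q < 0.20, na.rm = TRUE),
    q_lt_0.10 = sum(res$q < 0.10, na.rm = TRUE),
    q_lt_0.05 = sum(res$q < 0.05, na.rm = TRUE),
    p_lt_0.001 = sum(res$p < 0.001, na.rm = TRUE),
    p_lt_0.01 = sum(res$p < 0.01, na.rm = TRUE),
    p_lt_0.05 = sum(res$p < 0.05, na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' Tukey post hoc contrasts on the positive-part model scale
#'
#' For each requested feature, refits the positive-part mixed submodel and
#' reports all pairwise factor-level contrasts with studentized-range
#' (Tukey) adjustment; with two levels the adjusted p equals the unadjusted
#' contrast p. Levels without positive observations yield `NA` (untestable)
#' contrasts.
#'
#' @param x an averaged [feature_table()].
#' @param metadata the matching per-leaf metadata.
#' @param factor a categorical factor (`region`, `habitat`, `light`,
#'   `phenology`, `leaf_status`).
#' @param feature_ids features to test (typically those with `q < 0.20`).
#' @param pcnm optional [pcnm_axes()].
#' @return A data.frame of contrasts: `feature_id`, `contrast`, `estimate`,
#'   `se`, `p_tukey`.
#' @export
tukey_posthoc <- function(x, metadata, factor, feature_ids, pcnm = NULL) {
  if (!factor %in% c("region", "habitat", "light", "phenology", "leaf_status"))
    stopf("Tukey post hoc requires a categorical factor")
  spec <- cln_spec(factor)
  md <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  design <- cln_design(md, pcnm = pcnm)
  out <- vector("list", length(feature_ids))
  for (k in seq_along(feature_ids)) {
    j <- match(feature_ids[k], x$feature_ids)
    if (is.na(j)) stopf("unknown feature id: %s", feature_ids[k])
    y <- x$intensities[, j]
    pos <- fit_positive_part(y, design, spec)
    emm <- emmeans::emmeans(pos$fit_full, specs = factor,
                            lmer.df = "asymptotic", data = pos$data)
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    out[[k]] <- data.frame(feature_id = feature_ids[k],
                           contrast = prs$contrast,
                           estimate = prs$estimate, se = prs$SE,
                           p_tukey = prs$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
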