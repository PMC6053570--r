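## Ordination and variation partitioning: Bray-Curtis dissimilarity, NMDS
## (Kruskal stress-1, best of restarts), redundancy R^2 / adjusted R^2 by
## multivariate least squares, inclusion-exclusion variation partitioning,
## and marginal permutation F tests.

#' Bray-Curtis dissimilarity between samples
#'
#' `d_ij = sum|x_i - x_j| / sum(x_i + x_j)` over features; bounded in
#' `[0, 1]` for non-negative data.
#'
#' @param x a [feature_table()] or a non-negative samples x features matrix.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (any(m < 0)) stopf("Bray-Curtis requires non-negative intensities")
  tot <- rowSums(m)
  if (any(outer(tot, tot, `+`) == 0 & !diag(nrow(m))))
    stopf("a pair of samples has zero joint total")
  vegan::vegdist(m, method = "bray")
}

## one NMDS restart: chained monoMDS descent blocks recording the stress
## trace; each block restarts from the previous configuration, so the
## recorded stress sequence is non-increasing up to convergence noise
nmds_restart <- function(d, start, k, max_iter, block = 25L, tol = 1e-7) {
  conf <- start
  trace <- numeric(0)
  iter <- 0L
  prev <- Inf
  while (iter < max_iter) {
    fit <- vegan::monoMDS(d, y = conf, k = k, model = "global",
                          maxit = min(block, max_iter - iter),
                          smin = 1e-4, sratmax = 0.999999)
    conf <- fit$points
    trace <- c(trace, fit$stress)
    iter <- iter + block
    if (prev - fit$stress < tol) break
    prev <- fit$stress
  }
  list(points = conf, stress = fit$stress, trace = trace,
       converged = prev - fit$stress < tol)
}

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 between configuration distances and the input
#' dissimilarities (monotone regression descent), taking the best solution
#' over a principal-coordinates start plus random restarts. The returned
#' configuration is centred and rotated to its principal axes.
#'
#' @param d a `dist` of dissimilarities.
#' @param k target dimensionality (default 2; must be < number of samples).
#' @param restarts number of random restarts in addition to the PCoA start.
#' @param max_iter iteration budget per restart.
#' @param seed integer seed for the random starts.
#' @return An object of class `nmds_ordination`: `points` (n x k scores),
#'   `stress` (in `[0, 1]`), `converged`, `restart_stress` (final stress of
#'   every restart), `trace` (stress trace of the best restart), `seed`.
#' @export
nmds <- function(d, k = 2, restarts = 20, max_iter = 200, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (k >= n) stopf("k must be smaller than the number of samples")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- vector("list", restarts + 1L)
  pco <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(pco) < k) pco <- cbind(pco, matrix(rnorm(n * (k - ncol(pco)), 0, 1e-3), n))
  starts[[1L]] <- pco
  for (i in seq_len(restarts)) starts[[i + 1L]] <- matrix(rnorm(n * k), n, k)
  runs <- lapply(starts, function(s) nmds_restart(d, s, k, max_iter))
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  best <- runs[[which.min(stresses)]]
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pts <- pts %*% prcomp(pts, center = FALSE)$rotation
  colnames(pts) <- paste0("NMDS", seq_len(k))
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, stress = best$stress,
                 converged = best$converged, restart_stress = stresses,
                 trace = best$trace, seed = seed),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("nmds_ordination: %d samples in %d dimensions, stress %.4f (%s, %d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              length(x$restart_stress)))
  invisible(x)
}

## expand a predictor block (data.frame / matrix / vector) into a
## full-rank model matrix without intercept; treatment contrasts,
## alphabetically first level as reference
block_matrix <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  names(df) <- make.unique(make.names(names(df)), sep = "_")
  chr <- vapply(df, function(v) is.character(v) || is.factor(v), logical(1))
  df[chr] <- lapply(df[chr], factor)
  mm <- model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]
}

#' Redundancy R-squared of a multivariate response on predictors
#'
#' Multivariate least squares of the column-centred response on the encoded
#' predictors: `R^2` is the explained proportion of total sum of squares and
#' the adjusted value uses the Ezekiel correction
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`.
#'
#' @param Y numeric samples x features response matrix.
#' @param X predictor data.frame/matrix (categoricals become treatment
#'   contrasts).
#' @return A list: `r2`, `adj_r2`, `p` (predictor rank), `n`.
#' @export
redundancy_rsq <- function(Y, X) {
  Y <- as.matrix(Y)
  mm <- block_matrix(X)
  n <- nrow(Y)
  if (nrow(mm) != n) stopf("Y and X disagree on the number of samples")
  qx <- qr(cbind(1, mm))
  p <- qx$rank - 1L
  if (p < ncol(mm)) stopf("rank-deficient predictor matrix")
  if (n <= p + 1L) stopf("need n > p + 1 samples")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- qr.fitted(qx, Yc)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stopf("response has zero variance")
  r2 <- min(max(sum(fit^2) / ss_tot, 0), 1)  # guard rounding at a perfect fit
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), p = p, n = n)
}

#' Marginal permutation F test of a predictor block
#'
#' `F = (R^2 / p) / ((1 - R^2) / (n - p - 1))`; the null distribution is
#' obtained by permuting the rows of the response, and
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param Y response matrix.
#' @param X predictor block.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return A list: `F`, `p`, `r2`, `n_perm`, `seed`.
#' @export
permutation_f_test <- function(Y, X, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stopf("use at least 99 permutations")
  Y <- as.matrix(Y)
  obs <- redundancy_rsq(Y, X)
  fstat <- function(r2) (r2 / obs$p) / ((1 - r2) / (obs$n - obs$p - 1))
  f_obs <- fstat(obs$r2)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    fstat(redundancy_rsq(Y[sample(obs$n), , drop = FALSE], X)$r2)
  }, numeric(1))
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       r2 = obs$r2, n_perm = n_perm, seed = seed)
}

## all non-empty unions of block indices, e.g. "1", "12", "123"
union_keys <- function(nb) {
  keys <- unlist(lapply(seq_len(nb), function(k)
    apply(combn(nb, k), 2L, paste, collapse = "")))
  keys
}

#' Variation partitioning over 2-3 predictor blocks
#'
#' Computes the adjusted redundancy R-squared of every union of blocks and
#' solves the inclusion-exclusion system for unique and shared fractions;
#' the residual fraction is one minus the all-blocks adjusted R-squared.
#' Adjusted fractions may be slightly negative. Marginal (block-alone)
#' permutation F tests are attached per block.
#'
#' @param Y response matrix (samples x features).
#' @param blocks named list of 2-3 predictor blocks
#'   (data.frames/matrices/vectors aligned with `Y` rows).
#' @param n_perm permutations for the marginal tests (0 to skip).
#' @param seed integer seed.
#' @return An object of class `varpart_result`: `fractions` (named adjusted
#'   fractions: unique per block, shared combinations, `residual`),
#'   `adj_r2` and `raw_r2` per union, `tests` (per-block F and p), `n`.
#' @export
varpart_blocks <- function(Y, blocks, n_perm = 999, seed = 1L) {
  nb <- length(blocks)
  if (nb < 2L || nb > 3L) stopf("varpart_blocks supports 2 or 3 blocks")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stopf("blocks must be named")
  Y <- as.matrix(Y)
  keys <- union_keys(nb)
  fits <- lapply(keys, function(k) {
    idx <- as.integer(strsplit(k, "")[[1L]])
    Xs <- do.call(cbind, lapply(blocks[idx], block_matrix))
    redundancy_rsq(Y, Xs)
  })
  adj <- setNames(vapply(fits, `[[`, numeric(1), "adj_r2"), keys)
  raw <- setNames(vapply(fits, `[[`, numeric(1), "r2"), keys)
  ## membership matrix: fraction f (an intersection cell over a subset S of
  ## blocks) contributes to union U iff S and U intersect
  cells <- union_keys(nb)  # subsets of blocks labelling the fraction cells
  member <- vapply(cells, function(cell) {
    s <- as.integer(strsplit(cell, "")[[1L]])
    vapply(keys, function(k) {
      u <- as.integer(strsplit(k, "")[[1L]])
      as.numeric(length(intersect(s, u)) > 0L)
    }, numeric(1))
  }, numeric(length(keys)))
  frac <- solve(member, adj[keys])
  names(frac) <- vapply(cells, function(cell) {
    idx <- as.integer(strsplit(cell, "")[[1L]])
    paste(names(blocks)[idx], collapse = "&")
  }, character(1))
  all_key <- paste(seq_len(nb), collapse = "")
  frac <- c(frac, residual = unname(1 - adj[all_key]))
  tests <- NULL
  if (n_perm > 0) {
    tests <- lapply(seq_len(nb), function(i)
      permutation_f_test(Y, blocks[[i]], n_perm = n_perm,
                         seed = derive_seed(seed, names(blocks)[i])))
    names(tests) <- names(blocks)
  }
  structure(list(fractions = frac, adj_r2 = adj, raw_r2 = raw,
                 tests = tests, n = nrow(Y), block_names = names(blocks)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, digits = 3, ...) {
  cat(sprintf("varpart_result over %d samples, blocks: %s\n", x$n,
              paste(x$block_names, collapse = ", ")))
  cat("adjusted fractions:\n")
  print(round(x$fractions, digits))
  if (!is.null(x$tests)) {
    for (b in names(x$tests)) {
      t <- x$tests[[b]]
      cat(sprintf("  %s: F = %.3f, p = %.4g (%d permutations)\n",
                  b, t$F, t$p, t$n_perm))
    }
  }
  invisible(x)
}
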