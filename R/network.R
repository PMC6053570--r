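## Co-occurrence network over selected features: Spearman rank-correlation
## matrix with p-values, a significance-equivalent correlation threshold,
## positive-edge graph construction and per-region abundance profiles.

#' Spearman rank-correlation matrix with p-values
#'
#' Pairwise Spearman rho with average ranks for ties; p-values from the
#' t approximation (exact null distribution for n <= 10, via the standard
#' test machinery). Constant features give undefined correlations, reported
#' as `NA`.
#'
#' @param x samples x features matrix or a [feature_table()].
#' @return A list of symmetric matrices `rho` (unit diagonal) and `p`.
#' @export
spearman_matrix <- function(x) {
  m <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (nrow(m) < 3L) stopf("need at least 3 samples")
  if (ncol(m) < 2L) stopf("need at least 2 features")
  nf <- ncol(m)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  const <- apply(m, 2L, function(v) var(v) == 0)
  rho[const, ] <- NA_real_; rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  p <- matrix(NA_real_, nf, nf, dimnames = dimnames(rho))
  n <- nrow(m)
  for (i in seq_len(nf - 1L)) {
    if (const[i]) next
    for (j in seq((i + 1L), nf)) {
      if (const[j]) next
      ct <- suppressWarnings(
        cor.test(m[, i], m[, j], method = "spearman",
                 exact = n <= 10))
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(p) <- ifelse(const, NA_real_, 0)
  list(rho = rho, p = p, n = n)
}

## all n! Spearman rho values for ranks 1..n vs a permutation
enumerate_spearman <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  base <- seq_len(n)
  vapply(perms(base), function(p) 1 - 6 * sum((base - p)^2) / (n * (n^2 - 1)),
         numeric(1))
}

#' Critical Spearman correlation for a given significance level
#'
#' The smallest rho whose two-sided p-value does not exceed `alpha`: by
#' exhaustive permutation enumeration for `n <= 8`, and by inverting the
#' t approximation (`t = rho * sqrt((n - 2) / (1 - rho^2))`) otherwise.
#' At `n = 47` and `alpha = 0.01` this reproduces the conventional 0.372
#' co-occurrence threshold.
#'
#' @param n number of samples (>= 4).
#' @param alpha significance level.
#' @param two_sided logical (default `TRUE`).
#' @return The critical rho in `[0, 1]`.
#' @export
critical_rho <- function(n, alpha = 0.01, two_sided = TRUE) {
  if (n < 4) stopf("need n >= 4")
  if (alpha >= 1) return(0)
  if (n <= 8) {
    rhos <- enumerate_spearman(n)
    cand <- sort(unique(abs(rhos)))
    for (r in cand) {
      exceed <- if (two_sided) mean(abs(rhos) >= r - 1e-12)
                else mean(rhos >= r - 1e-12)
      if (exceed <= alpha) return(r)
    }
    return(Inf)  # alpha unattainably small even for perfect correlation
  }
  a <- if (two_sided) alpha / 2 else alpha
  tstar <- qt(1 - a, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Features are nodes; an undirected edge joins two features whose Spearman
#' rho meets the threshold (and is positive, by default, since only positive
#' correlations indicate co-occurrence). Isolated nodes are retained and
#' connected components labelled.
#'
#' @param sp a [spearman_matrix()] result (or a plain symmetric rho matrix).
#' @param threshold minimum rho for an edge (default 0.372, the conventional
#'   p < 0.01 equivalence; see [critical_rho()] to recompute from `n`).
#' @param positive_only drop non-positive correlations (default `TRUE`).
#' @return An object of class `cooc_network`: `nodes` (data.frame
#'   `feature_id`, `component`, `degree`), `edges` (data.frame `from`, `to`,
#'   `rho`, `p`), `graph` (an igraph object), `threshold`, `n_samples`.
#' @export
build_network <- function(sp, threshold = 0.372, positive_only = TRUE) {
  if (is.matrix(sp)) sp <- list(rho = sp, p = NULL, n = NA_integer_)
  rho <- sp$rho
  if (!isTRUE(all.equal(rho, t(rho), check.attributes = FALSE)))
    stopf("rho matrix must be symmetric")
  ids <- colnames(rho) %||% as.character(seq_len(ncol(rho)))
  adj <- !is.na(rho) & rho >= threshold
  if (positive_only) adj <- adj & rho > 0
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      rho = rho[idx],
                      p = if (!is.null(sp$p)) sp$p[idx] else NA_real_,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  nodes <- data.frame(feature_id = ids,
                      component = comp$membership[ids],
                      degree = igraph::degree(g)[ids],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, n_samples = sp$n),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (rho >= %.3f), %d components\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              length(unique(x$nodes$component))))
  invisible(x)
}

#' Mean abundance of each feature within each geographic region
#'
#' The per-node three-component profile used to annotate co-occurrence
#' networks (the pie-chart fractions): arithmetic mean of the (normalized)
#' intensity per region.
#'
#' @param x an averaged [feature_table()].
#' @param metadata the matching per-leaf metadata (with `region`).
#' @param feature_ids features to profile (default: all).
#' @return A features x regions matrix of mean abundances.
#' @export
region_profiles <- function(x, metadata, feature_ids = NULL) {
  stopifnot(inherits(x, "feature_table"))
  md <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$region)) stopf("region missing for some samples")
  feature_ids <- feature_ids %||% x$feature_ids
  j <- match(feature_ids, x$feature_ids)
  if (anyNA(j)) stopf("unknown feature id(s)")
  regions <- REGION_LEVELS[REGION_LEVELS %in% md$region]
  if (length(regions) == 0L) stopf("empty region")
  prof <- vapply(regions, function(r)
    colMeans(x$intensities[md$region == r, j, drop = FALSE]),
    numeric(length(j)))
  prof <- matrix(prof, nrow = length(j),
                 dimnames = list(feature_ids, regions))
  prof
}

#' Export a co-occurrence network as GraphML (plus a plain edge list)
#'
#' Node attributes carry the per-region mean-abundance profile and overall
#' mean abundance; edge attributes carry rho and p.
#'
#' @param net a [build_network()] result.
#' @param profiles a [region_profiles()] matrix covering the nodes.
#' @param path output GraphML path.
#' @param edgelist_path optional path for a tab-separated edge list.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, profiles, path, edgelist_path = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  ids <- igraph::V(g)$name
  i <- match(ids, rownames(profiles))
  if (anyNA(i)) stopf("profiles do not cover all nodes")
  for (r in colnames(profiles)) {
    g <- igraph::set_vertex_attr(g, paste0("mean_", r), value = profiles[i, r])
  }
  g <- igraph::set_vertex_attr(g, "mean_abundance",
                               value = rowMeans(profiles)[i])
  g <- igraph::set_vertex_attr(g, "component",
                               value = net$nodes$component[match(ids, net$nodes$feature_id)])
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(edgelist_path)) {
    utils::write.table(net$edges, edgelist_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
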