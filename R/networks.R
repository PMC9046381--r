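#' Thresholded Spearman co-occurrence network
#'
#' All-pairs Spearman correlations (mid-rank ties) between taxa across
#' samples; an undirected edge is kept iff `|rho| > rho_threshold` and the
#' Benjamini-Hochberg adjusted two-sided p-value is below `fdr_alpha`.
#' Taxa below the prevalence floor are removed before testing, and
#' constant (zero-variance) taxa are skipped with their count reported.
#' Two-sided p-values use the t approximation for n >= 8 samples and exact
#' permutation enumeration below. By default all tested taxa remain as
#' vertices (isolated ones included), mirroring published topology tables
#' whose vertex counts exceed the edge-incident taxa.
#'
#' @param table an [otu_table()] with >= 4 samples.
#' @param rho_threshold minimum |rho| for an edge (strict; default 0.6).
#' @param fdr_alpha BH-adjusted significance threshold (default 0.05).
#' @param min_prevalence minimum fraction of samples a taxon must occur in
#'   (default 0 = keep all).
#' @param keep_isolated retain vertices with no incident edge.
#' @return `cooccurrence_network` list: `vertices` (taxon_id, rel_abund,
#'   prevalence), `edges` (taxon_a, taxon_b, rho, p_adjusted, sign),
#'   `n_samples`, `skipped_constant` (count of constant taxa excluded).
#' @export
spearman_cooccurrence <- function(table, rho_threshold = 0.6,
                                  fdr_alpha = 0.05, min_prevalence = 0,
                                  keep_isolated = TRUE) {
  mat <- as_otu_matrix(table)
  n <- nrow(mat)
  if (n < 4) stop("need at least 4 samples")
  prevalence <- colMeans(mat > 0)
  mat <- mat[, prevalence >= min_prevalence, drop = FALSE]
  prevalence <- prevalence[prevalence >= min_prevalence]
  constant <- apply(mat, 2, function(x) length(unique(x)) == 1)
  n_constant <- sum(constant)
  if (n_constant > 0) {
    ca_log("spearman_cooccurrence: %d constant taxa skipped", n_constant)
    mat <- mat[, !constant, drop = FALSE]
    prevalence <- prevalence[!constant]
  }
  T_ <- ncol(mat)
  if (T_ < 2) stop("fewer than 2 variable taxa to correlate")

  rho <- cor(mat, method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  rho_v <- rho[idx]
  p_v <- spearman_pvalue(rho_v, n, mat, idx)
  p_adj <- p.adjust(p_v, method = "BH")
  keep <- abs(rho_v) > rho_threshold & p_adj < fdr_alpha &
    is.finite(rho_v)
  taxa <- colnames(mat)
  edges <- data.frame(taxon_a = taxa[idx[keep, 1]],
                      taxon_b = taxa[idx[keep, 2]],
                      rho = rho_v[keep],
                      p_adjusted = p_adj[keep],
                      sign = ifelse(rho_v[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE, row.names = NULL)
  rel <- colSums(mat) / sum(mat)
  vertices <- data.frame(taxon_id = taxa, rel_abund = as.numeric(rel),
                         prevalence = as.numeric(prevalence),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (!keep_isolated) {
    used <- unique(c(edges$taxon_a, edges$taxon_b))
    vertices <- vertices[vertices$taxon_id %in% used, , drop = FALSE]
  }
  structure(list(vertices = vertices, edges = edges, n_samples = n,
                 skipped_constant = n_constant),
            class = "cooccurrence_network")
}

# two-sided Spearman p-values: t approximation for n >= 8, exact
# enumeration of all n! rank permutations below (n <= 7)
spearman_pvalue <- function(rho_v, n, mat, idx) {
  if (n >= 8) {
    t_stat <- rho_v * sqrt((n - 2) / pmax(1 - rho_v^2, 1e-300))
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    p[abs(rho_v) >= 1 - 1e-12] <- 0
    return(pmin(p, 1))
  }
  perms <- all_permutations(n)
  vapply(seq_along(rho_v), function(e) {
    x <- rank(mat[, idx[e, 1]])
    y <- rank(mat[, idx[e, 2]])
    null_rho <- apply(perms, 1, function(pm) cor(x, y[pm]))
    mean(abs(null_rho) >= abs(rho_v[e]) - 1e-12)
  }, numeric(1))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

network_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("taxon_a", "taxon_b"), drop = FALSE],
    directed = FALSE, vertices = graph$vertices$taxon_id)
}

#' Network topology metrics
#'
#' The standard co-occurrence topology panel: edge/vertex counts,
#' connectance `E / (V (V - 1) / 2)`, average degree `2 E / V`, average
#' shortest-path length over connected (reachable) pairs, diameter (max
#' eccentricity within components), global transitivity (3 x triangles /
#' connected triples), number of connected components, and Freeman
#' centralizations of degree, betweenness and closeness normalized by
#' their theoretical maxima.
#'
#' @param graph a `cooccurrence_network` from [spearman_cooccurrence()].
#' @return one-row data.frame (`topology_metrics`).
#' @export
network_topology <- function(graph) {
  g <- network_igraph(graph)
  V_ <- igraph::vcount(g)
  E_ <- igraph::ecount(g)
  if (V_ < 1) stop("graph has no vertices")
  pos <- sum(graph$edges$sign == "positive")
  neg <- sum(graph$edges$sign == "negative")
  if (V_ <= 1) {
    warning("graph has a single vertex; path metrics reported as 0")
    apl <- 0; diam <- 0
  } else {
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    if (is.nan(apl)) apl <- 0  # no connected pair at all
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  }
  clust <- igraph::transitivity(g, type = "global")
  if (is.nan(clust)) clust <- 0
  comp <- igraph::components(g)$no
  centr_deg <- if (V_ > 2) {
    igraph::centr_degree(g, loops = FALSE)$centralization
  } else 0
  centr_btw <- if (V_ > 2) igraph::centr_betw(g)$centralization else 0
  centr_clo <- if (V_ > 2) {
    suppressWarnings(igraph::centr_clo(g)$centralization)
  } else 0
  if (is.nan(centr_clo)) centr_clo <- 0
  structure(data.frame(
    edges = E_, positive_edges = pos, negative_edges = neg,
    vertices = V_,
    connectance = if (V_ > 1) E_ / (V_ * (V_ - 1) / 2) else 0,
    average_degree = 2 * E_ / V_,
    average_path_length = apl, diameter = diam,
    clustering_coefficient = clust, clusters = comp,
    centralization_degree = centr_deg,
    centralization_betweenness = centr_btw,
    centralization_closeness = centr_clo,
    row.names = NULL), class = c("topology_metrics", "data.frame"))
}

#' Compare a network against Erdos-Renyi randomizations
#'
#' Draws `n_random` G(V, E) graphs with the observed vertex and edge
#' counts and reports z-scores for the global clustering coefficient and
#' the average path length:
#' `z = (observed - mean_random) / sd_random`. A z-score far from zero
#' flags non-random ("small-world") structure. When the random ensemble is
#' degenerate (sd 0, e.g. a complete graph) the z-score is `NaN` with a
#' warning.
#'
#' @param graph a `cooccurrence_network` with >= 3 vertices and >= 1 edge.
#' @param n_random number of random graphs (default 1000).
#' @param seed integer seed.
#' @return list with `z_clustering`, `z_path_length`, and the random-
#'   ensemble means and sds.
#' @export
random_network_comparison <- function(graph, n_random = 1000, seed = NULL) {
  g <- network_igraph(graph)
  V_ <- igraph::vcount(g)
  E_ <- igraph::ecount(g)
  if (V_ < 3 || E_ < 1) stop("need >= 3 vertices and >= 1 edge")
  obs_clust <- igraph::transitivity(g, type = "global")
  if (is.nan(obs_clust)) obs_clust <- 0
  obs_apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  stats <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      rg <- igraph::sample_gnm(V_, E_)
      cc <- igraph::transitivity(rg, type = "global")
      c(clust = if (is.nan(cc)) 0 else cc,
        apl = igraph::mean_distance(rg, directed = FALSE,
                                    unconnected = TRUE))
    }, c(clust = 0, apl = 0))
  })
  m <- rowMeans(stats)
  s <- apply(stats, 1, sd)
  z <- (c(obs_clust, obs_apl) - m) / s
  if (any(s == 0)) {
    warning("degenerate random ensemble (sd 0); z reported as NaN")
    z[s == 0] <- NaN
  }
  list(z_clustering = z[[1]], z_path_length = z[[2]],
       observed = c(clustering = obs_clust, path_length = obs_apl),
       random_mean = c(clustering = m[[1]], path_length = m[[2]]),
       random_sd = c(clustering = s[[1]], path_length = s[[2]]),
       n_random = as.integer(n_random))
}

#' Build one co-occurrence network per metadata group
#'
#' Splits the samples by a metadata column and runs
#' [spearman_cooccurrence()] plus [network_topology()] independently per
#' group (BH correction is applied within each group's test family).
#' Groups with fewer than `min_samples` samples are skipped with a
#' warning.
#'
#' @inheritParams spearman_cooccurrence
#' @param meta metadata data.frame (sample rownames).
#' @param group_column metadata column to split on.
#' @param min_samples minimum samples per group (default 4).
#' @return list with `networks` (named list of `cooccurrence_network`) and
#'   `topology` (one row per group).
#' @export
networks_by_group <- function(table, meta, group_column, min_samples = 4,
                              rho_threshold = 0.6, fdr_alpha = 0.05,
                              min_prevalence = 0) {
  mat <- as_otu_matrix(table)
  if (!group_column %in% names(meta)) {
    stop("no metadata column '", group_column, "'")
  }
  groups <- split(rownames(meta), meta[[group_column]])
  nets <- list()
  topo <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], rownames(mat))
    if (length(ids) < min_samples) {
      warning(sprintf("group '%s': only %d sample(s); skipped", g,
                      length(ids)))
      next
    }
    sub <- suppressWarnings(otu_table(mat[ids, , drop = FALSE]))
    nets[[g]] <- spearman_cooccurrence(sub, rho_threshold, fdr_alpha,
                                       min_prevalence)
    topo[[g]] <- cbind(group = g, network_topology(nets[[g]]))
  }
  list(networks = nets, topology = do.call(rbind, topo))
}
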