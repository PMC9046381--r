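#' Rarefy counts to a common depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]); samples shallower than `depth` are dropped
#' with a warning. Used upstream of alpha diversity so richness and Shannon
#' are compared at equal sequencing effort.
#'
#' @param table raw-count [otu_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed.
#' @return rarefied [otu_table()]; every row sums to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = NULL) {
  mat <- as_otu_matrix(table)
  if (is_normalized(table)) stop("rarefaction needs raw integer counts")
  if (depth < 1) stop("depth must be >= 1")
  if (any(mat != round(mat))) stop("rarefaction needs integer counts")
  tot <- rowSums(mat)
  shallow <- tot < depth
  if (all(shallow)) stop("every sample is below the rarefaction depth")
  if (any(shallow)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s", sum(shallow),
                    depth, paste(rownames(mat)[shallow], collapse = ", ")))
    mat <- mat[!shallow, , drop = FALSE]
  }
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # non-count input); integer counts are already validated above
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(mat, depth)))
  otu_table(out)
}

#' TMM normalization
#'
#' Trimmed mean of M-values scaling factors via [edgeR::calcNormFactors()]:
#' log-ratio trimming `trim_m`, intensity (absolute level) trimming
#' `trim_a`, reference sample chosen as the one whose upper quartile is
#' closest to the mean upper quartile, factors rescaled to geometric mean
#' one. Normalized abundances are `counts / (library size * factor)`, i.e.
#' composition-corrected relative abundances.
#'
#' @param table raw-count [otu_table()].
#' @param trim_m fraction of extreme log-ratios trimmed (default 0.3).
#' @param trim_a fraction of extreme intensities trimmed (default 0.05).
#' @return normalized [otu_table()] with attribute `norm_factors`
#'   (per-sample TMM factors, geometric mean 1).
#' @export
tmm_normalize <- function(table, trim_m = 0.3, trim_a = 0.05) {
  mat <- as_otu_matrix(table)
  dge <- edgeR::DGEList(counts = t(mat))
  dge <- edgeR::calcNormFactors(dge, method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a)
  factors <- dge$samples$norm.factors
  names(factors) <- rownames(mat)
  norm <- sweep(mat, 1, rowSums(mat) * factors, "/")
  out <- otu_table(norm, normalized = TRUE)
  attr(out, "norm_factors") <- factors
  out
}

#' Per-sample alpha diversity
#'
#' Richness (count of taxa with non-zero counts) and the Shannon index in
#' natural-log units (nats), `-sum(p_i * ln p_i)` over non-zero relative
#' abundances.
#'
#' @param table an [otu_table()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  mat <- as_otu_matrix(table)
  richness <- rowSums(mat > 0)
  shannon <- vegan::diversity(mat, index = "shannon")
  data.frame(sample_id = rownames(mat),
             richness = as.integer(richness),
             shannon = as.numeric(shannon),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity
#'
#' Rows are first standardized to relative abundances, then
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; output values lie in
#' \[0, 1\] and are invariant to scaling any sample's counts.
#'
#' @param table an [otu_table()] with >= 2 samples.
#' @return [dist_matrix()] of kind `bray_curtis`.
#' @export
bray_curtis <- function(table) {
  rel <- relative_abundance(table)
  if (nrow(rel) < 2) stop("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(rel, method = "bray"))
  dist_matrix(d, kind = "bray_curtis")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double-centre `-D^2/2`, eigendecompose, and
#' scale eigenvectors by the square roots of the positive eigenvalues.
#' Negative eigenvalues (semi-metric input such as Bray-Curtis) are
#' reported but excluded from `proportion_explained`; no Lingoes/Cailliez
#' correction is applied.
#'
#' @param dist a [dist_matrix()].
#' @param k number of axes requested; truncated (with a warning) to the
#'   number of positive eigenvalues.
#' @return list (`pcoa_result`) with `coordinates` (n x k), `eigenvalues`
#'   (all, descending) and `proportion_explained` (over positive
#'   eigenvalues, one entry per returned axis).
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  n_pos <- sum(pos)
  if (k > n_pos) {
    warning(sprintf("k = %d exceeds the %d positive eigenvalues; truncated",
                    k, n_pos))
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained =
                   eig[seq_len(k)] / sum(eig[eig > 0])),
            class = "pcoa_result")
}

#' Permutational multivariate analysis of variance
#'
#' One-factor perMANOVA on a distance matrix (Anderson's pseudo-F, via
#' [vegan::adonis2()]): total sum of squares from all pairwise distances,
#' within-group sum of squares from within-group distances,
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`, and
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_permutations + 1)` under free
#' permutation of the group labels (no strata).
#'
#' @param dist a [dist_matrix()].
#' @param grouping factor or character vector of group labels, aligned with
#'   the distance ids.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return list (`permanova_result`) with `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, grouping, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  grouping <- factor(grouping)
  if (length(grouping) != nrow(d)) {
    stop("grouping length must match the distance matrix")
  }
  if (nlevels(droplevels(grouping)) < 2) {
    stop("perMANOVA needs at least 2 groups with samples")
  }
  df <- data.frame(group = grouping)
  fit <- with_seed(seed,
    vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                   permutations = n_permutations))
  structure(list(pseudo_F = fit$F[1],
                 r_squared = min(max(fit$R2[1], 0), 1),
                 p_value = fit$`Pr(>F)`[1],
                 n_permutations = as.integer(n_permutations)),
            class = "permanova_result")
}
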