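#' Between-community mean nearest taxon distance
#'
#' For each ordered community pair (k, l), the abundance-weighted mean over
#' taxa i present in k of the patristic distance from i to its nearest
#' relative in l; the reported value is the average of both directions.
#' With `weighted = TRUE` (default) taxa are weighted by their relative
#' abundances, otherwise each of the `richness` taxa weighs `1/richness`.
#' Identical communities score exactly zero (every taxon's nearest taxon in
#' the other community is itself).
#'
#' @param table an [otu_table()]; every taxon with a non-zero count must be
#'   a tip of `tree`.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param weighted abundance weighting flag.
#' @return [dist_matrix()] of kind `beta_mntd`.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  mat <- as_otu_matrix(table)
  present <- colSums(mat) > 0
  mat <- mat[, present, drop = FALSE]
  missing <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing)) {
    stop("taxa with non-zero counts absent from the tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  }
  no_taxa <- rowSums(mat > 0) == 0
  if (any(no_taxa)) {
    stop("sample(s) with no tree-matched taxa: ",
         paste(rownames(mat)[no_taxa], collapse = ", "))
  }
  D <- patristic_matrix(tree, colnames(mat))
  F <- mntd_weights(mat, weighted)
  dist_matrix(bmntd_core(D, F), ids = rownames(mat), kind = "beta_mntd")
}

# patristic (cophenetic) distances restricted and ordered to `taxa`
patristic_matrix <- function(tree, taxa) {
  D <- ape::cophenetic.phylo(tree)
  D[taxa, taxa, drop = FALSE]
}

# per-sample taxon weights: relative abundance or 1/richness
mntd_weights <- function(mat, weighted) {
  if (weighted) {
    relative_abundance(mat)
  } else {
    pa <- (mat > 0) * 1
    sweep(pa, 1, rowSums(pa), "/")
  }
}

# core bMNTD kernel shared by the observed value and the null replicates.
# D: taxa x taxa patristic matrix; F: samples x taxa weight matrix whose
# rows sum to 1. Returns the symmetric samples x samples bMNTD matrix.
bmntd_core <- function(D, F) {
  n <- nrow(F)
  supp <- lapply(seq_len(n), function(k) which(F[k, ] > 0))
  # Dmin[i, l] = distance from taxon i to its nearest taxon in sample l
  Dmin <- vapply(supp, function(idx) {
    if (length(idx) == 1L) D[, idx]
    else do.call(pmin, lapply(idx, function(j) D[, j]))
  }, numeric(nrow(D)))
  B <- F %*% Dmin            # B[k, l] = direction k -> l
  M <- (B + t(B)) / 2
  diag(M) <- 0
  unname(M)
}

#' Beta nearest taxon index
#'
#' z-score of the observed [beta_mntd()] against a null distribution
#' obtained by shuffling taxon labels across all tree tips: each of the
#' `n_null` replicates draws one permutation of the patristic matrix,
#' applied to all sample pairs simultaneously (so the matrix is exactly
#' symmetric and cross-pair correlation is preserved).
#' `bNTI(k,l) = (bMNTD_obs - mean_null) / sd_null`; pairs whose null
#' standard deviation is zero (e.g. a star phylogeny) are reported `NaN`
#' with a warning. |bNTI| >= 2 signals selection (phylogenetic turnover
#' more, or less, than expected by chance); |bNTI| < 2 is consistent with
#' stochastic assembly.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip-shuffle replicates (>= 99).
#' @param seed integer seed.
#' @return [dist_matrix()] of kind `beta_nti` (signed z-scores).
#' @export
beta_nti <- function(table, tree, n_null = 999, weighted = TRUE,
                     seed = NULL) {
  if (n_null < 99) stop("n_null must be >= 99")
  mat <- as_otu_matrix(table)
  present <- colSums(mat) > 0
  mat <- mat[, present, drop = FALSE]
  missing <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing)) {
    stop("taxa with non-zero counts absent from the tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  D <- patristic_matrix(tree, colnames(mat))
  F <- mntd_weights(mat, weighted)
  obs <- bmntd_core(D, F)
  T_ <- ncol(mat)
  acc <- matrix(0, nrow(obs), ncol(obs))
  acc2 <- matrix(0, nrow(obs), ncol(obs))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(T_)
      null_b <- bmntd_core(D[perm, perm], F)
      acc <- acc + null_b
      acc2 <- acc2 + null_b^2
    }
  })
  mean_null <- acc / n_null
  var_null <- pmax((acc2 - n_null * mean_null^2) / (n_null - 1), 0)
  sd_null <- sqrt(var_null)
  z <- (obs - mean_null) / sd_null
  degenerate <- sd_null <= .Machine$double.eps^0.5
  diag(degenerate) <- FALSE
  if (any(degenerate)) {
    warning(sprintf("%d pair(s) with zero null sd reported as NaN",
                    sum(degenerate[lower.tri(degenerate)])))
    z[degenerate] <- NaN
  }
  diag(z) <- 0
  dimnames(z) <- list(rownames(mat), rownames(mat))
  dist_matrix(z, kind = "beta_nti")
}

# one null community per sample: draw `richness` member taxa weighted by
# occurrence frequency, give each one read, allocate the remaining reads
# multinomially by metacommunity relative abundance
rc_null_counts <- function(richness, totals, occ_freq, abund, T_) {
  n <- length(richness)
  out <- matrix(0, n, T_)
  for (k in seq_len(n)) {
    members <- sample.int(T_, richness[k], prob = occ_freq)
    out[k, members] <- 1
    extra <- totals[k] - richness[k]
    if (extra > 0) {
      w <- abund[members]
      if (sum(w) <= 0) w <- rep(1, length(members))
      out[k, members] <- out[k, members] +
        rmultinom(1, extra, w)[, 1]
    }
  }
  out
}

#' Bray-Curtis Raup-Crick index
#'
#' Null-model-standardized Bray-Curtis dissimilarity in \[-1, 1\]. Each
#' null replicate rebuilds every sample with its observed richness and
#' read total: member taxa are drawn without replacement with probability
#' proportional to their occurrence frequency across the table, each
#' member receives one read, and the remaining reads are allocated
#' multinomially in proportion to the taxon's total relative abundance.
#' For each pair, `RC_raw = (#\{null BC < obs BC\} + 0.5 * ties) / n_null`
#' and `RC = 2 (RC_raw - 0.5)`. RC > 0.95 indicates dispersal limitation,
#' RC < -0.95 homogenizing dispersal, |RC| <= 0.95 drift (conditional on
#' |bNTI| < 2).
#'
#' @param table raw-count [otu_table()].
#' @param n_null number of null replicates.
#' @param seed integer seed.
#' @return [dist_matrix()] of kind `raup_crick`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL) {
  mat <- as_otu_matrix(table)
  if (any(mat != round(mat))) stop("Raup-Crick needs integer counts")
  present <- colSums(mat) > 0
  mat <- mat[, present, drop = FALSE]
  T_ <- ncol(mat)
  richness <- rowSums(mat > 0)
  if (any(richness > T_)) stop("sample richness exceeds the taxa pool")
  totals <- rowSums(mat)
  occ_freq <- colMeans(mat > 0)
  abund <- colSums(mat) / sum(mat)
  obs <- as.matrix(vegan::vegdist(relative_abundance(mat), method = "bray"))

  n <- nrow(mat)
  less <- matrix(0, n, n)
  ties <- matrix(0, n, n)
  tol <- 1e-12
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      null_mat <- rc_null_counts(richness, totals, occ_freq, abund, T_)
      null_bc <- as.matrix(vegan::vegdist(
        sweep(null_mat, 1, rowSums(null_mat), "/"), method = "bray"))
      less <- less + (null_bc < obs - tol)
      ties <- ties + (abs(null_bc - obs) <= tol)
    }
  })
  rc <- 2 * ((less + 0.5 * ties) / n_null - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(mat), rownames(mat))
  dist_matrix(rc, kind = "raup_crick")
}

#' Partition assembly into five ecological processes
#'
#' Applies the standard two-stage threshold rule to the pairwise
#' [beta_nti()] and [raup_crick_bray()] matrices: bNTI > 2 indicates
#' heterogeneous (variable) selection and bNTI < -2 homogeneous selection;
#' among the remaining (stochastic, |bNTI| <= 2) pairs, RC > 0.95
#' indicates dispersal limitation, RC < -0.95 homogenizing dispersal, and
#' |RC| <= 0.95 drift. All inequalities are strict, so bNTI exactly +/-2
#' is stochastic and RC exactly +/-0.95 falls to drift. Pairs with NaN
#' bNTI are excluded from the fractions and counted in `excluded_pairs`.
#'
#' @param bnti [dist_matrix()] of kind `beta_nti`.
#' @param rc [dist_matrix()] of kind `raup_crick`, same ids.
#' @return `assembly_partition` list: `pairs` (long data.frame with bnti,
#'   rc, process), `fractions` (named, sums to 1), `deterministic_fraction`
#'   (|bNTI| >= 2), `stochastic_fraction`, `excluded_pairs`, `n_pairs`.
#' @export
partition_processes <- function(bnti, rc) {
  if (!identical(rownames(bnti), rownames(rc))) {
    stop("bnti and rc matrices must share ids in the same order")
  }
  b <- lower_pairs(bnti)
  r <- lower_pairs(rc)
  pairs <- data.frame(sample_i = b$sample_i, sample_j = b$sample_j,
                      bnti = b$value, rc = r$value,
                      stringsAsFactors = FALSE)
  pairs$process <- assign_process(pairs$bnti, pairs$rc)
  ok <- !is.na(pairs$process)
  excluded <- sum(!ok)
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "drift")
  counts <- table(factor(pairs$process[ok], levels = lev))
  n_ok <- sum(ok)
  fractions <- if (n_ok > 0) as.numeric(counts) / n_ok else rep(NA_real_, 5)
  names(fractions) <- lev
  det <- if (n_ok > 0) sum(abs(pairs$bnti[ok]) >= 2) / n_ok else NA_real_
  structure(list(pairs = pairs, fractions = fractions,
                 deterministic_fraction = det,
                 stochastic_fraction = 1 - det,
                 excluded_pairs = excluded, n_pairs = n_ok),
            class = "assembly_partition")
}

assign_process <- function(bnti, rc) {
  out <- rep(NA_character_, length(bnti))
  ok <- is.finite(bnti)
  out[ok & bnti > 2] <- "heterogeneous_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  sto <- ok & abs(bnti) <= 2
  out[sto & rc > 0.95] <- "dispersal_limitation"
  out[sto & rc < -0.95] <- "homogenizing_dispersal"
  out[sto & abs(rc) <= 0.95] <- "drift"
  out
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat(sprintf("assembly partition over %d sample pair(s)", x$n_pairs))
  if (x$excluded_pairs > 0) {
    cat(sprintf(" (%d excluded: NaN bNTI)", x$excluded_pairs))
  }
  cat("\n")
  for (p in names(x$fractions)) {
    cat(sprintf("  %-24s %6.2f%%\n", p, 100 * x$fractions[[p]]))
  }
  cat(sprintf("  deterministic |bNTI| >= 2: %.2f%%; stochastic: %.2f%%\n",
              100 * x$deterministic_fraction, 100 * x$stochastic_fraction))
  invisible(x)
}

#' Per-group assembly partitions
#'
#' Restricts [partition_processes()] to within-group sample pairs for each
#' level of a metadata column; groups with fewer than 2 samples are
#' skipped with a warning.
#'
#' @inheritParams partition_processes
#' @param meta metadata data.frame (sample rownames covering the matrix
#'   ids).
#' @param group_column metadata column to split on.
#' @return named list of `assembly_partition` objects.
#' @export
partition_by_group <- function(bnti, rc, meta, group_column) {
  if (!group_column %in% names(meta)) {
    stop("no metadata column '", group_column, "'")
  }
  ids <- rownames(bnti)
  if (!all(ids %in% rownames(meta))) {
    stop("metadata is missing samples present in the bNTI matrix")
  }
  groups <- split(ids, meta[ids, group_column])
  out <- list()
  for (g in names(groups)) {
    gi <- groups[[g]]
    if (length(gi) < 2) {
      warning(sprintf("group '%s': fewer than 2 samples; skipped", g))
      next
    }
    out[[g]] <- partition_processes(
      dist_matrix(bnti[gi, gi, drop = FALSE], kind = "beta_nti"),
      dist_matrix(rc[gi, gi, drop = FALSE], kind = "raup_crick"))
  }
  out
}
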