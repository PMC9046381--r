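#' Read a rooted phylogeny from Newick
#'
#' Wraps [ape::read.tree()] with the validation the downstream phylogenetic
#' stages require: unique tip labels, branch lengths present and
#' non-negative.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick file ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file ", path)
  validate_tree(tree)
  ca_log("read_tree_newick: %d tips from %s", length(tree$tip.label), path)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an ape phylo tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(tree)
}

#' Write a phylogeny to Newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Expects one row per sample with the sample id in the first column.
#' Recognized numeric columns are validated: `latitude` within \[-90, 90\],
#' `longitude` within \[-180, 180\].
#'
#' @param path path to a TSV file.
#' @return data.frame with sample ids as rownames.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  validate_metadata(df)
  ca_log("read_sample_metadata: %d samples, %d variables from %s",
         nrow(df), ncol(df), path)
  df
}

validate_metadata <- function(meta) {
  if ("latitude" %in% names(meta) &&
      any(abs(meta$latitude) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  if ("longitude" %in% names(meta) &&
      any(abs(meta$longitude) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]")
  }
  invisible(meta)
}

#' Write sample metadata to TSV
#' @param meta data.frame with sample ids as rownames.
#' @param path output path.
#' @param id_column header for the leading sample-id column.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path, id_column = "sample_id") {
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   rownames(meta), meta)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect an OTU table, a phylogeny and sample metadata
#'
#' Retains the samples present in both the table and the metadata, and
#' identifies the taxa present in both the table and the tree. Taxa absent
#' from the tree stay in the table (they are valid for taxonomic stages)
#' but are flagged: the pruned tree and the `phylo_taxa` element delimit the
#' input set for the phylogenetic stages. Everything dropped is logged.
#'
#' Idempotent: applying the function to its own output changes nothing.
#'
#' @param table an [otu_table()].
#' @param tree an [ape::phylo] tree.
#' @param meta metadata data.frame with sample rownames.
#' @return list with elements `table`, `tree` (pruned to shared taxa),
#'   `meta`, and `phylo_taxa` (character vector of taxa usable in
#'   phylogenetic stages).
#' @export
align_inputs <- function(table, tree, meta) {
  mat <- as_otu_matrix(table)
  shared_samples <- intersect(rownames(mat), rownames(meta))
  if (length(shared_samples) == 0) {
    stop("no samples shared between the OTU table and the metadata")
  }
  n_drop_tab <- nrow(mat) - length(shared_samples)
  n_drop_meta <- nrow(meta) - length(shared_samples)
  if (n_drop_tab > 0 || n_drop_meta > 0) {
    ca_log("align_inputs: dropping %d table sample(s) and %d metadata row(s) without a match",
           n_drop_tab, n_drop_meta)
  }
  mat <- mat[shared_samples, , drop = FALSE]
  meta <- meta[shared_samples, , drop = FALSE]

  phylo_taxa <- intersect(colnames(mat), tree$tip.label)
  if (length(phylo_taxa) == 0) {
    stop("no taxa shared between the OTU table and the tree")
  }
  n_flag <- ncol(mat) - length(phylo_taxa)
  if (n_flag > 0) {
    ca_log("align_inputs: %d taxon/taxa absent from the tree; retained for non-phylogenetic stages only",
           n_flag)
  }
  if (length(phylo_taxa) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, phylo_taxa)
  }
  list(table = otu_table(mat, normalized = is_normalized(table)),
       tree = tree, meta = meta, phylo_taxa = phylo_taxa)
}

#' Analysis configuration
#'
#' Bundles the knobs shared across the stochastic stages. Defaults follow
#' the standard usage of the methods implemented here: 999 permutations for
#' permutation tests, 999 randomizations for null models, |rho| > 0.6 with
#' FDR 0.05 for network edges, 95% confidence envelopes.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param n_permutations permutations for perMANOVA/Mantel-type tests.
#' @param n_null randomizations for the null models.
#' @param rho_threshold minimum |Spearman rho| for a network edge.
#' @param fdr_alpha Benjamini-Hochberg threshold for network edges.
#' @param ci_level confidence level for the neutral-model envelope.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 20220427L, n_permutations = 999L,
                       n_null = 999L, rho_threshold = 0.6,
                       fdr_alpha = 0.05, ci_level = 0.95) {
  stopifnot(n_permutations >= 1, n_null >= 1,
            ci_level > 0, ci_level < 1,
            rho_threshold >= 0, fdr_alpha > 0, fdr_alpha <= 1)
  structure(list(seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 n_null = as.integer(n_null),
                 rho_threshold = rho_threshold,
                 fdr_alpha = fdr_alpha,
                 ci_level = ci_level),
            class = "run_config")
}

#' Square distance matrix with a kind label
#'
#' Thin wrapper used by every stage that passes distances around: a square
#' symmetric matrix with zero diagonal, shared ids on both margins and a
#' `kind` attribute naming what it holds (`bray_curtis`, `geographic_km`,
#' `beta_mntd`, `beta_nti`, `raup_crick`, ...). Signed z-score matrices
#' (beta_nti) are exempt from the non-negativity check.
#'
#' @param values square numeric matrix.
#' @param ids character ids (defaults to the matrix dimnames).
#' @param kind label.
#' @return the labelled matrix.
#' @export
dist_matrix <- function(values, ids = rownames(values), kind = "distance") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(ids)) stop("distance matrix needs ids")
  dimnames(values) <- list(ids, ids)
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (!kind %in% c("beta_nti", "raup_crick") &&
      any(values < -1e-12, na.rm = TRUE)) {
    stop("negative distances in a '", kind, "' matrix")
  }
  attr(values, "kind") <- kind
  values
}

dm_kind <- function(dm) attr(dm, "kind") %||% "distance"

`%||%` <- function(a, b) if (is.null(a)) b else a

# off-diagonal lower-triangle values and the matching id pairs
lower_pairs <- function(dm) {
  ids <- rownames(dm)
  idx <- which(lower.tri(dm), arr.ind = TRUE)
  data.frame(sample_i = ids[idx[, 2]], sample_j = ids[idx[, 1]],
             value = dm[idx], stringsAsFactors = FALSE)
}
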