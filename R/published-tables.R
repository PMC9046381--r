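#' Published stonefly co-occurrence network topology summaries
#'
#' Per-family topology panel (edge/vertex counts, connectance, average
#' degree, path metrics, clustering, component counts and Freeman
#' centralizations) of the fungal co-occurrence networks reported for
#' eight wild stonefly families. Useful as a reference panel: the
#' arithmetic identities `average_degree = 2 E / V`,
#' `connectance = E / (V choose 2)` and
#' `edges = positive_edges + negative_edges` hold row by row and are what
#' [network_topology()] emits for any graph.
#'
#' @return data.frame, one row per stonefly family.
#' @export
stonefly_network_table <- function() {
  read.table(system.file("extdata", "stonefly_family_networks.tsv",
                         package = "comassembly"),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Published stonefly sequencing read accounting
#'
#' Total quality-filtered ITS read count and sample count of the stonefly
#' fungal survey; `floor(total / n)` gives the mean reads per sample.
#'
#' @return named numeric vector with `total_clean_reads` and `n_samples`.
#' @export
stonefly_read_accounting <- function() {
  df <- read.table(system.file("extdata", "stonefly_read_accounting.tsv",
                               package = "comassembly"),
                   sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df$value, df$quantity)
}
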