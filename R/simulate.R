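#' Simulate a pure-birth phylogeny
#'
#' Yule tree with `n_taxa` tips and strictly positive branch lengths; tip
#' labels `t1 ... tn`. The same seed always returns the same tree.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  # rphylo can emit zero-length terminal edges at coincident speciations;
  # nudge them so patristic distances stay strictly positive between tips
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  validate_tree(tree)
  tree
}

#' Simulate a metacommunity abundance distribution
#'
#' Relative abundances drawn from a lognormal with log-sd `sigma` and
#' normalized to sum to one; `sigma = 0` gives the uniform vector. Larger
#' `sigma` gives a steeper rank-abundance curve (a few dominant taxa and a
#' long rare tail), as amplicon surveys typically show.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param sigma lognormal log-sd (>= 0); default 2 spans several orders of
#'   magnitude at a thousand taxa.
#' @param seed integer seed.
#' @param sort_desc sort abundances descending.
#' @return list with `taxon_ids` and `rel_abund` (sums to 1), class
#'   `metacommunity`.
#' @export
simulate_metacommunity <- function(n_taxa, sigma = 2, seed = NULL,
                                   sort_desc = FALSE) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  x <- with_seed(seed, rlnorm(n_taxa, meanlog = 0, sdlog = sigma))
  if (sort_desc) x <- sort(x, decreasing = TRUE)
  structure(list(taxon_ids = paste0("t", seq_len(n_taxa)),
                 rel_abund = x / sum(x)),
            class = "metacommunity")
}

truth_record <- function(regime, m_true = NA_real_, selection_width = NA_real_,
                         trait_sigma = NA_real_, n_reads, seed) {
  list(regime = regime, m_true = m_true, selection_width = selection_width,
       trait_sigma = trait_sigma, n_reads = n_reads,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate neutral local communities
#'
#' Each sample is an independent local community of `n_reads` individuals
#' seeded by a multinomial draw from the metacommunity, then run through
#' `n_generations * n_reads` death-replacement events: the dead individual
#' is replaced from the metacommunity with probability `m` (immigration) or
#' by a copy of a surviving local individual otherwise (drift). This is the
#' generative model whose occurrence-frequency predictions
#' [fit_sloan_model()] fits, so recovering `m` from these tables is a fair
#' end-to-end check of the estimator.
#'
#' With `m = 1` every event resamples from the metacommunity and the table
#' is i.i.d. multinomial; with `m = 0` each community drifts to fixation.
#' The default `n_generations = 10` (community turnovers) erases the
#' initial condition at desk scale; studies of slow mixing near small `m`
#' should raise it (relaxation takes on the order of `1/m` turnovers).
#'
#' @param meta a `metacommunity` from [simulate_metacommunity()].
#' @param n_samples number of local communities.
#' @param n_reads individuals (reads) per community.
#' @param m migration probability per death event, in \[0, 1\].
#' @param n_generations community turnovers to simulate.
#' @param seed integer seed.
#' @return list with `table` (an [otu_table()], every row summing to
#'   `n_reads`) and `truth` (the generating parameters).
#' @export
simulate_neutral_communities <- function(meta, n_samples, n_reads, m,
                                         n_generations = 10, seed = NULL) {
  stopifnot(inherits(meta, "metacommunity"), n_samples >= 1, n_reads >= 1,
            m >= 0, m <= 1, n_generations >= 0)
  counts <- with_seed(seed, neutral_sim_cpp(meta$rel_abund,
                                            as.integer(n_samples),
                                            as.integer(n_reads), m,
                                            as.integer(n_generations)))
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                           meta$taxon_ids)
  keep <- colSums(counts) > 0
  list(table = suppressWarnings(otu_table(counts)),
       truth = truth_record("neutral", m_true = m, n_reads = n_reads,
                            seed = seed),
       n_taxa_observed = sum(keep))
}

#' Simulate environmentally filtered communities
#'
#' A quantitative trait is evolved along the tree by Brownian motion (rate
#' `trait_sigma`), and the sampling weight of taxon i in sample j is
#' `meta_i * exp(-(trait_i - env_j)^2 / (2 * selection_width^2))`: a
#' Gaussian environmental filter centred on the sample's environment.
#' Counts are one multinomial draw of `n_reads` per sample. Because the
#' trait carries phylogenetic signal (it evolved on the same tree used for
#' the phylogenetic null models), narrow filters produce the clustered /
#' overdispersed phylogenetic turnover that the beta nearest taxon index is
#' built to detect; `selection_width = Inf` removes the filter and recovers
#' the neutral `m = 1` multinomial case.
#'
#' @param tree phylogeny whose tips cover the metacommunity taxa.
#' @param meta a `metacommunity`.
#' @param env numeric vector, one environmental value per sample.
#' @param trait_sigma Brownian-motion rate (> 0).
#' @param selection_width Gaussian filter breadth (> 0; `Inf` = no
#'   selection).
#' @param n_reads reads per sample.
#' @param seed integer seed.
#' @return list with `table`, `truth`, and `traits` (named per-taxon trait
#'   values).
#' @export
simulate_selected_communities <- function(tree, meta, env, trait_sigma = 1,
                                          selection_width, n_reads,
                                          seed = NULL) {
  stopifnot(inherits(meta, "metacommunity"), n_reads >= 1)
  if (!all(meta$taxon_ids %in% tree$tip.label)) {
    stop("metacommunity taxa must all be tree tips")
  }
  if (is.na(selection_width) || selection_width <= 0) {
    stop("selection_width must be > 0")
  }
  n_samples <- length(env)
  res <- with_seed(seed, {
    traits <- ape::rTraitCont(tree, model = "BM", sigma = trait_sigma)
    traits <- traits[meta$taxon_ids]
    counts <- matrix(0L, n_samples, length(meta$taxon_ids))
    for (j in seq_len(n_samples)) {
      if (is.finite(selection_width)) {
        w <- meta$rel_abund *
          exp(-(traits - env[j])^2 / (2 * selection_width^2))
      } else {
        w <- meta$rel_abund
      }
      if (sum(w) <= 0) {
        stop(sprintf("sample %d: filter annihilated every taxon (env = %g)",
                     j, env[j]))
      }
      counts[j, ] <- rmultinom(1, n_reads, w)[, 1]
    }
    list(counts = counts, traits = traits)
  })
  dimnames(res$counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                               meta$taxon_ids)
  regime <- if (length(unique(env)) > 1) "heterogeneous_selection"
            else "homogeneous_selection"
  list(table = suppressWarnings(otu_table(res$counts)),
       truth = truth_record(regime, selection_width = selection_width,
                            trait_sigma = trait_sigma, n_reads = n_reads,
                            seed = seed),
       traits = res$traits)
}

#' Simulate spatially structured sample metadata
#'
#' Emulates a multi-site host survey: samples are split over `n_groups`
#' host groups, each group gets a spatial cluster centre inside a square
#' whose diagonal is `spatial_extent_km` (so the maximum pairwise distance
#' approximates the stated extent), and coordinates scatter around the centre
#' (cluster sd = 2% of the extent). Altitude, annual mean temperature (AMT,
#' degrees C) and annual mean precipitation (AP, mm) are linear in latitude
#' plus noise, so environmental distance correlates with geographic
#' distance as the Mantel and distance-decay stages assume. The domain is
#' centred near 30 N, 105 E (subtropical East Asia) purely so coordinates
#' look like a realistic survey.
#'
#' @param n_samples number of samples.
#' @param n_groups number of host groups (<= n_samples).
#' @param spatial_extent_km side of the sampling domain in km.
#' @param seed integer seed.
#' @return data.frame (rownames = sample ids) with host_family, host_genus,
#'   host_species, location, latitude, longitude, altitude, amt, ap.
#' @export
simulate_metadata <- function(n_samples, n_groups = 4,
                              spatial_extent_km = 2000, seed = NULL) {
  stopifnot(n_samples >= 1, n_groups >= 1, n_groups <= n_samples,
            spatial_extent_km >= 0)
  with_seed(seed, {
    lat0 <- 30; lon0 <- 105
    km_per_deg_lat <- 111.32
    km_per_deg_lon <- 111.32 * cos(lat0 * pi / 180)
    # centres live in a square whose diagonal is the stated extent, so the
    # maximum pairwise distance is ~spatial_extent_km plus cluster spread
    half_side <- spatial_extent_km / (2 * sqrt(2))
    half_lat <- half_side / km_per_deg_lat
    half_lon <- half_side / km_per_deg_lon
    centre_lat <- runif(n_groups, lat0 - half_lat, lat0 + half_lat)
    centre_lon <- runif(n_groups, lon0 - half_lon, lon0 + half_lon)
    spread_lat <- 0.02 * spatial_extent_km / km_per_deg_lat
    spread_lon <- 0.02 * spatial_extent_km / km_per_deg_lon

    grp <- sort(rep_len(seq_len(n_groups), n_samples))
    lat <- pmin(90, pmax(-90, centre_lat[grp] + rnorm(n_samples, 0, spread_lat)))
    lon <- pmin(180, pmax(-180, centre_lon[grp] + rnorm(n_samples, 0, spread_lon)))
    altitude <- pmax(0, 3000 - 60 * lat + rnorm(n_samples, 0, 150))
    amt <- 28 - 0.55 * lat + rnorm(n_samples, 0, 0.8)
    ap <- pmax(0, 2400 - 40 * lat + rnorm(n_samples, 0, 80))

    meta <- data.frame(
      host_family = paste0("family_", grp),
      host_genus = paste0("genus_", grp),
      host_species = paste0("species_", grp, letters[(seq_len(n_samples) %% 3) + 1]),
      location = paste0("site_", grp),
      latitude = lat, longitude = lon, altitude = altitude,
      amt = amt, ap = ap,
      stringsAsFactors = FALSE)
    rownames(meta) <- sprintf("S%03d", seq_len(n_samples))
    validate_metadata(meta)
    meta
  })
}
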