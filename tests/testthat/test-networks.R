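test_that("perfectly correlated taxa form signed edges", {
  set.seed(50)
  x <- sample(1:100, 20)
  m <- make_counts(cbind(x, x * 3 + 2, 101 - x, matrix(rpois(40, 5), 20, 2)))
  net <- spearman_cooccurrence(otu_table(m), rho_threshold = 0.6,
                               fdr_alpha = 0.05)
  e12 <- net$edges[net$edges$taxon_a == "t1" & net$edges$taxon_b == "t2", ]
  expect_equal(nrow(e12), 1L)
  expect_equal(e12$rho, 1)
  expect_equal(e12$sign, "positive")
  e13 <- net$edges[net$edges$taxon_a == "t1" & net$edges$taxon_b == "t3", ]
  expect_equal(e13$rho, -1)
  expect_equal(e13$sign, "negative")
})

test_that("edge detection is invariant to monotone transforms", {
  set.seed(51)
  m <- make_counts(matrix(rpois(100, 10) + 1, 20, 5))
  net1 <- spearman_cooccurrence(otu_table(m), rho_threshold = 0.3)
  m2 <- m
  m2[, 2] <- m2[, 2]^3  # strictly monotone transform of taxon 2
  net2 <- spearman_cooccurrence(otu_table(m2), rho_threshold = 0.3)
  expect_equal(net1$edges[, c("taxon_a", "taxon_b", "rho")],
               net2$edges[, c("taxon_a", "taxon_b", "rho")])
})

test_that("independent taxa yield essentially no edges after FDR", {
  n_edges <- vapply(1:8, function(s) {
    set.seed(100 + s)
    m <- make_counts(matrix(round(runif(50 * 30, 1, 1000)), 50, 30))
    nrow(spearman_cooccurrence(otu_table(m))$edges)
  }, numeric(1))
  expect_lt(mean(n_edges), 1)
})

test_that("topology metrics are exact on canonical graphs", {
  # complete graph K5
  k5_edges <- t(combn(paste0("t", 1:5), 2))
  net <- list(vertices = data.frame(taxon_id = paste0("t", 1:5),
                                    rel_abund = 0.2, prevalence = 1),
              edges = data.frame(taxon_a = k5_edges[, 1],
                                 taxon_b = k5_edges[, 2],
                                 rho = 1, p_adjusted = 0,
                                 sign = "positive",
                                 stringsAsFactors = FALSE),
              n_samples = 10, skipped_constant = 0)
  class(net) <- "cooccurrence_network"
  tm <- network_topology(net)
  expect_equal(tm$average_degree, 4)
  expect_equal(tm$connectance, 1)
  expect_equal(tm$clustering_coefficient, 1)
  expect_equal(tm$average_path_length, 1)
  expect_equal(tm$diameter, 1)
  expect_equal(tm$clusters, 1L)

  # path graph A-B-C-D
  pg <- net
  pg$vertices <- data.frame(taxon_id = LETTERS[1:4], rel_abund = 0.25,
                            prevalence = 1)
  pg$edges <- data.frame(taxon_a = c("A", "B", "C"),
                         taxon_b = c("B", "C", "D"),
                         rho = c(0.9, 0.9, -0.9), p_adjusted = 0,
                         sign = c("positive", "positive", "negative"),
                         stringsAsFactors = FALSE)
  tp <- network_topology(pg)
  expect_equal(tp$average_degree, 1.5)
  expect_equal(tp$diameter, 3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$average_path_length, 10 / 6)
  expect_equal(tp$positive_edges, 2L)
  expect_equal(tp$negative_edges, 1L)
  expect_equal(tp$edges, tp$positive_edges + tp$negative_edges)
})

test_that("topology identities hold for arbitrary thresholded networks", {
  set.seed(52)
  m <- make_counts(matrix(rpois(25 * 20, 6) + 1, 25, 20))
  # plant a few correlated blocks so edges exist
  m[, 2] <- m[, 1] + rpois(25, 1)
  m[, 3] <- m[, 1] + rpois(25, 1)
  m[, 5] <- max(m[, 4]) - m[, 4] + 1
  net <- spearman_cooccurrence(otu_table(m), rho_threshold = 0.5)
  tm <- network_topology(net)
  expect_equal(tm$edges, tm$positive_edges + tm$negative_edges)
  expect_equal(tm$average_degree, 2 * tm$edges / tm$vertices,
               tolerance = 1e-9)
  expect_equal(tm$connectance,
               tm$edges / choose(tm$vertices, 2), tolerance = 1e-9)
  expect_gte(tm$clusters, 1L)
})

test_that("path metrics and betweenness match exhaustive search", {
  set.seed(53)
  for (rep in 1:3) {
    V <- 7
    adj <- matrix(0, V, V)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on_idx <- sample(nrow(pairs), 9)
    for (k in on_idx) adj[pairs[k, 1], pairs[k, 2]] <- 1
    adj <- adj + t(adj)
    taxa <- paste0("t", 1:V)
    dimnames(adj) <- list(taxa, taxa)
    ew <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    net <- structure(list(
      vertices = data.frame(taxon_id = taxa, rel_abund = 1 / V,
                            prevalence = 1),
      edges = data.frame(taxon_a = taxa[ew[, 1]], taxon_b = taxa[ew[, 2]],
                         rho = 0.9, p_adjusted = 0, sign = "positive",
                         stringsAsFactors = FALSE),
      n_samples = 10, skipped_constant = 0),
      class = "cooccurrence_network")
    tm <- network_topology(net)
    sp <- brute_shortest_paths(adj)
    finite <- sp$dist[is.finite(sp$dist) & sp$dist > 0]
    expect_equal(tm$average_path_length, mean(finite), tolerance = 1e-9)
    expect_equal(tm$diameter, max(finite))
    # Freeman betweenness centralization against the brute-force counts
    btw <- brute_betweenness(adj)
    freeman <- sum(max(btw) - btw) / ((V - 1)^2 * (V - 2) / 2)
    expect_equal(tm$centralization_betweenness, freeman, tolerance = 1e-9)
  }
})

test_that("random-network comparison is deterministic and flags degeneracy", {
  set.seed(54)
  m <- make_counts(matrix(rpois(20 * 12, 8) + 1, 20, 12))
  m[, 2] <- m[, 1] + rpois(20, 1)
  m[, 4] <- m[, 3] + rpois(20, 1)
  m[, 6] <- m[, 5] + rpois(20, 1)
  net <- spearman_cooccurrence(otu_table(m), rho_threshold = 0.5,
                               keep_isolated = FALSE)
  skip_if(nrow(net$edges) < 1, "fixture produced no edges")
  z1 <- random_network_comparison(net, n_random = 50, seed = 55)
  z2 <- random_network_comparison(net, n_random = 50, seed = 55)
  expect_identical(z1$z_clustering, z2$z_clustering)
  expect_identical(z1$z_path_length, z2$z_path_length)

  # complete graph: every G(V, E) draw is the same graph, sd zero
  k4 <- t(combn(paste0("t", 1:4), 2))
  full <- structure(list(
    vertices = data.frame(taxon_id = paste0("t", 1:4), rel_abund = 0.25,
                          prevalence = 1),
    edges = data.frame(taxon_a = k4[, 1], taxon_b = k4[, 2], rho = 1,
                       p_adjusted = 0, sign = "positive",
                       stringsAsFactors = FALSE),
    n_samples = 10, skipped_constant = 0),
    class = "cooccurrence_network")
  expect_warning(zf <- random_network_comparison(full, n_random = 20,
                                                 seed = 56), "degenerate")
  expect_true(is.nan(zf$z_clustering) || is.nan(zf$z_path_length))
})

test_that("an Erdos-Renyi graph is not flagged as non-random", {
  set.seed(57)
  g <- igraph::sample_gnm(30, 60)
  el <- igraph::as_edgelist(g)
  taxa <- paste0("t", 1:30)
  net <- structure(list(
    vertices = data.frame(taxon_id = taxa, rel_abund = 1 / 30,
                          prevalence = 1),
    edges = data.frame(taxon_a = taxa[el[, 1]], taxon_b = taxa[el[, 2]],
                       rho = 0.9, p_adjusted = 0, sign = "positive",
                       stringsAsFactors = FALSE),
    n_samples = 10, skipped_constant = 0),
    class = "cooccurrence_network")
  z <- random_network_comparison(net, n_random = 200, seed = 58)
  expect_lt(abs(z$z_clustering), 4)
  expect_lt(abs(z$z_path_length), 4)
})

test_that("per-group networks apply FDR within groups and skip small ones", {
  set.seed(59)
  m <- make_counts(matrix(rpois(24 * 10, 6) + 1, 24, 10))
  m[1:12, 2] <- m[1:12, 1] + rpois(12, 1)
  meta <- data.frame(host_family = c(rep("A", 12), rep("B", 10),
                                     rep("C", 2)),
                     row.names = rownames(m))
  expect_warning(res <- networks_by_group(otu_table(m), meta,
                                          "host_family",
                                          rho_threshold = 0.5), "skipped")
  expect_setequal(names(res$networks), c("A", "B"))
  expect_equal(nrow(res$topology), 2L)
})
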