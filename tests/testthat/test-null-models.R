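test_that("beta-MNTD matches hand-computed values on tiny trees", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- make_counts(rbind(c(5, 0), c(0, 3)), taxon_ids = c("A", "B"))
  b <- beta_mntd(otu_table(m), tr)
  expect_equal(b["S1", "S2"], 2.0)

  # {A} vs {B, C}: direction A-> = min(d(A,B), d(A,C)) = 2;
  # direction -> = mean(d(B,A), d(C,A)) = mean(2, 4) = 3; value 2.5
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  m2 <- make_counts(rbind(c(4, 0, 0), c(0, 2, 2)),
                    taxon_ids = c("A", "B", "C"))
  b2 <- beta_mntd(otu_table(m2), tr2)
  expect_equal(b2["S1", "S2"], 2.5)
  D <- cophenetic(tr2)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(b2["S1", "S2"], brute_bmntd(m2, D)["S1", "S2"])

  # identical communities are at distance zero
  m3 <- make_counts(rbind(c(1, 2, 3), c(1, 2, 3)),
                    taxon_ids = c("A", "B", "C"))
  expect_equal(beta_mntd(otu_table(m3), tr2)["S1", "S2"], 0)
})

test_that("beta-MNTD equals the brute-force oracle on a random fixture", {
  set.seed(30)
  tr <- simulate_tree(8, seed = 30)
  m <- make_counts(matrix(rpois(40, 3), 5, 8))
  m[m == 0 & row(m) == 1] <- 1  # keep every sample non-empty
  m[rowSums(m) == 0, 1] <- 1
  tbl <- otu_table(m)
  D <- cophenetic(tr)[colnames(m), colnames(m)]
  for (w in c(TRUE, FALSE)) {
    got <- beta_mntd(tbl, tr, weighted = w)
    ref <- brute_bmntd(unclass(tbl), D, weighted = w)
    expect_equal(max(abs(got - ref[rownames(got), colnames(got)])), 0,
                 tolerance = 1e-12)
  }
})

test_that("beta-MNTD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  set.seed(31)
  tr <- simulate_tree(12, seed = 31)
  m <- make_counts(matrix(rpois(72, 4), 6, 12))
  m[rowSums(m) == 0, 1] <- 1
  tbl <- otu_table(m)
  got <- beta_mntd(tbl, tr, weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(unclass(tbl), cophenetic(tr),
                                      abundance.weighted = TRUE))
  ref <- ref[rownames(got), colnames(got)]
  diag(ref) <- 0
  expect_equal(unname(got[, ]), unname(ref), tolerance = 1e-10)
})

test_that("beta-NTI is symmetric, deterministic and NaN on degenerate trees", {
  mc <- simulate_metacommunity(30, sigma = 1.5, seed = 32)
  sim <- simulate_neutral_communities(mc, 8, 150, m = 0.5,
                                      n_generations = 10, seed = 33)
  tr <- simulate_tree(30, seed = 34)
  z1 <- quiet(beta_nti(sim$table, tr, n_null = 99, seed = 35))
  z2 <- quiet(beta_nti(sim$table, tr, n_null = 99, seed = 35))
  expect_identical(z1[, ], z2[, ])
  expect_equal(z1[, ], t(z1[, ]))

  # star phylogeny: all tip-to-tip distances equal, null sd is zero
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ms <- make_counts(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0)),
                    taxon_ids = c("A", "B", "C", "D"))
  expect_warning(zs <- beta_nti(otu_table(ms), star, n_null = 99,
                                seed = 36), "zero null sd")
  expect_true(all(is.nan(zs[lower.tri(zs)])))
})

test_that("Raup-Crick is bounded, deterministic, and -1 for duplicated samples", {
  mc <- simulate_metacommunity(40, sigma = 1.5, seed = 37)
  sim <- simulate_neutral_communities(mc, 6, 200, m = 1,
                                      n_generations = 2, seed = 38)
  m <- unclass(sim$table)
  m <- rbind(m, dup = m[1, ])  # exact copy of sample 1
  rownames(m) <- c(rownames(sim$table), "DUP")
  rc <- raup_crick_bray(otu_table(m), n_null = 99, seed = 39)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_equal(rc["S001", "DUP"], -1)
  rc2 <- raup_crick_bray(otu_table(m), n_null = 99, seed = 39)
  expect_identical(rc[, ], rc2[, ])
})

test_that("Raup-Crick is stable in the number of null replicates", {
  mc <- simulate_metacommunity(50, sigma = 1.5, seed = 40)
  sim <- simulate_neutral_communities(mc, 8, 250, m = 1,
                                      n_generations = 2, seed = 41)
  rc_small <- raup_crick_bray(sim$table, n_null = 99, seed = 42)
  rc_big <- raup_crick_bray(sim$table, n_null = 999, seed = 43)
  mc_tol <- 2 / sqrt(99) * 2  # two Monte-Carlo standard errors on RC scale
  expect_lt(median(abs(rc_small[lower.tri(rc_small)] -
                         rc_big[lower.tri(rc_big)])), mc_tol)
})

test_that("process assignment follows the threshold truth table exactly", {
  cases <- data.frame(
    bnti = c(3.0, -2.5, 1.0, 0.0, -1.0, 2.0, -2.0, 0.5, 0.5),
    rc = c(0.1, 0.5, 0.99, 0.20, -0.96, 0.99, -0.99, 0.95, -0.95),
    expected = c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "drift", "homogenizing_dispersal",
                 # boundary semantics: bNTI exactly +/-2 is stochastic,
                 # RC exactly +/-0.95 falls to drift
                 "dispersal_limitation", "homogenizing_dispersal",
                 "drift", "drift"),
    stringsAsFactors = FALSE)
  ids <- paste0("S", seq_len(nrow(cases) + 1))
  n <- length(ids)
  bnti <- matrix(0, n, n, dimnames = list(ids, ids))
  rc <- matrix(0, n, n, dimnames = list(ids, ids))
  # lay each case on the pair (S1, Sk)
  for (i in seq_len(nrow(cases))) {
    bnti[1, i + 1] <- bnti[i + 1, 1] <- cases$bnti[i]
    rc[1, i + 1] <- rc[i + 1, 1] <- cases$rc[i]
  }
  part <- partition_processes(dist_matrix(bnti, kind = "beta_nti"),
                              dist_matrix(rc, kind = "raup_crick"))
  got <- part$pairs
  key <- paste(got$sample_i, got$sample_j)
  for (i in seq_len(nrow(cases))) {
    row <- got[got$sample_i == "S1" & got$sample_j == ids[i + 1] |
                 got$sample_j == "S1" & got$sample_i == ids[i + 1], ]
    expect_equal(row$process, cases$expected[i],
                 label = sprintf("case bnti=%g rc=%g", cases$bnti[i],
                                 cases$rc[i]))
  }
  expect_equal(sum(part$fractions), 1, tolerance = 1e-9)
  expect_equal(part$deterministic_fraction + part$stochastic_fraction, 1)
})

test_that("NaN beta-NTI pairs are excluded and counted", {
  ids <- c("S1", "S2", "S3")
  bnti <- matrix(c(0, NaN, 3, NaN, 0, 0, 3, 0, 0), 3, 3,
                 dimnames = list(ids, ids))
  rc <- matrix(0, 3, 3, dimnames = list(ids, ids))
  part <- partition_processes(dist_matrix(bnti, kind = "beta_nti"),
                              dist_matrix(rc, kind = "raup_crick"))
  expect_equal(part$excluded_pairs, 1L)
  expect_equal(part$n_pairs, 2L)
  expect_equal(sum(part$fractions), 1, tolerance = 1e-9)
})

test_that("per-group partitions restrict to within-group pairs", {
  set.seed(44)
  ids <- sprintf("S%02d", 1:8)
  z <- matrix(rnorm(64), 8, 8); z <- (z + t(z)) / 2; diag(z) <- 0
  r <- matrix(runif(64, -0.5, 0.5), 8, 8); r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(z) <- dimnames(r) <- list(ids, ids)
  bnti <- dist_matrix(z, kind = "beta_nti")
  rc <- dist_matrix(r, kind = "raup_crick")
  meta1 <- data.frame(fam = rep("A", 8), row.names = ids)
  by1 <- partition_by_group(bnti, rc, meta1, "fam")
  global <- partition_processes(bnti, rc)
  expect_equal(by1$A$fractions, global$fractions)

  meta2 <- data.frame(fam = rep(c("A", "B"), each = 4), row.names = ids)
  by2 <- partition_by_group(bnti, rc, meta2, "fam")
  expect_equal(by2$A$n_pairs + by2$A$excluded_pairs, choose(4, 2))
  expect_equal(by2$B$n_pairs + by2$B$excluded_pairs, choose(4, 2))
  for (g in by2) expect_equal(sum(g$fractions), 1, tolerance = 1e-9)

  meta3 <- data.frame(fam = c(rep("A", 7), "B"), row.names = ids)
  expect_warning(partition_by_group(bnti, rc, meta3, "fam"), "fewer than 2")
})
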