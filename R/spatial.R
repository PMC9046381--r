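#' Pairwise great-circle distances between samples
#'
#' Haversine distances (km) from the metadata's `latitude` / `longitude`
#' columns, with mean Earth radius 6371.0 km.
#'
#' @param meta metadata data.frame with `latitude` and `longitude`.
#' @return [dist_matrix()] of kind `geographic_km`.
#' @export
haversine_matrix <- function(meta) {
  if (!all(c("latitude", "longitude") %in% names(meta))) {
    stop("metadata needs 'latitude' and 'longitude' columns")
  }
  bad <- !complete.cases(meta[, c("latitude", "longitude")])
  if (any(bad)) {
    stop("missing coordinate(s) for sample(s): ",
         paste(rownames(meta)[bad], collapse = ", "))
  }
  coords <- cbind(meta$longitude, meta$latitude)
  d <- geosphere::distm(coords,
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371000)
                        }) / 1000
  dimnames(d) <- list(rownames(meta), rownames(meta))
  dist_matrix(d, kind = "geographic_km")
}

#' Distance-decay of community similarity
#'
#' Ordinary least-squares regression of pairwise community similarity
#' (`1 - Bray-Curtis`) on pairwise geographic distance, over all
#' off-diagonal pairs. Because pairs sharing a sample are not independent,
#' the reported `p_value` comes from a Mantel-style permutation of sample
#' identities (one-sided in the direction of the observed correlation);
#' the naive OLS p-value is also returned for transparency.
#'
#' @param geo [dist_matrix()] of kind `geographic_km`.
#' @param community [dist_matrix()] of Bray-Curtis dissimilarities with
#'   the same ids.
#' @param n_permutations Mantel permutations (default 999).
#' @param seed integer seed.
#' @return `decay_result` list: `slope` (similarity per km), `intercept`,
#'   `r`, `p_value` (permutation), `p_value_ols`, `n_pairs`.
#' @export
distance_decay <- function(geo, community, n_permutations = 999,
                           seed = NULL) {
  if (!identical(rownames(geo), rownames(community))) {
    stop("geo and community matrices must share ids in the same order")
  }
  n <- nrow(geo)
  if (n < 3) stop("need at least 3 samples")
  lt <- lower.tri(geo)
  dist_v <- geo[lt]
  if (var(dist_v) == 0) stop("all geographic distances equal; slope undefined")
  sim <- 1 - as.matrix(community)
  sim_v <- sim[lt]
  fit <- lm(sim_v ~ dist_v)
  if (var(sim_v) == 0) {
    # flat similarity: slope 0 and no defined correlation to permute
    return(structure(list(slope = 0, intercept = mean(sim_v), r = 0,
                          p_value = NA_real_, p_value_ols = NA_real_,
                          n_pairs = sum(lt)),
                     class = "decay_result"))
  }
  r_obs <- cor(dist_v, sim_v)
  p_ols <- summary(fit)$coefficients[2, 4]
  dir <- if (r_obs < 0) -1 else 1
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      pm <- sample.int(n)
      dir * cor(dist_v, sim[pm, pm][lt]) >= dir * r_obs
    }, logical(1)))
  })
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r_obs,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 p_value_ols = p_ols,
                 n_pairs = sum(lt)),
            class = "decay_result")
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) between the off-diagonal entries of
#' two distance matrices, with significance from simultaneous row/column
#' permutation of the second matrix (via [vegan::mantel()]):
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_permutations + 1)`, one-sided.
#'
#' @param dm1,dm2 [dist_matrix()] objects with matching ids (n >= 4
#'   samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_permutations permutations (default 1000).
#' @param seed integer seed.
#' @param na_rm drop NA entries pairwise (needed for bNTI matrices with
#'   NaN pairs).
#' @return `mantel_result` list: `r`, `p_value`, `n_permutations`,
#'   `method`.
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        n_permutations = 1000, seed = NULL, na_rm = FALSE) {
  method <- match.arg(method)
  if (!identical(rownames(dm1), rownames(dm2))) {
    stop("matrices must share ids in the same order")
  }
  if (nrow(dm1) < 4) stop("need at least 4 samples")
  v1 <- dm1[lower.tri(dm1)]
  v2 <- dm2[lower.tri(dm2)]
  ok <- is.finite(v1) & is.finite(v2)
  if (var(v1[ok]) == 0 || var(v2[ok]) == 0) {
    stop("zero variance in a distance matrix; Mantel r undefined")
  }
  fit <- with_seed(seed,
    vegan::mantel(stats::as.dist(dm1), stats::as.dist(dm2),
                  method = method, permutations = n_permutations,
                  na.rm = na_rm))
  structure(list(r = unname(fit$statistic),
                 p_value = fit$signif,
                 n_permutations = as.integer(n_permutations),
                 method = method),
            class = "mantel_result")
}

#' Mantel test between bNTI and one environmental variable
#'
#' Builds the single-variable Euclidean (absolute-difference) distance
#' matrix for a numeric metadata column and delegates to [mantel_test()]
#' with pairwise removal of NaN bNTI pairs. Errors if more than half the
#' pairs are NaN.
#'
#' @param bnti [dist_matrix()] of kind `beta_nti`.
#' @param meta metadata data.frame covering the bNTI ids.
#' @param variable numeric metadata column name.
#' @inheritParams mantel_test
#' @return `mantel_result`.
#' @export
mantel_bnti_env <- function(bnti, meta, variable,
                            method = c("spearman", "pearson"),
                            n_permutations = 1000, seed = NULL) {
  method <- match.arg(method)
  if (!variable %in% names(meta)) stop("no metadata column '", variable, "'")
  ids <- rownames(bnti)
  if (!all(ids %in% rownames(meta))) {
    stop("metadata is missing samples present in the bNTI matrix")
  }
  x <- meta[ids, variable]
  if (!is.numeric(x)) stop("'", variable, "' is not numeric")
  env_d <- abs(outer(x, x, "-"))
  dimnames(env_d) <- list(ids, ids)
  frac_nan <- mean(!is.finite(bnti[lower.tri(bnti)]))
  if (frac_nan > 0.5) {
    stop(sprintf("%.0f%% of bNTI pairs are NaN; refusing the Mantel test",
                 100 * frac_nan))
  }
  mantel_test(bnti, dist_matrix(env_d, kind = "euclidean_env"),
              method = method, n_permutations = n_permutations,
              seed = seed, na_rm = frac_nan > 0)
}

#' Two-block variance partitioning on a community distance matrix
#'
#' Distance-based redundancy analysis partition of community variation
#' into the pure effect of block 1 (`fraction_a`), the shared effect
#' (`fraction_b`), the pure effect of block 2 (`fraction_c`) and the
#' residual, using Ezekiel-adjusted R-squared (via [vegan::varpart()]):
#' `a = R2adj(1 U 2) - R2adj(2)`, `c = R2adj(1 U 2) - R2adj(1)`,
#' `b = R2adj(1) - a`, `residual = 1 - R2adj(1 U 2)`. Negative adjusted
#' fractions are reported as-is (set `clamp = TRUE` to floor them at 0 in
#' a `fractions_clamped` copy). The testable marginal fractions (each full
#' block, and each pure block conditioned on the other) get permutation
#' p-values from [vegan::dbrda()] + [vegan::anova.cca].
#'
#' @param community [dist_matrix()] of community dissimilarities.
#' @param block_host numeric design matrix / data.frame for block 1
#'   (categorical variables one-hot encoded by the caller), rows aligned
#'   with the community ids.
#' @param block_env numeric design matrix for block 2; `NULL` degenerates
#'   to a single-block adjusted R-squared with `b = c = 0`.
#' @param n_permutations permutations for the fraction tests.
#' @param seed integer seed.
#' @param clamp also report fractions floored at zero.
#' @return `varpart_result` list: `fraction_a`, `fraction_b`,
#'   `fraction_c`, `residual` (summing to 1), `p_values`, and optionally
#'   `fractions_clamped`.
#' @export
variance_partition <- function(community, block_host, block_env = NULL,
                               n_permutations = 999, seed = NULL,
                               clamp = FALSE) {
  d <- stats::as.dist(as.matrix(community))
  X1 <- as.data.frame(block_host)
  n <- nrow(as.matrix(community))
  if (nrow(X1) != n) stop("block_host rows must match the community ids")
  if (ncol(X1) >= n) stop("block_host has more columns than samples")

  if (is.null(block_env)) {
    fit <- vegan::dbrda(d ~ ., data = X1)
    r2 <- vegan::RsquareAdj(fit)$adj.r.squared
    p <- with_seed(seed,
      stats::anova(fit, permutations = n_permutations)$`Pr(>F)`[1])
    return(structure(list(fraction_a = r2, fraction_b = 0, fraction_c = 0,
                          residual = 1 - r2,
                          p_values = c(block1 = p)),
                     class = "varpart_result"))
  }

  X2 <- as.data.frame(block_env)
  if (nrow(X2) != n) stop("block_env rows must match the community ids")
  if (ncol(X2) >= n) stop("block_env has more columns than samples")
  vp <- vegan::varpart(d, X1, X2)
  # indfract rows: pure X1 ([a] = X1|X2), pure X2 ([b] = X2|X1),
  # shared ([c]), residuals ([d])
  fr <- vp$part$indfract$Adj.R.squared

  dat <- cbind(X1, X2)
  f1 <- stats::as.formula(paste("d ~", paste(names(X1), collapse = "+")))
  f2 <- stats::as.formula(paste("d ~", paste(names(X2), collapse = "+")))
  fa <- stats::as.formula(paste("d ~", paste(names(X1), collapse = "+"),
                                "+ Condition(",
                                paste(names(X2), collapse = "+"), ")"))
  fc <- stats::as.formula(paste("d ~", paste(names(X2), collapse = "+"),
                                "+ Condition(",
                                paste(names(X1), collapse = "+"), ")"))
  p_values <- with_seed(seed, {
    test_one <- function(f) {
      # a fully collinear conditioned model has zero constrained rank;
      # its fraction is untestable and gets an NA p-value
      tryCatch({
        fit <- vegan::dbrda(f, data = dat)
        stats::anova(fit, permutations = n_permutations)$`Pr(>F)`[1]
      }, error = function(e) NA_real_)
    }
    c(block1 = test_one(f1), block2 = test_one(f2),
      pure_block1 = test_one(fa), pure_block2 = test_one(fc))
  })
  out <- structure(list(fraction_a = fr[1],
                        fraction_b = fr[3],
                        fraction_c = fr[2],
                        residual = fr[4],
                        p_values = p_values),
                   class = "varpart_result")
  if (clamp) {
    cl <- pmax(0, c(a = out$fraction_a, b = out$fraction_b,
                    c = out$fraction_c))
    out$fractions_clamped <- cl
  }
  out
}
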