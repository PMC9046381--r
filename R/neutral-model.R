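#' Per-OTU occurrence statistics
#'
#' The two summaries the neutral community model relates: `p`, the mean
#' across samples of an OTU's within-sample relative abundance (its
#' metacommunity abundance estimate), and `observed_frequency`, the
#' fraction of samples in which the OTU occurs. `N` is the mean sample
#' total rounded to the nearest integer. OTUs absent from every sample are
#' excluded with a warning.
#'
#' @param table raw-count [otu_table()] with >= 2 samples.
#' @return list with `stats` (data.frame: taxon_id, p, observed_frequency),
#'   `N`, and `n_samples`.
#' @export
occurrence_stats <- function(table) {
  mat <- as_otu_matrix(table)
  if (nrow(mat) < 2) stop("need at least 2 samples")
  absent <- colSums(mat) == 0
  if (any(absent)) {
    warning(sprintf("excluding %d OTU(s) absent from every sample",
                    sum(absent)))
    mat <- mat[, !absent, drop = FALSE]
  }
  rel <- relative_abundance(mat)
  list(stats = data.frame(taxon_id = colnames(mat),
                          p = colMeans(rel),
                          observed_frequency = colMeans(mat > 0),
                          stringsAsFactors = FALSE, row.names = NULL),
       N = as.integer(round(mean(rowSums(mat)))),
       n_samples = nrow(mat))
}

#' Neutral-model predicted occurrence frequency
#'
#' Under the neutral model, the relative abundance of an OTU with
#' metacommunity abundance `p` in a local community of `N` individuals with
#' migration rate `m` follows a Beta(N m p, N m (1 - p)) distribution; the
#' probability of detecting it above the detection limit `d` is therefore
#' `1 - pbeta(d, N m p, N m (1 - p))`. Monotone increasing in `p` and in
#' `m`.
#'
#' @param p mean relative abundance(s), each in (0, 1).
#' @param m migration rate in (0, 1].
#' @param N individuals (reads) per local community.
#' @param d detection limit as a relative abundance, in (0, 1].
#' @return predicted occurrence frequency in \[0, 1\], vectorized over `p`.
#' @export
predict_occurrence <- function(p, m, N, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly within (0, 1)")
  stopifnot(m > 0, m <= 1, d > 0, d <= 1, N >= 1)
  1 - pbeta(d, N * m * p, N * m * (1 - p))
}

#' Wilson score interval
#'
#' Closed-form Wilson interval for a binomial proportion: the default the
#' neutral-model envelope uses around each predicted frequency.
#'
#' @param phat proportion(s).
#' @param n number of trials.
#' @param level confidence level.
#' @return two-column matrix (`lower`, `upper`).
#' @export
wilson_interval <- function(phat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  z2 <- z^2
  centre <- (phat + z2 / (2 * n)) / (1 + z2 / n)
  half <- (z / (1 + z2 / n)) * sqrt(phat * (1 - phat) / n + z2 / (4 * n^2))
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model
#'
#' Least-squares fit of observed occurrence frequency against the
#' neutral-model prediction [predict_occurrence()] over all OTUs present in
#' the table, with the migration rate `m` as the single free parameter
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()], `m` bounded to
#' (1e-6, 1]; restarts from m = 0.001, 0.01, 0.1, 0.5 on failure).
#' Goodness of fit is `R^2 = 1 - SSE / SStot` about the mean observed
#' frequency; it may be negative and is reported as-is. The confidence
#' envelope is a Wilson score interval at `ci_level` around the predicted
#' frequency with `n = n_samples`, evaluated per OTU and on a dense
#' abundance grid; OTUs above the upper bound, below the lower bound, or
#' inside it are classified `above`, `below`, `neutral`.
#'
#' @param table raw-count [otu_table()].
#' @param d detection limit; default `1/N` (one read).
#' @param ci_level envelope confidence level.
#' @return `neutral_fit` list: `m`, `N`, `d`, `r_squared`, `n_samples`,
#'   `otus` (per-OTU data.frame with p, observed/predicted frequency,
#'   ci bounds and partition) and `grid` (envelope on a dense p grid).
#' @export
fit_sloan_model <- function(table, d = NULL, ci_level = 0.95) {
  occ <- occurrence_stats(table)
  N <- occ$N
  if (is.null(d)) d <- 1 / N
  dat <- occ$stats
  dat <- dat[dat$p > 0 & dat$observed_frequency > 0, , drop = FALSE]
  n_informative <- sum(dat$observed_frequency < 1)
  if (nrow(dat) == 0) stop("no OTUs available for the fit")
  if (n_informative < 10) {
    warning(sprintf(
      "only %d OTU(s) with occurrence frequency < 1; fit may be unstable",
      n_informative))
  }
  if (n_informative == 0) {
    # every OTU in every sample: frequency carries no information about m
    otus <- data.frame(dat, predicted_frequency = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       partition = NA_character_,
                       stringsAsFactors = FALSE)
    return(structure(list(m = NA_real_, N = N, d = d, r_squared = NA_real_,
                          n_samples = occ$n_samples, otus = otus,
                          grid = NULL),
                     class = "neutral_fit"))
  }

  p <- dat$p
  freq <- dat$observed_frequency
  fit <- NULL
  for (m0 in c(0.1, 0.001, 0.01, 0.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(freq ~ 1 - pbeta(d, N * m * p, N * m * (1 - p)),
                        start = list(m = m0), lower = 1e-6, upper = 1,
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("neutral-model fit failed to converge from starts 0.001/0.01/0.1/0.5; ",
         "N = ", N, ", d = ", d, ", ", nrow(dat), " OTUs")
  }
  m <- unname(coef(fit)[["m"]])
  pred <- predict_occurrence(p, m, N, d)
  sse <- sum((freq - pred)^2)
  sstot <- sum((freq - mean(freq))^2)
  r_squared <- if (sstot > 0) 1 - sse / sstot else NA_real_

  ci <- wilson_interval(pred, occ$n_samples, ci_level)
  partition <- ifelse(freq > ci[, "upper"], "above",
                      ifelse(freq < ci[, "lower"], "below", "neutral"))
  otus <- data.frame(taxon_id = dat$taxon_id, p = p,
                     observed_frequency = freq,
                     predicted_frequency = pred,
                     ci_low = ci[, "lower"], ci_high = ci[, "upper"],
                     partition = partition,
                     stringsAsFactors = FALSE, row.names = NULL)

  p_grid <- exp(seq(log(max(min(p) / 2, 1e-9)), log(max(p)),
                    length.out = 200))
  p_grid <- p_grid[p_grid > 0 & p_grid < 1]
  pred_grid <- predict_occurrence(p_grid, m, N, d)
  ci_grid <- wilson_interval(pred_grid, occ$n_samples, ci_level)
  grid <- data.frame(p = p_grid, predicted_frequency = pred_grid,
                     ci_low = ci_grid[, "lower"],
                     ci_high = ci_grid[, "upper"])

  structure(list(m = m, N = N, d = d, r_squared = r_squared,
                 n_samples = occ$n_samples, otus = otus, grid = grid),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g, N = %d, d = %.3g, R^2 = %.4g (%d samples, %d OTUs)\n",
              x$m, x$N, x$d, x$r_squared, x$n_samples, nrow(x$otus)))
  if (!all(is.na(x$otus$partition))) {
    tab <- table(factor(x$otus$partition,
                        levels = c("above", "neutral", "below")))
    cat(sprintf("  partition: %d above / %d neutral / %d below the envelope\n",
                tab["above"], tab["neutral"], tab["below"]))
  }
  invisible(x)
}

#' Fit the neutral model within each metadata group
#'
#' Repeats [fit_sloan_model()] on the sample subset of each level of a
#' metadata column; groups with fewer than `min_samples` samples are
#' skipped with a warning.
#'
#' @param table raw-count [otu_table()].
#' @param meta metadata data.frame (sample rownames).
#' @param group_column metadata column to split on.
#' @param min_samples minimum samples per group (default 5).
#' @param ... passed to [fit_sloan_model()].
#' @return named list of `neutral_fit` objects.
#' @export
fit_sloan_by_group <- function(table, meta, group_column, min_samples = 5,
                               ...) {
  mat <- as_otu_matrix(table)
  if (!group_column %in% names(meta)) {
    stop("no metadata column '", group_column, "'")
  }
  groups <- split(rownames(meta), meta[[group_column]])
  out <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], rownames(mat))
    if (length(ids) < min_samples) {
      warning(sprintf("group '%s': only %d sample(s); skipped", g,
                      length(ids)))
      next
    }
    sub <- suppressWarnings(otu_table(mat[ids, , drop = FALSE]))
    out[[g]] <- suppressWarnings(fit_sloan_model(sub, ...))
  }
  out
}
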