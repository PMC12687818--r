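#' Spearman rank correlation of two traits
#'
#' Computed on complete pairs with average-rank tie handling.
#'
#' @param x,y numeric vectors; at least 3 complete pairs required.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Bootstrap Spearman trait correlation network
#'
#' For each unordered trait pair, rows are resampled with replacement
#' `n_boot` times and Spearman's rho recomputed; a pair is significantly
#' correlated when the percentile (1 - alpha) interval of the bootstrap
#' distribution excludes zero. Edges carry the point-estimate rho and the
#' interval. Constant traits yield no edge.
#'
#' @param table numeric trait data.frame (missing values allowed;
#'   pairwise-complete rows are used per pair).
#' @param n_boot bootstrap replicates.
#' @param alpha significance level of the percentile interval.
#' @param seed RNG seed.
#' @return data.frame (class `correlation_network`): `trait_a`, `trait_b`,
#'   `rho`, `ci_low`, `ci_high`, `significant`.
#' @export
bootstrap_network <- function(table, n_boot = 1e5, alpha = 0.05, seed = 1L) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  feats <- names(table)
  pairs <- utils::combn(length(feats), 2)
  set.seed(seed)
  rows <- vector("list", ncol(pairs))
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    x <- table[[i]]; y <- table[[j]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    degenerate <- length(x) < 3 ||
      length(unique(x)) < 2 || length(unique(y)) < 2
    if (degenerate) {
      rows[[pi]] <- data.frame(trait_a = feats[i], trait_b = feats[j],
                               rho = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, significant = FALSE)
      next
    }
    rho <- spearman_rho(x, y)
    boot <- cpp_boot_spearman(x, y, as.integer(n_boot))
    ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
    rows[[pi]] <- data.frame(trait_a = feats[i], trait_b = feats[j],
                             rho = rho, ci_low = ci[1], ci_high = ci[2],
                             significant = ci[1] > 0 || ci[2] < 0)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_network", "data.frame")
  out
}
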