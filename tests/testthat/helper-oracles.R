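# Independent oracles used across the suite.

# CJS likelihood by exhaustive enumeration of the alive/dead latent chain
# (conditioned on release alive at occasion 1).
cjs_enumerate <- function(history, phi, p) {
  T <- length(history)
  m <- T - 1
  total <- 0
  for (code in 0:(2^m - 1)) {
    z <- c(1L, as.integer(intToBits(code)[1:m]))
    pr <- 1
    for (t in 2:T) {
      pr <- pr * if (z[t - 1] == 1) {
        if (z[t] == 1) phi[t - 1] else 1 - phi[t - 1]
      } else {
        if (z[t] == 1) 0 else 1
      }
      pr <- pr * if (z[t] == 1) {
        if (history[t] == 1) p[t - 1] else 1 - p[t - 1]
      } else {
        if (history[t] == 1) 0 else 1
      }
    }
    total <- total + pr
  }
  log(total)
}

# Brute-force nan-Euclidean KNN imputation (all-pairs distances).
knn_impute_brute <- function(tab, k) {
  X <- as.matrix(tab)
  n <- nrow(X); kf <- ncol(X)
  dist_ij <- function(i, j) {
    both <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(both)) return(NA_real_)
    sqrt(kf / sum(both) * sum((X[i, both] - X[j, both])^2))
  }
  out <- X
  for (i in seq_len(n)) for (j in seq_len(kf)) {
    if (!is.na(X[i, j])) next
    d <- vapply(seq_len(n), function(r)
      if (r == i || is.na(X[r, j])) NA_real_ else dist_ij(i, r), numeric(1))
    donors <- order(d)[seq_len(min(k, sum(!is.na(d))))]
    donors <- donors[!is.na(d[donors])]
    out[i, j] <- mean(X[donors, j])
  }
  as.data.frame(out)
}

# Path-dependent conditional expectation of a single extracted tree given a
# feature subset S (1-based feature ids), and exact Shapley values by
# subset enumeration; the oracle for the compiled SHAP kernel.
tree_expectation <- function(tr, S, x, node = 1) {
  if (tr$left[node] < 0) return(tr$value[node])
  f <- tr$feature[node] + 1
  l <- tr$left[node] + 1; r <- tr$right[node] + 1
  if (f %in% S) {
    if (x[f] <= tr$threshold[node]) tree_expectation(tr, S, x, l)
    else tree_expectation(tr, S, x, r)
  } else {
    (tr$cover[l] * tree_expectation(tr, S, x, l) +
       tr$cover[r] * tree_expectation(tr, S, x, r)) / tr$cover[node]
  }
}

shapley_enumerate <- function(tr, x, k) {
  phi <- numeric(k)
  subsets <- unlist(lapply(0:(k - 1), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  for (i in seq_len(k)) {
    for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(k - length(S) - 1) / factorial(k)
      phi[i] <- phi[i] +
        w * (tree_expectation(tr, c(S, i), x) - tree_expectation(tr, S, x))
    }
  }
  phi
}

# Spearman via the classical rank-difference formula (no ties).
spearman_rankdiff <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Small detection data.frame builder.
det_events <- function(days, lat, lon) {
  data.frame(bird_id = "B1", station_id = paste0("S", seq_along(days)),
             lat = lat, lon = lon, days_since_tag = days)
}
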