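#' Body condition index
#'
#' Weight divided by tarsus length (g/mm), a proxy for energy stores
#' relative to structural size.
#'
#' @param weight grams; @param tarsus millimetres (> 0).
#' @return g/mm; `NA` if either input is missing.
#' @export
body_condition <- function(weight, tarsus) {
  if (any(!is.na(tarsus) & tarsus <= 0)) stop("tarsus length must be > 0")
  weight / tarsus
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Initial great-circle bearing in compass degrees
#'
#' @inheritParams great_circle_km
#' @return degrees clockwise from north, in [0, 360).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) %% 360
}

#' Fall migratory orientation from a detection stream
#'
#' The bearing from the release site to the first station where the bird
#' was detected within a 300 km radius. Stations coincident with the
#' release point are skipped (bearing undefined at zero distance).
#'
#' @param release_lat,release_lon release coordinates, decimal degrees.
#' @param detections data.frame with `lat`, `lon`, `days_since_tag`,
#'   sorted by `days_since_tag`.
#' @param radius_km qualifying radius.
#' @return compass degrees in [0, 360), or `NA` if no detection qualifies.
#' @export
fall_bearing <- function(release_lat, release_lon, detections,
                         radius_km = 300) {
  if (nrow(detections) == 0) return(NA_real_)
  d <- great_circle_km(release_lat, release_lon,
                       detections$lat, detections$lon)
  ok <- which(d > 1e-6 & d <= radius_km)
  if (!length(ok)) return(NA_real_)
  i <- ok[1]
  initial_bearing(release_lat, release_lon,
                  detections$lat[i], detections$lon[i])
}

#' Fall migratory timing from a detection stream
#'
#' Day of year the bird was first detected within 30 km of its release
#' site during the fall window. The tagging event itself (timestamp 0) is
#' not counted as a detection.
#'
#' @inheritParams fall_bearing
#' @param release_day day of year of tagging.
#' @param radius_km qualifying radius around the release site.
#' @param fall_window day-of-year limits of fall migration.
#' @return day of year, or `NA` if no detection qualifies.
#' @export
fall_timing <- function(release_day, release_lat, release_lon, detections,
                        radius_km = 30, fall_window = c(213, 304)) {
  if (nrow(detections) == 0) return(NA_real_)
  d <- great_circle_km(release_lat, release_lon,
                       detections$lat, detections$lon)
  doy <- release_day + detections$days_since_tag
  ok <- which(detections$days_since_tag > 0 & d <= radius_km &
                doy >= fall_window[1] & doy <= fall_window[2])
  if (!length(ok)) return(NA_real_)
  doy[ok[1]]
}

#' Drop one member of every highly correlated feature pair
#'
#' Pairwise Pearson correlations are computed on complete pairs; pairs are
#' scanned in descending absolute correlation and, whenever |r| meets the
#' threshold and neither member was already dropped, the member that is
#' absent from (or later in) the priority keep-list is removed. Ties among
#' unlisted features are broken by column order.
#'
#' @param table data.frame / matrix of numeric features.
#' @param threshold absolute-correlation cutoff.
#' @param priority character vector; earlier entries win their pair.
#' @return character vector of retained feature names.
#' @export
correlation_prune <- function(table, threshold = 0.7, priority = character()) {
  X <- as.matrix(table)
  feats <- colnames(X)
  stopifnot(length(feats) >= 2)
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  ord <- order(-abs(R[pairs]))
  dropped <- character()
  rank_of <- function(f) {
    r <- match(f, priority)
    # unlisted features rank behind every listed one, by column order
    if (is.na(r)) length(priority) + match(f, feats) else r
  }
  for (idx in ord) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    if (abs(R[i, j]) < threshold) break
    a <- feats[i]; b <- feats[j]
    if (a %in% dropped || b %in% dropped) next
    dropped <- c(dropped, if (rank_of(a) <= rank_of(b)) b else a)
  }
  retained <- setdiff(feats, dropped)
  if (length(retained) == 1)
    warning("all features mutually correlated; keeping only ", retained)
  retained
}

#' Drop features with excessive missingness
#'
#' @param table feature data.frame.
#' @param max_frac maximum tolerated missing fraction (strictly greater
#'   is dropped).
#' @param whitelist features kept regardless of missingness.
#' @return character vector of retained feature names.
#' @export
missingness_filter <- function(table, max_frac = 0.25,
                               whitelist = character()) {
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  names(frac)[frac <= max_frac | names(frac) %in% whitelist]
}

#' Standardize features to zero mean and unit variance
#'
#' Means and standard deviations are computed ignoring missing values and
#' returned so held-out rows can be transformed with the same parameters
#' (no leakage).
#'
#' @param table numeric data.frame.
#' @param center,scale optional pre-computed parameters (from a training
#'   fit) to apply instead of estimating.
#' @return list: `values` (standardized data.frame), `center`, `scale`.
#' @export
standardize <- function(table, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- vapply(table, mean, numeric(1), na.rm = TRUE)
    scale <- vapply(table, stats::sd, numeric(1), na.rm = TRUE)
    zero <- names(scale)[!is.na(scale) & scale == 0]
    if (length(zero))
      stop("zero-variance feature(s): ", paste(zero, collapse = ", "))
  }
  values <- as.data.frame(mapply(function(x, m, s) (x - m) / s,
                                 table, center[names(table)],
                                 scale[names(table)], SIMPLIFY = FALSE))
  list(values = values, center = center, scale = scale)
}

# nan-Euclidean distance matrix between rows: squared differences are
# averaged over co-observed features and scaled back to the full feature
# count, sqrt(n_features / n_observed * sum_sq). No co-observed features
# gives NA.
nan_euclidean <- function(X) {
  n <- nrow(X); kf <- ncol(X)
  S <- matrix(0, n, n); C <- matrix(0L, n, n)
  for (j in seq_len(kf)) {
    v <- X[, j]
    obs <- !is.na(v)
    d2 <- outer(v, v, `-`)^2
    w <- outer(obs, obs, `&`)
    d2[!w] <- 0
    S <- S + d2
    C <- C + w
  }
  D <- sqrt(kf / C * S)
  D[C == 0] <- NA
  diag(D) <- NA
  D
}

#' K-nearest-neighbour imputation with the nan-Euclidean metric
#'
#' Each missing cell is replaced by the unweighted mean of the same feature
#' in the k nearest rows (nan-Euclidean distance over co-observed features)
#' that have the feature observed; if fewer than k such donors exist, all
#' available donors are used.
#'
#' @param table numeric data.frame with `NA` for missing values.
#' @param k number of neighbours.
#' @return list: `values` (complete data.frame), `imputed` (logical matrix
#'   of cells that were filled).
#' @export
knn_impute <- function(table, k = 5) {
  X <- as.matrix(table)
  none <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(none))
    stop("feature(s) with no observed values: ", paste(none, collapse = ", "))
  miss <- is.na(X)
  if (any(miss)) {
    D <- nan_euclidean(X)
    for (j in which(colSums(miss) > 0)) {
      donors_j <- which(!miss[, j])
      for (i in which(miss[, j])) {
        d <- D[i, donors_j]
        usable <- donors_j[!is.na(d)]
        d <- d[!is.na(d)]
        if (!length(usable))
          stop("row ", i, " has no usable imputation donors")
        sel <- usable[order(d)][seq_len(min(k, length(usable)))]
        X[i, j] <- mean(X[sel, j])
      }
    }
  }
  list(values = as.data.frame(X), imputed = miss)
}

#' Stratified train/test split
#'
#' Random partition performed independently within each class so class
#' proportions are preserved (within one sample per class).
#'
#' @param labels binary vector.
#' @param test_frac fraction held out.
#' @param seed integer seed; the split is deterministic given it.
#' @return list: `train`, `test` (integer row indices), `labels`.
#' @export
stratified_split <- function(labels, test_frac = 0.2, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0, 1)")
  classes <- unique(labels)
  if (any(table(labels) < 2)) stop("each class needs at least 2 members")
  set.seed(seed)
  test <- integer()
  for (cl in sort(classes)) {
    rows <- which(labels == cl)
    n_test <- round(length(rows) * test_frac)
    test <- c(test, sample(rows, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test,
       labels = labels)
}

#' Assemble the candidate predictor panel from trait and detection tables
#'
#' Derives body condition from weight and tarsus, and fall bearing / fall
#' timing from each bird's detection stream. The result is the pre-pruning
#' panel: seven retained morphology measures plus the redundant P7, P8, P9
#' and weight, behaviour, release metadata, ancestry, heterozygosity and
#' sex.
#'
#' @param traits trait table (one row per bird; see [read_traits()]).
#' @param detections detection table covering the same birds; if `NULL`,
#'   `fall_bearing` / `fall_timing` columns of `traits` are used instead.
#' @param fall_window passed to [fall_timing()].
#' @return data.frame of numeric candidate features with `bird_id` row
#'   identifiers in attribute `bird_ids`.
#' @export
assemble_features <- function(traits, detections = NULL,
                              fall_window = c(213, 304)) {
  n <- nrow(traits)
  if (!is.null(detections)) {
    bearing <- timing <- rep(NA_real_, n)
    det_split <- split(detections, detections$bird_id)
    for (i in seq_len(n)) {
      d <- det_split[[traits$bird_id[i]]]
      if (is.null(d)) next
      d <- d[order(d$days_since_tag), , drop = FALSE]
      bearing[i] <- fall_bearing(traits$release_lat[i], traits$release_lon[i], d)
      timing[i] <- fall_timing(traits$release_day[i], traits$release_lat[i],
                               traits$release_lon[i], d,
                               fall_window = fall_window)
    }
  } else {
    bearing <- traits$fall_bearing
    timing <- traits$fall_timing
  }
  out <- data.frame(
    distal = traits$distal, p10 = traits$p10,
    condition = body_condition(traits$weight, traits$tarsus),
    tarsus = traits$tarsus, kipps = traits$kipps, tail = traits$tail,
    wing_chord = traits$wing_chord,
    p7 = traits$p7, p8 = traits$p8, p9 = traits$p9, weight = traits$weight,
    fall_timing = timing, fall_bearing = bearing,
    release_day = traits$release_day, release_year = traits$release_year,
    ancestry = traits$ancestry, heterozygosity = traits$heterozygosity,
    sex = traits$sex)
  attr(out, "bird_ids") <- traits$bird_id
  out
}

#' Prune, filter, standardize and impute the predictor panel
#'
#' Applies, in order: correlation pruning (drops one member of each pair
#' with |r| >= `threshold`, keeping wing chord over the inner primaries and
#' body condition over raw weight by default), the missingness filter with
#' the behavioural whitelist, standardization, and KNN imputation. In the
#' default `"pooled"` mode the standardization and imputation
#' parameters are fitted on all rows before any split; in `"strict"` mode
#' they are fitted on `train_rows` only and applied to the rest.
#'
#' @param features output of [assemble_features()].
#' @param threshold,priority passed to [correlation_prune()].
#' @param max_missing,whitelist passed to [missingness_filter()].
#' @param k imputation neighbours.
#' @param mode `"pooled"` or `"strict"`.
#' @param train_rows row indices used to fit parameters in strict mode.
#' @param binary_features imputed values of these are snapped to the
#'   nearest observed class value.
#' @return object of class `feature_matrix`: `values` (complete,
#'   standardized), `imputed` provenance matrix, `center`, `scale`,
#'   `dropped_correlated`, `dropped_missing`, `feature_names`, `bird_ids`.
#' @export
prepare_features <- function(features, threshold = 0.7,
                             priority = c("wing_chord", "condition"),
                             max_missing = 0.25,
                             whitelist = c("fall_timing", "fall_bearing"),
                             k = 5, mode = c("pooled", "strict"),
                             train_rows = NULL,
                             binary_features = "sex") {
  mode <- match.arg(mode)
  keep <- correlation_prune(features, threshold, priority)
  dropped_corr <- setdiff(names(features), keep)
  tab <- features[keep]
  keep2 <- missingness_filter(tab, max_missing, whitelist)
  dropped_miss <- setdiff(keep, keep2)
  tab <- tab[keep2]
  fit_rows <- if (mode == "strict") {
    if (is.null(train_rows)) stop("strict mode requires train_rows")
    train_rows
  } else seq_len(nrow(tab))
  std_fit <- standardize(tab[fit_rows, , drop = FALSE])
  std <- standardize(tab, center = std_fit$center, scale = std_fit$scale)
  if (mode == "strict") {
    # impute held-out rows against the training pool only
    imp_train <- knn_impute(std$values[fit_rows, , drop = FALSE], k)
    vals <- std$values
    vals[fit_rows, ] <- imp_train$values
    miss <- is.na(as.matrix(std$values))
    other <- setdiff(seq_len(nrow(vals)), fit_rows)
    for (i in other) {
      if (!anyNA(std$values[i, ])) next
      pool <- rbind(vals[fit_rows, , drop = FALSE], std$values[i, , drop = FALSE])
      vals[i, ] <- knn_impute(pool, k)$values[nrow(pool), ]
    }
    imp <- list(values = vals, imputed = miss)
  } else {
    imp <- knn_impute(std$values, k)
  }
  for (bf in intersect(binary_features, names(imp$values))) {
    obs <- sort(unique(imp$values[[bf]][!imp$imputed[, bf]]))
    if (length(obs) == 2 && any(imp$imputed[, bf])) {
      x <- imp$values[[bf]][imp$imputed[, bf]]
      imp$values[[bf]][imp$imputed[, bf]] <-
        obs[1 + (abs(x - obs[2]) < abs(x - obs[1]))]
    }
  }
  structure(list(values = imp$values, imputed = imp$imputed,
                 center = std_fit$center, scale = std_fit$scale,
                 dropped_correlated = dropped_corr,
                 dropped_missing = dropped_miss,
                 feature_names = names(imp$values),
                 bird_ids = attr(features, "bird_ids")),
            class = "feature_matrix")
}
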