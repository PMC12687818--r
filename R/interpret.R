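#' Gini (mean-decrease-in-impurity) feature importance
#'
#' Total Gini impurity reduction attributed to each feature across all
#' trees, normalized to sum to 1, with the equal-contribution null line
#' 1/k for k features.
#'
#' @param model a [train_forest()] fit.
#' @return list: `importance` (named, sums to 1), `null_line`, class
#'   `importance_report`.
#' @export
gini_importance <- function(model) {
  if (!inherits(model, "survival_forest"))
    stop("gini_importance requires a tree-ensemble model")
  imp <- model$rf$importance[, "MeanDecreaseGini"]
  structure(list(importance = imp / sum(imp),
                 null_line = 1 / length(imp)),
            class = "importance_report")
}

#' Pairwise joint-permutation interaction screen
#'
#' For every unordered feature pair, both columns are permuted with
#' independent random permutations across the test rows (breaking the
#' pair's joint distribution, and any interaction carried by it, while
#' preserving each marginal), and the drop in macro-F1 relative to the
#' unpermuted baseline is recorded. Pairs with a mean drop >= `cutoff` are
#' retained. A shared permutation of both columns (which preserves the
#' pair's own interaction and breaks only their joint relation to the
#' remaining features) is available behind `shared_permutation`.
#'
#' @param model a [train_forest()] fit.
#' @param test_rows,test_labels held-out data (both classes present).
#' @param tau classification threshold applied to predicted probabilities.
#' @param n_repeats permutations averaged per pair.
#' @param cutoff retention threshold on the F1 drop.
#' @param shared_permutation use one shared permutation for both columns.
#' @param seed RNG seed.
#' @return data.frame (class `interaction_screen`): `feature_a`,
#'   `feature_b`, `delta_f1`, `retained`, with the baseline macro-F1 in
#'   attribute `baseline`.
#' @export
interaction_screen <- function(model, test_rows, test_labels, tau = 0.5,
                               n_repeats = 1, cutoff = 0.1,
                               shared_permutation = FALSE, seed = 1L) {
  X <- as.data.frame(test_rows)[model$feature_names]
  k <- ncol(X)
  if (k < 2) stop("interaction screen needs at least two features")
  n <- nrow(X)
  set.seed(seed)
  baseline <- macro_f1(test_labels,
                       as.integer(predict_prob(model, X) >= tau))
  pairs <- utils::combn(k, 2)
  delta <- numeric(ncol(pairs))
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      Xp <- X
      perm_i <- sample.int(n)
      perm_j <- if (shared_permutation) perm_i else sample.int(n)
      Xp[[i]] <- X[[i]][perm_i]
      Xp[[j]] <- X[[j]][perm_j]
      f1 <- macro_f1(test_labels,
                     as.integer(predict_prob(model, Xp) >= tau))
      drops[r] <- baseline - f1
    }
    delta[pi] <- mean(drops)
  }
  out <- data.frame(feature_a = model$feature_names[pairs[1, ]],
                    feature_b = model$feature_names[pairs[2, ]],
                    delta_f1 = delta,
                    retained = delta >= cutoff)
  attr(out, "baseline") <- baseline
  class(out) <- c("interaction_screen", "data.frame")
  out
}

# Convert a fitted randomForest ensemble into parallel-array trees with
# training-set node covers, the representation the compiled SHAP kernel
# consumes. Leaf value is 1 for a "survived" vote, 0 otherwise, so the
# forest margin is the vote fraction for class 1.
forest_trees <- function(model) {
  stopifnot(inherits(model, "survival_forest"))
  X <- model$train_x[, model$feature_names, drop = FALSE]
  pos_level <- length(model$levels)
  lapply(seq_len(model$rf$ntree), function(t) {
    tr <- randomForest::getTree(model$rf, t, labelVar = FALSE)
    left <- as.integer(tr[, "left daughter"] - 1L)
    right <- as.integer(tr[, "right daughter"] - 1L)
    leaf <- tr[, "status"] == -1
    left[leaf] <- -1L; right[leaf] <- -1L
    feature <- as.integer(tr[, "split var"] - 1L)
    tree <- list(left = left, right = right, feature = feature,
                 threshold = as.numeric(tr[, "split point"]),
                 value = as.numeric(tr[, "prediction"] == pos_level))
    tree$cover <- cpp_tree_cover(tree$left, tree$right, tree$feature,
                                 tree$threshold, X)
    tree
  })
}

#' Forest probability margin computed from the extracted trees
#'
#' Vote fraction for class 1 obtained by dropping rows down the package's
#' own array representation of the ensemble; equals
#' [predict_prob()] and anchors the SHAP additivity identity.
#'
#' @param model a [train_forest()] fit.
#' @param rows predictor rows.
#' @export
forest_margin <- function(model, rows) {
  X <- as.matrix(as.data.frame(rows)[model$feature_names])
  as.numeric(cpp_forest_margin(forest_trees(model), X))
}

#' Exact tree SHAP values with per-feature dependence tables
#'
#' Computes path-dependent tree SHAP values for every row: per-feature
#' contributions that sum, together with the base value (the cover-weighted
#' mean leaf value, i.e. the expected vote fraction over the training
#' set), exactly to the model's predicted probability for that row.
#'
#' @param model a [train_forest()] fit.
#' @param rows rows to explain (typically the training set).
#' @return list (class `shap_matrix`): `shap` (n x k matrix), `base_value`,
#'   `dependence` (per-feature data.frames of `value`, `shap`).
#' @export
shap_dependence <- function(model, rows) {
  X <- as.matrix(as.data.frame(rows)[model$feature_names])
  res <- cpp_forest_shap(forest_trees(model), X)
  shap <- res$phi
  dimnames(shap) <- list(NULL, model$feature_names)
  dependence <- lapply(model$feature_names, function(f)
    data.frame(value = X[, f], shap = shap[, f]))
  names(dependence) <- model$feature_names
  structure(list(shap = shap, base_value = res$base,
                 dependence = dependence),
            class = "shap_matrix")
}
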