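#' Synthetic Minority Oversampling Technique (SMOTE)
#'
#' Balances a binary training set by interpolating new minority-class rows:
#' each synthetic sample sits at a uniform random point on the segment
#' between a random minority row and one of its k nearest minority
#' neighbours (Euclidean). Original rows are preserved verbatim; synthesis
#' continues until the class counts are equal.
#'
#' @param rows numeric data.frame / matrix of predictors.
#' @param labels binary vector (0/1), same length as `nrow(rows)`.
#' @param k_neighbors neighbours searched within the minority class;
#'   reduced with a warning when the class is too small.
#' @return list: `rows`, `labels`, `synthetic` (logical flag per output
#'   row), `parents` (2-column matrix of minority row indices each
#'   synthetic sample interpolates between).
#' @export
smote <- function(rows, labels, k_neighbors = 5) {
  X <- as.matrix(rows)
  stopifnot(nrow(X) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2) stop("smote expects exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  n_new <- n_maj - n_min
  if (n_new == 0)
    return(list(rows = as.data.frame(X), labels = labels,
                synthetic = rep(FALSE, nrow(X)),
                parents = matrix(integer(), 0, 2)))
  if (n_min < 2) stop("minority class needs at least 2 members for SMOTE")
  k <- k_neighbors
  if (n_min < k + 1) {
    k <- n_min - 1
    warning("minority class too small; k_neighbors reduced to ", k)
  }
  min_idx <- which(labels == minority)
  Xm <- X[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- matrix(nn, nrow = k)
  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- nn[cbind(sample.int(k, n_new, replace = TRUE), base)]
  lambda <- runif(n_new)
  synth <- Xm[base, , drop = FALSE] +
    lambda * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  out <- rbind(X, synth)
  rownames(out) <- NULL
  list(rows = as.data.frame(out),
       labels = c(labels, rep(if (is.numeric(labels))
         as.numeric(minority) else minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)),
       parents = cbind(min_idx[base], min_idx[pick]))
}

#' Random-forest hyperparameter configuration
#'
#' Mirrors the tuned search space: number of trees, maximum depth, features
#' tried per split, and minimum node sizes, plus the balanced-bootstrap
#' switch. Depth and split minima are enforced through the backend's
#' node-count and terminal-node-size controls: a depth-d tree has at most
#' 2^d terminal nodes, and a node below `min_samples_split` cases (or whose
#' children would fall below `min_samples_leaf`) is not split.
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum depth, or `NULL` for unbounded.
#' @param max_features `"sqrt"`, `"log2"` or `"all"`.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param min_samples_leaf minimum terminal-node size.
#' @param balanced_bootstrap down-sample the majority class to the minority
#'   count in every tree's bootstrap.
#' @param seed integer seed for tree growing.
#' @export
forest_config <- function(n_estimators = 300, max_depth = NULL,
                          max_features = "sqrt", min_samples_split = 2,
                          min_samples_leaf = 1, balanced_bootstrap = TRUE,
                          seed = 1L) {
  stopifnot(max_features %in% c("sqrt", "log2", "all"))
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 max_features = max_features,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf,
                 balanced_bootstrap = balanced_bootstrap,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Default randomized-search domains for forest tuning
#' @export
forest_search_domains <- function() {
  list(n_estimators = c(100, 200, 300),
       max_depth = list(10, 20, NULL),
       max_features = c("sqrt", "log2", "all"),
       min_samples_split = c(2, 5, 10),
       min_samples_leaf = c(1, 2, 4))
}

#' Train a balanced random forest
#'
#' Grows an ensemble of classification trees whose bootstraps down-sample
#' the majority class to the minority count (a balanced random forest; on
#' already-balanced input, e.g. after SMOTE, this degenerates to an
#' ordinary bootstrap). Class probabilities are the fraction of tree votes.
#'
#' @param rows numeric predictor data.frame / matrix.
#' @param labels binary vector (0/1).
#' @param config a [forest_config()].
#' @return object of class `survival_forest` wrapping the fitted ensemble,
#'   the configuration, and the training matrix (kept for SHAP baselines).
#' @export
train_forest <- function(rows, labels, config = forest_config()) {
  X <- as.data.frame(rows)
  if (nrow(X) == 0) stop("empty training data")
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  y <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(y) < 2) stop("need two classes to train")
  k <- ncol(X)
  mtry <- switch(config$max_features,
                 sqrt = max(1, floor(sqrt(k))),
                 log2 = max(1, floor(log2(k))),
                 all = k)
  nodesize <- max(config$min_samples_leaf,
                  floor(config$min_samples_split / 2))
  maxnodes <- if (is.null(config$max_depth)) NULL else
    min(2^config$max_depth, nrow(X))
  sampsize <- if (config$balanced_bootstrap)
    rep(min(table(y)), nlevels(y)) else nrow(X)
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = config$n_estimators, mtry = mtry,
    nodesize = nodesize, maxnodes = maxnodes,
    strata = y, sampsize = sampsize, replace = TRUE, importance = FALSE)
  structure(list(rf = rf, config = config, feature_names = colnames(X),
                 levels = levels(y), train_x = as.matrix(X)),
            class = "survival_forest")
}

#' Predicted survival probability (fraction of tree votes for class 1)
#'
#' @param model a [train_forest()] fit.
#' @param rows predictor rows with the training columns.
#' @export
predict_prob <- function(model, rows) {
  stopifnot(inherits(model, "survival_forest"))
  rows <- as.data.frame(rows)[model$feature_names]
  p <- stats::predict(model$rf, rows, type = "prob")
  unname(p[, ncol(p)])
}

# Stratified fold assignment: within each class, rows are dealt round-robin
# across folds in random order.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < n_folds)
      stop("class ", cl, " too small for ", n_folds, "-fold stratified CV")
    fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
  }
  fold
}

# Mean stratified-CV macro-F1 of one configuration, with SMOTE applied
# inside each training fold only.
cv_macro_f1 <- function(rows, labels, config, n_folds = 5, k_smote = 5,
                        threshold = 0.5) {
  fold <- stratified_folds(labels, n_folds)
  scores <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    bal <- smote(rows[tr, , drop = FALSE], labels[tr], k_smote)
    fit <- train_forest(bal$rows, bal$labels, config)
    prob <- predict_prob(fit, rows[!tr, , drop = FALSE])
    pred <- as.integer(prob >= threshold)
    scores[f] <- macro_f1(labels[!tr], pred)
  }
  mean(scores)
}

#' Randomized hyperparameter search with stratified cross-validation
#'
#' Samples `n_candidates` configurations uniformly from the search domains
#' and scores each by 5-fold stratified CV macro-F1, applying SMOTE inside
#' each training fold only. Ties go to the first candidate drawn.
#'
#' @param rows,labels training data (pre-SMOTE).
#' @param domains named list of value sets, as [forest_search_domains()].
#' @param n_candidates configurations drawn.
#' @param seed RNG seed covering candidate draws, folds and tree growing.
#' @param n_folds CV folds.
#' @param k_smote SMOTE neighbours.
#' @return list: `config` (best [forest_config()]), `cv_table` of candidate
#'   scores.
#' @export
tune_hyperparameters <- function(rows, labels,
                                 domains = forest_search_domains(),
                                 n_candidates = 50, seed = 1L, n_folds = 5,
                                 k_smote = 5) {
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  set.seed(seed)
  draw <- function(dom) dom[[sample.int(length(dom), 1)]]
  cands <- lapply(seq_len(n_candidates), function(i) {
    forest_config(n_estimators = draw(domains$n_estimators),
                  max_depth = draw(domains$max_depth),
                  max_features = draw(domains$max_features),
                  min_samples_split = draw(domains$min_samples_split),
                  min_samples_leaf = draw(domains$min_samples_leaf),
                  seed = seed + i)
  })
  scores <- vapply(cands, function(cfg)
    cv_macro_f1(rows, labels, cfg, n_folds, k_smote), numeric(1))
  best <- which.max(scores)
  cv_table <- data.frame(
    candidate = seq_len(n_candidates),
    n_estimators = vapply(cands, `[[`, numeric(1), "n_estimators"),
    max_depth = vapply(cands, function(c)
      ifelse(is.null(c$max_depth), NA_real_, c$max_depth), numeric(1)),
    max_features = vapply(cands, `[[`, character(1), "max_features"),
    min_samples_split = vapply(cands, `[[`, numeric(1), "min_samples_split"),
    min_samples_leaf = vapply(cands, `[[`, numeric(1), "min_samples_leaf"),
    cv_macro_f1 = scores)
  list(config = cands[[best]], cv_table = cv_table)
}
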