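test_that("SMOTE balances classes by segment interpolation", {
  # already balanced: identity
  X <- data.frame(a = rnorm(10), b = rnorm(10))
  y <- rep(c(0, 1), each = 5)
  out <- smote(X, y)
  expect_equal(out$rows, X)
  expect_false(any(out$synthetic))

  # two minority points: synthetics lie on the connecting segment
  set.seed(4)
  X2 <- data.frame(a = c(0, 1, rnorm(6, 10)), b = c(0, 1, rnorm(6, 10)))
  y2 <- c(1, 1, rep(0, 6))
  expect_warning(out2 <- smote(X2, y2, k_neighbors = 5), "reduced")
  expect_equal(sum(out2$synthetic), 4)
  expect_equal(as.integer(table(out2$labels)), c(6L, 6L))
  synth <- out2$rows[out2$synthetic, ]
  expect_true(all(synth$a >= 0 & synth$a <= 1))
  expect_equal(synth$a, synth$b)   # segment between (0,0) and (1,1)

  # originals preserved verbatim, majority untouched
  expect_equal(out2$rows[!out2$synthetic, ], X2)
  expect_error(smote(data.frame(a = 1:5), c(1, 0, 0, 0, 0)),
               "at least 2 members")
})

test_that("SMOTE synthetics interpolate feature-wise between their parents", {
  set.seed(9)
  X <- as.data.frame(matrix(rnorm(60 * 3), 60, 3))
  y <- rep(c(0, 1), c(40, 20))
  out <- smote(X, y)
  expect_equal(as.integer(table(out$labels)), c(40L, 40L))
  synth_rows <- which(out$synthetic)
  for (s in seq_along(synth_rows)) {
    pa <- as.numeric(X[out$parents[s, 1], ])
    pb <- as.numeric(X[out$parents[s, 2], ])
    v <- as.numeric(out$rows[synth_rows[s], ])
    lo <- pmin(pa, pb) - 1e-12; hi <- pmax(pa, pb) + 1e-12
    expect_true(all(v >= lo & v <= hi))
    # collinearity: consistent interpolation fraction across features
    lam <- (v - pa) / (pb - pa)
    expect_lt(diff(range(lam)), 1e-9)
  }
})

test_that("balanced forest learns separable data and is seed-deterministic", {
  set.seed(5)
  n <- 200
  X <- data.frame(a = c(rnorm(140, 0), rnorm(60, 4)),
                  b = c(rnorm(140, 0), rnorm(60, 4)))
  y <- rep(c(0, 1), c(140, 60))
  fit <- train_forest(X, y, forest_config(n_estimators = 100, seed = 1))
  acc <- mean(as.integer(predict_prob(fit, X) >= 0.5) == y)
  expect_gte(acc, 0.99)

  fit2 <- train_forest(X, y, forest_config(n_estimators = 100, seed = 1))
  expect_equal(predict_prob(fit, X), predict_prob(fit2, X))
  expect_error(train_forest(X[0, ], integer(0)), "empty")
})

test_that("shuffled labels score at chance under stratified CV", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  y <- sample(rep(c(0, 1), 100))
  f1 <- hybridsurv:::cv_macro_f1(X, y, forest_config(n_estimators = 60,
                                                     seed = 2))
  expect_gte(f1, 0.35); expect_lte(f1, 0.65)
})

test_that("randomized search respects its domains and finds the argmax", {
  set.seed(7)
  X <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- as.integer(X$a + rnorm(120, 0, 0.5) > 0)
  single <- list(n_estimators = 50, max_depth = list(10),
                 max_features = "sqrt", min_samples_split = 2,
                 min_samples_leaf = 1)
  tuned <- tune_hyperparameters(X, y, domains = single, n_candidates = 3,
                                seed = 1)
  expect_equal(tuned$config$n_estimators, 50)
  expect_equal(tuned$config$max_depth, 10)

  dom <- forest_search_domains()
  tuned2 <- tune_hyperparameters(X, y, n_candidates = 4, seed = 2)
  expect_true(tuned2$config$n_estimators %in% dom$n_estimators)
  expect_true(tuned2$config$max_features %in% dom$max_features)
  expect_true(tuned2$config$min_samples_split %in% dom$min_samples_split)
  expect_true(tuned2$config$min_samples_leaf %in% dom$min_samples_leaf)
  best <- max(tuned2$cv_table$cv_macro_f1)
  expect_gte(best, min(tuned2$cv_table$cv_macro_f1))
  expect_error(tune_hyperparameters(X, y, n_candidates = 0), ">= 1")
})

test_that("fold-wise SMOTE never leaks validation rows", {
  set.seed(8)
  X <- as.data.frame(matrix(rnorm(100 * 2), 100, 2))
  y <- rep(c(0, 1), c(70, 30))
  fold <- hybridsurv:::stratified_folds(y, 5)
  for (f in 1:5) {
    tr <- which(fold != f)
    bal <- smote(X[tr, , drop = FALSE], y[tr])
    # parents index into the training subset only
    expect_true(all(bal$parents <= length(tr)))
    # original training rows appear verbatim
    expect_equal(bal$rows[!bal$synthetic, ], X[tr, ],
                 ignore_attr = TRUE)
  }
})
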