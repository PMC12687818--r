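test_that("body condition is weight over tarsus with guards", {
  expect_equal(body_condition(30, 30), 1.0)
  expect_equal(body_condition(33.0, 27.5), 1.2)
  expect_error(body_condition(30, 0), "tarsus")
  expect_true(is.na(body_condition(NA, 28)))
})

test_that("great-circle distance and initial bearing match hand values", {
  expect_equal(great_circle_km(49, -122, 49, -122), 0)
  expect_lt(abs(great_circle_km(49, -122, 49, -121) - 73.1), 0.5)
  expect_lt(abs(great_circle_km(0, 0, 0, 180) - 20015), 10)

  expect_equal(initial_bearing(50, -120, 45, -120), 180)
  expect_lt(abs(initial_bearing(49, -122, 49, -121) - 89.62), 0.05)
  # compass mirror: flipping the longitude offset reflects the bearing
  th <- initial_bearing(49, -122, 48.2, -121)
  th_m <- initial_bearing(49, -122, 48.2, -123)
  expect_equal(th_m, 360 - th, tolerance = 1e-9)
  expect_true(th >= 0 && th < 360)
})

test_that("fall bearing uses the first station inside 300 km", {
  rel <- c(49, -122)
  south <- geosphere::destPoint(c(-122, 49), 180, 200e3, r = 6371000)
  d <- det_events(c(0, 5), c(rel[1], south[2]), c(rel[2], south[1]))
  expect_equal(fall_bearing(rel[1], rel[2], d), 180, tolerance = 0.01)

  # release-site detections are skipped (zero distance)
  d0 <- det_events(c(0, 3), rep(rel[1], 2), rep(rel[2], 2))
  expect_true(is.na(fall_bearing(rel[1], rel[2], d0)))

  far <- geosphere::destPoint(c(-122, 49), 170, 450e3, r = 6371000)
  dfar <- det_events(4, far[2], far[1])
  expect_true(is.na(fall_bearing(rel[1], rel[2], dfar)))
})

test_that("fall timing requires proximity, the fall window, and movement", {
  rel <- c(49, -122)
  near <- geosphere::destPoint(c(-122, 49), 180, 10e3, r = 6371000)
  d <- det_events(10, near[2], near[1])
  expect_equal(fall_timing(240, rel[1], rel[2], d), 250)

  mid <- geosphere::destPoint(c(-122, 49), 180, 40e3, r = 6371000)
  close <- geosphere::destPoint(c(-122, 49), 180, 25e3, r = 6371000)
  d2 <- det_events(c(0, 20), c(mid[2], close[2]), c(mid[1], close[1]))
  expect_equal(fall_timing(240, rel[1], rel[2], d2), 260)

  expect_true(is.na(fall_timing(240, rel[1], rel[2], dfar <- det_events(
    4, geosphere::destPoint(c(-122, 49), 180, 80e3, r = 6371000)[2],
    geosphere::destPoint(c(-122, 49), 180, 80e3, r = 6371000)[1]))))
  # the tagging event itself (timestamp 0) never counts
  d0 <- det_events(0, rel[1], rel[2])
  expect_true(is.na(fall_timing(240, rel[1], rel[2], d0)))
})

test_that("correlation pruning drops redundant members by priority", {
  set.seed(1)
  x <- rnorm(200)
  tab <- data.frame(a = x, b = x, c = rnorm(200))
  kept <- correlation_prune(tab, priority = c("a"))
  expect_setequal(kept, c("a", "c"))

  # independent noise is never pruned
  tab2 <- data.frame(u = rnorm(1000), v = rnorm(1000))
  expect_setequal(correlation_prune(tab2), c("u", "v"))

  # row order invariance and idempotence
  tab3 <- data.frame(a = x, b = x + rnorm(200, 0, 0.1), c = rnorm(200))
  k1 <- correlation_prune(tab3, priority = "a")
  k2 <- correlation_prune(tab3[sample(200), ], priority = "a")
  expect_identical(k1, k2)
  expect_identical(correlation_prune(tab3[k1], priority = "a"), k1)

  # fully collinear panel with no priority collapses to one with a warning
  tab4 <- data.frame(a = x, b = 2 * x, c = -x)
  expect_warning(kept4 <- correlation_prune(tab4), "keeping only")
  expect_length(kept4, 1)
})

test_that("missingness filter is strict-greater with a whitelist", {
  tab <- data.frame(ok = 1:100,
                    boundary = c(rep(NA, 25), 26:100),
                    heavy = c(rep(NA, 30), 31:100),
                    listed = c(rep(NA, 28), 29:100))
  kept <- missingness_filter(tab, 0.25, whitelist = "listed")
  expect_setequal(kept, c("ok", "boundary", "listed"))
})

test_that("standardization is exact on fit rows and leak-free on others", {
  set.seed(2)
  tab <- data.frame(a = rnorm(100, 5, 2), b = runif(100))
  s <- standardize(tab)
  expect_lt(max(abs(colMeans(s$values))), 1e-9)
  expect_lt(max(abs(vapply(s$values, sd, numeric(1)) - 1)), 1e-9)
  expect_error(standardize(data.frame(k = rep(1, 10))), "zero-variance")

  test_tab <- data.frame(a = rnorm(50, 9, 2), b = runif(50))
  s2 <- standardize(test_tab, center = s$center, scale = s$scale)
  expect_gt(abs(mean(s2$values$a)), 0.5)   # shifted mean survives transform
})

test_that("KNN imputation matches the brute-force nan-Euclidean oracle", {
  tab <- data.frame(x = c(1, 2, 3), y = c(1, 2, NA))
  out <- knn_impute(tab, k = 2)
  expect_equal(out$values$y[3], 1.5)
  expect_true(out$imputed[3, 2])

  set.seed(3)
  for (rep in 1:5) {
    m2 <- matrix(rnorm(10 * 4), 10, 4)
    m2[cbind(sample(10, 6, TRUE), sample(4, 6, TRUE))] <- NA
    tab2 <- as.data.frame(m2)
    if (any(colSums(!is.na(tab2)) == 0)) next
    k <- sample(1:3, 1)
    expect_equal(knn_impute(tab2, k)$values, knn_impute_brute(tab2, k))
  }

  # identity on complete data; imputed values within observed range
  full <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_equal(knn_impute(full, 3)$values, full)
  tab3 <- data.frame(a = c(rnorm(20), NA), b = rnorm(21))
  v <- knn_impute(tab3, 5)$values$a[21]
  expect_gte(v, min(tab3$a, na.rm = TRUE))
  expect_lte(v, max(tab3$a, na.rm = TRUE))
  expect_error(knn_impute(data.frame(a = c(NA_real_, NA), b = c(1, 2)), 2),
               "no observed values")
})

test_that("stratified split preserves class proportions", {
  labels <- rep(c(0, 1), c(415, 185))   # 69.2% / 30.8% of 600
  sp <- stratified_split(labels, 0.2, seed = 5)
  expect_length(sp$test, 120)
  expect_equal(sum(labels[sp$test] == 0), 83)
  expect_equal(sum(labels[sp$test] == 1), 37)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(labels, 0.2, seed = 5))
  expect_error(stratified_split(c(0, 0, 0, 1), 0.2), "at least 2")
})

test_that("prepared panel reproduces the intended 14 features", {
  sim <- simulate_cohort(sim_config(n_birds = 500, seed = 17))
  raw <- assemble_features(sim$traits, sim$detections)
  fm <- prepare_features(raw)
  expect_setequal(fm$dropped_correlated, c("p7", "p8", "p9", "weight"))
  expect_length(fm$feature_names, 14)
  expect_false(anyNA(fm$values))
  # provenance marks exactly the pre-imputation missing cells
  expect_equal(sum(fm$imputed[, "fall_bearing"]),
               sum(is.na(raw$fall_bearing)))

  # strict mode: parameters fitted on training rows only
  sp <- stratified_split(rep(c(0, 1), 250), 0.2, seed = 1)
  fm_strict <- prepare_features(raw, mode = "strict", train_rows = sp$train)
  tr_means <- colMeans(fm_strict$values[sp$train, ])
  expect_lt(max(abs(tr_means)), 0.2)
  expect_false(anyNA(fm_strict$values))
})
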