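test_that("detection binning follows the half-open ten-day convention", {
  ev <- function(days) data.frame(days_since_tag = days)
  h <- bin_detections(ev(c(3, 14)))
  expect_equal(which(h == 1) - 1, c(0, 1))
  expect_equal(length(h), 30)

  h2 <- bin_detections(ev(305))
  expect_equal(which(h2 == 1) - 1, c(0, 29))   # beyond window -> final occasion

  h3 <- bin_detections(ev(c(0, 9.99, 10.0)))
  expect_equal(which(h3 == 1) - 1, c(0, 1))

  expect_error(bin_detections(ev(-1)), "negative")
  h4 <- bin_detections(ev(numeric(0)))
  expect_equal(which(h4 == 1) - 1, 0)
})

test_that("CJS likelihood matches hand-enumerated path probabilities", {
  expect_equal(cjs_likelihood(c(1, 1), 0.5, 0.5), log(0.25))
  expect_equal(cjs_likelihood(c(1, 0), 0.5, 0.5), log(0.75))
  expect_equal(cjs_likelihood(c(1, 0, 1), c(0.5, 0.5), c(0.5, 0.5)),
               log(0.0625))
  expect_error(cjs_likelihood(c(1, 0), 1.5, 0.5), "\\[0, 1\\]")
})

test_that("forward pass equals exhaustive latent-path enumeration", {
  params <- expand.grid(phi = c(0.2, 0.6, 0.9), p = c(0.3, 0.7))
  for (code in 0:15) {
    h <- c(1L, as.integer(intToBits(code)[1:4]))
    for (r in seq_len(nrow(params))) {
      phi <- rep(params$phi[r], 4); p <- rep(params$p[r], 4)
      expect_equal(cjs_likelihood(h, phi, p), cjs_enumerate(h, phi, p),
                   tolerance = 1e-10)
    }
    # time-varying parameters too
    phi <- c(0.9, 0.5, 0.7, 0.95); p <- c(0.4, 0.8, 0.2, 0.6)
    expect_equal(cjs_likelihood(h, phi, p), cjs_enumerate(h, phi, p),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to repeat detections within a bin", {
  ev <- function(days) data.frame(days_since_tag = days)
  h1 <- bin_detections(ev(c(12, 45)))
  h2 <- bin_detections(ev(c(12, 13, 17.5, 45, 45)))
  expect_identical(h1, h2)
})

test_that("fit_cjs recovers parameters and saturates on full detection", {
  # every bird detected at every occasion -> certainty at the bounds
  H <- matrix(1L, nrow = 10, ncol = 8)
  fit <- fit_cjs(H)
  expect_true(all(fit$phi > 1 - 1e-3))
  expect_true(all(fit$p > 1 - 1e-3))

  # constant-parameter recovery on simulation
  set.seed(42)
  phi_true <- 0.95; p_true <- 0.6
  n <- 500; T <- 30
  alive <- matrix(1L, n, T)
  for (t in 2:T) alive[, t] <- alive[, t - 1] * rbinom(n, 1, phi_true)
  H <- alive * matrix(rbinom(n * T, 1, p_true), n, T)
  H[, 1] <- 1L
  fit <- fit_cjs(H)
  expect_lt(mean(abs(fit$phi - phi_true)), 0.05)
  expect_lt(mean(abs(fit$p - p_true)), 0.05)
})

test_that("per-bird fits reproduce near-binary survival products", {
  H <- matrix(0L, 1, 30); H[1, 1] <- 1L   # seen only at release
  fit <- fit_cjs(H, mode = "per_bird")
  lab <- label_survival(fit)
  expect_lt(lab$overall_survival_prob, 0.001)
  expect_equal(lab$label, 0L)
})

test_that("survival labels binarize at 0.5 and respect final detections", {
  fake <- structure(list(phi = matrix(0.82, 1, 1), p = matrix(0.5, 1, 1),
                         mode = "per_bird",
                         histories = matrix(c(1L, 1L), 1, 2)),
                    class = "cjs_fit")
  expect_equal(label_survival(fake)$label, 1L)   # 0.82 -> survived
  fake$phi <- matrix(0.4999, 1, 1)
  expect_equal(label_survival(fake)$label, 0L)

  # detection on the final occasion forces posterior ~1 in cohort mode
  set.seed(7)
  H <- matrix(rbinom(600, 1, 0.5), 20, 30); H[, 1] <- 1L
  H[1, 30] <- 1L
  fit <- fit_cjs(H)
  lab <- label_survival(fit)
  expect_gt(lab$overall_survival_prob[1], 0.999)
  expect_true(all(lab$overall_survival_prob >= 0 &
                    lab$overall_survival_prob <= 1))
})

test_that("per-bird survival product shrinks with horizon", {
  probs <- vapply(c(5, 10, 20, 30), function(T) {
    fake <- structure(list(phi = matrix(0.97, 1, T - 1),
                           p = matrix(0.5, 1, T - 1), mode = "per_bird",
                           histories = matrix(1L, 1, T)),
                      class = "cjs_fit")
    label_survival(fake)$overall_survival_prob
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})
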