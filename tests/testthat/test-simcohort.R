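test_that("genotype simulation matches hybrid-class genetics", {
  set.seed(1)
  g <- simulate_genotype("F1", 50)
  expect_equal(unname(g), c(0.5, 1.0))
  expect_equal(unname(simulate_genotype("inland_parental", 10)), c(1, 0))
  expect_equal(unname(simulate_genotype("coastal_parental", 10)), c(0, 0))
  expect_error(simulate_genotype("mule", 10), "unknown hybrid class")

  # backcross expectation: q -> 0.75, H -> 0.5 (per-locus mixture mean)
  draws <- t(replicate(1000, simulate_genotype("backcross_inland", 1495)))
  expect_lt(abs(mean(draws[, 1]) - 0.75), 0.02)
  expect_lt(abs(mean(draws[, 2]) - 0.50), 0.02)
})

test_that("every simulated bird satisfies the triangle constraint", {
  sim <- simulate_cohort(sim_config(n_birds = 400, seed = 3))
  tr <- sim$traits
  expect_true(all(tr$heterozygosity <=
                    2 * pmin(tr$ancestry, 1 - tr$ancestry) + 1e-9))
  expect_true(all(tr$ancestry >= 0 & tr$ancestry <= 1))
})

test_that("morphology respects configured pairwise correlations", {
  cfg <- sim_config(n_birds = 500, seed = 11,
                    morphology_correlation = data.frame(
                      trait_a = "wing_chord", trait_b = "p8", r = 0.9))
  tr <- simulate_cohort(cfg)$traits
  r <- cor(tr$wing_chord, tr$p8)
  expect_gt(r, 0.8); expect_lt(r, 0.97)
  expect_equal(tr$condition, tr$weight / tr$tarsus)
})

test_that("invalid correlation targets are rejected", {
  cfg <- sim_config(n_birds = 20, seed = 1,
                    morphology_correlation = data.frame(
                      trait_a = c("wing_chord", "wing_chord", "p7"),
                      trait_b = c("p7", "tail", "tail"),
                      r = c(0.95, -0.95, 0.95)))
  expect_error(simulate_cohort(cfg), "positive semi-definite")
})

test_that("fall orientation rotates with ancestry and has a uniform limit", {
  mk <- function(cls) {
    props <- setNames(rep(0, 6), hybrid_classes)
    props[cls] <- 1
    simulate_cohort(sim_config(n_birds = 400, seed = 5,
                               class_proportions = props))$traits
  }
  inland <- mk("inland_parental")
  coastal <- mk("coastal_parental")
  circ_mean <- function(deg) {
    th <- deg * pi / 180
    (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
  }
  expect_lt(circ_mean(inland$fall_bearing_true), 180)   # east of due south
  expect_gt(circ_mean(coastal$fall_bearing_true), 180)  # west of due south

  # zero concentration: Rayleigh test must not reject uniformity
  set.seed(9)
  th <- hybridsurv:::rvonmises(1000, pi, 0)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  p_rayleigh <- exp(-1000 * rbar^2)
  expect_gt(p_rayleigh, 0.01)
})

test_that("planted survival honours base rate, effects, and saturation", {
  cfg <- sim_config(n_birds = 10000, seed = 2,
                    survival_coefficients = c(condition = 0))
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$traits$survived_true) - 0.309), 0.015)

  cfg2 <- sim_config(n_birds = 4000, seed = 4,
                     survival_coefficients = c(condition = 2))
  tr2 <- simulate_cohort(cfg2)$traits
  q <- cut(tr2$condition, quantile(tr2$condition, 0:4 / 4),
           include.lowest = TRUE)
  rates <- tapply(tr2$survived_true, q, mean)
  expect_true(all(diff(rates) > 0))

  cfg3 <- sim_config(n_birds = 200, seed = 6)
  cohort3 <- simulate_cohort(cfg3)$traits
  cfg3$survival_intercept <- 50   # logistic saturation
  expect_true(all(plant_survival(cohort3, cfg3)))

  expect_error(
    plant_survival(cohort3, sim_config(n_birds = 10,
                                       survival_coefficients = c(beak = 1))),
    "unknown survival term")
})

test_that("class imbalance matches the configured base rate", {
  for (s in c(1, 2)) {
    sim <- simulate_cohort(sim_config(n_birds = 600, seed = s))
    k <- sum(sim$traits$survived_true)
    bounds <- qbinom(c(0.005, 0.995), 600, 0.309)
    expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
  }
})

test_that("detection streams follow survival status", {
  cfg <- sim_config(n_birds = 500, seed = 8, detection_prob = 1)
  sim <- simulate_cohort(cfg)
  det <- sim$detections
  tr <- sim$traits
  surv_ids <- tr$bird_id[tr$survived_true]
  # certain detection: survivors seen in every occasion incl. spring
  for (id in surv_ids[1:5]) {
    d <- det$days_since_tag[det$bird_id == id]
    occ <- unique(pmin(floor(d / 10), 29))
    expect_true(all(0:29 %in% occ))
    expect_true(any(d > 240))
  }
  # non-survivors: silent after the death occasion (drawn in fall, <= 9)
  dead_ids <- tr$bird_id[!tr$survived_true]
  last_day <- tapply(det$days_since_tag[det$bird_id %in% dead_ids],
                     det$bird_id[det$bird_id %in% dead_ids], max)
  expect_true(all(last_day < 100))

  # release detection always present at day 0
  first_day <- tapply(det$days_since_tag, det$bird_id, min)
  expect_true(all(first_day == 0))

  # near-certain spring coverage at p = 0.8
  sim2 <- simulate_cohort(sim_config(n_birds = 2000, seed = 12,
                                     detection_prob = 0.8))
  det2 <- sim2$detections
  surv2 <- sim2$traits$bird_id[sim2$traits$survived_true]
  spring <- tapply(det2$days_since_tag, det2$bird_id, function(d) any(d > 240))
  expect_gte(mean(spring[surv2]), 0.99)

  cfg_bad <- cfg
  cfg_bad$detection_prob <- 1.2
  expect_error(simulate_detections(sim$traits, cfg_bad), "detection_prob")
})

test_that("behavioural missingness hits the configured fraction", {
  sim <- simulate_cohort(sim_config(n_birds = 1000, seed = 10))
  n_miss <- sum(is.na(sim$traits$fall_bearing))
  expect_gte(n_miss, 250); expect_lte(n_miss, 310)

  cfg0 <- sim_config(n_birds = 100, seed = 1, missing_frac_behaviour = 0)
  expect_false(anyNA(simulate_cohort(cfg0)$traits$fall_bearing))
  cfg1 <- sim_config(n_birds = 100, seed = 1, missing_frac_behaviour = 1)
  expect_true(all(is.na(simulate_cohort(cfg1)$traits$fall_timing)))
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- simulate_cohort(sim_config(n_birds = 150, seed = 21))
  b <- simulate_cohort(sim_config(n_birds = 150, seed = 21))
  c <- simulate_cohort(sim_config(n_birds = 150, seed = 22))
  expect_identical(a$traits, b$traits)
  expect_identical(a$detections, b$detections)
  expect_false(identical(a$traits, c$traits))
})

test_that("ancestry polarity flag flips the reported axis only", {
  a <- simulate_cohort(sim_config(n_birds = 100, seed = 33))
  b <- simulate_cohort(sim_config(n_birds = 100, seed = 33,
                                  polarity_inland_one = FALSE))
  expect_equal(a$traits$ancestry, 1 - b$traits$ancestry)
  expect_identical(a$traits$survived_true, b$traits$survived_true)
})
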