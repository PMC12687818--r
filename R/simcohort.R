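#' @useDynLib hybridsurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom randomForest randomForest getTree
#' @importFrom stats plogis qlogis rbinom rgamma rmultinom runif rnorm uniroot
NULL

#' Hybrid classes recognised by the cohort simulator
#'
#' Closed set of hybrid-zone genotype classes: the two parental forms, F1
#' and F2 hybrids, and first-generation backcrosses toward either parent.
#'
#' @export
hybrid_classes <- c("coastal_parental", "inland_parental", "F1", "F2",
                    "backcross_inland", "backcross_coastal")

#' Simulation configuration for a synthetic hybrid-zone cohort
#'
#' Bundles every knob of the cohort generator. Defaults describe the study
#' conditions the pipeline is built for: a fall-tagged juvenile cohort with
#' roughly 69/31 non-survivor/survivor imbalance, an ancestry panel of 1495
#' ancestry-informative markers, 28% missingness in the two
#' detection-derived behavioural features, and a planted survival model with
#' nonlinear ancestry and pairwise interaction effects.
#'
#' @param n_birds cohort size.
#' @param class_proportions named probabilities over [hybrid_classes]; must
#'   sum to 1 (tolerance 1e-9).
#' @param n_loci number of diploid ancestry-informative loci (idealized as
#'   fixed differences between the parental forms).
#' @param base_survival_rate marginal survival probability the planted model
#'   is calibrated to.
#' @param survival_coefficients named effect sizes on the logit scale. Names
#'   are covariate labels (`condition`, `ancestry`, `ancestry_sq`,
#'   `heterozygosity`, `year`, `eastness`, `tarsus`, `wing_chord`, `timing`,
#'   `release_day`, `sex`) or `a:b` pairwise products of those.
#' @param detection_prob per-occasion detection probability while alive.
#' @param missing_frac_behaviour fraction of birds whose fall bearing and
#'   fall timing are unobserved (applied independently per feature).
#' @param morphology_correlation data.frame with columns `trait_a`,
#'   `trait_b`, `r`: target trait-pair correlations overriding the default
#'   structure. The assembled matrix must be positive semi-definite.
#' @param bearing_kappa von Mises concentration of fall orientation.
#' @param bearing_swing half-range, in degrees, by which the mean fall
#'   bearing rotates from due south: inland ancestry (q = 1) pulls the mean
#'   east of south, coastal (q = 0) west of south.
#' @param polarity_inland_one if `FALSE`, reported ancestry is flipped to
#'   1 = coastal (the generator's internal truth is unchanged).
#' @param seed integer seed for the whole cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_birds = 479,
                       class_proportions = c(coastal_parental = 0.15,
                                             inland_parental = 0.15,
                                             F1 = 0.10,
                                             F2 = 0.20,
                                             backcross_inland = 0.20,
                                             backcross_coastal = 0.20),
                       n_loci = 1495,
                       base_survival_rate = 0.309,
                       survival_coefficients = c(
                         condition = 0.9,
                         ancestry = 3.0,
                         ancestry_sq = -3.2,
                         heterozygosity = 0.7,
                         year = 0.45,
                         eastness = 0.7,
                         "condition:year" = 0.5,
                         "ancestry:year" = -0.45,
                         "eastness:tarsus" = 0.45),
                       detection_prob = 0.8,
                       missing_frac_behaviour = 0.28,
                       morphology_correlation = NULL,
                       bearing_kappa = 4,
                       bearing_swing = 30,
                       polarity_inland_one = TRUE,
                       seed = 1L) {
  stopifnot(n_birds >= 1, n_loci >= 1)
  if (!setequal(names(class_proportions), hybrid_classes))
    stop("class_proportions must be named by the six hybrid classes")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  for (p in c(base_survival_rate, detection_prob, missing_frac_behaviour))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!is.null(morphology_correlation)) {
    stopifnot(is.data.frame(morphology_correlation),
              all(c("trait_a", "trait_b", "r") %in%
                    names(morphology_correlation)),
              all(abs(morphology_correlation$r) <= 1))
  }
  structure(list(n_birds = as.integer(n_birds),
                 class_proportions = class_proportions[hybrid_classes],
                 n_loci = as.integer(n_loci),
                 base_survival_rate = base_survival_rate,
                 survival_coefficients = survival_coefficients,
                 survival_intercept = NULL,
                 detection_prob = detection_prob,
                 missing_frac_behaviour = missing_frac_behaviour,
                 morphology_correlation = morphology_correlation,
                 bearing_kappa = bearing_kappa,
                 bearing_swing = bearing_swing,
                 polarity_inland_one = polarity_inland_one,
                 release_site = c(lat = 50.3, lon = -122.8),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Reference trait distributions (means, sds) the generator draws from; also
# the fixed scales plant_survival() standardizes against, so the planted
# model is a deterministic function of a bird's traits.
trait_reference <- function() {
  data.frame(
    trait = c("wing_chord", "kipps", "distal", "p7", "p8", "p9", "p10",
              "tail", "tarsus", "weight"),
    mean = c(95, 22, 35, 70, 72, 70, 30, 68, 28, 31),
    sd = c(3, 2, 2.5, 3, 3, 3, 2, 3, 1, 2.5))
}

#' Simulate a diploid ancestry genotype for one hybrid class
#'
#' Loci are idealized fixed differences between the coastal and inland
#' forms, so each locus carries 0, 1 or 2 inland alleles. Parental classes
#' are homozygous at every locus, F1s heterozygous at every locus, F2s draw
#' locus-wise from (1/4, 1/2, 1/4), and backcrosses from a 50:50 mixture of
#' the recurrent-parent homozygote and the heterozygote. The returned
#' summaries satisfy the triangle constraint H <= 2 min(q, 1 - q) by
#' construction.
#'
#' @param hybrid_class one of [hybrid_classes].
#' @param n_loci number of loci.
#' @return named numeric vector `c(ancestry, heterozygosity)`: the
#'   proportion of inland alleles and the proportion of heterozygous loci.
#' @export
simulate_genotype <- function(hybrid_class, n_loci) {
  stopifnot(n_loci >= 1)
  probs <- switch(as.character(hybrid_class),
                  coastal_parental  = c(1, 0, 0),
                  inland_parental   = c(0, 0, 1),
                  F1                = c(0, 1, 0),
                  F2                = c(0.25, 0.5, 0.25),
                  backcross_inland  = c(0, 0.5, 0.5),
                  backcross_coastal = c(0.5, 0.5, 0),
                  stop("unknown hybrid class: ", hybrid_class))
  counts <- as.vector(rmultinom(1, n_loci, probs))  # (coastal hom, het, inland hom)
  c(ancestry = (counts[2] + 2 * counts[3]) / (2 * n_loci),
    heterozygosity = counts[2] / n_loci)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa ~ 0 falls
# back to the uniform circular limit. mu in radians, output in [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  mu <- rep_len(mu, n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- (mu[i] + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Assemble the morphology correlation matrix: a tight block among wing
# chord and inner primaries, moderate correlation among the remaining wing
# measures, and a tarsus-weight link; user targets override entries.
morphology_sigma <- function(config) {
  ref <- trait_reference()
  traits <- ref$trait
  k <- length(traits)
  R <- matrix(0.15, k, k, dimnames = list(traits, traits))
  wing <- c("wing_chord", "kipps", "distal", "p7", "p8", "p9", "p10", "tail")
  R[wing, wing] <- 0.35
  block <- c("wing_chord", "p7", "p8", "p9")
  R[block, block] <- 0.85
  R["tarsus", "weight"] <- R["weight", "tarsus"] <- 0.5
  diag(R) <- 1
  if (!is.null(config$morphology_correlation)) {
    mc <- config$morphology_correlation
    for (i in seq_len(nrow(mc))) {
      a <- mc$trait_a[i]; b <- mc$trait_b[i]
      if (!a %in% traits || !b %in% traits)
        stop("unknown trait in morphology_correlation: ", a, "/", b)
      R[a, b] <- R[b, a] <- mc$r[i]
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("morphology correlation targets are not positive semi-definite")
  sds <- ref$sd
  Sigma <- R * tcrossprod(sds)
  attr(Sigma, "means") <- stats::setNames(ref$mean, traits)
  Sigma
}

#' Simulate morphology and behaviour for a genotyped cohort
#'
#' Morphology is drawn from a correlated multivariate normal (wing chord
#' and inner primaries P7-P9 form a tight block; weight tracks tarsus), with
#' a small ancestry shift on wing shape. Fall bearing is von Mises with a
#' mean that rotates from west of south (coastal ancestry) to east of south
#' (inland ancestry); release day and fall timing fall inside a fall
#' day-of-year window. Body condition is weight / tarsus (g/mm).
#'
#' @param cohort data.frame with `ancestry` and `heterozygosity` columns.
#' @param config a [sim_config()].
#' @return the cohort with trait columns appended; `fall_bearing_true` and
#'   `fall_timing_true` are the simulator's ground truth (never masked).
#' @export
simulate_traits <- function(cohort, config) {
  stopifnot(all(c("ancestry", "heterozygosity") %in% names(cohort)))
  n <- nrow(cohort)
  Sigma <- morphology_sigma(config)
  M <- MASS::mvrnorm(n, mu = attr(Sigma, "means"), Sigma = Sigma)
  M <- as.data.frame(M)
  q <- cohort$ancestry
  M$wing_chord <- M$wing_chord + 2.0 * (q - 0.5)
  M$kipps <- M$kipps + 1.5 * (q - 0.5)
  cohort <- cbind(cohort, M)
  cohort$condition <- cohort$weight / cohort$tarsus
  cohort$sex <- rbinom(n, 1, 0.5)
  cohort$release_year <- sample(c(2019, 2021, 2022, 2023), n, replace = TRUE,
                                prob = c(0.25, 0.25, 0.30, 0.20))
  cohort$release_day <- sample(213:273, n, replace = TRUE)
  site <- config$release_site
  cohort$release_lat <- site["lat"] + runif(n, -0.05, 0.05)
  cohort$release_lon <- site["lon"] + runif(n, -0.05, 0.05)
  mu_deg <- 180 - config$bearing_swing * (2 * q - 1)
  cohort$fall_bearing_true <-
    rvonmises(n, mu_deg * pi / 180, config$bearing_kappa) * 180 / pi
  delay <- 0.5 + rgamma(n, shape = 1, scale = 30)
  cohort$fall_timing_true <- pmin(cohort$release_day + delay, 304)
  cohort$fall_bearing <- cohort$fall_bearing_true
  cohort$fall_timing <- cohort$fall_timing_true
  cohort
}

# Standardized covariates the planted survival model is written in. Uses
# the generator's reference scales, not sample moments, so the model is a
# per-bird deterministic function.
survival_covariates <- function(cohort) {
  ref <- trait_reference()
  z <- function(tr) (cohort[[tr]] - ref$mean[ref$trait == tr]) /
    ref$sd[ref$trait == tr]
  list(condition = (cohort$condition - 31 / 28) / 0.09,
       ancestry = cohort$ancestry,
       ancestry_sq = cohort$ancestry^2,
       heterozygosity = cohort$heterozygosity,
       year = (cohort$release_year - 2021) / 1.5,
       eastness = sin(cohort$fall_bearing_true * pi / 180),
       tarsus = z("tarsus"),
       wing_chord = z("wing_chord"),
       timing = (cohort$fall_timing_true - 252) / 9,
       release_day = (cohort$release_day - 243) / 17.6,
       sex = cohort$sex - 0.5)
}

# Linear predictor (without intercept) of the planted survival model.
survival_eta <- function(cohort, coefficients) {
  cov <- survival_covariates(cohort)
  eta <- numeric(nrow(cohort))
  for (term in names(coefficients)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(cov)))
      stop("unknown survival term: ", term)
    x <- cov[[parts[1]]]
    if (length(parts) == 2) x <- x * cov[[parts[2]]]
    if (length(parts) > 2) stop("unknown survival term: ", term)
    eta <- eta + coefficients[[term]] * x
  }
  eta
}

#' Plant ground-truth survival on a simulated cohort
#'
#' Survival is Bernoulli on a logistic scale: eta = intercept + configured
#' effect terms (linear, quadratic via `_sq` suffix on ancestry, and `a:b`
#' pairwise products). With all coefficients zero the survival rate equals
#' `base_survival_rate` exactly; otherwise the intercept should first be
#' calibrated with [calibrate_survival_intercept()] (as [simulate_cohort()]
#' does) so the marginal rate still matches.
#'
#' @param cohort trait-complete cohort data.frame.
#' @param config a [sim_config()].
#' @return logical vector of planted survival outcomes.
#' @export
plant_survival <- function(cohort, config) {
  eta <- survival_eta(cohort, config$survival_coefficients)
  b0 <- config$survival_intercept
  if (is.null(b0)) b0 <- qlogis(config$base_survival_rate)
  runif(nrow(cohort)) < plogis(b0 + eta)
}

#' Calibrate the planted-survival intercept to the configured base rate
#'
#' Solves mean(plogis(b0 + eta)) = base_survival_rate over the cohort, so
#' nonzero effect coefficients do not drift the marginal class imbalance.
#'
#' @inheritParams plant_survival
#' @return intercept on the logit scale.
#' @export
calibrate_survival_intercept <- function(cohort, config) {
  eta <- survival_eta(cohort, config$survival_coefficients)
  target <- config$base_survival_rate
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(b0) mean(plogis(b0 + eta)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}

#' Mask behavioural features to emulate detection gaps
#'
#' Fall bearing and fall timing are independently set missing for a
#' configured fraction of birds (birds that evaded the receiver fence early
#' in migration). The `*_true` columns are left untouched.
#'
#' @inheritParams plant_survival
#' @return the cohort with `fall_bearing` / `fall_timing` masked.
#' @export
apply_missingness <- function(cohort, config) {
  f <- config$missing_frac_behaviour
  if (f < 0 || f > 1) stop("missing_frac_behaviour must lie in [0, 1]")
  n <- nrow(cohort)
  cohort$fall_bearing[runif(n) < f] <- NA_real_
  cohort$fall_timing[runif(n) < f] <- NA_real_
  cohort
}

# Spherical destination point: start (lat, lon) in degrees, initial bearing
# in degrees, distance in km on a sphere of radius 6371 km.
dest_point <- function(lat, lon, bearing, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, dist_km * 1000,
                            r = 6371000)
  list(lat = p[, 2], lon = p[, 1])
}

#' Simulate telemetry detection streams for a cohort
#'
#' Every bird gets a tagging detection at its release site at day 0. Birds
#' with an observed fall timing are re-detected near the release site at
#' that day; birds with an observed fall bearing are detected at a station
#' within 300 km placed along their true bearing. While alive, each
#' subsequent ten-day occasion yields a detection with probability
#' `detection_prob` at a station along the southward trajectory (all beyond
#' the 300 km orientation radius); non-survivors draw a death occasion
#' during fall after which they are never detected, while survivors keep
#' emitting detections through the spring window (day > 240).
#'
#' @inheritParams plant_survival
#' @return data.frame with columns `bird_id`, `station_id`, `lat`, `lon`,
#'   `days_since_tag`.
#' @export
simulate_detections <- function(cohort, config) {
  p <- config$detection_prob
  if (p < 0 || p > 1) stop("detection_prob must lie in [0, 1]")
  stopifnot("survived_true" %in% names(cohort))
  n <- nrow(cohort)
  death_occ <- ifelse(cohort$survived_true, 30L, sample(3:9, n, replace = TRUE))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    b <- cohort[i, ]
    ts <- 0; lat <- b$release_lat; lon <- b$release_lon
    if (!is.na(b$fall_timing)) {
      t1 <- max(b$fall_timing - b$release_day, 0.25)
      if (!is.na(b$fall_bearing)) {
        st <- dest_point(b$release_lat, b$release_lon, b$fall_bearing_true,
                         runif(1, 15, 28))
        ts <- c(ts, t1); lat <- c(lat, st$lat); lon <- c(lon, st$lon)
      } else {
        # re-detected by the tagging station only: timing observable,
        # bearing undefined at zero distance
        ts <- c(ts, t1); lat <- c(lat, b$release_lat); lon <- c(lon, b$release_lon)
      }
    } else if (!is.na(b$fall_bearing)) {
      st <- dest_point(b$release_lat, b$release_lon, b$fall_bearing_true,
                       runif(1, 150, 280))
      ts <- c(ts, runif(1, 3, 9)); lat <- c(lat, st$lat); lon <- c(lon, st$lon)
    }
    occ <- seq_len(min(death_occ[i], 29L))
    occ <- occ[runif(length(occ)) < p]
    if (length(occ)) {
      day <- 10 * occ + runif(length(occ), 0, 10)
      dist <- ifelse(occ <= 8, 400 + 420 * (occ - 1),
                     ifelse(occ <= 23, runif(length(occ), 3400, 4000),
                            runif(length(occ), 400, 1500)))
      st <- dest_point(b$release_lat, b$release_lon,
                       b$fall_bearing_true + rnorm(length(occ), 0, 4), dist)
      ts <- c(ts, day); lat <- c(lat, st$lat); lon <- c(lon, st$lon)
    }
    rows[[i]] <- data.frame(bird_id = b$bird_id,
                            lat = lat, lon = lon, days_since_tag = ts)
  }
  det <- do.call(rbind, rows)
  det$station_id <- paste0("ST", abs(round(det$lat * 100)), "_",
                           abs(round(det$lon * 100)))
  det <- det[order(det$bird_id, det$days_since_tag),
             c("bird_id", "station_id", "lat", "lon", "days_since_tag")]
  rownames(det) <- NULL
  det
}

#' Generate a full synthetic hybrid-zone cohort
#'
#' Runs the whole generator under one seed: hybrid-class draw, genotypes,
#' correlated traits, intercept-calibrated planted survival, behavioural
#' missingness, and detection streams.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list with elements `traits` (one row per bird,
#'   including ground-truth columns), `detections`, and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_birds
  cls <- sample(hybrid_classes, n, replace = TRUE,
                prob = config$class_proportions)
  geno <- t(vapply(cls, simulate_genotype, numeric(2),
                   n_loci = config$n_loci))
  cohort <- data.frame(bird_id = sprintf("B%04d", seq_len(n)),
                       hybrid_class = cls,
                       ancestry = geno[, 1],
                       heterozygosity = geno[, 2])
  cohort <- simulate_traits(cohort, config)
  config$survival_intercept <- calibrate_survival_intercept(cohort, config)
  cohort$survived_true <- plant_survival(cohort, config)
  cohort <- apply_missingness(cohort, config)
  detections <- simulate_detections(cohort, config)
  if (!config$polarity_inland_one)
    cohort$ancestry <- 1 - cohort$ancestry
  structure(list(traits = cohort, detections = detections, config = config),
            class = "sim_cohort")
}
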