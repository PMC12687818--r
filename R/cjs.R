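#' Bin a bird's detections into ten-day capture occasions
#'
#' Detections are binned over a 300-day study window into 30 occasions of
#' ten days, using half-open bins `[10k, 10(k+1))`. Occasion 0 is the
#' release/tagging occasion and is always set. Any detection after the
#' study window is folded onto the final occasion, since it proves the bird
#' was still alive then.
#'
#' @param events data.frame of detections for one bird with a
#'   `days_since_tag` column (days relative to tagging; must be >= 0).
#' @param study_days study window length in days.
#' @param occasion_days bin width in days.
#' @return integer 0/1 vector of length `study_days / occasion_days`.
#' @export
bin_detections <- function(events, study_days = 300, occasion_days = 10) {
  n_occ <- study_days %/% occasion_days
  h <- integer(n_occ)
  h[1] <- 1L
  if (nrow(events) > 0) {
    t <- events$days_since_tag
    if (any(t < 0)) stop("negative days_since_tag in detection events")
    occ <- pmin(floor(t / occasion_days), n_occ - 1)
    h[occ + 1] <- 1L
  }
  h
}

# Vectorized scaled HMM forward pass over a matrix of capture histories
# (n x T). States: alive / dead; conditioned on release at occasion 1.
# Returns per-bird log-likelihood and the final-occasion posterior
# P(alive at T | history).
cjs_forward <- function(H, phi, p) {
  n <- nrow(H); T <- ncol(H)
  stopifnot(length(phi) == T - 1, length(p) == T - 1)
  if (any(phi < 0 | phi > 1 | p < 0 | p > 1))
    stop("phi and p must lie in [0, 1]")
  a_alive <- rep(1, n); a_dead <- rep(0, n)
  ll <- rep(0, n)
  for (t in 2:T) {
    y <- H[, t]
    al <- a_alive * phi[t - 1]
    de <- a_alive * (1 - phi[t - 1]) + a_dead
    e_alive <- ifelse(y == 1, p[t - 1], 1 - p[t - 1])
    al <- al * e_alive
    de <- de * (y == 0)
    c_t <- al + de
    bad <- c_t <= 0
    if (any(bad)) {              # impossible history under these parameters
      ll[bad] <- -Inf
      c_t[bad] <- 1; al[bad] <- 0; de[bad] <- 1
    }
    ll <- ll + log(c_t)
    a_alive <- al / c_t
    a_dead <- de / c_t
  }
  list(loglik = ll, p_alive_end = a_alive)
}

#' Cormack-Jolly-Seber log-likelihood of one capture history
#'
#' Standard CJS probability conditioned on first capture, computed as a
#' two-state (alive/dead) hidden-Markov forward pass: survival `phi[t]`
#' governs the transition from occasion t to t+1, detection `p[t]` applies
#' to occasion t+1 given alive, and the dead state is absorbing and silent.
#'
#' @param history 0/1 capture vector, first entry 1 (release).
#' @param phi per-interval apparent-survival probabilities, length
#'   `length(history) - 1`.
#' @param p per-occasion detection probabilities (occasions 2..T), same
#'   length as `phi`.
#' @return log-likelihood.
#' @export
cjs_likelihood <- function(history, phi, p) {
  stopifnot(length(history) >= 2, history[1] == 1)
  cjs_forward(matrix(history, nrow = 1), phi, p)$loglik
}

#' Fit a time-varying CJS model to capture histories
#'
#' Maximizes the summed CJS log-likelihood over bounded per-interval
#' survival and detection probabilities by L-BFGS-B from a flat 0.5 start.
#' `cohort` mode (default) fits one shared parameter set across birds;
#' `per_bird` mode fits each bird's history alone, in which case the
#' time-varying parameters are unidentifiable and routinely sit on the
#' bounds, driving the survival product to ~0 or ~1.
#'
#' In the final interval only the product of survival and detection is
#' identified (a standard CJS ridge), so cohort mode ties the terminal
#' `phi` and `p` to their penultimate values by default; `per_bird` mode
#' keeps the fully time-varying parameterization.
#'
#' @param histories list of capture vectors, or a 0/1 matrix with one row
#'   per bird.
#' @param mode `"cohort"` or `"per_bird"`.
#' @param bounds parameter box; probabilities are kept off 0/1 so the
#'   log-likelihood stays finite.
#' @param tie_terminal constrain the last interval's parameters to equal
#'   the second-to-last (cohort mode only).
#' @return object of class `cjs_fit`: `phi`, `p` (matrices in `per_bird`
#'   mode), `loglik`, `mode`, `convergence`.
#' @export
fit_cjs <- function(histories, mode = c("cohort", "per_bird"),
                    bounds = c(1e-6, 1 - 1e-6),
                    tie_terminal = (mode[1] == "cohort")) {
  mode <- match.arg(mode)
  H <- if (is.matrix(histories)) histories else do.call(rbind, histories)
  storage.mode(H) <- "integer"
  T <- ncol(H); m <- T - 1
  tie <- isTRUE(tie_terminal) && mode == "cohort" && m >= 2
  mf <- if (tie) m - 1 else m          # free parameters per block
  expand <- function(v) if (tie) c(v, v[mf]) else v
  fit_one <- function(Hsub) {
    obj <- function(par) {
      -sum(cjs_forward(Hsub, expand(par[1:mf]),
                       expand(par[(mf + 1):(2 * mf)]))$loglik)
    }
    opt <- stats::optim(rep(0.5, 2 * mf), obj, method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2],
                        control = list(maxit = 500))
    list(phi = expand(opt$par[1:mf]),
         p = expand(opt$par[(mf + 1):(2 * mf)]),
         loglik = -opt$value, convergence = opt$convergence)
  }
  if (mode == "cohort") {
    if (nrow(H) < 2) stop("cohort mode requires at least 2 histories")
    f <- fit_one(H)
    structure(list(phi = f$phi, p = f$p, loglik = f$loglik,
                   mode = mode, convergence = f$convergence,
                   histories = H), class = "cjs_fit")
  } else {
    fits <- lapply(seq_len(nrow(H)), function(i) fit_one(H[i, , drop = FALSE]))
    structure(list(phi = do.call(rbind, lapply(fits, `[[`, "phi")),
                   p = do.call(rbind, lapply(fits, `[[`, "p")),
                   loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                   mode = mode,
                   convergence = vapply(fits, `[[`, numeric(1), "convergence"),
                   histories = H), class = "cjs_fit")
  }
}

#' Binary survival labels from a fitted CJS model
#'
#' In `per_bird` mode the overall apparent-survival probability is the
#' product of that bird's estimated per-interval survival probabilities; in
#' `cohort` mode it is the posterior probability of being alive on the
#' final occasion given the bird's history under the shared parameter
#' estimates. Labels are 1 when the probability exceeds 0.5.
#'
#' @param fit a [fit_cjs()] result.
#' @param bird_ids optional identifiers, recycled onto the history rows.
#' @return data.frame: `bird_id`, `overall_survival_prob`, `label`.
#' @export
label_survival <- function(fit, bird_ids = NULL) {
  stopifnot(inherits(fit, "cjs_fit"))
  H <- fit$histories
  if (fit$mode == "per_bird") {
    prob <- apply(fit$phi, 1, prod)
  } else {
    prob <- cjs_forward(H, fit$phi, fit$p)$p_alive_end
  }
  if (is.null(bird_ids)) bird_ids <- sprintf("B%04d", seq_len(nrow(H)))
  data.frame(bird_id = bird_ids,
             overall_survival_prob = prob,
             label = as.integer(prob > 0.5))
}

#' Label a detection table end to end
#'
#' Bins each bird's detections into capture histories, fits the CJS model,
#' and returns per-bird survival labels.
#'
#' @param detections detection data.frame (`bird_id`, `days_since_tag`, ...).
#' @param mode passed to [fit_cjs()].
#' @inheritParams bin_detections
#' @return data.frame as in [label_survival()].
#' @export
label_detections <- function(detections, mode = "cohort",
                             study_days = 300, occasion_days = 10) {
  ids <- sort(unique(detections$bird_id))
  H <- t(vapply(ids, function(id) {
    bin_detections(detections[detections$bird_id == id, , drop = FALSE],
                   study_days, occasion_days)
  }, integer(study_days %/% occasion_days)))
  fit <- fit_cjs(H, mode = mode)
  label_survival(fit, bird_ids = ids)
}
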