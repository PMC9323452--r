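#' Simulate individual capture-breeding histories
#'
#' Generates a marked population with the exact structure the estimation
#' model assumes: sequential Bernoulli layers for survival, breeding and
#' success with logit links, a zero-truncated productivity family, shared
#' multivariate-normal year effects on the link scale, and Bernoulli
#' detection with its own independent year effect. A fixed number of
#' newly marked juveniles (age 0) enters every year and is detected with
#' certainty at marking.
#'
#' @param vr A [vital_rate_model()].
#' @param cov A [covariance_structure()]; its `param_order` must equal the
#'   active parameters of `vr$config`.
#' @param effects A [draw_temporal_effects()] result spanning `n_years`.
#' @param recruits_per_year New marked juveniles per year.
#' @param n_years Number of study years T.
#' @param seed Optional integer seed.
#' @return Tibble with one row per individual-year from marking onward:
#'   `individual_id`, `entry_year`, `year`, `age`, `detected` (0/1),
#'   `state` (observed state, `NA` when not detected), `count` (offspring
#'   of detected successful breeders, otherwise `NA`), plus truth columns
#'   `true_state` and `true_alive`.
#' @examples
#' cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
#' vr <- vital_rate_model(cfg, mu = c(phi = 1, pi = 0.5, p = 2))
#' cov <- covariance_structure(
#'   sigma = c(phi_j = 0.3, phi_ad = 0.3, pi = 0.3),
#'   corr = diag(3)
#' )
#' eff <- draw_temporal_effects(cov, 10, seed = 1)
#' sim <- simulate_population(vr, cov, eff, recruits_per_year = 20,
#'                            n_years = 10, seed = 2)
#' @export
simulate_population <- function(vr, cov, effects, recruits_per_year, n_years,
                                seed = NULL) {
  stopifnot(inherits(vr, "vc_vital_rates"), inherits(cov, "vc_covariance"),
    inherits(effects, "vc_effects"))
  config <- vr$config
  if (!identical(cov$param_order, config$active_params)) {
    stop("cov$param_order must match config$active_params", call. = FALSE)
  }
  if (nrow(effects$alpha) != n_years ||
    !identical(colnames(effects$alpha), cov$param_order)) {
    stop("effects do not span n_years x active parameters", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  alpha <- effects$alpha
  alpha_p <- effects$alpha_p
  ab <- config$age_breaks
  f <- vr$age_effects
  g <- vr$bs_effects
  fam <- config$productivity_family
  type <- config$correlation_type
  psi_active <- "psi" %in% config$active_params
  pi_active <- "pi" %in% config$active_params
  bfa <- config$breeding_from_age

  n_total <- recruits_per_year * n_years
  id <- seq_len(n_total)
  entry <- rep(seq_len(n_years), each = recruits_per_year)
  state <- rep("juvenile", n_total) # latent state at the current year
  alive <- rep(TRUE, n_total)
  ever_bred <- rep(FALSE, n_total)

  # per-year record accumulators
  rec <- vector("list", n_years)
  rec[[1]] <- NULL
  store <- function(t, idx, det, cnt) {
    latent <- state[idx]
    tibble::tibble(
      individual_id = id[idx], entry_year = entry[idx], year = t,
      age = t - entry[idx], detected = det,
      state = ifelse(det == 1L, latent, NA_character_),
      count = ifelse(det == 1L, cnt, NA_integer_),
      true_state = latent, true_alive = alive[idx]
    )
  }

  # marking occasion: all recruits of year t detected with certainty
  for (t in seq_len(n_years)) {
    idx <- which(entry == t)
    rec[[t]] <- list(store(t, idx, rep(1L, length(idx)), rep(NA_integer_, length(idx))))
  }

  for (t in seq_len(n_years - 1L)) {
    at_risk <- which(entry <= t & alive)
    if (length(at_risk)) {
      tn <- t + 1L
      a1 <- tn - entry[at_risk] # age reached at the end of the interval
      srow <- survival_alpha_row(tn, type)
      juv <- a1 == 1L
      eta_phi <- rep(vr$mu$phi, length(at_risk))
      eta_phi[juv] <- eta_phi[juv] + alpha[srow, "phi_j"]
      if (any(!juv)) {
        ad <- !juv
        eta_phi[ad] <- eta_phi[ad] +
          f$phi[age_class_of(a1[ad], ab$phi)] +
          g$phi[state[at_risk[ad]]] +
          alpha[srow, "phi_ad"]
      }
      surv <- rbinom(length(at_risk), 1L, plogis(eta_phi)) == 1L

      dead_now <- at_risk[!surv]
      alive[dead_now] <- FALSE
      state[dead_now] <- "dead"

      liv <- at_risk[surv]
      a1l <- tn - entry[liv]
      cnt <- rep(NA_integer_, length(liv))
      if (length(liv)) {
        prev <- state[liv]
        can_breed <- a1l >= bfa
        breed <- rep(FALSE, length(liv))
        if (any(can_breed)) {
          if (psi_active) {
            eta_psi <- vr$mu$psi + f$psi[age_class_of(a1l[can_breed], ab$psi)] +
              g$psi[prev[can_breed]] + alpha[tn, "psi"]
            breed[can_breed] <- rbinom(sum(can_breed), 1L, plogis(eta_psi)) == 1L
          } else {
            breed[can_breed] <- TRUE
          }
        }
        success <- rep(FALSE, length(liv))
        if (any(breed)) {
          if (pi_active) {
            eta_pi <- vr$mu$pi + f$pi[age_class_of(a1l[breed], ab$pi)] +
              g$pi[prev[breed]] + alpha[tn, "pi"]
            success[breed] <- rbinom(sum(breed), 1L, plogis(eta_pi)) == 1L
          } else {
            success[breed] <- TRUE
          }
        }
        new_state <- character(length(liv))
        not_breeding <- !breed
        if (config$pre_breeder) {
          to_pre <- not_breeding & !ever_bred[liv]
          new_state[to_pre] <- "pre_breeder"
          new_state[not_breeding & ever_bred[liv]] <- "non_breeder"
        } else {
          new_state[not_breeding] <- "non_breeder"
        }
        new_state[breed & !success] <- "failed_breeder"
        new_state[success] <- "successful_breeder"
        if (any(success)) {
          eta_om <- if ("omega" %in% config$active_params) {
            vr$mu$omega + f$omega[age_class_of(a1l[success], ab$omega)] +
              alpha[tn, "omega"]
          } else {
            rep(0, sum(success))
          }
          cnt[success] <- productivity_draw(eta_om, fam, vr$sigma_omega_resid)
        }
        ever_bred[liv] <- ever_bred[liv] | breed
        state[liv] <- new_state

        eta_p <- vr$mu$p + f$p[age_class_of(a1l, ab$p)] + g$p[new_state] +
          alpha_p[tn]
        det <- rbinom(length(liv), 1L, plogis(eta_p))
        rec[[tn]] <- c(rec[[tn]], list(store(tn, liv, det, cnt)))
      }
      prev_dead <- which(entry <= t & !alive)
      if (length(prev_dead)) {
        rec[[tn]] <- c(
          rec[[tn]],
          list(store(tn, prev_dead, rep(0L, length(prev_dead)),
            rep(NA_integer_, length(prev_dead))))
        )
      }
    }
  }

  out <- dplyr::bind_rows(purrr::flatten(rec))
  dplyr::arrange(out, .data$individual_id, .data$year)
}

#' Simulate a complete study (effects + population)
#'
#' Convenience wrapper drawing the year effects and the population from a
#' single seed.
#'
#' @inheritParams simulate_population
#' @param seed Integer seed for both the year effects and the histories.
#' @return List with `data` (the capture-history tibble), `effects`, `vr`
#'   and `cov`.
#' @export
simulate_study <- function(vr, cov, recruits_per_year, n_years, seed = 1) {
  effects <- draw_temporal_effects(cov, n_years, seed = seed)
  data <- simulate_population(vr, cov, effects, recruits_per_year, n_years,
    seed = NULL
  )
  list(data = data, effects = effects, vr = vr, cov = cov)
}
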