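# Deterministic probability machinery: annual rate assembly, latent-state
# transition and observation models, and the per-individual forward
# (hidden Markov) log-likelihood marginalising unobserved alive/breeding
# states under imperfect detection. This R implementation is the
# reference; the MCMC sampler uses an equivalent compiled path.

#' Assemble annual demographic rates
#'
#' Evaluates the linear predictors `mu + f(age) + gamma * BS + alpha_t` of
#' each demographic parameter for one individual-year and maps them
#' through their inverse links. Survival into year `year` reads the
#' year-effect row dictated by the correlation type
#' ([apply_correlation_type()]); reproduction and detection at `year`
#' read row `year`. Inactive rates are returned as their fixed constants
#' (reproductive probability and success 1; productivity a single
#' offspring).
#'
#' @param vr A [vital_rate_model()].
#' @param effects A [draw_temporal_effects()] result (or any `vc_effects`).
#' @param year Year t (reproduction season).
#' @param age Age in years reached at year t (1 = first year).
#' @param prev_bs Latent state in year t-1 (previous breeding state);
#'   `"juvenile"` is the reference level used for first possible
#'   transitions.
#' @return List with `phi`, `psi`, `pi`, `omega_eta` (productivity
#'   location on its link scale), `omega_mean` (expected count), and `p`
#'   (named vector of detection probabilities by current state).
#' @examples
#' cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
#' vr <- vital_rate_model(cfg, mu = c(phi = 0, pi = 0, p = 0))
#' cov <- covariance_structure(sigma = c(phi_j = 0, phi_ad = 0, pi = 0))
#' eff <- draw_temporal_effects(cov, 5, seed = 1)
#' annual_rates(vr, eff, year = 2, age = 2, prev_bs = "successful_breeder")
#' @export
annual_rates <- function(vr, effects, year, age, prev_bs = "juvenile") {
  config <- vr$config
  alpha <- effects$alpha
  active <- config$active_params
  if (!all(colnames(alpha) %in% active) || !all(active %in% colnames(alpha))) {
    stop("effects columns do not match the active parameters", call. = FALSE)
  }
  ls <- live_states(config)
  if (!prev_bs %in% ls) stop("unknown previous state: ", prev_bs, call. = FALSE)
  ab <- config$age_breaks
  f <- vr$age_effects
  g <- vr$bs_effects
  srow <- survival_alpha_row(year, config$correlation_type)
  a_surv <- if (is.na(srow) || srow < 1 || srow > nrow(alpha)) {
    NA_real_
  } else if (age == 1) {
    alpha[srow, "phi_j"]
  } else {
    alpha[srow, "phi_ad"]
  }
  phi <- plogis(vr$mu$phi + f$phi[age_class_of(age, ab$phi)] +
    g$phi[[prev_bs]] + a_surv)
  psi <- if ("psi" %in% active) {
    plogis(vr$mu$psi + f$psi[age_class_of(age, ab$psi)] +
      g$psi[[prev_bs]] + alpha[year, "psi"])
  } else {
    1
  }
  if (age < config$breeding_from_age) psi <- 0
  pi_ <- if ("pi" %in% active) {
    plogis(vr$mu$pi + f$pi[age_class_of(age, ab$pi)] +
      g$pi[[prev_bs]] + alpha[year, "pi"])
  } else {
    1
  }
  if ("omega" %in% active) {
    omega_eta <- vr$mu$omega + f$omega[age_class_of(age, ab$omega)] +
      alpha[year, "omega"]
    omega_mean <- switch(config$productivity_family,
      bernoulli_extra_offspring = 1 + plogis(omega_eta),
      truncated_normal = omega_eta, # location; truncation shifts the mean upward
      truncated_poisson = ztpois_mean(exp(omega_eta))
    )
  } else {
    omega_eta <- NA_real_
    omega_mean <- 1
  }
  p <- plogis(vr$mu$p + f$p[age_class_of(age, ab$p)] + g$p[ls] +
    effects$alpha_p[year])
  names(p) <- ls
  list(
    phi = unname(phi), psi = unname(psi), pi = unname(pi_),
    omega_eta = unname(omega_eta), omega_mean = unname(omega_mean), p = p
  )
}

#' Latent-state transition matrix
#'
#' Composes the sequential Bernoulli layers (survive, breed, succeed)
#' into one stochastic matrix over the latent states. From any live state
#' the destination masses are `1 - phi` (dead), `phi * (1 - psi)`
#' (non-breeder, or pre-breeder for individuals that have never bred when
#' a pre-breeder state exists), `phi * psi * (1 - pi)` (failed) and
#' `phi * psi * pi` (successful); dead is absorbing.
#'
#' @param rates List with elements `phi`, `psi`, `pi`; each either a
#'   scalar or a named vector keyed by from-state.
#' @param states Character vector of latent states ending in `"dead"`
#'   (e.g. `c(live_states(config), "dead")`).
#' @return Row-stochastic matrix with `dimnames` `states` x `states`.
#' @examples
#' transition_matrix(
#'   list(phi = 0.8, psi = 0.5, pi = 0.5),
#'   c("juvenile", "non_breeder", "failed_breeder", "successful_breeder", "dead")
#' )
#' @export
transition_matrix <- function(rates, states) {
  stopifnot(states[length(states)] == "dead")
  live <- states[-length(states)]
  n <- length(states)
  m <- matrix(0, n, n, dimnames = list(states, states))
  get_rate <- function(r, s) {
    if (length(r) > 1) unname(r[[s]]) else unname(r)
  }
  for (s in live) {
    phi <- get_rate(rates$phi, s)
    psi <- get_rate(rates$psi %||% 1, s)
    pi_ <- get_rate(rates$pi %||% 1, s)
    m[s, "dead"] <- 1 - phi
    nb_dest <- if (s %in% c("juvenile", "pre_breeder") && "pre_breeder" %in% live) {
      "pre_breeder"
    } else {
      "non_breeder"
    }
    masses <- c(phi * (1 - psi), phi * psi * (1 - pi_), phi * psi * pi_)
    dests <- c(nb_dest, "failed_breeder", "successful_breeder")
    for (j in seq_along(dests)) {
      if (masses[j] == 0) next
      if (!dests[j] %in% states) {
        stop("transition mass to absent state '", dests[j],
          "' (inactive parameter referenced)",
          call. = FALSE
        )
      }
      m[s, dests[j]] <- m[s, dests[j]] + masses[j]
    }
  }
  m["dead", "dead"] <- 1
  m
}

#' Observation probability of one individual-year record
#'
#' Detected individuals have their state (and any offspring count)
#' recorded without error: a detection in a state matching the latent
#' state contributes `p` times the productivity mass/density of a
#' recorded count; a mismatching state contributes 0. Non-detection
#' contributes `1 - p` for live states and 1 for dead.
#'
#' @param rates An [annual_rates()] bundle (with `p` by state and the
#'   productivity location).
#' @param latent_state Latent state at the record's year.
#' @param record List or one-row data frame with `detected`, `state`,
#'   `count`.
#' @param family Productivity family (from the model config).
#' @param sigma_resid Residual SD for the truncated-normal family.
#' @return A probability (density when a continuous count is involved).
#' @export
observation_probs <- function(rates, latent_state, record,
                              family = "fixed_one", sigma_resid = NULL) {
  det <- record$detected == 1
  if (latent_state == "dead") {
    return(if (det) 0 else 1)
  }
  p <- unname(rates$p[[latent_state]])
  if (!det) {
    return(1 - p)
  }
  if (is.na(record$state) || record$state != latent_state) {
    return(0)
  }
  out <- p
  has_count <- !is.null(record$count) && !is.na(record$count)
  if (has_count) {
    if (latent_state != "successful_breeder") {
      stop("offspring count recorded for a non-successful observed state",
        call. = FALSE
      )
    }
    eta <- if (family == "fixed_one") 0 else rates$omega_eta
    out <- out * exp(productivity_logdens(record$count, eta, family, sigma_resid))
  }
  out
}

#' Forward log-likelihood of one capture history
#'
#' Marginalises all latent alive/breeding-state paths consistent with the
#' observed detections by the forward recursion of the hidden Markov
#' model, conditioning on the first capture (the individual's state at
#' marking is taken as known).
#'
#' @param history Tibble of one individual's records (columns `year`,
#'   `detected`, `state`, `count`; optionally `age` and `entry_year`).
#' @param vr A [vital_rate_model()].
#' @param effects Year effects spanning the study years.
#' @param n_years Last study year (defaults to the effects' span).
#' @return Log-likelihood (a single number, <= 0).
#' @export
forward_loglik <- function(history, vr, effects, n_years = length(effects$years)) {
  config <- vr$config
  det_rows <- history[history$detected == 1, , drop = FALSE]
  if (nrow(det_rows) == 0) stop("history has no first capture", call. = FALSE)
  entry <- min(det_rows$year)
  if (min(history$year) < entry) {
    stop("observation before entry year", call. = FALSE)
  }
  entry_state <- det_rows$state[det_rows$year == entry]
  entry_age <- if ("age" %in% names(history)) {
    history$age[history$year == entry][1]
  } else {
    0L
  }
  states <- c(live_states(config), "dead")
  fam <- config$productivity_family
  dist <- setNames(numeric(length(states)), states)
  dist[entry_state] <- 1
  ll <- 0
  det_by_year <- det_rows[det_rows$year > entry, , drop = FALSE]
  for (y in seq(entry + 1L, length.out = max(0L, n_years - entry))) {
    a1 <- entry_age + (y - entry)
    live <- states[-length(states)]
    per_state <- lapply(live, function(s) annual_rates(vr, effects, y, a1, s))
    names(per_state) <- live
    rates_vec <- list(
      phi = vapply(per_state, `[[`, numeric(1), "phi"),
      psi = vapply(per_state, `[[`, numeric(1), "psi"),
      pi = vapply(per_state, `[[`, numeric(1), "pi")
    )
    tm <- transition_matrix(rates_vec, states)
    dist <- drop(dist %*% tm)
    rec_row <- det_by_year[det_by_year$year == y, , drop = FALSE]
    record <- if (nrow(rec_row)) {
      list(detected = 1, state = rec_row$state[1], count = rec_row$count[1])
    } else {
      list(detected = 0, state = NA_character_, count = NA)
    }
    obs_rates <- per_state[[1]] # p and omega location do not depend on prev state
    w <- vapply(states, function(s) {
      dist[[s]] * observation_probs(obs_rates, s, record, fam, vr$sigma_omega_resid)
    }, numeric(1))
    cc <- sum(w)
    if (cc <= 0) {
      return(-Inf)
    }
    ll <- ll + log(cc)
    dist <- w / cc
  }
  ll
}

#' Dataset log-likelihood
#'
#' Sum of per-individual forward log-likelihoods; invariant to the
#' ordering of individuals.
#'
#' @param data Capture-history tibble (observed columns).
#' @param vr A [vital_rate_model()].
#' @param effects Year effects.
#' @param method `"cpp"` (compiled engine) or `"r"` (reference
#'   recursion); the two agree to numerical precision.
#' @param n_years Last study year (defaults to the effects' span).
#' @return List of class `vc_loglik` with `total` and `per_individual`
#'   (tibble `individual_id`, `loglik`).
#' @export
dataset_loglik <- function(data, vr, effects, method = c("cpp", "r"),
                           n_years = length(effects$years)) {
  method <- match.arg(method)
  if (method == "r") {
    ids <- unique(data$individual_id)
    ll <- vapply(ids, function(i) {
      forward_loglik(data[data$individual_id == i, , drop = FALSE], vr, effects,
        n_years = n_years
      )
    }, numeric(1))
    per <- tibble::tibble(individual_id = ids, loglik = ll)
  } else {
    engine <- build_engine(vr$config, n_years)
    packed <- pack_data(data, vr$config, n_years)
    theta <- build_theta(vr, effects, engine)
    res <- cpp_dataset_loglik(engine, packed, theta)
    per <- tibble::tibble(
      individual_id = packed$ids,
      loglik = as.numeric(res$per_individual)
    )
  }
  structure(list(total = sum(per$loglik), per_individual = per),
    class = "vc_loglik"
  )
}

#' @export
print.vc_loglik <- function(x, ...) {
  cat("<vc_loglik> total:", format(x$total), "over", nrow(x$per_individual),
    "individuals\n")
  invisible(x)
}
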