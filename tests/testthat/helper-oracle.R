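# Brute-force likelihood oracle: enumerates every latent state path
# consistent with the observations and sums path probabilities directly.
# Independent of the forward recursion it is used to check.

enum_loglik <- function(history, vr, effects, n_years = length(effects$years)) {
  config <- vr$config
  states <- c(live_states(config), "dead")
  det_rows <- history[history$detected == 1, , drop = FALSE]
  entry <- min(det_rows$year)
  entry_state <- det_rows$state[det_rows$year == entry][1]
  entry_age <- if ("age" %in% names(history)) {
    history$age[history$year == entry][1]
  } else {
    0L
  }
  years <- seq(entry + 1L, length.out = max(0L, n_years - entry))
  if (length(years) == 0) {
    return(0)
  }
  paths <- expand.grid(rep(list(states), length(years)),
    stringsAsFactors = FALSE
  )
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.character(paths[r, ])
    prob <- 1
    prev <- entry_state
    for (j in seq_along(years)) {
      y <- years[j]
      a1 <- entry_age + (y - entry)
      cur <- path[j]
      if (prev == "dead") {
        prob <- prob * (cur == "dead")
      } else {
        rates <- annual_rates(vr, effects, y, a1, prev)
        tm <- transition_matrix(
          list(phi = rates$phi, psi = rates$psi, pi = rates$pi), states
        )
        prob <- prob * tm[prev, cur]
      }
      if (prob == 0) break
      rec_row <- det_rows[det_rows$year == y, , drop = FALSE]
      record <- if (nrow(rec_row)) {
        list(detected = 1, state = rec_row$state[1], count = rec_row$count[1])
      } else {
        list(detected = 0, state = NA_character_, count = NA)
      }
      obs_rates <- annual_rates(vr, effects, y, a1,
        if (prev == "dead") states[1] else prev
      )
      prob <- prob * observation_probs(
        obs_rates, cur, record,
        config$productivity_family, vr$sigma_omega_resid
      )
      if (prob == 0) break
      prev <- cur
    }
    total <- total + prob
  }
  log(total)
}

# random small model + matching simulated histories for oracle comparisons
random_instance <- function(seed, n_years = 4) {
  set.seed(seed)
  variant <- sample(3, 1)
  if (variant == 1) {
    cfg <- model_config(
      active_params = c("phi_j", "phi_ad"),
      correlation_type = sample(2, 1)
    )
    mu <- c(phi = rnorm(1, 0.5, 0.5), p = rnorm(1, 1, 0.5))
  } else if (variant == 2) {
    cfg <- model_config(
      active_params = c("phi_j", "phi_ad", "pi"),
      correlation_type = sample(2, 1),
      bs_effects_on = "phi"
    )
    mu <- c(phi = rnorm(1, 0.5, 0.5), pi = rnorm(1, 0, 0.5), p = rnorm(1, 1, 0.5))
  } else {
    cfg <- model_config(
      active_params = c("phi_j", "phi_ad", "psi", "pi"),
      correlation_type = sample(2, 1)
    )
    mu <- c(
      phi = rnorm(1, 0.5, 0.5), psi = rnorm(1, 0.5, 0.5),
      pi = rnorm(1, 0, 0.5), p = rnorm(1, 1, 0.5)
    )
  }
  bs <- if (identical(cfg$bs_effects_on, "phi")) {
    list(phi = c(failed_breeder = rnorm(1, 0, 0.3)))
  } else {
    NULL
  }
  vr <- vital_rate_model(cfg,
    mu = mu,
    age_effects = list(phi = c(0, rnorm(1, 0.3, 0.2))),
    bs_effects = bs
  )
  k <- length(cfg$active_params)
  sig <- setNames(runif(k, 0.1, 0.5), cfg$active_params)
  cov <- covariance_structure(sigma = sig, sigma_p = runif(1, 0, 0.3))
  eff <- draw_temporal_effects(cov, n_years)
  sim <- simulate_population(vr, cov, eff,
    recruits_per_year = 3,
    n_years = n_years
  )
  list(cfg = cfg, vr = vr, cov = cov, eff = eff, sim = sim)
}
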