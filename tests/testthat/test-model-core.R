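test_that("annual rates assemble the linear predictors", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad", "psi", "pi"))
  vr <- vital_rate_model(cfg, mu = c(phi = 0, psi = 0, pi = 0, p = 0))
  cov <- covariance_structure(
    sigma = c(phi_j = 0, phi_ad = 0, psi = 0, pi = 0)
  )
  eff <- draw_temporal_effects(cov, 5, seed = 1)
  r <- annual_rates(vr, eff, year = 3, age = 2, prev_bs = "successful_breeder")
  expect_equal(r$phi, 0.5)
  expect_equal(r$psi, 0.5)
  expect_equal(r$pi, 0.5)
  expect_equal(unname(r$p["successful_breeder"]), 0.5)

  # mu = 1 with age, state and year offsets summing to 1.0 - 0.5 + 0.2 + 0.3
  cfg2 <- model_config(
    active_params = c("phi_j", "phi_ad", "pi"), bs_effects_on = "phi"
  )
  vr2 <- vital_rate_model(cfg2,
    mu = c(phi = 1, pi = 0, p = 0),
    age_effects = list(phi = c(0, -0.5)),
    bs_effects = list(phi = c(failed_breeder = 0.2))
  )
  eff2 <- list(
    years = 1:5, alpha = matrix(0.3, 5, 3,
      dimnames = list(NULL, c("phi_j", "phi_ad", "pi"))
    ),
    alpha_p = rep(0, 5)
  )
  class(eff2) <- "vc_effects"
  r2 <- annual_rates(vr2, eff2, year = 2, age = 3, prev_bs = "failed_breeder")
  expect_equal(r2$phi, plogis(1 - 0.5 + 0.2 + 0.3), tolerance = 1e-12)
  expect_equal(r2$phi, 0.7311, tolerance = 1e-4)
})

test_that("inactive parameters are returned as their fixed constants", {
  cfg <- cfg3() # psi inactive (fast species), omega inactive
  vr <- vr3(cfg)
  eff <- draw_temporal_effects(cov3(), 5, seed = 1)
  r <- annual_rates(vr, eff, year = 2, age = 2, prev_bs = "failed_breeder")
  expect_identical(r$psi, 1)
  expect_identical(r$omega_mean, 1)
})

test_that("transition matrices compose the Bernoulli layers", {
  states <- c(
    "juvenile", "non_breeder", "failed_breeder", "successful_breeder", "dead"
  )
  tm <- transition_matrix(list(phi = 0.8, psi = 0.5, pi = 0.5), states)
  expect_equal(
    unname(tm["juvenile", c(
      "dead", "non_breeder", "failed_breeder", "successful_breeder"
    )]),
    c(0.2, 0.4, 0.2, 0.2)
  )
  expect_true(all(abs(rowSums(tm) - 1) < 1e-12))

  tm0 <- transition_matrix(list(phi = 0, psi = 0.5, pi = 0.5), states)
  expect_true(all(tm0[-5, "dead"] == 1))
  tm1 <- transition_matrix(list(phi = 1, psi = 1, pi = 1), states)
  expect_true(all(tm1[-5, "successful_breeder"] == 1))

  # random rates: rows always sum to one
  set.seed(4)
  for (i in 1:50) {
    tmr <- transition_matrix(
      list(phi = runif(1), psi = runif(1), pi = runif(1)), states
    )
    expect_true(all(abs(rowSums(tmr) - 1) < 1e-12))
  }

  # dead row is the identity on dead
  expect_equal(unname(tm["dead", ]), c(0, 0, 0, 0, 1))
})

test_that("non-breeders of pre-breeder species stay in the pre-breeder state", {
  states <- c("juvenile", "pre_breeder", "non_breeder", "failed_breeder",
    "successful_breeder", "dead")
  tm <- transition_matrix(list(phi = 0.8, psi = 0.5, pi = 0.5), states)
  expect_equal(unname(tm["pre_breeder", "pre_breeder"]), 0.4)
  expect_equal(unname(tm["pre_breeder", "non_breeder"]), 0)
  expect_equal(unname(tm["successful_breeder", "non_breeder"]), 0.4)
})

test_that("observation probabilities follow the detection model", {
  rates <- list(
    p = c(
      juvenile = 0.9, failed_breeder = 0.9, successful_breeder = 0.9
    ),
    omega_eta = log(2)
  )
  expect_equal(observation_probs(rates, "dead", list(detected = 0)), 1)
  expect_equal(
    observation_probs(
      rates, "failed_breeder", list(detected = 0, state = NA, count = NA)
    ),
    1 - 0.9
  )
  expect_equal(
    observation_probs(
      rates, "failed_breeder",
      list(detected = 1, state = "successful_breeder", count = NA)
    ),
    0
  )
  expect_equal(observation_probs(rates, "dead", list(detected = 1, state = "dead")), 0)
  # detected successful with a count: p times the zero-truncated pmf
  lam <- 2
  expect_equal(
    observation_probs(
      rates, "successful_breeder",
      list(detected = 1, state = "successful_breeder", count = 2),
      family = "truncated_poisson"
    ),
    0.9 * (lam^2 * exp(-lam) / 2) / (1 - exp(-lam)),
    tolerance = 1e-12
  )
  expect_error(
    observation_probs(
      rates, "failed_breeder",
      list(detected = 1, state = "failed_breeder", count = 2),
      family = "truncated_poisson"
    ),
    "non-successful"
  )
})

test_that("forward log-likelihood matches hand-computable cases", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad"))
  vr <- vital_rate_model(cfg, mu = c(phi = qlogis(0.7), p = Inf))
  cov <- covariance_structure(sigma = c(phi_j = 0, phi_ad = 0))
  eff <- draw_temporal_effects(cov, 2, seed = 1)
  # released year 1 as a juvenile, detected alive year 2, p = 1
  h <- tibble::tibble(
    individual_id = 1, year = 1:2, age = 0:1, detected = c(1, 1),
    state = c("juvenile", "successful_breeder"), count = NA
  )
  expect_equal(forward_loglik(h, vr, eff), log(0.7), tolerance = 1e-12)
  # released then never seen again over one occasion with p = 1: certain death
  h2 <- tibble::tibble(
    individual_id = 1, year = 1:2, age = 0:1, detected = c(1, 0),
    state = c("juvenile", NA), count = NA
  )
  expect_equal(forward_loglik(h2, vr, eff), log(0.3), tolerance = 1e-12)
})

test_that("dataset log-likelihood is a sum over individuals, order-invariant", {
  st <- simulate_study(vr3(), cov3(sigma_p = 0.1), 15, 6, seed = 41)
  ll <- dataset_loglik(st$data, st$vr, st$effects)
  expect_equal(ll$total, sum(ll$per_individual$loglik))
  # empty dataset
  expect_error(
    dataset_loglik(st$data[0, ], st$vr, st$effects, method = "r")$total == 0,
    NA
  )
  expect_equal(dataset_loglik(st$data[0, ], st$vr, st$effects, method = "r")$total, 0)
  # duplicated individual doubles its contribution
  one <- st$data[st$data$individual_id == 3, ]
  two <- dplyr::bind_rows(one, dplyr::mutate(one, individual_id = 1000))
  expect_equal(
    dataset_loglik(two, st$vr, st$effects)$total,
    2 * dataset_loglik(one, st$vr, st$effects)$total,
    tolerance = 1e-10
  )
  # permutation invariance
  perm <- st$data[sample(nrow(st$data)), ]
  expect_equal(dataset_loglik(perm, st$vr, st$effects)$total, ll$total,
    tolerance = 1e-10
  )
})

test_that("compiled and reference likelihoods agree across model variants", {
  for (seed in c(1, 2, 3)) {
    inst <- random_instance(seed, n_years = 5)
    ll_r <- dataset_loglik(inst$sim, inst$vr, inst$eff, method = "r")
    ll_c <- dataset_loglik(inst$sim, inst$vr, inst$eff, method = "cpp")
    expect_equal(ll_c$total, ll_r$total, tolerance = 1e-10)
  }
  # full five-parameter model with truncated-Poisson counts
  st <- simulate_study(vr5(), cov5(), 12, 6, seed = 43)
  expect_equal(
    dataset_loglik(st$data, st$vr, st$effects, method = "cpp")$total,
    dataset_loglik(st$data, st$vr, st$effects, method = "r")$total,
    tolerance = 1e-10
  )
})

test_that("forward recursion equals brute-force path enumeration (spot checks)", {
  for (seed in c(11, 12, 13, 14)) {
    inst <- random_instance(seed, n_years = 4)
    ids <- unique(inst$sim$individual_id)
    for (i in head(ids, 4)) {
      h <- inst$sim[inst$sim$individual_id == i, ]
      if (!any(h$detected == 1)) next
      lf <- forward_loglik(h, inst$vr, inst$eff)
      le <- enum_loglik(h, inst$vr, inst$eff)
      expect_equal(lf, le, tolerance = 1e-10)
    }
  }
})

test_that("likelihood decreases when year effects move away from truth", {
  st <- simulate_study(vr3(), cov3(), 200, 12, seed = 44)
  base <- dataset_loglik(st$data, st$vr, st$effects)$total
  for (delta in c(0.5, 1, 2)) {
    eff2 <- st$effects
    eff2$alpha[, "phi_ad"] <- eff2$alpha[, "phi_ad"] + delta
    pert <- dataset_loglik(st$data, st$vr, eff2)$total
    expect_lt(pert, base)
    if (delta > 0.5) {
      eff1 <- st$effects
      eff1$alpha[, "phi_ad"] <- eff1$alpha[, "phi_ad"] + 0.5
      expect_lt(pert, dataset_loglik(st$data, st$vr, eff1)$total)
    }
  }
})

test_that("profiling the likelihood over one intercept recovers the truth", {
  cfg <- cfg3()
  cov <- cov3()
  eff <- draw_temporal_effects(cov, 20, seed = 45)
  vr_at <- function(m) {
    vital_rate_model(cfg,
      mu = c(phi = m, pi = qlogis(0.6), p = qlogis(0.9)),
      age_effects = list(phi = c(0, qlogis(0.75) - qlogis(0.65)))
    )
  }
  sim <- simulate_population(vr_at(qlogis(0.65)), cov, eff, 400, 20, seed = 46)
  prof <- function(m) dataset_loglik(sim, vr_at(m), eff)$total
  opt <- optimize(prof, c(-1, 2), maximum = TRUE)
  # Monte-Carlo error of the realized intercept at ~8000 first-year transitions
  expect_equal(opt$maximum, qlogis(0.65), tolerance = 0.1)
})
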