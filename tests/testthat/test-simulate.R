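test_that("degenerate rates give an always-alive, always-detected population", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
  vr <- vital_rate_model(cfg, mu = c(phi = Inf, pi = Inf, p = Inf))
  cov <- covariance_structure(
    sigma = c(phi_j = 0, phi_ad = 0, pi = 0)
  )
  eff <- draw_temporal_effects(cov, 6, seed = 1)
  sim <- simulate_population(vr, cov, eff, 10, 6, seed = 2)
  expect_true(all(sim$true_alive))
  expect_true(all(sim$detected == 1))
  post_entry <- sim[sim$year > sim$entry_year, ]
  expect_true(all(post_entry$true_state == "successful_breeder"))
})

test_that("realized survival matches the inverse-link rate (binomial check)", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad"))
  vr <- vital_rate_model(cfg, mu = c(phi = qlogis(0.8), p = Inf))
  cov <- covariance_structure(sigma = c(phi_j = 0, phi_ad = 0))
  eff <- draw_temporal_effects(cov, 25, seed = 1)
  sim <- simulate_population(vr, cov, eff, 5000, 25, seed = 3)
  # adult transitions: alive at age >= 1, outcome at the next year
  d <- as.data.frame(sim)
  d <- d[order(d$individual_id, d$year), ]
  alive_now <- d$true_alive & d$age >= 1 & d$year < 25
  nxt <- d$true_alive[match(
    paste(d$individual_id, d$year + 1),
    paste(d$individual_id, d$year)
  )]
  surv <- nxt[alive_now]
  expect_gt(length(surv), 100000)
  expect_true(mean(surv) > 0.796 && mean(surv) < 0.804)
})

test_that("truncated-Poisson productivity is positive with the right mean", {
  cfg <- model_config(
    active_params = c("phi_j", "phi_ad", "pi", "omega"),
    productivity_family = "truncated_poisson"
  )
  vr <- vital_rate_model(cfg, mu = c(
    phi = qlogis(0.9), pi = Inf, omega = log(2), p = Inf
  ))
  cov <- covariance_structure(
    sigma = c(phi_j = 0, phi_ad = 0, pi = 0, omega = 0)
  )
  eff <- draw_temporal_effects(cov, 12, seed = 1)
  sim <- simulate_population(vr, cov, eff, 800, 12, seed = 4)
  cnt <- sim$count[!is.na(sim$count)]
  expect_gt(length(cnt), 2000)
  expect_true(all(cnt >= 1))
  expect_equal(mean(cnt), 2 / (1 - exp(-2)), tolerance = 0.02)
})

test_that("death is absorbing and detection implies being alive", {
  st <- simulate_study(vr3(), cov3(sigma_p = 0.2), 50, 15, seed = 5)
  d <- dplyr::arrange(st$data, individual_id, year)
  dead_then <- d |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(
      ok = all(cummax(true_state == "dead") <= (true_state == "dead"))
    )
  expect_true(all(dead_then$ok))
  expect_true(all(d$true_alive[d$detected == 1]))
  expect_true(all(is.na(d$count) |
    (d$state == "successful_breeder" & d$detected == 1)))
})

test_that("realized conditional frequencies track mu + f + alpha_t", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
  vr <- vr3(cfg)
  cov <- cov3(sigma = 0.4)
  eff <- draw_temporal_effects(cov, 10, seed = 11)
  sim <- simulate_population(vr, cov, eff, 4000, 10, seed = 12)
  d <- as.data.frame(sim)
  nxt_state <- d$true_state[match(
    paste(d$individual_id, d$year + 1),
    paste(d$individual_id, d$year)
  )]
  # juvenile survival year by year against plogis(mu + alpha_t(row per type))
  for (t in c(3, 7)) {
    at_risk <- d$true_alive & d$age == 0 & d$year == t - 1
    p_hat <- mean(nxt_state[at_risk] != "dead")
    p_exp <- unname(plogis(qlogis(0.65) + eff$alpha[t, "phi_j"]))
    expect_equal(p_hat, p_exp, tolerance = 4 / sqrt(sum(at_risk)))
  }
  # success frequency among survivors at year t
  for (t in c(4, 8)) {
    trans <- d$true_alive & d$age >= 1 & d$year == t - 1 &
      !is.na(nxt_state) & nxt_state != "dead"
    p_hat <- mean(nxt_state[trans] == "successful_breeder")
    p_exp <- unname(plogis(qlogis(0.6) + eff$alpha[t, "pi"]))
    expect_equal(p_hat, p_exp, tolerance = 4 / sqrt(sum(trans)))
  }
})

test_that("strong positive coupling shows up in realized annual frequencies", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
  vr <- vr3(cfg)
  cov <- cov3(r_j_ad = 0.9, r_ad_pi = 0.9, r_j_pi = 0.81, sigma = 0.8)
  st <- simulate_study(vr, cov, 300, 30, seed = 21)
  d <- as.data.frame(st$data)
  nxt_state <- d$true_state[match(
    paste(d$individual_id, d$year + 1),
    paste(d$individual_id, d$year)
  )]
  ad <- d$true_alive & d$age >= 1 & d$year < 30 & !is.na(nxt_state)
  surv_freq <- tapply(nxt_state[ad] != "dead", d$year[ad] + 1, mean)
  surv_alive <- ad & nxt_state != "dead"
  succ_freq <- tapply(
    nxt_state[surv_alive] == "successful_breeder",
    d$year[surv_alive] + 1, mean
  )
  expect_gt(cor(surv_freq, succ_freq), 0)
  # and with zero variance the same statistic is centred at zero
  cov0 <- cov3(sigma = 0)
  st0 <- simulate_study(vr, cov0, 300, 30, seed = 22)
  d0 <- as.data.frame(st0$data)
  nxt0 <- d0$true_state[match(
    paste(d0$individual_id, d0$year + 1),
    paste(d0$individual_id, d0$year)
  )]
  ad0 <- d0$true_alive & d0$age >= 1 & d0$year < 30 & !is.na(nxt0)
  sf0 <- tapply(nxt0[ad0] != "dead", d0$year[ad0] + 1, mean)
  sa0 <- ad0 & nxt0 != "dead"
  cf0 <- tapply(nxt0[sa0] == "successful_breeder", d0$year[sa0] + 1, mean)
  expect_lt(abs(cor(sf0, cf0)), 0.5)
})
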