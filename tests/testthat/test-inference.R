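test_that("R-hat behaves like the Gelman-Rubin diagnostic", {
  set.seed(51)
  iid <- matrix(rnorm(4000), 2000, 2)
  expect_true(rhat(iid) >= 0.99 && rhat(iid) <= 1.02)
  sep <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(rhat(sep), 1.1)
  same <- matrix(rnorm(500), 500, 1)
  expect_equal(rhat(cbind(same, same)), sqrt((500 - 1) / 500))
  expect_error(rhat(matrix(rnorm(100), 100, 1)), ">= 2 chains")
  # cross-check against the coda implementation on a random case
  x <- matrix(rnorm(3000, c(0, 0.2)), 1500, 2)
  cd <- coda::gelman.diag(
    coda::mcmc.list(coda::mcmc(x[, 1]), coda::mcmc(x[, 2])),
    autoburnin = FALSE, transform = FALSE
  )$psrf[1]
  expect_equal(rhat(x), cd, tolerance = 0.02)
})

test_that("the sign probability P reproduces hand counts", {
  expect_equal(sign_probability(c(1, 2, 3, -1)), 0.75)
  expect_equal(sign_probability(rep(2, 10)), 1)
  expect_equal(sign_probability(c(-1, -2, -3, 1)), 0.75)
  expect_equal(sign_probability(c(-1, 1)), 0.5) # mean 0: no evidence either way
  set.seed(52)
  sym <- rnorm(20000)
  expect_equal(sign_probability(sym), 0.5, tolerance = 0.02)
})

test_that("posterior summaries report mean, CRI, P and R-hat per parameter", {
  set.seed(53)
  arr <- array(rnorm(2 * 1000 * 2, mean = rep(c(1, -2), each = 1)),
    dim = c(1000, 2, 2), dimnames = list(NULL, NULL, c("a", "b"))
  )
  arr[, , "a"] <- abs(arr[, , "a"])
  s <- posterior_summary(arr)
  expect_named(s, c("parameter", "mean", "sd", "q2.5", "q97.5", "P", "rhat"))
  expect_equal(s$P[s$parameter == "a"], 1)
  expect_lte(s$q2.5[1], s$q97.5[1])
  expect_error(posterior_summary(arr[0, , , drop = FALSE]), "empty")
  expect_warning(
    posterior_summary(arr[1:100, , , drop = FALSE]),
    "pooled draws"
  )
})

test_that("every covariance matrix drawn from the prior is PSD", {
  # prior-predictive draws of Sigma = D L L' D from the Bartlett
  # construction with half-normal expansion scales
  set.seed(54)
  k <- 3
  nu <- max(k, 3)
  worst <- Inf
  for (i in 1:10000) {
    L <- matrix(0, k, k)
    diag(L) <- sqrt(rchisq(k, nu - seq_len(k) + 1))
    L[lower.tri(L)] <- rnorm(k * (k - 1) / 2)
    d <- abs(rnorm(k))
    M <- diag(d) %*% L
    sig <- M %*% t(M)
    worst <- min(worst, min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values))
  }
  expect_gte(worst, 0)
})

test_that("a small certain-detection fit recovers the binomial survival MLE", {
  cfg <- model_config(active_params = c("phi_j", "phi_ad"))
  vr <- vital_rate_model(cfg, mu = c(phi = qlogis(0.75), p = 5))
  cov <- covariance_structure(
    sigma = c(phi_j = 0.01, phi_ad = 0.01), sigma_p = 0
  )
  st <- simulate_study(vr, cov, 30, 8, seed = 55)
  # binomial MLE of annual survival (p ~ 1: detection history = life history)
  d <- as.data.frame(st$data)
  nxt <- d$true_alive[match(
    paste(d$individual_id, d$year + 1),
    paste(d$individual_id, d$year)
  )]
  at_risk <- d$true_alive & d$year < 8
  mle <- mean(nxt[at_risk])
  fit <- suppressWarnings(fit_vital_rates(
    st$data, cfg,
    mcmc = mcmc_control(chains = 2, iterations = 3000, burn_in = 1000, seed = 56)
  ))
  s <- posterior_summary(fit, min_draws = 0)
  phi_hat <- plogis(s$mean[s$parameter == "mu_phi"])
  expect_lt(abs(phi_hat - mle), 0.1)
})

test_that("fits are reproducible for a fixed seed", {
  st <- simulate_study(vr3(), cov3(sigma_p = 0.1), 20, 6, seed = 57)
  mc <- mcmc_control(chains = 2, iterations = 400, burn_in = 200, seed = 58)
  f1 <- suppressWarnings(fit_vital_rates(st$data, cfg3(), mcmc = mc))
  f2 <- suppressWarnings(fit_vital_rates(st$data, cfg3(), mcmc = mc))
  expect_identical(f1$draws, f2$draws)
})

test_that("short series attenuate correlations relative to long series", {
  # same generating correlation; average |r| estimate should not be larger
  # for T = 10 than for T = 40
  est <- function(T, seed) {
    st <- simulate_study(vr3(), cov3(r_j_ad = 0.6, r_ad_pi = 0.4), 50, T,
      seed = seed
    )
    fit <- suppressWarnings(fit_vital_rates(
      st$data, cfg3(),
      mcmc = mcmc_control(chains = 2, iterations = 2000, burn_in = 800, seed = seed)
    ))
    s <- posterior_summary(fit, parameters = "^r\\[", min_draws = 0)
    mean(abs(s$mean))
  }
  short <- mean(vapply(1:8, function(s) est(10, 60 + s), numeric(1)))
  long <- mean(vapply(1:8, function(s) est(40, 70 + s), numeric(1)))
  expect_lte(short, long + 0.05)
})

test_that("tidy and glance methods return the documented tibbles", {
  st <- simulate_study(vr3(), cov3(sigma_p = 0.1), 15, 6, seed = 59)
  fit <- suppressWarnings(fit_vital_rates(
    st$data, cfg3(),
    mcmc = mcmc_control(chains = 2, iterations = 600, burn_in = 300, seed = 60)
  ))
  td <- suppressWarnings(tidy(fit, min_draws = 0))
  expect_s3_class(td, "tbl_df")
  expect_true("r[phi_j,phi_ad]" %in% td$parameter)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("rhat_max", "converged", "mean_loglik") %in% names(gl)))
  cd <- correlation_draws(fit)
  expect_setequal(
    unique(cd$pair),
    c("phi_j,phi_ad", "phi_j,pi", "phi_ad,pi")
  )
  expect_true(all(abs(cd$value) <= 1))
  # draws and summaries export
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  long <- read.csv(path)
  expect_setequal(names(long), c("chain", "iteration", "parameter", "value"))
  meta <- jsonlite::read_json(paste0(sub("\\.csv$", "", path), "_meta.json"))
  expect_equal(meta$chains, 2)
  write_summary(fit, path)
  expect_true("P" %in% names(read.csv(path)))
})
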