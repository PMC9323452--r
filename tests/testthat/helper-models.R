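# Shared fixture builders: small model configurations used across tests.

cfg3 <- function(correlation_type = 1) {
  model_config(
    active_params = c("phi_j", "phi_ad", "pi"),
    correlation_type = correlation_type
  )
}

vr3 <- function(cfg = cfg3(), phi_j = 0.65, phi_ad = 0.75, pi = 0.6, p = 0.9) {
  vital_rate_model(
    cfg,
    mu = c(phi = qlogis(phi_j), pi = qlogis(pi), p = qlogis(p)),
    age_effects = list(phi = c(0, qlogis(phi_ad) - qlogis(phi_j)))
  )
}

cov3 <- function(r_j_ad = 0.6, r_ad_pi = 0.4, r_j_pi = r_j_ad * r_ad_pi,
                 sigma = 0.4, sigma_p = 0) {
  covariance_structure(
    sigma = c(phi_j = sigma, phi_ad = sigma, pi = sigma),
    corr = matrix(
      c(
        1, r_j_ad, r_j_pi,
        r_j_ad, 1, r_ad_pi,
        r_j_pi, r_ad_pi, 1
      ), 3, 3
    ),
    sigma_p = sigma_p
  )
}

# a tiny full model with all five parameters active (truncated Poisson
# productivity) for likelihood stress tests
cfg5 <- function(correlation_type = 1) {
  model_config(
    active_params = c("phi_j", "phi_ad", "psi", "pi", "omega"),
    productivity_family = "truncated_poisson",
    correlation_type = correlation_type
  )
}

vr5 <- function(cfg = cfg5()) {
  vital_rate_model(
    cfg,
    mu = c(
      phi = qlogis(0.6), psi = qlogis(0.7), pi = qlogis(0.6),
      omega = log(2), p = qlogis(0.8)
    ),
    age_effects = list(phi = c(0, 0.5)),
    bs_effects = NULL
  )
}

random_leslie <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  rates <- data.frame(
    phi = runif(n, 0.2, 0.95),
    pi = runif(n, 0.3, 1),
    omega = runif(n, 0.5, 3)
  )
  build_projection_matrix(rates, phi_j = runif(1, 0.1, 0.9), rho = 0.5)
}

cov5 <- function(sigma = 0.3, sigma_p = 0.2) {
  k <- 5
  r <- diag(k)
  r[upper.tri(r)] <- c(0.5, 0.2, 0.1, 0.2, 0.1, 0.1, 0.3, 0.2, 0.1, 0.4)
  r <- r + t(r) - diag(k)
  covariance_structure(
    sigma = setNames(rep(sigma, k), c("phi_j", "phi_ad", "psi", "pi", "omega")),
    corr = r, sigma_p = sigma_p
  )
}
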