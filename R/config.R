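# Canonical orderings used throughout the package.
.vc_tv_params <- c("phi_j", "phi_ad", "psi", "pi", "omega")
.vc_rate_names <- c("phi", "psi", "pi", "omega", "p")
.vc_states <- c(
  "juvenile", "pre_breeder", "non_breeder",
  "failed_breeder", "successful_breeder", "dead"
)
.vc_families <- c(
  "fixed_one", "bernoulli_extra_offspring",
  "truncated_normal", "truncated_poisson"
)

#' Model structure configuration
#'
#' Describes which demographic parameters are modelled as time-varying,
#' how ages map onto age classes for each rate, which rates carry
#' previous-breeding-state effects, the productivity family, and the
#' correlation type (whether reproduction in year t is paired with
#' survival from the previous season, type 1, or to the next season,
#' type 2).
#'
#' @param active_params Character subset of
#'   `c("phi_j", "phi_ad", "psi", "pi", "omega")` modelled as time-varying.
#'   Juvenile and adult survival are always active.
#' @param age_breaks Named list (`phi`, `psi`, `pi`, `omega`, `p`) of
#'   increasing integer vectors starting at 1: ages at which a new age
#'   class opens for that rate. For survival the age is the age reached at
#'   the end of the interval, so class 1 is first-year (juvenile) survival.
#' @param bs_effects_on Character subset of `c("phi", "psi", "pi", "p")`
#'   naming the rates that carry a breeding-state effect (survival,
#'   breeding and success use the previous year's state; detection uses
#'   the current state).
#' @param productivity_family One of `"fixed_one"`,
#'   `"bernoulli_extra_offspring"`, `"truncated_normal"`,
#'   `"truncated_poisson"`. Must be `"fixed_one"` exactly when `omega` is
#'   inactive (a single offspring at best).
#' @param correlation_type 1 or 2 (see Details).
#' @param pre_breeder Use a pre-breeder state for individuals that have
#'   never bred? Requires `psi` active.
#' @param breeding_from_age First age (years) at which the breeding
#'   process applies; younger survivors remain pre-breeders.
#' @param detection_year_effect Include an independent temporal random
#'   effect on detection probability?
#' @return An object of class `vc_config`.
#' @details Under type 1 the rates governing survival into year t and
#'   reproduction at year t read the same row t of the temporal-effect
#'   matrix; under type 2 survival over (t, t+1] reads row t, pairing each
#'   reproductive season with survival to the next season.
#' @examples
#' model_config(active_params = c("phi_j", "phi_ad", "pi"))
#' @export
model_config <- function(active_params = c("phi_j", "phi_ad", "psi", "pi"),
                         age_breaks = NULL,
                         bs_effects_on = character(),
                         productivity_family = NULL,
                         correlation_type = 1,
                         pre_breeder = FALSE,
                         breeding_from_age = 1L,
                         detection_year_effect = TRUE) {
  active_params <- match.arg(active_params, .vc_tv_params, several.ok = TRUE)
  if (!all(c("phi_j", "phi_ad") %in% active_params)) {
    stop("active_params must contain 'phi_j' and 'phi_ad'", call. = FALSE)
  }
  active_params <- .vc_tv_params[.vc_tv_params %in% active_params]
  if (!correlation_type %in% c(1, 2)) {
    stop("correlation_type must be 1 or 2", call. = FALSE)
  }
  if (pre_breeder && !"psi" %in% active_params) {
    stop("pre_breeder state requires an active reproductive probability (psi)",
      call. = FALSE
    )
  }
  if (breeding_from_age > 1 && !pre_breeder) {
    stop("breeding_from_age > 1 requires pre_breeder = TRUE", call. = FALSE)
  }
  defaults <- list(phi = c(1L, 2L), psi = 1L, pi = 1L, omega = 1L, p = 1L)
  if (is.null(age_breaks)) age_breaks <- list()
  age_breaks <- utils::modifyList(defaults, lapply(age_breaks, as.integer))
  for (nm in .vc_rate_names) {
    b <- age_breaks[[nm]]
    if (b[1] != 1L || is.unsorted(b, strictly = TRUE)) {
      stop("age_breaks$", nm, " must be strictly increasing and start at 1",
        call. = FALSE
      )
    }
  }
  if (is.null(productivity_family)) {
    productivity_family <- if ("omega" %in% active_params) "truncated_poisson" else "fixed_one"
  }
  productivity_family <- match.arg(productivity_family, .vc_families)
  if (("omega" %in% active_params) == (productivity_family == "fixed_one")) {
    stop("productivity_family must be 'fixed_one' exactly when omega is inactive",
      call. = FALSE
    )
  }
  if (length(bs_effects_on)) {
    bs_effects_on <- match.arg(bs_effects_on, c("phi", "psi", "pi", "p"),
      several.ok = TRUE
    )
  }
  structure(
    list(
      active_params = active_params,
      age_breaks = age_breaks,
      bs_effects_on = bs_effects_on,
      productivity_family = productivity_family,
      correlation_type = as.integer(correlation_type),
      pre_breeder = pre_breeder,
      breeding_from_age = as.integer(breeding_from_age),
      detection_year_effect = detection_year_effect
    ),
    class = "vc_config"
  )
}

#' @export
print.vc_config <- function(x, ...) {
  cat("<vc_config>\n")
  cat("  time-varying:", paste(x$active_params, collapse = ", "), "\n")
  cat("  productivity:", x$productivity_family, "\n")
  cat("  correlation type:", x$correlation_type, "\n")
  cat("  latent states:", paste(live_states(x), collapse = ", "), "+ dead\n")
  invisible(x)
}

#' Latent state space implied by a configuration
#'
#' @param config A [model_config()].
#' @return Character vector of live latent states (the absorbing `dead`
#'   state is appended by consumers that need it).
#' @export
live_states <- function(config) {
  s <- "juvenile"
  if (config$pre_breeder) s <- c(s, "pre_breeder")
  if ("psi" %in% config$active_params) s <- c(s, "non_breeder")
  if ("pi" %in% config$active_params) s <- c(s, "failed_breeder")
  c(s, "successful_breeder")
}

n_age_classes <- function(config, rate) length(config$age_breaks[[rate]])

age_class_of <- function(age, breaks) {
  # age is the age in years at which the rate applies (>= 1)
  pmin(findInterval(age, breaks), length(breaks))
}

#' Vital-rate model: intercepts, age and breeding-state effects
#'
#' Bundles a [model_config()] with numeric values for the link-scale
#' intercepts, the per-age-class offsets `f` (first class fixed at 0) and
#' the previous-breeding-state offsets `gamma` (unnamed states are at the
#' reference level 0).
#'
#' @param config A [model_config()].
#' @param mu Named numeric: link-scale intercepts `phi`, `p`, plus `psi`,
#'   `pi`, `omega` when active.
#' @param age_effects Named list of numeric vectors matching
#'   `config$age_breaks` lengths; first element of each must be 0.
#' @param bs_effects Named list (`phi`, `psi`, `pi`, `p`) of named numeric
#'   vectors keyed by latent state (e.g. `c(failed_breeder = -0.2)`).
#' @param sigma_omega_resid Residual SD of the truncated-normal
#'   productivity family (required for that family only).
#' @return An object of class `vc_vital_rates`.
#' @examples
#' cfg <- model_config(active_params = c("phi_j", "phi_ad", "pi"))
#' vital_rate_model(cfg, mu = c(phi = qlogis(0.8), pi = 0, p = 2))
#' @export
vital_rate_model <- function(config, mu, age_effects = NULL, bs_effects = NULL,
                             sigma_omega_resid = NULL) {
  stopifnot(inherits(config, "vc_config"))
  mu <- as.list(mu)
  need <- c("phi", "p")
  if ("psi" %in% config$active_params) need <- c(need, "psi")
  if ("pi" %in% config$active_params) need <- c(need, "pi")
  if ("omega" %in% config$active_params) need <- c(need, "omega")
  missing_mu <- setdiff(need, names(mu))
  if (length(missing_mu)) {
    stop("mu is missing intercepts: ", paste(missing_mu, collapse = ", "),
      call. = FALSE
    )
  }
  fe <- lapply(.vc_rate_names, function(nm) {
    m <- n_age_classes(config, nm)
    v <- age_effects[[nm]] %||% numeric(m)
    if (length(v) != m) {
      stop("age_effects$", nm, " must have length ", m, call. = FALSE)
    }
    if (v[1] != 0) {
      stop("age_effects$", nm, ": first age class is the reference and must be 0",
        call. = FALSE
      )
    }
    v
  })
  names(fe) <- .vc_rate_names
  ls <- live_states(config)
  ge <- lapply(c("phi", "psi", "pi", "p"), function(nm) {
    v <- setNames(numeric(length(ls)), ls)
    user <- bs_effects[[nm]]
    if (!is.null(user)) {
      if (!nm %in% config$bs_effects_on) {
        stop("bs_effects$", nm, " given but '", nm,
          "' is not in config$bs_effects_on",
          call. = FALSE
        )
      }
      bad <- setdiff(names(user), ls)
      if (length(bad)) {
        stop("bs_effects$", nm, ": unknown state(s) ",
          paste(bad, collapse = ", "),
          call. = FALSE
        )
      }
      v[names(user)] <- user
    }
    if (v[["juvenile"]] != 0) {
      stop("bs_effects$", nm, ": 'juvenile' is the reference level (0)",
        call. = FALSE
      )
    }
    v
  })
  names(ge) <- c("phi", "psi", "pi", "p")
  if (config$productivity_family == "truncated_normal") {
    if (is.null(sigma_omega_resid) || sigma_omega_resid <= 0) {
      stop("sigma_omega_resid > 0 is required for the truncated_normal family",
        call. = FALSE
      )
    }
  } else if (!is.null(sigma_omega_resid)) {
    stop("sigma_omega_resid only applies to the truncated_normal family",
      call. = FALSE
    )
  }
  structure(
    list(
      config = config, mu = mu, age_effects = fe, bs_effects = ge,
      sigma_omega_resid = sigma_omega_resid
    ),
    class = "vc_vital_rates"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temporal variance-covariance structure of the year effects
#'
#' The year effects of the active time-varying parameters are drawn from a
#' multivariate normal on the link scale with covariance
#' `cov[X, X'] = r[X, X'] * sigma[X] * sigma[X']`; the detection year
#' effect is independent with SD `sigma_p`.
#'
#' @param sigma Named non-negative numeric of temporal SDs, in canonical
#'   order `phi_j, phi_ad, psi, pi, omega` (subset).
#' @param corr Correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite) matching `sigma`.
#' @param sigma_p Non-negative SD of the detection year effect.
#' @return An object of class `vc_covariance`.
#' @examples
#' covariance_structure(
#'   sigma = c(phi_j = 0.4, phi_ad = 0.4),
#'   corr = matrix(c(1, 0.6, 0.6, 1), 2)
#' )
#' @export
covariance_structure <- function(sigma, corr = diag(length(sigma)), sigma_p = 0) {
  if (is.null(names(sigma)) || !all(names(sigma) %in% .vc_tv_params)) {
    stop("sigma must be named with parameters among: ",
      paste(.vc_tv_params, collapse = ", "),
      call. = FALSE
    )
  }
  ord <- .vc_tv_params[.vc_tv_params %in% names(sigma)]
  sigma <- sigma[ord]
  if (any(sigma < 0) || sigma_p < 0) {
    stop("sigma and sigma_p must be non-negative", call. = FALSE)
  }
  corr <- as.matrix(corr)
  k <- length(sigma)
  if (!all(dim(corr) == k)) stop("corr must be ", k, "x", k, call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-10) {
    stop("corr is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(corr) - 1)) > 1e-10) {
    stop("corr must have a unit diagonal", call. = FALSE)
  }
  if (any(abs(corr) > 1 + 1e-10)) {
    stop("corr entries must lie in [-1, 1]", call. = FALSE)
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("corr is not positive semi-definite", call. = FALSE)
  }
  dimnames(corr) <- list(ord, ord)
  structure(
    list(param_order = ord, sigma = sigma, corr = corr, sigma_p = sigma_p),
    class = "vc_covariance"
  )
}

#' Prior specification
#'
#' Weakly informative defaults on the probability scale: normal priors for
#' link-scale intercepts and effects, a parameter-expanded Cholesky prior
#' for the temporal variance-covariance matrix (free lower-triangular
#' loadings with normal priors, half-normal expansion scales), and
#' half-normal priors for the detection-year and productivity residual
#' SDs.
#'
#' @param intercept_mean,intercept_sd Normal prior on link-scale intercepts.
#' @param effect_sd Normal(0, `effect_sd`^2) prior on age and
#'   breeding-state effects.
#' @param loading_sd Normal(0, `loading_sd`^2) prior on the off-diagonal
#'   elements of the lower-triangular loading matrix; diagonals follow
#'   chi distributions (Bartlett form), which makes the induced prior on
#'   each temporal correlation flat.
#' @param scale_sd Half-normal(0, `scale_sd`^2) prior on the diagonal
#'   expansion scales.
#' @param sigma_p_sd Half-normal prior SD for the detection year-effect SD.
#' @param sigma_omega_sd Half-normal prior SD for the truncated-normal
#'   productivity residual SD.
#' @return An object of class `vc_priors`.
#' @export
prior_spec <- function(intercept_mean = 0, intercept_sd = 1.5, effect_sd = 1,
                       loading_sd = 1, scale_sd = 1, sigma_p_sd = 1,
                       sigma_omega_sd = 1) {
  stopifnot(
    intercept_sd > 0, effect_sd > 0, loading_sd > 0, scale_sd > 0,
    sigma_p_sd > 0, sigma_omega_sd > 0
  )
  structure(
    list(
      intercept_mean = intercept_mean, intercept_sd = intercept_sd,
      effect_sd = effect_sd, loading_sd = loading_sd, scale_sd = scale_sd,
      sigma_p_sd = sigma_p_sd, sigma_omega_sd = sigma_omega_sd
    ),
    class = "vc_priors"
  )
}

#' MCMC sampler settings
#'
#' Defaults mirror a mid-range capture-recapture run: 10,000 iterations of
#' which 2,000 are discarded as burn-in (the adaptation phase), thinning
#' interval 5, three chains.
#'
#' @param chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param iterations Total iterations per chain, burn-in included.
#' @param burn_in Iterations discarded (and used for proposal adaptation).
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed driving all chains.
#' @export
mcmc_control <- function(chains = 3, iterations = 10000, burn_in = 2000,
                         thin = 5, seed = 1) {
  stopifnot(chains >= 1, iterations > burn_in, burn_in >= 1, thin >= 1)
  structure(
    list(
      chains = as.integer(chains), iterations = as.integer(iterations),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      seed = as.integer(seed)
    ),
    class = "vc_mcmc_control"
  )
}
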