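#' Fit the multi-state capture-recapture model
#'
#' Samples the joint posterior of intercepts, age and breeding-state
#' effects, year effects and the temporal variance-covariance matrix by
#' adaptive Metropolis-within-Gibbs, using the forward hidden-Markov
#' likelihood (latent alive/breeding states marginalised, conditioning on
#' first capture). The covariance of the year effects uses a
#' parameter-expanded Cholesky construction, so every sampled matrix is
#' positive semi-definite; temporal correlations are derived draw by draw
#' as the covariance divided by the product of the temporal SDs.
#'
#' @param data Capture-history tibble (columns `individual_id`, `year`,
#'   `detected`, `state`, `count`; optional `age`).
#' @param config A [model_config()] consistent with the data's states.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_control()].
#' @param n_years Last study year (default: `max(data$year)`).
#' @param keep_alpha Store the year-effect draws as well?
#' @return An object of class `vc_fit` with posterior draws (array
#'   `iterations x chains x parameters`), sampler metadata, and
#'   convergence diagnostics. Non-convergence (any monitored R-hat above
#'   1.1) is flagged in the metadata and as a warning, never silently
#'   ignored.
#' @seealso [posterior_summary()], [correlation_draws()], [tidy.vc_fit()]
#' @export
fit_vital_rates <- function(data, config, priors = prior_spec(),
                            mcmc = mcmc_control(), n_years = NULL,
                            keep_alpha = FALSE) {
  stopifnot(inherits(config, "vc_config"), inherits(priors, "vc_priors"))
  t0 <- Sys.time()
  n_years <- as.integer(n_years %||% max(data$year))
  engine <- build_engine(config, n_years)
  packed <- pack_data(data, config, n_years)
  if (packed$n == 0) stop("no detected individuals in data", call. = FALSE)
  lay <- engine$layout
  spec <- sampler_spec(engine, config, priors)

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    theta0 <- init_theta(engine, config, spec)
    chains[[ch]] <- cpp_run_chain(
      engine, packed, theta0, spec$blocks, spec$block_type, spec$block_year,
      spec$prior_code, spec$prior_mean, spec$prior_sd,
      mcmc$iterations, mcmc$burn_in, mcmc$thin, 3L
    )
  }

  named <- lapply(chains, function(cc) derive_draws(cc$draws, engine, spec, keep_alpha))
  pars <- colnames(named[[1]])
  draws <- array(
    unlist(named),
    dim = c(n_keep, length(pars), mcmc$chains)
  )
  draws <- aperm(draws, c(1, 3, 2))
  dimnames(draws) <- list(NULL, paste0("chain", seq_len(mcmc$chains)), pars)

  monitored <- pars[!grepl("^alpha", pars)]
  rh <- if (mcmc$chains >= 2) {
    vapply(monitored, function(p) rhat(draws[, , p, drop = TRUE]), numeric(1))
  } else {
    setNames(rep(NA_real_, length(monitored)), monitored)
  }
  converged <- all(is.na(rh) | rh <= 1.1)
  ll <- vapply(chains, function(cc) as.numeric(cc$loglik), numeric(n_keep))

  out <- structure(
    list(
      draws = draws, config = config, priors = priors, mcmc = mcmc,
      n_years = n_years,
      n_individuals = packed$n,
      rhat = rh, converged = converged,
      loglik = ll,
      accept = lapply(chains, function(cc) as.numeric(cc$accept)),
      runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "vc_fit"
  )
  if (!converged) {
    warning("MCMC convergence not reached: max R-hat = ",
      format(max(rh, na.rm = TRUE), digits = 4),
      call. = FALSE
    )
  }
  out
}

# block/prior layout for the sampler
sampler_spec <- function(engine, config, priors) {
  lay <- engine$layout
  nth <- lay$n_theta
  prior_code <- integer(nth)
  prior_mean <- numeric(nth)
  prior_sd <- rep(1, nth)

  relevant <- c("phi", "p", intersect(config$active_params, c("psi", "pi", "omega")))
  free_int <- integer()
  for (r in .vc_rate_names) {
    if (!r %in% relevant) next
    i <- lay$i_mu[[r]]
    prior_code[i] <- 1L
    prior_mean[i] <- priors$intercept_mean
    prior_sd[i] <- priors$intercept_sd
    free_int <- c(free_int, i)
    fs <- lay$i_f[[r]]
    if (length(fs) > 1) {
      i <- fs[-1]
      prior_code[i] <- 1L
      prior_sd[i] <- priors$effect_sd
      free_int <- c(free_int, i)
    }
  }
  for (r in config$bs_effects_on) {
    gs <- lay$i_g[[r]]
    i <- gs[setdiff(names(gs), c("juvenile", "successful_breeder"))]
    if (length(i)) {
      prior_code[i] <- 1L
      prior_sd[i] <- priors$effect_sd
      free_int <- c(free_int, unname(i))
    }
  }
  if (config$productivity_family == "truncated_normal") {
    i <- lay$i_logsigom
    prior_code[i] <- 2L
    prior_sd[i] <- priors$sigma_omega_sd
    free_int <- c(free_int, i)
  }
  # Bartlett-style triangular factor: chi-distributed diagonals (df
  # nu - k + 1 with nu = max(K, 3)) and normal off-diagonals give an
  # (empirically verified) flat induced prior on each correlation for
  # K <= 3 and the uniform-correlation-matrix behaviour beyond
  nu <- max(engine$K, 3)
  diag_slot <- engine$L_row == engine$L_col
  prior_code[lay$i_L[diag_slot]] <- 3L
  prior_mean[lay$i_L[diag_slot]] <- nu - engine$L_row[diag_slot]
  prior_code[lay$i_L[!diag_slot]] <- 1L
  prior_sd[lay$i_L[!diag_slot]] <- priors$loading_sd
  prior_code[lay$i_logdelta] <- 2L
  prior_sd[lay$i_logdelta] <- priors$scale_sd
  if (length(lay$i_logsigp)) {
    prior_code[lay$i_logsigp] <- 2L
    prior_sd[lay$i_logsigp] <- priors$sigma_p_sd
  }

  blocks <- list()
  types <- integer()
  years <- integer()
  for (chunk in split(free_int, ceiling(seq_along(free_int) / 6))) {
    blocks <- c(blocks, list(as.integer(chunk - 1L)))
    types <- c(types, 0L)
    years <- c(years, 0L)
  }
  for (t in seq_len(engine$T)) {
    ix <- lay$i_alpha[t, ]
    if (length(lay$i_alphap)) ix <- c(ix, lay$i_alphap[t])
    blocks <- c(blocks, list(as.integer(ix - 1L)))
    types <- c(types, 1L)
    years <- c(years, t)
  }
  for (i in c(lay$i_L, lay$i_logdelta)) {
    blocks <- c(blocks, list(as.integer(i - 1L)))
    types <- c(types, 2L)
    years <- c(years, 0L)
  }
  if (length(lay$i_logsigp)) {
    blocks <- c(blocks, list(as.integer(lay$i_logsigp - 1L)))
    types <- c(types, 3L)
    years <- c(years, 0L)
  }
  list(
    blocks = blocks, block_type = as.integer(types),
    block_year = as.integer(years),
    prior_code = as.integer(prior_code), prior_mean = prior_mean,
    prior_sd = prior_sd, free_int = free_int
  )
}

init_theta <- function(engine, config, spec) {
  lay <- engine$layout
  theta <- numeric(lay$n_theta)
  start <- c(
    phi = qlogis(0.7), psi = qlogis(0.8), pi = qlogis(0.6),
    omega = switch(config$productivity_family,
      truncated_normal = 2, truncated_poisson = log(2), 0
    ),
    p = qlogis(0.7)
  )
  for (r in .vc_rate_names) theta[lay$i_mu[[r]]] <- start[[r]]
  theta[spec$free_int] <- theta[spec$free_int] + rnorm(length(spec$free_int), 0, 0.3)
  diag_slot <- engine$L_row == engine$L_col
  theta[lay$i_L[diag_slot]] <- log(1) + rnorm(engine$K, 0, 0.1)
  theta[lay$i_L[!diag_slot]] <- rnorm(sum(!diag_slot), 0, 0.1)
  theta[lay$i_logdelta] <- log(0.25) + rnorm(engine$K, 0, 0.1)
  if (length(lay$i_logsigp)) theta[lay$i_logsigp] <- log(0.1)
  theta
}

# derive interpretable parameter draws from the raw theta draws
derive_draws <- function(raw, engine, spec, keep_alpha) {
  lay <- engine$layout
  config_active <- colnames(lay$i_alpha)
  K <- engine$K
  out <- list()
  for (r in .vc_rate_names) {
    i <- lay$i_mu[[r]]
    if (i %in% spec$free_int) out[[paste0("mu_", r)]] <- raw[, i]
    fs <- lay$i_f[[r]]
    if (length(fs) > 1) {
      for (k in 2:length(fs)) {
        if (fs[k] %in% spec$free_int) {
          out[[paste0("f_", r, "[", k, "]")]] <- raw[, fs[k]]
        }
      }
    }
  }
  for (r in c("phi", "psi", "pi", "p")) {
    gs <- lay$i_g[[r]]
    for (s in names(gs)) {
      if (gs[[s]] %in% spec$free_int) {
        out[[paste0("gamma_", r, "[", s, "]")]] <- raw[, gs[[s]]]
      }
    }
  }
  if (lay$i_logsigom %in% spec$free_int) {
    out[["sigma_omega_resid"]] <- exp(raw[, lay$i_logsigom])
  }
  Lm <- raw[, lay$i_L, drop = FALSE]
  diag_slot <- engine$L_row == engine$L_col
  Lm[, diag_slot] <- exp(Lm[, diag_slot])
  delta <- exp(raw[, lay$i_logdelta, drop = FALSE])
  rownorm <- matrix(0, nrow(raw), K)
  for (k in seq_len(K)) {
    cols <- which(engine$L_row == k - 1L)
    rownorm[, k] <- sqrt(rowSums(Lm[, cols, drop = FALSE]^2))
  }
  for (k in seq_len(K)) {
    out[[paste0("sigma[", config_active[k], "]")]] <- delta[, k] * rownorm[, k]
  }
  for (j in seq_len(K - 1)) {
    for (k in (j + 1):K) {
      num <- numeric(nrow(raw))
      for (cc in seq_len(K)) {
        ej <- which(engine$L_row == j - 1L & engine$L_col == cc - 1L)
        ek <- which(engine$L_row == k - 1L & engine$L_col == cc - 1L)
        if (length(ej) && length(ek)) num <- num + Lm[, ej] * Lm[, ek]
      }
      out[[paste0("r[", config_active[j], ",", config_active[k], "]")]] <-
        num / (rownorm[, j] * rownorm[, k])
    }
  }
  if (length(lay$i_logsigp)) out[["sigma_p"]] <- exp(raw[, lay$i_logsigp])
  if (keep_alpha) {
    for (k in seq_len(K)) {
      for (t in seq_len(engine$T)) {
        out[[paste0("alpha[", t, ",", config_active[k], "]")]] <-
          raw[, lay$i_alpha[t, k]]
      }
    }
    if (length(lay$i_alphap)) {
      for (t in seq_len(engine$T)) {
        out[[paste0("alpha_p[", t, "]")]] <- raw[, lay$i_alphap[t]]
      }
    }
  }
  do.call(cbind, out)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat comparing between- and within-chain
#' variances; values near 1 indicate well-mixed chains and values above
#' 1.1 are conventionally taken as non-convergence.
#'
#' @param x Matrix of draws, iterations x chains (>= 2 chains of equal
#'   length >= 10), or a list of equal-length chain vectors.
#' @return The potential scale reduction factor.
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(2000), 1000, 2))
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2) {
    stop("R-hat requires at least 2 chains; provide draws from >= 2 chains",
      call. = FALSE
    )
  }
  n <- nrow(x)
  if (n < 10) stop("R-hat requires chains of length >= 10", call. = FALSE)
  w <- mean(apply(x, 2, var))
  b <- n * var(colMeans(x))
  if (w == 0) {
    return(1)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sign probability of a posterior sample
#'
#' The proportion of draws sharing the sign of the posterior mean: 0.5
#' means no evidence of an effect of either sign, 1 means all posterior
#' mass on one side of zero.
#'
#' @param x Numeric vector of posterior draws.
#' @return A value in \[0.5, 1\] (up to discreteness).
#' @examples
#' sign_probability(c(1, 2, 3, -1)) # 0.75
#' @export
sign_probability <- function(x) {
  m <- mean(x)
  if (m > 0) mean(x > 0) else if (m < 0) mean(x < 0) else 0.5
}

#' Posterior summaries
#'
#' Per-parameter posterior mean, SD, equal-tailed 95% credible interval,
#' sign probability P (on draws pooled across chains) and R-hat.
#'
#' @param fit A `vc_fit` (or a 3-d draws array iterations x chains x
#'   parameters).
#' @param parameters Optional regular expression selecting parameters.
#' @param min_draws Minimum pooled draw count required for summaries.
#' @return Tibble with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `P`, `rhat`.
#' @export
posterior_summary <- function(fit, parameters = NULL, min_draws = 1000) {
  draws <- if (inherits(fit, "vc_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[1] == 0) stop("empty draws", call. = FALSE)
  pars <- dimnames(draws)[[3]]
  if (!is.null(parameters)) pars <- grep(parameters, pars, value = TRUE)
  n_pool <- dim(draws)[1] * dim(draws)[2]
  if (n_pool < min_draws) {
    warning("only ", n_pool, " pooled draws (< ", min_draws,
      "); summaries may be unstable",
      call. = FALSE
    )
  }
  multi <- dim(draws)[2] >= 2
  purrr::map_dfr(pars, function(p) {
    m <- draws[, , p, drop = TRUE]
    v <- as.numeric(m)
    q <- unname(quantile(v, c(0.025, 0.975), names = FALSE))
    tibble::tibble(
      parameter = p, mean = mean(v), sd = sd(v),
      q2.5 = q[1], q97.5 = q[2],
      P = sign_probability(v),
      rhat = if (multi) rhat(m) else NA_real_
    )
  })
}

#' @export
summary.vc_fit <- function(object, ...) posterior_summary(object, ...)

#' Broom-style methods for fitted objects
#'
#' `tidy()` returns the per-parameter posterior summary table; `glance()`
#' a one-row overview of the fit.
#'
#' @param x A `vc_fit`.
#' @param ... Passed to [posterior_summary()].
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.vc_fit <- function(x, ...) posterior_summary(x, ...)

#' @rdname tidy.vc_fit
#' @exportS3Method generics::glance
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    chains = dim(x$draws)[2],
    draws = dim(x$draws)[1] * dim(x$draws)[2],
    n_individuals = x$n_individuals,
    n_years = x$n_years,
    rhat_max = max(x$rhat, na.rm = TRUE),
    converged = x$converged,
    mean_loglik = mean(x$loglik),
    runtime_s = x$runtime
  )
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit>", dim(x$draws)[1], "draws x", dim(x$draws)[2], "chains,",
    x$n_individuals, "individuals,", x$n_years, "years\n")
  cat("  max R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
    if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(posterior_summary(x, parameters = "^(r\\[|sigma)", min_draws = 0))
  invisible(x)
}

#' Tidy draws of the temporal correlations
#'
#' @param fit A `vc_fit`.
#' @return Tibble with columns `chain`, `iteration`, `pair` (e.g.
#'   `"phi_j,phi_ad"`) and `value` (the correlation draw, in \[-1, 1\]).
#' @export
correlation_draws <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  pars <- grep("^r\\[", dimnames(fit$draws)[[3]], value = TRUE)
  purrr::map_dfr(pars, function(p) {
    m <- fit$draws[, , p, drop = TRUE]
    m <- as.matrix(m)
    tibble::tibble(
      chain = rep(seq_len(ncol(m)), each = nrow(m)),
      iteration = rep(seq_len(nrow(m)), ncol(m)),
      pair = sub("^r\\[(.*)\\]$", "\\1", p),
      value = as.numeric(m)
    )
  })
}

#' Export posterior draws and summaries
#'
#' Draws go to a tidy CSV (`chain`, `iteration`, `parameter`, `value`)
#' with a JSON sidecar holding the sampler metadata; summaries to a CSV
#' with one row per parameter.
#'
#' @param fit A `vc_fit`.
#' @param path Output CSV path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  dn <- dimnames(fit$draws)
  long <- tidyr::expand_grid(
    parameter = dn[[3]], chain = seq_along(dn[[2]]),
    iteration = seq_len(dim(fit$draws)[1])
  )
  long$value <- as.numeric(fit$draws[cbind(
    long$iteration, long$chain,
    match(long$parameter, dn[[3]])
  )])
  write.csv(long[, c("chain", "iteration", "parameter", "value")],
    path,
    row.names = FALSE
  )
  meta <- list(
    chains = fit$mcmc$chains, iterations = fit$mcmc$iterations,
    burn_in = fit$mcmc$burn_in, thin = fit$mcmc$thin, seed = fit$mcmc$seed,
    n_years = fit$n_years, n_individuals = fit$n_individuals,
    rhat_max = max(fit$rhat, na.rm = TRUE), converged = fit$converged
  )
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), "_meta.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_draws
#' @export
write_summary <- function(fit, path) {
  write.csv(as.data.frame(posterior_summary(fit, min_draws = 0)), path,
    row.names = FALSE
  )
  invisible(path)
}
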