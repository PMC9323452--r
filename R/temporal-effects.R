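#' Draw temporal random effects
#'
#' Year effects for the active time-varying demographic parameters are
#' i.i.d. rows from a multivariate normal with covariance
#' `r[X, X'] * sigma[X] * sigma[X']` on the link scale; the detection year
#' effect is an independent Normal(0, `sigma_p`^2) series.
#'
#' @param cov A [covariance_structure()].
#' @param n_years Number of years T (>= 2).
#' @param seed Optional integer seed (sets the RNG state).
#' @return An object of class `vc_effects`: list with `years` (1..T),
#'   `alpha` (T x K matrix, columns in `cov$param_order`) and `alpha_p`
#'   (length-T vector).
#' @examples
#' cov <- covariance_structure(
#'   sigma = c(phi_j = 0.3, phi_ad = 0.3),
#'   corr = matrix(c(1, 0.5, 0.5, 1), 2)
#' )
#' eff <- draw_temporal_effects(cov, n_years = 20, seed = 1)
#' dim(eff$alpha)
#' @export
draw_temporal_effects <- function(cov, n_years, seed = NULL) {
  stopifnot(inherits(cov, "vc_covariance"), n_years >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- length(cov$sigma)
  sig <- cov$corr * tcrossprod(cov$sigma)
  # symmetric square root tolerates exactly singular cases (sigma = 0, |r| = 1)
  es <- eigen(sig, symmetric = TRUE)
  rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  z <- matrix(rnorm(n_years * k), n_years, k)
  alpha <- z %*% rt
  alpha[, cov$sigma == 0] <- 0
  colnames(alpha) <- cov$param_order
  alpha_p <- rnorm(n_years, 0, cov$sigma_p)
  structure(
    list(years = seq_len(n_years), alpha = alpha, alpha_p = alpha_p),
    class = "vc_effects"
  )
}

#' Year-effect row indices implied by the correlation type
#'
#' Reproduction in year t always reads row t of the year-effect matrix.
#' Under type 1 survival into year t (the interval (t-1, t]) also reads
#' row t, pairing reproduction with survival from the previous season;
#' under type 2 survival over (t, t+1] reads row t, pairing reproduction
#' with survival to the next season. Boundary intervals that fall outside
#' 1..T (only reachable when simulating beyond the study years) are
#' assigned an extra independent row, coded `T + 1`.
#'
#' @param correlation_type 1 or 2 (or a [model_config()]).
#' @param n_years Number of study years T.
#' @return Tibble with one row per year: `year`, `reproduction_row`, and
#'   `survival_row` (the row used by survival into that year; `NA` for
#'   year 1, before which no within-study interval exists).
#' @examples
#' apply_correlation_type(1, 5)
#' apply_correlation_type(2, 5)
#' @export
apply_correlation_type <- function(correlation_type, n_years) {
  if (inherits(correlation_type, "vc_config")) {
    correlation_type <- correlation_type$correlation_type
  }
  stopifnot(correlation_type %in% c(1, 2), n_years >= 2)
  year <- seq_len(n_years)
  survival_row <- if (correlation_type == 1) year else year - 1L
  survival_row[survival_row < 1L] <- NA_integer_
  tibble::tibble(
    year = year,
    reproduction_row = year,
    survival_row = as.integer(survival_row)
  )
}

# Row of alpha used by survival into year t; under type 2 the interval
# (T, T+1] would read row T which is fine, but survival into an
# (unsimulated) year T+1 under type 1 would need the extra row.
survival_alpha_row <- function(t, correlation_type) {
  if (correlation_type == 1) t else t - 1L
}
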