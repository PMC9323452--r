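# Zero-truncated productivity families. Counts are offspring raised per
# successful attempt, so the support starts at 1 (Bernoulli-extra and
# truncated-Poisson) or at 0+ (continuous truncated normal, recorded as a
# rounded positive integer).

#' Zero-truncated Poisson density, distribution and random generation
#'
#' @param x,n Integer counts (>= 1) / number of draws.
#' @param lambda Positive rate of the untruncated Poisson.
#' @param log Return log density?
#' @return `dztpois` the (log) probability mass; `rztpois` random counts;
#'   `ztpois_mean` the mean `lambda / (1 - exp(-lambda))`.
#' @examples
#' ztpois_mean(2)  # 2 / (1 - exp(-2))
#' @export
dztpois <- function(x, lambda, log = FALSE) {
  out <- dpois(x, lambda, log = TRUE) - log1p(-exp(-lambda))
  out[x < 1 | x != floor(x)] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dztpois
#' @export
rztpois <- function(n, lambda) {
  # inverse-CDF on the truncated scale; exact and vectorised
  u <- runif(n, min = dpois(0, lambda), max = 1)
  qpois(u, lambda)
}

#' @rdname dztpois
#' @export
ztpois_mean <- function(lambda) lambda / (1 - exp(-lambda))

#' Normal distribution truncated at zero
#'
#' Productivity family for counts with a skewed, small-valued distribution:
#' a Normal(mean, sd) conditioned on being positive, identity link on the
#' location. Generated values are continuous; recorded counts are rounded
#' to the nearest positive integer while the density is evaluated at the
#' recorded value.
#'
#' @param x,n Values (> 0) / number of draws.
#' @param mean,sd Location and scale of the untruncated normal.
#' @param log Return log density?
#' @export
dtnorm0 <- function(x, mean, sd, log = FALSE) {
  out <- dnorm(x, mean, sd, log = TRUE) - pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out[x <= 0] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dtnorm0
#' @export
rtnorm0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, min = lo, max = 1), mean, sd)
}

#' @importFrom stats qpois
NULL

# Density of a recorded productivity count under a configured family.
# eta is the linear predictor on the family's link scale.
productivity_logdens <- function(count, eta, family, sigma_resid = NULL) {
  switch(family,
    fixed_one = ifelse(count == 1, 0, -Inf),
    bernoulli_extra_offspring = {
      q <- plogis(eta)
      ifelse(count == 2, log(q), ifelse(count == 1, log1p(-q), -Inf))
    },
    truncated_normal = dtnorm0(count, eta, sigma_resid, log = TRUE),
    truncated_poisson = dztpois(count, exp(eta), log = TRUE),
    stop("unknown productivity family: ", family, call. = FALSE)
  )
}

# One random productivity draw per element of eta.
productivity_draw <- function(eta, family, sigma_resid = NULL) {
  n <- length(eta)
  switch(family,
    fixed_one = rep(1L, n),
    bernoulli_extra_offspring = 1L + rbinom(n, 1L, plogis(eta)),
    truncated_normal = pmax(1L, as.integer(round(rtnorm0(n, eta, sigma_resid)))),
    truncated_poisson = as.integer(rztpois(n, exp(eta))),
    stop("unknown productivity family: ", family, call. = FALSE)
  )
}
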