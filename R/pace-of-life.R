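#' Build an age-structured projection matrix
#'
#' Pre-breeding-census female matrix: fecundity entries in the first row
#' are `f_a = psi_a * pi_a * omega_a * rho * phi_j` (breeding probability
#' x success x productivity x daughters-per-offspring x first-year
#' survival), the survival subdiagonal carries the adult survival of each
#' age class, and the terminal class has a self-loop.
#'
#' @param rates Data frame with one row per adult age class, columns
#'   `phi` (adult survival) and optionally `psi`, `pi`, `omega`
#'   (defaulting to 1).
#' @param phi_j First-year survival folded into the fecundities.
#' @param rho Daughters-per-offspring factor (0.5 for an even sex ratio).
#' @return Object of class `vc_projection`: list with the matrix `A`, the
#'   fecundity-component matrix `F`, the dominant eigenvalue `lambda`,
#'   stable age distribution `w` (sums to 1), reproductive values `v`
#'   (normalised so `v . w = 1`), elasticity matrix `E` (sums to 1) and
#'   the generation time `generation_time`.
#' @examples
#' # scalar model: a = f + s with f = 0.5, s = 0.5 gives lambda = 1, T = 2
#' pm <- build_projection_matrix(data.frame(phi = 0.5), phi_j = 1, rho = 0.5)
#' @export
build_projection_matrix <- function(rates, phi_j, rho = 0.5) {
  rates <- as.data.frame(rates)
  n <- nrow(rates)
  stopifnot(n >= 1, all(rates$phi > 0 & rates$phi < 1))
  psi <- rates$psi %||% rep(1, n)
  pi_ <- rates$pi %||% rep(1, n)
  omega <- rates$omega %||% rep(1, n)
  fec <- psi * pi_ * omega * rho * phi_j
  if (all(fec == 0)) {
    stop("all fecundities are zero: no generation time exists", call. = FALSE)
  }
  A <- matrix(0, n, n)
  Fm <- matrix(0, n, n)
  A[1, ] <- fec
  Fm[1, ] <- fec
  if (n > 1) {
    for (a in seq_len(n - 1)) A[a + 1, a] <- rates$phi[a]
  }
  A[n, n] <- A[n, n] + rates$phi[n]
  eigen_A <- eigen(A)
  ord <- order(Mod(eigen_A$values), decreasing = TRUE)
  lam1 <- eigen_A$values[ord[1]]
  if (abs(Im(lam1)) > 1e-10 || Re(lam1) <= 0) {
    stop("no real positive dominant eigenvalue: matrix not primitive",
      call. = FALSE
    )
  }
  if (n > 1 && isTRUE(all.equal(Mod(eigen_A$values[ord[2]]), Mod(lam1),
    tolerance = 1e-10
  ))) {
    warning("dominant eigenvalue is not unique: matrix may be non-primitive",
      call. = FALSE
    )
  }
  lambda <- Re(lam1)
  w <- Re(eigen_A$vectors[, ord[1]])
  w <- w / sum(w)
  ev_l <- eigen(t(A))
  ord_l <- order(Mod(ev_l$values), decreasing = TRUE)
  v <- Re(ev_l$vectors[, ord_l[1]])
  if (sum(v * w) < 0) v <- -v
  v <- v / sum(v * w)
  sens <- outer(v, w) # v_i w_j / (v . w), with v . w = 1
  E <- sens * A / lambda
  out <- structure(
    list(
      A = A, F = Fm, lambda = lambda, w = w, v = v, E = E,
      generation_time = NA_real_
    ),
    class = "vc_projection"
  )
  out$generation_time <- generation_time(out)
  out
}

#' Generation time from fecundity elasticities
#'
#' Generation time (mean age of mothers) is the inverse of the summed
#' elasticities of the growth rate to the fecundity components:
#' `T = 1 / sum_(i,j in F) e_ij` with
#' `e_ij = (F_ij / lambda) * v_i * w_j / (v . w)`. The equivalent
#' identity `T = lambda * (v . w) / (v F w)` provides an independent
#' numerical check.
#'
#' @param model A `vc_projection` from [build_projection_matrix()].
#' @return Generation time in years.
#' @examples
#' pm <- build_projection_matrix(data.frame(phi = 0.75), phi_j = 0.5, rho = 0.5)
#' generation_time(pm) # (f + s)/f = 4 for f = 0.25, s = 0.75
#' @export
generation_time <- function(model) {
  stopifnot(inherits(model, "vc_projection"))
  e_fec <- sum(model$v * (model$F %*% model$w)) / model$lambda
  # equals sum of per-entry fecundity elasticities since v . w = 1
  if (e_fec <= 0) stop("zero fecundity elasticity", call. = FALSE)
  1 / e_fec
}

#' @export
print.vc_projection <- function(x, ...) {
  cat("<vc_projection>", nrow(x$A), "age classes, lambda =",
    format(x$lambda, digits = 5), ", generation time =",
    format(x$generation_time, digits = 5), "\n")
  invisible(x)
}

#' Regress species correlations on generation time
#'
#' For each aligned posterior draw, ordinary least squares of the
#' species-specific correlation draws on the (fixed) species generation
#' times; posterior uncertainty in the correlations therefore propagates
#' into the slope. R-squared is computed at the posterior means.
#'
#' @param sets Tidy draw table with `generation_time` filled (see
#'   [species_correlation_set()]).
#' @param pair Parameter pair to regress.
#' @param n_draws Common draw count for alignment.
#' @param seed Resampling seed.
#' @return Object of class `vc_meta_regression`: list with `draws`
#'   (tibble `draw`, `slope`, `intercept`) and `summary` (one-row tibble
#'   with slope mean/SD/CRI/P, intercept mean, `r_squared`,
#'   `n_species`).
#' @export
meta_regression <- function(sets, pair, n_draws = 3000, seed = 1) {
  sets <- sets[sets$pair == pair & !is.na(sets$generation_time), , drop = FALSE]
  species <- unique(sets$species)
  if (length(species) < 3) {
    stop("meta-regression requires >= 3 species with the pair and generation times",
      call. = FALSE
    )
  }
  gt <- vapply(
    species,
    function(s) sets$generation_time[sets$species == s][1], numeric(1)
  )
  ymat <- vapply(
    species,
    function(s) resample_draws(sets$value[sets$species == s], n_draws, seed),
    numeric(n_draws)
  )
  x <- gt - mean(gt)
  sxx <- sum(x^2)
  slope <- as.numeric(ymat %*% x) / sxx
  intercept <- rowMeans(ymat) - slope * mean(gt)
  means <- colMeans(ymat)
  fitted_lm <- lm(means ~ gt)
  r2 <- summary(fitted_lm)$r.squared
  structure(
    list(
      draws = tibble::tibble(
        draw = seq_len(n_draws), slope = slope, intercept = intercept
      ),
      summary = tibble::tibble(
        pair = pair,
        slope_mean = mean(slope), slope_sd = sd(slope),
        slope_q2.5 = quantile(slope, 0.025),
        slope_q97.5 = quantile(slope, 0.975),
        slope_P = sign_probability(slope),
        intercept_mean = mean(intercept),
        r_squared = r2, n_species = length(species)
      ),
      species = tibble::tibble(
        species = species, generation_time = gt, mean_r = means
      )
    ),
    class = "vc_meta_regression"
  )
}

#' @export
print.vc_meta_regression <- function(x, ...) {
  cat("<vc_meta_regression>", x$summary$n_species, "species\n")
  print(x$summary)
  invisible(x)
}
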