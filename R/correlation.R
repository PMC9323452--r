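#' Temporal correlations from variance and covariance draws
#'
#' Computes the correlation `cov / (sigma_x * sigma_y)` draw by draw; draws with a
#' degenerate (zero) SD are excluded with a warning. Values are clipped
#' to \[-1, 1\] only within numerical tolerance (1e-12).
#'
#' @param sigma_x,sigma_y Posterior draws of the two temporal SDs.
#' @param cov_xy Matched posterior draws of the covariance.
#' @return Numeric vector of correlation draws.
#' @examples
#' correlations_from_sigma(0.3, 0.2, 0.03) # 0.5
#' @export
correlations_from_sigma <- function(sigma_x, sigma_y, cov_xy) {
  n <- length(cov_xy)
  if (length(sigma_x) != n || length(sigma_y) != n) {
    stop("draw vectors must have matching lengths", call. = FALSE)
  }
  ok <- sigma_x > 0 & sigma_y > 0
  if (!all(ok)) {
    warning(sum(!ok), " draw(s) with a zero SD excluded (degenerate variance)",
      call. = FALSE
    )
  }
  r <- cov_xy[ok] / (sigma_x[ok] * sigma_y[ok])
  out_of_range <- abs(r) > 1 + 1e-12
  if (any(out_of_range)) {
    stop("correlation draws outside [-1, 1] beyond numerical tolerance",
      call. = FALSE
    )
  }
  pmin(pmax(r, -1), 1)
}

#' Bundle species-level correlation draws
#'
#' Builds the tidy per-species draw table the synthesis functions
#' consume. Each species contributes, for each estimated parameter pair,
#' a vector of posterior correlation draws.
#'
#' @param species Species label.
#' @param fit A `vc_fit` (or a tibble as returned by
#'   [correlation_draws()]).
#' @param generation_time Optional generation time (years).
#' @return Tibble with columns `species`, `correlation_type`, `pair`,
#'   `draw`, `value`, `generation_time`.
#' @export
species_correlation_set <- function(species, fit, generation_time = NA_real_) {
  dr <- if (inherits(fit, "vc_fit")) correlation_draws(fit) else fit
  ctype <- if (inherits(fit, "vc_fit")) fit$config$correlation_type else NA_integer_
  dr |>
    dplyr::group_by(.data$pair) |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      species = species, correlation_type = ctype,
      pair = .data$pair, draw = .data$draw, value = .data$value,
      generation_time = generation_time
    )
}

# deterministic resampling of a draw vector to a common length: evenly
# thin when longer, recycle with a seeded resample when shorter
resample_draws <- function(x, n_draws, seed = 1) {
  if (length(x) == n_draws) {
    return(x)
  }
  if (length(x) > n_draws) {
    idx <- round(seq(1, length(x), length.out = n_draws))
    return(x[idx])
  }
  set.seed(seed)
  x[sample.int(length(x), n_draws, replace = TRUE)]
}

#' Grand mean correlation across species
#'
#' The posterior of the across-species mean correlation is formed by
#' averaging draws across species at equal draw indices (species
#' posteriors are independent; each is first resampled to a common draw
#' count with a fixed seed, making the procedure deterministic).
#'
#' @param sets Tidy draw table (rows from [species_correlation_set()],
#'   possibly several species bound together).
#' @param pair Optional pair label(s) to restrict to.
#' @param n_draws Common draw count (default 3000).
#' @param seed Seed for the deterministic resampling.
#' @return Object of class `vc_grand_mean`: list with `draws` (tibble
#'   `pair`, `draw`, `value`), `summary` (tibble with mean, sd, CRI, P
#'   and the contributing species count) and `n_draws`.
#' @export
grand_mean <- function(sets, pair = NULL, n_draws = 3000, seed = 1) {
  if (!is.null(pair)) sets <- sets[sets$pair %in% pair, , drop = FALSE]
  if (nrow(sets) == 0) stop("no contributing species for this pair", call. = FALSE)
  aligned <- sets |>
    dplyr::group_by(.data$pair, .data$species) |>
    dplyr::summarise(
      value = list(resample_draws(.data$value, n_draws, seed)),
      .groups = "drop"
    )
  draws <- aligned |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      value = list(rowMeans(do.call(cbind, .data$value))),
      .groups = "drop"
    )
  long <- draws |>
    dplyr::mutate(draw = list(seq_len(n_draws))) |>
    tidyr::unnest(c("draw", "value")) |>
    dplyr::select("pair", "draw", "value")
  smry <- draws |>
    dplyr::mutate(
      mean = vapply(.data$value, mean, numeric(1)),
      sd = vapply(.data$value, sd, numeric(1)),
      q2.5 = vapply(.data$value, quantile, numeric(1), probs = 0.025),
      q97.5 = vapply(.data$value, quantile, numeric(1), probs = 0.975),
      P = vapply(.data$value, sign_probability, numeric(1))
    ) |>
    dplyr::select("pair", "mean", "sd", "q2.5", "q97.5", "P", "n_species")
  structure(
    list(draws = long, summary = smry, n_draws = n_draws),
    class = "vc_grand_mean"
  )
}

#' @export
print.vc_grand_mean <- function(x, ...) {
  cat("<vc_grand_mean> over", max(x$summary$n_species), "species,", x$n_draws,
    "draws\n")
  print(x$summary)
  invisible(x)
}

#' Direction and overlap tallies of species-specific correlations
#'
#' Counts positive/negative posterior means per parameter pair, the
#' fraction of species-pair 95% credible intervals containing zero, and
#' (when both correlation types are present) the fraction of
#' species-pairs whose posterior-mean sign flips between type 1 and
#' type 2.
#'
#' @param sets Tidy draw table (as for [grand_mean()]).
#' @return List with `by_pair` (tibble), `overall` (one-row tibble) and
#'   `sign_flips` (tibble, one row per species-pair present in both
#'   types).
#' @export
direction_tally <- function(sets) {
  smry <- sets |>
    dplyr::group_by(.data$species, .data$correlation_type, .data$pair) |>
    dplyr::summarise(
      mean = mean(.data$value),
      q2.5 = quantile(.data$value, 0.025),
      q97.5 = quantile(.data$value, 0.975),
      .groups = "drop"
    ) |>
    dplyr::mutate(overlap0 = .data$q2.5 <= 0 & .data$q97.5 >= 0)
  by_pair <- smry |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_positive = sum(.data$mean > 0),
      n_negative = sum(.data$mean < 0),
      frac_cri_overlap_zero = mean(.data$overlap0),
      .groups = "drop"
    )
  overall <- tibble::tibble(
    n = nrow(smry),
    n_positive = sum(smry$mean > 0),
    n_negative = sum(smry$mean < 0),
    frac_positive = mean(smry$mean > 0),
    frac_cri_overlap_zero = mean(smry$overlap0)
  )
  flips <- smry |>
    dplyr::filter(.data$correlation_type %in% c(1, 2)) |>
    dplyr::select("species", "pair", "correlation_type", "mean") |>
    tidyr::pivot_wider(
      names_from = "correlation_type", values_from = "mean",
      names_prefix = "type"
    )
  if (all(c("type1", "type2") %in% names(flips))) {
    flips <- flips |>
      dplyr::filter(!is.na(.data$type1), !is.na(.data$type2)) |>
      dplyr::mutate(sign_flip = sign(.data$type1) != sign(.data$type2))
  } else {
    flips <- tibble::tibble(
      species = character(), pair = character(),
      type1 = numeric(), type2 = numeric(), sign_flip = logical()
    )
  }
  list(by_pair = by_pair, overall = overall, sign_flips = flips)
}

#' Contrast type-1 and type-2 correlation posteriors
#'
#' Forms the posterior of the difference `r_type2 - r_type1` for one
#' parameter pair estimated twice on the same data set (independent fits,
#' so differences pair draws of equal index after resampling to a common
#' count).
#'
#' @param type1,type2 Tidy draw tables for the two fits (same species and
#'   pair).
#' @param pair Pair label to contrast.
#' @param n_draws Common draw count.
#' @param seed Resampling seed.
#' @return List with `draws` (difference draws) and `summary` (one-row
#'   tibble with mean, sd, CRI and P of the difference).
#' @export
compare_types <- function(type1, type2, pair, n_draws = 3000, seed = 1) {
  v1 <- type1$value[type1$pair == pair]
  v2 <- type2$value[type2$pair == pair]
  if (!length(v1) || !length(v2)) {
    stop("pair '", pair, "' absent from one of the draw tables", call. = FALSE)
  }
  v1 <- resample_draws(v1, n_draws, seed)
  v2 <- resample_draws(v2, n_draws, seed + 1)
  if (length(v1) != length(v2)) stop("draw-count mismatch after resampling", call. = FALSE)
  dd <- v2 - v1
  list(
    draws = tibble::tibble(draw = seq_along(dd), value = dd),
    summary = tibble::tibble(
      pair = pair, mean = mean(dd), sd = sd(dd),
      q2.5 = quantile(dd, 0.025), q97.5 = quantile(dd, 0.975),
      P = sign_probability(dd)
    )
  )
}
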