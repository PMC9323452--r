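#' Trace and density plots for a fitted model
#'
#' @param object A `vc_fit`.
#' @param parameters Regular expression selecting parameters (default:
#'   the temporal SDs and correlations).
#' @param ... Unused.
#' @return A ggplot object (trace panels by parameter, coloured by chain).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vc_fit <- function(object, parameters = "^(r\\[|sigma)", ...) {
  pars <- grep(parameters, dimnames(object$draws)[[3]], value = TRUE)
  long <- purrr::map_dfr(pars, function(p) {
    m <- as.matrix(object$draws[, , p, drop = TRUE])
    tibble::tibble(
      chain = factor(rep(seq_len(ncol(m)), each = nrow(m))),
      iteration = rep(seq_len(nrow(m)), ncol(m)),
      parameter = p, value = as.numeric(m)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
    colour = .data$chain
  )) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = "value") +
    ggplot2::theme_minimal()
}

#' Forest plot of species-specific correlation estimates
#'
#' Posterior means with 95% credible intervals per species and parameter
#' pair, split by correlation type when both are present.
#'
#' @param sets Tidy draw table (see [species_correlation_set()]).
#' @return A ggplot object.
#' @export
plot_correlations <- function(sets) {
  smry <- sets |>
    dplyr::group_by(.data$species, .data$correlation_type, .data$pair) |>
    dplyr::summarise(
      mean = mean(.data$value),
      q2.5 = quantile(.data$value, 0.025),
      q97.5 = quantile(.data$value, 0.975),
      .groups = "drop"
    )
  ggplot2::ggplot(smry, ggplot2::aes(.data$mean, .data$species,
    colour = factor(.data$correlation_type)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$q2.5, xmax = .data$q97.5),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(
      x = "temporal correlation", y = NULL, colour = "correlation type"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vc_fit
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vc_grand_mean <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "grand mean correlation", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vc_fit
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vc_meta_regression <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$species, ggplot2::aes(.data$generation_time, .data$mean_r)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = s$intercept_mean, slope = s$slope_mean,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "generation time (years)", y = "posterior mean correlation",
      subtitle = sprintf(
        "slope = %.4f (P = %.2f), R² = %.2f",
        s$slope_mean, s$slope_P, s$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}
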