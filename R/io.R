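#' Write and read capture-history files
#'
#' Long-format CSV, one row per individual-year, UTF-8 with header:
#' columns `individual_id`, `year`, `detected` (0/1), `state` (string,
#' empty when not detected), `count` (integer or empty), plus optional
#' `true_*` truth columns flagged as latent.
#'
#' @param data Capture-history tibble (as from [simulate_population()]).
#' @param path File path.
#' @param include_truth Keep `true_*` columns (for recovery testing)?
#' @return `write_capture_history` returns `path` invisibly;
#'   `read_capture_history` returns a validated tibble.
#' @export
write_capture_history <- function(data, path, include_truth = TRUE) {
  keep <- c("individual_id", "entry_year", "year", "age", "detected", "state", "count")
  if (include_truth) keep <- c(keep, grep("^true_", names(data), value = TRUE))
  out <- as.data.frame(data[, intersect(keep, names(data))])
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_capture_history
#' @export
read_capture_history <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  req <- c("individual_id", "year", "detected", "state")
  miss <- setdiff(req, names(out))
  if (length(miss)) {
    stop("capture-history file lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(out) == 0) return(tibble::as_tibble(out))
  line <- seq_len(nrow(out)) + 1L # header is line 1
  bad <- which(!out$detected %in% c(0L, 1L))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": detected must be 0 or 1", call. = FALSE)
  }
  bad <- which(out$detected == 1L & is.na(out$state))
  if (length(bad)) {
    stop("line ", line[bad[1]], ": detected individual without a recorded state",
      call. = FALSE
    )
  }
  bad <- which(out$detected == 1L & out$state == "dead")
  if (length(bad)) {
    stop("line ", line[bad[1]], ": detected individual cannot be in state 'dead'",
      call. = FALSE
    )
  }
  bad <- which(!is.na(out$state) & !out$state %in% .vc_states)
  if (length(bad)) {
    stop("line ", line[bad[1]], ": unknown state '", out$state[bad[1]], "'",
      call. = FALSE
    )
  }
  if ("count" %in% names(out)) {
    bad <- which(!is.na(out$count) & out$detected == 1L &
      out$state != "successful_breeder")
    if (length(bad)) {
      stop("line ", line[bad[1]],
        ": offspring count recorded for a non-successful state",
        call. = FALSE
      )
    }
  }
  tibble::as_tibble(out)
}

#' Read and write simulation/model configuration YAML
#'
#' A simulation config has blocks `vital_rates` (with a nested `config`
#' describing the model structure), `covariance` and `design`
#' (`n_years`, `recruits_per_year`, `seed`).
#'
#' @param path YAML file path.
#' @return `read_sim_config`: list with `vr` ([vital_rate_model()]),
#'   `cov` ([covariance_structure()]) and `design`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfgy <- y$vital_rates$config
  config <- model_config(
    active_params = cfgy$active_params,
    age_breaks = cfgy$age_breaks,
    bs_effects_on = cfgy$bs_effects_on %||% character(),
    productivity_family = cfgy$productivity_family,
    correlation_type = cfgy$correlation_type %||% 1,
    pre_breeder = cfgy$pre_breeder %||% FALSE,
    breeding_from_age = cfgy$breeding_from_age %||% 1L,
    detection_year_effect = cfgy$detection_year_effect %||% TRUE
  )
  vry <- y$vital_rates
  vr <- vital_rate_model(
    config,
    mu = unlist(vry$mu),
    age_effects = vry$age_effects,
    bs_effects = lapply(vry$bs_effects, unlist),
    sigma_omega_resid = vry$sigma_omega_resid
  )
  cv <- y$covariance
  k <- length(cv$sigma)
  corr <- if (is.null(cv$corr)) diag(k) else matrix(unlist(cv$corr), k, k, byrow = TRUE)
  cov <- covariance_structure(
    sigma = unlist(cv$sigma), corr = corr,
    sigma_p = cv$sigma_p %||% 0
  )
  list(vr = vr, cov = cov, design = y$design)
}

#' @rdname read_sim_config
#' @param sim List with `vr`, `cov`, `design` (as from [read_sim_config()]).
#' @export
write_sim_config <- function(sim, path) {
  vr <- sim$vr
  cfg <- vr$config
  y <- list(
    vital_rates = list(
      config = list(
        active_params = cfg$active_params,
        age_breaks = cfg$age_breaks,
        bs_effects_on = cfg$bs_effects_on,
        productivity_family = cfg$productivity_family,
        correlation_type = cfg$correlation_type,
        pre_breeder = cfg$pre_breeder,
        breeding_from_age = cfg$breeding_from_age,
        detection_year_effect = cfg$detection_year_effect
      ),
      mu = vr$mu,
      age_effects = vr$age_effects,
      bs_effects = lapply(vr$bs_effects[cfg$bs_effects_on], as.list),
      sigma_omega_resid = vr$sigma_omega_resid
    ),
    covariance = list(
      sigma = as.list(sim$cov$sigma),
      corr = apply(sim$cov$corr, 1, as.list),
      sigma_p = sim$cov$sigma_p
    ),
    design = sim$design
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
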