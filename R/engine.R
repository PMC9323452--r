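# Bridge between the R-level model objects and the compiled likelihood /
# sampler engine. The engine works on a flat parameter vector theta; the
# layout below assigns one slot to every model quantity (fixed slots keep
# their value and are never proposed, so reference levels stay at 0).

build_engine <- function(config, n_years) {
  stopifnot(inherits(config, "vc_config"))
  ls <- live_states(config)
  S <- length(ls)
  codes <- setNames(seq_along(ls) - 1L, ls)
  ab <- config$age_breaks
  A <- max(unlist(ab), config$breeding_from_age)
  K <- length(config$active_params)
  colof <- function(p) {
    i <- match(p, config$active_params)
    if (is.na(i)) -1L else i - 1L
  }
  cls <- function(rate) as.integer(age_class_of(seq_len(A), ab[[rate]]))

  m <- vapply(.vc_rate_names, function(r) n_age_classes(config, r), integer(1))
  pos <- 0L
  take <- function(n) {
    out <- pos + seq_len(n)
    pos <<- pos + n
    out
  }
  i_mu <- setNames(take(5L), .vc_rate_names)
  i_f <- lapply(setNames(.vc_rate_names, .vc_rate_names), function(r) take(m[[r]]))
  gnames <- c("phi", "psi", "pi", "p")
  i_g <- lapply(setNames(gnames, gnames), function(r) setNames(take(S), ls))
  i_logsigom <- take(1L)
  i_alpha <- matrix(take(n_years * K), n_years, K,
    dimnames = list(NULL, config$active_params)
  )
  i_alphap <- if (config$detection_year_effect) take(n_years) else integer()
  i_L <- take(K * (K + 1L) / 2L)
  i_logdelta <- take(K)
  i_logsigp <- if (config$detection_year_effect) take(1L) else integer()
  n_theta <- pos

  layout <- list(
    i_mu = i_mu, i_f = i_f, i_g = i_g, i_logsigom = i_logsigom,
    i_alpha = i_alpha, i_alphap = i_alphap, i_L = i_L,
    i_logdelta = i_logdelta, i_logsigp = i_logsigp, n_theta = n_theta,
    n_classes = m, states = ls
  )

  list(
    T = as.integer(n_years), S = S, A = as.integer(A), K = as.integer(K),
    ctype = config$correlation_type,
    family = match(config$productivity_family, .vc_families) - 1L,
    bfa = config$breeding_from_age,
    det_year = as.integer(config$detection_year_effect),
    pre = unname(codes["pre_breeder"] %|NA|% -1L),
    non = unname(codes["non_breeder"] %|NA|% -1L),
    fail = unname(codes["failed_breeder"] %|NA|% -1L),
    succ = unname(codes["successful_breeder"]),
    col_psi = colof("psi"), col_pi = colof("pi"), col_om = colof("omega"),
    cls_phi = cls("phi"), cls_psi = cls("psi"), cls_pi = cls("pi"),
    cls_om = cls("omega"), cls_p = cls("p"),
    i_mu = unname(i_mu) - 1L,
    i_fphi = i_f$phi - 1L, i_fpsi = i_f$psi - 1L, i_fpi = i_f$pi - 1L,
    i_fom = i_f$omega - 1L, i_fp = i_f$p - 1L,
    i_gphi = unname(i_g$phi) - 1L, i_gpsi = unname(i_g$psi) - 1L,
    i_gpi = unname(i_g$pi) - 1L, i_gp = unname(i_g$p) - 1L,
    i_logsigom = i_logsigom - 1L,
    i_alpha0 = i_alpha[1, 1] - 1L,
    i_alphap0 = if (length(i_alphap)) i_alphap[1] - 1L else -1L,
    i_L0 = i_L[1] - 1L,
    L_row = row(diag(K))[lower.tri(diag(K), diag = TRUE)] - 1L,
    L_col = col(diag(K))[lower.tri(diag(K), diag = TRUE)] - 1L,
    i_logdelta0 = i_logdelta[1] - 1L,
    i_logsigp = if (length(i_logsigp)) i_logsigp - 1L else -1L,
    layout = layout, state_codes = codes
  )
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Pack observed capture histories into flat integer arrays for the
# engine. Only detection events are needed: any year between first and
# last detection without a detection row is an undetected year, and the
# years after the last detection are summarised by the
# probability-of-no-future-detection term.
pack_data <- function(data, config, n_years) {
  codes <- setNames(
    seq_along(live_states(config)) - 1L,
    live_states(config)
  )
  det <- data[data$detected == 1, , drop = FALSE]
  if (nrow(det) == 0) {
    return(list(
      ids = integer(), n = 0L, entry = integer(), entry_age = integer(),
      entry_state = integer(), tlast = integer(), off = integer(),
      obs_det = integer(), obs_state = integer(), obs_count = integer()
    ))
  }
  if (any(!det$state %in% names(codes))) {
    bad <- setdiff(unique(det$state), names(codes))
    stop("observed state(s) not in the configured state space: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  det <- det[det$year <= n_years, , drop = FALSE]
  ord <- order(det$individual_id, det$year)
  det <- det[ord, , drop = FALSE]
  has_age <- "age" %in% names(det)
  split_idx <- split(seq_len(nrow(det)), det$individual_id)
  n <- length(split_idx)
  ids <- as.vector(vapply(split_idx, function(ix) det$individual_id[ix[1]],
    det$individual_id[1]
  ))
  entry <- integer(n)
  entry_age <- integer(n)
  entry_state <- integer(n)
  tlast <- integer(n)
  off <- integer(n)
  obs_det <- integer(0)
  obs_state <- integer(0)
  obs_count <- integer(0)
  dlist <- vector("list", n)
  pos <- 0L
  for (k in seq_len(n)) {
    ix <- split_idx[[k]]
    yrs <- det$year[ix]
    entry[k] <- yrs[1]
    tlast[k] <- yrs[length(yrs)]
    entry_state[k] <- codes[[det$state[ix[1]]]]
    entry_age[k] <- if (has_age) as.integer(det$age[ix[1]]) else 0L
    len <- tlast[k] - entry[k]
    off[k] <- pos
    if (len > 0) {
      d <- integer(len)
      s <- rep(-1L, len)
      cnt <- rep(-1L, len)
      j <- yrs[-1] - entry[k]
      d[j] <- 1L
      s[j] <- codes[det$state[ix[-1]]]
      if ("count" %in% names(det)) {
        cv <- det$count[ix[-1]]
        cnt[j][!is.na(cv)] <- as.integer(cv[!is.na(cv)])
      }
      dlist[[k]] <- list(d = d, s = s, cnt = cnt)
      pos <- pos + len
    }
  }
  obs <- purrr::compact(dlist)
  list(
    ids = ids, n = n, entry = entry, entry_age = entry_age,
    entry_state = entry_state, tlast = tlast, off = off,
    obs_det = unlist(lapply(obs, `[[`, "d")) %||% integer(),
    obs_state = unlist(lapply(obs, `[[`, "s")) %||% integer(),
    obs_count = unlist(lapply(obs, `[[`, "cnt")) %||% integer()
  )
}

# Fill a theta vector from simulation-truth objects (for likelihood
# evaluation; the covariance working parameters are not needed there).
build_theta <- function(vr, effects, engine) {
  lay <- engine$layout
  config <- vr$config
  theta <- numeric(lay$n_theta)
  for (r in .vc_rate_names) {
    theta[lay$i_mu[[r]]] <- vr$mu[[r]] %||% 0
    theta[lay$i_f[[r]]] <- vr$age_effects[[r]]
  }
  for (r in c("phi", "psi", "pi", "p")) {
    theta[lay$i_g[[r]]] <- vr$bs_effects[[r]][lay$states]
  }
  theta[lay$i_logsigom] <- log(vr$sigma_omega_resid %||% 1)
  theta[lay$i_alpha] <- effects$alpha[, config$active_params, drop = FALSE]
  if (length(lay$i_alphap)) {
    theta[lay$i_alphap] <- effects$alpha_p
    theta[lay$i_logsigp] <- 0
  }
  theta[lay$i_logdelta] <- 0
  # identity loading matrix: log(1) = 0 diagonals, 0 off-diagonals
  theta[lay$i_L] <- 0
  theta
}
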