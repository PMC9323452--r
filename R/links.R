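#' Inverse link functions
#'
#' Maps a linear predictor from the link scale back to the response scale.
#' Survival, breeding, success and detection probabilities use the logit
#' link; productivity uses logit, identity or log depending on the
#' configured family.
#'
#' @param x Numeric vector on the link scale.
#' @param link One of `"logit"`, `"log"`, `"identity"`.
#' @return Numeric vector on the response scale: in (0, 1) for `"logit"`,
#'   positive for `"log"`, unchanged for `"identity"`.
#' @examples
#' inverse_link(0, "logit")   # 0.5
#' inverse_link(0, "log")     # 1
#' @export
inverse_link <- function(x, link = c("logit", "log", "identity")) {
  link <- match.arg(link)
  switch(link,
    logit = plogis(x),
    log = exp(x),
    identity = x
  )
}

link_for_family <- function(family) {
  switch(family,
    bernoulli_extra_offspring = "logit",
    truncated_normal = "identity",
    truncated_poisson = "log",
    fixed_one = "identity",
    stop("unknown productivity family: ", family, call. = FALSE)
  )
}
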