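#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy variance-component estimates
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `variance` and `share_pct`.
#' @export
tidy.reml_fit <- function(x, ...) x$components

#' @rdname tidy.reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n_obs = x$n_obs, converged = x$converged,
    iterations = x$iterations,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy a heritability conversion
#'
#' @param x An `h2_result`.
#' @param ... Unused.
#' @return The provenance tibble (`step`, `formula`, `value`).
#' @export
tidy.h2_result <- function(x, ...) x$provenance

#' @rdname tidy.h2_result
#' @export
glance.h2_result <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, V_A = x$V_A, V_D = x$V_D, V_Ec = x$V_Ec, V_e = x$V_e,
    V_P = x$V_P, v_p_mode = x$v_p_mode,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy the binomial mixed model
#'
#' @param x A `binomial_mixed_fit`.
#' @param ... Unused.
#' @return Coefficient tibble.
#' @export
tidy.binomial_mixed_fit <- function(x, ...) x$coefficients

#' @rdname tidy.binomial_mixed_fit
#' @export
glance.binomial_mixed_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    dispersion = x$dispersion, n_obs = x$n_obs, converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy life-history model fits
#'
#' @param x A `fecundity_fit` or `hatch_fit`.
#' @param ... Unused.
#' @return Coefficient tibble.
#' @export
tidy.fecundity_fit <- function(x, ...) x$coefficients

#' @rdname tidy.fecundity_fit
#' @export
glance.fecundity_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, theta = x$theta, nobs = x$nobs, mode = x$mode,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname tidy.fecundity_fit
#' @export
tidy.hatch_fit <- function(x, ...) x$coefficients

#' @rdname tidy.fecundity_fit
#' @export
glance.hatch_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, overdispersion = x$overdispersion, nobs = x$nobs,
    flags = paste(x$flags, collapse = ";")
  )
}
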