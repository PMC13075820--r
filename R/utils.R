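#' @importFrom rlang abort warn %||% .data
#' @importFrom stats var sd qt qbeta qlogis plogis pchisq rnorm rbinom rpois
#'   rnbinom rbeta rmultinom model.matrix as.formula coef vcov logLik glm
#'   binomial poisson setNames optim qnorm dbinom prop.test fitted deviance
#' @importFrom utils head
NULL

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_nonneg <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}

check_that <- function(ok, msg) if (!ok) abort(msg)

# zero-padded id labels: id_labels("D", 3) -> "D1" "D2" "D3"
id_labels <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(n)), "d"), seq_len(n))
}

# sub-seed for a pipeline stage, kept within 32-bit integer range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
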