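#' Additive genetic variance from the sire component
#'
#' Under haplodiploidy sires are haploid and transmit their entire genome, so
#' the among-sire variance equals half the additive genetic variance:
#' `V_A = 2 * var_sire`.
#'
#' @param var_sire Non-negative sire variance component.
#' @return `V_A`.
#' @export
#' @examples
#' additive_variance(0.5)
additive_variance <- function(var_sire) {
  check_that(is_nonneg(var_sire), "`var_sire` must be a non-negative variance")
  2 * var_sire
}

#' Dominance variance from the dam component
#'
#' The among-dam variance mixes additive, dominance and common-environment
#' variance: `var_dam = V_A / 4 + V_D / 2 + V_Ec`. Rearranged,
#' `V_D = 2 * (var_dam - V_A / 4 - V_Ec)`. Sampling noise routinely makes
#' this method-of-moments estimate negative, in which case it is truncated to
#' zero and flagged.
#'
#' @param var_dam,V_A,V_Ec Non-negative variances.
#' @return `V_D` with attribute `truncated` (logical).
#' @export
#' @examples
#' dominance_variance(var_dam = 0.3, V_A = 0.4, V_Ec = 0.1) # 0.2
dominance_variance <- function(var_dam, V_A, V_Ec) {
  for (nm in c("var_dam", "V_A", "V_Ec")) {
    check_that(is_nonneg(get(nm)), paste0("`", nm, "` must be a non-negative variance"))
  }
  vd <- 2 * (var_dam - V_A / 4 - V_Ec)
  truncated <- vd < 0
  structure(max(vd, 0), truncated = truncated)
}

#' Narrow-sense heritability
#'
#' `h2 = V_A / V_P` with phenotypic variance `V_P = V_A + V_D + V_e`.
#'
#' @param V_A,V_D,V_e Non-negative variances, not all zero.
#' @return `h2` in \[0, 1\].
#' @export
#' @examples
#' narrow_sense_h2(V_A = 1, V_D = 0.5, V_e = 0.5) # 0.5
narrow_sense_h2 <- function(V_A, V_D, V_e) {
  for (nm in c("V_A", "V_D", "V_e")) {
    check_that(is_nonneg(get(nm)), paste0("`", nm, "` must be a non-negative variance"))
  }
  V_P <- V_A + V_D + V_e
  if (V_P <= 0) abort("heritability undefined: all variance components are zero")
  V_A / V_P
}

#' Haplodiploid-adjusted heritability from fitted variance components
#'
#' Chains the haplodiploid sib-analysis conversion: common-environment
#' variance is taken as the block plus plant components
#' (`V_Ec = var_block + var_plant`), `V_A = 2 * var_sire`,
#' `V_D = 2 * (var_dam - V_A / 4 - V_Ec)` truncated at zero, and
#' `h2 = V_A / (V_A + V_D + V_e)` with `V_e` the residual. The default
#' (`v_p_mode = "narrow"`) phenotypic variance excludes the block and plant
#' components, following the conversion formulas literally;
#' `v_p_mode = "broad"` adds them for sensitivity analysis.
#'
#' @param vc A [fit_reml()] result or a data frame / named vector of
#'   variances with components for dam, sire, block, plant and residual.
#' @param dam,sire,block,plant,residual Term names in `vc`.
#' @param v_p_mode `"narrow"` (`V_P = V_A + V_D + V_e`) or `"broad"`
#'   (`V_P` additionally includes `V_Ec`).
#' @return An object of class `h2_result`: variances `V_A`, `V_D`, `V_Ec`,
#'   `V_e`, `V_P`, the heritability `h2`, flags, and a step-by-step
#'   `provenance` tibble recording each formula applied.
#' @export
#' @examples
#' h2_pipeline(c(dam_id = 0.45, sire_id = 0.13, block_id = 0.09,
#'               plant_id = 0.06, residual = 0.24))
h2_pipeline <- function(vc, dam = "dam_id", sire = "sire_id",
                        block = "block_id", plant = "plant_id",
                        residual = "residual",
                        v_p_mode = c("narrow", "broad")) {
  v_p_mode <- match.arg(v_p_mode)
  flags <- character(0)
  if (inherits(vc, "reml_fit")) {
    if (!vc$converged) abort("variance-component fit did not converge")
    flags <- vc$flags
    v <- setNames(vc$components$variance, vc$components$term)
  } else if (is.data.frame(vc)) {
    v <- setNames(vc$variance, vc$term)
  } else {
    v <- vc
  }
  need <- c(dam, sire, block, plant, residual)
  miss <- setdiff(need, names(v))
  if (length(miss) > 0) abort(paste0("missing variance component(s): ", paste(miss, collapse = ", ")))

  V_Ec <- unname(v[block] + v[plant])
  V_A <- additive_variance(unname(v[sire]))
  V_D <- dominance_variance(unname(v[dam]), V_A, V_Ec)
  if (attr(V_D, "truncated")) flags <- c(flags, "dominance_truncated")
  V_D <- as.numeric(V_D)
  V_e <- unname(v[residual])
  V_P <- V_A + V_D + V_e + if (v_p_mode == "broad") V_Ec else 0
  h2 <- if (V_P > 0) V_A / V_P else NA_real_
  if (V_P <= 0) flags <- c(flags, "zero_phenotypic_variance")

  provenance <- tibble::tibble(
    step = c("V_Ec", "V_A", "V_D", "V_e", "V_P", "h2"),
    formula = c(
      "var_block + var_plant",
      "2 * var_sire",
      "max(0, 2 * (var_dam - V_A/4 - V_Ec))",
      "var_residual",
      if (v_p_mode == "narrow") "V_A + V_D + V_e" else "V_A + V_D + V_e + V_Ec",
      "V_A / V_P"
    ),
    value = c(V_Ec, V_A, V_D, V_e, V_P, h2)
  )
  structure(
    list(V_A = V_A, V_D = V_D, V_Ec = V_Ec, V_e = V_e, V_P = V_P, h2 = h2,
         v_p_mode = v_p_mode, flags = unique(flags), provenance = provenance),
    class = "h2_result"
  )
}

#' @export
print.h2_result <- function(x, digits = 4, ...) {
  cat("Haplodiploid-adjusted narrow-sense heritability\n")
  cat(sprintf("  h2 = %.3f  (V_A = %.4g, V_D = %.4g, V_Ec = %.4g, V_e = %.4g, V_P[%s] = %.4g)\n",
              x$h2, x$V_A, x$V_D, x$V_Ec, x$V_e, x$v_p_mode, x$V_P))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-call heritability from a survival table
#'
#' Filters one treatment arm, fits the variance-component model to the
#' family proportion dead, and chains the haplodiploid conversion.
#'
#' @param surv A family survival table.
#' @param treatment Arm to analyse.
#' @param ... Passed to [h2_pipeline()].
#' @return An `h2_result`.
#' @export
#' @examples
#' surv <- simulate_survival_data(config_for_h2(0.3, seed = 1))
#' estimate_h2(surv)$h2
estimate_h2 <- function(surv, treatment = "exposed", ...) {
  d <- surv[surv$treatment == treatment, , drop = FALSE]
  check_that(nrow(d) > 0, paste0("no rows for treatment '", treatment, "'"))
  h2_pipeline(fit_reml(d, n_dead_day10 / n_nymphs), ...)
}
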