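#' Plot variance shares
#'
#' Bar chart of the percent of variance attributed to each random term.
#'
#' @param object A `reml_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reml_fit <- function(object, ...) {
  d <- object$components
  d$term <- stats::reorder(d$term, -d$share_pct)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$share_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of variance",
                  title = "REML variance components") +
    ggplot2::theme_minimal()
}

#' Per-family mortality by treatment
#'
#' Points are family-replicate percent mortality at day 10; horizontal lines
#' give the pooled mean with its exact binomial interval per arm.
#'
#' @param surv A family survival table.
#' @return A ggplot.
#' @export
plot_family_survival <- function(surv) {
  validate_survival_table(surv)
  pooled <- surv |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(dead = sum(.data$n_dead_day10), total = sum(.data$n_nymphs),
                     .groups = "drop")
  ci <- binom_ci(pooled$dead, pooled$total)
  pooled <- dplyr::bind_cols(pooled, ci[c("estimate", "lower", "upper")])
  ggplot2::ggplot(surv, ggplot2::aes(x = .data$family_id,
                                     y = 100 * .data$n_dead_day10 / .data$n_nymphs)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dam_id), show.legend = FALSE,
                        alpha = 0.8) +
    ggplot2::geom_hline(data = pooled, ggplot2::aes(yintercept = 100 * .data$estimate)) +
    ggplot2::geom_hline(data = pooled, ggplot2::aes(yintercept = 100 * .data$lower),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = pooled, ggplot2::aes(yintercept = 100 * .data$upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "family", y = "% dead at day 10") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Eggs laid per disk day by treatment
#'
#' @param life A life-history table.
#' @return A ggplot.
#' @export
plot_fecundity <- function(life) {
  validate_life_history_table(life)
  ggplot2::ggplot(life, ggplot2::aes(x = factor(.data$disk_day),
                                     y = .data$eggs_laid,
                                     fill = .data$treatment)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = "disk day", y = "eggs laid", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Hatching by day post-laying
#'
#' Percent of eggs hatching on each observation day, by treatment.
#'
#' @param life A life-history table.
#' @return A ggplot.
#' @export
plot_hatch <- function(life) {
  validate_life_history_table(life)
  d <- summarize_costs(life)$hatch_by_day
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$day),
                                  y = 100 * .data$proportion,
                                  fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "day post-laying", y = "% of eggs hatching", fill = NULL) +
    ggplot2::theme_minimal()
}
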