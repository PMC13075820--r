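#' Generate the breeding-design skeleton
#'
#' Lays out the family structure of the survival experiment without outcomes:
#' every dam-sire family appears in both treatment arms (family-matched
#' replicates), replicates are assigned to plants (and thereby blocks)
#' round-robin, and nymph counts per replicate are drawn Poisson (truncated
#' at 1) around `nymphs_per_family_mean`. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `family_id`, `dam_id`, `sire_id`,
#'   `block_id`, `plant_id`, `replicate`, `treatment`, `n_nymphs` and
#'   `n_dead_day10` (all `NA`: no outcomes yet).
#' @export
#' @examples
#' generate_design(sim_config(n_sires = 4, seed = 7))
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_fam <- config$n_sires * config$n_dams_per_sire
  check_that(n_fam >= 1, "design must contain at least one family")

  sire <- rep(seq_len(config$n_sires), each = config$n_dams_per_sire)
  dam <- seq_len(n_fam)
  fam <- tibble::tibble(
    family_id = id_labels("F", n_fam),
    dam_id = id_labels("D", n_fam)[dam],
    sire_id = id_labels("S", config$n_sires)[sire]
  )

  des <- tidyr::expand_grid(
    fam,
    treatment = c("control", "exposed"),
    replicate = seq_len(config$n_reps_per_family)
  )
  # round-robin plant assignment within each arm, over the
  # n_blocks x n_plants_per_block grid, so both arms span all plants
  n_plants <- config$n_blocks * config$n_plants_per_block
  plant_idx <- integer(nrow(des))
  for (tr in unique(des$treatment)) {
    rows <- which(des$treatment == tr)
    plant_idx[rows] <- (seq_along(rows) - 1L) %% n_plants + 1L
  }
  block_idx <- (plant_idx - 1L) %/% config$n_plants_per_block + 1L
  des$plant_id <- id_labels("P", n_plants)[plant_idx]
  des$block_id <- id_labels("B", config$n_blocks)[block_idx]

  des$n_nymphs <- withr::with_seed(
    stage_seed(config$seed, 101L),
    pmax(1L, rpois(nrow(des), config$nymphs_per_family_mean))
  )
  des$n_dead_day10 <- NA_integer_
  dplyr::select(
    des, "family_id", "dam_id", "sire_id", "block_id", "plant_id",
    "replicate", "treatment", "n_nymphs", "n_dead_day10"
  )
}

#' Draw latent family effects
#'
#' Draws the Gaussian random effects implied by the haplodiploid sib model:
#' sire effects with variance `V_A / 2` (haploid sires transmit their whole
#' genome), dam effects with variance `V_A / 4 + V_D / 2` plus the dam share
#' of `V_Ec`, and block and plant effects with their shares of `V_Ec`. Zero
#' variances give exactly zero effects.
#'
#' @param config A [sim_config()].
#' @return A list of class `family_effects` with tibbles `sire`, `dam`,
#'   `block`, `plant` (id and `effect` columns) and the per-level variances
#'   used, in `target_variances`.
#' @export
simulate_family_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_fam <- config$n_sires * config$n_dams_per_sire
  n_plants <- config$n_blocks * config$n_plants_per_block
  v <- c(
    sire = config$V_A / 2,
    dam = config$V_A / 4 + config$V_D / 2 + config$ec_share[["dam"]] * config$V_Ec,
    block = config$ec_share[["block"]] * config$V_Ec,
    plant = config$ec_share[["plant"]] * config$V_Ec
  )
  draw <- function(n, var) if (var <= 0) rep(0, n) else rnorm(n, 0, sqrt(var))
  eff <- withr::with_seed(stage_seed(config$seed, 202L), list(
    sire = tibble::tibble(sire_id = id_labels("S", config$n_sires),
                          effect = draw(config$n_sires, v[["sire"]])),
    dam = tibble::tibble(dam_id = id_labels("D", n_fam),
                         effect = draw(n_fam, v[["dam"]])),
    block = tibble::tibble(block_id = id_labels("B", config$n_blocks),
                           effect = draw(config$n_blocks, v[["block"]])),
    plant = tibble::tibble(plant_id = id_labels("P", n_plants),
                           effect = draw(n_plants, v[["plant"]]))
  ))
  eff$target_variances <- v
  structure(eff, class = "family_effects")
}

#' Simulate day-10 survival outcomes
#'
#' Combines the design skeleton with latent effects: each replicate's
#' survival probability is the inverse link of the treatment baseline plus
#' its sire, dam, block and plant effects plus a residual draw with variance
#' `V_e`; deaths are binomial. Under the identity link probabilities are
#' clamped to \[0, 1\].
#'
#' @param skeleton Output of [generate_design()].
#' @param effects Output of [simulate_family_effects()] from the same config.
#' @param config The [sim_config()] both were built from.
#' @return The skeleton tibble with `n_dead_day10` filled in.
#' @export
simulate_survival <- function(skeleton, effects, config) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "family_effects"))
  d <- skeleton
  eta <- effects$sire$effect[match(d$sire_id, effects$sire$sire_id)] +
    effects$dam$effect[match(d$dam_id, effects$dam$dam_id)] +
    effects$block$effect[match(d$block_id, effects$block$block_id)] +
    effects$plant$effect[match(d$plant_id, effects$plant$plant_id)]
  base <- ifelse(d$treatment == "exposed",
                 config$baseline_survival_exposed,
                 config$baseline_survival_control)
  withr::with_seed(stage_seed(config$seed, 303L), {
    resid <- if (config$V_e > 0) rnorm(nrow(d), 0, sqrt(config$V_e)) else 0
    p_survive <- if (config$link == "logit") {
      plogis(qlogis(clamp(base, 1e-12, 1 - 1e-12)) + eta + resid)
    } else {
      clamp(base + eta + resid)
    }
    d$n_dead_day10 <- rbinom(nrow(d), d$n_nymphs, 1 - p_survive)
  })
  d
}

#' Simulate a complete family survival table
#'
#' Chains [generate_design()], [simulate_family_effects()] and
#' [simulate_survival()] under one seed lineage.
#'
#' @param config A [sim_config()].
#' @return A family survival tibble.
#' @export
#' @examples
#' simulate_survival_data(sim_config(n_sires = 5, seed = 3))
simulate_survival_data <- function(config) {
  simulate_survival(generate_design(config),
                    simulate_family_effects(config), config)
}

# beta-binomial draws parameterised by mean p and intra-class correlation rho
rbetabinom <- function(n, size, p, rho) {
  if (rho <= 0) return(rbinom(n, size, p))
  theta <- (1 - rho) / rho
  pp <- rbeta(n, p * theta, (1 - p) * theta)
  rbinom(n, size, pp)
}

#' Simulate the life-history (fecundity and hatching) experiment
#'
#' One row per pair and disk day: eggs laid are negative binomial around a
#' pair-specific mean (log-normal pair effect, treatment-specific totals
#' spread over disk days), the number eventually hatching is beta-binomial,
#' and hatch days are assigned from the configured hatch-day distribution.
#' Cumulative hatch counts are reported for each observation day.
#'
#' @param config A [sim_config()]; only its `life_history` part and seed are
#'   used.
#' @return A tibble with columns `plant_id`, `replicate_id`, `treatment`,
#'   `disk_day`, `eggs_laid` and one cumulative `hatched_day<d>` column per
#'   observation day.
#' @export
#' @examples
#' life <- simulate_life_history(sim_config(seed = 9))
#' dplyr::count(life, treatment)
simulate_life_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lh <- config$life_history
  days <- as.integer(names(lh$hatch_day_probs))
  shape <- lh$disk_day_weights / mean(lh$disk_day_weights)

  pairs <- tidyr::expand_grid(
    treatment = c("control", "exposed"),
    plant = seq_len(lh$n_plants_per_arm),
    pair = seq_len(lh$n_pairs_per_plant)
  )
  pairs$plant_id <- paste0(ifelse(pairs$treatment == "control", "LC", "LE"),
                           sprintf("%02d", pairs$plant))
  pairs$replicate_id <- paste0(pairs$plant_id, ".", pairs$pair)

  withr::with_seed(stage_seed(config$seed, 404L), {
    pair_mult <- if (lh$sigma_pair > 0) {
      exp(rnorm(nrow(pairs), -lh$sigma_pair^2 / 2, lh$sigma_pair))
    } else {
      rep(1, nrow(pairs))
    }
    rows <- tidyr::expand_grid(pairs, disk_day = seq_len(lh$n_disks))
    rows$pair_mult <- rep(pair_mult, each = lh$n_disks)
    mean_total <- ifelse(rows$treatment == "control",
                         lh$mean_total_eggs_control, lh$mean_total_eggs_exposed)
    mu <- mean_total / lh$n_disks * shape[rows$disk_day] * rows$pair_mult
    rows$eggs_laid <- if (is.infinite(lh$nb_size)) {
      rpois(nrow(rows), mu)
    } else {
      rnbinom(nrow(rows), mu = mu, size = lh$nb_size)
    }
    p_hatch <- ifelse(rows$treatment == "control",
                      lh$hatch_prob_control, lh$hatch_prob_exposed)
    n_hatch <- rbetabinom(nrow(rows), rows$eggs_laid, p_hatch,
                          lh$hatch_overdispersion)
    by_day <- vapply(seq_len(nrow(rows)), function(i) {
      if (n_hatch[i] == 0) return(integer(length(days)))
      as.integer(rmultinom(1, n_hatch[i], lh$hatch_day_probs))
    }, integer(length(days)))
    cum <- apply(rbind(by_day), 2, cumsum)
    cum <- matrix(cum, nrow = length(days))
    for (j in seq_along(days)) {
      rows[[paste0("hatched_day", days[j])]] <- as.integer(cum[j, ])
    }
  })
  dplyr::select(rows, "plant_id", "replicate_id", "treatment", "disk_day",
                "eggs_laid", dplyr::starts_with("hatched_day"))
}
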