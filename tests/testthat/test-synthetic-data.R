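test_that("generate_design lays out families, treatments and round-robin plants", {
  # study-scale default: 35 full-sib families, every family in both arms
  des35 <- generate_design(sim_config(n_sires = 35, seed = 1))
  expect_equal(length(unique(des35$family_id)), 35)
  expect_true(check_family_matching(des35))

  # single family, single plant
  des1 <- generate_design(sim_config(n_sires = 1, n_blocks = 1,
                                     n_plants_per_block = 1, seed = 1))
  expect_equal(nrow(des1), 2) # one row per treatment
  expect_equal(unique(des1$plant_id), "P01")

  # half-sib: 10 sires x 3 dams -> 30 families, 3 rows per sire per arm
  des30 <- generate_design(sim_config(n_sires = 10, n_dams_per_sire = 3, seed = 1))
  expect_equal(length(unique(des30$family_id)), 30)
  tab <- table(des30$sire_id, des30$treatment)
  expect_true(all(tab == 3))

  # deterministic given the seed
  expect_identical(des30, generate_design(sim_config(n_sires = 10, n_dams_per_sire = 3, seed = 1)))
})

test_that("latent effects match their closed-form variances", {
  # zero variance -> exactly zero effects
  eff0 <- simulate_family_effects(sim_config(V_A = 0, V_D = 0, V_Ec = 0, seed = 3))
  expect_true(all(eff0$sire$effect == 0))
  expect_true(all(eff0$dam$effect == 0))
  expect_true(all(eff0$block$effect == 0))

  # sire variance = V_A / 2 at n = 1e5 (within 3 Monte-Carlo SEs)
  cfg_s <- sim_config(n_sires = 100000, V_A = 0.8, seed = 11)
  vs <- var(simulate_family_effects(cfg_s)$sire$effect)
  tol_s <- 3 * 0.4 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(vs - 0.4), tol_s)

  # dam variance = V_A/4 + V_D/2 + V_Ec (common environment carried by the
  # family) at n = 1e5
  cfg_d <- sim_config(n_sires = 100000, V_A = 0.4, V_D = 0.2, V_Ec = 0.1,
                      ec_share = c(dam = 1, block = 0, plant = 0), seed = 12)
  vd <- var(simulate_family_effects(cfg_d)$dam$effect)
  tol_d <- 3 * 0.3 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(vd - 0.3), tol_d)

  # block and plant carry their configured V_Ec shares
  cfg_b <- sim_config(n_blocks = 200, n_plants_per_block = 100, V_Ec = 0.5,
                      ec_share = c(dam = 0, block = 0.4, plant = 0.6), seed = 13)
  eff_b <- simulate_family_effects(cfg_b)
  expect_lt(abs(var(eff_b$plant$effect) - 0.3), 3 * 0.3 * sqrt(2 / (2e4 - 1)))
})

test_that("survival outcomes follow the configured probabilities", {
  # perfect survival, no variance -> zero deaths
  cfg1 <- sim_config(n_sires = 20, V_A = 0, V_D = 0, V_Ec = 0, V_e = 0,
                     baseline_survival_control = 1, baseline_survival_exposed = 1,
                     seed = 4)
  expect_true(all(simulate_survival_data(cfg1)$n_dead_day10 == 0))

  # pooled survival matches the study-anchored baselines at large n
  cfg2 <- sim_config(n_sires = 2000, V_A = 0, V_D = 0, V_Ec = 0, V_e = 0,
                     baseline_survival_control = 0.97,
                     baseline_survival_exposed = 0.30, seed = 5)
  surv <- simulate_survival_data(cfg2)
  pooled <- tapply(1 - surv$n_dead_day10 / surv$n_nymphs, surv$treatment, mean)
  expect_lt(abs(pooled[["exposed"]] - 0.30), 0.01)
  expect_lt(abs(pooled[["control"]] - 0.97), 0.01)

  # binomial expectation: p_survive 0.5, 20 nymphs -> mean deaths 10
  cfg3 <- sim_config(n_sires = 5000, V_A = 0, V_D = 0, V_Ec = 0, V_e = 0,
                     baseline_survival_control = 0.5,
                     baseline_survival_exposed = 0.5, seed = 6)
  skel <- generate_design(cfg3)
  skel$n_nymphs <- 20L
  out <- simulate_survival(skel, simulate_family_effects(cfg3), cfg3)
  expect_lt(abs(mean(out$n_dead_day10) - 10), 3 * sqrt(5) / sqrt(nrow(out)))

  # deaths never exceed nymphs; identical seeds give identical tables
  expect_true(all(out$n_dead_day10 <= out$n_nymphs))
  expect_identical(simulate_survival_data(cfg3), simulate_survival_data(cfg3))
})

test_that("life-history tables obey their construction", {
  # certain hatching: every egg hatches by the last day
  cfg <- sim_config(seed = 7, life_history = lh_config(
    hatch_prob_control = 1, hatch_prob_exposed = 1, hatch_overdispersion = 0
  ))
  life <- simulate_life_history(cfg)
  expect_equal(life$hatched_day8, life$eggs_laid)

  # cumulative hatch counts never decrease and never exceed eggs laid
  cfg2 <- sim_config(seed = 8)
  life2 <- simulate_life_history(cfg2)
  hm <- as.matrix(life2[grep("^hatched_day", names(life2))])
  expect_true(all(apply(hm, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(hm[, ncol(hm)] <= life2$eggs_laid))
  expect_identical(life2, simulate_life_history(cfg2))

  # Poisson limit: dispersion -> Inf and no pair effect gives var/mean ~ 1
  cfg3 <- sim_config(seed = 9, life_history = lh_config(
    n_plants_per_arm = 250, nb_size = Inf, sigma_pair = 0,
    mean_total_eggs_control = 20, mean_total_eggs_exposed = 20,
    disk_day_weights = c(1, 1, 1, 1)
  ))
  life3 <- simulate_life_history(cfg3)
  ratio <- var(life3$eggs_laid) / mean(life3$eggs_laid)
  expect_lt(abs(ratio - 1), 0.1)

  # treatment means recover the configured totals (defaults are the study's
  # printed 21.47 / 37.27) at large n
  cfg4 <- sim_config(seed = 10, life_history = lh_config(n_plants_per_arm = 400))
  totals <- simulate_life_history(cfg4) |>
    dplyr::group_by(treatment, replicate_id) |>
    dplyr::summarise(eggs = sum(eggs_laid), .groups = "drop") |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(m = mean(eggs), se = sd(eggs) / sqrt(dplyr::n()))
  m <- setNames(totals$m, totals$treatment)
  se <- setNames(totals$se, totals$treatment)
  expect_lt(abs(m[["control"]] - 37.27), 3 * se[["control"]])
  expect_lt(abs(m[["exposed"]] - 21.47), 3 * se[["exposed"]])
})
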