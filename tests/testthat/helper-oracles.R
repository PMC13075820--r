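# Independent oracle: direct maximisation of the restricted log-likelihood by
# a coarse grid multi-start followed by Nelder-Mead on the log-variance
# scale. Shares nothing with the EM machinery except the likelihood
# definition, which itself is evaluated by the dense restricted_loglik()
# (not by the mixed-model-equation identities the EM uses internally).
reml_oracle <- function(data, response_col, random, n_grid = 3) {
  data <- as.data.frame(data)
  data$.y_oracle <- data[[response_col]]
  vy <- stats::var(data$.y_oracle)
  K <- length(random)
  obj <- function(lv) {
    sig <- stats::setNames(exp(lv), c(random, "resid"))
    ll <- tryCatch(
      restricted_loglik(sig, data, .y_oracle, random = random),
      error = function(e) NA_real_
    )
    if (is.finite(ll)) -ll else 1e10
  }
  grid_vals <- log(vy * c(0.02, 0.3, 1))
  starts <- as.matrix(expand.grid(rep(list(grid_vals), K + 1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    v <- obj(starts[i, ])
    if (is.null(best) || v < best$value) best <- list(par = starts[i, ], value = v)
  }
  opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  sig <- stats::setNames(exp(opt$par), c(random, "resid"))
  # snap numerically-zero components so boundary fits compare cleanly
  sig[sig < 1e-10 * vy] <- 0
  list(sigma = sig, loglik = -opt$value)
}

# balanced one-way sire fixture with a hand-computed ANOVA decomposition:
# group means 2.5 / 4.5 / 6.5, MS_between = 16, MS_within = 15/9,
# sire variance (MSB - MSW)/m = 3.58333, residual = 1.66667
one_way_fixture <- function() {
  tibble::tibble(
    sire_id = rep(c("S1", "S2", "S3"), each = 4),
    y = c(1, 2, 3, 4, 3, 4, 5, 6, 5, 6, 7, 8)
  )
}

# 20-row fixture with 2 levels per factor (dam, sire, block, plant); the
# four partitions are pairwise distinct (periods 10 / 2 / 5 / 4) so no two
# variance components are aliased
two_level_fixture <- function(seed = 401) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      dam_id = rep(c("D1", "D2"), each = 10),
      sire_id = rep(c("S1", "S2"), 10),
      block_id = rep(rep(c("B1", "B2"), each = 5), 2),
      plant_id = rep(c("P1", "P1", "P2", "P2"), 5)
    )
    eff <- list(dam = c(D1 = -0.4, D2 = 0.4), sire = c(S1 = 0.3, S2 = -0.3),
                block = c(B1 = 0.2, B2 = -0.2), plant = c(P1 = -0.1, P2 = 0.1))
    d$y <- 1 + eff$dam[d$dam_id] + eff$sire[d$sire_id] +
      eff$block[d$block_id] + eff$plant[d$plant_id] + stats::rnorm(nrow(d), 0, 0.5)
    d
  })
}

# small half-sib survival fixture for the pipeline: 6 families (3 sires x 2
# dams), 2 replicates per family and treatment
six_family_fixture <- function(seed = 77) {
  simulate_survival_data(sim_config(
    n_sires = 3, n_dams_per_sire = 2, n_reps_per_family = 2,
    n_blocks = 2, n_plants_per_block = 2,
    V_A = 0.02, V_D = 0.005, V_Ec = 0.004, V_e = 0.002,
    baseline_survival_control = 0.95, baseline_survival_exposed = 0.4,
    link = "identity", seed = seed
  ))
}
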