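test_that("a constant response gives zero variances and a degenerate flag", {
  d <- tibble::tibble(y = rep(0.4, 12),
                      dam_id = rep(c("D1", "D2", "D3"), 4),
                      sire_id = rep(c("S1", "S2"), 6))
  fit <- fit_reml(d, y, random = c("dam_id", "sire_id"))
  expect_true(all(fit$components$variance == 0))
  expect_true("degenerate" %in% fit$flags)
  expect_true(fit$converged)
})

test_that("balanced one-way REML equals the ANOVA closed form", {
  d <- one_way_fixture()
  # hand-computed: MS_between = 16, MS_within = 15/9,
  # sire variance (16 - 15/9)/4, residual 15/9
  fit <- fit_reml(d, y, random = "sire_id")
  v <- setNames(fit$components$variance, fit$components$term)
  expect_equal(unname(v["sire_id"]), (16 - 15 / 9) / 4, tolerance = 1e-7)
  expect_equal(unname(v["residual"]), 15 / 9, tolerance = 1e-7)

  # and the same numbers from the ANOVA oracle computed in place
  m <- tapply(d$y, d$sire_id, mean)
  msb <- 4 * sum((m - mean(d$y))^2) / (length(m) - 1)
  msw <- sum((d$y - m[d$sire_id])^2) / (nrow(d) - length(m))
  expect_equal(unname(v["sire_id"]), (msb - msw) / 4, tolerance = 1e-7)
})

test_that("EM matches direct restricted-likelihood maximisation on a 20-row fixture", {
  d <- two_level_fixture()
  fit <- fit_reml(d, y, random = c("dam_id", "sire_id", "block_id", "plant_id"))
  oracle <- reml_oracle(d, "y", c("dam_id", "sire_id", "block_id", "plant_id"))
  v <- setNames(fit$components$variance, fit$components$term)
  for (k in c("dam_id", "sire_id", "block_id", "plant_id")) {
    expect_lt(abs(v[[k]] - oracle$sigma[[k]]), 1e-4)
  }
  expect_lt(abs(v[["residual"]] - oracle$sigma[["resid"]]), 1e-4)
})

test_that("restricted_loglik matches its closed form and transformation rules", {
  # intercept-only model, unit residual variance, centred response:
  # ll = -(n-1)/2 log(2pi) - sum(y^2)/2 - log(n)/2
  d <- tibble::tibble(y = c(-1, 0, 1))
  ll <- restricted_loglik(c(resid = 1), d, y, random = character(0))
  expect_equal(ll, -log(2 * pi) - 1 - 0.5 * log(3), tolerance = 1e-12)

  # scaling y by c and variances by c^2 shifts the loglik by -(n-1) log c
  d2 <- two_level_fixture()
  sig <- c(dam_id = 0.2, sire_id = 0.1, block_id = 0.05, plant_id = 0.02, resid = 0.3)
  base <- restricted_loglik(sig, d2, y, random = names(sig)[1:4])
  for (cc in c(0.5, 2, 10)) {
    d2c <- d2
    d2c$y <- cc * d2$y
    shifted <- restricted_loglik(cc^2 * sig, d2c, y, random = names(sig)[1:4])
    expect_equal(shifted, base - (nrow(d2) - 1) * log(cc), tolerance = 1e-8)
  }

  # the EM optimum is a maximum: perturbations do not increase the loglik
  fit <- fit_reml(d2, y, random = c("dam_id", "sire_id", "block_id", "plant_id"))
  v <- setNames(fit$components$variance, c("dam_id", "sire_id", "block_id", "plant_id", "resid"))
  ll_opt <- restricted_loglik(v, d2, y, random = names(v)[1:4])
  expect_equal(ll_opt, fit$loglik, tolerance = 1e-6)
  withr::with_seed(55, {
    for (i in 1:20) {
      pert <- v * exp(rnorm(5, 0, 0.2))
      expect_gte(ll_opt + 1e-6, restricted_loglik(pert, d2, y, random = names(v)[1:4]))
    }
  })

  expect_error(restricted_loglik(c(resid = 0), d, y, random = character(0)),
               "singular")
})

test_that("the restricted loglik trace is monotone non-decreasing", {
  for (s in 1:5) {
    surv <- simulate_survival_data(config_for_h2(0.3, n_sires = 20, seed = 600 + s))
    ex <- dplyr::filter(surv, treatment == "exposed")
    fit <- fit_reml(ex, n_dead_day10 / n_nymphs)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("variance estimates are scale-equivariant", {
  d <- two_level_fixture()
  fit1 <- fit_reml(d, y, random = c("dam_id", "sire_id"))
  for (cc in c(0.1, 7)) {
    d2 <- d
    d2$y <- cc * d$y
    fit2 <- fit_reml(d2, y, random = c("dam_id", "sire_id"))
    expect_equal(fit2$components$variance, cc^2 * fit1$components$variance,
                 tolerance = 1e-5)
  }
})

test_that("degenerate designs are rejected or flagged", {
  d <- tibble::tibble(y = rnorm(6), g = rep("only", 6), h = rep(c("a", "b"), 3))
  expect_error(fit_reml(d, y, random = c("g", "h")), "fewer than 2 levels")
  expect_error(fit_reml(d, y, random = "missing_col"), "not found")

  # identical partitions (pure full-sib dam/sire) are flagged as aliased
  surv <- simulate_survival_data(paper_survival_config(seed = 31))
  ex <- dplyr::filter(surv, treatment == "exposed")
  fit <- fit_reml(ex, n_dead_day10 / n_nymphs)
  expect_true(any(grepl("aliased_terms", fit$flags)))
})

test_that("components agree with an independent REML implementation", {
  # random-intercept data with two crossed factors, checked against lme4
  skip_if_not_installed("lme4")
  withr::with_seed(42, {
    g1 <- factor(rep(1:12, each = 5))
    g2 <- factor(rep(1:5, 12))
    y <- 2 + rnorm(12, 0, sqrt(0.5))[g1] + rnorm(5, 0, sqrt(0.3))[g2] + rnorm(60)
    d <- tibble::tibble(y = y, g1 = g1, g2 = g2)
  })
  fit <- fit_reml(d, y, random = c("g1", "g2"))
  lf <- lme4::lmer(y ~ 1 + (1 | g1) + (1 | g2), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  v <- setNames(fit$components$variance, fit$components$term)
  expect_equal(unname(v["g1"]), unname(ref["g1"]), tolerance = 1e-4)
  expect_equal(unname(v["g2"]), unname(ref["g2"]), tolerance = 1e-4)
  expect_equal(unname(v["residual"]), unname(ref["Residual"]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
})

test_that("variance_shares normalises to 100 and rejects all-zero input", {
  sh <- variance_shares(c(dam = 1, sire = 1, block = 1, plant = 1, residual = 1))
  expect_equal(sh$share_pct, rep(20, 5))
  expect_equal(sum(sh$share_pct), 100, tolerance = 1e-9)

  # the study's printed shares (which total 97 after rounding) renormalise
  # to percentages of the total, scale-invariantly
  for (cc in c(1, 0.04, 3e4)) {
    sh2 <- variance_shares(cc * c(dam = 0.45, sire = 0.13, block = 0.09,
                                  plant = 0.06, residual = 0.24))
    expect_equal(sh2$share_pct, 100 * c(45, 13, 9, 6, 24) / 97, tolerance = 1e-9)
    expect_equal(sum(sh2$share_pct), 100, tolerance = 1e-9)
  }

  expect_equal(variance_shares(c(a = 2, b = 0))$share_pct, c(100, 0))
  expect_error(variance_shares(c(a = 0, b = 0)), "all components are zero")
})
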