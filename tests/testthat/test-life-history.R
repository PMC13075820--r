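nb_null_data <- function(seed, n_per_arm = 120, mu = 8, size = 2) {
  withr::with_seed(seed, tibble::tibble(
    treatment = rep(c("control", "exposed"), each = n_per_arm),
    eggs_laid = stats::rnbinom(2 * n_per_arm, mu = mu, size = size)
  ))
}

test_that("beta-binomial pmf reduces exactly to the binomial at rho = 0", {
  x <- 0:20
  expect_equal(dbetabinom(x, rep(20L, 21), rep(0.3, 21), 0, log = TRUE),
               dbinom(x, 20, 0.3, log = TRUE))
  # proper pmf for rho > 0
  expect_equal(sum(dbetabinom(0:15, rep(15L, 16), rep(0.4, 16), 0.2)), 1,
               tolerance = 1e-12)
})

test_that("fit_fecundity recovers null and Poisson-limit behaviour", {
  # treatment coefficient is null-consistent: |z| < 2 in >= 93% of 500
  # identical-arm replicates
  hits <- vapply(1:500, function(s) {
    d <- nb_null_data(3000 + s, n_per_arm = 60)
    f <- fit_fecundity(d, formula = eggs_laid ~ treatment, mode = "none")
    abs(f$coefficients$statistic[2]) < 2
  }, logical(1))
  expect_gte(mean(hits), 0.93)

  # Poisson data: dispersion estimate explodes, coefficients match a Poisson
  # GLM within 1e-3
  withr::with_seed(91, {
    d <- tibble::tibble(
      treatment = rep(c("control", "exposed"), each = 300),
      eggs_laid = stats::rpois(600, lambda = rep(c(9, 6), each = 300))
    )
  })
  f <- fit_fecundity(d, formula = eggs_laid ~ treatment, mode = "none")
  g <- glm(eggs_laid ~ treatment, data = d, family = poisson())
  expect_gt(f$theta, 20) # variance/mean inflation under 1 + mu/theta ~ 1.4
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-3)

  expect_error(
    fit_fecundity(tibble::tibble(treatment = c("a", "b"), eggs_laid = c(0L, 0L)),
                  formula = eggs_laid ~ treatment, mode = "none"),
    "all counts are zero"
  )
})

test_that("fit_fecundity agrees with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  life <- simulate_life_history(sim_config(seed = 92))
  mine <- fit_fecundity(life, formula = eggs_laid ~ treatment + factor(disk_day),
                        mode = "pql")
  tmb <- glmmTMB::glmmTMB(
    eggs_laid ~ treatment + factor(disk_day) + (1 | plant_id / replicate_id),
    family = glmmTMB::nbinom2, data = life
  )
  ref <- glmmTMB::fixef(tmb)$cond
  expect_equal(mine$coefficients$estimate, unname(ref), tolerance = 0.15)
  expect_equal(sign(mine$coefficients$estimate[2]), sign(unname(ref[2])))
})

test_that("lr_test handles identity, nesting violations and real contrasts", {
  d <- nb_null_data(1, n_per_arm = 80)
  f <- fit_fecundity(d, formula = eggs_laid ~ treatment, mode = "none")
  same <- lr_test(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  r <- fit_fecundity(d, formula = eggs_laid ~ 1, mode = "none")
  expect_error(lr_test(r, f), "lower log-likelihood|no more parameters")

  # strong effect: p < 0.001 in >= 95% of replicates
  hits <- vapply(1:100, function(s) {
    withr::with_seed(4000 + s, {
      d2 <- tibble::tibble(
        treatment = rep(c("control", "exposed"), each = 60),
        eggs_laid = stats::rnbinom(120, mu = rep(c(12, 4), each = 60), size = 2)
      )
    })
    f2 <- fit_fecundity(d2, formula = eggs_laid ~ treatment, mode = "none")
    r2 <- fit_fecundity(d2, formula = eggs_laid ~ 1, mode = "none")
    lr_test(f2, r2)$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fit_hatch reduces to the binomial GLM without overdispersion", {
  withr::with_seed(93, {
    d <- tibble::tibble(
      treatment = rep(c("control", "exposed"), each = 100),
      eggs = rep(12L, 200)
    )
    d$hatched <- stats::rbinom(200, d$eggs, rep(c(0.3, 0.15), each = 100))
    d$unhatched <- d$eggs - d$hatched
  })
  fit <- fit_hatch(d, hatched, unhatched, ~treatment)
  g <- glm(cbind(hatched, unhatched) ~ treatment, data = d, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(g)), tolerance = 1e-3)
  expect_lt(fit$overdispersion, 0.02)
  # loglik identity at the boundary: beta-binomial at rho = 0 IS binomial
  expect_equal(
    sum(dbetabinom(d$hatched, d$eggs, fitted(g), 0, log = TRUE)),
    as.numeric(logLik(g)),
    tolerance = 1e-9
  )
})

test_that("fit_hatch recovers overdispersed treatment contrasts", {
  # large clutches so the intra-class correlation is identifiable
  cfg <- sim_config(seed = 94, life_history = lh_config(
    n_plants_per_arm = 40, mean_total_eggs_control = 100,
    mean_total_eggs_exposed = 80, sigma_pair = 0.2
  ))
  ht <- hatch_totals(simulate_life_history(cfg))
  fit <- fit_hatch(ht, hatched, unhatched, ~treatment)
  p_ctrl <- plogis(fit$coefficients$estimate[1])
  p_exp <- plogis(sum(fit$coefficients$estimate))
  expect_lt(abs(p_ctrl - 0.283), 0.05)
  expect_lt(abs(p_exp - 0.16), 0.05)
  expect_gt(fit$overdispersion, 0.005)

  # boundary data flagged
  b <- tibble::tibble(treatment = c("a", "a", "b", "b"),
                      hatched = c(5L, 7L, 3L, 8L), unhatched = 0L)
  expect_true("boundary" %in% fit_hatch(b, hatched, unhatched, ~treatment)$flags)
})

test_that("the day-effect test is uniform under a day-shuffled null", {
  # hatch probability constant; day labels carry no signal
  pv <- vapply(1:250, function(s) {
    withr::with_seed(5000 + s, {
      d <- tibble::tibble(
        day = sample(rep(4:8, each = 24)),
        eggs = stats::rpois(120, 8) + 1L
      )
      rho <- 0.06
      th <- (1 - rho) / rho
      p <- stats::rbeta(120, 0.25 * th, 0.75 * th)
      d$hatched <- stats::rbinom(120, d$eggs, p)
      d$unhatched <- d$eggs - d$hatched
    })
    full <- fit_hatch(d, hatched, unhatched, ~ factor(day))
    red <- fit_hatch(d, hatched, unhatched, ~1)
    lr_test(full, red)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("binomial confidence intervals match the beta-quantile closed form", {
  # Clopper-Pearson against stats::binom.test as an independent oracle
  for (x in c(0, 1, 28, 77, 100)) {
    ci <- binom_ci(x, 100)
    ref <- stats::binom.test(x, 100)$conf.int
    expect_equal(ci$lower, ref[1], tolerance = 1e-9)
    expect_equal(ci$upper, ref[2], tolerance = 1e-9)
  }
  # exact boundary behaviour
  expect_equal(binom_ci(0, 10)$lower, 0)
  expect_equal(binom_ci(10, 10)$upper, 1)
  expect_equal(binom_ci(0, 10, method = "wilson")$lower, 0)

  # interval always contains the point estimate; width shrinks with n
  withr::with_seed(95, {
    for (i in 1:25) {
      n <- sample(5:500, 1)
      x <- stats::rbinom(1, n, runif(1))
      for (m in c("clopper-pearson", "wilson")) {
        ci <- binom_ci(x, n, method = m)
        expect_lte(ci$lower, ci$estimate)
        expect_gte(ci$upper, ci$estimate)
        wider <- binom_ci(round(x / 4), max(ceiling(n / 4), 1), method = m)
        if (abs(wider$estimate - ci$estimate) < 0.05 && n >= 40) {
          expect_lte(ci$upper - ci$lower, wider$upper - wider$lower + 1e-9)
        }
      }
    }
  })
  expect_error(binom_ci(5, 4), "successes <= trials")
})

test_that("summarize_costs reproduces constructed tables", {
  # single replicate laying 10 eggs per day: total 40, degenerate CI
  one <- tibble::tibble(
    plant_id = "LC01", replicate_id = "LC01.1",
    treatment = rep(c("control", "exposed"), each = 4),
    disk_day = rep(1:4, 2), eggs_laid = 10L,
    hatched_day4 = 1L, hatched_day8 = 3L
  )
  cs <- summarize_costs(one)
  expect_equal(cs$fecundity$mean_total_eggs, c(40, 40))
  expect_true(all(cs$fecundity$flag == "degenerate_ci"))

  # a table built to match given group means reproduces them exactly
  built <- tidyr::expand_grid(
    treatment = c("control", "exposed"), pair = 1:6, disk_day = 1:4
  ) |>
    dplyr::mutate(
      plant_id = paste0(substr(treatment, 1, 1), pair),
      replicate_id = paste0(plant_id, ".1"),
      eggs_laid = ifelse(treatment == "control", 9L, 5L),
      hatched_day4 = 1L,
      hatched_day8 = ifelse(treatment == "control", 3L, 1L)
    )
  cs2 <- summarize_costs(built)
  expect_equal(setNames(cs2$fecundity$mean_total_eggs, cs2$fecundity$treatment),
               c(control = 36, exposed = 20))
  expect_equal(setNames(cs2$hatch$proportion, cs2$hatch$treatment),
               c(control = 3 / 9, exposed = 1 / 5))

  # an arm with no replicates is an error
  expect_error(summarize_costs(dplyr::filter(built, treatment == "control")),
               "one treatment arm")
})

test_that("hatch reshaping helpers are consistent with the cumulative table", {
  life <- simulate_life_history(sim_config(seed = 96))
  tot <- hatch_totals(life)
  expect_equal(tot$hatched + tot$unhatched, tot$eggs)
  inc <- hatch_increments(life)
  agg <- inc |>
    dplyr::group_by(replicate_id, disk_day) |>
    dplyr::summarise(hatched = sum(hatched), .groups = "drop") |>
    dplyr::arrange(replicate_id, disk_day)
  ref <- tot |>
    dplyr::arrange(replicate_id, disk_day)
  expect_equal(agg$hatched, ref$hatched)
})
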