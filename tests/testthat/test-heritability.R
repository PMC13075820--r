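test_that("the conversion formulas are exact", {
  expect_equal(additive_variance(0), 0)
  expect_equal(additive_variance(0.5), 1.0)
  expect_error(additive_variance(-0.1), "non-negative")

  # exact cancellation: var_dam = V_A/4 + V_Ec -> V_D = 0
  vd0 <- dominance_variance(var_dam = 0.2, V_A = 0.4, V_Ec = 0.1)
  expect_equal(as.numeric(vd0), 0)
  expect_false(attr(vd0, "truncated"))

  vd <- dominance_variance(var_dam = 0.3, V_A = 0.4, V_Ec = 0.1)
  expect_equal(as.numeric(vd), 0.2)

  # negative implied dominance truncates with a flag
  vdt <- dominance_variance(var_dam = 0.05, V_A = 0.4, V_Ec = 0.1)
  expect_equal(as.numeric(vdt), 0)
  expect_true(attr(vdt, "truncated"))

  expect_equal(narrow_sense_h2(0, 0.5, 0.5), 0)
  expect_equal(narrow_sense_h2(1, 0.5, 0.5), 0.5)
  expect_error(narrow_sense_h2(0, 0, 0), "undefined")
})

test_that("h2_pipeline chains the steps with provenance and scale invariance", {
  shares <- c(dam_id = 0.45, sire_id = 0.13, block_id = 0.09,
              plant_id = 0.06, residual = 0.24)
  res <- h2_pipeline(shares)
  # V_A = 0.26, V_D = 2(0.45 - 0.065 - 0.15) = 0.47, V_e = 0.24
  expect_equal(res$V_A, 0.26)
  expect_equal(res$V_D, 0.47, tolerance = 1e-12)
  expect_equal(res$V_Ec, 0.15)
  expect_equal(res$h2, 0.26 / 0.97, tolerance = 1e-12)
  expect_equal(res$provenance$value[res$provenance$step == "h2"], res$h2)

  # identical h2 for every positive rescaling
  for (cc in c(1e-3, 0.04, 5, 1e4)) {
    expect_equal(h2_pipeline(cc * shares)$h2, res$h2, tolerance = 1e-12)
  }

  # zero sire variance forces h2 = 0 whatever the other components
  res0 <- h2_pipeline(c(dam_id = 0.4, sire_id = 0, block_id = 0.1,
                        plant_id = 0.1, residual = 0.2))
  expect_equal(res0$h2, 0)

  # broad-V_P mode includes the common-environment variance
  broad <- h2_pipeline(shares, v_p_mode = "broad")
  expect_equal(broad$V_P, res$V_P + res$V_Ec)
  expect_lt(broad$h2, res$h2)

  expect_error(h2_pipeline(c(dam_id = 1, sire_id = 1)), "missing variance")

  # h2 always lands in [0, 1] across random component vectors
  withr::with_seed(77, {
    for (i in 1:50) {
      v <- stats::runif(5, 0, 2)
      names(v) <- names(shares)
      h <- h2_pipeline(v)$h2
      expect_gte(h, 0)
      expect_lte(h, 1)
    }
  })
})

test_that("estimate_h2 recovers a known heritability on one dataset", {
  surv <- simulate_survival_data(config_for_h2(0.5, seed = 81))
  res <- estimate_h2(surv)
  expect_gt(res$h2, 0.2)
  expect_lt(res$h2, 0.8)
})
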