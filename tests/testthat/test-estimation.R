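test_that("transfer-to-generation conversion uses log2 of the dilution", {
  expect_equal(transfers_to_generations(0), 0)
  expect_equal(transfers_to_generations(1), log2(100), tolerance = 1e-12)
  expect_equal(transfers_to_generations(1), 6.64, tolerance = 1e-2)
  expect_equal(transfers_to_generations(5), 33.2, tolerance = 1e-2)
  expect_equal(transfers_to_generations(2, dilution_factor = 8), 6)
  expect_error(transfers_to_generations(1, dilution_factor = 1), "> 1")
  expect_error(transfers_to_generations(-1), ">= 0")
})

test_that("persistence dataset validation reports offending rows", {
  good <- data.frame(variant = "U", replicate = 1, transfer = 0:2,
                     n_total = 100, n_host = c(100, 90, 85))
  expect_s3_class(persistence_dataset(good), "persistence_dataset")
  bad <- good; bad$n_host[2] <- 120
  expect_error(persistence_dataset(bad), "rows 2")
  expect_error(persistence_dataset(good[, -5]), "n_host")
})

test_that("predicted host fraction is monotone in the fitted parameters", {
  h_at_g10 <- function(p_def, p_par) {
    v <- plasmid_variant("m", p_def = p_def, p_par = p_par)
    plasmidstab:::.host_curve(v, cfg5, 10)[11]
  }
  hs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), h_at_g10, numeric(1), p_par = 0)
  expect_true(all(diff(hs) < 0))       # deeper deficiency, faster loss
  hp <- vapply(c(0, 0.25, 0.5, 0.75, 1), h_at_g10, numeric(1),
               p_def = 0.494)
  expect_true(all(diff(hp) > 0))       # better partitioning, slower loss
})

test_that("each parameter is recovered from its variant's synthetic data", {
  cases <- list(
    list(target = "p_def", label = "U", truth = 0.494, fixed = list()),
    list(target = "p_par", label = "P", truth = 0.456,
         fixed = list(p_def = 0.494)),
    list(target = "p_eff", label = "T", truth = 0.883,
         fixed = list(p_def = 0.494)))
  for (cs in cases) {
    d <- generate_persistence(
      synthetic_design(variant_preset(cs$label), seed = 314),
      cfg5)
    fit <- fit_parameter(d, cs$target, fixed = cs$fixed, config = cfg5,
                         n_boot = 300, seed = 314)
    expect_lt(abs(fit$estimate - cs$truth), 0.05)
    expect_gte(cs$truth, fit$ci95[["low"]])
    expect_lte(cs$truth, fit$ci95[["high"]])
    expect_false(fit$boundary)
    expect_true(fit$ci95[["low"]] <= fit$estimate &&
                  fit$estimate <= fit$ci95[["high"]])
  }
})

test_that("loss-free data give a flagged boundary estimate near zero", {
  stable_as_u <- plasmid_variant("U", 0, 0, 0)
  d <- generate_persistence(synthetic_design(stable_as_u, plating_n = 50,
                                             seed = 5), cfg5)
  d$n_host <- d$n_total  # no loss observed at all
  fit <- fit_parameter(d, "p_def", config = cfg5, n_boot = 50, seed = 5)
  expect_true(fit$boundary)
  expect_lt(fit$estimate, 1e-3)
})

test_that("estimation is deterministic given data and seed", {
  d <- generate_persistence(synthetic_design(variant_preset("U"), seed = 8),
                            cfg5)
  f1 <- fit_parameter(d, "p_def", config = cfg5, n_boot = 100, seed = 21)
  f2 <- fit_parameter(d, "p_def", config = cfg5, n_boot = 100, seed = 21)
  expect_identical(f1[c("estimate", "ci95", "boot")],
                   f2[c("estimate", "ci95", "boot")])
})

test_that("sequential calibration feeds the p_def estimate forward", {
  d <- generate_persistence(
    synthetic_design(variant_preset(c("U", "P", "T")), seed = 27), cfg5)
  fits <- estimate_parameters(d, cfg5, n_boot = 100, seed = 27)
  expect_equal(fits$p_par$fixed$p_def, fits$p_def$estimate)
  expect_equal(fits$p_eff$fixed$p_def, fits$p_def$estimate)
  expect_lt(abs(fits$p_def$estimate - 0.494), 0.05)
  expect_lt(abs(fits$p_par$estimate - 0.456), 0.12)
  expect_lt(abs(fits$p_eff$estimate - 0.883), 0.08)
  # p_par and p_eff cannot be fitted without a p_def
  expect_error(fit_parameter(d, "p_par", config = cfg5), "fixed\\$p_def")
})
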