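test_that("span reproduces the published laser-diffraction values", {
  expect_equal(round(span(2.50, 5.48, 11.48), 2), 1.64)
  expect_equal(round(span(2.38, 5.40, 11.53), 2), 1.69)
  expect_equal(span(3, 3, 3), 0)   # monodisperse
  expect_error(span(2, 0, 5), "positive")
  expect_error(span(6, 5, 11), "dv10 <= dv50")
})

toy_run <- function() {
  # 50 mass units above a 4 um cutoff, 50 on a 1 um stage, device 10,
  # total dose 120
  impactor_run(
    stages = data.frame(label = c("coarse", "fine", "filter"),
                        cutoff_um = c(4, 1, 0), mass = c(50, 50, 0)),
    device_parts = data.frame(label = "port", mass = 10),
    total_dose = 120
  )
}

test_that("dose fractions follow their definitions on a hand example", {
  # the two-point toy curve cannot bracket the GSD percentiles, which is
  # immaterial to the dose fractions under test
  s <- suppressWarnings(impactor_summary(toy_run(), fpf_from = "fine"))
  expect_equal(s$ed, 110)
  expect_equal(s$pd_percent, 100 * 110 / 120)   # 91.67
  expect_equal(s$pi_percent, 100 * 100 / 120)   # 83.33
  expect_equal(s$fpf_percent, 100 * 50 / 110)
  expect_lte(s$pi_percent, s$pd_percent)
})

test_that("FPF is invariant to uniform mass scaling", {
  r1 <- toy_run()
  r2 <- impactor_run(transform(r1$stages, mass = mass * 7),
                     transform(r1$device_parts, mass = mass * 7),
                     total_dose = 120 * 7)
  expect_equal(
    suppressWarnings(impactor_summary(r1, fpf_from = "fine"))$fpf_percent,
    suppressWarnings(impactor_summary(r2, fpf_from = "fine"))$fpf_percent)
})

test_that("degenerate single-stage distribution stays inside its window", {
  st <- aci_cutoffs()
  st$mass <- ifelse(st$label == "4", 100, 0)   # window [2.10, 3.3)
  run <- impactor_run(st, total_dose = 120)
  s <- impactor_summary(run)
  expect_gt(s$mmad_um, 2.10)
  expect_lt(s$mmad_um, 3.3)
  # GSD bounded by the single collection window's width
  expect_lt(s$gsd, sqrt(3.3 / 2.10))
  expect_gte(s$gsd, 1)
})

test_that("all mass on the filter reports the boundary with a warning", {
  st <- aci_cutoffs()
  st$mass <- ifelse(st$label == "filter", 100, 0)
  run <- impactor_run(st, total_dose = 120)
  w <- capture_warnings(s <- impactor_summary(run))
  expect_true(any(grepl("boundary|degenerate", w)))
  expect_lte(s$mmad_um, min(st$cutoff_um[st$cutoff_um > 0]))
})

test_that("cumulative undersize curve is monotone and ends at 100%", {
  run <- simulate_impactor(3.2, 1.7, 120, n_quanta = 2e4, seed = 5)
  curve <- mixaero:::cumulative_undersize(run)
  expect_true(all(diff(curve$undersize_pct) >= 0))
  st <- run$stages
  total <- sum(st$mass)
  # undersize just below the top cutoff accounts for everything finer
  expect_equal(max(curve$undersize_pct),
               100 * sum(st$mass[-1]) / total)
})

test_that("MMAD shifts coarser when mass moves one stage coarser", {
  st <- aci_cutoffs()
  st$mass <- c(0, 0, 10, 30, 40, 15, 5, 0, 0)
  s1 <- impactor_summary(impactor_run(st, total_dose = 120))
  st2 <- st
  st2$mass <- c(0, 10, 30, 40, 15, 5, 0, 0, 0)
  s2 <- impactor_summary(impactor_run(st2, total_dose = 120))
  expect_gt(s2$mmad_um, s1$mmad_um)
})

test_that("lognormal simulation recovers MMAD and GSD at moderate n", {
  s <- impactor_summary(simulate_impactor(3.2, 1.7, 120, n_quanta = 1e5,
                                          seed = 11))
  expect_equal(s$mmad_um, 3.2, tolerance = 0.15 / 3.2)
  expect_equal(s$gsd, 1.7, tolerance = 0.1 / 1.7)
  # probit-scale interpolation is near-exact for a lognormal
  sp <- impactor_summary(simulate_impactor(3.2, 1.7, 120, n_quanta = 1e5,
                                           seed = 11),
                         interpolation = "probit")
  expect_equal(sp$gsd, 1.7, tolerance = 0.02)
})

test_that("simulated dose accounting matches its construction", {
  run <- simulate_impactor(3.2, 1.7, total_dose = 120, n_quanta = 1e4,
                           device_fraction = 0.3, port_fraction = 0.01,
                           seed = 2)
  s <- impactor_summary(run)
  expect_equal(s$pd_percent, 70, tolerance = 1e-9)
  expect_equal(s$pi_percent, 70 * 0.99, tolerance = 1e-9)
  expect_lte(sum(run$stages$mass) + sum(run$device_parts$mass),
             run$total_dose)
})

test_that("monodisperse aerosol lands on the single containing stage", {
  run <- simulate_impactor(3.2, 1, 100, n_quanta = 1000, seed = 1)
  # 3.2 um falls in stage 4's collection window [2.1, 3.3)
  expect_equal(run$stages$mass[run$stages$label == "4"],
               sum(run$stages$mass))
})

test_that("impactor run validation catches malformed inputs", {
  expect_error(impactor_run(data.frame(label = "a", cutoff_um = 1,
                                       mass = -1), total_dose = 10),
               "non-negative")
  st <- data.frame(label = c("a", "b"), cutoff_um = c(1, 2), mass = c(1, 1))
  expect_error(impactor_run(st, total_dose = 10), "decreasing")
  st2 <- data.frame(label = c("a", "b"), cutoff_um = c(2, 1), mass = c(9, 9))
  expect_error(impactor_run(st2, total_dose = 10), "exceed")
  expect_error(simulate_impactor(3.2, 1.7, 120, n_quanta = 0), "n_quanta")
})
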