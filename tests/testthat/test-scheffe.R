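test_that("model matrix rows match hand products and term counts", {
  # pseudo vertex: all cross-products vanish
  v <- matrix(c(0, 0, 0, 0, 1), 1, dimnames = list(NULL, LETTERS[1:5]))
  row <- scheffe_model_matrix(v, "quadratic")
  expect_equal(unname(row[1, ]), c(0, 0, 0, 0, 1, rep(0, 10)))
  # centroid: A:B column is the hand product
  cen <- matrix(c(0.1818, 0.0909, 0.0909, 0.1364, 0.5), 1,
                dimnames = list(NULL, LETTERS[1:5]))
  expect_equal(unname(scheffe_model_matrix(cen, "quadratic")[1, "A:B"]),
               0.1818 * 0.0909)
  # term counts for 5 components
  expect_equal(ncol(scheffe_model_matrix(cen, "quadratic")), 15L)
  expect_equal(ncol(scheffe_model_matrix(cen, "special_cubic")), 25L)
})

test_that("fit equals the normal-equation oracle and recovers noiseless truth", {
  X <- scheffe_model_matrix(study$design, "quadratic")
  y <- study$responses$ps_dtx
  fit <- fit_scheffe(study$design, y, "quadratic")
  beta_ne <- solve(crossprod(X), crossprod(X, y))   # brute-force oracle
  expect_equal(unname(fit$model$coefficients), as.numeric(beta_ne),
               tolerance = 1e-8)
  # SS additivity
  expect_equal(fit$ss_model + fit$ss_residual, fit$ss_total_corrected,
               tolerance = 1e-6 * fit$ss_total_corrected)

  # noiseless synthetic responses: coefficients recovered to 1e-8
  truth <- dcn_models()$ps_dtx
  y0 <- simulate_responses(truth, study$design, noise_sd = 0)
  fit0 <- fit_scheffe(study$design, y0, "quadratic")
  expect_equal(fit0$model$coefficients, truth$coefficients,
               tolerance = 1e-8)
  expect_equal(r_squared(fit0), 1, tolerance = 1e-10)
})

test_that("refit coefficients track the published equation", {
  fit <- fit_scheffe(study$design, study$responses$ps_dtx, "quadratic")
  expect_equal(unname(fit$model$coefficients["A:B"]), -191.85,
               tolerance = 1.0)   # absolute, 2-dp response rounding
})

test_that("predictions reproduce the published worked examples", {
  m <- dcn_models()
  opt <- c(6.0, 2.5, 2.0, 2.5, 87.0)
  expect_equal(round(predict(m$ps_dtx, opt), 1), 97.2)
  expect_equal(round(predict(m$ps_ccm, opt), 1), 98.4)
  # linear blending: water pseudo-vertex returns the water coefficient
  expect_equal(predict(m$vmd_dtx, c(4, 2, 1, 1.5, 91.5)), 5.21)
  # VMD at the optimum: printed-coefficient rounding allows +-0.02
  expect_equal(predict(m$vmd_dtx, opt), 5.28, tolerance = 0.02 / 5.28)
})

test_that("fitted values are invariant to affine re-coding of the simplex", {
  # same runs expressed over the raw proportion simplex: the quadratic
  # Scheffe space is closed under affine re-coding, so fits must agree
  raw_region <- mixture_region(study_region$names, lower = rep(0, 5),
                               upper = rep(100, 5), total = 100)
  y <- study$responses$ps_dtx
  f_pseudo <- fit_scheffe(study$design, y, "quadratic")
  f_raw <- fit_scheffe(mixture_design(study$design$runs, raw_region), y,
                       "quadratic")
  expect_equal(f_raw$fitted, f_pseudo$fitted, tolerance = 1e-6)
})

test_that("residuals are orthogonal to the model space", {
  fit <- fit_scheffe(study$design, study$responses$ps_ccm, "quadratic")
  X <- scheffe_model_matrix(study$design, "quadratic")
  expect_lt(max(abs(crossprod(X, fit$residuals))),
            1e-6 * max(abs(study$responses$ps_ccm)))
})

test_that("predict on a training run equals that run's fitted value", {
  fit <- fit_scheffe(study$design, study$responses$ps_dtx, "quadratic")
  i <- c(1L, 7L, 24L)
  expect_equal(predict(fit, study$design$runs[i, ]), fit$fitted[i])
})

test_that("out-of-region prediction warns but returns a value", {
  m <- dcn_models()$ps_dtx
  expect_warning(v <- predict(m, c(7, 2, 1, 1.5, 88.5)), "extrapolating")
  expect_true(is.finite(v))
})

test_that("surface grid is consistent with predict and clips infeasible corners", {
  m <- dcn_models()$ps_dtx
  g <- surface_grid(m, free = c("A", "B"), resolution = 2)
  expect_equal(g$predicted,
               suppressWarnings(predict(m, as.matrix(g[, 1:5]))))
  # monotonicity spot check on the linear VMD surface: more surfactant
  # (C, the smallest blending coefficient) lowers the predicted VMD
  vmd <- dcn_models()$vmd_dtx
  lo <- predict(vmd, c(5, 2.5, 1.0, 2.25, 89.25))
  hi <- predict(vmd, c(5, 2.5, 2.0, 2.25, 88.25))
  expect_lt(hi, lo)
  # a slice whose corners run out of water: dropped and counted
  g2 <- surface_grid(dcn_models()$ps_dtx, free = c("A", "D"),
                     fixed = c(B = 3, C = 2), resolution = 5)
  expect_gte(attr(g2, "dropped"), 0)
  expect_true(all(g2$E >= 86 - 1e-9 & g2$E <= 91.5 + 1e-9))
})

test_that("rank deficiency and underdetermined fits raise errors", {
  r3 <- unit_simplex(3)
  tiny <- mixture_design(rbind(c(.5, .3, .2), c(.2, .5, .3), c(.3, .2, .5)),
                         r3)
  expect_error(fit_scheffe(tiny, 1:3, "quadratic"), "only 3 runs")
  dup <- mixture_design(rbind(diag(3), diag(3)), r3)
  expect_error(fit_scheffe(dup, rnorm(6), "quadratic"), "collinear")
})
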