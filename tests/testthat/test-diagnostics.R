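fit_ps_dtx <- fit_scheffe(study$design, study$responses$ps_dtx, "quadratic")
fit_vmd_dtx <- fit_scheffe(study$design, study$responses$vmd_dtx, "linear")

test_that("ANOVA reproduces the published model and lack-of-fit statistics", {
  at <- mixture_anova(fit_ps_dtx)
  model <- at$rows[at$rows$term == "Model", ]
  expect_equal(model$df, 14L)
  expect_equal(model$ms, 37.87, tolerance = 0.01)   # printed model MS
  expect_equal(model$f, 81.30, tolerance = 0.05)    # 2-dp response rounding
  expect_lt(model$p, 1e-4)

  lof <- at$rows[at$rows$term == "Lack of fit", ]
  pe <- at$rows[at$rows$term == "Pure error", ]
  expect_equal(lof$f, 2.28, tolerance = 0.15)
  expect_equal(lof$p, 0.22, tolerance = 0.1)
  expect_equal(pe$ms, 0.27, tolerance = 0.1)        # printed 0.27
  # replicate structure: centroid x4 plus the duplicated vertex pair
  sizes <- lengths(study$design$replicate_groups)
  expect_equal(sort(sizes[sizes > 1], decreasing = TRUE), c(4L, 2L))
  expect_equal(pe$df, 4L)
})

test_that("sums of squares are additive at both decomposition levels", {
  for (fit in list(fit_ps_dtx, fit_vmd_dtx)) {
    at <- mixture_anova(fit)
    g <- function(term) at$rows[at$rows$term == term, ]
    tol <- 1e-6 * fit$ss_total_corrected
    expect_equal(g("Model")$ss + g("Residual")$ss, fit$ss_total_corrected,
                 tolerance = tol)
    expect_equal(g("Lack of fit")$ss + g("Pure error")$ss, g("Residual")$ss,
                 tolerance = tol)
    expect_equal(g("Model")$df + g("Residual")$df, fit$n - 1L)
    # each partial term SS is bounded by the model SS; F >= 0; p in [0,1]
    terms <- at$rows[grepl(":", at$rows$term), ]
    expect_true(all(terms$ss <= g("Model")$ss + 1e-9))
    expect_true(all(terms$ss >= -1e-9))
    expect_true(all(at$rows$f >= 0, na.rm = TRUE))
    expect_true(all(at$rows$p >= 0 & at$rows$p <= 1, na.rm = TRUE))
  }
})

test_that("linear terms are not individually tested, interactions are", {
  at <- mixture_anova(fit_ps_dtx)
  expect_false(any(at$rows$term %in% LETTERS[1:5]))
  expect_equal(sum(grepl(":", at$rows$term)), 10L)
  # the VMD linear model has no interaction rows at all
  expect_equal(sum(grepl(":", mixture_anova(fit_vmd_dtx)$rows$term)), 0L)
})

test_that("fit statistics match the published values for all four responses", {
  expect_equal(r_squared(fit_ps_dtx), 0.9922, tolerance = 5e-4)
  expect_equal(adequate_precision(fit_ps_dtx), 35.58, tolerance = 0.03)
  fit_ccm <- fit_scheffe(study$design, study$responses$ps_ccm, "quadratic")
  expect_equal(r_squared(fit_ccm), 0.9984, tolerance = 5e-4)
  expect_equal(r_squared(fit_vmd_dtx), 0.6894, tolerance = 0.01)
  expect_equal(adequate_precision(fit_vmd_dtx), 11.80, tolerance = 0.03)
  # the >4 signal-to-noise threshold holds for every reported fit
  expect_gt(adequate_precision(fit_ccm), 4)
  vmd_f <- mixture_anova(fit_vmd_dtx)$rows
  expect_equal(vmd_f$f[vmd_f$term == "Model"], 10.11, tolerance = 0.03)
})

test_that("saturated fits hit the adequate-precision and anova guards", {
  truth <- dcn_models()$ps_dtx
  y0 <- simulate_responses(truth, study$design, noise_sd = 0)
  f0 <- fit_scheffe(study$design, y0, "quadratic")
  expect_warning(ap <- adequate_precision(f0), "infinite")
  expect_identical(ap, Inf)
})

test_that("anova without replicates omits the lack-of-fit split with warning", {
  r3 <- unit_simplex(3)
  des <- mixture_design(rbind(diag(3), c(.5, .5, 0), c(.5, 0, .5),
                              c(0, .5, .5), rep(1 / 3, 3)), r3)
  f <- fit_scheffe(des, c(1, 2, 3, 1.4, 2.2, 2.7, 2.1), "linear")
  expect_warning(at <- mixture_anova(f), "no replicated")
  expect_false("Lack of fit" %in% at$rows$term)
})

test_that("model selection picks quadratic for particle size, linear for VMD", {
  s_ps <- select_scheffe_order(study$design, study$responses$ps_dtx)
  expect_equal(s_ps$order, "quadratic")
  s_vmd <- select_scheffe_order(study$design, study$responses$vmd_dtx)
  expect_equal(s_vmd$order, "linear")
  # per-order candidate tables are reported
  expect_true(all(c("linear", "quadratic") %in% names(s_ps$candidates)))
})

test_that("selection recovers a linear truth under small noise", {
  truth <- dcn_models()$vmd_dtx
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    y <- simulate_responses(truth, study$design, noise_sd = 0.05, seed = s)
    sel <- suppressWarnings(select_scheffe_order(study$design, y))
    hits <- hits + (sel$order == "linear")
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("predicted-vs-actual pairs and slope behave as calibration", {
  truth <- dcn_models()$ps_dtx
  y0 <- simulate_responses(truth, study$design, noise_sd = 0)
  pva0 <- predicted_vs_actual(fit_scheffe(study$design, y0, "quadratic"))
  expect_equal(pva0$pairs$actual, pva0$pairs$fitted, tolerance = 1e-9)
  expect_equal(pva0$slope, 1, tolerance = 1e-9)

  pva <- predicted_vs_actual(fit_ps_dtx)
  # residual scale anchored by the printed residual MS (~0.47)
  expect_true(all(abs(pva$pairs$actual - pva$pairs$fitted) < 2.5))
  # VMD fit is visibly less calibrated than particle size
  pva_vmd <- predicted_vs_actual(fit_vmd_dtx)
  r2 <- function(p) cor(p$pairs$actual, p$pairs$fitted)^2
  expect_lt(r2(pva_vmd), r2(pva))
})
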