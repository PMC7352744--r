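#' Reference docetaxel / curcumin nanoemulsion study data
#'
#' Embedded data from a published D-optimal mixture-design study of
#' aerosolized docetaxel (DTX)- and curcumin (CCM)-loaded nanoemulsions.
#' Components: A = PKOE:safflower seed oil mixture (1:1), B = lecithin,
#' C = Tween 85:Span 85 (9:1), D = glycerol, E = water; all wt%, total
#' 100.
#'
#' * `dcn_region()` — the bounded design space (component limits).
#' * `dcn_design()` — the 24-run design with both responses per drug:
#'   particle size (nm) and aerosol volume median diameter VMD (um).
#' * `dcn_models()` — the four published regression equations as
#'   `scheffe_model` objects in pseudo coding (quadratic for particle
#'   size, linear for VMD), coefficients exactly as printed (2 dp).
#' * `dcn_validation()` — the external validation formulations (three
#'   random + the optimum per drug) with actual and predicted responses.
#' * `dcn_aerosol()` — laser-diffraction percentiles and cascade-impactor
#'   summary statistics (mean and sd) of the two optimized formulations.
#' * `dcn_goal()` — the desirability goal configuration under which
#'   [optimize_formulation()] reproduces the study's reported optimum
#'   composition (read from `inst/extdata/dcn_goal.yaml`).
#'
#' @return See each description above; designs are [mixture_design()]
#'   objects, tables are data frames.
#' @name dcn_data
NULL

#' @rdname dcn_data
#' @export
dcn_region <- function() {
  mixture_region(
    names = c("A", "B", "C", "D", "E"),
    lower = c(4.0, 2.0, 1.0, 1.5, 86.0),
    upper = c(6.0, 3.0, 2.0, 3.0, 91.5),
    total = 100
  )
}

#' @rdname dcn_data
#' @export
dcn_design <- function() {
  df <- data.frame(
    A = c(4, 4, 4, 5, 6, 6, 6, 4, 6, 6, 5, 6, 6, 4, 4, 5, 5, 5, 5, 5, 5,
          5, 5, 4),
    B = c(2, 3, 3, 2.5, 2, 2, 2.5, 2, 3, 3, 3, 3, 2, 2, 3, 2, 3, 2, 3, 2,
          2.5, 2.5, 2.5, 3),
    C = c(1, 1, 2, 1.5, 1, 1.5, 2, 2, 1, 1.5, 2, 2, 2, 1.5, 1.5, 1, 1, 2,
          1, 2, 1.5, 1.5, 1.5, 2),
    D = c(1.5, 3, 3, 2.25, 3, 1.5, 1.5, 1.5, 1.5, 3, 1.5, 2.25, 3, 3, 1.5,
          1.5, 3, 3, 1.5, 1.5, 2.25, 2.25, 2.25, 3),
    E = c(91.5, 89, 88, 88.75, 88, 89, 88, 90.5, 88.5, 86.5, 88.5, 86.75,
          87, 89.5, 90, 90.5, 88, 88, 89.5, 89.5, 88.75, 88.75, 88.75, 88),
    ps_dtx = c(114.41, 113.12, 101.88, 102.93, 103.16, 106.14, 96.92,
               103.11, 104.55, 105.32, 94.59, 96.48, 99.31, 108.50, 109.07,
               108.71, 107.16, 100.11, 106.08, 100.77, 102.89, 103.88,
               103.76, 102.52),
    ps_ccm = c(118.38, 113.80, 98.49, 106.76, 119.92, 103.90, 94.55,
               109.21, 120.01, 105.42, 97.26, 97.19, 102.72, 113.11,
               113.07, 112.76, 113.31, 102.43, 118.04, 98.72, 107.57,
               106.32, 106.28, 97.51),
    vmd_dtx = c(5.19, 5.33, 5.13, 5.43, 5.24, 5.31, 5.34, 5.15, 5.47,
                5.41, 5.32, 5.27, 5.22, 5.11, 5.29, 5.27, 5.55, 5.12,
                5.34, 5.14, 5.22, 5.27, 5.29, 5.30),
    vmd_ccm = c(5.28, 5.22, 5.26, 5.31, 5.21, 5.45, 5.15, 5.11, 5.15,
                5.32, 5.50, 5.10, 5.17, 5.37, 5.24, 5.20, 5.10, 5.31,
                5.25, 5.23, 5.28, 5.11, 5.36, 5.39)
  )
  list(
    design = mixture_design(df[, c("A", "B", "C", "D", "E")], dcn_region()),
    responses = df[, c("ps_dtx", "ps_ccm", "vmd_dtx", "vmd_ccm")]
  )
}

#' @rdname dcn_data
#' @export
dcn_models <- function() {
  region <- dcn_region()
  list(
    ps_dtx = scheffe_model(
      c(128.29, 208.83, -219.77, 133.96, 114.30,
        -191.85, 350.39, -96.55, -54.91, 115.41, -79.11, -126.94,
        349.42, 336.19, -49.55),
      order = "quadratic", region = region),
    vmd_dtx = scheffe_model(
      c(5.55, 5.99, 4.60, 5.17, 5.21), order = "linear", region = region),
    ps_ccm = scheffe_model(
      c(168.39, 244.63, 149.55, 28.09, 118.53,
        -184.49, -327.76, 90.15, -99.98, -438.80, -168.24, -129.62,
        29.91, -102.07, 123.59),
      order = "quadratic", region = region),
    vmd_ccm = scheffe_model(
      c(5.48, 6.06, 5.29, 4.91, 5.10), order = "linear", region = region)
  )
}

#' @rdname dcn_data
#' @export
dcn_validation <- function() {
  data.frame(
    formulation = c("DNE_1", "DNE_2", "DNE_3", "DNE_opt",
                    "CNE_1", "CNE_2", "CNE_3", "CNE_opt"),
    drug = rep(c("DTX", "CCM"), each = 4L),
    A = c(5.50, 4.50, 5.20, 6.00, 5.20, 4.80, 4.50, 6.00),
    B = c(2.60, 2.40, 2.25, 2.50, 2.70, 2.70, 2.30, 2.50),
    C = c(1.60, 1.40, 1.60, 2.00, 1.70, 1.30, 1.60, 2.00),
    D = c(2.20, 2.30, 2.20, 2.50, 2.00, 2.10, 2.40, 2.50),
    E = c(88.10, 89.40, 88.75, 87.00, 88.40, 89.10, 89.20, 87.00),
    ps_actual = c(103.5, 107.3, 102.4, 95.8, 103.1, 113.2, 108.8, 96.9),
    ps_predicted = c(101.5, 106.1, 102.8, 97.2, 102.6, 110.8, 110.5, 98.4),
    ps_rse = c(1.97, 1.13, 0.39, 1.44, 0.49, 2.17, 1.54, 1.52),
    vmd_actual = c(5.45, 5.39, 5.41, 5.48, 5.44, 5.34, 5.25, 5.40),
    vmd_predicted = c(5.31, 5.22, 5.26, 5.28, 5.31, 5.26, 5.17, 5.32),
    vmd_rse = c(2.64, 3.26, 2.85, 3.79, 2.45, 1.52, 1.55, 1.50),
    stringsAsFactors = FALSE
  )
}

#' @rdname dcn_data
#' @export
dcn_aerosol <- function() {
  data.frame(
    characteristic = c("dv10_um", "dv50_um", "dv90_um", "span",
                       "pd_percent", "pi_percent", "mmad_um", "gsd",
                       "fpf_percent"),
    dne_mean = c(2.50, 5.48, 11.48, 1.64, 70.82, 70.13, 3.19, 1.71, 76.85),
    dne_sd = c(0.05, 0.14, 0.83, 0.12, 10.66, 10.61, 0.15, 0.08, 6.01),
    cne_mean = c(2.38, 5.40, 11.53, 1.69, 73.89, 72.67, 3.08, 1.67, 83.30),
    cne_sd = c(0.08, 0.16, 0.92, 0.14, 4.03, 3.89, 0.15, 0.15, 2.81),
    stringsAsFactors = FALSE
  )
}

#' @rdname dcn_data
#' @param models Named list of Scheffe models to score (defaults to the
#'   published equations, [dcn_models()]).
#' @export
dcn_goal <- function(models = dcn_models()) {
  read_goal_yaml(system.file("extdata", "dcn_goal.yaml",
                             package = "mixaero", mustWork = TRUE),
                 models)
}
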