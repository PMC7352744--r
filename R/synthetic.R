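#' Simulate responses from a known Scheffe surface
#'
#' Generates per-run responses \eqn{y_i = f(x_i) + N(0, sd^2)} with
#' i.i.d. homoscedastic Gaussian noise on top of a known Scheffe
#' polynomial — the error structure assumed by the ordinary
#' least-squares / ANOVA analysis. Bit-reproducible for a fixed seed;
#' the caller's RNG state is untouched.
#'
#' @param truth A `scheffe_model` (ground-truth surface).
#' @param design A [mixture_design()] within the truth's region.
#' @param noise_sd Response-unit noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric response vector, one value per run.
#' @export
simulate_responses <- function(truth, design, noise_sd, seed = 1L) {
  stopifnot(noise_sd >= 0)
  mu <- predict(truth, design$runs)
  if (noise_sd == 0) return(mu)
  with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
}

#' Simulate a cascade impactor run from a lognormal aerosol
#'
#' Draws `n_quanta` aerodynamic diameters from a lognormal distribution
#' (median `median_um`, geometric standard deviation `gsd`), bins them
#' into stages by cutoff window, and converts counts to deposited mass.
#' Mass accounting: a `device_fraction` of the loaded dose stays in the
#' nebulizer (excluded from the emitted dose), a further `port_fraction`
#' of the emitted dose lands on the impactor inlet assembly (counted in
#' the emitted dose but not on any stage), and the remainder is
#' distributed over the stages proportionally to the sampled quanta. By
#' construction PD is 100(1 - device_fraction) and PI is slightly below
#' it.
#'
#' @param median_um Median aerodynamic diameter (um).
#' @param gsd Geometric standard deviation (>= 1; 1 = monodisperse).
#' @param total_dose Drug mass loaded.
#' @param cutoffs Stage cutoff table, see [aci_cutoffs()].
#' @param device_fraction Fraction of the dose retained in the nebulizer.
#' @param port_fraction Fraction of the emitted dose on the inlet
#'   assembly.
#' @param n_quanta Number of mass quanta sampled (> 0).
#' @param seed Integer seed.
#' @return An [impactor_run()].
#' @export
simulate_impactor <- function(median_um, gsd, total_dose,
                              cutoffs = aci_cutoffs(),
                              device_fraction = 0.3, port_fraction = 0.01,
                              n_quanta = 1e5, seed = 1L) {
  stopifnot(gsd >= 1, median_um > 0, n_quanta > 0,
            device_fraction >= 0, device_fraction < 1,
            port_fraction >= 0, port_fraction < 1)
  if (any(diff(cutoffs$cutoff_um) >= 0)) {
    stop("cutoffs must be strictly decreasing")
  }
  d <- with_seed(seed, stats::rlnorm(n_quanta, log(median_um), log(gsd)))
  # stage j collects diameters in [cutoff_j, cutoff_{j-1}); the top stage
  # also takes everything coarser, the filter everything finer
  breaks <- c(Inf, cutoffs$cutoff_um[cutoffs$cutoff_um > 0], 0)
  counts <- as.numeric(table(cut(d, rev(breaks), right = FALSE)))
  counts <- rev(counts)
  emitted <- total_dose * (1 - device_fraction)
  stage_total <- emitted * (1 - port_fraction)
  stages <- data.frame(label = cutoffs$label, cutoff_um = cutoffs$cutoff_um,
                       mass = stage_total * counts / n_quanta,
                       stringsAsFactors = FALSE)
  device <- data.frame(label = "inlet_assembly",
                       mass = emitted * port_fraction,
                       stringsAsFactors = FALSE)
  impactor_run(stages, device, total_dose)
}
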