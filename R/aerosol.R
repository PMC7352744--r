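#' Span of a laser-diffraction droplet size distribution
#'
#' \eqn{(DV_{90} - DV_{10}) / DV_{50}}: how far apart the 10% and 90%
#' undersize points are, normalized by the volume median diameter.
#'
#' @param dv10,dv50,dv90 Percentile diameters in micrometres,
#'   `0 < dv10 <= dv50 <= dv90`.
#' @return Dimensionless span (vectorized).
#' @examples
#' span(2.50, 5.48, 11.48)  # 1.64
#' @export
span <- function(dv10, dv50, dv90) {
  if (any(dv50 <= 0)) stop("dv50 must be positive")
  if (any(dv10 <= 0 | dv10 > dv50 | dv50 > dv90)) {
    stop("need 0 < dv10 <= dv50 <= dv90")
  }
  (dv90 - dv10) / dv50
}

#' Default eight-stage cascade impactor cutoff table
#'
#' Nominal lower cutoff diameters for stages 0-7 plus the back-up filter
#' of an eight-stage Andersen cascade impactor. Stages 3-6 correspond to
#' the collection windows 3.3-4.70, 2.10-3.3, 1.10-2.10 and
#' 0.65-1.10 um used in the reference nanoemulsion study; the remaining
#' stages carry the standard nominal values and should be replaced when
#' a calibrated table for the operating flow rate is available.
#'
#' @return Data frame with columns `label`, `cutoff_um` (strictly
#'   decreasing; filter = 0).
#' @export
aci_cutoffs <- function() {
  data.frame(
    label = c(as.character(0:7), "filter"),
    cutoff_um = c(9.0, 5.8, 4.7, 3.3, 2.1, 1.1, 0.65, 0.43, 0),
    stringsAsFactors = FALSE
  )
}

#' Construct a cascade impactor run
#'
#' @param stages Data frame with columns `label`, `cutoff_um` (strictly
#'   decreasing lower cutoff diameters; the final back-up filter has
#'   cutoff 0) and `mass` (deposited drug mass, any consistent unit).
#' @param device_parts Optional data frame with columns `label`, `mass`
#'   for non-stage collection surfaces of the impactor assembly
#'   (adapter, mouthpiece, inlet cone, induction port).
#' @param total_dose Drug mass loaded into the nebulizer.
#' @return Object of class `impactor_run`.
#' @export
impactor_run <- function(stages, device_parts = NULL, total_dose) {
  stopifnot(all(c("label", "cutoff_um", "mass") %in% names(stages)))
  if (any(stages$mass < 0)) stop("stage masses must be non-negative")
  if (any(diff(stages$cutoff_um) >= 0)) {
    stop("stage cutoffs must be strictly decreasing")
  }
  if (is.null(device_parts)) {
    device_parts <- data.frame(label = character(), mass = numeric())
  }
  if (any(device_parts$mass < 0)) stop("device masses must be non-negative")
  if (total_dose <= 0) stop("total_dose must be positive")
  dep <- sum(stages$mass) + sum(device_parts$mass)
  if (dep > total_dose * (1 + 1e-9)) {
    stop("total deposits (", signif(dep, 6), ") exceed total_dose (",
         total_dose, ")")
  }
  structure(
    list(stages = stages, device_parts = device_parts,
         total_dose = total_dose),
    class = "impactor_run"
  )
}

# cumulative % undersize at each non-filter cutoff; ascending diameter
cumulative_undersize <- function(run) {
  st <- run$stages
  total <- sum(st$mass)
  below <- rev(cumsum(rev(st$mass)))    # mass on this stage and finer
  under <- c(below[-1L], 0)             # mass strictly finer than cutoff
  keep <- st$cutoff_um > 0
  data.frame(diameter_um = rev(st$cutoff_um[keep]),
             undersize_pct = rev(100 * under[keep] / total))
}

interp_percentile <- function(curve, pct, interpolation) {
  x <- curve$undersize_pct
  ld <- log10(curve$diameter_um)
  # trim plateau points (zero-mass stages) to the innermost cutoffs so
  # interpolation brackets each jump by its actual collection window
  n <- length(x)
  if (n > 2L) {
    keep <- vapply(seq_len(n), function(i) {
      (i < n && x[i + 1L] > x[i]) || (i > 1L && x[i] > x[i - 1L])
    }, logical(1))
    if (any(keep)) {
      x <- x[keep]
      ld <- ld[keep]
    }
  }
  if (interpolation == "probit") {
    ok <- x > 0 & x < 100
    x <- stats::qnorm(x[ok] / 100)
    ld <- ld[ok]
    pct_t <- stats::qnorm(pct / 100)
  } else {
    pct_t <- pct
  }
  dup <- duplicated(x)
  x <- x[!dup]
  ld <- ld[!dup]
  if (length(x) < 2L) {
    warning("degenerate cumulative curve; reporting boundary diameter")
    return(10^ld[1L])
  }
  if (pct_t < min(x) || pct_t > max(x)) {
    warning(sprintf("percentile %.2f%% outside the cumulative curve; %s",
                    pct, "extrapolating from the end segment"))
    ix <- if (pct_t < min(x)) order(x)[1:2] else order(x, decreasing = TRUE)[2:1]
    sl <- (ld[ix[2]] - ld[ix[1]]) / (x[ix[2]] - x[ix[1]])
    return(10^(ld[ix[1]] + sl * (pct_t - x[ix[1]])))
  }
  10^stats::approx(x, ld, xout = pct_t, ties = "ordered")$y
}

#' Summarize a cascade impactor run
#'
#' Computes the aerodynamic performance metrics:
#' * emitted dose `ed` — all drug collected from the impactor assembly
#'   (device parts plus every stage and the filter);
#' * percent dispersed `pd_percent` — 100 ED / total dose;
#' * percent inhaled `pi_percent` — 100 (stage 0 through 7, filter
#'   included by default) / total dose;
#' * `mmad_um` — diameter at 50% cumulative mass undersize, interpolated
#'   linearly in log10(diameter) on the cutoff-diameter curve
#'   (probit-scale interpolation available);
#' * `gsd` — sqrt(d(84.13%) / d(15.87%)) by the same interpolation;
#' * fine particle fraction `fpf_percent` — 100 (stage `fpf_from`
#'   through filter) / ED.
#'
#' @param run An [impactor_run()].
#' @param fpf_from Label of the first stage counted in the FPF
#'   (default `"4"`).
#' @param pi_include_filter Count the back-up filter in PI (default
#'   `TRUE`; the alternative reading of "stages 0 to 7" excludes it).
#' @param interpolation `"loglinear"` (default) or `"probit"` scale for
#'   the MMAD/GSD percentile interpolation.
#' @return Object of class `impactor_summary` with fields `ed`,
#'   `pd_percent`, `pi_percent`, `mmad_um`, `gsd`, `fpf_percent`.
#' @export
impactor_summary <- function(run, fpf_from = "4", pi_include_filter = TRUE,
                             interpolation = c("loglinear", "probit")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(run, "impactor_run"))
  st <- run$stages
  stage_mass <- sum(st$mass)
  if (stage_mass <= 0) stop("no mass on any stage")
  ed <- stage_mass + sum(run$device_parts$mass)
  pd <- 100 * ed / run$total_dose
  pi_mass <- if (pi_include_filter) stage_mass else
    sum(st$mass[st$label != "filter"])
  pi <- 100 * pi_mass / run$total_dose
  fpf_ix <- match(fpf_from, st$label)
  if (is.na(fpf_ix)) stop("no stage labelled '", fpf_from, "'")
  fpf <- 100 * sum(st$mass[fpf_ix:nrow(st)]) / ed
  curve <- cumulative_undersize(run)
  mmad <- interp_percentile(curve, 50, interpolation)
  d84 <- interp_percentile(curve, 84.13, interpolation)
  d16 <- interp_percentile(curve, 15.87, interpolation)
  gsd <- sqrt(d84 / d16)
  structure(
    list(ed = ed, pd_percent = pd, pi_percent = pi,
         mmad_um = mmad, gsd = gsd, fpf_percent = fpf),
    class = "impactor_summary"
  )
}

#' @export
print.impactor_summary <- function(x, ...) {
  cat(sprintf(paste0("Impactor summary: ED %.4g, PD %.2f%%, PI %.2f%%, ",
                     "MMAD %.2f um, GSD %.2f, FPF %.2f%%\n"),
              x$ed, x$pd_percent, x$pi_percent, x$mmad_um, x$gsd,
              x$fpf_percent))
  invisible(x)
}
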