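#' Define a bounded mixture design space
#'
#' A mixture region is the intersection of the simplex
#' \eqn{\sum_j x_j = \mathrm{total}} with per-component box constraints
#' \eqn{L_j \le x_j \le U_j}. In formulation work the components are
#' ingredient amounts in wt% and `total` is 100.
#'
#' @param names Character vector of component labels.
#' @param lower,upper Numeric vectors of per-component bounds, same units
#'   as `total`.
#' @param total Amount all components must sum to (default 100 wt%).
#'
#' @return An object of class `mixture_region` with elements `names`,
#'   `lower`, `upper`, `total`.
#' @examples
#' mixture_region(c("oil", "water"), lower = c(10, 0), upper = c(40, 90))
#' @export
mixture_region <- function(names, lower, upper, total = 100) {
  q <- length(names)
  stopifnot(length(lower) == q, length(upper) == q, q >= 2)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (any(lower < 0) || any(lower > upper) || any(upper > total)) {
    stop("component bounds must satisfy 0 <= lower <= upper <= total")
  }
  if (sum(lower) > total + 1e-9 || sum(upper) < total - 1e-9) {
    stop("empty mixture region: need sum(lower) <= total <= sum(upper)")
  }
  structure(
    list(names = as.character(names), lower = lower, upper = upper,
         total = total),
    class = "mixture_region"
  )
}

#' @export
print.mixture_region <- function(x, ...) {
  cat("Mixture region:", length(x$names), "components, total =", x$total, "\n")
  print(data.frame(component = x$names, lower = x$lower, upper = x$upper),
        row.names = FALSE)
  invisible(x)
}

n_components <- function(region) length(region$names)

#' Centroid of a mixture region
#'
#' The vertex centroid of the constrained region: the mean of its extreme
#' vertices. For a region whose free components form a full box (one
#' filler component absorbing the difference) this is the point with every
#' free component at the middle of its range.
#'
#' @param region A [mixture_region()].
#' @return Numeric vector of component amounts.
#' @export
region_centroid <- function(region) {
  v <- region_vertices(region)
  if (nrow(v) == 0L) stop("region has no vertices")
  cen <- colMeans(v)
  names(cen) <- region$names
  cen
}

# checks one blend (vector) against region bounds; returns TRUE/character
check_in_region <- function(x, region, tol = 1e-8) {
  if (abs(sum(x) - region$total) > max(tol, 1e-9 * region$total)) {
    return(sprintf("amounts sum to %.10g, not %g", sum(x), region$total))
  }
  bad <- which(x < region$lower - tol | x > region$upper + tol)
  if (length(bad)) {
    return(sprintf("component(s) %s outside bounds",
                   paste(region$names[bad], collapse = ", ")))
  }
  TRUE
}
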