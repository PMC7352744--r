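#' Pseudo-component (L-pseudo) coding
#'
#' Maps a lower-bounded mixture region onto the unit simplex by the affine
#' rescaling \eqn{x'_i = (x_i - L_i) / (\mathrm{total} - \sum_j L_j)}.
#' Fitting Scheffe polynomials in pseudo coordinates keeps the model
#' matrix well conditioned when the region is a thin slice of the full
#' simplex, and is the coding in which the study's published equations
#' are expressed.
#'
#' @param x Numeric vector (one blend) or matrix/data.frame (one blend per
#'   row) of real component amounts summing to `region$total`.
#' @param region A [mixture_region()].
#' @param check If `TRUE` (default), error on blends outside the region;
#'   if `FALSE`, only the sum constraint is enforced (used by prediction,
#'   which warns on extrapolation instead of failing).
#' @return Same shape as `x`, pseudo amounts summing to 1 per blend.
#' @examples
#' reg <- mixture_region(c("A", "B", "C", "D", "E"),
#'                       lower = c(4, 2, 1, 1.5, 86),
#'                       upper = c(6, 3, 2, 3, 91.5))
#' to_pseudo(c(6, 2.5, 2, 2.5, 87), reg)
#' @export
to_pseudo <- function(x, region, check = TRUE) {
  denom <- region$total - sum(region$lower)
  if (denom <= 0) {
    stop("degenerate region: sum of lower bounds equals the total ",
         "(zero-volume region, pseudo coding undefined)")
  }
  if (is.null(dim(x))) {
    msg <- check_in_region(x, region)
    if (!isTRUE(msg) && check) stop("blend out of region: ", msg)
    out <- (x - region$lower) / denom
    names(out) <- region$names
    return(out)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == n_components(region))
  if (check) {
    for (i in seq_len(nrow(x))) {
      msg <- check_in_region(x[i, ], region)
      if (!isTRUE(msg)) stop("run ", i, " out of region: ", msg)
    }
  }
  out <- sweep(x, 2, region$lower) / denom
  colnames(out) <- region$names
  out
}

#' @rdname to_pseudo
#' @param xp Pseudo amounts (vector or matrix) summing to 1 per blend.
#' @export
from_pseudo <- function(xp, region) {
  denom <- region$total - sum(region$lower)
  if (is.null(dim(xp))) {
    out <- xp * denom + region$lower
    names(out) <- region$names
    return(out)
  }
  xp <- as.matrix(xp)
  out <- sweep(xp * denom, 2, region$lower, "+")
  colnames(out) <- region$names
  out
}
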