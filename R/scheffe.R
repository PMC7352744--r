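#' Scheffe canonical polynomial terms
#'
#' The Scheffe parameterization has no intercept: the mixture constraint
#' makes a constant column redundant. Term sets by order, for q
#' components:
#' * `linear` — the q single-component terms;
#' * `quadratic` — plus the q(q-1)/2 pairwise products;
#' * `special_cubic` — plus all three-way products.
#'
#' @param q Number of components.
#' @param order One of `"linear"`, `"quadratic"`, `"special_cubic"`.
#' @param names Optional component labels (default `x1`, `x2`, ...).
#' @return List of integer index vectors, canonically ordered (singles by
#'   index, then pairs lexicographic, then triples), named like `"A"`,
#'   `"A:B"`, `"A:B:C"`.
#' @export
scheffe_terms <- function(q, order = c("linear", "quadratic", "special_cubic"),
                          names = NULL) {
  order <- match.arg(order)
  if (is.null(names)) names <- paste0("x", seq_len(q))
  terms <- as.list(seq_len(q))
  if (order %in% c("quadratic", "special_cubic")) {
    terms <- c(terms, utils::combn(q, 2L, simplify = FALSE))
  }
  if (order == "special_cubic") {
    if (q < 3L) stop("special cubic model needs at least 3 components")
    terms <- c(terms, utils::combn(q, 3L, simplify = FALSE))
  }
  names(terms) <- vapply(terms, function(ix) paste(names[ix], collapse = ":"),
                         character(1))
  terms
}

#' Scheffe model matrix
#'
#' Column j for term t is the product of that term's pseudo-component
#' columns, one row per run. Fitting is always done in pseudo coding
#' (see [to_pseudo()]); pass a `mixture_design` to have the conversion
#' applied, or a plain matrix that is already pseudo-coded.
#'
#' @param design A [mixture_design()] (real coordinates; converted
#'   internally) or a numeric matrix of pseudo coordinates.
#' @param order Model order, see [scheffe_terms()].
#' @return Numeric matrix, n runs by p terms, canonically ordered columns.
#' @export
scheffe_model_matrix <- function(design, order = c("linear", "quadratic",
                                                   "special_cubic")) {
  order <- match.arg(order)
  if (inherits(design, "mixture_design")) {
    P <- to_pseudo(design$runs, design$region)
  } else {
    P <- as.matrix(design)
  }
  nm <- colnames(P)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(P)))
  terms <- scheffe_terms(ncol(P), order, nm)
  X <- vapply(terms, function(ix) {
    apply(P[, ix, drop = FALSE], 1L, prod)
  }, numeric(nrow(P)))
  if (nrow(P) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(terms)))
  X
}

#' Construct a Scheffe model from known coefficients
#'
#' Used both for the published regression equations (shipped as fixtures,
#' see [dcn_models()]) and as the ground truth of synthetic-data
#' simulations.
#'
#' @param coefficients Named numeric vector in canonical term order
#'   (names are checked against the region's component labels).
#' @param order Model order.
#' @param region The [mixture_region()] the model is defined over.
#' @param coding Coding of the coefficients; only `"pseudo"` is supported
#'   for construction (the package fits and reports in pseudo coding).
#' @return Object of class `scheffe_model`.
#' @export
scheffe_model <- function(coefficients, order = c("linear", "quadratic",
                                                  "special_cubic"),
                          region, coding = "pseudo") {
  order <- match.arg(order)
  coding <- match.arg(coding, "pseudo")
  terms <- scheffe_terms(n_components(region), order, region$names)
  if (length(coefficients) != length(terms)) {
    stop("expected ", length(terms), " coefficients for a ", order,
         " model in ", n_components(region), " components, got ",
         length(coefficients))
  }
  if (!is.null(names(coefficients)) &&
      !identical(names(coefficients), names(terms))) {
    coefficients <- coefficients[names(terms)]
    if (anyNA(coefficients)) stop("coefficient names do not match terms")
  }
  names(coefficients) <- names(terms)
  structure(
    list(coefficients = coefficients, order = order, region = region,
         coding = coding, terms = terms),
    class = "scheffe_model"
  )
}

#' @export
print.scheffe_model <- function(x, ...) {
  cat("Scheffe", x$order, "model (", x$coding, "coding ) over",
      n_components(x$region), "components\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit a Scheffe polynomial by no-intercept least squares
#'
#' Converts the design to pseudo coding, builds the canonical model
#' matrix and solves the least-squares problem by QR decomposition.
#' The total sum of squares is mean-corrected: although the model has no
#' intercept, the mixture constraint makes the columns sum to one, so the
#' response mean is the natural null model and the convention reproduces
#' the fit statistics reported by standard mixture-design software.
#'
#' @param design A [mixture_design()].
#' @param y Numeric response vector, one value per run.
#' @param order Model order, see [scheffe_terms()].
#' @return Object of class `scheffe_fit`: the fitted `model`
#'   (a [scheffe_model()]), `fitted`, `residuals`, `ss_total_corrected`,
#'   `ss_model`, `ss_residual`, `dof` (residual), `n`, `p`, and the
#'   training `design` and `y`.
#' @export
fit_scheffe <- function(design, y, order = c("linear", "quadratic",
                                             "special_cubic")) {
  order <- match.arg(order)
  stopifnot(inherits(design, "mixture_design"))
  y <- as.numeric(y)
  n <- nrow(design$runs)
  if (length(y) != n) stop("length(y) != number of runs")
  X <- scheffe_model_matrix(design, order)
  p <- ncol(X)
  if (n < p) {
    stop("cannot fit ", order, " model: ", p, " terms but only ", n, " runs")
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient model matrix; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  fitted <- as.numeric(fit$fitted.values)
  res <- as.numeric(fit$residuals)
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(model = scheffe_model(fit$coefficients, order, design$region),
         fitted = fitted, residuals = res,
         ss_total_corrected = sst, ss_model = sst - ssr, ss_residual = ssr,
         dof = n - p, n = n, p = p, design = design, y = y),
    class = "scheffe_fit"
  )
}

#' @export
print.scheffe_fit <- function(x, ...) {
  cat("Scheffe", x$model$order, "fit:", x$n, "runs,", x$p, "terms\n")
  cat(sprintf("  R-squared %.4f (adj %.4f), residual MS %.4g on %d df\n",
              r_squared(x), adj_r_squared(x),
              x$ss_residual / max(x$dof, 1L), x$dof))
  print(round(x$model$coefficients, 4))
  invisible(x)
}

#' Predict from a Scheffe model at real-coordinate blends
#'
#' Blends are converted to pseudo coding and the polynomial evaluated.
#' Out-of-region blends produce a warning (extrapolation), not an error.
#'
#' @param object A `scheffe_model` or `scheffe_fit`.
#' @param newdata Numeric vector (one blend, real wt%) or matrix/
#'   data.frame of blends; if omitted for a fit, the training runs.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.scheffe_model <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else
    as.matrix(newdata)
  for (i in seq_len(nrow(x))) {
    msg <- check_in_region(x[i, ], object$region)
    if (!isTRUE(msg)) {
      warning("blend ", i, " outside the model region (extrapolating): ",
              msg, call. = FALSE)
    }
  }
  P <- to_pseudo(x, object$region, check = FALSE)
  X <- scheffe_model_matrix(P, object$order)
  as.numeric(X %*% object$coefficients)
}

#' @rdname predict.scheffe_model
#' @export
predict.scheffe_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  predict(object$model, newdata, ...)
}

#' Evaluate a Scheffe model on a regular grid of a 2- or 3-component slice
#'
#' Varies the chosen free components over a lattice spanning their bounds
#' while holding the other non-filler components at stated values; the
#' filler component absorbs the difference. Grid points falling outside
#' the region are dropped (and counted in the `dropped` attribute), so
#' the result is suitable for contour / surface displays of the fitted
#' response over the feasible slice.
#'
#' @param model A `scheffe_model` (or `scheffe_fit`).
#' @param free Integer or character vector of 2 or 3 free components.
#' @param fixed Named numeric vector of values for the remaining
#'   components other than `filler` (defaults to the region centroid
#'   values).
#' @param filler Component absorbing the difference (default: the one
#'   with the widest range among non-free components).
#' @param resolution Number of grid levels per free component.
#' @return Data frame of blends (real wt%) with a `predicted` column;
#'   attribute `dropped` counts out-of-region lattice points excluded.
#' @export
surface_grid <- function(model, free, fixed = NULL, filler = NULL,
                         resolution = 21L) {
  if (inherits(model, "scheffe_fit")) model <- model$model
  region <- model$region
  q <- n_components(region)
  if (is.character(free)) free <- match(free, region$names)
  stopifnot(length(free) %in% c(2L, 3L), !anyNA(free))
  if (any(region$upper[free] - region$lower[free] <= 0)) {
    stop("free component with collapsed bounds: ",
         paste(region$names[free][region$upper[free] - region$lower[free] <= 0],
               collapse = ", "))
  }
  rest <- setdiff(seq_len(q), free)
  if (is.null(filler)) {
    filler <- rest[which.max(region$upper[rest] - region$lower[rest])]
  } else if (is.character(filler)) filler <- match(filler, region$names)
  held <- setdiff(rest, filler)
  cen <- region_centroid(region)
  held_vals <- cen[held]
  if (!is.null(fixed)) {
    ix <- match(names(fixed), region$names[held])
    if (anyNA(ix)) stop("fixed must name non-free, non-filler components")
    held_vals[ix] <- fixed
  }
  axes <- lapply(free, function(j) {
    seq(region$lower[j], region$upper[j], length.out = resolution)
  })
  g <- as.matrix(expand.grid(axes))
  blends <- matrix(NA_real_, nrow(g), q, dimnames = list(NULL, region$names))
  blends[, free] <- g
  for (k in seq_along(held)) blends[, held[k]] <- held_vals[k]
  blends[, filler] <- region$total - rowSums(blends[, -filler, drop = FALSE])
  keep <- blends[, filler] >= region$lower[filler] - 1e-9 &
    blends[, filler] <= region$upper[filler] + 1e-9
  dropped <- sum(!keep)
  blends <- blends[keep, , drop = FALSE]
  pred <- suppressWarnings(predict(model, blends))
  out <- cbind(as.data.frame(blends), predicted = pred)
  attr(out, "dropped") <- dropped
  out
}
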