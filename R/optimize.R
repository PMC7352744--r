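#' Residual standard error (percent) of a validation pair
#'
#' \eqn{100 (y_{actual} - y_{predicted}) / y_{predicted}}: the external
#' validation statistic comparing a measured response to the model
#' prediction. The signed value is returned; reports conventionally show
#' the magnitude.
#'
#' @param actual,predicted Numeric vectors (recycled).
#' @return Signed percent error.
#' @examples
#' rse_percent(95.8, 97.2)  # -1.44
#' @export
rse_percent <- function(actual, predicted) {
  if (any(predicted == 0)) stop("predicted value of 0: RSE undefined")
  100 * (actual - predicted) / predicted
}

#' Validate fitted models against measured formulations
#'
#' Computes one validation record per (formulation, response): the model
#' prediction at the formulation's composition, the signed and absolute
#' RSE, and a flag when |RSE| exceeds the acceptance bound. Formulations
#' outside the model region generate an extrapolation warning; missing
#' measured values are skipped with a warning.
#'
#' @param models Named list of `scheffe_model` / `scheffe_fit` objects
#'   sharing one region.
#' @param formulations Data frame with the region's component columns
#'   plus one measured-response column per model name; optionally a
#'   `formulation` id column.
#' @param rse_bound Flagging threshold on |RSE| in percent (default 5).
#' @return Data frame with columns `formulation`, `response`, `actual`,
#'   `predicted`, `rse`, `abs_rse`, `flagged`.
#' @export
validate_formulations <- function(models, formulations, rse_bound = 5) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  models <- lapply(models, function(m) {
    if (inherits(m, "scheffe_fit")) m$model else m
  })
  region <- models[[1]]$region
  comp <- as.matrix(formulations[, region$names, drop = FALSE])
  empty <- data.frame(formulation = character(), response = character(),
                      actual = numeric(), predicted = numeric(),
                      rse = numeric(), abs_rse = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE)
  if (nrow(comp) == 0L) return(empty)
  ids <- if ("formulation" %in% names(formulations)) {
    as.character(formulations$formulation)
  } else as.character(seq_len(nrow(comp)))
  out <- list()
  for (resp in names(models)) {
    if (!resp %in% names(formulations)) {
      warning("no measured column for response '", resp, "'; skipped")
      next
    }
    actual <- as.numeric(formulations[[resp]])
    pred <- predict(models[[resp]], comp)
    keep <- !is.na(actual)
    if (any(!keep)) {
      warning(sum(!keep), " formulation(s) lack a measured '", resp,
              "' value; skipped")
    }
    rse <- rse_percent(actual[keep], pred[keep])
    out[[resp]] <- data.frame(
      formulation = ids[keep], response = rep(resp, sum(keep)),
      actual = actual[keep], predicted = pred[keep],
      rse = rse, abs_rse = abs(rse), flagged = abs(rse) > rse_bound,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Desirability goals for responses and components
#'
#' Derringer-style one-sided / triangular desirabilities on \[0, 1\]:
#' * `minimize` — 1 at or below `low`, 0 at or above `high`;
#' * `maximize` — mirrored;
#' * `target` — 1 at `target`, falling linearly to 0 at `low` / `high`;
#' * `in_range` — 1 inside \[`low`, `high`\], 0 outside.
#'
#' `response_goal` scores a model prediction; `component_goal` scores a
#' component amount directly (bounds default to the region bounds at
#' optimization time). `weight` is the goal's exponent in the weighted
#' geometric mean.
#'
#' @param model A `scheffe_model` / `scheffe_fit` (response goal).
#' @param component Component name (component goal).
#' @param direction Goal direction, see above.
#' @param low,high Desirability anchor points (response units / wt%).
#' @param target Target value for `direction = "target"`.
#' @param weight Positive importance weight (default 1).
#' @param name Label used in reports.
#' @return Object of class `mix_goal`.
#' @export
response_goal <- function(model, direction = c("minimize", "maximize",
                                               "target", "in_range"),
                          low, high, target = NULL, weight = 1,
                          name = NULL) {
  direction <- match.arg(direction)
  if (inherits(model, "scheffe_fit")) model <- model$model
  stopifnot(weight > 0)
  structure(
    list(kind = "response", model = model, direction = direction,
         low = low, high = high, target = target, weight = weight,
         name = if (is.null(name)) "response" else name),
    class = "mix_goal"
  )
}

#' @rdname response_goal
#' @export
component_goal <- function(component, direction = c("minimize", "maximize",
                                                    "target", "in_range"),
                           low = NULL, high = NULL, target = NULL,
                           weight = 1, name = NULL) {
  direction <- match.arg(direction)
  stopifnot(weight > 0)
  structure(
    list(kind = "component", component = component, direction = direction,
         low = low, high = high, target = target, weight = weight,
         name = if (is.null(name)) component else name),
    class = "mix_goal"
  )
}

d_scale <- function(v, goal) {
  lo <- goal$low
  hi <- goal$high
  switch(goal$direction,
    minimize = pmin(1, pmax(0, (hi - v) / (hi - lo))),
    maximize = pmin(1, pmax(0, (v - lo) / (hi - lo))),
    target = {
      t <- goal$target
      ifelse(v <= t,
             pmax(0, (v - lo) / (t - lo)),
             pmax(0, (hi - v) / (hi - t)))
    },
    in_range = as.numeric(v >= lo & v <= hi)
  )
}

#' Overall desirability of blends under a set of goals
#'
#' The weighted geometric mean of the per-goal desirabilities,
#' \eqn{D = (\prod_k d_k^{w_k})^{1/\sum_k w_k}}; any fully undesirable
#' goal (d = 0) zeroes the overall score.
#'
#' @param x Blend (numeric vector) or matrix of blends, real wt%.
#' @param goals List of [response_goal()] / [component_goal()] objects
#'   (at least one response goal).
#' @param region A [mixture_region()] supplying default component-goal
#'   bounds.
#' @return Numeric vector of overall desirabilities in \[0, 1\].
#' @export
desirability <- function(x, goals, region) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, region$names))
  x <- as.matrix(x)
  stopifnot(length(goals) >= 1L)
  if (!any(vapply(goals, function(g) g$kind == "response", logical(1)))) {
    stop("at least one response goal is required")
  }
  logd <- 0
  wsum <- 0
  for (g in goals) {
    if (g$kind == "response") {
      v <- suppressWarnings(predict(g$model, x))
    } else {
      j <- match(g$component, region$names)
      if (is.na(j)) stop("unknown component in goal: ", g$component)
      if (is.null(g$low)) g$low <- region$lower[j]
      if (is.null(g$high)) g$high <- region$upper[j]
      v <- x[, j]
    }
    d <- d_scale(v, g)
    logd <- logd + g$weight * log(pmax(d, 0))   # log(0) = -Inf zeroes D
    wsum <- wsum + g$weight
  }
  exp(logd / wsum)
}

#' Optimize a formulation by desirability over the mixture region
#'
#' Grid seeding plus shrinking-grid local refinement: the free
#' components (all but the filler) are laid on a `resolution`-level
#' lattice, the filler absorbs the difference, infeasible points are
#' dropped, and the best lattice point is refined by repeatedly halving
#' the search box on a 5-level local lattice until the step falls below
#' 1e-7 wt%. Deterministic for fixed inputs; the refined optimum is
#' never worse than the best grid point.
#'
#' @param goals List of goals, see [desirability()].
#' @param region A [mixture_region()].
#' @param resolution Lattice levels per free component (default 21).
#' @param filler Component computed by difference (default: widest
#'   range).
#' @return List with `blend` (named wt% vector), `desirability`,
#'   `predictions` (named vector of response-goal predictions at the
#'   optimum), and `grid_best` (best unrefined lattice desirability).
#' @export
optimize_formulation <- function(goals, region, resolution = 21L,
                                 filler = NULL) {
  q <- n_components(region)
  if (is.null(filler)) {
    filler <- which.max(region$upper - region$lower)
  } else if (is.character(filler)) filler <- match(filler, region$names)
  free <- setdiff(seq_len(q), filler)

  eval_grid <- function(axes) {
    g <- as.matrix(expand.grid(axes))
    x <- matrix(NA_real_, nrow(g), q, dimnames = list(NULL, region$names))
    x[, free] <- g
    x[, filler] <- region$total - rowSums(g)
    keep <- x[, filler] >= region$lower[filler] - 1e-9 &
      x[, filler] <= region$upper[filler] + 1e-9
    x <- x[keep, , drop = FALSE]
    if (nrow(x) == 0L) return(NULL)
    list(x = x, d = desirability(x, goals, region))
  }

  axes <- lapply(free, function(j) {
    seq(region$lower[j], region$upper[j], length.out = resolution)
  })
  g0 <- eval_grid(axes)
  if (is.null(g0)) stop("empty feasible set on the search lattice")
  best_i <- which.max(g0$d)
  grid_best <- g0$d[best_i]
  if (grid_best <= 0) {
    warning("flat (all-zero) desirability on the lattice; ",
            "returning the first feasible lattice point")
  }
  best_x <- g0$x[best_i, ]
  best_d <- grid_best

  step <- vapply(free, function(j) {
    (region$upper[j] - region$lower[j]) / (resolution - 1L)
  }, numeric(1))
  while (max(step) > 1e-7) {
    axes <- lapply(seq_along(free), function(k) {
      j <- free[k]
      v <- best_x[j] + step[k] * seq(-1, 1, length.out = 5L)
      pmin(pmax(v, region$lower[j]), region$upper[j])
    })
    g <- eval_grid(axes)
    if (!is.null(g)) {
      i <- which.max(g$d)
      if (g$d[i] > best_d) {
        best_d <- g$d[i]
        best_x <- g$x[i, ]
      }
    }
    step <- step / 2
  }

  resp <- goals[vapply(goals, function(g) g$kind == "response", logical(1))]
  preds <- vapply(resp, function(g) {
    suppressWarnings(predict(g$model, best_x))
  }, numeric(1))
  names(preds) <- vapply(resp, function(g) g$name, character(1))
  list(blend = best_x, desirability = best_d, predictions = preds,
       grid_best = grid_best)
}

#' Read a desirability goal configuration from YAML
#'
#' The file has two blocks, `responses` and `components`; each entry
#' gives `direction` and its anchors (`low` / `high` / `target`) and an
#' optional `weight`. Response entries name the model (in `models`) they
#' score via `model:`.
#'
#' @param path YAML file path.
#' @param models Named list of fitted / constructed Scheffe models
#'   supplying the response predictions.
#' @return List of goals suitable for [optimize_formulation()].
#' @export
read_goal_yaml <- function(path, models) {
  cfg <- yaml::read_yaml(path)
  goals <- list()
  for (e in cfg$responses) {
    m <- models[[e$model]]
    if (is.null(m)) stop("goal file names unknown model '", e$model, "'")
    goals[[length(goals) + 1L]] <- response_goal(
      m, direction = e$direction, low = e$low, high = e$high,
      target = e$target, weight = if (is.null(e$weight)) 1 else e$weight,
      name = e$model
    )
  }
  for (e in cfg$components) {
    goals[[length(goals) + 1L]] <- component_goal(
      e$component, direction = e$direction, low = e$low, high = e$high,
      target = e$target, weight = if (is.null(e$weight)) 1 else e$weight
    )
  }
  goals
}
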