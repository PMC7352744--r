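#' D-efficiency of a mixture design
#'
#' \eqn{\det(X'X/n)^{1/p}} for the Scheffe model matrix of the given
#' order in pseudo coding — the scale-free per-parameter information of a
#' design, invariant under run reordering. A rank-deficient design
#' returns 0 with a warning.
#'
#' @param design A [mixture_design()].
#' @param order Scheffe model order.
#' @return Non-negative scalar.
#' @export
d_efficiency <- function(design, order = c("linear", "quadratic",
                                           "special_cubic")) {
  order <- match.arg(order)
  X <- scheffe_model_matrix(design, order)
  p <- ncol(X)
  n <- nrow(X)
  if (qr(X)$rank < p) {
    warning("rank-deficient design for the ", order, " model; D-efficiency 0")
    return(0)
  }
  d <- determinant(crossprod(X), logarithm = TRUE)
  exp(as.numeric(d$modulus) / p) / n
}

log_det_xtx <- function(X) {
  if (qr(X)$rank < ncol(X)) return(-Inf)
  as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
}

#' Select a D-optimal mixture design by point exchange
#'
#' Greedy point (Fedorov-style) exchange over a candidate list: starting
#' from seeded random full-rank subsets, each sweep tries every
#' (design-point, candidate) swap and accepts the best improvement of
#' \eqn{\det(X'X)} of the pseudo-coded Scheffe model matrix, until no
#' swap improves; the best of `restarts` restarts is kept. The objective
#' is recomputed from scratch at each accepted swap (designs here are
#' tiny) and is non-decreasing across iterations; the per-sweep trace is
#' stored in the `objective_trace` attribute. Replicate slots append
#' copies of the overall centroid (or the selected point of maximum
#' prediction-variance leverage), mirroring the usual lack-of-fit /
#' pure-error budget of mixture designs.
#'
#' @param candidates Candidate blends: matrix of real wt% rows, e.g. from
#'   [candidate_points()].
#' @param region A [mixture_region()].
#' @param order Scheffe model order the design should support.
#' @param n_runs Total number of runs including replicates.
#' @param n_replicates Number of replicate runs appended (default 0).
#' @param seed Integer seed making restarts deterministic.
#' @param restarts Number of random restarts (default 10).
#' @param replicate_point `"centroid"` (overall region centroid) or
#'   `"max_leverage"` (selected point with the largest hat value).
#' @return A [mixture_design()]; attributes `objective` (final
#'   log det(X'X) of the distinct-point design) and `objective_trace`.
#' @export
d_optimal_design <- function(candidates, region,
                             order = c("linear", "quadratic", "special_cubic"),
                             n_runs, n_replicates = 0L, seed = 1L,
                             restarts = 10L,
                             replicate_point = c("centroid", "max_leverage")) {
  order <- match.arg(order)
  replicate_point <- match.arg(replicate_point)
  candidates <- as.matrix(candidates)
  m <- n_runs - n_replicates
  F_all <- scheffe_model_matrix(to_pseudo(candidates, region), order)
  p <- ncol(F_all)
  if (m < p) {
    stop("infeasible: ", m, " distinct runs cannot estimate ", p,
         " model terms")
  }
  nc <- nrow(candidates)
  if (nc < m) stop("fewer candidates (", nc, ") than requested runs (", m, ")")
  if (qr(F_all)$rank < p) {
    stop("rank deficiency: candidate set does not span the ", order,
         " model space")
  }

  if (nc == m) {
    sel <- seq_len(m)   # no freedom: keep input order
    trace <- log_det_xtx(F_all[sel, , drop = FALSE])
  } else {
    best_obj <- -Inf
    best_sel <- NULL
    best_trace <- NULL
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        sel <- sample.int(nc, m)
        obj <- log_det_xtx(F_all[sel, , drop = FALSE])
        tries <- 0L
        while (!is.finite(obj) && tries < 50L) {
          sel <- sample.int(nc, m)
          obj <- log_det_xtx(F_all[sel, , drop = FALSE])
          tries <- tries + 1L
        }
        if (!is.finite(obj)) next
        trace <- obj
        repeat {
          improved <- FALSE
          for (i in seq_len(m)) {
            cur <- sel
            objs <- vapply(seq_len(nc), function(cc) {
              if (cc %in% cur[-i]) return(-Inf)
              cur[i] <- cc
              log_det_xtx(F_all[cur, , drop = FALSE])
            }, numeric(1))
            best_c <- which.max(objs)   # ties -> first candidate index
            if (objs[best_c] > obj + 1e-12) {
              sel[i] <- best_c
              obj <- objs[best_c]
              improved <- TRUE
            }
          }
          trace <- c(trace, obj)
          if (!improved) break
        }
        if (obj > best_obj) {
          best_obj <- obj
          best_sel <- sel
          best_trace <- trace
        }
      }
    })
    if (is.null(best_sel)) stop("singular model matrix for every start")
    sel <- best_sel
    trace <- best_trace
  }

  runs <- candidates[sel, , drop = FALSE]
  if (n_replicates > 0L) {
    rep_pt <- if (replicate_point == "centroid") {
      region_centroid(region)
    } else {
      Xs <- F_all[sel, , drop = FALSE]
      hat <- diag(Xs %*% solve(crossprod(Xs), t(Xs)))
      runs[which.max(hat), ]
    }
    runs <- rbind(runs, matrix(rep_pt, n_replicates, length(rep_pt),
                               byrow = TRUE))
  }
  des <- mixture_design(runs, region)
  attr(des, "objective") <- log_det_xtx(F_all[sel, , drop = FALSE])
  attr(des, "objective_trace") <- trace
  des
}
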