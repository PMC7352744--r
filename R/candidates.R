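#' Extreme vertices of a constrained mixture region
#'
#' Every vertex of the polytope \{L <= x <= U, sum(x) = total\} has at
#' least q-1 components at a bound, so vertices are enumerated by fixing
#' each subset of q-1 components at lower/upper bounds and solving the
#' remaining one by difference, keeping feasible solutions (the classic
#' extreme-vertices construction).
#'
#' @param region A [mixture_region()].
#' @param tol Feasibility/deduplication tolerance.
#' @return Matrix of vertices (rows), lexicographically sorted.
#' @export
region_vertices <- function(region, tol = 1e-9) {
  q <- n_components(region)
  L <- region$lower
  U <- region$upper
  bnd <- rbind(L, U)
  out <- list()
  grid <- as.matrix(expand.grid(rep(list(1:2), q - 1L)))
  for (j in seq_len(q)) {
    others <- setdiff(seq_len(q), j)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(q)
      x[others] <- bnd[cbind(grid[g, ], others)]
      x[j] <- region$total - sum(x[others])
      if (x[j] >= L[j] - tol && x[j] <= U[j] + tol) {
        x[j] <- min(max(x[j], L[j]), U[j])
        out[[length(out) + 1L]] <- x
      }
    }
  }
  v <- do.call(rbind, out)
  colnames(v) <- region$names
  dedupe_rows(v, tol)
}

dedupe_rows <- function(m, tol = 1e-9) {
  if (is.null(m) || nrow(m) == 0L) return(m)
  keys <- apply(round(m / tol) * tol, 1L,
                function(r) paste(sprintf("%.12g", r), collapse = "|"))
  m <- m[!duplicated(keys), , drop = FALSE]
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Candidate points for D-optimal mixture design selection
#'
#' Builds the standard candidate list for a constrained mixture region:
#' extreme vertices, centroids of every face of the region (a face being
#' the set of vertices sharing a common subset of active bound
#' constraints, its centroid the mean of those vertices — edge midpoints
#' and higher-dimensional face centroids arise as special cases), and the
#' overall centroid. For a region whose non-filler components form a full
#' box (the filler absorbing the difference) this equals the 3-level grid
#' \{L, (L+U)/2, U\} over the free components.
#'
#' @param region A [mixture_region()].
#' @param tol Deduplication tolerance.
#' @return Matrix of candidate blends (real wt%), lexicographically
#'   sorted, deduplicated.
#' @export
candidate_points <- function(region, tol = 1e-9) {
  v <- region_vertices(region, tol)
  if (is.null(v) || nrow(v) == 0L) stop("empty mixture region")
  q <- n_components(region)
  cand <- list(v, matrix(colMeans(v), 1L, q))
  # faces: consistent subsets of (component, side) active constraints
  sides <- list(region$lower, region$upper)
  for (k in seq_len(max(q - 2L, 1L))) {
    comps <- utils::combn(q, k)
    side_grid <- as.matrix(expand.grid(rep(list(1:2), k)))
    for (ci in seq_len(ncol(comps))) {
      cc <- comps[, ci]
      for (g in seq_len(nrow(side_grid))) {
        target <- vapply(seq_len(k),
                         function(i) sides[[side_grid[g, i]]][cc[i]],
                         numeric(1))
        on_face <- which(apply(v, 1L, function(row) {
          all(abs(row[cc] - target) <= tol)
        }))
        if (length(on_face) >= 2L) {
          cand[[length(cand) + 1L]] <-
            matrix(colMeans(v[on_face, , drop = FALSE]), 1L, q)
        }
      }
    }
  }
  m <- do.call(rbind, cand)
  colnames(m) <- region$names
  dedupe_rows(m, tol)
}
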