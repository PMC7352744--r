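#' Construct a mixture design
#'
#' Bundles an ordered set of mixture runs (real wt% coordinates) with its
#' region and the automatically detected replicate structure (groups of
#' runs with identical composition to 1e-9).
#'
#' @param runs Matrix or data.frame, one row per run, one column per
#'   component (real amounts summing to `region$total`).
#' @param region A [mixture_region()].
#' @return An object of class `mixture_design`: list with `runs` (matrix),
#'   `region`, and `replicate_groups` (list of integer index vectors, one
#'   per distinct composition, in order of first occurrence).
#' @export
mixture_design <- function(runs, region) {
  runs <- as.matrix(runs)
  if (ncol(runs) != n_components(region)) {
    stop("design has ", ncol(runs), " columns but region has ",
         n_components(region), " components")
  }
  if (!is.numeric(runs)) stop("design runs must be numeric")
  colnames(runs) <- region$names
  for (i in seq_len(nrow(runs))) {
    msg <- check_in_region(runs[i, ], region)
    if (!isTRUE(msg)) stop("run ", i, " invalid: ", msg)
  }
  structure(
    list(runs = runs, region = region,
         replicate_groups = replicate_groups(runs)),
    class = "mixture_design"
  )
}

#' Partition run indices by identical composition
#'
#' @param runs Numeric matrix of compositions (or a `mixture_design`).
#' @param tol Equality tolerance on each coordinate.
#' @return List of integer vectors; each element collects the runs sharing
#'   one distinct composition, ordered by first occurrence.
#' @export
replicate_groups <- function(runs, tol = 1e-9) {
  if (inherits(runs, "mixture_design")) runs <- runs$runs
  runs <- as.matrix(runs)
  keys <- apply(round(runs / tol) * tol, 1L,
                function(r) paste(sprintf("%.12g", r), collapse = "|"))
  idx <- split(seq_len(nrow(runs)), factor(keys, levels = unique(keys)))
  names(idx) <- NULL
  idx
}

#' @export
print.mixture_design <- function(x, ...) {
  n_rep <- sum(lengths(x$replicate_groups) > 1L)
  cat("Mixture design:", nrow(x$runs), "runs,",
      length(x$replicate_groups), "distinct compositions",
      if (n_rep) sprintf("(%d replicated)", n_rep) else "", "\n")
  print(round(x$runs, 6))
  invisible(x)
}

#' Read / write a mixture design as CSV
#'
#' The interchange format is one row per run and one named column per
#' component (real wt%); an optional leading `run` column carries run ids
#' and is ignored on reading. Round-trips are lossless at 12 significant
#' digits.
#'
#' @param path File path.
#' @param region A [mixture_region()]; column names must match
#'   `region$names` (any order).
#' @return `read_design_csv` returns a [mixture_design()];
#'   `write_design_csv` returns `path` invisibly.
#' @export
read_design_csv <- function(path, region) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty design file: ", path)
  if ("run" %in% names(df)) df$run <- NULL
  missing_cols <- setdiff(region$names, names(df))
  if (length(missing_cols)) {
    stop("design file lacks component column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[region$names]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(df)[j], if (is.na(bad)) 1L else bad))
    }
  }
  mixture_design(as.matrix(df), region)
}

#' @rdname read_design_csv
#' @param design A [mixture_design()].
#' @export
write_design_csv <- function(design, path) {
  df <- as.data.frame(signif(design$runs, 12))
  df <- cbind(run = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
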