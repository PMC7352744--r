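#' R-squared and adjusted R-squared of a Scheffe fit
#'
#' Both use the mean-corrected total sum of squares (see [fit_scheffe()]
#' for why the correction is legitimate despite the no-intercept
#' parameterization).
#'
#' @param fit A [fit_scheffe()] result.
#' @return Scalar; `r_squared` lies in \[0, 1\].
#' @export
r_squared <- function(fit) {
  if (fit$ss_total_corrected <= 0) {
    stop("constant responses: R-squared undefined")
  }
  1 - fit$ss_residual / fit$ss_total_corrected
}

#' @rdname r_squared
#' @export
adj_r_squared <- function(fit) {
  r2 <- r_squared(fit)
  1 - (1 - r2) * (fit$n - 1) / (fit$n - fit$p)
}

#' Adequate precision (signal-to-noise) of a Scheffe fit
#'
#' The range of fitted values over the design runs divided by the average
#' prediction standard error, \eqn{\sqrt{p \, MS_{res} / n}}. Values
#' above 4 indicate the model discriminates adequately over the design
#' space. A saturated (zero residual) fit returns `Inf` with a warning.
#'
#' @param fit A [fit_scheffe()] result.
#' @return Positive scalar (possibly `Inf`).
#' @export
adequate_precision <- function(fit) {
  if (fit$dof <= 0) stop("no residual degrees of freedom")
  ms_res <- fit$ss_residual / fit$dof
  # numerically zero residual (an interpolating fit) counts as saturated
  if (ms_res <= 1e-10 * max(fit$ss_total_corrected / fit$n, 1)) {
    warning("zero residual mean square; adequate precision is infinite")
    return(Inf)
  }
  (max(fit$fitted) - min(fit$fitted)) / sqrt(fit$p * ms_res / fit$n)
}

#' Mixture-model analysis of variance
#'
#' Decomposes the mean-corrected total sum of squares of a Scheffe fit
#' into model and residual, splits the residual into lack-of-fit and
#' pure error using the design's replicate groups, and tests each
#' interaction term by its partial (single-term-deletion) sum of squares.
#' Single-component terms receive no individual test: under the mixture
#' constraint they are not separately estimable effects in the Scheffe
#' parameterization. No multiplicity correction is applied across terms.
#'
#' @param fit A [fit_scheffe()] result (its design carries the replicate
#'   structure).
#' @return Object of class `mixture_anova`: `rows` (data frame with
#'   columns `term`, `df`, `ss`, `ms`, `f`, `p`), plus `r2`, `adj_r2`,
#'   `adequate_precision`, `n`, `p_terms`. If the design has no
#'   replicated composition the lack-of-fit rows are omitted with a
#'   warning.
#' @export
mixture_anova <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  n <- fit$n
  p <- fit$p
  if (fit$dof <= 0) stop("saturated model: no residual degrees of freedom")
  ms_res <- fit$ss_residual / fit$dof
  df_model <- p - 1L   # mixture constraint absorbs one df
  ms_model <- fit$ss_model / df_model
  f_model <- ms_model / ms_res
  rows <- data.frame(
    term = "Model", df = df_model, ss = fit$ss_model, ms = ms_model,
    f = f_model, p = stats::pf(f_model, df_model, fit$dof, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )

  # partial (extra) SS from deleting each interaction term and refitting
  X <- scheffe_model_matrix(fit$design, fit$model$order)
  term_len <- lengths(fit$model$terms)
  for (j in which(term_len >= 2L)) {
    red <- stats::lm.fit(X[, -j, drop = FALSE], fit$y)
    ss_j <- sum(red$residuals^2) - fit$ss_residual
    f_j <- ss_j / ms_res
    rows <- rbind(rows, data.frame(
      term = names(fit$model$terms)[j], df = 1L, ss = ss_j, ms = ss_j,
      f = f_j, p = stats::pf(f_j, 1L, fit$dof, lower.tail = FALSE)
    ))
  }

  rows <- rbind(rows, data.frame(
    term = "Residual", df = fit$dof, ss = fit$ss_residual, ms = ms_res,
    f = NA_real_, p = NA_real_
  ))

  groups <- fit$design$replicate_groups
  rep_groups <- groups[lengths(groups) >= 2L]
  if (length(rep_groups) == 0L) {
    warning("no replicated compositions: lack-of-fit split omitted")
  } else {
    ss_pe <- sum(vapply(rep_groups, function(ix) {
      sum((fit$y[ix] - mean(fit$y[ix]))^2)
    }, numeric(1)))
    df_pe <- sum(lengths(rep_groups) - 1L)
    df_lof <- fit$dof - df_pe
    ss_lof <- fit$ss_residual - ss_pe
    if (df_lof > 0L && df_pe > 0L) {
      ms_lof <- ss_lof / df_lof
      ms_pe <- ss_pe / df_pe
      f_lof <- if (ms_pe > 0) ms_lof / ms_pe else NA_real_
      rows <- rbind(rows,
        data.frame(term = "Lack of fit", df = df_lof, ss = ss_lof,
                   ms = ms_lof, f = f_lof,
                   p = if (is.na(f_lof)) NA_real_ else
                     stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)),
        data.frame(term = "Pure error", df = df_pe, ss = ss_pe, ms = ms_pe,
                   f = NA_real_, p = NA_real_))
    }
  }
  rownames(rows) <- NULL
  structure(
    list(rows = rows, r2 = r_squared(fit), adj_r2 = adj_r_squared(fit),
         adequate_precision = adequate_precision(fit), n = n, p_terms = p),
    class = "mixture_anova"
  )
}

#' @export
print.mixture_anova <- function(x, digits = 4, ...) {
  cat("Mixture-model ANOVA (", x$n, "runs,", x$p_terms, "terms )\n")
  df <- x$rows
  df$ss <- signif(df$ss, digits)
  df$ms <- signif(df$ms, digits)
  df$f <- ifelse(is.na(df$f), "", sprintf("%.2f", df$f))
  df$p <- ifelse(is.na(df$p), "",
                 ifelse(df$p < 1e-4, "<0.0001", sprintf("%.4f", df$p)))
  print(df, row.names = FALSE)
  cat(sprintf("R-squared %.4f  adj %.4f  adequate precision %.2f\n",
              x$r2, x$adj_r2, x$adequate_precision))
  invisible(x)
}

anova_row <- function(at, term) {
  r <- at$rows[at$rows$term == term, ]
  if (nrow(r) == 0L) NULL else r
}

#' Select the best-supported Scheffe model order
#'
#' Fits every estimable order (linear, quadratic, and special cubic where
#' run count allows), computes each ANOVA, and selects the highest order
#' that is (a) significant — for the linear model the overall model F,
#' for higher orders the sequential F-test of the terms added over the
#' next-lower order (the standard fit-summary rule of mixture-design
#' software, which protects against overfitting noise with the extra
#' interaction terms); (b) free of significant lack of fit (lack-of-fit
#' p above `alpha`, or no replicate information); and (c) an improvement
#' in adjusted R-squared over the incumbent. If no order qualifies the
#' linear model is returned with a warning.
#'
#' @param design A [mixture_design()].
#' @param y Response vector.
#' @param alpha Significance level of the selection rule (default 0.05).
#' @return List with `order` (the chosen tag), `fit` (its `scheffe_fit`),
#'   and `candidates` (named list of per-order `mixture_anova` tables).
#' @export
select_scheffe_order <- function(design, y, alpha = 0.05) {
  orders <- c("linear", "quadratic", "special_cubic")
  q <- n_components(design$region)
  fits <- list()
  tables <- list()
  for (ord in orders) {
    p_need <- length(scheffe_terms(q, ord))
    if (nrow(design$runs) <= p_need) next    # need residual df
    fits[[ord]] <- fit_scheffe(design, y, ord)
    tables[[ord]] <- suppressWarnings(mixture_anova(fits[[ord]]))
  }
  if (length(fits) == 0L) stop("too few runs to fit even the linear model")
  chosen <- NULL
  prev <- NULL
  for (ord in names(fits)) {
    at <- tables[[ord]]
    fit <- fits[[ord]]
    if (is.null(prev)) {
      sig_p <- anova_row(at, "Model")$p
    } else {
      # sequential F-test of the terms added over the next-lower order
      df_add <- fit$p - fits[[prev]]$p
      ss_add <- fits[[prev]]$ss_residual - fit$ss_residual
      f_add <- (ss_add / df_add) / (fit$ss_residual / fit$dof)
      sig_p <- stats::pf(f_add, df_add, fit$dof, lower.tail = FALSE)
    }
    lof <- anova_row(at, "Lack of fit")
    lof_ok <- is.null(lof) || is.na(lof$p) || lof$p > alpha
    better <- is.null(chosen) || at$adj_r2 > tables[[chosen]]$adj_r2
    if (sig_p < alpha && lof_ok && better) chosen <- ord
    prev <- ord
  }
  if (is.null(chosen)) {
    warning("no model order significant at alpha = ", alpha,
            "; returning the linear fit")
    chosen <- names(fits)[1]
  }
  list(order = chosen, fit = fits[[chosen]], candidates = tables)
}

#' Predicted-versus-actual pairs and calibration slope
#'
#' @param fit A [fit_scheffe()] result.
#' @return List with `pairs` (data frame `actual`, `fitted`) and `slope`,
#'   the regression slope of actual on fitted (1 for a perfect fit).
#' @export
predicted_vs_actual <- function(fit) {
  pairs <- data.frame(actual = fit$y, fitted = fit$fitted)
  slope <- if (stats::var(fit$fitted) > 0) {
    stats::cov(pairs$actual, pairs$fitted) / stats::var(pairs$fitted)
  } else NA_real_
  list(pairs = pairs, slope = slope)
}
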