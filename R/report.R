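#' Format analysis results for reporting
#'
#' `report_anova` renders a [mixture_anova()] table either as aligned
#' text (numbers at conventional 2-dp precision, p-values as `<0.0001`
#' below that threshold) or as a JSON string carrying full precision
#' with a stable key order. `report_validation` does the same for a
#' [validate_formulations()] table.
#'
#' @param x A `mixture_anova` or validation data frame.
#' @param format `"text"` or `"json"`.
#' @return Character scalar (invisibly printed for text).
#' @export
report_anova <- function(x, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "mixture_anova"))
  if (format == "json") {
    payload <- list(
      rows = x$rows, r2 = x$r2, adj_r2 = x$adj_r2,
      adequate_precision = x$adequate_precision,
      n = x$n, p_terms = x$p_terms
    )
    return(as.character(jsonlite::toJSON(payload, dataframe = "rows",
                                         digits = NA, auto_unbox = TRUE,
                                         na = "null")))
  }
  df <- x$rows
  lines <- c(
    sprintf("%-12s %4s %10s %10s %8s %8s",
            "Source", "df", "SS", "MS", "F", "p"),
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("%-12s %4d %10.2f %10.2f %8s %8s",
              df$term[i], df$df[i], df$ss[i], df$ms[i],
              if (is.na(df$f[i])) "" else sprintf("%.2f", df$f[i]),
              if (is.na(df$p[i])) "" else if (df$p[i] < 1e-4) "<0.0001"
              else sprintf("%.4f", df$p[i]))
    }, character(1)),
    sprintf("R-squared %.4f  adj R-squared %.4f  adequate precision %.2f",
            x$r2, x$adj_r2, x$adequate_precision)
  )
  paste(lines, collapse = "\n")
}

#' @rdname report_anova
#' @export
report_validation <- function(x, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(x, dataframe = "rows",
                                         digits = NA, auto_unbox = TRUE)))
  }
  if (nrow(x) == 0L) return("(no validation records)")
  hdr <- sprintf("%-10s %-8s %9s %9s %7s %7s", "Formulation", "Response",
                 "Actual", "Predicted", "RSE%", "Flag")
  body <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-10s %-8s %9.2f %9.2f %7.2f %7s",
            x$formulation[i], x$response[i], x$actual[i], x$predicted[i],
            x$abs_rse[i], if (x$flagged[i]) "*" else "")
  }, character(1))
  paste(c(hdr, body), collapse = "\n")
}
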