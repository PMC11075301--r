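#' Ordinary least-squares regression of a statistic against time
#'
#' @param months numeric time axis (months).
#' @param values statistic per month; NA pairs are dropped.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value` (two-sided for
#'   the slope), `n`. Fewer than 3 complete points is an error.
#' @export
regress_vs_time <- function(months, values) {
  ok <- !is.na(months) & !is.na(values)
  months <- months[ok]; values <- values[ok]
  if (length(months) < 3) stop_config("need >= 3 non-missing points")
  if (sd(values) == 0)
    return(list(slope = 0, intercept = values[1], r_squared = 0,
                p_value = NA_real_, n = length(months)))
  fit <- lm(values ~ months)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4]
                 else NA_real_,
       n = length(months))
}

#' Per-month log fold change between two group series
#'
#' `log_base(A / C)` at each month the two series share. Months where either
#' value is 0 (or C is negative) are reported NA with a warning.
#'
#' @param series_a named numeric vector, names = months (group A).
#' @param series_c named numeric vector, names = months (group C).
#' @param base logarithm base (default 2).
#' @return named numeric vector of logFC over the shared months.
#' @export
log_fc <- function(series_a, series_c, base = 2) {
  months <- intersect(names(series_a), names(series_c))
  if (!length(months)) stop_config("no overlapping months")
  a <- series_a[months]; c_ <- series_c[months]
  bad <- is.na(a) | is.na(c_) | a <= 0 | c_ <= 0
  if (any(bad)) warning("non-positive or missing values at month(s) ",
                        paste(months[bad], collapse = ", "),
                        "; logFC reported NA")
  out <- rep(NA_real_, length(months))
  out[!bad] <- log(a[!bad] / c_[!bad], base = base)
  setNames(out, months)
}

#' All-pairs correlation between two parameter tables
#'
#' Correlates every column of `x_table` with every column of `y_table`
#' (default: `x_table` with itself) across matched rows — e.g. network
#' complexity indices against stability indices over the monthly networks.
#' Cells with fewer than `min_pairs` complete observations, or with a
#' zero-variance series, are NA with a warning.
#'
#' @param x_table data.frame/matrix, rows = observations, columns =
#'   parameters.
#' @param y_table second table (default `x_table`).
#' @param method "spearman" (default) or "pearson".
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param min_pairs minimum complete pairs per cell (default 4).
#' @param adjust optional "BH" for Benjamini-Hochberg adjusted p-values.
#' @return data.frame: `x`, `y`, `method`, `r`, `p_value`, `n`,
#'   `significant`.
#' @export
correlate_parameters <- function(x_table, y_table = NULL,
                                 method = c("spearman", "pearson"),
                                 alpha = 0.05, min_pairs = 4,
                                 adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  x_table <- as.data.frame(x_table)
  y_table <- as.data.frame(y_table %||% x_table)
  cells <- expand.grid(x = names(x_table), y = names(y_table),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    xv <- x_table[[cells$x[i]]]; yv <- y_table[[cells$y[i]]]
    ok <- !is.na(xv) & !is.na(yv)
    if (sum(ok) < min_pairs) {
      warning("cell ", cells$x[i], " x ", cells$y[i],
              ": fewer than ", min_pairs, " pairs")
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
      warning("cell ", cells$x[i], " x ", cells$y[i],
              ": zero-variance series")
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(cor.test(xv[ok], yv[ok], method = method))
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, res)
  p <- res[, "p"]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(x = cells$x, y = cells$y, method = method,
             r = res[, "r"], p_value = p, n = as.integer(res[, "n"]),
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}
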