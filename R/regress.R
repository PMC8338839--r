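# Least-squares inference: simple regressions (b) and two-predictor partial
# regressions (b'), reported with R^2, F and p-values in the style of the
# figure captions.  Fits go through stats::lm / summary.lm; the structured
# result object carries everything a report needs.

.ols_result <- function(fit, n) {
  s <- summary(fit)
  co <- s$coefficients
  fstat <- s$fstatistic
  if (is.null(fstat)) fstat <- c(NaN, NaN, NaN)
  list(
    n = n,
    coefficients = stats::setNames(co[, 1], rownames(co)),
    standard_errors = stats::setNames(co[, 2], rownames(co)),
    t_statistics = stats::setNames(co[, 3], rownames(co)),
    p_values = stats::setNames(co[, 4], rownames(co)),
    r_squared = s$r.squared,
    f_statistic = unname(fstat[1]),
    df = unname(fstat[2:3]),
    p_overall = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE))
  )
}

#' Simple linear regression with R-squared, F and p-values
#'
#' @param y response values.
#' @param x predictor values (must not be constant).
#' @return list of class `ols_fit` with elements `n`, `coefficients`
#'   (intercept and slope), `standard_errors`, `t_statistics`, `p_values`,
#'   `r_squared`, `f_statistic`, `df` (1, n - 2) and `p_overall`.
#' @export
ols_simple <- function(y, x) {
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3L) insufficient_data_error("simple regression needs n >= 3")
  if (stats::var(x) == 0) collinearity_error("predictor x is constant")
  if (stats::var(y) == 0) {
    # constant response: zero slope, no variance to explain
    nm <- c("(Intercept)", "x")
    return(structure(list(
      n = n,
      coefficients = stats::setNames(c(y[1], 0), nm),
      standard_errors = stats::setNames(c(0, 0), nm),
      t_statistics = stats::setNames(c(NA_real_, NA_real_), nm),
      p_values = stats::setNames(c(NA_real_, NA_real_), nm),
      r_squared = 0, f_statistic = 0, df = c(1, n - 2), p_overall = 1
    ), class = "ols_fit"))
  }
  structure(.ols_result(stats::lm(y ~ x), n), class = "ols_fit")
}

#' Two-predictor least-squares regression (partial coefficients)
#'
#' Fits `y ~ x1 + x2`; the slope on each predictor is its partial regression
#' coefficient holding the other fixed. Per-coefficient t tests use n - 3
#' degrees of freedom; the overall F test uses (2, n - 3).
#'
#' @param y response values.
#' @param x1,x2 predictor values; the design must be full rank.
#' @return list of class `ols_fit`, as in [ols_simple()], with slopes named
#'   `x1` and `x2`.
#' @export
ols_two <- function(y, x1, x2) {
  keep <- !is.na(y) & !is.na(x1) & !is.na(x2)
  y <- y[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  n <- length(y)
  if (n < 4L) insufficient_data_error("two-predictor regression needs n >= 4")
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) {
    collinearity_error("design is rank-deficient (x2 affine in x1?)")
  }
  fit <- stats::lm(y ~ x1 + x2)
  structure(.ols_result(fit, n), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("least-squares fit, n = %d\n", x$n))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    t = x$t_statistics, p = x$p_values)
  print(format(tab, digits = 4))
  cat(sprintf("R^2 = %.4g, F(%g, %g) = %.4g, p = %.4g\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_overall))
  invisible(x)
}

#' Degree regressions of B and recombination rate
#'
#' Runs the three analyses relating background selection to pleiotropy on an
#' annotated table: the simple regression of B on degree (coefficient b),
#' the simple regression of log10 RR on degree, and the two-predictor
#' partial regression of B on degree and recombination rate (coefficients
#' b'). Rows with missing B or RR are dropped with a count.
#'
#' @param annotated data.frame from [annotate_items()] with columns `B`,
#'   `RR`, `log10RR`, `degree`, `complete`.
#' @param rr_scale `"log10"` (default, matching the plotted scale) or
#'   `"raw"` for cM/Mb.
#' @return list of class `degree_regressions` with elements `b_simple`
#'   (B ~ degree), `rr_simple` (log10 RR ~ degree), `b_partial`
#'   (B ~ degree + RR), `n`, `n_dropped`, `rr_scale`.
#' @export
degree_regressions <- function(annotated, rr_scale = c("log10", "raw")) {
  rr_scale <- match.arg(rr_scale)
  ok <- annotated$complete & !is.na(annotated$degree)
  tab <- annotated[ok, , drop = FALSE]
  n_dropped <- sum(!ok)
  if (nrow(tab) < 4L) {
    insufficient_data_error(sprintf(
      "only %d complete rows; degree regressions need >= 4", nrow(tab)))
  }
  rr <- if (rr_scale == "log10") tab$log10RR else tab$RR
  structure(list(
    b_simple = ols_simple(tab$B, tab$degree),
    rr_simple = ols_simple(tab$log10RR, tab$degree),
    b_partial = ols_two(tab$B, tab$degree, rr),
    n = nrow(tab),
    n_dropped = n_dropped,
    rr_scale = rr_scale
  ), class = "degree_regressions")
}

#' @export
print.degree_regressions <- function(x, ...) {
  cat(sprintf("degree regressions on %d rows (%d dropped), RR scale: %s\n\n",
              x$n, x$n_dropped, x$rr_scale))
  cat("B ~ degree (simple):\n"); print(x$b_simple)
  cat("\nlog10RR ~ degree (simple):\n"); print(x$rr_simple)
  cat("\nB ~ degree + RR (partial):\n"); print(x$b_partial)
  invisible(x)
}
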