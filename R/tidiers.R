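# Broom-style accessors for fitted objects produced by the package.

new_ripple_fit <- function(fit, context) {
  sm <- summary(fit)
  structure(
    list(model = fit, context = context,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared, n = length(sm$residuals)),
    class = "ripple_fit")
}

#' @export
print.ripple_fit <- function(x, ...) {
  cat(sprintf("<ripple_fit> %s\n  slope = %.4g, intercept = %.4g, R^2 = %.4f (n = %d)\n",
              x$context, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Tidy a ripple_fit
#'
#' Coefficient-level summary of a fitted regression (one row per term).
#'
#' @param x A `ripple_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.ripple_fit <- function(x, ...) {
  cf <- unname(summary(x$model)$coefficients)
  tibble(term = rownames(summary(x$model)$coefficients),
         estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' Glance at a ripple_fit
#'
#' One-row model summary.
#'
#' @inheritParams tidy.ripple_fit
#' @return Tibble with `r.squared`, `adj.r.squared`, `sigma`, `p.value`,
#'   `nobs`.
#' @export
glance.ripple_fit <- function(x, ...) {
  sm <- summary(x$model)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         sigma = sm$sigma, p.value = unname(p), nobs = x$n)
}

#' Variance in a response explained by one spatial axis
#'
#' Ordinary least squares of `response` on `axis`, reporting the fraction of
#' variance explained. Used e.g. for ripple duration vs medio-lateral seed
#' position and for modulation contrast vs unit position.
#'
#' @param data A data frame.
#' @param response,axis Column names (strings).
#' @return A `ripple_fit`.
#' @export
axis_variance_explained <- function(data, response, axis = "ml") {
  data <- as_tibble(data)[, c(response, axis)]
  data <- data[complete.cases(data), ]
  if (nrow(data) < 4) abort("need at least 4 complete observations")
  if (var(data[[axis]]) == 0) abort("degenerate predictor spread")
  fit <- lm(stats::reformulate(axis, response), data = data)
  new_ripple_fit(fit, paste(response, "~", axis))
}

#' @export
generics::tidy

#' @export
generics::glance
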