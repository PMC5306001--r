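#' Hyperparameters for stochastic canopy-growth curves
#'
#' Average canopy height (ACH) over the nesting season is modelled with a
#' Michaelis-Menten curve, \eqn{ACH(t) = a t / (b + t)}, where `a` is the
#' asymptotic height (m) and `b` the day at which half the asymptote is
#' reached. Curve-to-curve variation is produced by drawing `a` and `b`
#' from normal distributions; non-positive draws are rejected and redrawn
#' so every realised curve is a valid saturating growth curve.
#'
#' The defaults describe a native warm-season grass sward approaching
#' about 1 m by mid-season: `a_mean = 1` m with 15 cm spread, and
#' half-height at day 15 of a ~60-day season with a 3-day spread.
#'
#' @param a_mean,a_sd Mean and standard deviation (m) of the asymptote `a`.
#' @param b_mean,b_sd Mean and standard deviation (days) of the
#'   half-saturation day `b`.
#' @return An object of class `"growth_params"`.
#' @examples
#' gp <- growth_params()
#' set.seed(1)
#' sample_growth_curve(gp)
#' @export
growth_params <- function(a_mean = 1.0, a_sd = 0.15, b_mean = 15, b_sd = 3) {
  vals <- c(a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd)
  if (!all(is.finite(vals)))
    stop("growth hyperparameters must be finite", call. = FALSE)
  if (a_mean <= 0 || b_mean <= 0)
    stop("'a_mean' and 'b_mean' must be positive", call. = FALSE)
  if (a_sd < 0 || b_sd < 0)
    stop("'a_sd' and 'b_sd' must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Michaelis-Menten growth hyperparameters\n")
  cat(sprintf("  asymptote a ~ N(%.3g m, sd %.3g)\n", x$a_mean, x$a_sd))
  cat(sprintf("  half-saturation b ~ N(%.3g d, sd %.3g)\n", x$b_mean, x$b_sd))
  invisible(x)
}

#' Construct a realised growth curve
#'
#' @param a Asymptote height in metres (> 0).
#' @param b Half-saturation day (> 0); `ach(curve, b)` equals `a / 2`.
#' @return An object of class `"growth_curve"`.
#' @seealso [sample_growth_curve()], [ach()]
#' @export
growth_curve <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("'a' and 'b' must be positive and finite", call. = FALSE)
  structure(list(a = a, b = b), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Michaelis-Menten growth curve: a = %.4g m, b = %.4g d\n",
              x$a, x$b))
  invisible(x)
}

#' Draw random growth curves
#'
#' Draws `a ~ N(a_mean, a_sd)` and `b ~ N(b_mean, b_sd)` from the current
#' RNG stream, redrawing any non-positive value so the normal shape is
#' preserved away from zero (rejection, not truncation at zero).
#'
#' @param params A [growth_params()] object.
#' @return A `"growth_curve"` object (`sample_growth_curve`) or a list of
#'   them (`sample_growth_curves`).
#' @export
sample_growth_curve <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  growth_curve(positive_normal(1, params$a_mean, params$a_sd),
               positive_normal(1, params$b_mean, params$b_sd))
}

#' @rdname sample_growth_curve
#' @param n Number of curves to draw.
#' @export
sample_growth_curves <- function(n, params) {
  lapply(seq_len(n), function(i) sample_growth_curve(params))
}

# rejection sampler for a positive normal variate
positive_normal <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("positive-normal rejection sampler failed to converge; ",
           "check that the mean is positive", call. = FALSE)
  }
  x
}

#' Evaluate average canopy height on a given day
#'
#' `ach()` is generic so that tests and diagnostics can substitute
#' degenerate vegetation (see [constant_curve()]). For a Michaelis-Menten
#' curve it returns `a * day / (b + day)`: zero at day 0, strictly
#' increasing, and bounded above by `a`.
#'
#' @param curve A curve object.
#' @param day Non-negative day (vectorised).
#' @return ACH in metres.
#' @examples
#' ach(growth_curve(1, 10), c(0, 10, 1e6))
#' @export
ach <- function(curve, day) UseMethod("ach")

#' @export
ach.growth_curve <- function(curve, day) {
  if (any(day < 0)) stop("'day' must be non-negative", call. = FALSE)
  curve$a * day / (curve$b + day)
}

#' A constant-height vegetation stand-in
#'
#' Returns a curve object whose [ach()] is `height` on every day. With it,
#' all four measurement protocols record identical covariates, which
#' isolates the growth-driven component of measurement-timing bias.
#'
#' @param height Constant canopy height in metres.
#' @export
constant_curve <- function(height) {
  stopifnot(is.finite(height), height >= 0)
  structure(list(height = height), class = c("constant_curve"))
}

#' @export
ach.constant_curve <- function(curve, day) {
  if (any(day < 0)) stop("'day' must be non-negative", call. = FALSE)
  rep_len(curve$height, length(day))
}

#' Tabulate curves for plotting or export
#'
#' @param curves A list of curve objects.
#' @param days Days at which to evaluate (default 0 to 60).
#' @return A data frame with columns `curve_id`, `day`, `ach`, suitable for
#'   [utils::write.csv()].
#' @export
curve_table <- function(curves, days = 0:60) {
  if (inherits(curves, "growth_curve") || inherits(curves, "constant_curve"))
    curves <- list(curves)
  do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(curve_id = i, day = days, ach = ach(curves[[i]], days))
  }))
}

#' @export
plot.growth_curve <- function(x, days = 0:60, ...) {
  graphics::plot(days, ach(x, days), type = "l",
                 xlab = "day of season", ylab = "ACH (m)", ...)
  invisible(x)
}
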