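#' Guinier fit of the low-angle region of a SAXS profile
#'
#' Fits `ln I = ln I0 - q^2 Rg^2 / 3` over the widest low-q window whose
#' upper end satisfies `q * Rg <= qrg_max`. The window is found iteratively:
#' starting from the lowest usable points, the fit is repeated with the
#' window recomputed from the current Rg estimate until Rg changes by less
#' than 0.1%. Points are weighted by `1/sigma_lnI^2` when the profile
#' carries uncertainties.
#'
#' @param profile A [saxs_profile()].
#' @param qrg_max Dimensionless cap on `q * Rg` for the fitted window
#'   (default 1.3, the conventional validity limit of the Guinier
#'   approximation for globular particles).
#' @param min_points Minimum number of points required in the window.
#' @return An object of class `guinier_fit` with elements `rg` (Angstrom),
#'   `i0`, `q_range_used` (the dimensionless `q * Rg` bounds actually
#'   used), `r_squared`, `n_points`.
#' @examples
#' q <- seq(0.003, 0.05, length.out = 120)
#' fit <- guinier_fit(saxs_profile(q, 7 * exp(-q^2 * 55.4^2 / 3)))
#' fit$rg
#' @export
guinier_fit <- function(profile, qrg_max = 1.3, min_points = 5L) {
  stopifnot(inherits(profile, "saxs_profile"))
  ok <- profile$q > 0 & profile$intensity > 0
  q <- profile$q[ok]
  I <- profile$intensity[ok]
  s <- if ("sigma" %in% names(profile)) profile$sigma[ok] else NULL
  if (length(q) < min_points) abort("no admissible Guinier window")

  fit_window <- function(idx) {
    y <- log(I[idx])
    x <- q[idx]^2
    w <- if (is.null(s)) rep(1, length(idx)) else (I[idx] / s[idx])^2
    fit <- lm(y ~ x, weights = w)
    slope <- coef(fit)[[2]]
    list(slope = slope, intercept = coef(fit)[[1]],
         r2 = suppressWarnings(summary(fit)$r.squared))  # exact fits warn
  }

  # seed with the first min_points * 2 points (or all, if fewer)
  idx <- seq_len(min(length(q), max(min_points, 10L)))
  f <- fit_window(idx)
  if (f$slope >= 0) abort("negative slope condition violated (slope >= 0)")
  rg <- sqrt(-3 * f$slope)
  for (iter in seq_len(100)) {
    idx_new <- which(q * rg <= qrg_max)
    if (length(idx_new) < min_points) {
      if (iter == 1) abort("no admissible Guinier window")
      break
    }
    f_new <- fit_window(idx_new)
    if (f_new$slope >= 0) break
    rg_new <- sqrt(-3 * f_new$slope)
    converged <- abs(rg_new - rg) / rg < 1e-3
    idx <- idx_new; f <- f_new; rg <- rg_new
    if (converged) break
  }
  structure(
    list(rg = rg, i0 = exp(f$intercept),
         q_range_used = c(min(q[idx]) * rg, max(q[idx]) * rg),
         r_squared = f$r2, n_points = length(idx), qrg_max = qrg_max),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.2f A, I(0) = %.4g, qRg in [%.3f, %.3f], n = %d, R^2 = %.4f\n",
    x$rg, x$i0, x$q_range_used[1], x$q_range_used[2], x$n_points, x$r_squared))
  invisible(x)
}

#' @rdname guinier_fit
#' @param x A `guinier_fit`.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0))
}

#' @rdname guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, i0 = x$i0, r_squared = x$r_squared,
                 n_points = x$n_points,
                 qrg_min = x$q_range_used[1], qrg_max_used = x$q_range_used[2])
}

#' Dimensionless (Rg-normalized) Kratky curve
#'
#' Computes `x = q * Rg`, `y = x^2 * I(q) / I(0)`. For a globular particle
#' the curve is bell-shaped with a maximum of `3/e` at `x = sqrt(3)`; a
#' monotonic rise at large `x` indicates conformational flexibility.
#'
#' @param profile A [saxs_profile()].
#' @param fit A [guinier_fit()] of the same profile (supplies Rg and I0).
#' @return A tibble of class `kratky_curve` with columns `x` (qRg) and `y`.
#' @export
dimensionless_kratky <- function(profile, fit) {
  stopifnot(inherits(profile, "saxs_profile"), inherits(fit, "guinier_fit"))
  if (fit$i0 <= 0) abort("i0 must be > 0")
  out <- tibble::tibble(x = profile$q * fit$rg,
                        y = (profile$q * fit$rg)^2 * profile$intensity / fit$i0)
  class(out) <- c("kratky_curve", class(out))
  out
}

#' @export
autoplot.kratky_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(q * R[g]),
                  y = expression((q * R[g])^2 * I(q) / I(0)),
                  title = "Dimensionless Kratky plot") +
    ggplot2::theme_minimal()
}
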