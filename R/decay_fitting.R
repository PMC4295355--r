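# Inverse problem: mono/biexponential decomposition of decay curves by
# peel-off stripping with optional nonlinear least-squares refinement, and
# the initial-slope apparent diffusion coefficient.

# Positive-amplitude points of a curve, ordered by b. Noisy amplitudes that
# dipped below zero are dropped before any log-domain fit.
positive_points <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  keep <- is.finite(curve$amplitudes) & curve$amplitudes > 0
  list(b = curve$b_values[keep], a = curve$amplitudes[keep])
}

loglin_fit <- function(b, a) {
  fit <- stats::lm.fit(cbind(1, b), log(a))
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]))
}

#' Mono-exponential fit
#'
#' Least-squares line through (b, ln amplitude): the diffusion coefficient is
#' minus the slope and the population (fraction of the b = 0 amplitude) is
#' the exponentiated intercept. Used for the water calibration standard and
#' as a fallback when stripping fails on effectively single-phase curves.
#'
#' @param curve A [decay_curve()]; at least 3 points with positive amplitude.
#' @return A list with class `exponential_component`: fields `d` (m^2/s) and
#'   `population`.
#' @export
fit_mono <- function(curve) {
  pts <- positive_points(curve)
  if (length(pts$b) < 3L) {
    pfg_abort("mono-exponential fit needs >= 3 positive-amplitude points",
              "pfg_insufficient_data")
  }
  co <- loglin_fit(pts$b, pts$a)
  d <- -co$slope
  if (!is.finite(d) || d <= 0) {
    pfg_abort("degenerate mono-exponential fit: non-positive decay rate",
              "pfg_degenerate_fit")
  }
  structure(list(d = d, population = exp(co$intercept)),
            class = "exponential_component")
}

#' Initial-slope apparent diffusion coefficient
#'
#' ADC from the initial slope of the log-attenuation plot: minus the
#' least-squares slope of ln A versus b over the first `n_initial`
#' (smallest-b) points. For a biexponential curve this estimates the
#' population-weighted ADC of [weighted_adc()] as b tends to 0.
#'
#' @param curve A [decay_curve()].
#' @param n_initial Number of leading points to use (>= 2).
#' @return ADC, m^2 s^-1.
#' @export
initial_slope_adc <- function(curve, n_initial = 3) {
  pts <- positive_points(curve)
  if (!is.numeric(n_initial) || length(n_initial) != 1L || n_initial < 2) {
    pfg_abort("`n_initial` must be >= 2", "pfg_invalid_input")
  }
  n_initial <- as.integer(n_initial)
  if (n_initial > length(pts$b)) {
    pfg_abort("`n_initial` exceeds the number of usable points",
              "pfg_invalid_input")
  }
  co <- loglin_fit(pts$b[seq_len(n_initial)], pts$a[seq_len(n_initial)])
  -co$slope
}

biexp_rms <- function(b, a, p1, d_fast, d_slow) {
  pred <- p1 * exp(-b * d_fast) + (1 - p1) * exp(-b * d_slow)
  sqrt(mean((a - pred)^2))
}

#' Peel-off (stripping) biexponential fit
#'
#' Decomposes a decay curve into fast and slow exponential components.
#' The slow component is fitted first on the large-b tail of the
#' log-attenuation curve, where the fast phase has died away; it is then
#' subtracted ("peeled off") and the fast component is fitted to the
#' log-residuals. Populations are renormalized to sum to one. With
#' `refine = TRUE` the stripped estimates seed an amplitude-domain nonlinear
#' least-squares fit of the full two-term model (Levenberg-Marquardt).
#'
#' The tail is the largest-b `tail_fraction` of the points, further restricted
#' to b >= 3 / ADC0 (ADC0 from the initial slope, a lower bound on the fast
#' coefficient) whenever at least 3 points survive, so that the fast phase
#' contributes < 5% of the signal there. Residuals below
#' `residual_floor * A(0)`, or below 5% of the peak residual, are dropped
#' before the log transform to avoid fitting noise-dominated differences.
#'
#' @param curve A [decay_curve()] with >= 6 positive-amplitude points.
#' @param tail_fraction Fraction of points (by descending b) used for the
#'   slow-phase fit, in (0, 0.8].
#' @param refine Run nonlinear least-squares refinement seeded by the
#'   stripped estimates.
#' @param n_initial Points used for the recorded initial-slope ADC.
#' @param residual_floor Positivity floor for stripped residuals, as a
#'   fraction of the b = 0 amplitude.
#' @return An object of class `biexp_fit`: components `fast` and `slow`
#'   (each with `d`, `population`), `adc_initial_slope`, `method`
#'   (`"peel_off"` or `"peel_off_refined"`), `residual_rms`, `n_points_used`.
#' @export
peel_off_fit <- function(curve, tail_fraction = 0.4, refine = TRUE,
                         n_initial = 3, residual_floor = 1e-6) {
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1L ||
      tail_fraction <= 0 || tail_fraction > 0.8) {
    pfg_abort("`tail_fraction` must lie in (0, 0.8]", "pfg_invalid_input")
  }
  pts <- positive_points(curve)
  n <- length(pts$b)
  if (n < 6L) {
    pfg_abort("peel-off fit needs >= 6 positive-amplitude points",
              "pfg_insufficient_data")
  }
  a0 <- pts$a[1]
  adc0 <- initial_slope_adc(curve, n_initial = n_initial)

  # Slow phase from the tail of the log-attenuation curve.
  n_tail <- max(3L, as.integer(ceiling(tail_fraction * n)))
  tail_idx <- seq.int(n - n_tail + 1L, n)
  if (is.finite(adc0) && adc0 > 0) {
    far <- which(pts$b >= 3 / adc0)
    far <- intersect(far, tail_idx)
    if (length(far) >= 3L) tail_idx <- far
  }
  slow_co <- loglin_fit(pts$b[tail_idx], pts$a[tail_idx])
  d_slow <- -slow_co$slope
  pop_slow <- exp(slow_co$intercept)
  if (!is.finite(d_slow) || d_slow <= 0) {
    pfg_abort("stripping failed: slow-phase tail is not decaying",
              "pfg_stripping_failure")
  }

  # Fast phase from the log-residuals after subtracting the slow component.
  # Besides the absolute positivity floor, residuals below 5% of the peak
  # residual are excluded: once the fast phase has decayed, the residuals are
  # dominated by noise and slow-fit mismatch, and their logs would drag the
  # fast-phase slope toward zero.
  resid <- pts$a - pop_slow * exp(-pts$b * d_slow)
  floor_abs <- max(residual_floor * a0, 0.05 * max(resid))
  keep <- which(resid > floor_abs)
  if (length(keep) < 3L) {
    pfg_abort("stripping failed: fewer than 3 usable residual points",
              "pfg_stripping_failure")
  }
  fast_co <- loglin_fit(pts$b[keep], resid[keep])
  d_fast <- -fast_co$slope
  pop_fast <- exp(fast_co$intercept)
  if (!is.finite(d_fast) || d_fast <= d_slow) {
    pfg_abort("stripping failed: fast component not faster than slow component",
              "pfg_stripping_failure")
  }

  pop_sum <- pop_fast + pop_slow
  if (pop_sum < 0.95 || pop_sum > 1.05) {
    pfg_warn(sprintf(
      "stripped populations sum to %.3f before renormalization", pop_sum),
      "pfg_population_closure")
  }
  p1 <- pop_fast / pop_sum
  method <- "peel_off"
  rms <- biexp_rms(pts$b, pts$a, p1, d_fast, d_slow)

  if (isTRUE(refine)) {
    # Rates are log-parameterized: they span orders of magnitude and must
    # stay positive, and the log scale keeps the Jacobian well conditioned.
    refined <- tryCatch({
      fit <- minpack.lm::nlsLM(
        a ~ p1r * exp(-b * exp(ldf)) + (1 - p1r) * exp(-b * exp(lds)),
        data = list(a = pts$a, b = pts$b),
        start = list(p1r = p1, ldf = log(d_fast), lds = log(d_slow)),
        lower = c(0, log(1e-16), log(1e-16)),
        upper = c(1, log(1e-6), log(1e-6)),
        control = minpack.lm::nls.lm.control(maxiter = 500))
      cf <- stats::coef(fit)
      list(p1 = unname(cf["p1r"]),
           d_fast = exp(unname(cf["ldf"])),
           d_slow = exp(unname(cf["lds"])))
    }, error = function(e) NULL)
    if (!is.null(refined)) {
      rms_ref <- biexp_rms(pts$b, pts$a, refined$p1, refined$d_fast,
                           refined$d_slow)
      if (is.finite(rms_ref) && rms_ref <= rms) {
        if (refined$d_fast <= refined$d_slow) {
          pfg_abort("refinement violated the fast > slow ordering",
                    "pfg_order_violation")
        }
        p1 <- refined$p1
        d_fast <- refined$d_fast
        d_slow <- refined$d_slow
        rms <- rms_ref
        method <- "peel_off_refined"
      }
    }
  }

  structure(
    list(fast = structure(list(d = d_fast, population = p1),
                          class = "exponential_component"),
         slow = structure(list(d = d_slow, population = 1 - p1),
                          class = "exponential_component"),
         adc_initial_slope = adc0,
         method = method,
         residual_rms = rms,
         n_points_used = n),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit>", x$method, "\n")
  cat(sprintf("  fast: D = %.4g m^2/s, population = %.3f\n",
              x$fast$d, x$fast$population))
  cat(sprintf("  slow: D = %.4g m^2/s, population = %.3f\n",
              x$slow$d, x$slow$population))
  cat(sprintf("  initial-slope ADC = %.4g m^2/s, residual RMS = %.3g (%d points)\n",
              x$adc_initial_slope, x$residual_rms, x$n_points_used))
  invisible(x)
}

#' Fit a collection of decay curves
#'
#' Applies [peel_off_fit()] to each curve, falling back to [fit_mono()] when
#' stripping fails (effectively single-phase curves). Results are returned in
#' the scaled units of the regression layer: fast coefficients in 1e-9 m^2/s,
#' slow coefficients in 1e-11 m^2/s.
#'
#' @param curves Named list of [decay_curve()] objects.
#' @param ... Passed to [peel_off_fit()].
#' @return A data.frame with columns `curve_id`, `d_fast_1e9`, `d_slow_1e11`,
#'   `p1`, `adc_1e9`, `method`, `residual_rms`, `n_points_used`.
#' @export
fit_decay_curves <- function(curves, ...) {
  stopifnot(is.list(curves), length(curves) > 0L)
  ids <- names(curves)
  if (is.null(ids)) ids <- sprintf("curve%03d", seq_along(curves))
  rows <- lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    fit <- tryCatch(peel_off_fit(cu, ...),
                    pfg_stripping_failure = function(e) NULL)
    if (is.null(fit)) {
      mono <- fit_mono(cu)
      data.frame(curve_id = ids[i],
                 d_fast_1e9 = mono$d * 1e9,
                 d_slow_1e11 = NA_real_,
                 p1 = 1,
                 adc_1e9 = mono$d * 1e9,
                 method = "mono",
                 residual_rms = NA_real_,
                 n_points_used = length(positive_points(cu)$b))
    } else {
      data.frame(curve_id = ids[i],
                 d_fast_1e9 = fit$fast$d * 1e9,
                 d_slow_1e11 = fit$slow$d * 1e11,
                 p1 = fit$fast$population,
                 adc_1e9 = fit$adc_initial_slope * 1e9,
                 method = fit$method,
                 residual_rms = fit$residual_rms,
                 n_points_used = fit$n_points_used)
    }
  })
  do.call(rbind, rows)
}
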