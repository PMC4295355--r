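# Forward model for pulsed-field-gradient (PFG) echo attenuation of
# two-phase water, and the acquisition fixtures used throughout.

#' Pulse-sequence acquisition parameters
#'
#' Bundles the acquisition geometry of a stimulated-echo PFG experiment:
#' gyromagnetic ratio, gradient pulse duration, diffusion time, half echo
#' spacing, and the ramp of gradient amplitudes at which the echo is sampled.
#' All quantities are SI.
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1. Default is the proton value.
#' @param delta Gradient pulse duration, s.
#' @param t_d Diffusion time (separation of gradient pulse leading edges), s.
#' @param tau Half echo spacing, s (informational).
#' @param g_values Ordered, non-negative gradient amplitudes, T m^-1.
#' @param repetition_time Repetition time, s (informational).
#'
#' @return An object of class `pulse_sequence`.
#' @seealso [acquisition_default()], [acquisition_extended()], [compute_b_value()]
#' @export
pulse_sequence <- function(gamma = 2.675e8,
                           delta = 2e-4,
                           t_d = 0.02,
                           tau = 0.01,
                           g_values = seq(0, 4, length.out = 25),
                           repetition_time = 2) {
  check_number(gamma, "gamma", positive = TRUE)
  check_number(delta, "delta", positive = TRUE)
  check_number(t_d, "t_d", positive = TRUE)
  check_number(tau, "tau", positive = TRUE)
  if (!is.numeric(g_values) || length(g_values) < 1L || anyNA(g_values)) {
    pfg_abort("`g_values` must be a non-empty numeric vector", "pfg_invalid_input")
  }
  if (any(g_values < 0)) {
    pfg_abort("`g_values` must be non-negative", "pfg_invalid_input")
  }
  if (is.unsorted(g_values)) {
    pfg_abort("`g_values` must be non-decreasing", "pfg_invalid_input")
  }
  structure(
    list(gamma = gamma, delta = delta, t_d = t_d, tau = tau,
         g_values = as.numeric(g_values), repetition_time = repetition_time),
    class = "pulse_sequence"
  )
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat("<pulse_sequence>\n")
  cat(sprintf("  gamma: %.4g rad/s/T, delta: %.4g s, t_d: %.4g s, tau: %.4g s\n",
              x$gamma, x$delta, x$t_d, x$tau))
  cat(sprintf("  %d gradient steps, g in [%.3g, %.3g] T/m\n",
              length(x$g_values), min(x$g_values), max(x$g_values)))
  cat(sprintf("  b range: [0, %.4g] s/m^2\n",
              max(compute_b_value(x, max(x$g_values)))))
  invisible(x)
}

#' Default acquisition fixture
#'
#' Single-diffusion-time stimulated-echo acquisition: proton gamma,
#' delta = 0.2 ms, t_d = 20 ms, 2 tau = 20 ms, gradient ramp 0 to 4 T/m in
#' 25 steps, repetition time 2 s.
#'
#' @return A `pulse_sequence`.
#' @export
acquisition_default <- function() pulse_sequence()

#' Extended-b acquisition fixture
#'
#' A sweep of diffusion times (default 11, 50, 200 and 800 ms), each with the
#' default gradient ramp. The long-t_d members extend the maximum b-value to
#' ~3.7e10 s/m^2 so that the slow diffusion phase (D around 1.7e-11 m^2/s) is
#' attenuated enough to be identifiable: at t_d = 20 ms alone,
#' max(b) * D_slow is only ~0.015 and stripping cannot separate the phases.
#'
#' @param t_d Numeric vector of diffusion times, s.
#' @param n_steps Number of gradient steps per ramp.
#' @return A list of `pulse_sequence` objects (class `pulse_sequence_set`).
#' @export
acquisition_extended <- function(t_d = c(0.011, 0.05, 0.2, 0.8), n_steps = 25) {
  seqs <- lapply(t_d, function(td) {
    pulse_sequence(t_d = td, g_values = seq(0, 4, length.out = n_steps))
  })
  structure(seqs, class = "pulse_sequence_set")
}

#' Diffusion weighting b-value
#'
#' Computes the Stejskal-Tanner weighting b = gamma^2 delta^2 g^2 t_d for a
#' gradient amplitude `g` under the acquisition `seq`.
#'
#' @param seq A `pulse_sequence`.
#' @param g Gradient amplitude(s), T m^-1; must be non-negative.
#' @return b-value(s), s m^-2.
#' @export
compute_b_value <- function(seq, g) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (!is.numeric(g) || anyNA(g)) {
    pfg_abort("`g` must be numeric", "pfg_invalid_input")
  }
  if (any(g < 0)) {
    pfg_abort("gradient amplitude `g` must be >= 0", "pfg_invalid_input")
  }
  seq$gamma^2 * seq$delta^2 * g^2 * seq$t_d
}

# b-grid of a sequence or a set of sequences: union, sorted, deduplicated.
b_grid <- function(seq) {
  seqs <- if (inherits(seq, "pulse_sequence")) list(seq) else seq
  if (length(seqs) == 0L) pfg_abort("empty acquisition", "pfg_invalid_input")
  b <- unlist(lapply(seqs, function(s) compute_b_value(s, s$g_values)))
  sort(unique(b))
}

#' Two-compartment diffusion parameters
#'
#' Fast/slow diffusion-phase parameters of the biexponential model: diffusion
#' coefficients `d_fast > d_slow > 0` (m^2/s) and the fast-phase spin
#' population fraction `p1` (the slow-phase fraction is `1 - p1`).
#'
#' @param d_fast Fast-phase diffusion coefficient, m^2 s^-1.
#' @param d_slow Slow-phase diffusion coefficient, m^2 s^-1.
#' @param p1 Fast-phase population fraction in `[0, 1]`.
#' @return An object of class `compartment_set`.
#' @export
compartment_set <- function(d_fast, d_slow, p1) {
  check_number(d_fast, "d_fast", positive = TRUE)
  check_number(d_slow, "d_slow", positive = TRUE)
  check_number(p1, "p1")
  if (d_fast <= d_slow) {
    pfg_abort("`d_fast` must exceed `d_slow`", "pfg_invalid_input")
  }
  if (p1 < 0 || p1 > 1) {
    pfg_abort("`p1` must lie in [0, 1]", "pfg_invalid_input")
  }
  structure(list(d_fast = d_fast, d_slow = d_slow, p1 = p1),
            class = "compartment_set")
}

#' @export
print.compartment_set <- function(x, ...) {
  cat(sprintf("<compartment_set> d_fast = %.4g m^2/s, d_slow = %.4g m^2/s, p1 = %.3f\n",
              x$d_fast, x$d_slow, x$p1))
  invisible(x)
}

#' Biexponential echo attenuation
#'
#' Normalized signal of two water phases in slow exchange:
#' `S(b)/S(0) = p1 exp(-b d_fast) + (1 - p1) exp(-b d_slow)`.
#'
#' @param b Diffusion weighting(s), s m^-2; non-negative.
#' @param compartments A [compartment_set()].
#' @return Normalized amplitude(s) in (0, 1].
#' @export
biexp_signal <- function(b, compartments) {
  stopifnot(inherits(compartments, "compartment_set"))
  if (!is.numeric(b) || anyNA(b)) pfg_abort("`b` must be numeric", "pfg_invalid_input")
  if (any(b < 0)) pfg_abort("`b` must be >= 0", "pfg_invalid_input")
  compartments$p1 * exp(-b * compartments$d_fast) +
    (1 - compartments$p1) * exp(-b * compartments$d_slow)
}

#' Population-weighted apparent diffusion coefficient
#'
#' Volume-weighted mean diffusivity of the two phases,
#' `ADC = p1 d_fast + (1 - p1) d_slow`, which the initial slope of the
#' log-attenuation curve estimates as b tends to 0.
#'
#' @inheritParams biexp_signal
#' @return ADC in m^2 s^-1, always within `[d_slow, d_fast]`.
#' @export
weighted_adc <- function(compartments) {
  stopifnot(inherits(compartments, "compartment_set"))
  compartments$p1 * compartments$d_fast +
    (1 - compartments$p1) * compartments$d_slow
}

#' Decay curve container
#'
#' Normalized echo attenuation `A(g)/A(0)` sampled on a strictly increasing
#' b-value grid.
#'
#' @param b_values Strictly increasing b-values, s m^-2; first entry >= 0.
#' @param amplitudes Normalized amplitudes (same length as `b_values`).
#' @param noise_sigma Additive noise scale used at synthesis, or `NA` for
#'   measured/unknown curves.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(b_values, amplitudes, noise_sigma = NA_real_) {
  if (!is.numeric(b_values) || !is.numeric(amplitudes) ||
      length(b_values) != length(amplitudes) || length(b_values) < 1L) {
    pfg_abort("`b_values` and `amplitudes` must be numeric vectors of equal length",
              "pfg_invalid_input")
  }
  if (b_values[1] < 0 || any(diff(b_values) <= 0)) {
    pfg_abort("`b_values` must be strictly increasing with first entry >= 0",
              "pfg_invalid_input")
  }
  structure(list(b_values = as.numeric(b_values),
                 amplitudes = as.numeric(amplitudes),
                 noise_sigma = noise_sigma),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d points, b in [%.4g, %.4g] s/m^2%s\n",
              length(x$b_values), min(x$b_values), max(x$b_values),
              if (is.na(x$noise_sigma)) "" else
                sprintf(", synthesized with noise_sigma = %.3g", x$noise_sigma)))
  invisible(x)
}

#' Synthesize a decay curve
#'
#' Evaluates the biexponential forward model on the b-grid of an acquisition
#' and adds zero-mean Gaussian noise of scale `noise_sigma` to the amplitudes.
#' With `noise_sigma = 0` the forward model is returned exactly. A fixed
#' `seed` makes the noise realization reproducible without touching the
#' caller's RNG state.
#'
#' @param seq A `pulse_sequence` or a list of them (e.g.
#'   [acquisition_extended()]); the b-grids are pooled.
#' @param compartments A [compartment_set()].
#' @param noise_sigma Amplitude noise standard deviation, >= 0.
#' @param seed Optional integer seed for the noise.
#' @return A [decay_curve()].
#' @export
synthesize_curve <- function(seq, compartments, noise_sigma = 0, seed = NULL) {
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  b <- b_grid(seq)
  a <- biexp_signal(b, compartments)
  if (noise_sigma > 0) {
    a <- a + with_seed(seed, stats::rnorm(length(b), 0, noise_sigma))
  }
  decay_curve(b, a, noise_sigma = noise_sigma)
}

#' Water calibration-standard curve
#'
#' Single-exponential attenuation `A(g)/A(0) = exp(-b D)` of the water
#' standard used to calibrate the spectrometer (D = 2.7e-9 m^2/s at 303 K,
#' independent of diffusion time).
#'
#' @param seq Acquisition fixture; defaults to [acquisition_default()].
#' @param d Standard diffusivity, m^2 s^-1.
#' @param noise_sigma,seed Passed to the noise model as in [synthesize_curve()].
#' @return A [decay_curve()].
#' @export
water_standard_curve <- function(seq = acquisition_default(), d = 2.7e-9,
                                 noise_sigma = 0, seed = NULL) {
  check_number(d, "d", positive = TRUE)
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  b <- b_grid(seq)
  a <- exp(-b * d)
  if (noise_sigma > 0) {
    a <- a + with_seed(seed, stats::rnorm(length(b), 0, noise_sigma))
  }
  decay_curve(b, a, noise_sigma = noise_sigma)
}

#' Read and write decay-curve tables
#'
#' Curves are exchanged as long-format delimited text with a header row and
#' columns `curve_id`, `b_value_si`, `amplitude` (period decimal separator).
#' Lines starting with `#` are treated as comments.
#'
#' @param curves Named list of [decay_curve()] objects.
#' @param path File path.
#' @param header_lines Optional character vector written as `#` comments.
#' @return `write_decay_curves()` returns `path` invisibly;
#'   `read_decay_curves()` returns a named list of `decay_curve` objects.
#' @export
write_decay_curves <- function(curves, path, header_lines = NULL) {
  stopifnot(is.list(curves), length(curves) > 0L)
  ids <- names(curves)
  if (is.null(ids)) ids <- sprintf("curve%03d", seq_along(curves))
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    data.frame(curve_id = ids[i], b_value_si = cu$b_values,
               amplitude = cu$amplitudes)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay_curves
#' @export
read_decay_curves <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("curve_id", "b_value_si", "amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    pfg_abort(sprintf("curve table is missing columns: %s",
                      paste(miss, collapse = ", ")), "pfg_schema_error")
  }
  out <- lapply(split(df, df$curve_id), function(d) {
    d <- d[order(d$b_value_si), ]
    decay_curve(d$b_value_si, d$amplitude)
  })
  out[unique(df$curve_id)]
}
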