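# Internal helpers: classed conditions, scoped RNG, truncated normals.

pfg_abort <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, class = c(class, "pfg_error"), call = call, ...))
}

pfg_warn <- function(message, class, ...) {
  warning(warningCondition(message, class = c(class, "pfg_warning"), ...))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pfg_abort(sprintf("`%s` must be a single finite number", name),
              "pfg_invalid_input")
  }
  if (positive && x <= 0) {
    pfg_abort(sprintf("`%s` must be > 0", name), "pfg_invalid_input")
  }
  if (nonneg && x < 0) {
    pfg_abort(sprintf("`%s` must be >= 0", name), "pfg_invalid_input")
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a per-unit child seed from a base seed. Kept below 2^31 - 1.
child_seed <- function(seed, index, stream = 1L) {
  (as.double(seed) * 1009 + index * 9973 + stream * 7919) %% 2147483629
}

# Inverse-CDF sampler for a normal(mu, sd) truncated to [lo, hi].
rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (lo > hi) pfg_abort("truncation bounds infeasible (min > max)",
                         "pfg_config_error")
  if (sd == 0) {
    if (mu < lo || mu > hi) {
      pfg_abort("zero-sd mean outside truncation bounds", "pfg_config_error")
    }
    return(rep(mu, n))
  }
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  if (sd == 0) return(mu)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# Location such that the truncated-normal mean equals `target`.
calibrate_truncnorm_mu <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
                 interval = c(target - 8 * sd, target + 8 * sd),
                 tol = 1e-10)$root
}
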