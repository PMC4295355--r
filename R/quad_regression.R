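# Second-order response-surface regression: design-matrix construction,
# ordinary least-squares fitting with R^2 and per-coefficient t-tests, and
# polynomial evaluation.

#' Second-order design matrix
#'
#' Expands predictor rows into a second-order polynomial design. Column order
#' is: intercept, linear terms in input order, squared terms in input order,
#' then (for `full_second_order` only) pairwise products `xi:xj` with i < j
#' in input order. A `pure_quadratic` design in k predictors has `1 + 2k`
#' columns; a `full_second_order` design has `1 + 2k + k(k-1)/2`.
#'
#' @param x A numeric matrix or data.frame of predictor rows (n x k), or a
#'   single numeric vector of length k.
#' @param design_kind `"pure_quadratic"` (no interactions) or
#'   `"full_second_order"`.
#' @param term_names Optional predictor names; defaults to column names.
#' @return Numeric design matrix with named columns.
#' @export
build_design <- function(x, design_kind = c("pure_quadratic", "full_second_order"),
                         term_names = NULL) {
  design_kind <- match.arg(design_kind)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.numeric(x) || anyNA(x)) {
    pfg_abort("predictors must be numeric without missing values",
              "pfg_invalid_input")
  }
  k <- ncol(x)
  if (k < 1L) pfg_abort("need at least one predictor", "pfg_invalid_input")
  if (is.null(term_names)) term_names <- colnames(x)
  if (is.null(term_names)) term_names <- paste0("x", seq_len(k))
  if (length(term_names) != k) {
    pfg_abort("`term_names` length must match the number of predictors",
              "pfg_invalid_input")
  }
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  for (j in seq_len(k)) cols[[term_names[j]]] <- x[, j]
  for (j in seq_len(k)) cols[[paste0(term_names[j], "^2")]] <- x[, j]^2
  if (design_kind == "full_second_order" && k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        cols[[paste0(term_names[i], ":", term_names[j])]] <- x[, i] * x[, j]
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  attr(out, "design_kind") <- design_kind
  attr(out, "term_names") <- term_names
  out
}

#' Construct a quadratic model object
#'
#' Low-level constructor used both by [fit_quadratic()] and for coefficient
#' sets transcribed from the literature (see [reference_predictors()]).
#'
#' @param coefficients Named numeric vector aligned with the columns of
#'   [build_design()] for `term_names` and `design_kind`.
#' @param term_names Predictor names, in design order.
#' @param design_kind Design kind (see [build_design()]).
#' @param r_squared Coefficient of determination computed by this package
#'   (`NA` for transcribed coefficient sets).
#' @param reported_r_squared R^2 reported at the source for transcribed sets.
#' @param response_name,response_units Labels.
#' @param coef_table Optional data.frame of OLS estimates/SE/t/p.
#' @param n Number of observations used in the fit (`NA` if not fitted here).
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(coefficients, term_names, design_kind,
                            r_squared = NA_real_,
                            reported_r_squared = NA_real_,
                            response_name = "", response_units = "",
                            coef_table = NULL, n = NA_integer_) {
  k <- length(term_names)
  expected <- 1L + 2L * k +
    if (design_kind == "full_second_order") (k * (k - 1L)) %/% 2L else 0L
  if (length(coefficients) != expected) {
    pfg_abort(sprintf(
      "coefficient count %d does not match a %s design in %d predictors (expect %d)",
      length(coefficients), design_kind, k, expected), "pfg_invalid_input")
  }
  structure(list(design_kind = design_kind,
                 term_names = term_names,
                 coefficients = coefficients,
                 r_squared = r_squared,
                 reported_r_squared = reported_r_squared,
                 response_name = response_name,
                 response_units = response_units,
                 coef_table = coef_table,
                 n = n),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat(sprintf("<quadratic_model> %s%s ~ %s(%s)\n",
              x$response_name,
              if (nzchar(x$response_units)) paste0(" [", x$response_units, "]") else "",
              x$design_kind, paste(x$term_names, collapse = ", ")))
  print(round(x$coefficients, digits))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f (n = %d)\n", x$r_squared, x$n))
  if (!is.na(x$reported_r_squared)) {
    cat(sprintf("  reported R^2 = %.2f (transcribed coefficient set)\n",
                x$reported_r_squared))
  }
  invisible(x)
}

#' Fit a second-order regression by ordinary least squares
#'
#' Builds the design with [build_design()] and solves the least-squares
#' problem. `R^2 = 1 - SS_res / SS_tot`; when the response is constant the
#' convention `R^2 = 0` is used and all non-intercept coefficients are zero.
#' Per-coefficient t-tests are reported for information only; no terms are
#' pruned. Predictors are used on their raw scales (see the unit contract in
#' the package vignette).
#'
#' @param x Predictor rows (n x k matrix or data.frame).
#' @param y Numeric response of length n.
#' @inheritParams build_design
#' @param response_name,response_units Labels stored on the model.
#' @return A [quadratic_model()] with `r_squared` and `coef_table`.
#' @export
fit_quadratic <- function(x, y, design_kind = c("pure_quadratic", "full_second_order"),
                          term_names = NULL, response_name = "y",
                          response_units = "") {
  design_kind <- match.arg(design_kind)
  d <- build_design(x, design_kind, term_names)
  if (!is.numeric(y) || length(y) != nrow(d) || anyNA(y)) {
    pfg_abort("`y` must be a numeric response matching the predictor rows",
              "pfg_invalid_input")
  }
  p <- ncol(d)
  n <- nrow(d)
  if (n <= p) {
    pfg_abort(sprintf(
      "underdetermined design: %d observations for %d coefficients", n, p),
      "pfg_underdetermined_design")
  }
  if (stats::var(y) == 0) {
    cf <- c(y[1], rep(0, p - 1L))
    names(cf) <- colnames(d)
    return(quadratic_model(cf, attr(d, "term_names"), design_kind,
                           r_squared = 0, response_name = response_name,
                           response_units = response_units, n = n))
  }
  qr_d <- qr(d)
  if (qr_d$rank < p) {
    bad <- colnames(d)[qr_d$pivot[seq.int(qr_d$rank + 1L, p)]]
    pfg_abort(sprintf("rank-deficient design; collinear columns: %s",
                      paste(bad, collapse = ", ")), "pfg_collinearity",
              columns = bad)
  }
  fit <- stats::lm(y ~ d - 1)
  cf <- stats::coef(fit)
  names(cf) <- colnames(d)
  # noiseless interpolation makes summary() warn about a perfect fit; the
  # t-tests are reported for information only, so that is acceptable here
  sm <- suppressWarnings(summary(fit))
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "std_error", "t_value", "p_value")
  rownames(ct) <- colnames(d)
  resid <- stats::residuals(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  quadratic_model(cf, attr(d, "term_names"), design_kind,
                  r_squared = r2, response_name = response_name,
                  response_units = response_units, coef_table = ct, n = n)
}

#' Evaluate a quadratic model
#'
#' Inner product of the model coefficients with the [build_design()] row(s)
#' for `x`.
#'
#' @param model A [quadratic_model()].
#' @param x Predictor vector of length k, or an n x k matrix/data.frame.
#' @return Predicted response(s).
#' @export
evaluate_model <- function(model, x) {
  stopifnot(inherits(model, "quadratic_model"))
  k <- length(model$term_names)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k) {
      pfg_abort(sprintf("predictor vector has length %d; model expects %d",
                        length(x), k), "pfg_invalid_input")
    }
    x <- matrix(x, nrow = 1)
  } else if (ncol(x) != k) {
    pfg_abort(sprintf("predictor matrix has %d columns; model expects %d",
                      ncol(x), k), "pfg_invalid_input")
  }
  d <- build_design(x, model$design_kind, model$term_names)
  drop(d %*% model$coefficients)
}

#' Unit conversions between SI and the regression scale
#'
#' The regression and scoring layers use fast-phase coefficients in units of
#' 1e-9 m^2/s and slow-phase coefficients in units of 1e-11 m^2/s, so that
#' numeric magnitudes are of order 0.3 to 4. These helpers are exact
#' multiplications.
#'
#' @param d Diffusion coefficient(s).
#' @return Converted value(s).
#' @name diffusion_units
NULL

#' @rdname diffusion_units
#' @export
d_fast_to_scaled <- function(d) d * 1e9

#' @rdname diffusion_units
#' @export
d_fast_to_si <- function(d) d * 1e-9

#' @rdname diffusion_units
#' @export
d_slow_to_scaled <- function(d) d * 1e11

#' @rdname diffusion_units
#' @export
d_slow_to_si <- function(d) d * 1e-11
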