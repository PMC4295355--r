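# Cancer-probability (CanP) scoring: published quadratic scoring models,
# clamping to the 0-to-1 probability scale, binary classification,
# linear-probability refitting, and response-surface grids.

canp_predictors <- function(variant) {
  switch(variant,
         morphology = MORPH_PREDICTORS,
         diffusion2 = c("d_fast", "d_slow"),
         diffusion3 = c("d_fast", "d_slow", "p1"),
         pfg_abort(sprintf("unknown CanP variant '%s'", variant),
                   "pfg_invalid_input"))
}

canp_design_kind <- function(variant) {
  if (variant == "morphology") "pure_quadratic" else "full_second_order"
}

#' Construct a cancer-probability scoring model
#'
#' A CanP model couples a [quadratic_model()] surface with a decision
#' threshold. The variant fixes the predictor list and design:
#' `morphology` uses the five histological percentages in a pure-quadratic
#' design; `diffusion2` uses (d_fast, d_slow) and `diffusion3`
#' (d_fast, d_slow, p1) in full second-order designs. Diffusion predictors
#' are on the regression scale (1e-9 / 1e-11 m^2/s).
#'
#' @param variant `"morphology"`, `"diffusion2"` or `"diffusion3"`.
#' @param model A [quadratic_model()] over the variant's predictors.
#' @param threshold Decision cutoff on the clamped probability; a specimen is
#'   labelled malignant when probability >= threshold.
#' @return An object of class `canp_model`.
#' @export
canp_model <- function(variant, model, threshold = 0.5) {
  variant <- match.arg(variant, c("morphology", "diffusion2", "diffusion3"))
  stopifnot(inherits(model, "quadratic_model"))
  if (!identical(model$term_names, canp_predictors(variant)) ||
      model$design_kind != canp_design_kind(variant)) {
    pfg_abort(sprintf("model terms/design do not match CanP variant '%s'",
                      variant), "pfg_invalid_input")
  }
  check_number(threshold, "threshold")
  structure(list(variant = variant, model = model, threshold = threshold),
            class = "canp_model")
}

#' @export
print.canp_model <- function(x, ...) {
  cat(sprintf("<canp_model> variant '%s', threshold %.2f\n", x$variant,
              x$threshold))
  print(x$model)
  invisible(x)
}

#' Published cancer-probability models
#'
#' The three published CanP scoring equations: a pure-quadratic surface over
#' the five histological percentages, and full second-order surfaces over the
#' two and three diffusion parameters. Coefficients are transcribed in
#' `inst/extdata/reference_coefficients.tsv`.
#'
#' @param threshold Decision cutoff applied by [canp_score()].
#' @return Named list of [canp_model()] objects: `morphology`, `diffusion2`,
#'   `diffusion3`.
#' @export
canp_reference_models <- function(threshold = 0.5) {
  tab <- read_reference_coefficients()
  out <- lapply(c(morphology = "morphology", diffusion2 = "diffusion2",
                  diffusion3 = "diffusion3"), function(v) {
    qm <- reference_model(tab, paste0("canp_", v), canp_predictors(v),
                          canp_design_kind(v), "CanP", "")
    canp_model(v, qm, threshold = threshold)
  })
  out
}

#' Score specimens with a cancer-probability model
#'
#' Evaluates the quadratic surface at the predictor values; the probability
#' is the raw score clamped to `[0, 1]` (realizing the published 0-to-1
#' probability convention and the flat saturation regions of the published
#' response surfaces), and the label is `malignant` when the probability
#' reaches the threshold. Diffusion inputs far outside the regression scale
#' (outside `[0.01, 100]`) trigger a suspicious-units warning, since SI
#' inputs would silently collapse the quadratic terms.
#'
#' @param model A [canp_model()].
#' @param x Predictor vector (length = variant predictors) or n x k
#'   matrix/data.frame; data.frames may carry extra columns, which are
#'   ignored.
#' @param threshold Optional override of the model threshold.
#' @return A data.frame with columns `raw_score`, `probability`, `label`.
#' @export
canp_score <- function(model, x, threshold = model$threshold) {
  stopifnot(inherits(model, "canp_model"))
  preds <- canp_predictors(model$variant)
  if (is.data.frame(x)) {
    miss <- setdiff(preds, names(x))
    if (length(miss) > 0L) {
      pfg_abort(sprintf("missing predictor columns: %s",
                        paste(miss, collapse = ", ")), "pfg_invalid_input")
    }
    x <- as.matrix(x[preds])
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(preds)) {
    pfg_abort(sprintf("predictor input has %d columns; variant '%s' expects %s",
                      ncol(x), model$variant, paste(preds, collapse = ", ")),
              "pfg_invalid_input")
  }
  if (!is.null(colnames(x))) x <- x[, preds, drop = FALSE]
  colnames(x) <- preds
  if (model$variant != "morphology") {
    dvals <- x[, c("d_fast", "d_slow"), drop = FALSE]
    if (any(dvals != 0 & (abs(dvals) < 0.01 | abs(dvals) > 100))) {
      pfg_warn(paste("diffusion inputs outside [0.01, 100]; expected scaled",
                     "units (1e-9 / 1e-11 m^2/s), not SI"),
               "pfg_suspicious_units")
    }
  }
  raw <- unname(evaluate_model(model$model, x))
  prob <- pmin(1, pmax(0, raw))
  data.frame(raw_score = raw,
             probability = prob,
             label = ifelse(prob >= threshold, "malignant", "nonmalignant"))
}

#' Refit a cancer-probability surface on labelled specimens
#'
#' Ordinary least squares of the 0/1 malignancy indicator on the variant's
#' quadratic design - a linear-probability response surface, mirroring how
#' the published equations were obtained. Logistic regression is deliberately
#' not offered here, to keep the refit comparable with the published models.
#'
#' @param x Predictor rows (matrix or data.frame; data.frames may carry extra
#'   columns).
#' @param labels Binary outcome: 1/TRUE/"cancer" = malignant,
#'   0/FALSE/"control" = nonmalignant. Both classes must be present.
#' @param variant CanP variant (see [canp_model()]).
#' @param threshold Decision cutoff stored on the returned model.
#' @return A [canp_model()] whose quadratic model carries `r_squared`.
#' @export
fit_canp <- function(x, labels, variant = c("morphology", "diffusion2", "diffusion3"),
                     threshold = 0.5) {
  variant <- match.arg(variant)
  preds <- canp_predictors(variant)
  if (is.data.frame(x)) {
    miss <- setdiff(preds, names(x))
    if (length(miss) > 0L) {
      pfg_abort(sprintf("missing predictor columns: %s",
                        paste(miss, collapse = ", ")), "pfg_invalid_input")
    }
    x <- as.matrix(x[preds])
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "cancer"
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) {
    pfg_abort("`labels` must be binary (0/1, logical, or control/cancer)",
              "pfg_invalid_input")
  }
  if (length(unique(y)) < 2L) {
    pfg_abort("both classes must be present to fit a CanP model",
              "pfg_degenerate_labels")
  }
  qm <- fit_quadratic(x, y, canp_design_kind(variant), term_names = preds,
                      response_name = "CanP")
  canp_model(variant, qm, threshold = threshold)
}

#' Probability surface on a 2-D grid
#'
#' Evaluates a CanP model on a regular grid over two predictors, the rest
#' held fixed (conventionally at whole-cohort means). Values are clamped
#' probabilities, so saturated regions show up as flat plateaus at 0 and 1.
#'
#' @param model A [canp_model()].
#' @param axis1,axis2 Named lists `list(name =, range = c(lo, hi))` for the
#'   two grid axes; names must be distinct variant predictors.
#' @param fixed Named numeric vector of values for the remaining predictors
#'   (may be empty when the variant has exactly two predictors).
#' @param n_grid Grid points per axis (>= 2).
#' @return An object of class `canp_surface`: list with `x`, `y` (axis
#'   values), `prob` (matrix, rows indexed by `x`), `axes`, `fixed`.
#' @export
surface_grid <- function(model, axis1, axis2, fixed = numeric(0), n_grid = 25) {
  stopifnot(inherits(model, "canp_model"))
  preds <- canp_predictors(model$variant)
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$range) ||
        length(ax$range) != 2L || !all(is.finite(ax$range))) {
      pfg_abort("each axis must be list(name =, range = c(lo, hi)) with finite range",
                "pfg_invalid_input")
    }
    if (!ax$name %in% preds) {
      pfg_abort(sprintf("'%s' is not a predictor of variant '%s'",
                        ax$name, model$variant), "pfg_invalid_input")
    }
  }
  if (identical(axis1$name, axis2$name)) {
    pfg_abort("grid axes must be distinct predictors", "pfg_invalid_input")
  }
  if (!is.numeric(n_grid) || n_grid < 2) {
    pfg_abort("`n_grid` must be >= 2", "pfg_invalid_input")
  }
  rest <- setdiff(preds, c(axis1$name, axis2$name))
  miss <- setdiff(rest, names(fixed))
  if (length(miss) > 0L) {
    pfg_abort(sprintf("missing fixed values for: %s",
                      paste(miss, collapse = ", ")), "pfg_invalid_input")
  }
  xs <- seq(axis1$range[1], axis1$range[2], length.out = n_grid)
  ys <- seq(axis2$range[1], axis2$range[2], length.out = n_grid)
  grid <- expand.grid(xs, ys, KEEP.OUT.ATTRS = FALSE)
  pts <- matrix(0, nrow(grid), length(preds),
                dimnames = list(NULL, preds))
  pts[, axis1$name] <- grid[[1]]
  pts[, axis2$name] <- grid[[2]]
  for (nm in rest) pts[, nm] <- fixed[[nm]]
  prob <- suppressWarnings(canp_score(model, pts)$probability)
  structure(list(x = xs, y = ys,
                 prob = matrix(prob, n_grid, n_grid),
                 axes = c(axis1$name, axis2$name),
                 fixed = fixed,
                 variant = model$variant),
            class = "canp_surface")
}

#' @export
print.canp_surface <- function(x, ...) {
  cat(sprintf("<canp_surface> %s: %s x %s grid (%d x %d), prob in [%.3f, %.3f]\n",
              x$variant, x$axes[1], x$axes[2], length(x$x), length(x$y),
              min(x$prob), max(x$prob)))
  invisible(x)
}

#' Write a probability surface as a delimited matrix table
#'
#' Rows are axis-1 values, columns axis-2 values; the first column holds the
#' axis-1 coordinate.
#'
#' @param surface A [surface_grid()] result.
#' @param path Output file.
#' @param header_lines Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, header_lines = NULL) {
  stopifnot(inherits(surface, "canp_surface"))
  df <- data.frame(surface$x, surface$prob)
  names(df) <- c(surface$axes[1],
                 paste0(surface$axes[2], "_", signif(surface$y, 6)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
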