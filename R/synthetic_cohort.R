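# Synthetic cohort generator calibrated to the published group statistics:
# six-part histological compositions, group-wise diffusion parameters
# (group-parameter mode) or diffusion parameters derived from the published
# composition regressions with R^2-calibrated residual noise
# (equation-driven mode), plus decay-curve synthesis.

# Published per-variable summary statistics (mean, sd, min, max).
# Composition in percent; diffusion parameters on the regression scale
# (d_fast 1e-9 m^2/s, d_slow 1e-11 m^2/s, p1 fraction, adc 1e-9 m^2/s).
# Note: the published cancer-group slow coefficient (mean 0.86, sd 0.68,
# range 0.40-3.84) is internally inconsistent with its TNM sub-columns
# (means >= 1.75); the printed numbers are kept verbatim.
GROUP_PARAM_TABLE <- list(
  control = list(
    n = 6L,
    composition = list(
      p   = c(16.7, 19.7, 0.01, 54.7),
      st  = c(35.7,  8.8, 25.5, 49.0),
      at  = c(32.6, 21.0, 0.01, 53.8),
      pce = c( 4.0,  6.4, 0.01, 17.0),
      pve = c( 5.9,  5.8, 0.01, 13.6),
      v   = c( 5.1,  4.9, 0.20, 14.1)),
    diffusion = list(
      d_fast = c(1.25, 0.13, 1.10, 1.40),
      d_slow = c(1.67, 0.15, 0.50, 1.91),
      p1     = c(0.48, 0.17, 0.27, 0.77),
      adc    = c(0.78, 0.28, 0.41, 1.16))),
  cancer = list(
    n = 11L,
    composition = list(
      p   = c(30.7, 15.7, 10.3, 56.6),
      st  = c(39.9, 13.6, 26.1, 64.2),
      at  = c(11.6, 16.1, 0.01, 50.4),
      pce = c( 7.1,  6.9, 0.01, 16.0),
      pve = c( 7.5, 11.1, 0.01, 32.3),
      v   = c( 3.1,  2.6, 0.10,  7.3)),
    diffusion = list(
      d_fast = c(0.97, 0.25, 0.57, 1.25),
      d_slow = c(0.86, 0.68, 0.40, 3.84),
      p1     = c(0.75, 0.22, 0.23, 0.97),
      adc    = c(1.62, 1.28, 0.33, 3.43))),
  cancer_t2n0m0 = list(
    n = 6L,
    composition = NULL,  # no published TNM split of the composition table
    diffusion = list(
      d_fast = c(0.93, 0.24, 0.60, 1.20),
      d_slow = c(1.75, 0.17, 1.50, 1.98),
      p1     = c(0.74, 0.28, 0.23, 0.97),
      adc    = c(0.85, 0.34, 0.33, 1.22))),
  cancer_t2n1m0 = list(
    n = 5L,
    composition = NULL,
    diffusion = list(
      d_fast = c(1.01, 0.28, 0.57, 1.29),
      d_slow = c(2.00, 1.03, 1.40, 3.84),
      p1     = c(0.78, 0.14, 0.63, 0.95),
      adc    = c(2.54, 1.30, 0.79, 3.43)))
)

#' Published group parameters
#'
#' Per-variable mean/SD/min/max of the six histological constituents and of
#' the diffusion parameters, transcribed from the published control and
#' cancer group tables. TNM sub-columns of the cancer group are available as
#' optional diffusion-parameter overrides (`cancer_t2n0m0`,
#' `cancer_t2n1m0`; they carry no composition split).
#'
#' @param group One of `"control"`, `"cancer"`, `"cancer_t2n0m0"`,
#'   `"cancer_t2n1m0"`.
#' @return A list with fields `group`, `n`, `composition` (named list of
#'   `c(mean, sd, min, max)`) and `diffusion` (same layout; scaled units).
#' @export
breast_group_params <- function(group = c("control", "cancer",
                                          "cancer_t2n0m0", "cancer_t2n1m0")) {
  group <- match.arg(group)
  gp <- GROUP_PARAM_TABLE[[group]]
  structure(c(list(group = group), gp), class = "group_params")
}

#' Cohort generation configuration
#'
#' Settings for [generate_cohort()]. `group_parameter` mode draws diffusion
#' parameters from the published group statistics; `equation_driven` mode
#' computes them from the published composition regressions
#' ([reference_predictors()]) at each specimen's sampled composition, plus
#' Gaussian residual noise calibrated so a refit attains the target R^2
#' (`sigma^2 = Var(predicted) (1 - R^2) / R^2`, with `Var(predicted)` taken
#' over the sampled cohort before noise is added).
#'
#' @param n_control,n_cancer Group sizes; defaults are the published study
#'   design (6 control, 11 cancer).
#' @param mode `"group_parameter"` or `"equation_driven"`.
#' @param target_r2 Named vector of target R^2 for `d_fast`, `d_slow`, `p1`
#'   (equation-driven mode); defaults are the published values.
#' @param acquisition Acquisition fixture for curve synthesis; the default
#'   [acquisition_extended()] makes the slow phase identifiable.
#' @param noise_sigma Amplitude noise scale for curve synthesis.
#' @param seed Integer seed; fixes the whole cohort.
#' @param make_curves Synthesize decay curves (disable for regression-only
#'   studies).
#' @param use_tnm_overrides In group-parameter mode, draw cancer diffusion
#'   parameters from the TNM sub-column statistics instead of the pooled
#'   cancer column.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 6, n_cancer = 11,
                          mode = c("group_parameter", "equation_driven"),
                          target_r2 = c(d_fast = 0.92, d_slow = 0.81, p1 = 0.93),
                          acquisition = acquisition_extended(),
                          noise_sigma = 0.005,
                          seed = 1,
                          make_curves = TRUE,
                          use_tnm_overrides = FALSE) {
  mode <- match.arg(mode)
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_number(seed, "seed")
  if (mode == "equation_driven") {
    need <- c("d_fast", "d_slow", "p1")
    if (!all(need %in% names(target_r2)) ||
        any(target_r2[need] <= 0) || any(target_r2[need] > 1)) {
      pfg_abort("`target_r2` must name d_fast, d_slow, p1 with values in (0, 1]",
                "pfg_config_error")
    }
  }
  structure(list(n_control = as.integer(n_control),
                 n_cancer = as.integer(n_cancer),
                 mode = mode, target_r2 = target_r2,
                 acquisition = acquisition, noise_sigma = noise_sigma,
                 seed = seed, make_curves = isTRUE(make_curves),
                 use_tnm_overrides = isTRUE(use_tnm_overrides)),
            class = "cohort_config")
}

# One truncated-normal draw matrix (n x variables) with the location
# calibrated so the truncated mean equals the published mean.
sample_truncnorm_block <- function(params, n) {
  vals <- lapply(params, function(q) {
    mu <- calibrate_truncnorm_mu(q[1], q[2], q[3], q[4])
    rtruncnorm(n, mu, q[2], q[3], q[4])
  })
  do.call(cbind, vals)
}

#' Sample histological compositions
#'
#' Draws the six constituent percentages from truncated normals whose
#' locations are calibrated so the truncated means equal the published group
#' means, then normalizes each specimen to a 100% section total by rescaling
#' the slack above the published minima (two-sidedly; skipped when the raw
#' sum is already within 100 +/- 0.5) and clipping at the published maxima.
#' Every draw therefore respects the published ranges, and group means stay
#' at the published values up to the small normalization shift. With all SDs
#' zero the published means are returned exactly.
#'
#' @param gp A [breast_group_params()] object with a `composition` field.
#' @param n Number of specimens to draw.
#' @param seed Optional seed.
#' @return A data.frame with columns `p`, `st`, `at`, `pce`, `pve`, `v`.
#' @export
sample_composition <- function(gp, n = 1, seed = NULL) {
  stopifnot(inherits(gp, "group_params"))
  if (is.null(gp$composition)) {
    pfg_abort(sprintf("group '%s' has no published composition statistics",
                      gp$group), "pfg_config_error")
  }
  for (q in gp$composition) {
    if (q[3] > q[4]) pfg_abort("infeasible composition bounds (min > max)",
                               "pfg_config_error")
  }
  x <- with_seed(seed, sample_truncnorm_block(gp$composition, n))
  mins <- vapply(gp$composition, `[`, numeric(1), 3)
  maxs <- vapply(gp$composition, `[`, numeric(1), 4)
  s <- rowSums(x)
  adjust <- abs(s - 100) > 0.5
  lam <- ifelse(adjust, (100 - sum(mins)) / (s - sum(mins)), 1)
  x <- sweep(sweep(x, 2, mins, "-") * lam, 2, mins, "+")
  x <- pmin(x, matrix(maxs, n, length(maxs), byrow = TRUE))
  out <- as.data.frame(x)
  names(out) <- names(gp$composition)
  out
}

#' Sample diffusion-compartment parameters
#'
#' In `group_parameter` mode, draws `d_fast` (1e-9 m^2/s), `d_slow`
#' (1e-11 m^2/s) and `p1` from mean-calibrated truncated normals of the
#' group's published statistics. In `equation_driven` mode, evaluates the
#' published composition regressions at each row of `composition` and adds
#' Gaussian residuals with the R^2-calibrated variance; `p1` is clipped to
#' (0, 1) and positivity plus the fast > slow ordering (in SI units) are
#' enforced by resampling the offending residuals (at most 100 attempts).
#'
#' @param gp A [breast_group_params()] object.
#' @param mode Sampling mode (see [cohort_config()]).
#' @param composition Data.frame of compositions (equation-driven mode).
#' @param target_r2 Target R^2 per response (equation-driven mode).
#' @param n Number of draws (group-parameter mode; equation-driven mode uses
#'   `nrow(composition)`).
#' @param seed Optional seed.
#' @return A data.frame with columns `d_fast_1e9`, `d_slow_1e11`, `p1`.
#' @export
sample_compartments <- function(gp, mode = c("group_parameter", "equation_driven"),
                                composition = NULL,
                                target_r2 = c(d_fast = 0.92, d_slow = 0.81,
                                              p1 = 0.93),
                                n = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "group_parameter") {
    stopifnot(inherits(gp, "group_params"))
    pars <- gp$diffusion[c("d_fast", "d_slow", "p1")]
    x <- with_seed(seed, sample_truncnorm_block(pars, n))
    out <- data.frame(d_fast_1e9 = x[, 1], d_slow_1e11 = x[, 2], p1 = x[, 3])
  } else {
    if (is.null(composition)) {
      pfg_abort("equation-driven mode needs a `composition` data.frame",
                "pfg_config_error")
    }
    models <- reference_predictors()
    comp <- as.matrix(composition[MORPH_PREDICTORS])
    pred <- list(d_fast = evaluate_model(models$d_fast, comp),
                 d_slow = evaluate_model(models$d_slow, comp),
                 p1 = evaluate_model(models$p1, comp))
    m <- nrow(comp)
    out <- with_seed(seed, {
      draws <- lapply(c(d_fast = "d_fast", d_slow = "d_slow", p1 = "p1"),
                      function(resp) {
        r2 <- target_r2[[resp]]
        sigma <- if (r2 >= 1) 0 else
          stats::sd(pred[[resp]]) * sqrt((1 - r2) / r2)
        pred[[resp]] + stats::rnorm(m, 0, sigma)
      })
      df <- data.frame(d_fast_1e9 = draws$d_fast,
                       d_slow_1e11 = draws$d_slow,
                       p1 = pmin(0.999, pmax(0.001, draws$p1)))
      # Enforce positivity and the SI-scale ordering by residual resampling.
      sig_f <- if (target_r2[["d_fast"]] >= 1) 0 else
        stats::sd(pred$d_fast) * sqrt((1 - target_r2[["d_fast"]]) / target_r2[["d_fast"]])
      sig_s <- if (target_r2[["d_slow"]] >= 1) 0 else
        stats::sd(pred$d_slow) * sqrt((1 - target_r2[["d_slow"]]) / target_r2[["d_slow"]])
      for (i in seq_len(m)) {
        attempts <- 0L
        while ((df$d_fast_1e9[i] <= 0 || df$d_slow_1e11[i] <= 0 ||
                df$d_fast_1e9[i] * 1e-9 <= df$d_slow_1e11[i] * 1e-11)) {
          attempts <- attempts + 1L
          if (attempts > 100L) {
            pfg_abort("equation-driven resampling failed 100 times (predicted diffusion coefficients non-physical)",
                      "pfg_config_error")
          }
          df$d_fast_1e9[i] <- pred$d_fast[i] + stats::rnorm(1, 0, sig_f)
          df$d_slow_1e11[i] <- pred$d_slow[i] + stats::rnorm(1, 0, sig_s)
        }
      }
      df
    })
  }
  out
}

#' Generate a synthetic specimen cohort
#'
#' Composes [sample_composition()], [sample_compartments()] and
#' [synthesize_curve()] into a full cohort. Each specimen consumes its own
#' seed stream derived from the configuration seed and the specimen index, so
#' the cohort is reproducible and individual specimens do not depend on group
#' ordering. Cancer specimens carry TNM sublabels split 6:5 (the published
#' design), affecting labels only unless `use_tnm_overrides` is set.
#'
#' @param config A [cohort_config()].
#' @return An object of class `pfg_cohort`: list with `specimens` (data.frame
#'   with identifiers, group labels, composition, true diffusion parameters in
#'   scaled units, and `adc_1e9` = population-weighted ADC), `curves` (named
#'   list of [decay_curve()], or `NULL`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_tot <- config$n_control + config$n_cancer
  if (n_tot < 1L) pfg_abort("empty cohort", "pfg_config_error")
  groups <- c(rep("control", config$n_control), rep("cancer", config$n_cancer))
  ids <- sprintf("S%03d", seq_len(n_tot))

  # TNM sublabels within the cancer group, in the published 6:5 proportion.
  n_t2n0 <- round(config$n_cancer * 6 / 11)
  tnm <- c(rep("none", config$n_control),
           rep("T2N0M0", n_t2n0), rep("T2N1M0", config$n_cancer - n_t2n0))

  gp <- list(control = breast_group_params("control"),
             cancer = breast_group_params("cancer"),
             T2N0M0 = breast_group_params("cancer_t2n0m0"),
             T2N1M0 = breast_group_params("cancer_t2n1m0"))

  # In equation-driven mode the published surfaces define the diffusion
  # parameters; compositions where those surfaces extrapolate to non-physical
  # values (negative diffusivity, spin population outside (0, 1)) lie outside
  # the surfaces' domain of validity and are redrawn.
  models <- if (config$mode == "equation_driven") reference_predictors() else NULL
  physical <- function(comp_row) {
    if (is.null(models)) return(TRUE)
    x <- as.matrix(comp_row[MORPH_PREDICTORS])
    evaluate_model(models$d_fast, x) > 0.05 &&
      evaluate_model(models$d_slow, x) > 0.05 &&
      evaluate_model(models$p1, x) > 0.001 &&
      evaluate_model(models$p1, x) < 0.999
  }
  comp <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    for (attempt in 0:100) {
      ci <- sample_composition(gp[[groups[i]]], n = 1,
                               seed = child_seed(config$seed, i, 1L) +
                                 attempt * 131071)
      if (physical(ci)) return(ci)
    }
    pfg_abort("could not draw a composition with physical predicted diffusion parameters in 100 attempts",
              "pfg_config_error")
  }))

  if (config$mode == "group_parameter") {
    cmp <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
      g <- if (config$use_tnm_overrides && groups[i] == "cancer") tnm[i]
           else groups[i]
      sample_compartments(gp[[g]], "group_parameter", n = 1,
                          seed = child_seed(config$seed, i, 2L))
    }))
  } else {
    # Residual SDs are calibrated once per cohort from the predicted spread.
    cmp <- sample_compartments(NULL, "equation_driven", composition = comp,
                               target_r2 = config$target_r2,
                               seed = child_seed(config$seed, 0L, 2L))
  }

  adc <- cmp$p1 * cmp$d_fast_1e9 + (1 - cmp$p1) * cmp$d_slow_1e11 * 1e-2
  specimens <- data.frame(specimen_id = ids, group = groups, tnm = tnm,
                          stroma_class = ifelse(comp$st >= 50, "ge50", "lt50"),
                          comp, cmp, adc_1e9 = adc)

  curves <- NULL
  if (config$make_curves) {
    curves <- lapply(seq_len(n_tot), function(i) {
      cs <- compartment_set(d_fast = cmp$d_fast_1e9[i] * 1e-9,
                            d_slow = cmp$d_slow_1e11[i] * 1e-11,
                            p1 = cmp$p1[i])
      synthesize_curve(config$acquisition, cs,
                       noise_sigma = config$noise_sigma,
                       seed = child_seed(config$seed, i, 3L))
    })
    names(curves) <- ids
  }

  structure(list(specimens = specimens, curves = curves, config = config),
            class = "pfg_cohort")
}

#' @export
print.pfg_cohort <- function(x, ...) {
  cat(sprintf("<pfg_cohort> %d specimens (%d control, %d cancer), mode '%s'%s\n",
              nrow(x$specimens), sum(x$specimens$group == "control"),
              sum(x$specimens$group == "cancer"), x$config$mode,
              if (is.null(x$curves)) "" else
                sprintf(", %d curves", length(x$curves))))
  invisible(x)
}
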