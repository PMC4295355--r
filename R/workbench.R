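# Pipeline orchestration and file-format validation: specimen-table schema
# checks, the simulate -> fit -> regress -> score -> summarize workflow, and
# a machine-readable run manifest.

SPECIMEN_COLUMNS <- c("specimen_id", "group", "tnm", "stroma_class",
                      "p", "st", "at", "pce", "pve", "v",
                      "d_fast_1e9", "d_slow_1e11", "p1", "adc_1e9")
SPECIMEN_NUMERIC <- c("p", "st", "at", "pce", "pve", "v",
                      "d_fast_1e9", "d_slow_1e11", "p1", "adc_1e9")

#' Write and read specimen tables
#'
#' Delimited text (CSV, period decimals, header row) with optional `#`
#' comment header lines carrying the run seed and parameters.
#'
#' @param specimens Specimen data.frame.
#' @param path File path.
#' @param header_lines Optional character vector written as `#` comments.
#' @return `write_specimen_table()` returns `path` invisibly;
#'   `read_specimen_table()` returns a data.frame.
#' @export
write_specimen_table <- function(specimens, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(specimens, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_specimen_table
#' @export
read_specimen_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

number_re <- "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"

#' Validate a specimen table
#'
#' Checks the header schema, numeric parsability (period decimal separator),
#' composition invariants (each constituent in `[0, 100]`, six-part sum at
#' most 100.5), unit-scale plausibility of the diffusion columns
#' (`d_fast_1e9` in `[0.1, 5]`, `d_slow_1e11` in `[0.1, 10]`, `p1` in
#' `[0, 1]`), and label validity. Returns a row-level error report rather
#' than failing on the first bad row; only a malformed header aborts.
#'
#' @param x Path to a delimited specimen table, or a data.frame.
#' @return A list with `ok` (logical), `errors` (data.frame with columns
#'   `row`, `column`, `rule`, `message`) and `data` (the parsed table, or
#'   `NULL` if unparsable).
#' @export
validate_specimen_table <- function(x) {
  errors <- data.frame(row = integer(0), column = character(0),
                       rule = character(0), message = character(0))
  add_error <- function(row, column, rule, message) {
    errors[nrow(errors) + 1L, ] <<- list(row, column, rule, message)
  }

  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) pfg_abort(sprintf("file not found: %s", x),
                                   "pfg_invalid_input")
    raw <- utils::read.csv(x, colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    raw <- x
  } else {
    pfg_abort("`x` must be a file path or a data.frame", "pfg_invalid_input")
  }

  miss <- setdiff(SPECIMEN_COLUMNS, names(raw))
  if (length(miss) > 0L) {
    pfg_abort(sprintf("specimen table header is missing columns: %s",
                      paste(miss, collapse = ", ")),
              "pfg_schema_error", missing_columns = miss)
  }

  df <- raw
  for (col in SPECIMEN_NUMERIC) {
    if (is.character(raw[[col]])) {
      cell <- trimws(raw[[col]])
      bad <- which(!grepl(number_re, cell) & cell != "NA" & cell != "")
      for (i in bad) {
        add_error(i, col, "numeric_parse",
                  sprintf("cell '%s' (row %d, column %s) is not a period-decimal number",
                          cell[i], i, col))
      }
      val <- suppressWarnings(as.numeric(cell))
      df[[col]] <- val
    }
  }
  if (any(errors$rule == "numeric_parse")) {
    return(list(ok = FALSE, errors = errors, data = NULL))
  }

  rules <- list(
    list(cols = c("p", "st", "at", "pce", "pve", "v"), lo = 0, hi = 100,
         rule = "composition_range"),
    list(cols = "d_fast_1e9", lo = 0.1, hi = 5, rule = "d_fast_scale"),
    list(cols = "d_slow_1e11", lo = 0.1, hi = 10, rule = "d_slow_scale"),
    list(cols = "p1", lo = 0, hi = 1, rule = "p1_range"),
    list(cols = "adc_1e9", lo = 0.01, hi = 10, rule = "adc_scale")
  )
  for (r in rules) {
    for (col in r$cols) {
      v <- df[[col]]
      bad <- which(is.finite(v) & (v < r$lo | v > r$hi))
      for (i in bad) {
        add_error(i, col, r$rule,
                  sprintf("%s = %g outside [%g, %g] (row %d)",
                          col, v[i], r$lo, r$hi, i))
      }
    }
  }
  sums <- rowSums(df[c("p", "st", "at", "pce", "pve", "v")])
  for (i in which(is.finite(sums) & sums > 100.5)) {
    add_error(i, "composition", "composition_sum",
              sprintf("constituents sum to %.2f > 100.5 (row %d)", sums[i], i))
  }
  bad_group <- which(!df$group %in% c("control", "cancer"))
  for (i in bad_group) {
    add_error(i, "group", "group_label",
              sprintf("group '%s' is not control/cancer (row %d)",
                      df$group[i], i))
  }
  expected_class <- ifelse(df$st >= 50, "ge50", "lt50")
  bad_cls <- which(is.finite(df$st) & df$stroma_class != expected_class)
  for (i in bad_cls) {
    add_error(i, "stroma_class", "stroma_class_consistency",
              sprintf("stroma_class '%s' inconsistent with st = %g (row %d)",
                      df$stroma_class[i], df$st[i], i))
  }

  list(ok = nrow(errors) == 0L, errors = errors, data = df)
}

#' Pipeline run configuration
#'
#' Bundles the stage toggles and module parameters of [run_pipeline()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Run seed, recorded in every output header.
#' @param cohort A [cohort_config()]; its seed is overridden by `seed`.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "fit", "regress", "score", "summarize")`.
#' @param tail_fraction,n_initial,refine Passed to [peel_off_fit()].
#' @param threshold Decision cutoff for scoring.
#' @param score_variants CanP variants applied in the score stage.
#' @param specimens_file Optional existing specimen table consumed instead of
#'   the simulate stage.
#' @param verbose Log stage progress and timing to the console.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("pfg_run_"),
                       seed = 1,
                       cohort = cohort_config(seed = seed),
                       stages = c("simulate", "fit", "regress", "score",
                                  "summarize"),
                       tail_fraction = 0.4, n_initial = 3, refine = TRUE,
                       threshold = 0.5,
                       score_variants = c("morphology", "diffusion2",
                                          "diffusion3"),
                       specimens_file = NULL,
                       verbose = FALSE) {
  stages <- match.arg(stages, c("simulate", "fit", "regress", "score",
                                "summarize"), several.ok = TRUE)
  cohort$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, cohort = cohort,
                 stages = stages, tail_fraction = tail_fraction,
                 n_initial = n_initial, refine = isTRUE(refine),
                 threshold = threshold, score_variants = score_variants,
                 specimens_file = specimens_file, verbose = isTRUE(verbose)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config
  flat$out_dir <- NULL  # the hash identifies parameters, not paths
  saveRDS(rapply(unclass(flat), as.character, how = "unlist"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end analysis pipeline
#'
#' Chains the enabled stages: `simulate` (synthetic cohort + curves), `fit`
#' (peel-off decomposition of every curve, mono fallback), `regress`
#' (pure-quadratic regressions of the fitted diffusion parameters on the
#' five histological predictors), `score` (published CanP models applied to
#' the fitted specimen table), and `summarize` (group summaries and the
#' correlation table). Stage dependencies are checked before anything runs;
#' outputs are written atomically (a failed stage leaves `.partial` files)
#' and every output starts with a `#` header carrying the seed and the
#' parameter hash. A JSON manifest records the seed, parameters, stage
#' timings and collected warnings.
#'
#' @param config A [run_config()].
#' @return A list with `manifest` (also written to `manifest.json`), `files`
#'   (named output paths), and the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  have_specimens <- "simulate" %in% stages || !is.null(config$specimens_file)
  if ("fit" %in% stages && !"simulate" %in% stages) {
    pfg_abort("stage 'fit' requires stage 'simulate' (it consumes the synthesized curves)",
              "pfg_dependency_error")
  }
  if ("score" %in% stages &&
      any(config$score_variants %in% c("diffusion2", "diffusion3")) &&
      !"fit" %in% stages && is.null(config$specimens_file)) {
    pfg_abort("diffusion-based scoring requires stage 'fit' or a fitted specimen table",
              "pfg_dependency_error")
  }
  if (any(c("regress", "summarize") %in% stages) && !have_specimens) {
    pfg_abort("stages 'regress'/'summarize' require stage 'simulate' or `specimens_file`",
              "pfg_dependency_error")
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  header <- c(sprintf("seed: %s", format(config$seed)),
              sprintf("param_hash: %s", hash),
              sprintf("pfgbreast: %s",
                      as.character(utils::packageVersion("pfgbreast"))))
  manifest <- list(seed = config$seed, param_hash = hash,
                   package_version = as.character(utils::packageVersion("pfgbreast")),
                   stages = stages,
                   parameters = list(
                     mode = config$cohort$mode,
                     n_control = config$cohort$n_control,
                     n_cancer = config$cohort$n_cancer,
                     noise_sigma = config$cohort$noise_sigma,
                     tail_fraction = config$tail_fraction,
                     n_initial = config$n_initial,
                     refine = config$refine,
                     threshold = config$threshold,
                     score_variants = config$score_variants),
                   warnings = character(0), timings_s = list())
  files <- list()
  results <- list()

  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  grab_warnings <- function(expr) {
    withCallingHandlers(expr, pfg_warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  out_path <- function(name) file.path(config$out_dir, name)
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- FALSE
    tryCatch({
      fun()
      ok <- TRUE
    }, error = function(e) {
      pfg_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "pfg_stage_failure", stage = name)
    }, finally = {
      if (!ok) {
        # keep partial outputs identifiable
        part <- list.files(config$out_dir, full.names = TRUE,
                           pattern = "\\.tmp$")
        file.rename(part, sub("\\.tmp$", ".partial", part))
      }
    })
    manifest$timings_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg("stage %-9s done in %.2f s", name,
            manifest$timings_s[[name]])
  }
  # Write via a .tmp file, renamed on success, so interrupted stages leave
  # .partial artifacts instead of truncated outputs.
  atomic_write <- function(writer, obj, name) {
    tmp <- out_path(paste0(name, ".tmp"))
    writer(obj, tmp, header_lines = header)
    final <- out_path(name)
    file.rename(tmp, final)
    files[[name]] <<- final
    final
  }

  run_stage("simulate", function() {
    cohort <- generate_cohort(config$cohort)
    results$cohort <<- cohort
    atomic_write(write_specimen_table, cohort$specimens, "specimens_true.csv")
    if (!is.null(cohort$curves)) {
      atomic_write(write_decay_curves, cohort$curves, "curves.csv")
    }
  })

  specimens <- NULL
  if ("simulate" %in% stages) {
    specimens <- results$cohort$specimens
  } else if (!is.null(config$specimens_file)) {
    chk <- validate_specimen_table(config$specimens_file)
    if (!chk$ok) {
      pfg_abort(sprintf("input specimen table failed validation (%d errors)",
                        nrow(chk$errors)), "pfg_schema_error",
                report = chk$errors)
    }
    specimens <- chk$data
  }

  run_stage("fit", function() {
    fits <- grab_warnings(
      fit_decay_curves(results$cohort$curves,
                       tail_fraction = config$tail_fraction,
                       refine = config$refine,
                       n_initial = config$n_initial))
    n_mono <- sum(fits$method == "mono")
    if (n_mono > 0L) {
      manifest$warnings <<- c(manifest$warnings,
        sprintf("%d curve(s) fell back to mono-exponential fits", n_mono))
    }
    fitted <- specimens
    idx <- match(fitted$specimen_id, fits$curve_id)
    for (col in c("d_fast_1e9", "d_slow_1e11", "p1", "adc_1e9")) {
      fitted[[col]] <- fits[[col]][idx]
    }
    fitted$fit_method <- fits$method[idx]
    fitted$residual_rms <- fits$residual_rms[idx]
    results$fitted <<- fitted
    atomic_write(write_specimen_table, fitted, "specimens_fitted.csv")
  })

  analysis_tab <- if (!is.null(results$fitted)) results$fitted else specimens

  run_stage("regress", function() {
    ok <- stats::complete.cases(analysis_tab[c(MORPH_PREDICTORS, "d_fast_1e9",
                                               "d_slow_1e11", "p1")])
    tab <- analysis_tab[ok, , drop = FALSE]
    models <- list(
      d_fast = fit_quadratic(tab[MORPH_PREDICTORS], tab$d_fast_1e9,
                             "pure_quadratic", response_name = "d_fast",
                             response_units = "1e-9 m^2/s"),
      d_slow = fit_quadratic(tab[MORPH_PREDICTORS], tab$d_slow_1e11,
                             "pure_quadratic", response_name = "d_slow",
                             response_units = "1e-11 m^2/s"),
      p1 = fit_quadratic(tab[MORPH_PREDICTORS], tab$p1, "pure_quadratic",
                         response_name = "p1"))
    results$regressions <<- models
    coef_tab <- do.call(rbind, lapply(names(models), function(nm) {
      m <- models[[nm]]
      data.frame(response = nm, term = names(m$coefficients),
                 estimate = unname(m$coefficients),
                 r_squared = m$r_squared, n = m$n)
    }))
    atomic_write(write_specimen_table, coef_tab, "regression_coefficients.csv")
  })

  run_stage("score", function() {
    models <- canp_reference_models(threshold = config$threshold)
    sc <- data.frame(specimen_id = analysis_tab$specimen_id,
                     group = analysis_tab$group)
    for (v in config$score_variants) {
      xin <- if (v == "morphology") analysis_tab[MORPH_PREDICTORS] else
        data.frame(d_fast = analysis_tab$d_fast_1e9,
                   d_slow = analysis_tab$d_slow_1e11,
                   p1 = analysis_tab$p1)
      res <- grab_warnings(canp_score(models[[v]], xin))
      sc[[paste0(v, "_prob")]] <- res$probability
      sc[[paste0(v, "_label")]] <- res$label
    }
    results$scores <<- sc
    atomic_write(write_specimen_table, sc, "scores.csv")
  })

  run_stage("summarize", function() {
    summ <- group_summary_table(analysis_tab)
    results$summary <<- summ
    atomic_write(write_specimen_table, summ, "summary.csv")
    corr <- grab_warnings(correlation_table(analysis_tab))
    results$correlations <<- corr
    atomic_write(write_specimen_table, corr, "correlations.csv")
  })

  manifest$files <- lapply(files, basename)
  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$manifest <- manifest_path
  c(list(manifest = manifest, files = files), results)
}
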