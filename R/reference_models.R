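# Published coefficient sets bundled as auditable plain text
# (inst/extdata/reference_coefficients.tsv) and exposed as quadratic_model
# objects.

MORPH_PREDICTORS <- c("p", "st", "at", "pce", "v")

read_reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.tsv",
                      package = "pfgbreast", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

reference_model <- function(tab, model_name, term_names, design_kind,
                            response_name, response_units) {
  rows <- tab[tab$model == model_name, ]
  d <- build_design(matrix(0, 1, length(term_names)), design_kind, term_names)
  cf <- stats::setNames(rows$value[match(colnames(d), rows$term)], colnames(d))
  if (anyNA(cf)) {
    pfg_abort(sprintf("reference coefficient file lacks terms for model '%s'",
                      model_name), "pfg_config_error")
  }
  quadratic_model(cf, term_names, design_kind,
                  reported_r_squared = rows$reported_r_squared[1],
                  response_name = response_name,
                  response_units = response_units)
}

#' Published diffusion-parameter predictors
#'
#' The three published pure-quadratic regressions of the diffusion parameters
#' on the five histological predictors (parenchyma, stroma, adipose tissue,
#' pericellular edema, vessels; raw percentages): the fast-phase coefficient
#' (response in 1e-9 m^2/s), the slow-phase coefficient (1e-11 m^2/s) and the
#' fast-phase spin population (dimensionless). Coefficients are transcribed
#' verbatim in `inst/extdata/reference_coefficients.tsv`, which also records
#' the transcription assumptions.
#'
#' @return Named list of three [quadratic_model()] objects:
#'   `d_fast`, `d_slow`, `p1`.
#' @export
reference_predictors <- function() {
  tab <- read_reference_coefficients()
  list(
    d_fast = reference_model(tab, "d_fast", MORPH_PREDICTORS, "pure_quadratic",
                             "d_fast", "1e-9 m^2/s"),
    d_slow = reference_model(tab, "d_slow", MORPH_PREDICTORS, "pure_quadratic",
                             "d_slow", "1e-11 m^2/s"),
    p1 = reference_model(tab, "p1", MORPH_PREDICTORS, "pure_quadratic",
                         "p1", "")
  )
}
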