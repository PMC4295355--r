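# Shared fixtures built in code.

# Published control-group compartment parameters (SI units).
control_compartments <- function() {
  compartment_set(d_fast = 1.25e-9, d_slow = 1.67e-11, p1 = 0.48)
}

# Group-mean predictor points on the regression scale.
control_means_diffusion <- function() c(d_fast = 1.25, d_slow = 1.67, p1 = 0.48)
cancer_means_diffusion <- function() c(d_fast = 0.97, d_slow = 0.86, p1 = 0.75)
cancer_means_composition <- function() c(p = 30.7, st = 39.9, at = 11.6,
                                         pce = 7.1, v = 3.1)

rel_err <- function(est, tru) abs(est - tru) / abs(tru)

# Independent polynomial oracle: explicit term-by-term second-order sum,
# written without build_design / evaluate_model.
poly_oracle <- function(coefs, terms, x) {
  total <- 0
  for (i in seq_along(terms)) {
    tm <- terms[i]
    val <- if (tm == "(Intercept)") {
      1
    } else if (grepl("\\^2$", tm)) {
      x[[sub("\\^2$", "", tm)]]^2
    } else if (grepl(":", tm, fixed = TRUE)) {
      pr <- strsplit(tm, ":", fixed = TRUE)[[1]]
      x[[pr[1]]] * x[[pr[2]]]
    } else {
      x[[tm]]
    }
    total <- total + coefs[i] * val
  }
  total
}

# Read the shipped coefficient file directly (bypassing reference_predictors).
raw_reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.tsv",
                      package = "pfgbreast")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Brute-force two-sided rank-sum p-value by direct enumeration over value
# subsets (independent of the package's implementation).
bruteforce_ranksum_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n_a)])
  ev <- n_a * (length(pooled) + 1) / 2
  combos <- combn(length(pooled), n_a)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(sums - ev) >= abs(obs - ev) - 1e-9)
}
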