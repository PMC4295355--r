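# Group-level statistics: mean/SD/range summaries with high-low ratios,
# exact Wilcoxon rank-sum comparisons, Spearman correlations, and the
# parameter-by-constituent correlation table.

#' Summary of one variable in one group
#'
#' Sample mean, sample SD (n - 1 denominator), range, and the ratio of the
#' highest to the lowest value (defined only when the minimum is positive;
#' for a single observation the ratio is 1 and the SD is `NA`).
#'
#' @param values Numeric vector, length >= 1.
#' @param variable,group Labels carried through to the output.
#' @return A one-row data.frame with columns `variable`, `group`, `n`,
#'   `mean`, `sd`, `min`, `max`, `ratio_high_low`.
#' @export
group_summary <- function(values, variable = "", group = "") {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    pfg_abort("`values` must be a non-empty numeric vector without NAs",
              "pfg_invalid_input")
  }
  n <- length(values)
  lo <- min(values)
  hi <- max(values)
  ratio <- if (lo > 0) hi / lo else NA_real_
  data.frame(variable = variable, group = group, n = n,
             mean = mean(values),
             sd = if (n > 1L) stats::sd(values) else NA_real_,
             min = lo, max = hi, ratio_high_low = ratio)
}

#' Group summary table for a specimen table
#'
#' Applies [group_summary()] to each variable within each group, mirroring
#' the mean +/- SD / range / high-low ratio layout of published cohort
#' tables.
#'
#' @param specimens Specimen data.frame with a `group` column.
#' @param variables Character vector of numeric columns to summarize.
#' @return A data.frame of stacked [group_summary()] rows.
#' @export
group_summary_table <- function(specimens,
                                variables = c("p", "st", "at", "pce", "pve", "v",
                                              "d_fast_1e9", "d_slow_1e11",
                                              "p1", "adc_1e9")) {
  variables <- intersect(variables, names(specimens))
  rows <- list()
  for (g in unique(specimens$group)) {
    sub <- specimens[specimens$group == g, , drop = FALSE]
    for (v in variables) {
      vals <- sub[[v]]
      vals <- vals[is.finite(vals)]
      if (length(vals) > 0L) {
        rows[[length(rows) + 1L]] <- group_summary(vals, variable = v, group = g)
      }
    }
  }
  do.call(rbind, rows)
}

# Rank-sum of sample `a` within the pooled mid-ranks, its null mean, and the
# tie-corrected null variance.
ranksum_stats <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  e_w <- n_a * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v_w <- n_a * n_b / 12 * ((n + 1) - tie_term)
  list(w = w, e_w = e_w, v_w = v_w, ranks = r, n_a = n_a, n_b = n_b)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided comparison of two samples by the rank-sum statistic of the first
#' sample, using mid-ranks for ties. The two-sided p-value is computed
#' exactly, by full enumeration of all assignments of the pooled ranks to the
#' first sample (valid under ties as well), whenever both samples have at
#' most `exact_max` observations or the pooled sample has at most
#' `exact_total`; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_max Largest per-group size for which the exact enumeration is
#'   used.
#' @param exact_total Pooled size up to which enumeration is always used.
#' @return A list with `statistic` (rank sum of `a`), `p_two_sided`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 10, exact_total = 12) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 1L || length(b) < 1L ||
      anyNA(a) || anyNA(b)) {
    pfg_abort("`a` and `b` must be non-empty numeric vectors without NAs",
              "pfg_invalid_input")
  }
  st <- ranksum_stats(a, b)
  if ((st$n_a <= exact_max && st$n_b <= exact_max) ||
      st$n_a + st$n_b <= exact_total) {
    splits <- utils::combn(st$n_a + st$n_b, st$n_a)
    sums <- colSums(matrix(st$ranks[splits], nrow = st$n_a))
    dev <- abs(st$w - st$e_w)
    p <- mean(abs(sums - st$e_w) >= dev - 1e-9)
    return(list(statistic = st$w, p_two_sided = p, method = "exact"))
  }
  dev <- abs(st$w - st$e_w)
  z <- max(0, dev - 0.5) / sqrt(st$v_w)
  list(statistic = st$w, p_two_sided = min(1, 2 * stats::pnorm(-z)),
       method = "normal_approx")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. The default p-value uses the
#' t-approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom; for small samples (n <= 12) a permutation p-value is available -
#' exhaustive over all n! permutations when n <= 7, otherwise from random
#' resamples.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_method `"t_approx"` or `"permutation"`.
#' @param n_perm Number of random resamples for the permutation p.
#' @param seed Optional seed for the random permutations.
#' @return A list with `rho`, `p_value`, `method`, `n`. When either variable
#'   has zero rank variance, `rho` is `NA` and the result carries
#'   `undefined = TRUE`.
#' @export
spearman_cor <- function(x, y, p_method = c("t_approx", "permutation"),
                         n_perm = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y)) {
    pfg_abort("`x` and `y` must be numeric vectors of equal length >= 3",
              "pfg_invalid_input")
  }
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    pfg_warn("zero rank variance: Spearman correlation undefined",
             "pfg_undefined_correlation")
    return(list(rho = NA_real_, p_value = NA_real_, method = p_method,
                n = n, undefined = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "t_approx") {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 12) {
      pfg_abort("permutation p-value supported for n <= 12 only",
                "pfg_invalid_input")
    }
    rho_perm <- function(perm) stats::cor(rx, ry[perm])
    if (n <= 7) {
      perms <- all_permutations(n)
      stats_perm <- vapply(perms, rho_perm, numeric(1))
      p <- mean(abs(stats_perm) >= abs(rho) - 1e-12)
    } else {
      stats_perm <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) rho_perm(sample.int(n)), numeric(1))
      })
      p <- (1 + sum(abs(stats_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    }
  }
  list(rho = rho, p_value = p, method = p_method, n = n, undefined = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) {
      out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  }
  out
}

#' Correlation table of diffusion parameters versus constituents
#'
#' Spearman correlations of each diffusion parameter with each histological
#' constituent, within subgroups: the control group, and the low/high stroma
#' classes (< 50% versus >= 50%, spanning control and cancer specimens);
#' optionally the entire cancer group. Subgroups with fewer than `min_n`
#' specimens are skipped with a warning.
#'
#' @param specimens Specimen data.frame with columns `group`, `st`, the
#'   constituents and the diffusion parameters.
#' @param params Diffusion-parameter columns.
#' @param constituents Histological-constituent columns.
#' @param subgroups Subset of `c("control", "stroma_lt50", "stroma_ge50",
#'   "all_cancer")`.
#' @param min_n Minimum subgroup size.
#' @param ... Passed to [spearman_cor()].
#' @return A data.frame with columns `diffusion_param`, `constituent`,
#'   `subgroup`, `n`, `rho`, `p_value`.
#' @export
correlation_table <- function(specimens,
                              params = c("adc_1e9", "d_fast_1e9", "p1",
                                         "d_slow_1e11"),
                              constituents = c("p", "st", "at", "pce", "pve", "v"),
                              subgroups = c("control", "stroma_lt50",
                                            "stroma_ge50"),
                              min_n = 3, ...) {
  subgroups <- match.arg(subgroups,
                         c("control", "stroma_lt50", "stroma_ge50",
                           "all_cancer"), several.ok = TRUE)
  pick <- list(
    control = specimens$group == "control",
    stroma_lt50 = specimens$st < 50,
    stroma_ge50 = specimens$st >= 50,
    all_cancer = specimens$group == "cancer"
  )
  rows <- list()
  for (sg in subgroups) {
    sub <- specimens[pick[[sg]], , drop = FALSE]
    if (nrow(sub) < min_n) {
      pfg_warn(sprintf("subgroup '%s' has %d < %d specimens; skipped",
                       sg, nrow(sub), min_n), "pfg_undersized_subgroup")
      next
    }
    for (pm in params) {
      for (ct in constituents) {
        res <- spearman_cor(sub[[ct]], sub[[pm]], ...)
        rows[[length(rows) + 1L]] <- data.frame(
          diffusion_param = pm, constituent = ct, subgroup = sg,
          n = res$n, rho = res$rho, p_value = res$p_value)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(diffusion_param = character(0),
                      constituent = character(0), subgroup = character(0),
                      n = integer(0), rho = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, rows)
}
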