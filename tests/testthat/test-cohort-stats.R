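test_that("group summaries report mean, SD, range and high/low ratio", {
  s <- group_summary(c(1, 2, 3, 4), variable = "x", group = "g")
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(c(s$min, s$max), c(1, 4))
  expect_equal(s$ratio_high_low, 4)

  s1 <- group_summary(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_equal(s1$ratio_high_low, 1)

  sc <- group_summary(rep(2.5, 4))
  expect_equal(sc$sd, 0)
  expect_equal(sc$ratio_high_low, 1)

  # ratio undefined when the minimum is not positive
  expect_true(is.na(group_summary(c(0, 1, 2))$ratio_high_low))
  expect_error(group_summary(numeric(0)), class = "pfg_invalid_input")
})

test_that("a merged sample never has a smaller range than its parts", {
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(2:10, 1))
    b <- rnorm(sample(2:10, 1))
    sm <- group_summary(c(a, b))
    expect_lte(sm$min, min(group_summary(a)$min, group_summary(b)$min))
    expect_gte(sm$max, max(group_summary(a)$max, group_summary(b)$max))
  }
})

test_that("exact Wilcoxon p-values match direct enumeration", {
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_identical(res$method, "exact")
  expect_equal(res$statistic, 6)
  expect_equal(res$p_two_sided, 0.1)

  # identical multisets: p = 1 by symmetry
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(1, 2, 2))$p_two_sided, 1)

  # tie-free data against the exact distribution in stats::wilcox.test
  set.seed(5)
  for (n_a in c(2, 3, 5, 6)) {
    for (n_b in c(2, 4, 6)) {
      a <- rnorm(n_a)
      b <- rnorm(n_b, 0.5)
      ours <- wilcoxon_rank_sum(a, b)
      ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12,
                   label = sprintf("p for n_a=%d n_b=%d", n_a, n_b))
    }
  }

  # tied data against the test-local brute-force enumeration
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:4, sample(3:6, 1), replace = TRUE)
    b <- sample(2:5, sample(3:6, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_two_sided,
                 bruteforce_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact Wilcoxon p at n = 10 per group", {
  set.seed(12)
  for (i in 1:30) {
    a <- rnorm(10)
    b <- rnorm(10, runif(1, 0, 1))
    exact <- wilcoxon_rank_sum(a, b, exact_max = 10)
    approx <- wilcoxon_rank_sum(a, b, exact_max = 0)
    expect_identical(exact$method, "exact")
    expect_identical(approx$method, "normal_approx")
    expect_lt(abs(exact$p_two_sided - approx$p_two_sided), 0.02)
  }
})

test_that("Spearman correlation handles monotone and degenerate inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)

  # invariance under strictly monotone transforms
  set.seed(2)
  u <- rnorm(15)
  v <- rnorm(15)
  expect_equal(spearman_cor(u, v)$rho, spearman_cor(exp(u), v)$rho)
  expect_equal(spearman_cor(u, v)$rho, spearman_cor(u, qnorm(pnorm(v)))$rho)

  res <- suppressWarnings(spearman_cor(rep(1, 5), 1:5))
  expect_true(res$undefined)
  expect_true(is.na(res$rho))

  expect_error(spearman_cor(1:2, 1:2), class = "pfg_invalid_input")
})

test_that("t-approximation p is close to the exhaustive permutation p at n = 6", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(6, 0.5 * x)
    pt_ <- spearman_cor(x, y, p_method = "t_approx")$p_value
    pp <- spearman_cor(x, y, p_method = "permutation")$p_value
    expect_lt(abs(pt_ - pp), 0.05)
  }
})

test_that("the Spearman estimate agrees with stats::cor.test", {
  set.seed(14)
  x <- rnorm(12)
  y <- rnorm(12, x)
  ref <- cor.test(x, y, method = "spearman")
  expect_equal(spearman_cor(x, y)$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("correlation tables cover parameters x constituents x subgroups", {
  co <- generate_cohort(cohort_config(n_control = 8, n_cancer = 12,
                                      seed = 4, make_curves = FALSE))
  sp <- co$specimens
  # make sure all three default subgroups are populated
  sp$st[1:4] <- 55
  sp$stroma_class <- ifelse(sp$st >= 50, "ge50", "lt50")
  tab <- correlation_table(sp)
  expect_equal(nrow(tab), 4 * 6 * 3)
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))

  # a noiseless monotone dependence gives rho = 1 in every subgroup
  sp$d_slow_1e11 <- 0.5 + 0.01 * sp$pce
  tab2 <- correlation_table(sp, params = "d_slow_1e11", constituents = "pce")
  expect_equal(tab2$rho, rep(1, 3), tolerance = 1e-12)

  # undersized subgroups are skipped with a warning
  sp2 <- sp[sp$st < 50, ]
  expect_warning(correlation_table(sp2), class = "pfg_undersized_subgroup")
})

test_that("equation-driven cohorts show the published sign structure", {
  co <- generate_cohort(cohort_config(n_control = 71, n_cancer = 129,
                                      mode = "equation_driven", seed = 10,
                                      make_curves = FALSE))
  sp <- co$specimens
  # refitting the generating design recovers the sign structure of the
  # published surfaces (the dominant linear terms)
  m <- fit_quadratic(sp[c("p", "st", "at", "pce", "v")], sp$d_fast_1e9,
                     "pure_quadratic")
  ref <- reference_predictors()$d_fast$coefficients
  big <- c("p", "st", "pce", "v")  # |coef| >= 0.06 on the percent scale
  expect_identical(sign(m$coefficients[big]), sign(ref[big]))
  # the published population surface rises with parenchyma
  expect_gt(spearman_cor(sp$p, sp$p1)$rho, 0)
})

test_that("group summary tables stack per-group summaries", {
  co <- generate_cohort(cohort_config(seed = 2, make_curves = FALSE))
  tab <- group_summary_table(co$specimens)
  expect_setequal(unique(tab$group), c("control", "cancer"))
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
  ctrl_n <- tab$n[tab$group == "control"]
  expect_true(all(ctrl_n == 6))
})
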