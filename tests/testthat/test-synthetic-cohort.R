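test_that("zero-variance composition sampling returns the published means exactly", {
  gp <- breast_group_params("cancer")
  gp$composition <- lapply(gp$composition, function(q) c(q[1], 0, q[3], q[4]))
  comp <- sample_composition(gp, n = 3, seed = 1)
  expect_equal(unname(unlist(comp[1, ])),
               c(30.7, 39.9, 11.6, 7.1, 7.5, 3.1))
  expect_equal(comp[1, ], comp[3, ], ignore_attr = TRUE)
})

test_that("sampled compositions respect the published ranges and means", {
  for (gname in c("control", "cancer")) {
    gp <- breast_group_params(gname)
    comp <- sample_composition(gp, n = 10000, seed = 20)
    for (nm in names(gp$composition)) {
      q <- gp$composition[[nm]]
      expect_gte(min(comp[[nm]]), q[3] - 1e-9)
      expect_lte(max(comp[[nm]]), q[4] + 1e-9)
    }
    expect_true(all(rowSums(comp) <= 100.5))
  }
  # published anchor: cancer parenchyma mean 30.7 within +/- 1.5
  comp_c <- sample_composition(breast_group_params("cancer"), 10000, seed = 21)
  expect_lt(abs(mean(comp_c$p) - 30.7), 1.5)
})

test_that("infeasible composition bounds raise a config error", {
  gp <- breast_group_params("control")
  gp$composition$p <- c(10, 5, 50, 40)  # min > max
  expect_error(sample_composition(gp, 1, seed = 1), class = "pfg_config_error")
})

test_that("group-parameter compartments draw from the published statistics", {
  gp <- breast_group_params("control")
  gp$diffusion <- lapply(gp$diffusion, function(q) c(q[1], 0, q[3], q[4]))
  cmp <- sample_compartments(gp, "group_parameter", n = 2, seed = 1)
  expect_equal(unname(unlist(cmp[1, ])), c(1.25, 1.67, 0.48))

  cmp2 <- sample_compartments(breast_group_params("control"),
                              "group_parameter", n = 5000, seed = 2)
  q <- breast_group_params("control")$diffusion
  expect_lt(abs(mean(cmp2$d_fast_1e9) - q$d_fast[1]), 0.02)
  expect_lt(abs(mean(cmp2$p1) - q$p1[1]), 0.02)
  expect_true(all(cmp2$d_fast_1e9 >= q$d_fast[3] & cmp2$d_fast_1e9 <= q$d_fast[4]))
})

test_that("equation-driven compartments sit on the published surfaces at R^2 = 1", {
  comp <- sample_composition(breast_group_params("control"), 50, seed = 3)
  cmp <- sample_compartments(NULL, "equation_driven", composition = comp,
                             target_r2 = c(d_fast = 1, d_slow = 1, p1 = 1),
                             seed = 4)
  rp <- reference_predictors()
  x <- as.matrix(comp[c("p", "st", "at", "pce", "v")])
  expect_equal(cmp$d_fast_1e9, unname(evaluate_model(rp$d_fast, x)),
               tolerance = 1e-12)
  expect_equal(cmp$d_slow_1e11, unname(evaluate_model(rp$d_slow, x)),
               tolerance = 1e-12)
  expect_true(all(cmp$p1 > 0 & cmp$p1 < 1))
})

test_that("equation-driven cohorts refit near the target R^2", {
  co <- generate_cohort(cohort_config(n_control = 71, n_cancer = 129,
                                      mode = "equation_driven", seed = 5,
                                      make_curves = FALSE))
  sp <- co$specimens
  m <- fit_quadratic(sp[c("p", "st", "at", "pce", "v")], sp$d_fast_1e9,
                     "pure_quadratic")
  expect_lt(abs(m$r_squared - 0.92), 0.05)
})

test_that("cohorts are reproducible and follow the study design", {
  cfg <- cohort_config(seed = 6)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$specimens, co2$specimens)
  expect_identical(co1$curves$S001$amplitudes, co2$curves$S001$amplitudes)

  sp <- co1$specimens
  expect_equal(nrow(sp), 17)
  expect_equal(sum(sp$group == "control"), 6)
  expect_equal(sum(sp$group == "cancer"), 11)
  expect_equal(sum(sp$tnm == "T2N0M0"), 6)
  expect_equal(sum(sp$tnm == "T2N1M0"), 5)
  expect_identical(sp$stroma_class, ifelse(sp$st >= 50, "ge50", "lt50"))
  expect_equal(length(co1$curves), 17)

  # the recorded ADC is the population-weighted mean in scaled units
  expect_equal(sp$adc_1e9,
               sp$p1 * sp$d_fast_1e9 + (1 - sp$p1) * sp$d_slow_1e11 / 100)
})

test_that("fitting the synthesized curves recovers the generating parameters", {
  # control-group round trip at the default noise level
  co <- generate_cohort(cohort_config(n_control = 30, n_cancer = 0, seed = 7))
  fits <- suppressWarnings(fit_decay_curves(co$curves))
  sp <- co$specimens
  expect_lt(median(rel_err(fits$d_fast_1e9, sp$d_fast_1e9)), 0.02)
  expect_lt(median(rel_err(fits$d_slow_1e11, sp$d_slow_1e11)), 0.02)
  expect_lt(median(rel_err(fits$p1, sp$p1)), 0.02)

  # mixed cohort: the cancer group's published slow coefficients extend down
  # to 0.40e-11 m^2/s, where max(b d_slow) ~ 0.15 and the slow phase is only
  # weakly encoded, so its recovery is correspondingly looser
  com <- generate_cohort(cohort_config(seed = 8))
  fm <- suppressWarnings(fit_decay_curves(com$curves))
  spm <- com$specimens
  expect_lt(median(rel_err(fm$d_fast_1e9, spm$d_fast_1e9)), 0.02)
  expect_lt(median(rel_err(fm$p1, spm$p1)), 0.02)
  expect_lt(median(rel_err(fm$d_slow_1e11, spm$d_slow_1e11), na.rm = TRUE), 0.06)
})

test_that("TNM overrides switch the cancer diffusion statistics", {
  cfg <- cohort_config(n_control = 0, n_cancer = 44, seed = 9,
                       make_curves = FALSE, use_tnm_overrides = TRUE)
  sp <- generate_cohort(cfg)$specimens
  q0 <- breast_group_params("cancer_t2n0m0")$diffusion$d_slow
  sub0 <- sp$d_slow_1e11[sp$tnm == "T2N0M0"]
  expect_true(all(sub0 >= q0[3] & sub0 <= q0[4]))
})
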