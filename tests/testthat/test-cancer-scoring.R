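test_that("scores agree with the independent term-by-term oracle", {
  models <- canp_reference_models()
  tab <- raw_reference_coefficients()
  ranges <- list(
    morphology = function(n) cbind(p = runif(n, 0, 60), st = runif(n, 25, 65),
                                   at = runif(n, 0, 50), pce = runif(n, 0, 16),
                                   v = runif(n, 0, 12)),
    diffusion2 = function(n) cbind(d_fast = runif(n, 0.5, 1.5),
                                   d_slow = runif(n, 0.4, 4)),
    diffusion3 = function(n) cbind(d_fast = runif(n, 0.5, 1.5),
                                   d_slow = runif(n, 0.4, 4),
                                   p1 = runif(n, 0.2, 1)))
  set.seed(17)
  for (v in names(models)) {
    x <- ranges[[v]](100)
    res <- canp_score(models[[v]], x)
    rows <- tab[tab$model == paste0("canp_", v), ]
    oracle <- vapply(seq_len(nrow(x)), function(i) {
      poly_oracle(rows$value, rows$term, as.list(as.data.frame(x)[i, ]))
    }, numeric(1))
    expect_equal(res$raw_score, oracle, tolerance = 1e-10)
    expect_true(all(res$probability >= 0 & res$probability <= 1))
  }
})

test_that("probabilities are the clamped raw scores", {
  m <- canp_reference_models()$diffusion2
  res <- suppressWarnings(canp_score(m, rbind(c(0.1, 0.4), c(1.2, 0.5))))
  expect_true(res$raw_score[1] < 0)
  expect_identical(res$probability[1], 0)
  expect_identical(res$label[1], "nonmalignant")
  expect_true(res$raw_score[2] > 1)
  expect_identical(res$probability[2], 1)
  expect_identical(res$label[2], "malignant")
})

test_that("published group-mean points classify correctly at threshold 0.5", {
  models <- canp_reference_models()
  ctrl <- control_means_diffusion()
  canc <- cancer_means_diffusion()

  r2c <- canp_score(models$diffusion2, ctrl[c("d_fast", "d_slow")])
  expect_equal(r2c$raw_score, 0.3215, tolerance = 1e-10)
  expect_identical(r2c$label, "nonmalignant")

  r3c <- canp_score(models$diffusion3, ctrl)
  expect_equal(r3c$raw_score, 0.053664, tolerance = 1e-10)
  expect_identical(r3c$label, "nonmalignant")

  r2k <- canp_score(models$diffusion2, canc[c("d_fast", "d_slow")])
  expect_identical(r2k$label, "malignant")
  expect_identical(r2k$probability, 1)

  r3k <- canp_score(models$diffusion3, canc)
  expect_equal(r3k$raw_score, 1.476128, tolerance = 1e-10)
  expect_identical(r3k$label, "malignant")
  expect_identical(r3k$probability, 1)
})

test_that("SI-scale diffusion inputs trigger a suspicious-units warning", {
  m <- canp_reference_models()$diffusion2
  expect_warning(canp_score(m, c(1.25e-9, 1.67e-11)),
                 class = "pfg_suspicious_units")
  expect_silent(canp_score(m, c(1.25, 1.67)))
})

test_that("refit separates a cohort with a wide group gap", {
  set.seed(23)
  n <- 20
  x <- rbind(cbind(d_fast = rnorm(n, 2.0, 0.05), d_slow = rnorm(n, 3, 0.1)),
             cbind(d_fast = rnorm(n, 0.5, 0.05), d_slow = rnorm(n, 1, 0.1)))
  labels <- rep(c(0, 1), each = n)
  m <- fit_canp(x, labels, "diffusion2")
  res <- canp_score(m, x)
  expect_identical(res$label,
                   rep(c("nonmalignant", "malignant"), each = n))
  expect_gt(m$model$r_squared, 0.9)
})

test_that("single-class labels are rejected", {
  x <- cbind(d_fast = runif(20, 0.5, 1.5), d_slow = runif(20, 0.4, 4))
  expect_error(fit_canp(x, rep(1, 20), "diffusion2"),
               class = "pfg_degenerate_labels")
})

test_that("refitting data simulated from the published three-parameter model recovers it", {
  set.seed(29)
  n <- 300
  x <- cbind(d_fast = runif(n, 0.5, 1.5), d_slow = runif(n, 0.4, 4),
             p1 = runif(n, 0.2, 1))
  truth <- canp_reference_models()$diffusion3
  y_surface <- canp_score(truth, x)$raw_score
  sigma <- 1e-4
  y <- y_surface + rnorm(n, 0, sigma)
  qm <- fit_quadratic(x, y, "full_second_order",
                      term_names = c("d_fast", "d_slow", "p1"))
  expect_lt(max(abs(qm$coefficients - truth$model$coefficients)), 100 * sigma)
})

test_that("probability surfaces show the saturation plateaus", {
  m <- canp_reference_models()$diffusion2
  surf <- surface_grid(m, list(name = "d_fast", range = c(0.5, 1.5)),
                       list(name = "d_slow", range = c(0.4, 4)), n_grid = 30)
  expect_true(all(surf$prob >= 0 & surf$prob <= 1))
  expect_true(any(surf$prob == 0))
  expect_true(any(surf$prob == 1))

  # axis order only transposes the grid
  surf_t <- surface_grid(m, list(name = "d_slow", range = c(0.4, 4)),
                         list(name = "d_fast", range = c(0.5, 1.5)), n_grid = 30)
  expect_equal(surf$prob, t(surf_t$prob))

  expect_error(surface_grid(m, list(name = "d_fast", range = c(0, 1)),
                            list(name = "d_fast", range = c(0, 1))),
               class = "pfg_invalid_input")

  # three-predictor variant needs the remaining predictor fixed
  m3 <- canp_reference_models()$diffusion3
  expect_error(surface_grid(m3, list(name = "d_fast", range = c(0.5, 1.5)),
                            list(name = "d_slow", range = c(0.4, 4))),
               class = "pfg_invalid_input")
  surf3 <- surface_grid(m3, list(name = "d_fast", range = c(0.5, 1.5)),
                        list(name = "d_slow", range = c(0.4, 4)),
                        fixed = c(p1 = 0.65), n_grid = 10)
  expect_true(all(dim(surf3$prob) == c(10, 10)))

  # matrix-format export round trip
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_surface(surf3, path, header_lines = "seed: 1")
  back <- read.csv(path, comment.char = "#")
  expect_equal(nrow(back), 10)
  expect_equal(unname(as.matrix(back[, -1])), unname(surf3$prob),
               tolerance = 1e-6)
})
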