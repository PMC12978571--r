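test_that("power-law fit recovers exact generative parameters", {
  x <- rep(c(3, 3.5, 4, 4.5, 5), 4)
  f1 <- fit_power_law(x, x)
  expect_equal(f1$alpha, 1, tolerance = 1e-7)
  expect_equal(f1$beta, 1, tolerance = 1e-7)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  y <- 1.5 * x^0.5
  f2 <- fit_power_law(x, y)
  expect_equal(f2$alpha, 1.5, tolerance = 1e-6)
  expect_equal(f2$beta, 0.5, tolerance = 1e-6)
  # dense grid-search oracle agrees at its own resolution
  g <- grid_search_power(x, y)
  expect_equal(unname(g["alpha"]), 1.5, tolerance = 0.005)
  expect_equal(unname(g["beta"]), 0.5, tolerance = 0.005)
  expect_error(fit_power_law(x[1:5], y[1:5]), "at least 10")
})

test_that("optimizer SSE never exceeds the grid-search oracle", {
  set.seed(12)
  for (r in 1:5) {
    x <- rep(c(3, 3.5, 4, 4.5, 5), 6)
    y <- runif(1, 0.8, 2) * x^runif(1, 0.3, 1.2) * exp(rnorm(30, 0, 0.15))
    f <- fit_power_law(x, y)
    g <- grid_search_power(x, y)
    expect_lte(f$sse, unname(g["sse"]) + 1e-8)
  }
})

test_that("power-law fit agrees with independent nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(7)
  x <- rep(c(3, 3.5, 4, 4.5, 5), 8)
  y <- 1.4 * x^0.6 * exp(rnorm(40, 0, 0.1))
  f <- fit_power_law(x, y)
  nf <- minpack.lm::nlsLM(y ~ a * x^b, start = list(a = 1, b = 1))
  expect_equal(f$alpha, coef(nf)[["a"]], tolerance = 1e-5)
  expect_equal(f$beta, coef(nf)[["b"]], tolerance = 1e-5)
})

test_that("power-law fit is scale-equivariant", {
  set.seed(3)
  x <- rep(c(3, 3.5, 4, 4.5, 5), 4)
  y <- 1.2 * x^0.7 * exp(rnorm(20, 0, 0.1))
  f1 <- fit_power_law(x, y)
  f2 <- fit_power_law(x, 3 * y)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-7)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-7)
})

test_that("linear fit matches the normal-equations oracle", {
  f <- fit_linear(c(1, 2, 3, 4), 2 + c(1, 2, 3, 4))
  expect_equal(f$alpha, 2, tolerance = 1e-12)
  expect_equal(f$beta, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(fit_linear(c(1, 2, 3), c(5, 5, 5))$beta, 0)
  set.seed(5)
  x <- runif(20, 3, 5); y <- 1 + 0.5 * x + rnorm(20, 0, 0.2)
  f2 <- fit_linear(x, y)
  X <- cbind(1, x)
  ab <- solve(t(X) %*% X, t(X) %*% y)   # brute-force normal equations
  expect_equal(c(f2$alpha, f2$beta), as.numeric(ab), tolerance = 1e-10)
  expect_error(fit_linear(rep(4, 5), 1:5), "degenerate")
})

test_that("model comparison uses a shared criterion and sensible tie-breaks", {
  x <- rep(c(3, 3.5, 4, 4.5, 5), 4)
  # noiseless linear data with nonzero intercept: linear wins, power SSE > 0
  y <- 2 + x
  pw <- fit_power_law(x, y)
  ln <- fit_linear(x, y)
  expect_gt(pw$sse, 0)
  expect_equal(ln$sse, 0, tolerance = 1e-20)
  expect_equal(compare_models(pw, ln)$winner, "linear")
  # power-law generator with noise: power wins in the majority (the margin
  # shrinks with noise, since the curve is near-linear over 3-5 s)
  set.seed(9)
  x160 <- rep(c(3, 3.5, 4, 4.5, 5), 32)
  wins <- vapply(1:100, function(r) {
    yy <- 1.5 * x160^0.5 * exp(rnorm(160, 0, 0.05))
    compare_models(fit_power_law(x160, yy), fit_linear(x160, yy))$winner
  }, "")
  expect_gt(mean(wins == "power"), 0.5)
})

test_that("per-subject fits and the mixed model recover injected effects", {
  fits <- expand.grid(subject_id = sprintf("s%02d", 1:30),
                      is_threat = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  fits$arm <- rep(c("LT", "PLC", "AVP"), each = 10)[
    as.integer(sub("s", "", fits$subject_id))]
  fits$sex <- rep(c("M", "F"), 30)[as.integer(sub("s", "", fits$subject_id))]
  fits$beta <- 0.55 - 0.15 * (fits$arm == "LT") - 0.09 * fits$is_threat
  fits$alpha <- 1.5 + 0.3 * (fits$arm == "AVP")
  lb <- lme_on_parameters(fits, "beta")
  co <- lb$coefficients
  expect_equal(co$estimate[co$term == "armLT"], -0.15, tolerance = 1e-6)
  la <- lme_on_parameters(fits, "alpha")
  expect_equal(la$coefficients$estimate[la$coefficients$term == "armAVP"],
               0.3, tolerance = 1e-6)
})

test_that("injected LT coefficient is covered by its 95% CI in most replicates", {
  set.seed(31)
  cover <- vapply(1:40, function(r) {
    fits <- expand.grid(subject_id = sprintf("s%02d", 1:24),
                        is_threat = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
    fits$arm <- rep(c("LT", "PLC", "AVP"), each = 8)[
      as.integer(sub("s", "", fits$subject_id))]
    fits$sex <- "M"
    subj_re <- rnorm(24, 0, 0.05)
    fits$beta <- 0.55 - 0.15 * (fits$arm == "LT") +
      subj_re[as.integer(sub("s", "", fits$subject_id))] +
      rnorm(nrow(fits), 0, 0.05)
    fits$alpha <- 1.5
    co <- lme_on_parameters(fits, "beta")$coefficients
    i <- co$term == "armLT"
    co$ci_low[i] <= -0.15 && -0.15 <= co$ci_high[i]
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("fit_by_subject splits by threat condition and drops small cells", {
  cfg <- sim_config(n_subjects_per_arm = 2, repetitions = 2, seed = 13)
  b <- filter_jttc_outliers(generate_behavior(generate_design(cfg), cfg))
  f <- fit_by_subject(b)
  expect_equal(nrow(f), 6 * 2)  # 6 subjects x 2 conditions
  expect_true(all(f$n_trials == 40))
  expect_true(all(f$alpha > 0))
})
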