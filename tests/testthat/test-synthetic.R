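test_that("config invariants hold: stochastic matrices, orthonormal basis, 40 cells", {
  cfg <- small_config()
  for (P in cfg$transition_matrices) {
    expect_true(all(P >= 0))
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  }
  w <- trapezoid_weights(cfg$u_grid)
  G <- t(cfg$eigenfunctions) %*% (cfg$eigenfunctions * w)
  expect_lt(max(abs(G - diag(3))), 1e-6)
  expect_equal(length(cfg$attc_levels) * length(cfg$categories) *
                 length(cfg$initial_size_fracs), 40)
  expect_error(sim_config(repetitions = 0), "positive integer")
  expect_error(sim_config(transition_matrices = list(
    LT = matrix(1, 8, 8), PLC = diag(8), AVP = diag(8))), "sum to 1")
})

test_that("design is a balanced factorial with seeded, reproducible order", {
  cfg <- small_config(seed = 11)
  d <- generate_design(cfg)
  one <- d[d$subject_id == d$subject_id[1], ]
  cells <- table(paste(one$attc, one$category, one$initial_frac))
  expect_length(cells, 40)
  expect_true(all(cells == cfg$repetitions))
  expect_equal(nrow(one), 40)
  cfg4 <- sim_config(n_subjects_per_arm = 1, seed = 3)
  expect_equal(nrow(generate_design(cfg4)) / 3, 160)
  d2 <- generate_design(small_config(seed = 11))
  expect_identical(d, d2)
  d3 <- generate_design(small_config(seed = 12))
  expect_false(identical(d$attc, d3$attc))
})

test_that("behavioral responses follow the configured power law", {
  cfg <- small_config(alpha0 = 1, beta0 = 1, noise_sd_log_jttc = 0,
                      alpha_arm = c(LT = 0, PLC = 0, AVP = 0),
                      beta_arm = c(LT = 0, PLC = 0, AVP = 0),
                      alpha_female = 0, beta_female = 0,
                      alpha_threat = 0, beta_threat = 0)
  b <- generate_behavior(generate_design(cfg), cfg)
  expect_equal(b$jttc, b$attc)

  cfg2 <- small_config(alpha0 = 1.5, beta0 = 0.5, noise_sd_log_jttc = 0,
                       alpha_arm = c(LT = 0, PLC = 0, AVP = 0),
                       beta_arm = c(LT = 0, PLC = 0, AVP = 0),
                       alpha_female = 0, beta_female = 0,
                       alpha_threat = 0, beta_threat = 0)
  b2 <- generate_behavior(generate_design(cfg2), cfg2)
  expect_equal(b2$jttc[b2$attc == 4][1], 3.0)  # 1.5 * 4^0.5
  expect_true(all(b2$jttc > 0))
  expect_error(generate_behavior(
    generate_design(cfg2),
    small_config(beta0 = 0.1, beta_arm = c(LT = -0.2, PLC = 0, AVP = 0))),
    "beta_eff")
})

test_that("an injected LT shift on beta shows up in the fitted parameters", {
  cfg <- sim_config(n_subjects_per_arm = 5, repetitions = 2,
                    noise_sd_log_jttc = 0.1, seed = 21)
  b <- generate_behavior(generate_design(cfg), cfg)
  fit_arm <- function(a) {
    d <- b[b$arm == a, ]
    mean(vapply(split(d, d$subject_id),
                function(s) fit_power_law(s$attc, s$jttc)$beta, 0))
  }
  expect_lt(fit_arm("LT"), fit_arm("PLC"))
})

test_that("pupil traces reduce to the deterministic reconstruction when noise is off", {
  cfg <- small_config(score_sds = c(0, 0, 0), ar1_innov_sd = 0,
                      noise_sd_log_jttc = 0,
                      score_arm = list(LT = c(0, 0, 0), PLC = c(0, 0, 0),
                                       AVP = c(0, 0, 0)),
                      score_threat = c(0, 0, 0))
  b <- generate_behavior(generate_design(cfg), cfg)
  p <- generate_pupil(b, cfg)
  # same condition + same duration => identical traces
  plc <- b[b$arm == "PLC" & b$attc == 4 & !b$is_threat, ]
  t1 <- p[p$subject_id == plc$subject_id[1] & p$trial == plc$trial[1], ]
  t2 <- p[p$subject_id == plc$subject_id[2] & p$trial == plc$trial[2], ]
  expect_equal(t1$d, t2$d, tolerance = 1e-12)
  # trace minus tonic minus mean function equals 0 (all scores zero)
  kp <- b$keypress_ms[1]
  tr <- p[p$subject_id == b$subject_id[1] & p$trial == b$trial[1], ]
  post <- tr$t >= 300
  u <- warp_time(tr$t[post], kp)
  mu <- approx(cfg$u_grid, cfg$mean_fn, xout = u, rule = 2)$y
  expect_lt(max(abs(tr$d[post] - cfg$tonic_mm[[b$arm[1]]] - mu)), 1e-9)
})

test_that("a fixed score vector adds exactly its weighted eigenfunction", {
  cfg <- small_config(score_sds = c(0, 0, 0), ar1_innov_sd = 0,
                      noise_sd_log_jttc = 0,
                      alpha_arm = c(LT = 0, PLC = 0, AVP = 0),
                      beta_arm = c(LT = 0, PLC = 0, AVP = 0),
                      alpha_female = 0, beta_female = 0,
                      alpha_threat = 0, beta_threat = 0,
                      tonic_mm = c(LT = 3.5, PLC = 3.5, AVP = 3.5),
                      score_arm = list(LT = c(2, 0, 0), PLC = c(0, 0, 0),
                                       AVP = c(0, 0, 0)),
                      score_threat = c(0, 0, 0))
  b <- generate_behavior(generate_design(cfg), cfg)
  p <- generate_pupil(b, cfg)
  lt <- b[b$arm == "LT" & !b$is_threat, ][1, ]
  plc <- b[b$arm == "PLC" & b$attc == lt$attc & !b$is_threat, ][1, ]
  tr_lt <- p[p$subject_id == lt$subject_id & p$trial == lt$trial, ]
  tr_plc <- p[p$subject_id == plc$subject_id & p$trial == plc$trial, ]
  post <- tr_lt$t >= 300
  u <- warp_time(tr_lt$t[post], lt$keypress_ms)
  phi1 <- approx(cfg$u_grid, cfg$eigenfunctions[, 1], xout = u, rule = 2)$y
  expect_lt(max(abs((tr_lt$d[post] - tr_plc$d[post]) - 2 * phi1)), 1e-9)
})

test_that("the arm tonic offset appears in mean baselines", {
  cfg <- sim_config(n_subjects_per_arm = 4, repetitions = 4, seed = 5,
                    blink_rate = 0, tonic_mm = c(LT = 3.5, PLC = 3.5,
                                                 AVP = 3.7))
  b <- generate_behavior(generate_design(cfg), cfg)
  b <- b[b$arm %in% c("PLC", "AVP"), ]
  p <- generate_pupil(b, cfg)
  base <- p[p$t < 300, ]
  arm_of <- b$arm[match(paste(base$subject_id, base$trial),
                        paste(b$subject_id, b$trial))]
  diff <- mean(base$d[arm_of == "AVP"]) - mean(base$d[arm_of == "PLC"])
  expect_equal(diff, 0.2, tolerance = 0.1)
})

test_that("blink gaps mark samples invalid at the configured rate", {
  cfg <- small_config(blink_rate = 2)
  b <- generate_behavior(generate_design(cfg), cfg)
  p <- generate_pupil(b, cfg)
  expect_gt(mean(!p$valid), 0)
  expect_true(all(p$d[!p$valid] == 0))
})

test_that("state sequences are seeded draws from the configured chains", {
  expect_equal(simulate_markov_chain(diag(8) * 1 + 0, 20, start = "1")[1:20],
               rep("1", 20))
  U <- matrix(1 / 8, 8, 8, dimnames = list(paste0("S", 1:8),
                                           paste0("S", 1:8)))
  set.seed(4)
  s <- simulate_markov_chain(U, 1e5)
  freq <- table(s) / 1e5
  expect_true(all(abs(freq - 0.125) < 0.01))

  cfg <- small_config(seed = 31)
  s1 <- generate_state_sequences(cfg)
  s2 <- generate_state_sequences(small_config(seed = 31))
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 6 * 40)
  expect_error(simulate_markov_chain(matrix(1, 2, 2), 5), "sum to 1")
})

test_that("noiseless generated behavior round-trips through the fitter", {
  cfg <- small_config(noise_sd_log_jttc = 0, seed = 8)
  b <- generate_behavior(generate_design(cfg), cfg)
  one <- b[b$subject_id == b$subject_id[1] & b$is_threat, ]
  f <- fit_power_law(one$attc, one$jttc)
  expect_equal(f$alpha, one$alpha_eff[1], tolerance = 1e-6)
  expect_equal(f$beta, one$beta_eff[1], tolerance = 1e-6)
})

test_that("transition matrices estimated from long chains match the truth", {
  P <- default_transition_matrices()$AVP
  seqs <- make_sequences(P, n_subjects = 5, len = 1e4, seed = 9)
  m <- estimate_transitions(seqs)
  expect_lt(max(abs(m$P - P)), 0.02)
})

test_that("config round-trips through JSON", {
  cfg <- small_config(seed = 17)
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg$transition_matrices, cfg2$transition_matrices)
  expect_equal(cfg$score_sds, cfg2$score_sds)
  expect_identical(cfg$tonic_mm, cfg2$tonic_mm)
  expect_identical(cfg$alpha_arm, cfg2$alpha_arm)
  expect_identical(generate_design(cfg), generate_design(cfg2))
  b <- generate_behavior(generate_design(cfg), cfg)
  # decimal text serialization can perturb the last ulp of a double
  expect_equal(generate_pupil(b[1:2, ], cfg),
               generate_pupil(b[1:2, ], cfg2), tolerance = 1e-12)
  unlink(path)
})
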