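states2 <- c("A", "B")

test_that("transition estimation pools within-subject pairs only", {
  m <- estimate_transitions(data.frame(subject_id = "s", profile =
                                         rep("E1", 4)))
  expect_equal(m$P["E1", "E1"], 1)
  expect_equal(length(m$unobserved), 7)
  alt <- data.frame(subject_id = "s", profile = c("A", "B", "A", "B", "A"))
  m2 <- estimate_transitions(alt, states = states2)
  expect_equal(m2$P["A", "B"], 1)
  expect_equal(m2$P["B", "A"], 1)
  # no pair spans two subjects
  two <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                    profile = c("A", "A", "B", "B"))
  m3 <- estimate_transitions(two, states = states2)
  expect_equal(unname(m3$counts["A", "B"]), 0)
  expect_equal(m3$n_transitions, 2)
})

test_that("stationary distributions solve pi P = pi", {
  U <- matrix(1 / 8, 8, 8)
  expect_equal(unname(stationary_distribution(U)), rep(1 / 8, 8))
  P2 <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  pi2 <- stationary_distribution(P2)
  expect_equal(unname(pi2), c(5 / 6, 1 / 6), tolerance = 1e-12)
  expect_lt(max(abs(pi2 %*% P2 - pi2)), 1e-9)
  expect_error(stationary_distribution(diag(2)), "non-unique")
})

test_that("stationary distribution matches long-run occupancy", {
  P <- default_transition_matrices()$PLC
  pi_th <- stationary_distribution(P)
  set.seed(11)
  s <- simulate_markov_chain(P, 1e5)
  occ <- table(factor(s, levels = rownames(P))) / 1e5
  expect_lt(sum(abs(occ - pi_th)) / 2, 0.02)  # total variation
})

test_that("occupancy contrast reproduces hand-computed chi-squared and residuals", {
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  oc <- occupancy_contrast(tab)
  expect_equal(oc$chisq, 20)
  expect_equal(oc$df, 1)
  expect_equal(oc$residuals_z[1, 1], 10 / sqrt(20 * 0.5 * 0.5),
               tolerance = 1e-9)
  expect_equal(oc$residuals_z[1, 1], 4.472136, tolerance = 1e-6)
  # a table equal to its expectation has zero residuals
  tab2 <- outer(c(40, 60), c(0.3, 0.3, 0.4))
  oc2 <- occupancy_contrast(tab2)
  expect_equal(oc2$chisq, 0, tolerance = 1e-12)
  expect_lt(max(abs(oc2$residuals_z)), 1e-9)
  # 3 groups x 8 states -> df = 14
  set.seed(12)
  tab3 <- matrix(rpois(24, 50), 3, 8)
  expect_equal(occupancy_contrast(tab3)$df, 14)
  expect_error(occupancy_contrast(matrix(c(0, 0, 3, 4), 2)), "empty margin")
})

test_that("block entropy hits its analytic extremes and bounds", {
  expect_equal(sequence_entropy(data.frame(subject_id = "s",
                                           profile = rep("E1", 60))), 0)
  alt <- data.frame(subject_id = "s", profile = rep(c("A", "B"), 200))
  expect_equal(sequence_entropy(alt, k = 3), 1)  # blocks ABA, BAB equiprobable
  set.seed(13)
  iid <- data.frame(subject_id = "s",
                    profile = sample(paste0("S", 1:8), 1e5, replace = TRUE))
  expect_equal(sequence_entropy(iid, k = 3), 9, tolerance = 0.05)
  # bounds and monotonicity from concentrated to uniform
  mk <- function(self) {
    P <- matrix((1 - self) / 8, 8, 8,
                dimnames = list(paste0("S", 1:8), paste0("S", 1:8)))
    diag(P) <- diag(P) + self
    P
  }
  hs <- vapply(c(0.8, 0.4, 0), function(s) {
    seqs <- make_sequences(mk(s), 5, 400, seed = 14)
    sequence_entropy(seqs, k = 3)
  }, 0)
  expect_true(all(diff(hs) > 0))
  expect_true(all(hs >= 0 & hs <= 9))
  expect_error(sequence_entropy(alt, k = 0), "block length")
})

test_that("subject bootstrap gives degenerate CIs for constant statistics and is seeded", {
  seqs <- make_sequences(default_transition_matrices()$LT, 6, 80, seed = 15)
  const <- function(d) 42
  bc <- bootstrap_cis(seqs, const, n_boot = 50, seed = 1)
  expect_equal(unname(bc$ci_low), 42)
  expect_equal(unname(bc$ci_high), 42)
  ent <- function(d) sequence_entropy(d, k = 3)
  b1 <- bootstrap_cis(seqs, ent, n_boot = 50, seed = 2)
  b2 <- bootstrap_cis(seqs, ent, n_boot = 50, seed = 2)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_lte(b1$ci_low, b1$ci_high)
})

test_that("group comparisons are anti-symmetric and null-calibrated", {
  sa <- make_sequences(default_transition_matrices()$PLC, 8, 100, seed = 16,
                       arm = "A")
  sb <- make_sequences(default_transition_matrices()$PLC, 8, 100, seed = 17,
                       arm = "B")
  self <- compare_groups(sa, sa, n_boot = 30, seed = 3)
  expect_true(all(self$diff == 0, na.rm = TRUE))
  ab <- compare_groups(sa, sb, n_boot = 60, seed = 3)
  ba <- compare_groups(sb, sa, n_boot = 60, seed = 3)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  # same chain in both groups: few significant cells
  expect_lt(mean(ab$significant, na.rm = TRUE), 0.2)
})

test_that("within-group transition flags find attractors and inflated pathways", {
  U <- matrix(1 / 8, 8, 8,
              dimnames = rep(list(paste0("S", 1:8)), 2))
  mu <- estimate_transitions(make_sequences(U, 10, 200, seed = 18),
                             states = paste0("S", 1:8))
  wu <- within_group_significant_transitions(mu)
  expect_length(wu$attractors, 0)
  expect_lt(mean(wu$significant, na.rm = TRUE), 0.1)
  # diagonal-dominant chain: every state is an attractor
  D <- matrix(0.4 / 7, 8, 8, dimnames = rep(list(paste0("S", 1:8)), 2))
  diag(D) <- 0.6
  md <- estimate_transitions(make_sequences(D, 10, 300, seed = 19),
                             states = paste0("S", 1:8))
  wd <- within_group_significant_transitions(md)
  expect_equal(sort(wd$attractors), paste0("S", 1:8))
  # E1-centric chain with heterogeneous rows: states 2-4 feed E1 heavily,
  # states 5-8 are uniform, so the feeder cells exceed the independence
  # expectation and get flagged
  sts <- c("E1", paste0("S", 2:8))
  E <- matrix(1 / 8, 8, 8, dimnames = list(sts, sts))
  E[2:4, ] <- 0.4 / 7
  E[2:4, 1] <- 0.6
  stopifnot(all(abs(rowSums(E) - 1) < 1e-12))
  me <- estimate_transitions(make_sequences(E, 10, 300, seed = 20),
                             states = sts)
  we <- within_group_significant_transitions(me)
  expect_gte(sum(we$significant[2:4, "E1"], na.rm = TRUE), 2)
  expect_true(all(c("from", "to", "p_transition", "significant",
                    "visible") %in% names(we$graph)))
})

test_that("entropy contrasts order groups by chain dispersion", {
  conc <- matrix(0.1 / 7, 8, 8, dimnames = rep(list(paste0("S", 1:8)), 2))
  diag(conc) <- 0.9
  unif <- matrix(1 / 8, 8, 8, dimnames = rep(list(paste0("S", 1:8)), 2))
  groups <- list(conc = make_sequences(conc, 6, 150, seed = 21),
                 unif = make_sequences(unif, 6, 150, seed = 22))
  ec <- entropy_contrast(groups, n_boot = 60, seed = 4)
  expect_equal(ec$ordering, c("unif", "conc"))
  expect_true(all(ec$entropy$ci_low <= ec$entropy$estimate &
                    ec$entropy$estimate <= ec$entropy$ci_high))
  d <- ec$contrasts
  expect_true(d$significant[1])
  # identical groups: difference CI straddles zero
  g2 <- list(a = groups$unif,
             b = make_sequences(unif, 6, 150, seed = 23))
  ec2 <- entropy_contrast(g2, n_boot = 60, seed = 5)
  expect_false(ec2$contrasts$significant[1])
})
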