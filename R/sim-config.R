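#' Simulation configuration for the looming-threat paradigm
#'
#' Builds the configuration object that drives the synthetic-data generator.
#' The defaults emulate a three-arm (Losartan, placebo, vasopressin)
#' randomized design with 37 subjects per arm, each completing 160 trials of a
#' full 5 (actual time-to-collision) x 4 (stimulus category) x 2 (initial
#' size) factorial across two blocks, with power-law behavioral responses,
#' pupil traces built from a mean function plus three orthonormal
#' eigenfunctions with condition-dependent scores, AR(1) measurement noise and
#' blink artifacts, and per-arm first-order Markov chains over the eight
#' behavioral-pupillary profiles (E1-E4, L1-L4).
#'
#' @param n_subjects_per_arm subjects per treatment arm.
#' @param arms treatment arm labels; the first matching "PLC" is the
#'   reference arm in downstream contrasts.
#' @param screen_width_px horizontal display resolution in pixels.
#' @param initial_size_fracs initial stimulus widths as fractions of the
#'   screen width.
#' @param attc_levels actual time-to-collision levels in seconds.
#' @param categories stimulus category labels.
#' @param threat_categories subset of \code{categories} flagged as threat.
#' @param n_blocks number of blocks the trials are split into.
#' @param repetitions repetitions of each factorial cell per subject
#'   (\code{5 * 4 * 2 * repetitions} trials per subject).
#' @param alpha0,beta0 baseline power-law parameters (placebo, male,
#'   non-threat cell): \code{jTTC = alpha * aTTC^beta}.
#' @param alpha_arm,beta_arm named additive shifts on alpha/beta per arm.
#' @param alpha_female,beta_female additive shift for female subjects.
#' @param alpha_threat,beta_threat additive shift for threat trials.
#' @param noise_sd_log_jttc SD of the multiplicative log-normal response
#'   noise (log scale).
#' @param prop_female proportion of female subjects per arm.
#' @param tonic_mm named per-arm tonic (baseline) pupil diameter in mm.
#' @param score_sds SDs of the three eigenfunction scores (mm).
#' @param score_arm,score_threat named lists/vectors of additive mean shifts
#'   on the 3-vector of scores.
#' @param ar1_coef,ar1_innov_sd AR(1) noise model for pupil samples.
#' @param blink_rate expected blink events per trial (Poisson).
#' @param blink_dur_ms blink duration range in ms.
#' @param sample_ms pupil sampling interval in ms.
#' @param transition_matrices optional named list of 8x8 row-stochastic
#'   matrices per arm; defaults to \code{\link{default_transition_matrices}}.
#' @param seed integer seed governing all randomness.
#'
#' @return An object of class \code{"sim_config"}.
#' @seealso [generate_design()], [generate_behavior()], [generate_pupil()],
#'   [generate_state_sequences()]
#' @export
sim_config <- function(n_subjects_per_arm = 37,
                       arms = c("LT", "PLC", "AVP"),
                       screen_width_px = 1280,
                       initial_size_fracs = c(0.20, 0.30),
                       attc_levels = c(3.0, 3.5, 4.0, 4.5, 5.0),
                       categories = c("snake", "spider", "butterfly", "rabbit"),
                       threat_categories = c("snake", "spider"),
                       n_blocks = 2,
                       repetitions = 4,
                       alpha0 = 1.5, beta0 = 0.55,
                       alpha_arm = c(LT = 0, PLC = 0, AVP = 0.3),
                       beta_arm = c(LT = -0.15, PLC = 0, AVP = 0),
                       alpha_female = 0, beta_female = -0.167,
                       alpha_threat = 0, beta_threat = -0.09,
                       noise_sd_log_jttc = 0.1,
                       prop_female = 0.5,
                       tonic_mm = c(LT = 3.5, PLC = 3.5, AVP = 3.7),
                       score_sds = sqrt(c(0.62, 0.18, 0.07)) * 0.5,
                       score_arm = list(LT = c(-0.1, 0, 0),
                                        PLC = c(0, 0, 0),
                                        AVP = c(0, 0.1, 0)),
                       score_threat = c(0, 0.05, 0.02),
                       ar1_coef = 0.95, ar1_innov_sd = 0.056,
                       blink_rate = 1, blink_dur_ms = c(100, 300),
                       sample_ms = 10,
                       transition_matrices = NULL,
                       seed = 1L) {
  if (repetitions < 1 || repetitions != round(repetitions))
    stop("`repetitions` must be a positive integer")
  if (!all(threat_categories %in% categories))
    stop("`threat_categories` must be a subset of `categories`")
  if (any(initial_size_fracs <= 0) || any(initial_size_fracs >= 1))
    stop("`initial_size_fracs` must lie in (0, 1)")
  if (any(attc_levels <= 0)) stop("`attc_levels` must be positive")
  if (noise_sd_log_jttc < 0) stop("`noise_sd_log_jttc` must be >= 0")
  if (length(score_sds) != 3 || any(score_sds < 0))
    stop("`score_sds` must be 3 non-negative values")
  arms <- as.character(arms)
  if (is.null(transition_matrices))
    transition_matrices <- default_transition_matrices(arms)
  for (a in arms) {
    P <- transition_matrices[[a]]
    if (is.null(P)) stop("no transition matrix for arm ", a)
    check_stochastic(P)
  }
  ef <- default_eigenfunctions()
  cfg <- list(
    n_subjects_per_arm = as.integer(n_subjects_per_arm), arms = arms,
    screen_width_px = screen_width_px,
    initial_size_fracs = initial_size_fracs, attc_levels = attc_levels,
    categories = categories, threat_categories = threat_categories,
    n_blocks = as.integer(n_blocks), repetitions = as.integer(repetitions),
    alpha0 = alpha0, beta0 = beta0,
    alpha_arm = alpha_arm, beta_arm = beta_arm,
    alpha_female = alpha_female, beta_female = beta_female,
    alpha_threat = alpha_threat, beta_threat = beta_threat,
    noise_sd_log_jttc = noise_sd_log_jttc, prop_female = prop_female,
    tonic_mm = tonic_mm,
    u_grid = ef$u, mean_fn = ef$mean, eigenfunctions = ef$phi,
    score_sds = score_sds, score_arm = score_arm, score_threat = score_threat,
    ar1_coef = ar1_coef, ar1_innov_sd = ar1_innov_sd,
    blink_rate = blink_rate, blink_dur_ms = blink_dur_ms,
    sample_ms = sample_ms,
    transition_matrices = transition_matrices,
    profile_states = c("E1", "E2", "E3", "E4", "L1", "L2", "L3", "L4"),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Looming-paradigm simulation config\n")
  cat(sprintf("  %d arms (%s) x %d subjects, %d trials/subject\n",
              length(x$arms), paste(x$arms, collapse = ", "),
              x$n_subjects_per_arm,
              length(x$attc_levels) * length(x$categories) *
                length(x$initial_size_fracs) * x$repetitions))
  cat(sprintf("  power law: alpha0 = %.3g, beta0 = %.3g, log-noise SD = %.3g\n",
              x$alpha0, x$beta0, x$noise_sd_log_jttc))
  cat(sprintf("  pupil: %d ms sampling, score SDs %s\n", x$sample_ms,
              paste(signif(x$score_sds, 3), collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# row-stochasticity within 1e-12, non-negative entries
check_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square")
  if (any(P < 0)) stop("transition matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (within 1e-12)")
  invisible(TRUE)
}

#' Default per-arm transition matrices over the eight profiles
#'
#' Each row mixes a self-transition weight, optional "pull" mass toward
#' attractor profiles, and a uniform remainder.  The placebo chain is
#' concentrated and E1-dominant (E1 self-transition 0.615, analytic trigram
#' entropy 7.22 bits); vasopressin has attractors at E3/L3 (plus a milder L2
#' pull; 8.01 bits); Losartan is closest to uniform (8.54 bits), so the
#' generating chains are ordered LT > AVP > PLC in sequence entropy.
#'
#' @param arms arm labels; names matching LT/PLC/AVP get the corresponding
#'   default, anything else gets the near-uniform chain.
#' @return named list of 8x8 row-stochastic matrices with profile dimnames.
#' @export
default_transition_matrices <- function(arms = c("LT", "PLC", "AVP")) {
  states <- c("E1", "E2", "E3", "E4", "L1", "L2", "L3", "L4")
  mk <- function(self, pulls = numeric(0)) {
    P <- matrix((1 - self - sum(pulls)) / 8, 8, 8,
                dimnames = list(states, states))
    diag(P) <- diag(P) + self
    for (j in seq_along(pulls))
      P[, names(pulls)[j]] <- P[, names(pulls)[j]] + pulls[j]
    P
  }
  defaults <- list(
    PLC = mk(0.38, c(E1 = 0.18)),
    AVP = mk(0.34, c(E3 = 0.06, L3 = 0.06, L2 = 0.04)),
    LT  = mk(0.25))
  out <- lapply(arms, function(a)
    if (a %in% names(defaults)) defaults[[a]] else mk(0.25))
  names(out) <- arms
  out
}

#' Default mean function and orthonormal eigenfunctions on [0, 1]
#'
#' Templates follow the qualitative component shapes seen in looming
#' pupillometry: an early steep rise followed by a plateau (sustained
#' vigilance), an initial inhibition with later activation (proactive
#' engagement), and an early peak / mid trough / late recovery (cognitive
#' shift).  Raw templates are Gram-Schmidt orthonormalized under trapezoid
#' quadrature on a 201-point grid, so they integrate exactly as an
#' orthonormal system for the generator and round-trip tests.
#'
#' @param n_grid grid resolution on [0, 1].
#' @return list with \code{u} (grid), \code{mean} (mean function values) and
#'   \code{phi} (n_grid x 3 orthonormal basis).
#' @export
default_eigenfunctions <- function(n_grid = 201) {
  u <- seq(0, 1, length.out = n_grid)
  raw <- cbind(
    1 / (1 + exp(-12 * (u - 0.2))),   # early steep rise -> plateau
    tanh(4 * (u - 0.55)),             # inhibition early, activation late
    cos(2 * pi * u))                  # peak - trough - recovery
  w <- trapezoid_weights(u)
  phi <- raw
  for (j in 1:3) {
    for (k in seq_len(j - 1))
      phi[, j] <- phi[, j] - sum(w * phi[, j] * phi[, k]) * phi[, k]
    phi[, j] <- phi[, j] / sqrt(sum(w * phi[, j]^2))
  }
  list(u = u, mean = 0.3 * u * (2 - u), phi = phi)
}

#' Trapezoid quadrature weights for a (possibly irregular) grid
#' @param u increasing grid.
#' @return weights w with \code{sum(w * f)} approximating the integral of f.
#' @export
trapezoid_weights <- function(u) {
  n <- length(u)
  if (n < 2) stop("grid needs at least 2 points")
  d <- diff(u)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Serialize / restore a simulation config
#'
#' Round-trips the configuration through JSON so a run can be reproduced
#' from its manifest.  Matrices are stored with their dimnames.
#'
#' @param config a \code{sim_config}.
#' @param path file to write / read.
#' @return \code{read_sim_config} returns the restored \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named atomic vectors serialize as JSON objects only when made lists
  for (f in c("alpha_arm", "beta_arm", "tonic_mm")) x[[f]] <- as.list(x[[f]])
  x$transition_matrices <- lapply(x$transition_matrices, function(P)
    list(states = rownames(P), P = unname(P)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- lapply(x$transition_matrices, function(e) {
    P <- as.matrix(e$P)
    dimnames(P) <- list(e$states, e$states)
    P
  })
  sim_config(
    n_subjects_per_arm = x$n_subjects_per_arm, arms = x$arms,
    screen_width_px = x$screen_width_px,
    initial_size_fracs = x$initial_size_fracs, attc_levels = x$attc_levels,
    categories = x$categories, threat_categories = x$threat_categories,
    n_blocks = x$n_blocks, repetitions = x$repetitions,
    alpha0 = x$alpha0, beta0 = x$beta0,
    alpha_arm = unlist(x$alpha_arm), beta_arm = unlist(x$beta_arm),
    alpha_female = x$alpha_female, beta_female = x$beta_female,
    alpha_threat = x$alpha_threat, beta_threat = x$beta_threat,
    noise_sd_log_jttc = x$noise_sd_log_jttc, prop_female = x$prop_female,
    tonic_mm = unlist(x$tonic_mm),
    score_sds = x$score_sds,
    score_arm = lapply(x$score_arm, as.numeric),
    score_threat = x$score_threat,
    ar1_coef = x$ar1_coef, ar1_innov_sd = x$ar1_innov_sd,
    blink_rate = x$blink_rate, blink_dur_ms = x$blink_dur_ms,
    sample_ms = x$sample_ms,
    transition_matrices = tm, seed = x$seed)
}
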