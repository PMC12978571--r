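#' Generate the factorial trial design
#'
#' Builds, per subject, the full factorial of actual time-to-collision (5
#' levels) x stimulus category (4 levels) x initial size (2 levels), repeated
#' \code{config$repetitions} times (default 4, i.e. 160 trials), randomizes
#' trial order under the config seed, and assigns block labels by splitting
#' the ordered trials evenly.  Subjects are assigned to arms in equal numbers
#' and to sex by \code{prop_female} (deterministic counts, shuffled).
#'
#' @param config a [sim_config()].
#' @return a data.frame of trial records: \code{subject_id, arm, sex, block,
#'   trial, category, is_threat, attc, initial_frac, velocity, psv_bin}.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "design"))
  cell <- expand.grid(attc = config$attc_levels,
                      category = config$categories,
                      initial_frac = config$initial_size_fracs,
                      stringsAsFactors = FALSE)
  cells_per_subject <- nrow(cell)  # 5 x 4 x 2 = 40 for the default design
  n_trials <- cells_per_subject * config$repetitions
  edges <- default_psv_edges(config)
  out <- vector("list", length(config$arms) * config$n_subjects_per_arm)
  idx <- 0L
  for (arm in config$arms) {
    n_f <- round(config$prop_female * config$n_subjects_per_arm)
    sexes <- sample(c(rep("F", n_f),
                      rep("M", config$n_subjects_per_arm - n_f)))
    for (s in seq_len(config$n_subjects_per_arm)) {
      idx <- idx + 1L
      d <- cell[rep(seq_len(cells_per_subject), config$repetitions), ]
      d <- d[sample.int(n_trials), , drop = FALSE]
      rownames(d) <- NULL
      d$subject_id <- sprintf("%s_%02d", arm, s)
      d$arm <- arm
      d$sex <- sexes[s]
      d$trial <- seq_len(n_trials)
      d$block <- ceiling(d$trial / ceiling(n_trials / config$n_blocks))
      d$is_threat <- d$category %in% config$threat_categories
      d$velocity <- compute_velocity(config$screen_width_px,
                                     d$initial_frac * config$screen_width_px,
                                     d$attc)
      d$psv_bin <- assign_psv(d$velocity, edges)
      out[[idx]] <- d
    }
  }
  d <- do.call(rbind, out)
  d[, c("subject_id", "arm", "sex", "block", "trial", "category",
        "is_threat", "attc", "initial_frac", "velocity", "psv_bin")]
}

# effective power-law parameters for each design row
effective_params <- function(design, config) {
  alpha <- config$alpha0 +
    unname(config$alpha_arm[design$arm]) +
    ifelse(design$sex == "F", config$alpha_female, 0) +
    ifelse(design$is_threat, config$alpha_threat, 0)
  beta <- config$beta0 +
    unname(config$beta_arm[design$arm]) +
    ifelse(design$sex == "F", config$beta_female, 0) +
    ifelse(design$is_threat, config$beta_threat, 0)
  if (any(alpha <= 0)) stop("configured effects give alpha_eff <= 0")
  if (any(beta <= 0)) stop("configured effects give beta_eff <= 0")
  list(alpha = alpha, beta = beta)
}

#' Generate power-law behavioral responses
#'
#' Adds judged time-to-collision to a design:
#' \code{jTTC = alpha_eff * aTTC^beta_eff * exp(eps)} with
#' \code{eps ~ N(0, noise_sd_log_jttc)}; the effective parameters compose the
#' baseline with the configured arm/sex/threat shifts.  Multiplicative
#' log-normal noise keeps responses positive and matches the log scale on
#' which responses are later clustered.
#'
#' @param design output of [generate_design()].
#' @param config the same [sim_config()].
#' @return the design with columns \code{alpha_eff, beta_eff, jttc,
#'   keypress_ms} added.
#' @export
generate_behavior <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "behavior"))
  par <- effective_params(design, config)
  eps <- rnorm(nrow(design), 0, config$noise_sd_log_jttc)
  design$alpha_eff <- par$alpha
  design$beta_eff <- par$beta
  design$jttc <- par$alpha * design$attc^par$beta * exp(eps)
  design$keypress_ms <- 300 + 1000 * design$jttc
  design
}

# evaluate the stored mean/eigenfunctions at arbitrary u by linear interpolation
eval_mean <- function(config, u)
  approx(config$u_grid, config$mean_fn, xout = u, rule = 2)$y

eval_phi <- function(config, u)
  vapply(1:3, function(j)
    approx(config$u_grid, config$eigenfunctions[, j], xout = u, rule = 2)$y,
    numeric(length(u)))

# per-trial score means from condition shifts
score_means_for <- function(design, config) {
  m <- matrix(0, nrow(design), 3)
  for (a in unique(design$arm))
    m[design$arm == a, ] <- matrix(config$score_arm[[a]],
                                   sum(design$arm == a), 3, byrow = TRUE)
  m[design$is_threat, ] <- sweep(m[design$is_threat, , drop = FALSE], 2,
                                 config$score_threat, "+")
  m
}

#' Generate pupil traces for a behavioral design
#'
#' Each trial's trace runs from 0 to its key press (300 ms baseline +
#' jTTC) on a regular \code{sample_ms} grid.  From stimulus onset the signal
#' is the mean function plus score-weighted eigenfunctions evaluated at the
#' trial's warped time (the generative inverse of the piecewise-linear
#' normalization), on top of the arm's tonic level; the baseline segment
#' carries the tonic level only.  AR(1) noise is added throughout and blink
#' gaps (invalid, zeroed runs) are injected at a Poisson rate.
#'
#' @param design output of [generate_behavior()] (needs \code{jttc}).
#' @param config the same [sim_config()].
#' @param keep_scores if TRUE, attach the drawn scores as an attribute
#'   \code{"scores"} (trials x 3), for round-trip tests.
#' @return a data.frame of samples: \code{subject_id, trial, t, d, valid}.
#' @export
generate_pupil <- function(design, config, keep_scores = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design$jttc)) stop("design has no jttc; run generate_behavior()")
  set.seed(stage_seed(config$seed, "pupil"))
  mu_shift <- score_means_for(design, config)
  out <- vector("list", nrow(design))
  scores <- matrix(NA_real_, nrow(design), 3)
  for (i in seq_len(nrow(design))) {
    kp <- design$keypress_ms[i]
    if (kp <= 300 + config$sample_ms)
      stop("trial ", i, " shorter than the baseline window")
    t <- seq(0, kp, by = config$sample_ms)
    s <- rnorm(3, mu_shift[i, ], config$score_sds)
    scores[i, ] <- s
    d <- rep(config$tonic_mm[[design$arm[i]]], length(t))
    post <- t >= 300
    u <- warp_time(t[post], kp)
    d[post] <- d[post] + eval_mean(config, u) + drop(eval_phi(config, u) %*% s)
    if (config$ar1_innov_sd > 0) {
      e <- as.numeric(stats::filter(rnorm(length(t), 0, config$ar1_innov_sd),
                                    config$ar1_coef, method = "recursive"))
      d <- d + e
    }
    valid <- rep(TRUE, length(t))
    n_blink <- rpois(1, config$blink_rate)
    for (b in seq_len(n_blink)) {
      onset <- runif(1, 0, kp)
      dur <- runif(1, config$blink_dur_ms[1], config$blink_dur_ms[2])
      gap <- t >= onset & t < onset + dur
      valid[gap] <- FALSE
      d[gap] <- 0
    }
    out[[i]] <- data.frame(subject_id = design$subject_id[i],
                           trial = design$trial[i], t = t, d = d,
                           valid = valid)
  }
  res <- do.call(rbind, out)
  if (keep_scores) attr(res, "scores") <- scores
  res
}

#' Simulate a first-order Markov chain
#'
#' @param P row-stochastic transition matrix with state dimnames.
#' @param n sequence length.
#' @param start optional starting state label; default draws from the
#'   stationary distribution.
#' @return character vector of state labels.
#' @export
simulate_markov_chain <- function(P, n, start = NULL) {
  check_stochastic(P)
  states <- rownames(P)
  if (is.null(states)) states <- as.character(seq_len(nrow(P)))
  s <- integer(n)
  s[1] <- if (is.null(start)) {
    pi0 <- stationary_distribution(P)
    sample.int(nrow(P), 1, prob = pi0)
  } else match(start, states)
  if (is.na(s[1])) stop("unknown start state")
  for (i in seq_len(n - 1) + 1)
    s[i] <- sample.int(nrow(P), 1, prob = P[s[i - 1], ])
  states[s]
}

#' Generate per-subject profile-state sequences
#'
#' Draws, for each subject, a sequence of profile labels of length equal to
#' that subject's trial count from the subject's arm-specific transition
#' matrix, starting from the chain's stationary distribution.
#'
#' @param config a [sim_config()].
#' @param n_trials sequence length per subject (default the design's trial
#'   count).
#' @return a data.frame \code{subject_id, arm, trial, profile}.
#' @export
generate_state_sequences <- function(config, n_trials = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_trials))
    n_trials <- length(config$attc_levels) * length(config$categories) *
      length(config$initial_size_fracs) * config$repetitions
  set.seed(stage_seed(config$seed, "states"))
  out <- list()
  for (arm in config$arms) {
    P <- config$transition_matrices[[arm]]
    for (s in seq_len(config$n_subjects_per_arm)) {
      seqs <- simulate_markov_chain(P, n_trials)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%02d", arm, s), arm = arm,
        trial = seq_len(n_trials), profile = seqs)
    }
  }
  do.call(rbind, out)
}

#' Write / read the generator's CSV dialect
#'
#' Plain UTF-8 CSV with "." decimal separator and a header row; trial tables
#' and pupil sample streams use the column layouts produced by
#' [generate_behavior()] and [generate_pupil()].
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{read_trials_csv}/\code{read_pupil_csv} return data.frames.
#' @export
write_trials_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
write_pupil_csv <- write_trials_csv

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")

#' @rdname write_trials_csv
#' @export
read_pupil_csv <- read_trials_csv
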