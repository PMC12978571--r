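#' Deterministic per-stage seeds
#'
#' Fans one global seed out to reproducible per-stage seeds so stages can be
#' re-run in isolation: \code{(seed * 97 + 1009 * stage_index) mod (2^31-1)},
#' with the stage index taken from a fixed stage table.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("design", "behavior", "pupil", "states", "preprocess",
              "fpca", "profiles", "dynamics", "stats")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 97 + 1009 * i) %% 2147483647)
}

#' Validate trial and pupil input tables
#'
#' Schema and sanity checks for externally supplied data: required columns,
#' positive responses, and per-trial monotone timestamps.
#'
#' @param trials trial table (data.frame or CSV path).
#' @param pupil pupil sample table (data.frame or CSV path), optional.
#' @return list: \code{ok}, \code{errors} (character), \code{n_trials},
#'   \code{n_samples}.
#' @export
validate_inputs <- function(trials, pupil = NULL) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  errors <- character(0)
  need <- c("subject_id", "arm", "sex", "category", "is_threat", "attc",
            "initial_frac", "jttc")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    errors <- c(errors, paste("trials: missing column(s):",
                              paste(miss, collapse = ", ")))
  if ("jttc" %in% names(trials) && any(trials$jttc <= 0, na.rm = TRUE))
    errors <- c(errors, "trials: non-positive jttc values")
  n_samples <- NA_integer_
  if (!is.null(pupil)) {
    if (is.character(pupil)) pupil <- read_pupil_csv(pupil)
    pneed <- c("subject_id", "trial", "t", "d")
    pmiss <- setdiff(pneed, names(pupil))
    if (length(pmiss))
      errors <- c(errors, paste("pupil: missing column(s):",
                                paste(pmiss, collapse = ", ")))
    if (all(pneed %in% names(pupil))) {
      key <- interaction(pupil$subject_id, pupil$trial, drop = TRUE)
      bad <- vapply(split(pupil$t, key),
                    function(t) is.unsorted(t, strictly = TRUE), TRUE)
      if (any(bad))
        errors <- c(errors, paste("pupil: non-monotone timestamps in",
                                  sum(bad), "trial(s), e.g.",
                                  names(bad)[which(bad)[1]]))
      n_samples <- nrow(pupil)
    }
  }
  list(ok = length(errors) == 0, errors = errors,
       n_trials = nrow(trials), n_samples = n_samples)
}

#' Run the integrated pipeline end-to-end
#'
#' Orchestrates synthetic generation (or user data), behavioral filtering
#' and power-law fits, pupil trajectory normalization, FPCA with the 85%/5%
#' retention rule, two-level profiling, and Markov-chain dynamics, and
#' returns a manifest of seeds, filter-cascade counts and per-stage results.
#' Idempotent given a fixed config seed.
#'
#' @param config a [sim_config()].
#' @param stages subset of \code{c("behavior", "pupil", "profiles",
#'   "dynamics")} to run ("pupil" covers trajectories and FPCA; later stages
#'   require earlier ones).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param n_boot bootstrap replicates for stability/dynamics summaries.
#' @param use_generated_states if TRUE (default) the dynamics stage runs on
#'   generator state sequences; if FALSE it uses the fitted profile
#'   assignments from the profiles stage.
#' @return manifest list.
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("behavior", "pupil", "profiles",
                                    "dynamics"),
                         out_dir = NULL, n_boot = 200,
                         use_generated_states = TRUE) {
  manifest <- list(seed = config$seed, stages = stages,
                   counts = list(), status = list())
  save_csv <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trials_csv(x, file.path(out_dir, name))
    }
  }
  design <- generate_design(config)
  trials <- generate_behavior(design, config)
  manifest$counts$raw_trials <- nrow(trials)
  trials <- filter_jttc_outliers(trials)
  manifest$counts$after_sd_filter <- sum(trials$included)
  save_csv(trials, "trials.csv")
  res <- list(trials = trials)

  if ("behavior" %in% stages) {
    fits <- fit_by_subject(trials)
    lme_beta <- lme_on_parameters(fits, "beta")
    lme_alpha <- lme_on_parameters(fits, "alpha")
    res$fits <- fits
    res$lme <- list(beta = lme_beta$coefficients,
                    alpha = lme_alpha$coefficients)
    manifest$counts$subject_condition_fits <- nrow(fits)
    manifest$status$behavior <- "ok"
    save_csv(fits, "power_law_fits.csv")
  } else manifest$status$behavior <- "skipped"

  if ("pupil" %in% stages) {
    pupil <- generate_pupil(trials[trials$included, ], config)
    traj <- build_trajectories(pupil, trials[trials$included, ])
    manifest$counts$after_duration_filter <-
      manifest$counts$after_sd_filter -
      sum(traj$excluded$reason == "short trial")
    manifest$counts$trajectories <- nrow(traj$X)
    fp <- fit_fpca(traj$X, traj$grid)
    ret <- retain_components(fp)
    res$trajectories <- traj
    res$fpca <- fp
    res$retained <- ret$retained
    manifest$status$pupil <- "ok"
    if (!is.null(out_dir)) write_fpca_json(fp, file.path(out_dir,
                                                         "fpca.json"))
  } else manifest$status$pupil <- "skipped"

  if ("profiles" %in% stages) {
    if (!"pupil" %in% stages) stop("profiles stage requires pupil stage")
    idx <- res$trajectories$index
    tkey <- paste(trials$subject_id, trials$trial)
    jt <- trials$jttc[match(paste(idx$subject_id, idx$trial), tkey)]
    sc <- res$fpca$scores[, res$retained, drop = FALSE]
    pr <- assign_profiles(jt, sc, seed = stage_seed(config$seed, "profiles"))
    stab <- list()
    for (g in c("E", "L")) {
      l2 <- pr$level2[[g]]
      if (isTRUE(l2$unclustered)) next
      i <- pr$labels1 == g
      Z <- scale(sc[i, , drop = FALSE])
      stab[[g]] <- list(
        bootstrap = bootstrap_stability(Z, l2$labels, l2$k,
                                        n_boot = n_boot,
                                        seed = stage_seed(config$seed,
                                                          "profiles")),
        cv = cross_validate_clusters(Z, l2$labels, l2$k,
                                     seed = stage_seed(config$seed,
                                                       "profiles")))
    }
    res$profiles <- pr
    res$stability <- stab
    res$proportion_cor <- if (!is.null(res$fits))
      proportion_correlations(idx$subject_id, pr$labels1, res$fits)
    manifest$counts$profiled_trials <- length(pr$profile)
    manifest$status$profiles <- "ok"
    if (!is.null(out_dir))
      save_csv(data.frame(idx, profile = pr$profile), "profiles.csv")
  } else manifest$status$profiles <- "skipped"

  if ("dynamics" %in% stages) {
    seqs <- if (use_generated_states) {
      generate_state_sequences(config)
    } else {
      idx <- res$trajectories$index
      d <- data.frame(idx, profile = as.character(res$profiles$profile),
                      arm = trials$arm[match(paste(idx$subject_id,
                                                   idx$trial), tkey)])
      d[order(d$subject_id, d$trial), ]
    }
    states <- config$profile_states
    groups <- split(seqs, seqs$arm)
    models <- lapply(groups, estimate_transitions, states = states)
    occ <- t(vapply(groups, function(g)
      as.numeric(table(factor(g$profile, levels = states))),
      numeric(length(states))))
    colnames(occ) <- states
    res$dynamics <- list(
      models = models,
      stationary = lapply(models, function(m)
        tryCatch(stationary_distribution(m), error = function(e) NULL)),
      occupancy = occupancy_contrast(occ),
      entropy = entropy_contrast(groups, n_boot = n_boot,
                                 seed = stage_seed(config$seed,
                                                   "dynamics")),
      within = lapply(models, within_group_significant_transitions))
    manifest$counts$state_sequences <- length(unique(seqs$subject_id))
    manifest$status$dynamics <- "ok"
    if (!is.null(out_dir)) {
      for (g in names(models))
        save_csv(as.data.frame(models[[g]]$P),
                 paste0("transitions_", g, ".csv"))
      jsonlite::write_json(
        list(entropy = res$dynamics$entropy$entropy,
             ordering = res$dynamics$entropy$ordering),
        file.path(out_dir, "entropy.json"), digits = NA, pretty = TRUE)
    }
  } else manifest$status$dynamics <- "skipped"

  res$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  res
}
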