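#' Approach velocity of a looming stimulus
#'
#' \code{velocity = (screen_width - initial_width) / attc} in pixels/s: the
#' rate at which the stimulus must expand to fill the screen at the actual
#' time-to-collision.
#'
#' @param screen_width screen width in pixels.
#' @param initial_width initial stimulus width in pixels.
#' @param attc actual time-to-collision in seconds.
#' @return velocity in pixels/s (vectorized).
#' @export
compute_velocity <- function(screen_width, initial_width, attc) {
  if (any(attc <= 0)) stop("attc must be positive")
  if (any(initial_width < 0) || any(initial_width > screen_width))
    stop("initial_width must lie in [0, screen_width]")
  (screen_width - initial_width) / attc
}

#' Default physical-stimulus-velocity (PSV) bin edges
#'
#' Equal-width partition of the design's velocity range into five intervals.
#' Range endpoints are taken at 0.1 px/s precision (the reporting precision
#' of the velocities), which yields the conventional printed boundaries
#' 179.2, 211.6, 244.0, ... for the default 1280-px design.
#'
#' @param config a [sim_config()] (or any list with \code{screen_width_px},
#'   \code{initial_size_fracs}, \code{attc_levels}).
#' @param n_bins number of intervals.
#' @return numeric vector of \code{n_bins + 1} increasing edges.
#' @export
default_psv_edges <- function(config, n_bins = 5) {
  w <- config$screen_width_px
  v <- compute_velocity(w,
                        rep(config$initial_size_fracs * w,
                            each = length(config$attc_levels)),
                        rep(config$attc_levels,
                            length(config$initial_size_fracs)))
  lo <- round(min(v), 1)
  hi <- round(max(v), 1)
  seq(lo, hi, length.out = n_bins + 1)
}

#' Assign a velocity to its PSV ordinal bin
#'
#' Intervals are left-closed/right-open with the last interval closed, so a
#' velocity on a shared boundary belongs to the upper bin and the overall
#' maximum to V5.  Velocities are compared at the same 0.1 px/s reporting
#' precision as the default edges (set \code{round_digits = NULL} for exact
#' comparison).
#'
#' @param velocity velocities in pixels/s (vectorized).
#' @param edges strictly increasing vector of 6 boundaries.
#' @param round_digits precision at which velocities are binned.
#' @return factor with levels \code{V1..V5}.
#' @export
assign_psv <- function(velocity, edges, round_digits = 1) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  n_bins <- length(edges) - 1
  v <- if (is.null(round_digits)) velocity else round(velocity, round_digits)
  eps <- 1e-9 * diff(range(edges))
  bad <- v < edges[1] - eps | v > edges[length(edges)] + eps
  if (any(bad))
    stop("velocity out of PSV range: ",
         paste(signif(velocity[bad], 6), collapse = ", "))
  i <- findInterval(v + eps, edges)
  i <- pmin(pmax(i, 1L), n_bins)
  factor(paste0("V", i), levels = paste0("V", seq_len(n_bins)))
}

#' Flag per-subject jTTC outliers
#'
#' Two-stage behavioral screen: trials already marked as technical artifacts
#' or incomplete are excluded first; among the remainder, trials whose jTTC
#' deviates more than \code{n_sd} (default 5) SDs from the subject's mean are
#' flagged as outliers.  A zero SD flags nothing.
#'
#' @param trials data.frame with \code{subject_id} and \code{jttc}; an
#'   optional logical \code{artifact} column marks stage-one exclusions.
#' @param n_sd SD multiple.
#' @return the data.frame with logical \code{included} and character
#'   \code{exclusion_reason} columns.
#' @export
filter_jttc_outliers <- function(trials, n_sd = 5) {
  stopifnot(all(c("subject_id", "jttc") %in% names(trials)))
  artifact <- if (is.null(trials$artifact)) rep(FALSE, nrow(trials))
              else trials$artifact
  included <- !artifact
  reason <- ifelse(artifact, "artifact", NA_character_)
  for (s in unique(trials$subject_id)) {
    i <- which(trials$subject_id == s & included)
    if (length(i) < 2) next
    m <- mean(trials$jttc[i])
    sdev <- sd(trials$jttc[i])
    if (sdev == 0) next
    out <- abs(trials$jttc[i] - m) > n_sd * sdev
    included[i[out]] <- FALSE
    reason[i[out]] <- sprintf("jttc_outlier_%gsd", n_sd)
  }
  trials$included <- included
  trials$exclusion_reason <- reason
  trials
}

#' Convert pupil area samples to diameter
#'
#' \code{d = alpha_scale * L * phi(area)} with the visual-angle term taken
#' proportional to \code{sqrt(area)} (the areal-to-linear conversion), the
#' proportionality constant folded into \code{alpha_scale * L}.  When the
#' input is already a diameter the values pass through unchanged.
#'
#' @param values area samples (arbitrary camera pixel units) or diameters.
#' @param alpha_scale empirical scaling factor (> 0).
#' @param L pupil-to-camera distance in mm (> 0).
#' @param units_in \code{"area_px"} or \code{"diameter_mm"}.
#' @return diameters (mm when calibrated).
#' @export
convert_area_to_diameter <- function(values, alpha_scale = 1, L = 1,
                                     units_in = c("area_px", "diameter_mm")) {
  units_in <- match.arg(units_in)
  if (units_in == "diameter_mm") return(values)
  if (alpha_scale <= 0 || L <= 0) stop("alpha_scale and L must be positive")
  if (any(values < 0, na.rm = TRUE)) stop("negative pupil area")
  alpha_scale * L * sqrt(values)
}

#' Clean a raw pupil trace
#'
#' Marks signal-loss/blink samples (zeros, NAs, pre-flagged invalid) and pads
#' each invalid run by \code{pad_ms} on both sides; invalidates samples
#' outside the physiological band (applied only when \code{units_mm}) and
#' samples beyond \code{n_sd} SDs of the trial mean; then linearly
#' interpolates all invalid samples.  The sample count never changes.
#'
#' @param trace data.frame with \code{t} (ms), \code{d}, and optionally
#'   \code{valid}.
#' @param pad_ms padding margin around invalid runs.
#' @param plausible_mm physiological band (mm).
#' @param units_mm are values in mm (enables the band check)?
#' @param n_sd trial-level outlier bound.
#' @param max_interp_frac above this interpolated fraction the trial is
#'   flagged for exclusion.
#' @return the trace with \code{d} interpolated and \code{valid} updated;
#'   attributes \code{interp_frac} and \code{excluded}.
#' @export
clean_trace <- function(trace, pad_ms = 100, plausible_mm = c(1.5, 9),
                        units_mm = TRUE, n_sd = 5, max_interp_frac = 0.30) {
  stopifnot(all(c("t", "d") %in% names(trace)))
  n <- nrow(trace)
  valid <- if (is.null(trace$valid)) rep(TRUE, n) else trace$valid
  valid <- valid & !is.na(trace$d) & trace$d != 0
  # pad invalid runs: a sample within pad_ms of an invalid one is suspect
  if (any(!valid) && pad_ms > 0) {
    bad_t <- trace$t[!valid]
    runs <- split(bad_t, cumsum(c(1, diff(bad_t) > 1.5 * median(diff(trace$t)))))
    for (r in runs)
      valid[trace$t >= min(r) - pad_ms & trace$t <= max(r) + pad_ms] <- FALSE
  }
  if (units_mm)
    valid[!is.na(trace$d) &
            (trace$d < plausible_mm[1] | trace$d > plausible_mm[2])] <- FALSE
  if (sum(valid) >= 2) {
    m <- mean(trace$d[valid])
    sdev <- sd(trace$d[valid])
    if (sdev > 0) valid[valid][abs(trace$d[valid] - m) > n_sd * sdev] <- FALSE
  }
  interp_frac <- mean(!valid)
  if (sum(valid) >= 2) {
    trace$d <- approx(trace$t[valid], trace$d[valid], xout = trace$t,
                      rule = 2)$y
    trace$valid <- TRUE   # interpolated values are usable downstream
    trace$interpolated <- !valid
  } else {
    trace$valid <- valid
    trace$interpolated <- !valid
  }
  attr(trace, "interp_frac") <- interp_frac
  attr(trace, "excluded") <- interp_frac > max_interp_frac || sum(valid) < 2
  trace
}

#' Down-sample a trace into fixed bins
#'
#' Each bin's value is the mean of its valid samples; the bin timestamp is
#' the bin start.  Bins with no valid sample carry \code{valid = FALSE}.
#'
#' @param trace data.frame with \code{t}, \code{d}, optional \code{valid}.
#' @param bin_ms bin width in ms.
#' @return binned data.frame \code{t, d, valid}.
#' @export
downsample_trace <- function(trace, bin_ms = 10) {
  stopifnot(all(c("t", "d") %in% names(trace)))
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace)) else trace$valid
  bin <- floor(trace$t / bin_ms)
  bins <- sort(unique(bin))
  ok <- valid & !is.na(trace$d)
  sums <- tapply(ifelse(ok, trace$d, 0), bin, sum)
  cnts <- tapply(as.numeric(ok), bin, sum)
  d <- as.numeric(sums[as.character(bins)]) /
    as.numeric(cnts[as.character(bins)])
  data.frame(t = bins * bin_ms, d = d,
             valid = as.numeric(cnts[as.character(bins)]) > 0)
}

#' Baseline-correct a trace
#'
#' Subtracts the mean diameter over the pre-stimulus window from every
#' sample, isolating the task-evoked change.  Idempotent.
#'
#' @param trace data.frame with \code{t}, \code{d}, optional \code{valid}.
#' @param window half-open baseline window \code{[window[1], window[2])} ms.
#' @return corrected trace with attributes \code{baseline_mean} (of the
#'   original input) and \code{corrected = TRUE}.
#' @export
baseline_correct <- function(trace, window = c(0, 300)) {
  stopifnot(all(c("t", "d") %in% names(trace)))
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace)) else trace$valid
  in_win <- trace$t >= window[1] & trace$t < window[2] & valid & !is.na(trace$d)
  if (!any(in_win)) stop("no valid samples in the baseline window")
  b <- mean(trace$d[in_win])
  trace$d <- trace$d - b
  attr(trace, "baseline_mean") <- b
  attr(trace, "corrected") <- TRUE
  trace
}

#' Phase windows and per-phase means
#'
#' Returns the three analysis windows in absolute trial time (0 = fixation
#' onset): stimulus presentation [300, 1300), early imagination
#' [1300, 1800), and late imagination [keypress - 500, keypress), plus the
#' mean corrected diameter in each.  Trials shorter than \code{min_ms} are
#' excluded so the windows cannot overlap in the wrong order.
#'
#' @param trace baseline-corrected trace (\code{t}, \code{d}, optional
#'   \code{valid}).
#' @param keypress_ms key-press time in ms (\code{300 + 1000 * jttc}).
#' @param min_ms minimum trial duration.
#' @return list with \code{windows} (3x2 matrix, ms) and \code{means}
#'   (named numeric), or a list with \code{excluded = TRUE} and a reason.
#' @export
phase_windows <- function(trace, keypress_ms, min_ms = 2300) {
  if (keypress_ms < min_ms)
    return(list(excluded = TRUE, reason = "short trial"))
  windows <- rbind(stimulus = c(300, 1300),
                   early_imagination = c(1300, 1800),
                   late_imagination = c(keypress_ms - 500, keypress_ms))
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace)) else trace$valid
  means <- apply(windows, 1, function(w) {
    i <- trace$t >= w[1] & trace$t < w[2] & valid & !is.na(trace$d)
    if (!any(i)) NA_real_ else mean(trace$d[i])
  })
  list(excluded = FALSE, windows = windows, means = means)
}
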