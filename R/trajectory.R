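#' Piecewise-linear time warp onto [0, 1]
#'
#' Maps the fixed stimulus epoch [300, 1300] ms linearly onto [0, 0.5] and
#' the variable imagination epoch [1300, keypress] onto [0.5, 1], making
#' trials of different durations comparable on a unified scale.  The warp is
#' continuous at the 1300-ms breakpoint, strictly increasing, and bijective.
#'
#' @param t_ms time in ms from trial start (0 = fixation onset), vectorized.
#' @param keypress_ms key-press (imagined collision) time in ms; must exceed
#'   the stimulus offset.
#' @param stim stimulus epoch bounds in ms.
#' @return normalized time in [0, 1].
#' @export
warp_time <- function(t_ms, keypress_ms, stim = c(300, 1300)) {
  if (keypress_ms <= stim[2]) stop("keypress at or before stimulus offset")
  span <- stim[2] - stim[1]
  ifelse(t_ms <= stim[2],
         0.5 * (t_ms - stim[1]) / span,
         0.5 + 0.5 * (t_ms - stim[2]) / (keypress_ms - stim[2]))
}

#' @rdname warp_time
#' @param u normalized time in [0, 1].
#' @export
unwarp_time <- function(u, keypress_ms, stim = c(300, 1300)) {
  if (keypress_ms <= stim[2]) stop("keypress at or before stimulus offset")
  span <- stim[2] - stim[1]
  ifelse(u <= 0.5,
         stim[1] + u / 0.5 * span,
         stim[2] + (u - 0.5) / 0.5 * (keypress_ms - stim[2]))
}

#' Penalized cubic B-spline smoothing on the normalized time scale
#'
#' Fits a penalized least-squares cubic B-spline (default 20 basis
#' functions) to samples on [0, 1], with the roughness penalty chosen by
#' generalized cross-validation, and evaluates it on a regular common grid.
#' Pass a tiny fixed \code{sp} to obtain a near-interpolating fit.
#'
#' @param u sample positions in [0, 1].
#' @param y sample values.
#' @param n_basis B-spline basis dimension.
#' @param grid_size number of common-grid points (grid is
#'   \code{seq(0, 1, length.out = grid_size)}).
#' @param sp optional fixed smoothing parameter; \code{NULL} uses GCV.
#' @return list of class \code{"normalized_trajectory"}: \code{grid},
#'   \code{values}, \code{fit} (the mgcv model), \code{edf}.
#' @export
smooth_bspline <- function(u, y, n_basis = 20, grid_size = 101, sp = NULL) {
  keep <- is.finite(u) & is.finite(y)
  u <- u[keep]; y <- y[keep]
  if (length(u) < n_basis + 1)
    stop("too few valid samples (", length(u), ") for a ", n_basis,
         "-basis spline")
  if (var(y) == 0) {
    grid <- seq(0, 1, length.out = grid_size)
    return(structure(list(grid = grid, values = rep(y[1], grid_size),
                          fit = NULL, edf = 1),
                     class = "normalized_trajectory"))
  }
  f <- mgcv::gam(y ~ s(u, bs = "bs", k = n_basis, m = c(3, 2)),
                 sp = sp, method = "GCV.Cp")
  grid <- seq(0, 1, length.out = grid_size)
  structure(list(grid = grid,
                 values = as.numeric(predict(f, data.frame(u = grid))),
                 fit = f, edf = sum(f$edf)),
            class = "normalized_trajectory")
}

#' Build the trial-by-grid trajectory matrix
#'
#' For each trial: restrict the baseline-corrected, downsampled trace to
#' [stimulus onset, key press], warp to [0, 1], and smooth onto the common
#' grid.  Trials whose key press precedes the minimum duration, that lack
#' enough valid samples, or whose cleaning flagged them are skipped with a
#' reason.
#'
#' @param pupil pupil samples (\code{subject_id, trial, t, d, valid}).
#' @param trials trial table with \code{subject_id, trial, keypress_ms} (and
#'   optionally \code{included}).
#' @param grid_size common grid resolution.
#' @param n_basis spline basis dimension.
#' @param min_ms minimum trial duration in ms.
#' @param baseline_window baseline window for correction, ms.
#' @return list: \code{X} (trials x grid matrix, rownames
#'   "subject_id.trial"), \code{grid}, \code{index} (data.frame mapping rows
#'   to subject/trial), \code{excluded} (data.frame of skipped trials with
#'   reasons).
#' @export
build_trajectories <- function(pupil, trials, grid_size = 101, n_basis = 20,
                               min_ms = 2300, baseline_window = c(0, 300)) {
  if (!is.null(trials$included)) trials <- trials[trials$included, ]
  key_p <- interaction(pupil$subject_id, pupil$trial, drop = TRUE)
  traces <- split(pupil, key_p)
  rows <- list(); idx <- list(); excl <- list()
  for (i in seq_len(nrow(trials))) {
    id <- paste(trials$subject_id[i], trials$trial[i], sep = ".")
    tr <- traces[[id]]
    reason <- NULL
    if (is.null(tr)) reason <- "no pupil data"
    else if (trials$keypress_ms[i] < min_ms) reason <- "short trial"
    if (is.null(reason)) {
      tr <- tryCatch(baseline_correct(tr, baseline_window),
                     error = function(e) NULL)
      if (is.null(tr)) reason <- "no valid baseline"
    }
    if (is.null(reason)) {
      post <- tr$t >= 300 & tr$t <= trials$keypress_ms[i] & tr$valid
      if (sum(post) < n_basis + 1) reason <- "too few valid samples"
      else {
        u <- warp_time(tr$t[post], trials$keypress_ms[i])
        sm <- tryCatch(smooth_bspline(u, tr$d[post], n_basis = n_basis,
                                      grid_size = grid_size),
                       error = function(e) NULL)
        if (is.null(sm)) reason <- "smoothing failed"
        else {
          rows[[id]] <- sm$values
          idx[[id]] <- data.frame(subject_id = trials$subject_id[i],
                                  trial = trials$trial[i])
        }
      }
    }
    if (!is.null(reason))
      excl[[id]] <- data.frame(subject_id = trials$subject_id[i],
                               trial = trials$trial[i], reason = reason)
  }
  X <- do.call(rbind, rows)
  list(X = X, grid = seq(0, 1, length.out = grid_size),
       index = do.call(rbind, idx),
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(subject_id = character(),
                                  trial = integer(), reason = character()))
}

#' Pupillary velocity trajectories
#'
#' Central finite-difference slope of each normalized trajectory with
#' respect to warped time (forward/backward differences at the ends).
#' Computed on the warped scale, so a trial's "velocity" is change per unit
#' of normalized task progress rather than per millisecond.
#'
#' @param X trials x grid trajectory matrix.
#' @param grid common grid on [0, 1]; default equally spaced.
#' @return matrix of the same shape with d(value)/d(normalized time).
#' @export
trajectory_velocity <- function(X, grid = NULL) {
  X <- as.matrix(X)
  G <- ncol(X)
  if (G < 3) stop("need at least 3 grid points")
  if (is.null(grid)) grid <- seq(0, 1, length.out = G)
  V <- X
  V[, 1] <- (X[, 2] - X[, 1]) / (grid[2] - grid[1])
  V[, G] <- (X[, G] - X[, G - 1]) / (grid[G] - grid[G - 1])
  mid <- 2:(G - 1)
  V[, mid] <- (X[, mid + 1] - X[, mid - 1]) /
    rep(grid[mid + 1] - grid[mid - 1], each = nrow(X))
  V
}
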