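#' Fit the power-law psychophysical model by least squares
#'
#' Fits \code{jTTC = alpha * aTTC^beta} by minimizing the sum of squared
#' errors in the original response scale.  For a fixed exponent the optimal
#' scale has the closed form \code{alpha(beta) = sum(y * x^beta) /
#' sum(x^(2*beta))}, so the fit reduces to a one-dimensional profiled search
#' over beta: a coarse grid locates the basin and \code{optimize()} refines
#' it to tolerance 1e-10.  An optional log-space fit (OLS of log y on log x)
#' is available but is not the default.
#'
#' @param attc actual times-to-collision (s), positive.
#' @param jttc judged times-to-collision (s), positive.
#' @param beta_range search interval for the exponent.
#' @param min_trials minimum trial count for a valid fit.
#' @param log_space fit in log space instead of the response scale?
#' @return list of class \code{"power_law_fit"}: \code{alpha, beta, sse, r2,
#'   aic, bic, n_trials, converged}.
#' @export
fit_power_law <- function(attc, jttc, beta_range = c(-1, 4),
                          min_trials = 10, log_space = FALSE) {
  keep <- is.finite(attc) & is.finite(jttc)
  x <- attc[keep]; y <- jttc[keep]
  n <- length(x)
  if (n < min_trials)
    stop("need at least ", min_trials, " trials (got ", n, ")")
  if (any(x <= 0) || any(y <= 0)) stop("attc and jttc must be positive")
  if (log_space) {
    f <- lm(log(y) ~ log(x))
    alpha <- exp(coef(f)[[1]]); beta <- coef(f)[[2]]
  } else {
    prof_sse <- function(b) {
      xb <- x^b
      sum(y^2) - sum(y * xb)^2 / sum(xb^2)
    }
    grid <- seq(beta_range[1], beta_range[2], length.out = 101)
    sse_g <- vapply(grid, prof_sse, 0)
    i <- which.min(sse_g)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    beta <- optimize(prof_sse, c(lo, hi), tol = 1e-10)$minimum
    # second bracketing pass: optimize() bottoms out near sqrt(eps)
    beta <- optimize(prof_sse, c(beta - 1e-5, beta + 1e-5),
                     tol = 1e-12)$minimum
    alpha <- sum(y * x^beta) / sum(x^(2 * beta))
  }
  res <- y - alpha * x^beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(alpha = alpha, beta = beta, sse = sse, r2 = r2,
                 aic = ic_gaussian(n, sse, k = 2)["aic"],
                 bic = ic_gaussian(n, sse, k = 2)["bic"],
                 n_trials = n, converged = is.finite(alpha) && alpha > 0),
            class = "power_law_fit")
}

# shared information-criterion convention: sigma^2 profiled out, k slope/scale
# parameters, identical for the linear and power-law models
ic_gaussian <- function(n, sse, k) {
  sse <- max(sse, .Machine$double.eps)
  c(aic = n * log(sse / n) + 2 * k, bic = n * log(sse / n) + k * log(n))
}

#' Fit the linear psychophysical model
#'
#' Ordinary least squares for \code{jTTC = alpha + beta * aTTC}; the baseline
#' model against which the power law is compared.
#'
#' @inheritParams fit_power_law
#' @return list of class \code{"linear_fit"}: \code{alpha} (intercept),
#'   \code{beta} (slope), \code{sse, r2, aic, bic, n_trials}.
#' @export
fit_linear <- function(attc, jttc) {
  keep <- is.finite(attc) & is.finite(jttc)
  x <- attc[keep]; y <- jttc[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 trials")
  if (length(unique(x)) < 2) stop("degenerate design: single aTTC value")
  f <- lm(y ~ x)
  sse <- sum(resid(f)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(alpha = coef(f)[[1]], beta = coef(f)[[2]], sse = sse,
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 aic = ic_gaussian(n, sse, 2)["aic"],
                 bic = ic_gaussian(n, sse, 2)["bic"], n_trials = n),
            class = "linear_fit")
}

#' Compare power-law and linear fits on the same trials
#'
#' Both criteria use the same profiled-Gaussian convention with k = 2
#' parameters, so the comparison reduces to the SSEs.  The lower criterion
#' wins; exact ties go to the linear model (simpler interpretation).
#'
#' @param power a \code{power_law_fit}.
#' @param linear a \code{linear_fit} on the identical trials.
#' @return list: \code{winner} ("power" or "linear"), \code{delta_aic},
#'   \code{delta_bic} (power minus linear).
#' @export
compare_models <- function(power, linear) {
  stopifnot(inherits(power, "power_law_fit"), inherits(linear, "linear_fit"))
  if (power$n_trials != linear$n_trials)
    stop("fits are not on the same trial set")
  d_aic <- unname(power$aic - linear$aic)
  d_bic <- unname(power$bic - linear$bic)
  list(winner = if (d_aic < 0) "power" else "linear",
       delta_aic = d_aic, delta_bic = d_bic)
}

#' Fit the psychophysical models per subject and condition
#'
#' Splits trials by subject and threat condition, fits both models, and
#' compares them.  Fits with fewer than \code{min_trials} trials are dropped.
#'
#' @param trials data.frame with \code{subject_id, arm, sex, is_threat,
#'   attc, jttc} (and optionally \code{included}).
#' @param min_trials minimum trials per (subject, condition) fit.
#' @return data.frame with one row per (subject, condition):
#'   arm, sex, alpha, beta, sse, r2, aic, bic, n_trials, winner.
#' @export
fit_by_subject <- function(trials, min_trials = 10) {
  if (!is.null(trials$included)) trials <- trials[trials$included, ]
  key <- interaction(trials$subject_id, trials$is_threat, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    if (nrow(d) < min_trials) return(NULL)
    pw <- fit_power_law(d$attc, d$jttc, min_trials = min_trials)
    ln <- fit_linear(d$attc, d$jttc)
    data.frame(subject_id = d$subject_id[1], arm = d$arm[1], sex = d$sex[1],
               is_threat = d$is_threat[1], alpha = pw$alpha, beta = pw$beta,
               sse = pw$sse, r2 = pw$r2, aic = unname(pw$aic),
               bic = unname(pw$bic), n_trials = pw$n_trials,
               winner = compare_models(pw, ln)$winner)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-effects tests on fitted power-law parameters
#'
#' Fits (REML) \code{parameter ~ (arm + sex + is_threat)^2 + (1 | subject)}
#' with the placebo arm, male sex and non-threat as reference levels, and
#' returns the fixed-effect table with Satterthwaite p-values and 95%
#' confidence intervals.
#'
#' @param fits output of [fit_by_subject()].
#' @param parameter \code{"alpha"} or \code{"beta"}.
#' @param reference_arm reference level for the arm factor.
#' @return list: \code{coefficients} (data.frame: term, estimate, se, df, t,
#'   p, ci_low, ci_high), \code{singular} flag, \code{model}.
#' @export
lme_on_parameters <- function(fits, parameter = c("beta", "alpha"),
                              reference_arm = "PLC") {
  parameter <- match.arg(parameter)
  d <- data.frame(y = fits[[parameter]],
                  arm = stats::relevel(factor(fits$arm), ref = reference_arm),
                  sex = factor(fits$sex),
                  threat = factor(fits$is_threat,
                                  levels = c(FALSE, TRUE),
                                  labels = c("nonthreat", "threat")),
                  subject = factor(fits$subject_id))
  vars <- c("arm", "sex", "threat")
  vars <- vars[vapply(vars, function(v) nlevels(droplevels(d[[v]])) > 1, TRUE)]
  if (!length(vars)) stop("no factor with >= 2 levels")
  rhs <- if (length(vars) > 1)
    paste0("(", paste(vars, collapse = " + "), ")^2") else vars
  form <- as.formula(paste("y ~", rhs, "+ (1 | subject)"))
  m <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = d)))
  co <- as.data.frame(summary(m)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  ci <- co$estimate + outer(co$se * qt(0.975, pmax(co$df, 1)), c(-1, 1))
  out <- data.frame(term = rownames(co), co,
                    ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL)
  list(coefficients = out, singular = lme4::isSingular(m), model = m)
}
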