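#' Functional principal component analysis on a common grid
#'
#' Eigendecomposition of the trapezoid-weighted sample covariance of the
#' trajectory ensemble.  With quadrature weights W, the generalized problem
#' \code{C W phi = lambda phi} is symmetrized as
#' \code{W^(1/2) C W^(1/2) v = lambda v}, \code{phi = W^(-1/2) v}, so the
#' eigenfunctions are orthonormal in the quadrature inner product and the
#' eigenvalues sum to the total weighted variance (Parseval).  Scores are
#' the quadrature inner products of the centered trajectories with each
#' eigenfunction.  Sign convention: each eigenfunction is flipped so that
#' its integral over [0, 0.5] (the stimulus epoch) is non-negative.
#'
#' @param X trials x grid matrix of (smoothed, baseline-corrected)
#'   trajectories.
#' @param grid common grid on [0, 1]; default equally spaced.
#' @return object of class \code{"fpca_model"}: \code{grid, weights,
#'   mean_fn, eigenfunctions} (grid x J), \code{eigenvalues},
#'   \code{explained_share}, \code{scores} (trials x J), \code{n}.
#' @export
fit_fpca <- function(X, grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); G <- ncol(X)
  if (n < 2) stop("need at least 2 trajectories")
  if (is.null(grid)) grid <- seq(0, 1, length.out = G)
  w <- trapezoid_weights(grid)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(w * apply(Xc, 2, function(col) sum(col^2) / (n - 1)))
  if (total_var < 1e-14) stop("degenerate ensemble: zero total variance")
  C <- crossprod(Xc) / (n - 1)
  sw <- sqrt(w)
  M <- (sw %o% sw) * C
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  lambda <- e$values[keep]
  phi <- sweep(e$vectors[, keep, drop = FALSE], 1, sw, "/")
  half <- grid <= 0.5
  for (j in seq_along(lambda)) {
    if (sum(w[half] * phi[half, j]) < 0) phi[, j] <- -phi[, j]
  }
  scores <- Xc %*% (phi * w)
  structure(list(grid = grid, weights = w, mean_fn = mu,
                 eigenfunctions = phi, eigenvalues = lambda,
                 explained_share = lambda / sum(lambda),
                 scores = scores, n = n),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("FPCA of %d trajectories on a %d-point grid\n",
              x$n, length(x$grid)))
  J <- min(5, length(x$eigenvalues))
  cat("  leading shares:",
      paste(sprintf("%.1f%%", 100 * x$explained_share[1:J]), collapse = " "),
      "\n")
  invisible(x)
}

#' Component retention rule
#'
#' Takes the smallest prefix of components whose cumulative explained share
#' exceeds \code{cum_threshold}, then drops any member whose individual
#' share is at or below \code{indiv_threshold}.  If the cumulative share
#' never exceeds the threshold, all positive-share components are retained
#' with a warning.
#'
#' @param model a fitted [fit_fpca()] model.
#' @param cum_threshold cumulative-variance threshold (default 0.85).
#' @param indiv_threshold individual-share floor (default 0.05).
#' @return list: \code{prefix} (indices meeting the cumulative rule),
#'   \code{retained} (final index set), \code{shares}.
#' @export
retain_components <- function(model, cum_threshold = 0.85,
                              indiv_threshold = 0.05) {
  shares <- if (inherits(model, "fpca_model")) model$explained_share
            else as.numeric(model)
  cs <- cumsum(shares)
  if (any(cs > cum_threshold)) {
    prefix <- seq_len(which(cs > cum_threshold)[1])
  } else {
    warning("cumulative share never exceeds ", cum_threshold,
            "; retaining all components")
    prefix <- seq_along(shares)
  }
  retained <- prefix[shares[prefix] > indiv_threshold]
  list(prefix = prefix, retained = retained, shares = shares)
}

#' Reconstruct trajectories from scores
#'
#' \code{mean + sum_j score_j * phi_j} over the selected components.
#'
#' @param model a fitted [fit_fpca()] model.
#' @param scores matrix (trials x length(components)) or vector of scores.
#' @param components component indices (default all).
#' @param centered if TRUE, omit the mean function.
#' @return matrix (trials x grid) of reconstructed trajectories.
#' @export
reconstruct_fpca <- function(model, scores, components = NULL,
                             centered = FALSE) {
  stopifnot(inherits(model, "fpca_model"))
  if (is.null(components)) components <- seq_along(model$eigenvalues)
  scores <- matrix(scores, ncol = length(components))
  out <- scores %*% t(model$eigenfunctions[, components, drop = FALSE])
  if (!centered) out <- sweep(out, 2, model$mean_fn, "+")
  out
}

#' Associations of component scores with experimental conditions
#'
#' For each component, tests each supplied factor (one-way ANOVA) or numeric
#' covariate (Pearson correlation) against the trial scores, and adjusts the
#' p-values by Benjamini-Hochberg within the component's family of tests.
#'
#' @param scores trials x J score matrix.
#' @param factors data.frame of per-trial factors/covariates (aligned rows).
#' @param components columns of \code{scores} to test (default all).
#' @return data.frame: component, variable, type, statistic, estimate, p,
#'   p_adj.
#' @export
score_condition_tests <- function(scores, factors, components = NULL) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(factors))
  if (is.null(components)) components <- seq_len(ncol(scores))
  rows <- list()
  for (j in components) {
    fam <- list()
    for (v in names(factors)) {
      x <- factors[[v]]
      if (is.numeric(x)) {
        ct <- cor.test(scores[, j], x)
        fam[[v]] <- data.frame(component = j, variable = v,
                               type = "correlation",
                               statistic = unname(ct$statistic),
                               estimate = unname(ct$estimate),
                               p = ct$p.value)
      } else {
        x <- droplevels(factor(x))
        if (nlevels(x) < 2) next
        a <- anova(lm(scores[, j] ~ x))
        fam[[v]] <- data.frame(component = j, variable = v, type = "anova",
                               statistic = a[1, "F value"],
                               estimate = NA_real_, p = a[1, "Pr(>F)"])
      }
    }
    fam <- do.call(rbind, fam)
    fam$p_adj <- p.adjust(fam$p, method = "BH")
    rows[[as.character(j)]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an FPCA model to JSON
#'
#' Stores grid, mean function, eigenfunctions and eigenvalues (not the
#' per-trial scores, which are written separately as CSV).
#'
#' @param model a fitted [fit_fpca()] model.
#' @param path output path.
#' @export
write_fpca_json <- function(model, path) {
  stopifnot(inherits(model, "fpca_model"))
  jsonlite::write_json(
    list(grid = model$grid, mean_fn = model$mean_fn,
         eigenfunctions = unname(model$eigenfunctions),
         eigenvalues = model$eigenvalues,
         explained_share = model$explained_share),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}
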