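#' Estimate a first-order transition model from profile sequences
#'
#' Pools within-subject consecutive pairs (never across subjects or blocks)
#' into an 8x8 count table and row-normalizes it.  Rows with zero counts are
#' flagged unobserved, not imputed.
#'
#' @param sequences data.frame with \code{subject_id}, \code{profile}
#'   (ordered by acquisition within subject) and optionally \code{block}.
#' @param states state labels (default the 8 profiles E1..L4).
#' @return object of class \code{"transition_model"}: \code{counts}
#'   (8x8), \code{P} (row-stochastic, NA rows where unobserved),
#'   \code{unobserved} (state labels), \code{n_transitions},
#'   \code{n_subjects}.
#' @export
estimate_transitions <- function(sequences,
                                 states = c("E1", "E2", "E3", "E4",
                                            "L1", "L2", "L3", "L4")) {
  stopifnot(all(c("subject_id", "profile") %in% names(sequences)))
  prof <- as.character(sequences$profile)
  if (!all(prof %in% states))
    stop("profiles outside the state set: ",
         paste(setdiff(unique(prof), states), collapse = ", "))
  K <- length(states)
  grp <- if (is.null(sequences$block)) as.character(sequences$subject_id)
         else paste(sequences$subject_id, sequences$block)
  idx <- match(prof, states)
  n <- length(idx)
  if (n < 2) stop("need a sequence of length >= 2")
  same <- grp[-n] == grp[-1]          # pairs never span subjects/blocks
  from <- idx[-n][same]
  to <- idx[-1][same]
  counts <- matrix(tabulate((from - 1L) * K + to, nbins = K * K),
                   K, K, byrow = TRUE, dimnames = list(states, states))
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, NA, rs)
  structure(list(counts = counts, P = P,
                 unobserved = states[rs == 0],
                 n_transitions = sum(counts),
                 n_subjects = length(unique(sequences$subject_id))),
            class = "transition_model")
}

#' Stationary distribution of a transition matrix
#'
#' Normalized left eigenvector of P at eigenvalue 1.  Errors when the
#' eigenvalue-1 eigenspace is not one-dimensional (e.g. the identity
#' matrix), in which case the caller may fall back to empirical occupancy.
#'
#' @param P row-stochastic matrix.
#' @param tol eigenvalue tolerance.
#' @return stationary probability vector (named like P's rows).
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  if (inherits(P, "transition_model")) P <- P$P
  if (any(is.na(P))) stop("P has unobserved rows")
  check_stochastic(P)
  e <- eigen(t(P))
  at_one <- abs(e$values - 1) < tol
  if (sum(at_one) == 0) stop("no eigenvalue 1 found")
  if (sum(at_one) > 1) stop("non-unique stationary distribution")
  v <- Re(e$vectors[, which(at_one)])
  pi <- v / sum(v)
  if (any(pi < -1e-9)) stop("negative stationary probabilities")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  names(pi) <- rownames(P)
  pi
}

#' Chi-squared occupancy contrast with adjusted standardized residuals
#'
#' Pearson chi-squared test of a state-occupancy contingency table (e.g.
#' groups x 8 profiles) with per-cell adjusted standardized residuals
#' \code{(O - E) / sqrt(E (1 - row share)(1 - col share))}; cells with
#' |z| > 1.96 are flagged as driving the effect.
#'
#' @param tab contingency table (matrix), rows = groups, cols = states.
#' @return list: \code{chisq}, \code{df}, \code{p}, \code{residuals_z},
#'   \code{flagged} (logical matrix), \code{expected}.
#' @export
occupancy_contrast <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, residuals_z = ct$stdres,
       flagged = abs(ct$stdres) > 1.96, expected = ct$expected)
}

#' Block (higher-order) sequence entropy
#'
#' Shannon entropy, in bits, of the empirical distribution of overlapping
#' length-k state blocks, pooled within a group but never spanning subject
#' (or block) boundaries.  Bounded by \code{k * log2(n_states)}; 0 for a
#' constant sequence.
#'
#' @param sequences data.frame with \code{subject_id}, \code{profile},
#'   optional \code{block}; or a list of character vectors.
#' @param k block length (default 3).
#' @return entropy in bits.
#' @export
sequence_entropy <- function(sequences, k = 3) {
  if (k < 1) stop("block length must be >= 1")
  seqs <- if (is.data.frame(sequences)) {
    grp <- if (is.null(sequences$block))
      sequences$subject_id else
      interaction(sequences$subject_id, sequences$block, drop = TRUE)
    split(as.character(sequences$profile), grp)
  } else sequences
  blocks <- unlist(lapply(seqs, function(s) {
    n <- length(s)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1),
           function(i) paste(s[i:(i + k - 1)], collapse = "|"), "")
  }))
  if (length(blocks) == 0) stop("no block of length ", k, " available")
  p <- table(blocks) / length(blocks)
  -sum(p * log2(p))
}

#' Subject-level bootstrap confidence intervals
#'
#' Resamples whole subjects (their full sequences) with replacement and
#' returns percentile confidence bounds of an arbitrary statistic of the
#' resampled group.
#'
#' @param sequences data.frame with \code{subject_id} and whatever the
#'   statistic needs.
#' @param statistic function taking a sequences data.frame and returning a
#'   numeric scalar, vector, or matrix (NA allowed for undefined cells).
#' @param n_boot replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list: \code{estimate} (statistic on the full data),
#'   \code{ci_low}, \code{ci_high} (same shape), \code{replicates}
#'   (n_boot x length matrix), \code{n_boot}.
#' @export
bootstrap_cis <- function(sequences, statistic, n_boot = 1000, conf = 0.95,
                          seed = 1) {
  subjects <- unique(sequences$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  est <- statistic(sequences)
  set.seed(seed)
  by_subj <- split(sequences, sequences$subject_id)
  reps <- matrix(NA_real_, n_boot, length(est))
  for (b in seq_len(n_boot)) {
    pick <- sample(subjects, replace = TRUE)
    boot <- do.call(rbind, lapply(seq_along(pick), function(j) {
      d <- by_subj[[pick[j]]]
      d$subject_id <- paste0("b", j)   # resampled copies are distinct
      d
    }))
    val <- tryCatch(statistic(boot), error = function(e) NULL)
    if (!is.null(val)) reps[b, ] <- as.numeric(val)
  }
  a <- (1 - conf) / 2
  lo <- apply(reps, 2, quantile, probs = a, na.rm = TRUE)
  hi <- apply(reps, 2, quantile, probs = 1 - a, na.rm = TRUE)
  shape <- function(v) { x <- est; x[] <- v; x }
  list(estimate = est, ci_low = shape(lo), ci_high = shape(hi),
       replicates = reps, n_boot = n_boot)
}

# statistic helper: flattened transition matrix of a sequences data.frame
transition_stat <- function(states) {
  function(d) estimate_transitions(d, states = states)$P
}

#' Between-group transition differences with bootstrap CIs
#'
#' Per-cell difference \code{P_A - P_B} with a percentile bootstrap CI of
#' the difference obtained by independent subject resampling within each
#' group.  A cell is significant when its CI excludes zero; bootstrap
#' sign-based p-values with optional Benjamini-Hochberg correction across
#' the 64 cells are also returned.  Cells unobserved in either group are
#' marked incomparable (NA).
#'
#' @param seq_a,seq_b sequences data.frames for the two groups.
#' @param states state labels.
#' @param n_boot bootstrap replicates per group.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @param bh apply BH across cells?
#' @return list: \code{diff}, \code{ci_low}, \code{ci_high},
#'   \code{significant} (CI excludes 0), \code{p} (bootstrap sign p),
#'   \code{p_adj} (if \code{bh}), \code{incomparable} (logical matrix).
#' @export
compare_groups <- function(seq_a, seq_b,
                           states = c("E1", "E2", "E3", "E4",
                                      "L1", "L2", "L3", "L4"),
                           n_boot = 1000, conf = 0.95, seed = 1,
                           bh = FALSE) {
  st <- transition_stat(states)
  ba <- bootstrap_cis(seq_a, st, n_boot = n_boot, conf = conf, seed = seed)
  bb <- bootstrap_cis(seq_b, st, n_boot = n_boot, conf = conf,
                      seed = seed + 1)
  d <- ba$estimate - bb$estimate
  dreps <- ba$replicates - bb$replicates
  a <- (1 - conf) / 2
  lo <- apply(dreps, 2, quantile, probs = a, na.rm = TRUE)
  hi <- apply(dreps, 2, quantile, probs = 1 - a, na.rm = TRUE)
  shape <- function(v) { x <- d; x[] <- v; x }
  ci_low <- shape(lo); ci_high <- shape(hi)
  p <- apply(dreps, 2, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(NA_real_)
    2 * min(mean(r <= 0), mean(r >= 0))
  })
  p <- shape(pmin(p, 1))
  incomparable <- is.na(d)
  significant <- !incomparable & (ci_low > 0 | ci_high < 0)
  out <- list(diff = d, ci_low = ci_low, ci_high = ci_high,
              significant = significant, p = p,
              incomparable = incomparable)
  if (bh) {
    padj <- p
    padj[] <- p.adjust(as.numeric(p), method = "BH")
    out$p_adj <- padj
  }
  out
}

#' Significant within-group transitions and attractor states
#'
#' Tests each cell of the transition count table against the independence
#' expectation via adjusted standardized residuals, converts them to normal
#' two-sided p-values, and adjusts across the 64 cells by
#' Benjamini-Hochberg.  A state is an attractor when its self-transition
#' probability exceeds \code{attractor_threshold}.  Edges below
#' \code{visibility_threshold} are marked hidden for plotting only.
#'
#' @param model a [estimate_transitions()] model.
#' @param attractor_threshold self-transition probability defining an
#'   attractor.
#' @param visibility_threshold plot-only edge visibility cut.
#' @param alpha significance level on the adjusted p-values.
#' @return list: \code{residuals_z}, \code{p_adj}, \code{significant}
#'   (logical matrix), \code{attractors} (state labels), \code{graph}
#'   (data.frame of edges: from, to, p_transition, significant, visible).
#' @export
within_group_significant_transitions <- function(model,
                                                 attractor_threshold = 0.45,
                                                 visibility_threshold = 0.10,
                                                 alpha = 0.05) {
  stopifnot(inherits(model, "transition_model"))
  counts <- model$counts
  keep <- rowSums(counts) > 0 & colSums(counts) > 0
  ct <- suppressWarnings(chisq.test(counts[keep, keep, drop = FALSE],
                                    correct = FALSE))
  z <- matrix(NA_real_, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  z[keep, keep] <- ct$stdres
  p <- 2 * pnorm(-abs(z))
  p_adj <- p
  p_adj[] <- p.adjust(as.numeric(p), method = "BH")
  significant <- !is.na(p_adj) & p_adj < alpha & z > 0
  attractors <- rownames(counts)[!is.na(diag(model$P)) &
                                   diag(model$P) > attractor_threshold]
  edges <- which(!is.na(model$P) & model$P > 0, arr.ind = TRUE)
  graph <- data.frame(from = rownames(counts)[edges[, 1]],
                      to = colnames(counts)[edges[, 2]],
                      p_transition = model$P[edges],
                      significant = significant[edges],
                      visible = model$P[edges] > visibility_threshold)
  list(residuals_z = z, p_adj = p_adj, significant = significant,
       attractors = attractors, graph = graph)
}

#' Group entropies and pairwise contrasts with bootstrap CIs
#'
#' Computes each group's block entropy with a subject-level bootstrap CI,
#' then every pairwise difference with a CI from the independent group
#' bootstrap replicates, and reports the entropy ordering.
#'
#' @param groups named list of sequences data.frames.
#' @param k block length.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list: \code{entropy} (data.frame: group, estimate, ci_low,
#'   ci_high), \code{contrasts} (data.frame: a, b, diff, ci_low, ci_high,
#'   significant), \code{ordering} (group names, decreasing entropy).
#' @export
entropy_contrast <- function(groups, k = 3, n_boot = 1000, conf = 0.95,
                             seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  stat <- function(d) sequence_entropy(d, k = k)
  boots <- lapply(seq_along(groups), function(i)
    bootstrap_cis(groups[[i]], stat, n_boot = n_boot, conf = conf,
                  seed = seed + i))
  names(boots) <- names(groups)
  # percentile bounds extended to the point estimate: the plug-in block
  # entropy is biased downward under subject resampling, which can push the
  # whole percentile interval below the estimate for small groups
  ent <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, estimate = boots[[g]]$estimate,
               ci_low = min(unname(boots[[g]]$ci_low),
                            boots[[g]]$estimate),
               ci_high = max(unname(boots[[g]]$ci_high),
                             boots[[g]]$estimate))))
  a <- (1 - conf) / 2
  pairs <- utils::combn(names(groups), 2)
  contrasts <- do.call(rbind, apply(pairs, 2, function(pr) {
    dr <- boots[[pr[1]]]$replicates[, 1] - boots[[pr[2]]]$replicates[, 1]
    lo <- quantile(dr, a, na.rm = TRUE)
    hi <- quantile(dr, 1 - a, na.rm = TRUE)
    data.frame(a = pr[1], b = pr[2],
               diff = boots[[pr[1]]]$estimate - boots[[pr[2]]]$estimate,
               ci_low = unname(lo), ci_high = unname(hi),
               significant = lo > 0 | hi < 0)
  }))
  list(entropy = ent,
       contrasts = contrasts,
       ordering = ent$group[order(ent$estimate, decreasing = TRUE)])
}
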