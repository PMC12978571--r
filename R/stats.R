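#' Mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Aggregates the response to one cell mean per subject x within-factor
#' cell, fits the multivariate linear model of the wide cell-mean table on
#' the between-subject design (sum-to-zero contrasts, type-III sums of
#' squares), and extracts the univariate mixed-design table with
#' Greenhouse-Geisser epsilon and corrected p-values from
#' \code{car::Anova}.  Subjects with incomplete within-cells are dropped
#' listwise and reported.
#'
#' @param data long-format data.frame.
#' @param dv response column name.
#' @param subject subject id column name.
#' @param within character vector of within-subject factor columns.
#' @param between character vector of between-subject factor columns
#'   (optional).
#' @return list: \code{table} (data.frame: effect, df_num, df_den, F, pes,
#'   gg_epsilon, p_uncorrected, p_gg), \code{dropped_subjects},
#'   \code{anova} (the car object).
#' @export
rm_anova <- function(data, dv, subject, within, between = character(0)) {
  for (v in c(dv, subject, within, between))
    if (!v %in% names(data)) stop("column not found: ", v)
  data[[subject]] <- factor(data[[subject]])
  for (v in c(within, between)) data[[v]] <- factor(data[[v]])
  agg <- aggregate(data[[dv]],
                   by = c(lapply(data[c(subject, within)], identity)),
                   FUN = mean)
  names(agg) <- c(subject, within, ".y")
  idata <- expand.grid(lapply(agg[within], levels),
                       KEEP.OUT.ATTRS = FALSE)
  names(idata) <- within
  cellkey <- function(d) interaction(d[within], drop = FALSE, sep = ":")
  agg$.cell <- factor(cellkey(agg), levels = levels(cellkey(idata)))
  n_cells <- nrow(idata)
  wide <- reshape(agg[, c(subject, ".cell", ".y")], timevar = ".cell",
                  idvar = subject, direction = "wide")
  complete <- rowSums(is.na(wide[, -1, drop = FALSE])) == 0
  dropped <- as.character(wide[[subject]][!complete])
  wide <- wide[complete, ]
  if (nrow(wide) < 2) stop("fewer than 2 complete subjects")
  Y <- as.matrix(wide[, paste0(".y.", levels(agg$.cell)), drop = FALSE])
  oc <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(oc), add = TRUE)
  if (length(between)) {
    bt <- unique(data[c(subject, between)])
    bt <- bt[match(wide[[subject]], bt[[subject]]), , drop = FALSE]
    bform <- as.formula(paste("Y ~", paste(between, collapse = " * ")))
    environment(bform) <- environment()
    mlm <- lm(bform, data = bt)
  } else {
    mlm <- lm(Y ~ 1)
  }
  idesign <- as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  eff <- rownames(ut)
  res <- data.frame(
    effect = eff,
    df_num = ut[, "num Df"], df_den = ut[, "den Df"],
    F = ut[, "F value"],
    pes = ut[, "Sum Sq"] / (ut[, "Sum Sq"] + ut[, "Error SS"]),
    gg_epsilon = NA_real_,
    p_uncorrected = ut[, "Pr(>F)"], p_gg = ut[, "Pr(>F)"],
    row.names = NULL)
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa) > 0) {
    m <- match(rownames(pa), res$effect)
    res$gg_epsilon[m] <- pa[, "GG eps"]
    res$p_gg[m] <- pa[, "Pr(>F[GG])"]
  }
  # within effects with a single numerator df are spherical by construction
  within_eff <- vapply(res$effect, function(e)
    any(vapply(within, function(wv) grepl(wv, e, fixed = TRUE), TRUE)), TRUE)
  res$gg_epsilon[within_eff & is.na(res$gg_epsilon)] <- 1
  res <- res[res$effect != "(Intercept)", ]
  list(table = res, dropped_subjects = dropped, anova = av)
}

# drop non-significant highest-order interaction terms by LRT (ML refits)
prune_interactions_lrt <- function(rhs, data, subject, alpha = 0.05) {
  repeat {
    full <- as.formula(paste("y ~", rhs, "+ (1|", subject, ")"))
    tt <- attr(terms(as.formula(paste("~", rhs))), "term.labels")
    ord <- attr(terms(as.formula(paste("~", rhs))), "order")
    if (max(ord) < 2) return(rhs)
    cand <- tt[ord == max(ord)]
    m_full <- suppressMessages(suppressWarnings(
      lme4::lmer(full, data = data, REML = FALSE)))
    drop_any <- FALSE
    for (trm in cand) {
      red <- setdiff(tt, trm)
      f_red <- as.formula(paste("y ~", paste(red, collapse = " + "),
                                "+ (1|", subject, ")"))
      m_red <- suppressMessages(suppressWarnings(
        lme4::lmer(f_red, data = data, REML = FALSE)))
      p <- anova(m_red, m_full)[2, "Pr(>Chisq)"]
      if (is.na(p) || p > alpha) {
        tt <- red
        rhs <- paste(tt, collapse = " + ")
        drop_any <- TRUE
        break
      }
    }
    if (!drop_any) return(rhs)
  }
}

#' Pointwise functional mixed-model contrast
#'
#' Approximates a functional mixed model by fitting, at every grid point of
#' the normalized trajectories, a linear mixed model with the supplied
#' fixed-effect structure and a subject random intercept, then adjusting
#' each coefficient's p-values across grid points by Benjamini-Hochberg.
#' Optionally, non-significant highest-order interactions are pruned first
#' by likelihood-ratio tests on the time-averaged response.  Grid points
#' where the fit fails are flagged and left NA.
#'
#' @param Y trials x grid trajectory matrix.
#' @param data per-trial data.frame holding the model variables.
#' @param fixed right-hand-side fixed-effect formula, e.g.
#'   \code{~ arm * is_threat}.
#' @param subject subject id column name in \code{data}.
#' @param prune prune higher-order interactions by LRT first?
#' @param q BH level used for the significance masks.
#' @return list: \code{grid_index}, \code{terms}, \code{estimate} /
#'   \code{p} / \code{p_adj} (grid x term matrices), \code{significant}
#'   (logical grid x term), \code{failed} (logical per grid point),
#'   \code{pruned_rhs}.
#' @export
pointwise_functional_contrast <- function(Y, data, fixed, subject =
                                            "subject_id", prune = TRUE,
                                          q = 0.05) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(data), subject %in% names(data))
  rhs <- paste(deparse(fixed[[2]]), collapse = "")
  d <- data
  if (prune) {
    d$y <- rowMeans(Y)
    rhs <- prune_interactions_lrt(rhs, d, subject)
  }
  G <- ncol(Y)
  form <- as.formula(paste("y ~", rhs, "+ (1|", subject, ")"))
  est <- pmat <- NULL
  failed <- logical(G)
  for (g in seq_len(G)) {
    d$y <- Y[, g]
    m <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d))), error = function(e) NULL)
    if (is.null(m)) { failed[g] <- TRUE; next }
    co <- summary(m)$coefficients
    if (is.null(est)) {
      est <- matrix(NA_real_, G, nrow(co), dimnames = list(NULL,
                                                           rownames(co)))
      pmat <- est
    }
    est[g, rownames(co)] <- co[, "Estimate"]
    pmat[g, rownames(co)] <- co[, "Pr(>|t|)"]
  }
  if (is.null(est)) stop("model failed at every grid point")
  p_adj <- apply(pmat, 2, p.adjust, method = "BH")
  list(grid_index = seq_len(G), terms = colnames(est), estimate = est,
       p = pmat, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj <= q, failed = failed,
       pruned_rhs = rhs)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjustment of a p-value family with the rejection set at level
#' \code{q}.
#'
#' @param p p-values in [0, 1] (NA allowed and preserved).
#' @param q FDR level.
#' @return list: \code{p_adj} (same order as input), \code{reject}
#'   (logical).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(p_adj = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p_adj <- p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = !is.na(p_adj) & p_adj <= q)
}
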