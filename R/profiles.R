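#' Mean silhouette coefficient
#'
#' Standard silhouette over Euclidean distances.  For large inputs a seeded
#' subsample of \code{max_n} points is scored (the full distance matrix is
#' quadratic in n).
#'
#' @param X numeric matrix (points x features) or vector.
#' @param labels integer/factor cluster labels.
#' @param max_n subsample cap.
#' @param seed subsample seed.
#' @return mean silhouette width in [-1, 1].
#' @export
silhouette_mean <- function(X, labels, max_n = 2000, seed = 1) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (n > max_n) {
    set.seed(seed)
    i <- sample.int(n, max_n)
    X <- X[i, , drop = FALSE]; labels <- labels[i]
  }
  D <- as.matrix(dist(X))
  n <- nrow(D)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { sil[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(D[i, labels == k]), 0))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' \code{(B/(k-1)) / (W/(n-k))}.
#'
#' @inheritParams silhouette_mean
#' @return CH index (larger = better separated).
#' @export
ch_index <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X); k <- length(unique(labels))
  if (k < 2) stop("need at least 2 clusters")
  gm <- colMeans(X)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ci)^2)
    B <- B + nrow(Xi) * sum((ci - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Level-1 clustering: early vs late responses on log jTTC
#'
#' k-means with k = 2 on the one-dimensional log-transformed responses
#' (multiple restarts, seeded).  The cluster with the smaller centroid is
#' labeled E (early), the other L (late).  A silhouette below
#' \code{sil_flag} marks the two-cluster structure as weak.
#'
#' @param jttc judged times-to-collision in seconds (positive).
#' @param nstart k-means restarts.
#' @param seed RNG seed.
#' @param sil_flag threshold below which the split is flagged; silhouettes
#'   of forced one-dimensional 2-splits run high (about 0.57 even for
#'   unimodal log-normal data, above 0.8 for well-separated mixtures), so
#'   the flag sits between those reference shapes.
#' @return list: \code{labels} (factor E/L), \code{centroids_log} (named,
#'   E < L), \code{silhouette}, \code{weak} flag.
#' @export
cluster_level1 <- function(jttc, nstart = 50, seed = 1, sil_flag = 0.65) {
  if (any(jttc <= 0)) stop("jttc must be positive")
  x <- log(jttc)
  if (length(unique(x)) < 2) stop("degenerate: all responses identical")
  set.seed(seed)
  km <- kmeans(x, centers = 2, nstart = nstart, iter.max = 50)
  e_cl <- which.min(km$centers)
  labels <- factor(ifelse(km$cluster == e_cl, "E", "L"), levels = c("E", "L"))
  sil <- silhouette_mean(matrix(x), labels, seed = seed)
  list(labels = labels,
       centroids_log = c(E = min(km$centers), L = max(km$centers)),
       silhouette = sil, weak = sil < sil_flag)
}

#' Level-2 clustering: component scores within a behavioral subgroup
#'
#' Standardizes the retained component scores within the subgroup, runs
#' k-means for each candidate k, and selects the k maximizing the rank-sum
#' of the Calinski-Harabasz index and mean silhouette (ties to the smaller
#' k).  Cluster indices are relabeled in order of descending cluster size.
#'
#' @param scores trials x components score matrix (one behavioral subgroup).
#' @param k_range candidate cluster counts.
#' @param nstart k-means restarts.
#' @param seed RNG seed.
#' @param min_per_k required trials per candidate cluster; subgroups smaller
#'   than \code{max(k_range) * min_per_k} are reported unclustered.
#' @param sil_flag silhouette level below which the chosen solution is
#'   flagged.
#' @return list: \code{labels} (integer, 1 = largest cluster), \code{k},
#'   \code{centers} (on the standardized scale), \code{scaling} (center/sd),
#'   \code{metrics} (per-k CH and silhouette), \code{weak} flag; or
#'   \code{list(unclustered = TRUE)} when too small.
#' @export
cluster_level2 <- function(scores, k_range = 2:6, nstart = 50, seed = 1,
                           min_per_k = 5, sil_flag = 0.3) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < max(k_range) * min_per_k)
    return(list(unclustered = TRUE, n = n))
  ctr <- colMeans(scores)
  sds <- apply(scores, 2, sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(scores, 2, ctr), 2, sds, "/")
  fits <- list(); ch <- sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed + i)
    fits[[i]] <- kmeans(Z, centers = k_range[i], nstart = nstart,
                        iter.max = 50)
    ch[i] <- ch_index(Z, fits[[i]]$cluster)
    sil[i] <- silhouette_mean(Z, fits[[i]]$cluster, seed = seed)
  }
  score_rank <- rank(ch, ties.method = "average") +
    rank(sil, ties.method = "average")
  best <- which(score_rank == max(score_rank))[1]   # ties -> smaller k
  km <- fits[[best]]
  ord <- order(tabulate(km$cluster, nbins = k_range[best]),
               decreasing = TRUE)
  relab <- match(km$cluster, ord)
  list(labels = relab, k = k_range[best],
       centers = km$centers[ord, , drop = FALSE],
       scaling = list(center = ctr, sd = sds),
       metrics = data.frame(k = k_range, ch = ch, silhouette = sil),
       weak = sil[best] < sil_flag)
}

#' Two-level profile assignment (E1-E4 / L1-L4)
#'
#' Combines the level-1 behavioral split on log jTTC with level-2 k-means on
#' the retained component scores within each subgroup into joint profile
#' labels.
#'
#' @param jttc per-trial responses (s).
#' @param scores trials x retained-components score matrix (aligned).
#' @param k_range,nstart,seed passed to the clustering levels.
#' @param k2 optional fixed level-2 k (skips model selection).
#' @return list: \code{profile} (factor, e.g. E1..E4/L1..L4), \code{level1},
#'   \code{level2} (per-subgroup results), \code{labels1} (E/L factor).
#' @export
assign_profiles <- function(jttc, scores, k_range = 2:6, nstart = 50,
                            seed = 1, k2 = NULL) {
  scores <- as.matrix(scores)
  stopifnot(length(jttc) == nrow(scores))
  l1 <- cluster_level1(jttc, nstart = nstart, seed = seed)
  profile <- character(length(jttc))
  level2 <- list()
  for (g in c("E", "L")) {
    i <- which(l1$labels == g)
    kr <- if (is.null(k2)) k_range else k2
    l2 <- cluster_level2(scores[i, , drop = FALSE], k_range = kr,
                         nstart = nstart, seed = seed)
    level2[[g]] <- l2
    if (isTRUE(l2$unclustered)) profile[i] <- paste0(g, "?")
    else profile[i] <- paste0(g, l2$labels)
  }
  lev <- unique(c(t(outer(c("E", "L"), 1:4, paste0))))
  lev <- c(lev[lev %in% profile], setdiff(unique(profile), lev))
  list(profile = factor(profile, levels = lev),
       level1 = l1, level2 = level2, labels1 = l1$labels)
}

#' Bootstrap stability of a clustering
#'
#' Resamples trials with replacement, reclusters each replicate with the
#' same k, and scores the adjusted Rand index between the replicate labels
#' and the reference labels restricted to the resampled points.
#'
#' @param X data matrix used for the reference clustering (standardized as
#'   clustered).
#' @param ref_labels reference cluster labels.
#' @param k number of clusters.
#' @param n_boot bootstrap replicates.
#' @param nstart k-means restarts per replicate.
#' @param seed RNG seed.
#' @return list: \code{mean}, \code{sd}, \code{ari} (per-replicate values),
#'   \code{n_failed}.
#' @export
bootstrap_stability <- function(X, ref_labels, k, n_boot = 1000,
                                nstart = 10, seed = 1) {
  X <- as.matrix(X)
  set.seed(seed)
  ari <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(nrow(X), replace = TRUE)
    km <- tryCatch(suppressWarnings(
      kmeans(X[i, , drop = FALSE], centers = k, nstart = nstart,
             iter.max = 50)),
                   error = function(e) NULL)
    if (is.null(km)) next
    ari[b] <- mclust::adjustedRandIndex(km$cluster, ref_labels[i])
  }
  ok <- !is.na(ari)
  list(mean = mean(ari[ok]), sd = sd(ari[ok]), ari = ari,
       n_failed = sum(!ok))
}

# all permutations of 1..k (k <= 7 is plenty here)
perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    m <- cbind(i, sub + (sub >= i))
    out <- rbind(out, m)
  }
  out
}

#' Accuracy of labels after optimal cluster matching
#'
#' Maximum agreement between two labelings over all permutations of the
#' predicted cluster ids (exact assignment by enumeration; k is small).
#'
#' @param pred predicted cluster labels (integers 1..k).
#' @param truth reference labels (integers 1..k).
#' @param k number of clusters.
#' @return accuracy in [0, 1].
#' @export
matched_accuracy <- function(pred, truth, k) {
  P <- perms(k)
  best <- 0
  for (r in seq_len(nrow(P))) {
    acc <- mean(P[r, pred] == truth)
    if (acc > best) best <- acc
  }
  best
}

#' Cross-validated cluster assignment accuracy
#'
#' Splits trials into folds; for each fold, k-means centroids are fitted on
#' the training portion and held-out trials are assigned to the nearest
#' centroid; accuracy is the agreement with the full-data labels after
#' optimal label matching.
#'
#' @param X data matrix (standardized as clustered).
#' @param labels full-data cluster labels (integers 1..k).
#' @param k number of clusters.
#' @param n_folds folds.
#' @param nstart k-means restarts.
#' @param seed RNG seed.
#' @return list: \code{mean}, \code{sd}, \code{fold_accuracy},
#'   \code{n_skipped}.
#' @export
cross_validate_clusters <- function(X, labels, k, n_folds = 5, nstart = 25,
                                    seed = 1) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  n <- nrow(X)
  if (n < n_folds * k) stop("too few trials for ", n_folds, "-fold CV")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  acc <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    train <- fold != f
    km <- tryCatch(suppressWarnings(
      kmeans(X[train, , drop = FALSE], centers = k, nstart = nstart,
             iter.max = 50)),
                   error = function(e) NULL)
    if (is.null(km) || nrow(km$centers) < k) next
    D <- as.matrix(dist(rbind(km$centers, X[!train, , drop = FALSE])))
    assign <- apply(D[-(1:k), 1:k, drop = FALSE], 1, which.min)
    acc[f] <- matched_accuracy(assign, labels[!train], k)
  }
  ok <- !is.na(acc)
  list(mean = mean(acc[ok]), sd = sd(acc[ok]), fold_accuracy = acc,
       n_skipped = sum(!ok))
}

#' Subject-level subgroup proportions vs power-law parameters
#'
#' Correlates each subject's proportion of early (E) and late (L) trials
#' with the subject's fitted alpha and beta (Pearson), adjusting the family
#' of four tests by Benjamini-Hochberg.  Since proportions sum to 1 the E
#' and L correlations are exactly opposite in sign.
#'
#' @param subject_id per-trial subject ids.
#' @param labels1 per-trial E/L labels.
#' @param fits per-subject parameter table with \code{subject_id, alpha,
#'   beta} (averaged over conditions if fitted per condition).
#' @return data.frame: subgroup, parameter, r, p, p_adj, n.
#' @export
proportion_correlations <- function(subject_id, labels1, fits) {
  prop_e <- tapply(labels1 == "E", subject_id, mean)
  par <- aggregate(fits[, c("alpha", "beta")],
                   by = list(subject_id = fits$subject_id), FUN = mean)
  common <- intersect(names(prop_e), par$subject_id)
  pe <- prop_e[common]
  par <- par[match(common, par$subject_id), ]
  rows <- list()
  for (sg in c("E", "L")) {
    p_sg <- if (sg == "E") pe else 1 - pe
    for (pm in c("alpha", "beta")) {
      if (sd(p_sg) == 0) {
        rows[[paste(sg, pm)]] <- data.frame(subgroup = sg, parameter = pm,
                                            r = NA_real_, p = NA_real_,
                                            n = length(common))
      } else {
        ct <- cor.test(p_sg, par[[pm]])
        rows[[paste(sg, pm)]] <- data.frame(subgroup = sg, parameter = pm,
                                            r = unname(ct$estimate),
                                            p = ct$p.value,
                                            n = length(common))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Profile score-sign summary
#'
#' Characterizes each profile by the sign of its mean standardized component
#' scores: "+" / "-" when the absolute mean z exceeds \code{neutral_z},
#' otherwise "~0".
#'
#' @param profile per-trial profile labels.
#' @param scores trials x components score matrix.
#' @param neutral_z threshold for the neutral band.
#' @return data.frame: profile, one sign column per component, n.
#' @export
profile_sign_summary <- function(profile, scores, neutral_z = 0.2) {
  scores <- as.matrix(scores)
  Z <- scale(scores)
  rows <- lapply(levels(factor(profile)), function(p) {
    i <- profile == p
    mz <- colMeans(Z[i, , drop = FALSE])
    signs <- ifelse(abs(mz) < neutral_z, "~0", ifelse(mz > 0, "+", "-"))
    out <- data.frame(profile = p, n = sum(i))
    for (j in seq_along(signs)) out[[paste0("PC", j)]] <- signs[j]
    out
  })
  do.call(rbind, rows)
}
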