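#' PAM clustering on a distance matrix
#'
#' Partitioning around medoids: BUILD initialization followed by
#' best-improvement SWAP local search to convergence, operating directly
#' on the distances. Ties break toward the lowest sample index, and the
#' total cost `sum d(i, medoid(i))` is non-increasing across swaps.
#' Clusters are numbered by ascending medoid index so results are
#' invariant to input order up to relabeling.
#'
#' @param dist square distance matrix.
#' @param k number of clusters, `2 <= k < n` (k = 1 is allowed for
#'   internal use).
#' @return list with `assignments` (1..k per sample, named), `medoid_ids`
#'   and `cost`.
#' @export
pam_cluster <- function(dist, k) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1) stop("k must be at least 1")
  res <- .pam_cpp(D, as.integer(k))
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  list(assignments = stats::setNames(res$assignments, ids),
       medoid_ids = ids[res$medoids],
       cost = res$cost)
}

#' Calinski-Harabasz index from distances
#'
#' Distance-only formulation: within-cluster dispersion
#' `W = sum_c (1/n_c) sum_{i<j in c} d_ij^2`, total dispersion
#' `T = (1/n) sum_{i<j} d_ij^2`, `B = T - W`, and
#' `CH = (B / (k-1)) / (W / (n-k))`. On Euclidean-embeddable distance
#' matrices this equals the familiar centroid-based form computed in
#' full principal-coordinate space.
#'
#' @param dist square distance matrix.
#' @param assignments cluster labels (>= 2 nonempty clusters).
#' @return CH value (`Inf` when `W` is exactly 0).
#' @export
ch_index <- function(dist, assignments) {
  D2 <- as.matrix(dist)^2
  n <- nrow(D2)
  cl <- as.character(assignments)
  k <- length(unique(cl))
  if (k < 2) stop("need at least 2 clusters")
  tot <- sum(D2[upper.tri(D2)]) / n
  W <- 0
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1) {
      sub <- D2[idx, idx]
      W <- W + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  B <- tot - W
  if (W <= 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by the CH curve
#'
#' Runs [pam_cluster()] for each k in `k_range` and returns the k
#' maximizing the Calinski-Harabasz index (ties to the smallest k). The
#' result is flagged `weak_structure` when the curve has no interior
#' peak (its maximum sits at the smallest scanned k, the signature of a
#' structureless cloud, whose CH declines monotonically from k = 2) or
#' when the maximum is within 1.2x of the curve's median.
#'
#' @param dist square distance matrix.
#' @param k_range candidate cluster counts.
#' @return list with `best_k`, `ch_curve` (named by k), `weak_structure`.
#' @export
select_k <- function(dist, k_range = 2:10) {
  D <- as.matrix(dist)
  k_range <- k_range[k_range >= 2 & k_range < nrow(D)]
  if (!length(k_range)) stop("empty usable k_range")
  if (length(k_range) == 1) warning("k_range of length 1")
  ch <- vapply(k_range, function(k) {
    cl <- pam_cluster(D, k)
    ch_index(D, cl$assignments)
  }, numeric(1))
  names(ch) <- k_range
  best <- k_range[which.max(ch)]
  list(best_k = best, ch_curve = ch,
       weak_structure = best == min(k_range) ||
         max(ch) < 1.2 * median(ch))
}

#' LDA effect-size marker ranking
#'
#' A LEfSe-style biomarker score, fully specified and deterministic
#' under a seed. Features (relative abundances, rescaled to a per-million
#' scale) are first screened per feature by a Kruskal-Wallis test across
#' classes at level `alpha`; for each class, one-vs-rest two-class
#' Fisher LDA is bootstrapped (`n_boot` rounds of 2/3 per-class
#' subsampling, ridge-stabilized within-class covariance). The per-round
#' effect of feature j is `0.5 * (|d_lda_j| + |d_raw_j|)` where
#' `d_raw_j` is the class-mean difference and
#' `d_lda_j = w_j * (w . d_raw)` with `w` the unit-norm discriminant;
#' the score is `log10` of the mean effect over rounds. Features with
#' score at or above `lda_threshold` are returned ranked by score.
#'
#' @param table a [taxon_profile_table()] or samples x features matrix.
#' @param class_labels per-sample class labels (>= 2 classes, each with
#'   >= 3 samples).
#' @param alpha Kruskal-Wallis screening level.
#' @param lda_threshold minimum log10 effect score (the field's
#'   conventional 2.0 default).
#' @param n_boot bootstrap rounds.
#' @param seed integer seed.
#' @return data.frame (class, taxon_id, lda_score, kw_p, enriched_mean,
#'   rest_mean) ranked by descending score within class.
#' @export
lda_effect_scores <- function(table, class_labels, alpha = 0.05,
                              lda_threshold = 2.0, n_boot = 30,
                              seed = 1) {
  X <- if (inherits(table, "taxon_profile_table")) table$relabund else table
  cl <- as.character(class_labels)
  stopifnot(nrow(X) == length(cl))
  tab <- table(cl)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 3)) stop("every class needs >= 3 samples")
  Xm <- X * 1e6
  keep <- apply(Xm, 2, function(v) sd(v) > 0)
  kw_p <- rep(NA_real_, ncol(Xm))
  kw_p[keep] <- apply(Xm[, keep, drop = FALSE], 2, function(v)
    suppressWarnings(kruskal.test(v, factor(cl))$p.value))
  sel <- which(keep & !is.na(kw_p) & kw_p < alpha)
  if (!length(sel)) return(empty_marker_table())
  Z <- Xm[, sel, drop = FALSE]
  classes <- sort(unique(cl))
  set.seed(seed)
  out <- list()
  for (g in classes) {
    y <- cl == g
    eff <- matrix(NA_real_, n_boot, ncol(Z))
    for (b in seq_len(n_boot)) {
      idx1 <- which(y); idx0 <- which(!y)
      s1 <- sample(idx1, ceiling(2 / 3 * length(idx1)))
      s0 <- sample(idx0, ceiling(2 / 3 * length(idx0)))
      eff[b, ] <- lda_round_effect(Z[s1, , drop = FALSE],
                                   Z[s0, , drop = FALSE])
    }
    mean_eff <- colMeans(eff)
    score <- log10(pmax(mean_eff, 1e-30))
    m1 <- colMeans(Z[y, , drop = FALSE])
    m0 <- colMeans(Z[!y, , drop = FALSE])
    res <- data.frame(class = g, taxon_id = colnames(Z),
                      lda_score = score, kw_p = kw_p[sel],
                      enriched_mean = m1 / 1e6, rest_mean = m0 / 1e6,
                      stringsAsFactors = FALSE)
    res <- res[res$lda_score >= lda_threshold & m1 > m0, , drop = FALSE]
    out[[g]] <- res[order(-res$lda_score), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) empty_marker_table() else res
}

empty_marker_table <- function() {
  data.frame(class = character(0), taxon_id = character(0),
             lda_score = numeric(0), kw_p = numeric(0),
             enriched_mean = numeric(0), rest_mean = numeric(0),
             stringsAsFactors = FALSE)
}

lda_round_effect <- function(Z1, Z0) {
  m1 <- colMeans(Z1); m0 <- colMeans(Z0)
  d_raw <- m1 - m0
  p <- ncol(Z1)
  S <- (crossprod(scale(Z1, scale = FALSE)) +
          crossprod(scale(Z0, scale = FALSE))) /
    (nrow(Z1) + nrow(Z0) - 2)
  S <- S + diag(1e-6 * max(sum(diag(S)), 1e-12) / p, p)
  w <- tryCatch(solve(S, d_raw), error = function(e) d_raw)
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  d_lda <- w * sum(w * d_raw)
  0.5 * (abs(d_lda) + abs(d_raw))
}

#' Full urotyping pipeline
#'
#' root-JSD distances, CH-based selection of k (or an override), PAM
#' clustering, one-vs-rest LDA effect-size marker ranking per cluster,
#' and the dominant taxon (rank-1 marker) per cluster.
#'
#' @param table a feature-filtered species-level
#'   [taxon_profile_table()].
#' @param k_range candidate cluster counts for [select_k()].
#' @param k_override force this k instead of scanning.
#' @param lda_threshold marker score floor (see [lda_effect_scores()]);
#'   the dominant taxon is taken from the unthresholded ranking so a
#'   cluster always has one.
#' @param seed integer seed.
#' @return an object of class `urotype_model`: `k`, `assignments`,
#'   `medoid_ids`, `ch_curve`, `markers`, `dominant_taxon`.
#' @export
assign_urotypes <- function(table, k_range = 2:10, k_override = NULL,
                            lda_threshold = 2.0, seed = 1) {
  D <- beta_distance(table, "jsd_root")
  if (is.null(k_override)) {
    sk <- select_k(D, k_range)
    k <- sk$best_k; curve <- sk$ch_curve
  } else {
    k <- k_override
    curve <- stats::setNames(ch_index(D, pam_cluster(D, k)$assignments), k)
  }
  cl <- pam_cluster(D, k)
  markers_all <- lda_effect_scores(table, cl$assignments,
                                   lda_threshold = -Inf, seed = seed)
  dominant <- vapply(as.character(seq_len(k)), function(g) {
    sub <- markers_all[markers_all$class == g, ]
    if (!nrow(sub)) NA_character_ else sub$taxon_id[1]
  }, character(1))
  structure(list(k = k,
                 assignments = cl$assignments,
                 medoid_ids = cl$medoid_ids,
                 ch_curve = curve,
                 markers = markers_all[markers_all$lda_score >=
                                         lda_threshold, ],
                 dominant_taxon = dominant,
                 seed = seed),
            class = "urotype_model")
}

#' @export
print.urotype_model <- function(x, ...) {
  cat(sprintf("urotype_model: k = %d over %d samples\n", x$k,
              length(x$assignments)))
  sz <- table(x$assignments)
  for (g in names(sz))
    cat(sprintf("  urotype %s: n = %d (%.1f%%), dominant %s\n", g, sz[g],
                100 * sz[g] / length(x$assignments),
                display_name(x$dominant_taxon[as.integer(g)])))
  invisible(x)
}

#' Welch t-tests of each urotype's dominant taxon
#'
#' Tests, per cluster, whether the dominant taxon's relative abundance
#' differs between that cluster and all other samples (Welch two-sample
#' t-test), with BH adjustment across clusters.
#'
#' @param table the profile table used for clustering.
#' @param model a `urotype_model`.
#' @return data.frame (cluster, taxon_id, t, p_value, q_value).
#' @export
dominant_enrichment_tests <- function(table, model) {
  X <- table$relabund
  res <- lapply(seq_len(model$k), function(g) {
    tid <- model$dominant_taxon[g]
    v <- X[, tid]
    inside <- model$assignments == g
    if (sd(v[inside]) == 0 && sd(v[!inside]) == 0) {
      data.frame(cluster = g, taxon_id = tid, t = 0, p_value = 1,
                 degenerate = TRUE)
    } else {
      tt <- t.test(v[inside], v[!inside])
      data.frame(cluster = g, taxon_id = tid, t = unname(tt$statistic),
                 p_value = tt$p.value, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b two label vectors over the same samples.
#' @return ARI in `[-1, 1]`; 1 means identical up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
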