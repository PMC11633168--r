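#' Alpha diversity of a single profile
#'
#' Shannon uses the natural logarithm, `H = -sum p log p`; Simpson is the
#' Gini-Simpson form `1 - sum p^2`. The profile is renormalized
#' internally so unnormalized vectors are accepted.
#'
#' @param profile non-negative abundance vector for one sample.
#' @param index `"shannon"` or `"simpson"`.
#' @return a single numeric value.
#' @export
alpha_diversity <- function(profile, index = c("shannon", "simpson")) {
  index <- match.arg(index)
  if (any(profile < 0) || any(!is.finite(profile)))
    stop("profile must be finite and non-negative")
  s <- sum(profile)
  if (s == 0) stop("all-zero profile")
  p <- profile / s
  p <- p[p > 0]
  switch(index,
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2))
}

#' Pairwise beta-diversity distance matrix
#'
#' Bray-Curtis: `sum |x - y| / sum (x + y)`. Root-JSD: the square root of
#' the Jensen-Shannon divergence with natural logarithm, the enterotype
#' convention; zeros receive a pseudocount (default 1e-10) followed by
#' renormalization, so disjoint profiles come out at `sqrt(log 2)` up to
#' pseudocount tolerance.
#'
#' @param table a [taxon_profile_table()] or plain samples x taxa matrix
#'   with non-negative rows.
#' @param metric `"bray_curtis"` or `"jsd_root"`.
#' @param pseudocount zero replacement for `jsd_root`.
#' @return an object of class `distance_matrix`: a symmetric matrix with
#'   zero diagonal and a `metric` attribute.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "jsd_root"),
                          pseudocount = 1e-10) {
  metric <- match.arg(metric)
  X <- if (inherits(table, "taxon_profile_table")) table$relabund else table
  stopifnot(is.matrix(X))
  if (any(!is.finite(X))) stop("non-finite abundance")
  ids <- rownames(X)
  if (metric == "bray_curtis") {
    n <- nrow(X)
    D <- matrix(0, n, n)
    num <- as.matrix(stats::dist(X, method = "manhattan"))
    den <- outer(rowSums(X), rowSums(X), "+")
    D <- ifelse(den > 0, num / den, 0)
    diag(D) <- 0
  } else {
    P <- X + pseudocount
    P <- P / rowSums(P)
    D <- .jsd_pairwise_cpp(P)
  }
  dimnames(D) <- list(ids, ids)
  structure(D, metric = metric, class = c("distance_matrix", "matrix"))
}

as_distance_matrix <- function(D, metric = "custom") {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  structure(D, metric = metric, class = c("distance_matrix", "matrix"))
}

#' Principal coordinate analysis
#'
#' Classical (Torgerson) scaling: Gower double-centering of `-D^2 / 2`,
#' eigendecomposition, axes ordered by eigenvalue. Axes with negative
#' eigenvalues are dropped (not corrected) but their eigenvalues are
#' reported.
#'
#' @param dist a square distance matrix.
#' @param n_axes number of axes to return (default: all positive).
#' @return list with `coordinates` (samples x axes, scaled so that
#'   squared distances are reproduced on Euclidean-embeddable input),
#'   `eigenvalues` (all, descending) and `proportion_explained` over the
#'   positive part.
#' @export
pcoa <- function(dist, n_axes = NULL) {
  D <- as.matrix(dist)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9 & e$values > 0
  npos <- sum(pos)
  if (is.null(n_axes)) n_axes <- npos
  if (n_axes > npos) {
    warning("only ", npos, " positive axes available; truncating")
    n_axes <- npos
  }
  coords <- e$vectors[, seq_len(npos), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(npos)]), npos)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(npos))
  list(coordinates = coords[, seq_len(n_axes), drop = FALSE],
       all_positive_coordinates = coords,
       eigenvalues = e$values,
       proportion_explained =
         e$values[seq_len(npos)] / sum(e$values[pos]))
}

permanova_ss <- function(D2, labels) {
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- D2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

#' One-factor PERMANOVA
#'
#' Partitions the sum of squared distances by group labels via the Gower
#' identity, and assesses significance by free permutation of sample
#' labels: `P = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param dist square distance matrix.
#' @param labels group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `r_squared`, `pseudo_f`, `p_value`, `df`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1) {
  D <- as.matrix(dist)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(D))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("each group needs >= 2 samples")
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value")
  D2 <- D^2
  k <- length(tab)
  n <- nrow(D)
  ss <- permanova_ss(D2, labels)
  ss_b <- ss["total"] - ss["within"]
  f_obs <- (ss_b / (k - 1)) / (ss["within"] / (n - k))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    ssp <- permanova_ss(D2, perm)
    fp <- ((ssp["total"] - ssp["within"]) / (k - 1)) /
      (ssp["within"] / (n - k))
    if (fp >= f_obs - 1e-12) hits <- hits + 1L
  }
  list(r_squared = unname(ss_b / ss["total"]),
       pseudo_f = unname(f_obs),
       p_value = (1 + hits) / (1 + n_perm),
       df = c(between = k - 1, within = n - k),
       n_permutations = n_perm,
       seed = seed)
}

#' Exhaustive-enumeration PERMANOVA p-value
#'
#' Enumerates every assignment of the observed label multiset (feasible
#' for small n); the permutation p-value at `n_perm = all` equals the
#' enumeration tail probability.
#'
#' @inheritParams permanova
#' @return list with `p_value`, `pseudo_f`, `n_enumerated`.
#' @export
permanova_exact <- function(dist, labels) {
  D2 <- as.matrix(dist)^2
  labels <- as.character(labels)
  n <- length(labels)
  if (n > 10) stop("exhaustive enumeration limited to n <= 10")
  tab <- table(labels)
  k <- length(tab)
  f_of <- function(lab) {
    ss <- permanova_ss(D2, lab)
    ((ss["total"] - ss["within"]) / (k - 1)) /
      (ss["within"] / (n - k))
  }
  f_obs <- f_of(labels)
  perms <- multiset_assignments(labels)
  fs <- apply(perms, 1, f_of)
  list(p_value = mean(fs >= f_obs - 1e-12),
       pseudo_f = unname(f_obs),
       n_enumerated = nrow(perms))
}

# all distinct assignments of the label multiset to positions
multiset_assignments <- function(labels) {
  groups <- sort(unique(labels))
  counts <- table(labels)[groups]
  n <- length(labels)
  fill <- function(open, gi) {
    g <- groups[gi]
    if (gi == length(groups))
      return(matrix(rep(g, length(open)), nrow = 1,
                    dimnames = list(NULL, NULL)))
    picks <- utils::combn(length(open), counts[[g]])
    out <- list()
    for (j in seq_len(ncol(picks))) {
      rest <- fill(open[-picks[, j]], gi + 1)
      blk <- matrix(g, nrow(rest), length(open))
      blk[, -picks[, j]] <- rest
      out[[j]] <- blk
    }
    do.call(rbind, out)
  }
  part <- fill(seq_len(n), 1)
  # map back to absolute positions (open always spans 1..n at the root)
  part
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' Runs [permanova()] on every pair of groups and applies
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair.
#' @export
pairwise_permanova <- function(dist, labels, n_perm = 999, seed = 1) {
  labels <- as.character(labels)
  D <- as.matrix(dist)
  grp <- sort(unique(labels))
  pairs <- utils::combn(grp, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    idx <- labels %in% c(a, b)
    r <- permanova(D[idx, idx], labels[idx], n_perm = n_perm,
                   seed = seed + j)
    data.frame(group1 = a, group2 = b, r_squared = r$r_squared,
               pseudo_f = r$pseudo_f, p_value = r$p_value)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}
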