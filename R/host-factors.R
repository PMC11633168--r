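#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up with monotonicity enforcement:
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )`, capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]` (`NA` passed through).
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric(0))
  q <- rep(NA_real_, m)
  ok <- which(!is.na(p_values))
  mm <- length(ok)
  p <- p_values[ok]
  o <- order(p)
  ranked <- p[o] * mm / seq_len(mm)
  ranked <- rev(cummin(rev(ranked)))
  ranked <- pmin(ranked, 1)
  qq <- numeric(mm)
  qq[o] <- ranked
  q[ok] <- qq
  q
}

dummy_code <- function(x) {
  if (is.numeric(x)) return(matrix(x, ncol = 1))
  f <- factor(x)
  if (nlevels(f) < 2) stop("constant covariate")
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

#' Univariable distance-based redundancy analysis
#'
#' Embeds the distance matrix by PCoA (positive axes, eigenvalue-scaled),
#' regresses the coordinates on the covariate, and reports
#' `R^2 = trace explained / total inertia`. Significance comes from an
#' ANOVA-like permutation test: covariate rows are freely permuted and
#' the pseudo-F recomputed, `P = (1 + #{F >= F_obs}) / (1 + n_perm)`.
#' With a full set of group dummies on a Euclidean-embeddable distance
#' matrix this reproduces the one-factor PERMANOVA R-squared.
#'
#' @param dist square distance matrix (typically Bray-Curtis).
#' @param covariate numeric vector or categorical (dummy-coded
#'   internally); missing values drop those samples.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param name,category labels carried into the result.
#' @return a `factor_effect` list: `covariate`, `category`, `r_squared`,
#'   `adj_r_squared` (Ezekiel), `pseudo_f`, `p_value`, `n`, `df`.
#' @export
univariable_dbrda <- function(dist, covariate, n_perm = 999, seed = 1,
                              name = "covariate", category = "other") {
  D <- as.matrix(dist)
  keep <- !is.na(covariate)
  if (!all(keep)) {
    D <- D[keep, keep, drop = FALSE]
    covariate <- covariate[keep]
  }
  X <- dummy_code(covariate)
  if (any(apply(X, 2, sd) == 0)) stop("constant covariate")
  emb <- pcoa(D)
  Y <- emb$all_positive_coordinates
  Y <- scale(Y, scale = FALSE)
  n <- nrow(Y)
  total <- sum(Y^2)
  r2_of <- function(Xc) {
    Xc <- scale(Xc, scale = FALSE)
    qr_x <- qr(Xc)
    fitted <- qr.fitted(qr_x, Y)
    sum(fitted^2) / total
  }
  p_x <- qr(scale(X, scale = FALSE))$rank
  r2 <- r2_of(X)
  f_obs <- (r2 / p_x) / ((1 - r2) / (n - p_x - 1))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    r2p <- r2_of(X[sample.int(n), , drop = FALSE])
    fp <- (r2p / p_x) / ((1 - r2p) / (n - p_x - 1))
    if (fp >= f_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(covariate = name, category = category,
                 r_squared = r2,
                 adj_r_squared = ezekiel_adjust(r2, n, p_x),
                 pseudo_f = f_obs,
                 p_value = (1 + hits) / (1 + n_perm),
                 n = n, df = p_x, seed = seed),
            class = "factor_effect")
}

ezekiel_adjust <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Screen many host factors by univariable dbRDA
#'
#' Runs [univariable_dbrda()] per covariate column, BH-adjusts the
#' permutation p-values, and marks which factors survive `fdr`.
#'
#' @param dist square distance matrix.
#' @param covariates data.frame of host factors (numeric or categorical).
#' @param categories optional named vector mapping covariate name to
#'   category.
#' @param n_perm,seed as in [univariable_dbrda()].
#' @param fdr BH threshold for the `significant` column.
#' @return data.frame, one row per covariate, with `q_value` and
#'   `significant`.
#' @export
screen_host_factors <- function(dist, covariates, categories = NULL,
                                n_perm = 999, seed = 1, fdr = 0.05) {
  res <- lapply(names(covariates), function(nm) {
    cat_nm <- if (!is.null(categories) && nm %in% names(categories))
      categories[[nm]] else "other"
    fe <- univariable_dbrda(dist, covariates[[nm]], n_perm = n_perm,
                            seed = seed, name = nm, category = cat_nm)
    data.frame(covariate = nm, category = cat_nm,
               r_squared = fe$r_squared,
               adj_r_squared = fe$adj_r_squared,
               p_value = fe$p_value, n = fe$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < fdr
  out[order(-out$r_squared), ]
}

#' Greedy collinearity pruning
#'
#' Scans covariates in priority order (by default descending univariable
#' R-squared, ties broken lexicographically) and keeps a covariate iff
#' its absolute Spearman correlation with every already-kept covariate
#' is at or below `threshold`.
#'
#' @param covariate_matrix data.frame or matrix of numeric covariates.
#' @param priority optional numeric vector (higher = scanned earlier);
#'   defaults to the order of the columns.
#' @param threshold absolute Spearman correlation cutoff (default 0.6).
#' @return list with `retained` (names), `dropped` (data.frame of
#'   dropped covariate, conflicting kept covariate, and their rho).
#' @export
prune_collinear <- function(covariate_matrix, priority = NULL,
                            threshold = 0.6) {
  M <- as.data.frame(covariate_matrix)
  nms <- names(M)
  ord <- if (is.null(priority)) seq_along(nms) else
    order(-priority, nms)
  kept <- character(0)
  dropped <- list()
  for (i in ord) {
    nm <- nms[i]
    conflict <- NULL
    for (kn in kept) {
      rho <- suppressWarnings(
        cor(M[[nm]], M[[kn]], method = "spearman",
            use = "pairwise.complete.obs"))
      if (!is.na(rho) && abs(rho) > threshold) {
        conflict <- data.frame(dropped = nm, kept = kn, rho = rho,
                               stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(conflict)) kept <- c(kept, nm)
    else dropped[[length(dropped) + 1L]] <- conflict
  }
  list(retained = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(dropped = character(0), kept = character(0),
                    rho = numeric(0)))
}

#' Variation partitioning across covariate categories
#'
#' For each category, the Ezekiel-adjusted dbRDA R-squared of that
#' category's covariates alone; the total is the adjusted R-squared of
#' all covariates jointly. `adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param dist square distance matrix.
#' @param covariates data.frame of (pruned) covariates.
#' @param category_map named vector mapping every covariate to a
#'   category.
#' @return list with `per_category` (data.frame: category,
#'   adj_r_squared, r_squared, n_covariates), `total_adj_r_squared`,
#'   `total_r_squared`.
#' @export
variation_partition <- function(dist, covariates, category_map) {
  stopifnot(all(names(covariates) %in% names(category_map)))
  D <- as.matrix(dist)
  cc <- complete.cases(covariates)
  D <- D[cc, cc, drop = FALSE]
  covariates <- covariates[cc, , drop = FALSE]
  emb <- pcoa(D)
  Y <- scale(emb$all_positive_coordinates, scale = FALSE)
  n <- nrow(Y)
  total <- sum(Y^2)
  r2_of <- function(df) {
    X <- do.call(cbind, lapply(df, dummy_code))
    X <- scale(X, scale = FALSE)
    p <- qr(X)$rank
    if (p >= n - 1) stop("over-parameterized: p >= n - 1")
    fitted <- qr.fitted(qr(X), Y)
    c(r2 = sum(fitted^2) / total, p = p)
  }
  cats <- unique(category_map[names(covariates)])
  per <- lapply(cats, function(cg) {
    cols <- names(covariates)[category_map[names(covariates)] == cg]
    v <- r2_of(covariates[cols])
    data.frame(category = cg, r_squared = v["r2"],
               adj_r_squared = ezekiel_adjust(v["r2"], n, v["p"]),
               n_covariates = length(cols), stringsAsFactors = FALSE)
  })
  tot <- r2_of(covariates)
  list(per_category = do.call(rbind, per),
       total_r_squared = unname(tot["r2"]),
       total_adj_r_squared = unname(ezekiel_adjust(tot["r2"], n, tot["p"])),
       n = n)
}

#' Pairwise feature-phenotype correlations
#'
#' Pearson or Spearman correlation of every feature against every
#' phenotype (binary indicators such as urotype membership are accepted
#' as features), with two-sided p-values and BH q-values, plus a top-N
#' extraction by q-value.
#'
#' @param feature_matrix samples x features.
#' @param phenotype_matrix samples x phenotypes (numeric).
#' @param method `"pearson"` or `"spearman"`.
#' @param top_n rows to mark in the `top` column (default 20).
#' @return data.frame (feature, phenotype, estimate, p_value, q_value,
#'   n, top) sorted by q then p.
#' @export
correlate_features <- function(feature_matrix, phenotype_matrix,
                               method = c("pearson", "spearman"),
                               top_n = 20) {
  method <- match.arg(method)
  Fm <- as.matrix(feature_matrix)
  Pm <- as.matrix(phenotype_matrix)
  stopifnot(nrow(Fm) == nrow(Pm))
  res <- list()
  for (i in seq_len(ncol(Fm))) {
    for (j in seq_len(ncol(Pm))) {
      x <- Fm[, i]; y <- Pm[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                      exact = FALSE))
      res[[length(res) + 1L]] <- data.frame(
        feature = colnames(Fm)[i], phenotype = colnames(Pm)[j],
        estimate = unname(ct$estimate), p_value = ct$p.value,
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(feature = character(0), phenotype = character(0),
                      estimate = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), n = integer(0),
                      top = logical(0)))
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, out$p_value), ]
  out$top <- seq_len(nrow(out)) <= top_n
  rownames(out) <- NULL
  out
}

#' Binary urotype-membership indicator matrix
#' @param model a `urotype_model`.
#' @return samples x k 0/1 matrix.
#' @export
urotype_indicators <- function(model) {
  k <- model$k
  M <- vapply(seq_len(k), function(g) as.numeric(model$assignments == g),
              numeric(length(model$assignments)))
  colnames(M) <- paste0("urotype", seq_len(k))
  rownames(M) <- names(model$assignments)
  M
}
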