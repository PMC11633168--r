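#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, sums the
#' probabilities of all heterozygote configurations no more probable
#' than the observed one. Symmetric in ref/alt swap; monomorphic
#' variants give p = 1. The test is conservative (p stochastically
#' larger than uniform under HWE).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  n_alt <- n_het + 2 * n_hom_alt
  n_ref <- n_het + 2 * n_hom_ref
  rare <- min(n_alt, n_ref)
  # heterozygote count shares the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) -
      (lgamma(2 * n + 1) - lgamma(rare + 1) - lgamma(2 * n - rare + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

#' Variant quality control
#'
#' Drops variants failing any of: genotype call rate above `call_rate`,
#' minor allele frequency (on non-missing dosages) at least `maf`, and
#' exact HWE p-value above `hwe_p`.
#'
#' @param genotypes a [genotype_table()].
#' @param call_rate minimum call rate (exclusive bound, default 0.98).
#' @param maf minimum minor allele frequency (inclusive, default 0.01).
#' @param hwe_p minimum exact HWE p-value (exclusive, default 1e-5).
#' @return list with `genotypes` (retained) and `report` (per-rule drop
#'   counts and per-variant stats).
#' @export
variant_qc <- function(genotypes, call_rate = 0.98, maf = 0.01,
                       hwe_p = 1e-5) {
  D <- genotypes$dosages
  n <- nrow(D)
  cr <- colMeans(!is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  mafs <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    hwe_exact_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 2, na.rm = TRUE))
  }, numeric(1))
  fail_cr <- cr <= call_rate
  fail_maf <- is.na(mafs) | mafs < maf
  fail_hwe <- hwe <= hwe_p
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("no variants survive QC")
  out <- genotype_table(genotypes$variants[keep, , drop = FALSE],
                        D[, keep, drop = FALSE], genotypes$sample_ids)
  list(genotypes = out,
       report = list(n_input = ncol(D), n_retained = sum(keep),
                     n_fail_call_rate = sum(fail_cr),
                     n_fail_maf = sum(fail_maf),
                     n_fail_hwe = sum(fail_hwe),
                     stats = data.frame(id = genotypes$variants$id,
                                        call_rate = cr, maf = mafs,
                                        hwe_p = hwe, kept = keep)))
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages, standardizes each variant by mean `2p`
#' and sd `sqrt(2p(1-p))`, and returns the top eigenvectors of the
#' sample covariance. Signs are fixed by making each PC's
#' largest-magnitude loading positive.
#'
#' @param genotypes a QC-passed [genotype_table()].
#' @param n_pc number of components (default 10; truncated with a
#'   warning if it exceeds the available rank).
#' @return samples x n_pc matrix with an `eigenvalues` attribute.
#' @export
genotype_pcs <- function(genotypes, n_pc = 10) {
  D <- genotypes$dosages
  n <- nrow(D); m <- ncol(D)
  if (n_pc > min(n, m)) {
    warning("n_pc truncated to ", min(n, m))
    n_pc <- min(n, m)
  }
  p <- colMeans(D, na.rm = TRUE) / 2
  Z <- D
  for (j in seq_len(m)) {
    v <- Z[, j]
    v[is.na(v)] <- 2 * p[j]
    denom <- sqrt(2 * p[j] * (1 - p[j]))
    Z[, j] <- if (denom > 0) (v - 2 * p[j]) / denom else 0
  }
  K <- tcrossprod(Z) / m
  e <- eigen(K, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    big <- which.max(abs(V[, j]))
    if (V[big, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- genotypes$sample_ids
  colnames(V) <- paste0("PC", seq_len(n_pc))
  attr(V, "eigenvalues") <- e$values
  V
}

#' Prepare a taxon's association response
#'
#' Model routing by prevalence: taxa present in more than half the
#' samples get a linear residual response (zeros replaced by half the
#' taxon's minimum nonzero abundance, log10, residualized on the
#' covariates by least squares); taxa in (0.10, 0.5] get a
#' presence/absence indicator for logistic modeling; taxa at or below
#' 10% prevalence are excluded.
#'
#' @param abundances per-sample relative abundances of one taxon.
#' @param covariates data.frame/matrix of covariates (age, sex, BMI,
#'   read counts, genotype PCs), complete rows.
#' @param taxon_id label carried through.
#' @return a `taxon_response` list (`model_kind`, `response`,
#'   `prevalence`, `pseudocount`, `covariate_names`) or `NULL` when the
#'   taxon is excluded.
#' @export
prepare_taxon_response <- function(abundances, covariates,
                                   taxon_id = "taxon") {
  prev <- mean(abundances > 0)
  if (prev <= 0.10) return(NULL)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qrx$rank, " collinear covariate column(s)")
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  if (prev > 0.5) {
    nz <- abundances[abundances > 0]
    pc <- min(nz) / 2
    y <- log10(ifelse(abundances > 0, abundances, pc))
    resid <- qr.resid(qr(X), y)
    list(taxon_id = taxon_id, model_kind = "linear_residual",
         prevalence = prev, response = resid, pseudocount = pc,
         covariate_names = colnames(X))
  } else {
    list(taxon_id = taxon_id, model_kind = "logistic_pa",
         prevalence = prev, response = as.integer(abundances > 0),
         pseudocount = NA_real_, covariate_names = colnames(X))
  }
}

#' Dual-model association scan
#'
#' Linear route: the residualized log10 abundance is regressed on each
#' variant's dosage (simple regression, Wald t). Logistic route: the
#' presence indicator is regressed on dosage plus the covariates by
#' maximum likelihood (Wald z on dosage), with a Firth-penalized
#' fallback on separation. Missing dosages are dropped per variant;
#' monomorphic variants are skipped.
#'
#' @param genotypes a QC-passed [genotype_table()].
#' @param responses list of `taxon_response` objects (see
#'   [prepare_taxon_response()]).
#' @param covariates data.frame used for the logistic models (same
#'   samples, same order as the genotype rows).
#' @param alpha genome-wide significance level (default 5e-8).
#' @return list with `records` (data.frame: variant_id, taxon_id,
#'   model_kind, beta, se, p_value, n, maf, firth) and `hits`
#'   (records with `p_value < alpha`).
#' @export
association_scan <- function(genotypes, responses, covariates = NULL,
                             alpha = 5e-8) {
  D <- genotypes$dosages
  vids <- genotypes$variants$id
  af <- colMeans(D, na.rm = TRUE) / 2
  mafs <- pmin(af, 1 - af)
  recs <- list()
  for (resp in responses) {
    if (is.null(resp)) next
    if (resp$model_kind == "linear_residual") {
      sc <- linear_scan(D, resp$response)
      recs[[length(recs) + 1L]] <- data.frame(
        variant_id = vids, taxon_id = resp$taxon_id,
        model_kind = "linear_residual", beta = sc$beta, se = sc$se,
        p_value = sc$p, n = sc$n, maf = mafs, firth = FALSE,
        stringsAsFactors = FALSE)
    } else {
      if (is.null(covariates))
        stop("logistic models need the covariate matrix")
      C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
      sc <- .logistic_scan_cpp(D, as.numeric(resp$response), C)
      recs[[length(recs) + 1L]] <- data.frame(
        variant_id = vids, taxon_id = resp$taxon_id,
        model_kind = "logistic_pa", beta = sc$beta, se = sc$se,
        p_value = sc$p, n = sc$n, maf = mafs, firth = sc$firth,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  records$skipped <- is.na(records$p_value)
  list(records = records,
       hits = records[!is.na(records$p_value) &
                        records$p_value < alpha, ])
}

# vectorized per-variant simple regression y ~ dosage with per-variant
# complete cases
linear_scan <- function(D, y) {
  M <- !is.na(D)
  Dz <- D; Dz[!M] <- 0
  nv <- colSums(M)
  sg <- colSums(Dz)
  sgg <- colSums(Dz^2)
  sy <- as.numeric(crossprod(M, y))
  syy <- as.numeric(crossprod(M, y^2))
  sgy <- as.numeric(crossprod(Dz, y))
  sxx <- sgg - sg^2 / nv
  sxy <- sgy - sg * sy / nv
  syy_c <- syy - sy^2 / nv
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  rss <- syy_c - ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
  df <- nv - 2
  se <- sqrt(pmax(rss, 0) / pmax(df, 1) / ifelse(sxx > 1e-12, sxx, NA))
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = beta, se = se, p = p, n = nv)
}

#' Genotype-by-environment interaction test
#'
#' Fits `response ~ dosage + env + dosage:env` (plus covariates for the
#' logistic route) and Wald-tests the interaction coefficient. The
#' interaction estimate is invariant to affine recoding of `env`
#' (intercept and main effects absorb shifts).
#'
#' @param genotype per-sample dosage vector for one variant.
#' @param env numeric environment (binary sex coded 0/1, or a hormone
#'   level).
#' @param response a `taxon_response`.
#' @param covariates data.frame used for the logistic route.
#' @return data.frame (beta_gxe, se, p_gxe, n, model_kind).
#' @export
gxe_interaction <- function(genotype, env, response, covariates = NULL) {
  if (sd(env, na.rm = TRUE) == 0) stop("constant environment")
  ok <- !is.na(genotype) & !is.na(env)
  g <- genotype[ok]; e <- env[ok]
  y <- response$response[ok]
  if (response$model_kind == "linear_residual") {
    fit <- lm(y ~ g * e)
    cf <- summary(fit)$coefficients
    row <- cf["g:e", ]
    data.frame(beta_gxe = row[1], se = row[2], p_gxe = row[4],
               n = sum(ok), model_kind = "linear_residual")
  } else {
    df <- data.frame(y = y, g = g, e = e)
    if (!is.null(covariates))
      df <- cbind(df, as.data.frame(covariates)[ok, , drop = FALSE])
    fit <- glm(y ~ . + g:e, data = df, family = binomial())
    cf <- summary(fit)$coefficients
    row <- cf["g:e", ]
    data.frame(beta_gxe = row[1], se = row[2], p_gxe = row[4],
               n = sum(ok), model_kind = "logistic_pa")
  }
}

#' Genotype-by-group stratified summary
#'
#' Collapses the dosage into carrier classes (e.g. `AA` vs `GA/GG`),
#' reports cell means with normal-theory 95% confidence intervals per
#' genotype class and group, and the Spearman correlation of an
#' environment variable with the abundance within each genotype class.
#'
#' @param genotype dosage vector.
#' @param group_labels per-sample stratum (e.g. sex).
#' @param taxon_abund per-sample abundance.
#' @param env optional numeric vector for the within-class Spearman
#'   correlations (defaults to a numeric coding of `group_labels`).
#' @param collapse named list mapping class label to the dosage values
#'   it contains (default `list(ref = 0, carrier = c(1, 2))`).
#' @return list with `cells` (class x group means/CI) and `spearman`
#'   (per genotype class rho and p, `NA` when undefined).
#' @export
stratified_effect_summary <- function(genotype, group_labels, taxon_abund,
                                      env = NULL,
                                      collapse = list(ref = 0,
                                                      carrier = c(1, 2))) {
  gl <- as.character(group_labels)
  if (is.null(env)) env <- as.numeric(factor(gl))
  cls <- rep(NA_character_, length(genotype))
  for (nm in names(collapse)) cls[genotype %in% collapse[[nm]]] <- nm
  if (any(is.na(cls) & !is.na(genotype)))
    stop("collapsing rule does not partition the observed dosages")
  cells <- list()
  for (nm in names(collapse)) for (g in unique(gl)) {
    idx <- which(cls == nm & gl == g)
    if (!length(idx)) {
      cells[[length(cells) + 1L]] <- data.frame(
        genotype_class = nm, group = g, n = 0L, mean = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_)
      next
    }
    v <- taxon_abund[idx]
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    cells[[length(cells) + 1L]] <- data.frame(
      genotype_class = nm, group = g, n = length(idx), mean = mean(v),
      ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  }
  sp <- lapply(names(collapse), function(nm) {
    idx <- which(cls == nm)
    if (length(idx) < 3 || sd(taxon_abund[idx]) == 0 ||
        sd(env[idx]) == 0)
      return(data.frame(genotype_class = nm, rho = NA_real_,
                        p_value = NA_real_, n = length(idx)))
    ct <- suppressWarnings(cor.test(env[idx], taxon_abund[idx],
                                    method = "spearman", exact = FALSE))
    data.frame(genotype_class = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(idx))
  })
  list(cells = do.call(rbind, cells), spearman = do.call(rbind, sp))
}
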