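test_that("hwe exact test matches full enumeration and is symmetric", {
  cases <- list(c(1, 0, 1), c(3, 2, 1), c(2, 5, 3), c(0, 0, 4),
                c(4, 1, 0), c(2, 2, 2))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enum_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_exact_test(cs[3], cs[2], cs[1]), tolerance = 1e-12)
  }
  expect_equal(hwe_exact_test(0, 0, 10), 1)  # monomorphic
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("hwe exact test is conservative under the null", {
  set.seed(10)
  n <- 200
  ps <- vapply(1:2000, function(r) {
    p <- runif(1, 0.1, 0.5)
    g <- rbinom(n, 2, p)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  # p stochastically >= uniform: empirical CDF at levels never far above
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(ps < a), a * 1.35)
})

test_that("variant QC drops by call rate, MAF and HWE", {
  set.seed(3)
  n <- 500
  good <- rbinom(n, 2, 0.3)
  low_cr <- good; low_cr[sample(n, round(0.03 * n))] <- NA  # 97% call rate
  low_maf <- rbinom(n, 2, 0.005)
  hwe_bad <- sample(rep(c(0, 2), each = n / 2))             # no hets
  dos <- cbind(good = good, low_cr = low_cr, low_maf = low_maf,
               hwe_bad = hwe_bad)
  gt <- genotype_table(data.frame(chrom = "1", pos = 1:4 * 100,
                                  id = colnames(dos), ref = "A",
                                  alt = "G"),
                       dos, sprintf("S%03d", 1:n))
  qc <- variant_qc(gt)
  expect_equal(qc$genotypes$variants$id, "good")
  st <- qc$report$stats
  expect_false(st$kept[st$id == "low_cr"])
  expect_false(st$kept[st$id == "low_maf"])
  expect_false(st$kept[st$id == "hwe_bad"])
})

test_that("inbred variants are caught by the HWE rule", {
  set.seed(4)
  caught <- vapply(1:20, function(r) {
    n <- 687; p <- 0.3; f <- 0.5
    probs <- c((1 - p)^2 + f * p * (1 - p),
               2 * p * (1 - p) * (1 - f),
               p^2 + f * p * (1 - p))
    g <- sample(0:2, n, TRUE, prob = probs)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)) <= 1e-5
  }, logical(1))
  expect_gte(mean(caught), 0.95)
})

test_that("genotype PCs separate simulated subpopulations", {
  set.seed(6)
  n <- 200; m <- 400
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(pmax(p1 + runif(m, -0.2, 0.2), 0.05), 0.95)
  dos <- matrix(0, n, m)
  for (j in 1:m)
    dos[, j] <- rbinom(n, 2, ifelse(pop == 0, p1[j], p2[j]))
  gt <- genotype_table(data.frame(chrom = "1", pos = 1:m,
                                  id = paste0("v", 1:m), ref = "A",
                                  alt = "G"), dos, paste0("S", 1:n))
  pcs <- genotype_pcs(gt, 5)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  # determinism incl. sign convention
  expect_identical(pcs, genotype_pcs(gt, 5))
  expect_warning(genotype_pcs(gt, 1000), "truncated")
})

test_that("taxon response routing follows the prevalence rules", {
  set.seed(8)
  n <- 200
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, .5))
  mk <- function(prev) {
    a <- rlnorm(n, -6, 1)
    a[sample(n, round((1 - prev) * n))] <- 0
    a
  }
  r60 <- prepare_taxon_response(mk(0.60), covs)
  expect_equal(r60$model_kind, "linear_residual")
  expect_equal(mean(r60$response), 0, tolerance = 1e-10)
  r30 <- prepare_taxon_response(mk(0.30), covs)
  expect_equal(r30$model_kind, "logistic_pa")
  expect_true(all(r30$response %in% 0:1))
  expect_null(prepare_taxon_response(mk(0.08), covs))
})

test_that("two-stage residual scan equals the joint model when dosage is orthogonal to covariates", {
  set.seed(9)
  n <- 240
  g <- rbinom(n, 2, 0.4)
  # covariate constructed orthogonal to dosage (and to the intercept)
  z0 <- rnorm(n)
  z <- resid(lm(z0 ~ g))
  y <- 0.2 * g + 0.5 * z + rnorm(n)
  covs <- data.frame(z = z)
  resp <- prepare_taxon_response(10^(y - max(y) - 1), covs)  # all nonzero
  gt <- genotype_table(data.frame(chrom = "1", pos = 100, id = "v1",
                                  ref = "A", alt = "G"),
                       matrix(g, ncol = 1), paste0("S", 1:n))
  sc <- association_scan(gt, list(resp))
  joint <- summary(lm(y ~ g + z))$coefficients
  expect_equal(sc$records$beta[1], joint["g", 1], tolerance = 1e-8)
  # p-values agree to leading order (df differ by the covariate count)
  expect_equal(log10(sc$records$p_value[1]), log10(joint["g", 4]),
               tolerance = 0.05)
})

test_that("logistic scan matches glm on small fixtures", {
  set.seed(11)
  n <- 150
  g <- rbinom(n, 2, 0.3)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * g + 0.3 * x))
  gt <- genotype_table(data.frame(chrom = "1", pos = 1, id = "v1",
                                  ref = "A", alt = "G"),
                       matrix(g, ncol = 1), paste0("S", 1:n))
  resp <- list(taxon_id = "t", model_kind = "logistic_pa",
               prevalence = mean(y), response = y,
               pseudocount = NA, covariate_names = "x")
  sc <- association_scan(gt, list(resp), data.frame(x = x))
  ref <- summary(glm(y ~ x + g, family = binomial()))$coefficients
  expect_equal(sc$records$beta[1], ref["g", 1], tolerance = 1e-6)
  expect_equal(sc$records$se[1], ref["g", 2], tolerance = 1e-6)
  expect_equal(sc$records$p_value[1], ref["g", 4], tolerance = 1e-6)
})

test_that("separation triggers the Firth fallback with finite estimates", {
  n <- 80
  g <- c(rep(0, 40), rep(2, 40))
  y <- c(rep(0, 40), rep(1, 40))       # perfect separation
  gt <- genotype_table(data.frame(chrom = "1", pos = 1, id = "v1",
                                  ref = "A", alt = "G"),
                       matrix(g, ncol = 1), paste0("S", 1:n))
  resp <- list(taxon_id = "t", model_kind = "logistic_pa",
               prevalence = 0.5, response = y, pseudocount = NA,
               covariate_names = character(0))
  set.seed(12)
  sc <- association_scan(gt, list(resp),
                         data.frame(x = rnorm(n)))
  expect_true(sc$records$firth[1])
  expect_true(is.finite(sc$records$beta[1]))
  expect_lt(sc$records$p_value[1], 1e-3)
})

test_that("constant dosage is skipped with zero MAF", {
  n <- 50
  gt <- genotype_table(data.frame(chrom = "1", pos = 1:2,
                                  id = c("mono", "ok"), ref = "A",
                                  alt = "G"),
                       cbind(rep(0, n), rbinom(n, 2, .4)),
                       paste0("S", 1:n))
  resp <- list(taxon_id = "t", model_kind = "linear_residual",
               prevalence = 1, response = rnorm(n), pseudocount = 1,
               covariate_names = character(0))
  sc <- association_scan(gt, list(resp))
  expect_true(sc$records$skipped[sc$records$variant_id == "mono"])
  expect_equal(sc$records$maf[sc$records$variant_id == "mono"], 0)
  expect_false(sc$records$skipped[sc$records$variant_id == "ok"])
})

test_that("gxe interaction: affine invariance and null behavior", {
  set.seed(13)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  e01 <- rbinom(n, 1, 0.5)
  y <- 0.3 * g + 0.5 * e01 + rnorm(n)
  resp <- list(taxon_id = "t", model_kind = "linear_residual",
               prevalence = 1, response = y, pseudocount = 1,
               covariate_names = character(0))
  a <- gxe_interaction(g, e01, resp)
  b <- gxe_interaction(g, e01 + 1, resp)
  expect_equal(a$beta_gxe, b$beta_gxe, tolerance = 1e-10)
  expect_equal(a$p_gxe, b$p_gxe, tolerance = 1e-10)
  expect_error(gxe_interaction(g, rep(1, n), resp), "constant")
  # planted interaction is detected
  y2 <- 0.2 * g + 0.1 * e01 + 0.6 * g * e01 + rnorm(n)
  resp2 <- resp; resp2$response <- y2
  expect_lt(gxe_interaction(g, e01, resp2)$p_gxe, 0.01)
})

test_that("stratified summary partitions samples and flags degeneracy", {
  set.seed(14)
  n <- 120
  g <- rbinom(n, 2, 0.4)
  sex <- sample(c("female", "male"), n, TRUE)
  ab <- rlnorm(n, -5, 1)
  s <- stratified_effect_summary(g, sex, ab)
  expect_equal(sum(s$cells$n), n)
  expect_equal(nrow(s$cells), 4)  # 2 classes x 2 groups
  # constant abundance: spearman undefined -> NA
  s0 <- stratified_effect_summary(g, sex, rep(1, n))
  expect_true(all(is.na(s0$spearman$rho)))
  expect_true(all(s0$cells$mean[s0$cells$n > 0] == 1))
})

test_that("QC and scans are order-independent", {
  gt <- generate_genotypes(150, 60, missing_rate = 0.02, seed = 21)
  o <- sample(60)
  qc1 <- variant_qc(gt)
  gt2 <- genotype_table(gt$variants[o, ], gt$dosages[, o],
                        gt$sample_ids)
  qc2 <- variant_qc(gt2)
  expect_setequal(qc1$genotypes$variants$id, qc2$genotypes$variants$id)
})
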