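test_that("pam matches exhaustive medoid search on clustered instances", {
  # BUILD+SWAP is a local search: on clustered data it reaches the
  # global optimum (the canonical implementation behaves identically)
  set.seed(9)
  for (r in 1:5) {
    centers <- matrix(rnorm(6, sd = 8), 3, 2)
    pts <- centers[rep(1:3, length.out = 8), ] + matrix(rnorm(16, 0, 0.4), 8, 2)
    D <- euclid_dist(pts)
    for (k in 2:3) {
      ours <- pam_cluster(D, k)
      brute <- pam_brute_force(D, k)
      expect_equal(ours$cost, brute$cost, tolerance = 1e-10)
    }
  }
})

test_that("pam cost is single-swap locally optimal on arbitrary instances", {
  set.seed(19)
  for (r in 1:5) {
    pts <- matrix(rnorm(16), 8, 2)
    D <- euclid_dist(pts)
    res <- pam_cluster(D, 3)
    med <- match(res$medoid_ids, rownames(D))
    for (m in seq_along(med)) for (h in setdiff(1:8, med)) {
      trial <- med; trial[m] <- h
      cost <- sum(apply(D[, trial, drop = FALSE], 1, min))
      expect_gte(cost, res$cost - 1e-10)
    }
  }
})

test_that("pam recovers well-separated pairs and validates k", {
  pts <- rbind(matrix(rnorm(8, 0, .01), 4, 2),
               matrix(rnorm(8, 50, .01), 4, 2))
  D <- euclid_dist(pts)
  cl <- pam_cluster(D, 2)
  expect_equal(unname(cl$assignments), rep(c(1, 2), each = 4))
  expect_error(pam_cluster(D, 8), "smaller")
  expect_error(pam_cluster(D, 0), "at least 1")
})

test_that("pam labels are invariant to input order up to relabeling", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  D <- euclid_dist(pts)
  o <- sample(20)
  a <- pam_cluster(D, 2)$assignments
  b <- pam_cluster(D[o, o], 2)$assignments
  expect_equal(adjusted_rand_index(a[names(b)], b), 1)
})

test_that("pam agrees with cluster::pam on cost", {
  skip_if_not_installed("cluster")
  set.seed(30)
  X <- matrix(rgamma(40 * 12, 1), 40, 12)
  X <- X / rowSums(X)
  rownames(X) <- paste0("S", 1:40)
  D <- beta_distance(X, "jsd_root")
  for (k in c(2, 4)) {
    ours <- pam_cluster(D, k)
    ref <- cluster::pam(as.dist(D), k)
    ref_cost <- sum(apply(as.matrix(D)[, ref$medoids, drop = FALSE],
                          1, min))
    expect_lte(ours$cost, ref_cost + 1e-8)
  }
})

test_that("distance-form CH equals centroid-form CH in PCoA space", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  D <- euclid_dist(pts)
  lab <- rep(1:2, each = 10)
  ch_d <- ch_index(D, lab)
  # centroid form on the embedding
  Y <- pcoa(D)$all_positive_coordinates
  n <- nrow(Y); k <- 2
  gm <- colMeans(Y)
  ssb <- ssw <- 0
  for (g in 1:2) {
    Yg <- Y[lab == g, , drop = FALSE]
    cg <- colMeans(Yg)
    ssb <- ssb + nrow(Yg) * sum((cg - gm)^2)
    ssw <- ssw + sum(sweep(Yg, 2, cg)^2)
  }
  ch_c <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(ch_d, ch_c, tolerance = 1e-8)
})

test_that("CH prefers the true split and handles degenerate clusters", {
  pts <- two_cluster_points(6, gap = 8, sd = 0.2, seed = 3)
  D <- euclid_dist(pts)
  truth <- rep(1:2, each = 6)
  set.seed(1)
  rand <- sample(truth)
  expect_gt(ch_index(D, truth), ch_index(D, rand))
  # identical points within clusters -> W = 0 -> Inf sentinel
  D0 <- matrix(1, 4, 4) - diag(4)
  D0[1, 2] <- D0[2, 1] <- 0
  D0[3, 4] <- D0[4, 3] <- 0
  expect_equal(ch_index(D0, c(1, 1, 2, 2)), Inf)
})

test_that("select_k recovers k=5 on separated cohorts and flags blobs", {
  g <- generate_profiles(sim_config(n_study = 150, dominant_share = 0.4),
                         seed = 51)
  D <- beta_distance(g$table, "jsd_root")
  sk <- select_k(D, 2:8)
  expect_equal(sk$best_k, 5)
  expect_named(sk$ch_curve, as.character(2:8))
  # single blob: weak-structure flag
  set.seed(5)
  X <- matrix(rgamma(60 * 20, 5), 60, 20)
  X <- X / rowSums(X)
  rownames(X) <- paste0("S", 1:60)
  sk0 <- select_k(beta_distance(X, "jsd_root"), 2:6)
  expect_true(sk0$weak_structure)
  expect_false(sk$weak_structure)
  expect_warning(select_k(D, 4), "length 1")
})

test_that("lda effect scores: scale arithmetic, screening, symmetry", {
  set.seed(33)
  n <- 60
  cl <- rep(c("a", "b"), each = n / 2)
  X <- matrix(abs(rnorm(n * 5, 0.001, 2e-4)), n, 5)
  # feature 1: class-mean difference 0.01 -> 10,000 per million -> score ~ 4
  X[cl == "a", 1] <- X[cl == "a", 1] + 0.01
  # feature 5: identical across classes
  X[, 5] <- 0.002
  colnames(X) <- paste0("f", 1:5)
  rownames(X) <- paste0("S", 1:n)
  res <- lda_effect_scores(X, cl, lda_threshold = 2, seed = 1)
  expect_false("f5" %in% res$taxon_id)   # constant: excluded pre-test
  f1 <- res[res$taxon_id == "f1", ]
  expect_equal(f1$class, "a")
  expect_equal(f1$lda_score, 4, tolerance = 0.15)
  # swapped labels flip enrichment only
  res2 <- lda_effect_scores(X, ifelse(cl == "a", "b", "a"), seed = 1)
  f1b <- res2[res2$taxon_id == "f1", ]
  expect_equal(f1b$class, "b")
  expect_error(lda_effect_scores(X, c("a", rep("b", n - 1))), ">= 3")
})

test_that("lda effect scores are deterministic under seed", {
  g <- generate_profiles(sim_config(n_study = 100, n_taxa = 30), seed = 3)
  r1 <- lda_effect_scores(g$table, g$truth$cluster_labels, seed = 7)
  r2 <- lda_effect_scores(g$table, g$truth$cluster_labels, seed = 7)
  expect_identical(r1, r2)
})

test_that("urotyping pipeline recovers planted structure end to end", {
  g <- generate_profiles(sim_config(n_study = 200), seed = 61)
  ff <- feature_filter(g$table)
  m <- assign_urotypes(ff, seed = 61)
  expect_equal(m$k, 5)
  expect_gte(adjusted_rand_index(m$assignments, g$truth$cluster_labels),
             0.9)
  # dominant taxon of each cluster equals the generator's, mapped by
  # majority overlap
  mapping <- match_clusters(m$assignments, g$truth$cluster_labels)
  for (g_pred in names(mapping)) {
    truth_dom <- g$truth$dominant_taxon[paste0("cluster", mapping[g_pred])]
    expect_equal(unname(m$dominant_taxon[as.integer(g_pred)]),
                 unname(truth_dom))
  }
  # determinism
  m2 <- assign_urotypes(ff, seed = 61)
  expect_identical(m$assignments, m2$assignments)
  expect_identical(m$markers, m2$markers)
})

test_that("k override beats a misspecified k under weak separation", {
  aris <- vapply(1:8, function(r) {
    g <- generate_profiles(sim_config(n_study = 120, dominant_share = 0.18,
                                      theta = 25), seed = 700 + r)
    D <- beta_distance(g$table, "jsd_root")
    a5 <- adjusted_rand_index(pam_cluster(D, 5)$assignments,
                              g$truth$cluster_labels)
    a3 <- adjusted_rand_index(pam_cluster(D, 3)$assignments,
                              g$truth$cluster_labels)
    a5 - a3
  }, numeric(1))
  expect_gte(median(aris), 0)
})

test_that("dominant enrichment tests: planted effects and degenerate input", {
  g <- generate_profiles(sim_config(n_study = 200), seed = 71)
  ff <- feature_filter(g$table)
  m <- assign_urotypes(ff, seed = 71)
  et <- dominant_enrichment_tests(ff, m)
  expect_true(all(et$q_value < 0.01))
  # identical groups -> t = 0, p = 1 sentinel
  ra <- matrix(0.25, 8, 4)
  rownames(ra) <- paste0("S", 1:8)
  tab <- tiny_profile(ra)
  fake <- structure(list(k = 2, assignments = stats::setNames(
    rep(1:2, each = 4), rownames(ra)),
    dominant_taxon = rep(tab$taxa$taxon_id[1], 2)),
    class = "urotype_model")
  et0 <- dominant_enrichment_tests(tab, fake)
  expect_true(all(et0$p_value == 1))
  expect_true(all(et0$degenerate))
})

test_that("shuffled labels give uniform dominant-test p-values", {
  g <- generate_profiles(sim_config(n_study = 150), seed = 81)
  ff <- feature_filter(g$table)
  m <- assign_urotypes(ff, k_override = 5, seed = 81)
  set.seed(81)
  ps <- unlist(lapply(1:30, function(r) {
    fake <- m
    fake$assignments[] <- sample(m$assignments)
    dominant_enrichment_tests(ff, fake)$p_value
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.005)
})
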