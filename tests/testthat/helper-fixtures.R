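# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

tiny_profile <- function(ra, ids = NULL, domain = "bacteria") {
  # ra: samples x taxa matrix of fractions
  if (is.null(ids))
    ids <- paste0("k__Bacteria|s__T", seq_len(ncol(ra)))
  if (is.null(rownames(ra))) rownames(ra) <- paste0("S", seq_len(nrow(ra)))
  taxa <- data.frame(taxon_id = ids, rank = "species", lineage = ids,
                     domain = rep(domain, length.out = length(ids)),
                     name = sub("^.*s__", "", ids),
                     stringsAsFactors = FALSE)
  taxon_profile_table(ra, taxa,
                      normalized = all(abs(rowSums(ra) - 1) < 1e-6))
}

euclid_dist <- function(pts) {
  # pts: n x d coordinate matrix -> Euclidean distance_matrix
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("S", seq_len(nrow(D)))
  D
}

# two tight clusters far apart in 2-D
two_cluster_points <- function(n_per = 5, gap = 10, sd = 0.1, seed = 42) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per, 0, sd), ncol = 2),
        matrix(rnorm(2 * n_per, gap, sd), ncol = 2))
}

# brute-force PAM: exhaustive minimization over all medoid sets
pam_brute_force <- function(D, k) {
  n <- nrow(D)
  sets <- utils::combn(n, k)
  best <- Inf; best_set <- NULL
  for (j in seq_len(ncol(sets))) {
    med <- sets[, j]
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best - 1e-12) { best <- cost; best_set <- med }
  }
  list(medoids = best_set, cost = best)
}

# independent two-line oracles
bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)
jsd_root_oracle <- function(x, y, pc = 1e-10) {
  x <- x + pc; x <- x / sum(x); y <- y + pc; y <- y / sum(y)
  m <- (x + y) / 2
  kl <- function(a, b) sum(a * log(a / b))
  sqrt(0.5 * kl(x, m) + 0.5 * kl(y, m))
}

# exact HWE by direct enumeration of the conditional distribution
hwe_enum_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  hets <- seq(0, n)
  probs <- vapply(hets, function(h) {
    haa <- (na - h) / 2
    hbb <- n - h - haa
    if (haa < 0 || hbb < 0 || haa != round(haa)) return(0)
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) -
          lfactorial(hbb) + h * log(2) -
          (lfactorial(2 * n) - lfactorial(na) - lfactorial(2 * n - na)))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hets == ab]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

default_gwas_covariates <- function(sheet, pcs) {
  data.frame(age = sheet$age,
             sex = as.numeric(sheet$sex == "male"),
             bmi = sheet$bmi,
             reads = sheet$total_read_count,
             pcs)
}

# map predicted clusters onto truth clusters by maximum overlap
match_clusters <- function(pred, truth) {
  tab <- table(pred, truth)
  apply(tab, 1, function(r) colnames(tab)[which.max(r)])
}
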