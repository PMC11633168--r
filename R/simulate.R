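#' The built-in mock-community expected species
#'
#' Ten equimolar pseudo-species standing in for a commercial mock
#' community standard. These are the taxa exempt from the mock-control
#' contaminant criteria.
#'
#' @return character vector of 10 taxon ids.
#' @export
mock_expected_species <- function() {
  paste0("k__Bacteria|s__Mock_species_", sprintf("%02d", 1:10))
}

#' Simulation configuration
#'
#' Defaults describe a low-biomass urinary cohort: five latent community
#' types ("urotypes"), each dominated by one taxon with mean share 0.30;
#' clusters 1 and 3 enriched in females and 2/4/5 in males; lognormal
#' rank-abundance background perturbed per cluster; Dirichlet-multinomial
#' sampling on a read-count layer; 96-well plates; lognormal library PCR
#' concentrations around 2 ng/uL.
#'
#' @param n_study number of study samples.
#' @param n_taxa number of (bacterial) background taxa.
#' @param k number of latent community types.
#' @param dominant_share mean relative-abundance share of each cluster's
#'   dominant taxon.
#' @param theta Dirichlet precision (larger = tighter clusters).
#' @param cluster_sd log-normal sd of per-cluster background
#'   perturbations (cluster identity beyond the dominant taxon).
#' @param sex_bias in `[0, 1)`: cluster-prior tilt; female-enriched
#'   clusters get prior weight `1 + sex_bias` for females and
#'   `1 - sex_bias` for males (mirrored for male-enriched clusters).
#' @param female_clusters indices of female-enriched clusters.
#' @param p_female marginal probability of a female sample.
#' @param n_sex_taxa number of sex-structured background taxa (half
#'   female-enriched, half male-enriched).
#' @param sex_fold mean fold-change of a sex-structured taxon in its
#'   enriched sex.
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters.
#' @param pcr_meanlog,pcr_sdlog lognormal PCR-concentration parameters
#'   (ng/uL), drawn independently of composition (no concentration
#'   structure until contaminants are spiked).
#' @param plate_capacity samples per 96-well plate (leaves room for
#'   controls).
#' @param n_plates force a number of plates (round-robin assignment);
#'   `NULL` derives it from capacity.
#' @param phenotype_links data.frame(phenotype, taxon_index, effect):
#'   each phenotype gains `effect` times the z-scored log10 abundance of
#'   the linked taxon. `taxon_index` of 0 links to the cluster-1 dominant.
#' @return config list.
#' @export
sim_config <- function(n_study = 600, n_taxa = 100, k = 5,
                       dominant_share = 0.30, theta = 120,
                       cluster_sd = 0.8, sex_bias = 0.5,
                       female_clusters = c(1, 3), p_female = 0.5,
                       n_sex_taxa = 10, sex_fold = 2,
                       depth_meanlog = log(5e4), depth_sdlog = 0.4,
                       pcr_meanlog = log(2), pcr_sdlog = 0.7,
                       plate_capacity = 94, n_plates = NULL,
                       phenotype_links = data.frame(
                         phenotype = "testosterone", taxon_index = 0,
                         effect = 0.5)) {
  if (k > n_taxa) stop("k must not exceed n_taxa")
  as.list(environment())
}

#' Generate a synthetic urinary cohort
#'
#' Draws per-sample community types from sex-tilted priors, compositions
#' from cluster-specific Dirichlet distributions (one dominant taxon per
#' cluster plus a perturbed lognormal background, with sex-structured
#' taxa), then reads by multinomial sampling at lognormal depth.
#' Phenotypes (age, BMI, a testosterone-like hormone) are attached to the
#' sample sheet; configured phenotype-taxon links are planted and
#' recorded. PCR concentrations are drawn independently of composition.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @return list with `table` (a [taxon_profile_table()]), `sheet` (a
#'   [sample_sheet()]) and `truth` (a `simulation_truth` list recording
#'   cluster labels, dominant taxa, sex-effect taxa and phenotype links).
#' @export
generate_profiles <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cf <- config
  n <- cf$n_study
  # taxa: background + one dominant per cluster drawn from the background
  base_w <- rlnorm(cf$n_taxa, meanlog = 0, sdlog = 1.2)
  base_w <- pmax(base_w / sum(base_w), 0.002)
  base_w <- base_w / sum(base_w)
  dominant_idx <- order(base_w, decreasing = TRUE)[seq_len(cf$k)]
  taxon_ids <- paste0("k__Bacteria|s__Taxon_", sprintf("%03d", seq_len(cf$n_taxa)))

  sex_taxa <- integer(0); sex_sign <- integer(0)
  if (cf$n_sex_taxa > 0) {
    pool <- setdiff(seq_len(cf$n_taxa), dominant_idx)
    sex_taxa <- sort(sample(pool, cf$n_sex_taxa))
    sex_sign <- rep(c(1L, -1L), length.out = cf$n_sex_taxa) # +1 female
  }

  # cluster-specific mean compositions
  cluster_means <- lapply(seq_len(cf$k), function(c) {
    w <- base_w * rlnorm(cf$n_taxa, 0, cf$cluster_sd)
    w <- w / sum(w)
    w <- w * (1 - cf$dominant_share) / (1 - w[dominant_idx[c]])
    w[dominant_idx[c]] <- cf$dominant_share
    w / sum(w)
  })

  sex <- ifelse(runif(n) < cf$p_female, "female", "male")
  prior <- rep(1, cf$k)
  tilt_f <- ifelse(seq_len(cf$k) %in% cf$female_clusters,
                   1 + cf$sex_bias, 1 - cf$sex_bias)
  tilt_m <- ifelse(seq_len(cf$k) %in% cf$female_clusters,
                   1 - cf$sex_bias, 1 + cf$sex_bias)
  labels <- vapply(sex, function(s) {
    w <- prior * (if (s == "female") tilt_f else tilt_m)
    sample.int(cf$k, 1, prob = w)
  }, integer(1))

  depth <- pmax(round(rlnorm(n, cf$depth_meanlog, cf$depth_sdlog)), 2000)
  counts <- matrix(0L, n, cf$n_taxa)
  for (i in seq_len(n)) {
    alpha <- cluster_means[[labels[i]]] * cf$theta
    if (length(sex_taxa)) {
      fold <- ifelse((sex[i] == "female") == (sex_sign > 0),
                     cf$sex_fold, 1)
      alpha[sex_taxa] <- alpha[sex_taxa] * fold
    }
    p <- rgamma(cf$n_taxa, shape = alpha)
    p <- p / sum(p)
    counts[i, ] <- rmultinom(1, depth[i], p)
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(counts) <- sample_ids
  ra <- counts / depth

  taxa <- data.frame(taxon_id = taxon_ids, rank = "species",
                     lineage = taxon_ids,
                     domain = "bacteria",
                     name = display_name(taxon_ids),
                     stringsAsFactors = FALSE)
  table <- taxon_profile_table(ra, taxa, read_counts = counts,
                               total_reads = depth)

  n_plates <- if (is.null(cf$n_plates))
    ceiling(n / cf$plate_capacity) else cf$n_plates
  plate_id <- paste0("P", sprintf("%02d", ((seq_len(n) - 1) %% n_plates) + 1))

  age <- round(rnorm(n, 29, 6))
  bmi <- round(rnorm(n, 22, 3), 1)
  testosterone <- ifelse(sex == "male", rnorm(n, 15, 3),
                         rnorm(n, 1.2, 0.5))
  sheet_df <- data.frame(
    sample_id = sample_ids, role = "study", plate_id = plate_id,
    pcr_concentration = rlnorm(n, cf$pcr_meanlog, cf$pcr_sdlog),
    sex = sex, age = age, bmi = bmi, total_read_count = depth,
    testosterone = testosterone, stringsAsFactors = FALSE)

  links <- cf$phenotype_links
  planted_links <- NULL
  if (!is.null(links) && nrow(links)) {
    for (r in seq_len(nrow(links))) {
      ti <- links$taxon_index[r]
      if (ti == 0) ti <- dominant_idx[1]
      z <- log10(ra[, ti] + 1e-6)
      z <- (z - mean(z)) / sd(z)
      ph <- links$phenotype[r]
      base <- if (ph %in% names(sheet_df)) sheet_df[[ph]] else rnorm(n)
      sheet_df[[ph]] <- base + links$effect[r] * sd(base) * z
      planted_links <- rbind(planted_links, data.frame(
        phenotype = ph, taxon_id = taxon_ids[ti],
        effect = links$effect[r], stringsAsFactors = FALSE))
    }
  }
  truth <- structure(list(
    contaminant_taxa = data.frame(taxon_id = character(0),
                                  scope = character(0)),
    cluster_labels = stats::setNames(labels, sample_ids),
    dominant_taxon = stats::setNames(taxon_ids[dominant_idx],
                                     paste0("cluster", seq_len(cf$k))),
    sex_effect_taxa = if (length(sex_taxa)) data.frame(
      taxon_id = taxon_ids[sex_taxa], sign = sex_sign,
      stringsAsFactors = FALSE) else
        data.frame(taxon_id = character(0), sign = integer(0)),
    planted_effects = NULL,
    phenotype_links = planted_links,
    contamination_fraction = stats::setNames(rep(0, n), sample_ids),
    seed = seed, config = cf), class = "simulation_truth")
  list(table = table, sheet = sample_sheet(sheet_df), truth = truth)
}

#' Contamination spike specification
#'
#' @param n_cohort number of cohort-wide contaminant taxa.
#' @param n_plate number of plate-specific contaminant taxa (each
#'   assigned to one plate).
#' @param load_scale expected contaminant read share is
#'   `load_scale / pcr_concentration` (capped at `max_share`); the
#'   low-biomass signature, load inversely related to DNA concentration.
#' @param load_noise_sd lognormal noise on the per-sample load.
#' @param max_share cap on the expected per-sample contaminant share.
#' @param mock_share total contaminant share spiked into each mock
#'   control (split across that plate's contaminants).
#' @param mocks_per_plate mock controls generated per plate (one
#'   extraction + one library mock when 2).
#' @return spike-spec list.
#' @export
contaminant_spec <- function(n_cohort = 16, n_plate = 4,
                             load_scale = 0.08, load_noise_sd = 0.5,
                             max_share = 0.6, mock_share = 0.01,
                             mocks_per_plate = 2) {
  as.list(environment())
}

#' Spike contaminants and emit mock controls
#'
#' Adds contaminant taxa whose per-sample read load is inversely
#' proportional to the sample's PCR concentration (times lognormal
#' noise), appends per-plate mock-control samples containing the 10
#' expected species (equimolar) plus that plate's contaminants, and
#' updates the truth object. With `spec$n_cohort + spec$n_plate == 0`
#' the study table is unchanged and only clean mocks are added.
#'
#' @param table,sheet,truth output of [generate_profiles()].
#' @param spec a [contaminant_spec()].
#' @param seed integer seed.
#' @return list with updated `table`, `sheet`, `truth`.
#' @export
spike_contaminants <- function(table, sheet, truth,
                               spec = contaminant_spec(), seed = 1) {
  set.seed(seed + 1L)
  n <- length(table$sample_ids)
  plates <- sort(unique(sheet$plate_id[sheet$role == "study"]))
  stopifnot(!is.null(table$read_counts))
  counts <- table$read_counts

  cohort_ids <- if (spec$n_cohort > 0)
    paste0("k__Bacteria|s__Contam_cohort_",
           sprintf("%02d", seq_len(spec$n_cohort))) else character(0)
  plate_ids <- if (spec$n_plate > 0)
    paste0("k__Bacteria|s__Contam_plate_",
           sprintf("%02d", seq_len(spec$n_plate))) else character(0)
  plate_home <- if (spec$n_plate > 0)
    sample(plates, spec$n_plate, replace = spec$n_plate > length(plates))
  else character(0)
  mock_ids <- mock_expected_species()
  new_ids <- c(cohort_ids, plate_ids, mock_ids)
  n_new <- length(new_ids)

  counts <- cbind(counts, matrix(0L, n, n_new,
                                 dimnames = list(rownames(counts), new_ids)))
  contam_w <- if (spec$n_cohort > 0) {
    w <- rlnorm(spec$n_cohort, 0, 0.8); w / sum(w)
  } else numeric(0)

  pcr <- sheet$pcr_concentration[match(table$sample_ids, sheet$sample_id)]
  plate_of <- sheet$plate_id[match(table$sample_ids, sheet$sample_id)]
  tot0 <- rowSums(counts)
  contam_added <- numeric(n)
  for (i in seq_len(n)) {
    share <- spec$load_scale / pcr[i] * rlnorm(1, 0, spec$load_noise_sd)
    share <- min(share, spec$max_share)
    if (share >= 1) stop("contaminant share >= 1; re-parameterize")
    extra_total <- tot0[i] * share / (1 - share)
    add <- numeric(0)
    idx <- integer(0)
    if (spec$n_cohort > 0) {
      add <- c(add, extra_total * contam_w)
      idx <- c(idx, match(cohort_ids, colnames(counts)))
    }
    pj <- which(plate_home == plate_of[i])
    if (length(pj)) {
      add <- c(add, rep(extra_total * 0.5 / length(pj), length(pj)))
      idx <- c(idx, match(plate_ids[pj], colnames(counts)))
    }
    if (length(idx)) {
      newc <- rpois(length(idx), add)
      counts[i, idx] <- counts[i, idx] + newc
      contam_added[i] <- sum(newc)
    }
  }

  # mock controls: expected species equimolar + this plate's contaminants
  mock_roles <- rep(c("mock_extraction", "mock_library"),
                    length.out = spec$mocks_per_plate)
  mock_rows <- list(); mock_meta <- list()
  for (pl in plates) {
    for (m in seq_len(spec$mocks_per_plate)) {
      depth <- max(round(rlnorm(1, log(5e4), 0.4)), 2000)
      comp <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
      comp[mock_ids] <- 1 / 10
      cont_here <- c(cohort_ids, plate_ids[plate_home == pl])
      if (length(cont_here)) {
        per <- spec$mock_share / length(cont_here)
        comp[cont_here] <- per
      }
      comp <- comp / sum(comp)
      mock_rows[[length(mock_rows) + 1L]] <-
        as.integer(rmultinom(1, depth, comp))
      mock_meta[[length(mock_meta) + 1L]] <- data.frame(
        sample_id = sprintf("MOCK_%s_%d", pl, m), role = mock_roles[m],
        plate_id = pl,
        pcr_concentration = rlnorm(1, log(1.5), 0.3),
        sex = NA_character_, age = NA_real_, bmi = NA_real_,
        total_read_count = depth, stringsAsFactors = FALSE)
    }
  }
  if (length(mock_rows)) {
    mock_mat <- do.call(rbind, mock_rows)
    meta <- do.call(rbind, mock_meta)
    rownames(mock_mat) <- meta$sample_id
    colnames(mock_mat) <- colnames(counts)
    counts <- rbind(counts, mock_mat)
    extra_cols <- setdiff(names(sheet), names(meta))
    for (cc in extra_cols) meta[[cc]] <- NA
    sheet <- sample_sheet(rbind(as.data.frame(sheet),
                                meta[names(sheet)]))
  }

  tot <- rowSums(counts)
  ra <- counts / tot
  taxa <- rbind(table$taxa, data.frame(
    taxon_id = new_ids, rank = "species", lineage = new_ids,
    domain = "bacteria", name = display_name(new_ids),
    stringsAsFactors = FALSE))
  out_table <- taxon_profile_table(ra, taxa, read_counts = counts,
                                   total_reads = tot)
  truth$contaminant_taxa <- data.frame(
    taxon_id = c(cohort_ids, plate_ids),
    scope = c(rep("cohort", length(cohort_ids)),
              if (length(plate_ids)) paste0("plate:", plate_home)),
    stringsAsFactors = FALSE)
  cf <- contam_added / tot[seq_len(n)]
  truth$contamination_fraction <- stats::setNames(cf, table$sample_ids)
  list(table = out_table, sheet = sheet, truth = truth)
}

#' Generate independent diploid genotypes
#'
#' Dosages are i.i.d. Binomial(2, maf) per variant (Hardy-Weinberg by
#' construction), with uniform per-variant minor allele frequencies and
#' missing calls dropped in completely at random.
#'
#' @param n_samples,n_variants dimensions.
#' @param maf_range minor-allele-frequency range, within `(0, 0.5]`.
#' @param missing_rate per-call missing probability, within `[0, 0.1]`.
#' @param seed integer seed.
#' @param sample_ids optional ids (default `S0001`...).
#' @return a [genotype_table()] with a `maf` attribute (true values).
#' @export
generate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0.01, seed = 1,
                               sample_ids = NULL) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate <= 0.1)
  set.seed(seed + 2L)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n_samples * n_variants, 2,
                       rep(maf, each = n_samples)),
                nrow = n_samples)
  if (missing_rate > 0)
    dos[runif(length(dos)) < missing_rate] <- NA
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  variants <- data.frame(
    chrom = as.character(1 + (seq_len(n_variants) - 1) %% 22),
    pos = seq_len(n_variants) * 1000L,
    id = sprintf("var%05d", seq_len(n_variants)),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  out <- genotype_table(variants, dos, sample_ids)
  attr(out, "maf") <- maf
  out
}

#' Plant genotype-taxon associations
#'
#' Abundance mode multiplies the taxon's read counts by
#' `10^(beta * dosage)` (plus any genotype-by-environment term) before
#' renormalization; presence mode redraws the taxon's detection
#' indicator from `logit P = alpha + beta * centered dosage`, with
#' `alpha` set to preserve the taxon's marginal prevalence, resampling
#' nonzero counts for newly present samples.
#'
#' @param genotypes a [genotype_table()] whose samples are a superset of
#'   the table's samples.
#' @param table a [taxon_profile_table()] with read counts.
#' @param truth a `simulation_truth` to update.
#' @param effects data.frame with columns `variant_id`, `taxon_id`,
#'   `mode` (`"abundance"`/`"presence"`), `beta`; optional `gxe_env`
#'   (sheet column name) and `gxe_beta` with `env` a per-sample numeric
#'   vector supplied via the `env` argument.
#' @param seed integer seed.
#' @param env optional named list of per-sample environment vectors for
#'   G-by-E terms.
#' @return list with updated `table` and `truth`.
#' @export
plant_associations <- function(genotypes, table, truth, effects,
                               seed = 1, env = NULL) {
  set.seed(seed + 3L)
  counts <- table$read_counts
  stopifnot(!is.null(counts))
  ids <- table$sample_ids
  gmap <- match(ids, genotypes$sample_ids)
  if (anyNA(gmap)) stop("genotypes missing for some profile samples")
  for (r in seq_len(nrow(effects))) {
    ef <- effects[r, ]
    j <- match(ef$taxon_id, table$taxa$taxon_id)
    if (is.na(j)) stop("taxon ", ef$taxon_id, " absent from table")
    v <- match(ef$variant_id, genotypes$variants$id)
    if (is.na(v)) stop("variant ", ef$variant_id, " absent")
    dose <- genotypes$dosages[gmap, v]
    dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    shift <- ef$beta * dose
    if (!is.null(ef$gxe_beta) && !is.na(ef$gxe_beta) &&
        !is.null(env) && !is.null(env[[ef$gxe_env]]))
      shift <- shift + ef$gxe_beta * dose * env[[ef$gxe_env]]
    if (ef$mode == "abundance") {
      counts[, j] <- round(counts[, j] * 10^shift)
    } else {
      prev <- mean(counts[, j] > 0)
      alpha <- qlogis(min(max(prev, 0.02), 0.98))
      p <- plogis(alpha + shift - mean(shift))
      present <- runif(length(p)) < p
      nz <- counts[counts[, j] > 0, j]
      if (!length(nz)) nz <- 10
      newc <- counts[, j]
      newc[!present] <- 0L
      need <- present & counts[, j] == 0
      newc[need] <- sample(nz, sum(need), replace = TRUE)
      counts[, j] <- newc
    }
  }
  tot <- rowSums(counts)
  ra <- counts / tot
  out <- taxon_profile_table(ra, table$taxa, read_counts = counts,
                             total_reads = tot)
  truth$planted_effects <- rbind(truth$planted_effects, effects)
  list(table = out, truth = truth)
}
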