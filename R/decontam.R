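#' Default thresholds for the three-step decontamination
#'
#' Step 1 flags a species cohort-wide when ANY of these hold:
#' (a) relative abundance significantly (Spearman, p < `p_spearman`)
#' correlated with PCR concentration; (b) `p_freq < p_freq_max` or
#' occurrence in fewer than `min_occurrence` study samples; (c) detected
#' in the mock controls, other than the expected mock species, with mean
#' relative abundance above `mock_mean`; (d) cohort-summed read count
#' below `min_reads`. Step 2 then flags, per 96-well plate, surviving
#' non-expected species seen in that plate's mock above `mock_mean`.
#'
#' @param p_spearman two-sided Spearman significance level for (a).
#' @param spearman_direction `"two_sided"` (the literal criterion) or
#'   `"negative"` (restrict to rho < 0, the contaminant-theoretic
#'   variant).
#' @param p_freq_max frequency-model p-value cutoff for (b).
#' @param min_occurrence minimum number of study samples with nonzero
#'   abundance for (b).
#' @param mock_mean mock-control mean relative-abundance floor for (c)
#'   and for Step 2.
#' @param min_reads minimum cohort-summed read count for (d).
#' @param reads_per_sample apply (d) per sample instead of cohort-summed
#'   (non-default interpretation).
#' @param expected_species taxon ids exempt from the mock criteria.
#' @return a named list of parameters.
#' @export
decontam_params <- function(p_spearman = 0.05,
                            spearman_direction = c("two_sided", "negative"),
                            p_freq_max = 0.3,
                            min_occurrence = 4,
                            mock_mean = 1e-4,
                            min_reads = 1000,
                            reads_per_sample = FALSE,
                            expected_species = mock_expected_species()) {
  list(p_spearman = p_spearman,
       spearman_direction = match.arg(spearman_direction),
       p_freq_max = p_freq_max,
       min_occurrence = min_occurrence,
       mock_mean = mock_mean,
       min_reads = min_reads,
       reads_per_sample = reads_per_sample,
       expected_species = expected_species)
}

#' Frequency-model contaminant p-value
#'
#' Compares, on samples with positive abundance and measured
#' concentration, a contaminant model (log10 frequency vs log10
#' concentration with slope fixed at -1, free intercept) against a
#' non-contaminant model (slope 0, free intercept) by the residual
#' sum-of-squares ratio `lambda = SS_contam / SS_noncontam`, referred to
#' an F(n-1, n-1) distribution. Small values are contaminant-like. The
#' statistic is invariant to rescaling the concentrations by a positive
#' constant.
#'
#' @param freqs per-sample relative abundance of one taxon.
#' @param conc per-sample PCR concentration (ng/uL).
#' @param min_samples minimum usable samples (default 5); below this the
#'   p-value is undefined (`NA`).
#' @return p-value in `[0, 1]`, or `NA` when undefined.
#' @export
freq_contaminant_pvalue <- function(freqs, conc, min_samples = 5) {
  use <- which(freqs > 0 & !is.na(conc) & conc > 0)
  n <- length(use)
  if (n < min_samples) return(NA_real_)
  y <- log10(freqs[use])
  x <- log10(conc[use])
  ss_contam <- sum((y + x - mean(y + x))^2)
  ss_non <- sum((y - mean(y))^2)
  lambda <- ss_contam / max(ss_non, 1e-12)
  pf(lambda, n - 1, n - 1)
}

new_flag <- function(taxon_id, reasons = character(0), scope = "cohort",
                     p_freq = NA_real_, spearman_rho = NA_real_,
                     spearman_p = NA_real_, occurrence = NA_integer_,
                     total_reads = NA_real_) {
  list(taxon_id = taxon_id, flagged = length(reasons) > 0,
       reasons = reasons, scope = scope, p_freq = p_freq,
       spearman_rho = spearman_rho, spearman_p = spearman_p,
       occurrence = occurrence, total_reads = total_reads)
}

#' Step 1: cohort-wide contaminant flags
#'
#' Applies the four OR-combined criteria (see [decontam_params()]) to
#' every taxon, using study samples for the concentration-based
#' statistics and mock controls for the mock criterion.
#'
#' @param table a [taxon_profile_table()] with a read-count layer (for
#'   criterion (d); without one (d) is skipped with a warning).
#' @param sheet a [sample_sheet()] covering the table's samples.
#' @param params a [decontam_params()] list.
#' @return list of per-taxon flag records (`contaminant_flags` class);
#'   `flagged` is `TRUE` iff at least one criterion held.
#' @export
flag_cohort_contaminants <- function(table, sheet,
                                     params = decontam_params()) {
  stopifnot(inherits(table, "taxon_profile_table"))
  sheet <- sheet[match(table$sample_ids, sheet$sample_id), ]
  study <- which(sheet$role == "study")
  mocks <- which(sheet$role %in% c("mock_extraction", "mock_library"))
  conc <- if (!is.null(sheet$pcr_concentration))
    sheet$pcr_concentration[study] else rep(NA_real_, length(study))
  have_conc <- any(!is.na(conc))
  if (!have_conc)
    warning("no PCR concentrations: criteria (a) and (b, p_freq) skipped")
  if (!length(mocks))
    warning("no mock controls: mock criterion skipped")
  if (is.null(table$read_counts))
    warning("no read-count layer: read-count criterion skipped")
  lapply(seq_len(nrow(table$taxa)), function(j) {
    tid <- table$taxa$taxon_id[j]
    fr <- table$relabund[study, j]
    reasons <- character(0)
    rho <- p_sp <- pf_ <- NA_real_
    if (have_conc) {
      usable <- !is.na(conc)
      if (sum(usable) >= 3 && sd(fr[usable]) > 0) {
        ct <- suppressWarnings(
          cor.test(fr[usable], conc[usable], method = "spearman",
                   exact = FALSE))
        rho <- unname(ct$estimate); p_sp <- ct$p.value
        hit <- !is.na(p_sp) && p_sp < params$p_spearman
        if (params$spearman_direction == "negative")
          hit <- hit && !is.na(rho) && rho < 0
        if (hit) reasons <- c(reasons, "CORR_PCR")
      }
      pf_ <- freq_contaminant_pvalue(fr, conc)
      if (!is.na(pf_) && pf_ < params$p_freq_max)
        reasons <- c(reasons, "PFREQ")
    }
    occ <- sum(fr > 0)
    if (occ < params$min_occurrence) reasons <- c(reasons, "OCCURRENCE")
    if (length(mocks) && !(tid %in% params$expected_species)) {
      mock_mean <- mean(table$relabund[mocks, j])
      if (mock_mean > params$mock_mean)
        reasons <- c(reasons, "MOCK_COHORT")
    }
    reads <- NA_real_
    if (!is.null(table$read_counts)) {
      reads <- if (params$reads_per_sample)
        max(table$read_counts[study, j]) else sum(table$read_counts[study, j])
      if (reads < params$min_reads) reasons <- c(reasons, "READS")
    }
    new_flag(tid, reasons, "cohort", p_freq = pf_, spearman_rho = rho,
             spearman_p = p_sp, occurrence = as.integer(occ),
             total_reads = reads)
  })
}

#' Step 2: plate-specific contaminant flags
#'
#' On taxa surviving Step 1, flags any non-expected species detected in a
#' plate's mock control above the mean-abundance floor; removal is scoped
#' to that plate only.
#'
#' @inheritParams flag_cohort_contaminants
#' @param cohort_flags output of [flag_cohort_contaminants()]; taxa
#'   already flagged cohort-wide are not re-flagged.
#' @return list of flag records with scope `"plate:<id>"`.
#' @export
flag_plate_contaminants <- function(table, sheet,
                                    params = decontam_params(),
                                    cohort_flags = NULL) {
  sheet <- sheet[match(table$sample_ids, sheet$sample_id), ]
  removed <- if (is.null(cohort_flags)) character(0) else
    vapply(Filter(function(f) f$flagged, cohort_flags),
           `[[`, character(1), "taxon_id")
  mock_idx <- which(sheet$role %in% c("mock_extraction", "mock_library"))
  plates <- unique(sheet$plate_id[sheet$role == "study"])
  plates <- plates[!is.na(plates)]
  flags <- list()
  for (pl in plates) {
    pm <- mock_idx[sheet$plate_id[mock_idx] %in% pl]
    if (!length(pm)) {
      warning("plate ", pl, " has no mock control; skipped")
      next
    }
    mm <- colMeans(table$relabund[pm, , drop = FALSE])
    hits <- which(mm > params$mock_mean &
                    !(table$taxa$taxon_id %in% params$expected_species) &
                    !(table$taxa$taxon_id %in% removed))
    for (j in hits)
      flags[[length(flags) + 1L]] <-
        new_flag(table$taxa$taxon_id[j], "PLATE_MOCK",
                 scope = paste0("plate:", pl))
  }
  flags
}

#' Step 3: apply flags, drop non-bacterial taxa, renormalize
#'
#' Zeroes flagged taxa (cohort-wide or on the flagged plate only),
#' removes taxa outside `keep_domains`, renormalizes every sample to sum
#' 1, and reports the per-sample contaminated fraction (reads of flagged
#' taxa over total reads, computed before renormalization). Samples
#' losing all their reads are marked empty and excluded from the cleaned
#' table.
#'
#' @param table a [taxon_profile_table()].
#' @param flags combined Step 1 + Step 2 flag list.
#' @param sheet a [sample_sheet()] (needed to resolve plate scopes).
#' @param keep_domains taxon domains retained (default bacteria only).
#' @param drop_controls remove mock/negative control samples from the
#'   cleaned table (default `TRUE`).
#' @return list with `table` (cleaned, renormalized) and `report` (a
#'   `decontam_report`: per-sample contaminated fractions, removal counts
#'   by reason, summary stats).
#' @export
apply_decontamination <- function(table, flags, sheet = NULL,
                                  keep_domains = "bacteria",
                                  drop_controls = TRUE) {
  stopifnot(inherits(table, "taxon_profile_table"))
  W <- if (!is.null(table$read_counts)) table$read_counts else table$relabund
  tot <- rowSums(W)
  removed_mass <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  zero_mask <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  plate_of <- if (!is.null(sheet))
    stats::setNames(sheet$plate_id, sheet$sample_id) else NULL
  reason_counts <- integer(0)
  for (f in flags) {
    if (!f$flagged) next
    j <- match(f$taxon_id, table$taxa$taxon_id)
    if (is.na(j)) next
    rows <- if (identical(f$scope, "cohort")) {
      seq_len(nrow(W))
    } else {
      pl <- sub("^plate:", "", f$scope)
      if (is.null(plate_of))
        stop("plate-scoped flags require the sample sheet")
      which(plate_of[rownames(W)] %in% pl)
    }
    zero_mask[rows, j] <- TRUE
    for (r in f$reasons)
      reason_counts[r] <- (if (r %in% names(reason_counts))
        reason_counts[r] else 0L) + 1L
  }
  removed_mass[zero_mask] <- W[zero_mask]
  contaminated_fraction <- ifelse(tot > 0, rowSums(removed_mass) / tot, 0)

  W2 <- W; W2[zero_mask] <- 0
  keep_tax <- table$taxa$domain %in% keep_domains
  cohort_removed <- colSums(!zero_mask) == 0  # fully removed everywhere
  retain <- keep_tax & !cohort_removed
  W3 <- W2[, retain, drop = FALSE]
  tax3 <- table$taxa[retain, , drop = FALSE]
  rownames(tax3) <- NULL

  keep_samp <- rep(TRUE, nrow(W3))
  if (drop_controls && !is.null(sheet)) {
    role <- stats::setNames(sheet$role, sheet$sample_id)[rownames(W3)]
    keep_samp <- is.na(role) | role == "study"
  }
  rs <- rowSums(W3)
  empty <- rs == 0
  keep_samp <- keep_samp & !empty
  W3 <- W3[keep_samp, , drop = FALSE]
  rs <- rs[keep_samp]
  ra <- W3 / rs
  rc <- if (!is.null(table$read_counts)) W3 else NULL
  cleaned <- taxon_profile_table(ra, tax3, read_counts = rc,
                                 normalized = TRUE)
  frac <- contaminated_fraction
  report <- structure(list(
    per_sample_contaminated_fraction = stats::setNames(frac, rownames(W)),
    n_taxa_removed = sum(table$taxa$taxon_id %in%
                           vapply(Filter(function(f) f$flagged, flags),
                                  `[[`, character(1), "taxon_id")),
    n_taxa_removed_by_reason = reason_counts,
    n_nonbacterial_removed = sum(!keep_tax),
    n_taxa_retained = ncol(W3),
    n_samples_emptied = sum(empty),
    summary = c(mean = mean(frac), median = median(frac),
                quantile(frac, c(0.25, 0.75, 0.95)))),
    class = "decontam_report")
  list(table = cleaned, report = report)
}

#' @export
print.decontam_report <- function(x, ...) {
  cat(sprintf(
    "decontam_report: %d taxa flagged, %d non-bacterial removed, %d retained\n",
    x$n_taxa_removed, x$n_nonbacterial_removed, x$n_taxa_retained))
  cat(sprintf("  contaminated fraction: mean %.2f%%, median %.2f%%\n",
              100 * x$summary["mean"], 100 * x$summary["median"]))
  invisible(x)
}

#' Prevalence / mean-abundance feature filter
#'
#' Keeps taxa present in more than `min_prevalence` of samples AND with
#' mean relative abundance above `min_mean_relabund`. No renormalization
#' is applied: downstream ratio-preserving analyses use the retained
#' fraction as-is, and the table is flagged unnormalized.
#'
#' @param table a decontaminated [taxon_profile_table()].
#' @param min_prevalence fraction of samples (strictly greater-than).
#' @param min_mean_relabund mean relative abundance (strictly
#'   greater-than).
#' @return filtered `taxon_profile_table` (unnormalized) with a
#'   `filter_params` attribute.
#' @export
feature_filter <- function(table, min_prevalence = 0.10,
                           min_mean_relabund = 1e-4) {
  stopifnot(inherits(table, "taxon_profile_table"))
  prev <- colMeans(table$relabund > 0)
  mn <- colMeans(table$relabund)
  keep <- prev > min_prevalence & mn > min_mean_relabund
  if (!any(keep))
    stop("feature filter removed every taxon (prevalence floor ",
         min_prevalence, ", mean floor ", min_mean_relabund, ")")
  out <- subset_profile(table, taxa = keep, renormalize = FALSE)
  attr(out, "filter_params") <- c(min_prevalence = min_prevalence,
                                  min_mean_relabund = min_mean_relabund)
  out
}

#' Flags as a tidy data.frame
#' @param flags list of flag records.
#' @return data.frame with one row per flag.
#' @export
flags_as_data_frame <- function(flags) {
  do.call(rbind, lapply(flags, function(f)
    data.frame(taxon_id = f$taxon_id, flagged = f$flagged,
               reasons = paste(f$reasons, collapse = ";"),
               scope = f$scope, p_freq = f$p_freq,
               spearman_rho = f$spearman_rho, spearman_p = f$spearman_p,
               occurrence = f$occurrence, total_reads = f$total_reads,
               stringsAsFactors = FALSE)))
}
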