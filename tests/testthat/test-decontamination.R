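test_that("freq_contaminant_pvalue separates the two generative models", {
  conc <- exp(seq(log(0.5), log(20), length.out = 10))
  # frequency exactly proportional to 1/concentration: contaminant-like
  expect_lt(freq_contaminant_pvalue(0.01 / conc, conc), 0.01)
  # constant frequency: non-contaminant-like
  expect_gt(freq_contaminant_pvalue(rep(0.01, 10), conc), 0.5)
  # invariant to rescaling concentration by a positive constant
  f <- c(0.02, 0.01, 0.005, 0.004, 0.002, 0.01, 0.02, 0.004)
  cc <- c(1, 2, 4, 5, 9, 2.5, 1.2, 5.5)
  expect_equal(freq_contaminant_pvalue(f, cc),
               freq_contaminant_pvalue(f, 1000 * cc), tolerance = 1e-12)
  # under 5 usable samples -> undefined
  expect_true(is.na(freq_contaminant_pvalue(c(0.1, 0.1, 0, 0, 0),
                                            rep(1, 5))))
})

test_that("p_freq calibration: slope -1 taxa score below slope-0 taxa", {
  set.seed(21)
  n <- 50
  p_cont <- p_null <- numeric(200)
  for (r in 1:200) {
    conc <- rlnorm(n, log(2), 0.7)
    f_cont <- 10^(-2 - log10(conc) + rnorm(n, 0, 0.3))
    f_null <- 10^(-2 + rnorm(n, 0, 0.3))
    p_cont[r] <- freq_contaminant_pvalue(f_cont, conc)
    p_null[r] <- freq_contaminant_pvalue(f_null, conc)
  }
  expect_lt(median(p_cont), median(p_null))
  expect_lt(wilcox.test(p_cont, p_null, alternative = "less")$p.value,
            1e-6)
})

make_decon_fixture <- function() {
  # 8 study samples on 2 plates + 2 mocks; read-count layer present
  set.seed(77)
  n <- 8
  counts <- matrix(rpois(n * 4, c(500, 300, 200, 100)), n, 4,
                   byrow = TRUE)
  counts[, 4] <- c(40, 30, 0, 0, 0, 0, 0, 0)   # occurrence 2 (< 4)
  ids <- c("k__Bacteria|s__A", "k__Bacteria|s__B",
           "k__Eukaryota|s__Yeast", "k__Bacteria|s__Rare")
  mock_counts <- rbind(c(0, 12, 0, 0), c(0, 9, 0, 0))  # B in both mocks
  counts <- rbind(counts, mock_counts)
  rownames(counts) <- c(sprintf("S%d", 1:n), "M1", "M2")
  ra <- counts / rowSums(counts)
  taxa <- data.frame(taxon_id = ids, rank = "species", lineage = ids,
                     domain = c("bacteria", "bacteria", "non-bacteria",
                                "bacteria"),
                     name = sub(".*s__", "", ids), stringsAsFactors = FALSE)
  tab <- taxon_profile_table(ra, taxa, read_counts = counts)
  sheet <- sample_sheet(data.frame(
    sample_id = rownames(counts),
    role = c(rep("study", n), "mock_extraction", "mock_extraction"),
    plate_id = c(rep(c("P1", "P2"), each = n / 2), "P1", "P2"),
    pcr_concentration = c(rlnorm(n, log(2), 0.5), 1.5, 1.5),
    stringsAsFactors = FALSE))
  list(table = tab, sheet = sheet)
}

test_that("cohort flags implement the OR of the four criteria", {
  fx <- make_decon_fixture()
  fl <- flag_cohort_contaminants(fx$table, fx$sheet,
                                 decontam_params(min_reads = 1000))
  df <- flags_as_data_frame(fl)
  # occurrence in < 4 study samples
  rare <- df[df$taxon_id == "k__Bacteria|s__Rare", ]
  expect_true(rare$flagged)
  expect_match(rare$reasons, "OCCURRENCE")
  expect_match(rare$reasons, "READS")      # 70 reads < 1000 cohort-wide
  # taxon B: present in mocks above 1e-4, not an expected species
  b <- df[df$taxon_id == "k__Bacteria|s__B", ]
  expect_match(b$reasons, "MOCK_COHORT")
  # expected species are exempt from the mock criterion
  fl2 <- flag_cohort_contaminants(
    fx$table, fx$sheet,
    decontam_params(min_reads = 0,
                    expected_species = "k__Bacteria|s__B"))
  b2 <- flags_as_data_frame(fl2)
  expect_false(grepl("MOCK_COHORT",
                     b2$reasons[b2$taxon_id == "k__Bacteria|s__B"]))
})

test_that("read-count criterion uses the cohort-summed interpretation", {
  fx <- make_decon_fixture()
  # taxon A has thousands of reads; with min_reads above its total it flips
  totA <- sum(fx$table$read_counts[1:8, "k__Bacteria|s__A"])
  fl <- flag_cohort_contaminants(fx$table, fx$sheet,
                                 decontam_params(min_reads = totA + 1))
  df <- flags_as_data_frame(fl)
  expect_match(df$reasons[df$taxon_id == "k__Bacteria|s__A"], "READS")
})

test_that("plate flags are scoped and thresholded", {
  fx <- make_decon_fixture()
  # taxon A at 5e-4 in P1's mock only (B is made an expected species so
  # only A drives the plate criterion)
  tab <- fx$table
  counts <- tab$read_counts
  counts["M1", "k__Bacteria|s__A"] <- 50
  counts["M1", "k__Bacteria|s__B"] <- 99950
  counts["M2", "k__Bacteria|s__B"] <- 1e5
  ra <- counts / rowSums(counts)
  tab2 <- taxon_profile_table(ra, tab$taxa, read_counts = counts)
  pars <- decontam_params(expected_species = "k__Bacteria|s__B")
  pf <- flag_plate_contaminants(tab2, fx$sheet, pars)
  df <- flags_as_data_frame(pf)
  a_rows <- df[df$taxon_id == "k__Bacteria|s__A", ]
  expect_true("plate:P1" %in% a_rows$scope)
  expect_false("plate:P2" %in% a_rows$scope)
  # at 5e-5 (below the 1e-4 floor): not flagged
  counts["M1", "k__Bacteria|s__A"] <- 5
  counts["M1", "k__Bacteria|s__B"] <- 99995
  ra <- counts / rowSums(counts)
  tab3 <- taxon_profile_table(ra, tab$taxa, read_counts = counts)
  pf3 <- flag_plate_contaminants(tab3, fx$sheet, pars)
  expect_false("k__Bacteria|s__A" %in% flags_as_data_frame(pf3)$taxon_id)
})

test_that("apply_decontamination: fractions, renormalization, idempotence", {
  # sample where flagged taxon holds 10% of reads
  counts <- rbind(S1 = c(900, 100), S2 = c(1000, 0))
  ids <- c("k__Bacteria|s__Good", "k__Bacteria|s__Bad")
  taxa <- data.frame(taxon_id = ids, rank = "species", lineage = ids,
                     domain = "bacteria", name = c("Good", "Bad"),
                     stringsAsFactors = FALSE)
  tab <- taxon_profile_table(counts / rowSums(counts), taxa,
                             read_counts = counts)
  fl <- list(list(taxon_id = "k__Bacteria|s__Bad", flagged = TRUE,
                  reasons = "MOCK_COHORT", scope = "cohort"))
  out <- apply_decontamination(tab, fl)
  expect_equal(unname(out$report$per_sample_contaminated_fraction),
               c(0.10, 0))
  expect_equal(unname(rowSums(out$table$relabund)), c(1, 1))
  # idempotence: re-applying with the same flags changes nothing
  out2 <- apply_decontamination(out$table, fl)
  expect_equal(out2$table$relabund, out$table$relabund)
  expect_equal(unname(out2$report$per_sample_contaminated_fraction),
               c(0, 0))
  # no flags on an all-bacterial table: identity
  out3 <- apply_decontamination(tab, list())
  expect_equal(out3$table$relabund, tab$relabund)
  expect_true(all(out3$report$per_sample_contaminated_fraction == 0))
})

test_that("non-bacterial taxa are removed without counting as contamination", {
  fx <- make_decon_fixture()
  out <- apply_decontamination(fx$table, list(), fx$sheet)
  expect_false("k__Eukaryota|s__Yeast" %in% out$table$taxa$taxon_id)
  expect_equal(out$report$n_nonbacterial_removed, 1)
  expect_true(all(out$report$per_sample_contaminated_fraction == 0))
  expect_equal(unname(rowSums(out$table$relabund)),
               rep(1, nrow(out$table$relabund)), tolerance = 1e-9)
})

test_that("feature filter applies both rules strictly", {
  set.seed(5)
  n <- 100
  ra <- matrix(0, n, 3)
  ra[1:9, 1] <- 0.5          # 9% prevalence -> dropped
  ra[1:11, 2] <- 0.02        # 11% prevalence, mean 2.2e-3 -> kept
  ra[1:50, 3] <- 1e-4        # mean 5e-5 at 50% prevalence -> dropped
  ra[, 2] <- ra[, 2] + 1e-6  # keep rows nonzero
  rownames(ra) <- paste0("S", 1:n)
  tab <- tiny_profile(ra)
  tab$normalized <- FALSE
  ff <- feature_filter(tab)
  expect_equal(ff$taxa$taxon_id, "k__Bacteria|s__T2")
  # zero thresholds -> identity on the taxon set
  ff0 <- feature_filter(tab, 0, 0)
  expect_equal(nrow(ff0$taxa), 3)
  expect_error(feature_filter(tab, 0.999, 0.9), "removed every")
})

test_that("removing criteria monotonically shrinks the flag set", {
  g <- generate_profiles(sim_config(n_study = 150, n_taxa = 40,
                                    n_plates = 2), seed = 17)
  s <- spike_contaminants(g$table, g$sheet, g$truth, contaminant_spec(),
                          seed = 17)
  full <- flag_cohort_contaminants(s$table, s$sheet, decontam_params())
  # disable the mock and reads criteria: flags must be a subset
  weak <- flag_cohort_contaminants(
    s$table, s$sheet, decontam_params(mock_mean = Inf, min_reads = 0))
  f_full <- flags_as_data_frame(full)
  f_weak <- flags_as_data_frame(weak)
  expect_true(all(f_weak$taxon_id[f_weak$flagged] %in%
                    f_full$taxon_id[f_full$flagged]))
})
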