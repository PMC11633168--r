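#' Diploid genotype dosage table
#'
#' Biallelic variants only; dosage counts copies of the alternate allele
#' (0/1/2, `NA` for missing).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`.
#' @param dosages numeric matrix, samples in rows, variants in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector matching `nrow(dosages)`.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(variants, dosages, sample_ids) {
  stopifnot(is.data.frame(variants), is.matrix(dosages),
            nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  if (nrow(variants) && any(variants$pos < 1)) stop("pos must be >= 1")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosage must be 0, 1, 2 or missing")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(variants = variants, dosages = dosages,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d variants\n",
              length(x$sample_ids), nrow(x$variants)))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Read genotypes from a VCF
#'
#' Dosage is the per-sample count of alternate alleles in the GT field;
#' `./.` (or any call containing `.`) becomes missing. Multiallelic
#' records are skipped with a reported count (or rejected in strict
#' mode); phasing is ignored.
#'
#' @param path VCF v4.x file (plain text or bgzipped).
#' @param strict error instead of skipping multiallelic records.
#' @return a [genotype_table()] with a `n_multiallelic_skipped`
#'   attribute.
#' @export
read_genotypes <- function(path, strict = FALSE) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1
  if (any(multi) && strict) stop("multiallelic record(s) in strict mode")
  keep <- !multi
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) gt <- matrix(character(0), nrow = sum(keep), ncol = 0)
  gt <- gt[keep, , drop = FALSE]
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr),
    ref = as.character(rr$REF),
    alt = vapply(seq_len(sum(keep)), function(i)
      as.character(alt[keep][[i]][1]), character(1)),
    stringsAsFactors = FALSE)
  dos <- gt_to_dosage(gt)
  out <- genotype_table(variants, t(dos), colnames(gt))
  attr(out, "n_multiallelic_skipped") <- sum(multi)
  out
}

gt_to_dosage <- function(gt) {
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  if (!length(gt)) return(dos)
  clean <- gsub("\\|", "/", gt)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  hit <- lut[clean]
  dos[] <- hit
  dos
}

#' Write genotypes as a minimal VCF v4.2
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param seed optional seed recorded in the VCF header.
#' @export
write_genotypes <- function(gt, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", header_comment("vcf", seed)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", gt$sample_ids),
                   collapse = "\t"), con)
  if (nrow(gt$variants)) {
    gtstr <- matrix(c("0/0", "0/1", "1/1")[gt$dosages + 1],
                    nrow = nrow(gt$dosages))
    gtstr[is.na(gt$dosages)] <- "./."
    lines <- vapply(seq_len(nrow(gt$variants)), function(j) {
      v <- gt$variants[j, ]
      paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
              gtstr[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
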