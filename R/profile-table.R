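#' @useDynLib urobiome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
NULL

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Taxon relative-abundance profile table
#'
#' The universal currency of the pipeline: a samples x taxa matrix of
#' relative abundances with per-taxon lineage metadata and an optional
#' read-count layer. Per-sample abundances sum to 1 unless the table is
#' explicitly flagged `unnormalized` (in which case the retained fraction
#' is recorded per sample).
#'
#' @param relabund numeric matrix, samples in rows, taxa in columns,
#'   entries in `[0, 1]`.
#' @param taxa data.frame with columns `taxon_id`, `rank`, `lineage`,
#'   `domain` (one of `"bacteria"`, `"non-bacteria"`); one row per column
#'   of `relabund`.
#' @param read_counts optional non-negative integer matrix conformal with
#'   `relabund`; when present `relabund == read_counts / total_reads`.
#' @param total_reads optional per-sample non-negative totals; derived
#'   from `read_counts` when omitted.
#' @param normalized logical; `FALSE` marks a table whose rows sum to a
#'   retained fraction below 1 (e.g. after feature filtering).
#' @return an object of class `taxon_profile_table`.
#' @export
taxon_profile_table <- function(relabund, taxa, read_counts = NULL,
                                total_reads = NULL, normalized = TRUE) {
  stopifnot(is.matrix(relabund), is.data.frame(taxa))
  if (ncol(relabund) != nrow(taxa))
    stop("taxa metadata must have one row per abundance column")
  if (anyDuplicated(taxa$taxon_id))
    stop("duplicated taxon_id")
  if (any(relabund < 0, na.rm = TRUE))
    stop("negative relative abundance")
  if (is.null(rownames(relabund)))
    stop("relabund must carry sample ids as rownames")
  colnames(relabund) <- taxa$taxon_id
  if (!is.null(read_counts)) {
    stopifnot(all(dim(read_counts) == dim(relabund)))
    if (any(read_counts < 0, na.rm = TRUE)) stop("negative read count")
    if (is.null(total_reads)) total_reads <- rowSums(read_counts)
    dimnames(read_counts) <- dimnames(relabund)
  }
  if (!is.null(total_reads)) {
    stopifnot(length(total_reads) == nrow(relabund))
    total_reads <- stats::setNames(as.numeric(total_reads),
                                   rownames(relabund))
  }
  obj <- structure(
    list(sample_ids = rownames(relabund),
         taxa = taxa,
         relabund = relabund,
         read_counts = read_counts,
         total_reads = total_reads,
         normalized = isTRUE(normalized)),
    class = "taxon_profile_table")
  validate_profile_table(obj)
  obj
}

validate_profile_table <- function(x, tol = 1e-9) {
  rs <- rowSums(x$relabund)
  nonempty <- rs > 0
  if (x$normalized && any(abs(rs[nonempty] - 1) > 1e-6))
    stop("normalized table has per-sample sums deviating from 1")
  if (!is.null(x$read_counts) && !is.null(x$total_reads)) {
    ok <- x$total_reads > 0
    frac <- x$read_counts[ok, , drop = FALSE] / x$total_reads[ok]
    if (x$normalized && max(abs(frac - x$relabund[ok, , drop = FALSE])) > 1e-6)
      stop("read_counts / total_reads inconsistent with relabund")
  }
  invisible(x)
}

#' @export
print.taxon_profile_table <- function(x, ...) {
  cat(sprintf("taxon_profile_table: %d samples x %d taxa (%s)\n",
              length(x$sample_ids), nrow(x$taxa),
              if (x$normalized) "normalized" else "unnormalized"))
  cat(sprintf("  ranks: %s; counts layer: %s\n",
              paste(unique(x$taxa$rank), collapse = ","),
              if (is.null(x$read_counts)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.taxon_profile_table <- function(x) dim(x$relabund)

rank_from_lineage <- function(lineage) {
  last <- sub("^.*\\|", "", lineage)
  pref <- substr(last, 1, 3)
  hit <- match(pref, RANK_PREFIXES)
  ifelse(is.na(hit), NA_character_, names(RANK_PREFIXES)[hit])
}

display_name <- function(lineage) {
  last <- sub("^.*\\|", "", lineage)
  sub("^[kpcofgs]__", "", last)
}

lineage_domain <- function(lineage) {
  king <- sub("\\|.*$", "", lineage)
  king <- sub("^k__", "", king)
  ifelse(king %in% c("Bacteria", ""), "bacteria", "non-bacteria")
}

#' Subset a profile table
#'
#' @param table a [taxon_profile_table()].
#' @param samples,taxa character or logical selectors; `NULL` keeps all.
#' @param renormalize rescale each retained sample to sum 1 (default
#'   `FALSE`: sums record the retained fraction and the table is flagged
#'   unnormalized).
#' @return a `taxon_profile_table`.
#' @export
subset_profile <- function(table, samples = NULL, taxa = NULL,
                           renormalize = FALSE) {
  stopifnot(inherits(table, "taxon_profile_table"))
  si <- if (is.null(samples)) table$sample_ids else samples
  ti <- if (is.null(taxa)) table$taxa$taxon_id else taxa
  if (is.logical(si)) si <- table$sample_ids[si]
  if (is.logical(ti)) ti <- table$taxa$taxon_id[ti]
  ra <- table$relabund[si, ti, drop = FALSE]
  tx <- table$taxa[match(ti, table$taxa$taxon_id), , drop = FALSE]
  rownames(tx) <- NULL
  rc <- if (!is.null(table$read_counts))
    table$read_counts[si, ti, drop = FALSE] else NULL
  tot <- if (!is.null(table$total_reads)) table$total_reads[si] else NULL
  if (renormalize) {
    rs <- rowSums(ra)
    keep <- rs > 0
    ra[keep, ] <- ra[keep, , drop = FALSE] / rs[keep]
    if (!is.null(rc)) {
      tot <- rowSums(rc)
      rc2 <- rc
      rc2[tot > 0, ] <- rc[tot > 0, , drop = FALSE]
      rc <- rc2
    }
    taxon_profile_table(ra, tx, read_counts = NULL, total_reads = tot,
                        normalized = TRUE)
  } else {
    obj <- structure(
      list(sample_ids = si, taxa = tx, relabund = ra, read_counts = rc,
           total_reads = tot, normalized = FALSE),
      class = "taxon_profile_table")
    obj
  }
}

#' Read a MetaPhlAn-style taxon profile TSV
#'
#' Accepts the usual MetaPhlAn layout: lineage strings (rank prefixes
#' `k__`/`p__`/.../`s__`, pipe-separated) in the first column and one
#' column of abundances per sample. Percent-scale tables (columns summing
#' to about 100) and fractional tables are both accepted; the dialect is
#' decided by the median column sum (`> 2` means percent) and abundances
#' are always returned as fractions. The table is restricted to
#' `expected_rank` and renormalized so retained rows sum to 1.
#'
#' @param path TSV file path.
#' @param expected_rank taxonomic rank to retain (default `"species"`).
#' @param renormalize rescale retained rows to sum 1 (default `TRUE`).
#' @return a [taxon_profile_table()]; samples whose column sums are zero
#'   are kept but flagged via an `empty_samples` attribute.
#' @export
read_profile_table <- function(path, expected_rank = "species",
                               renormalize = TRUE) {
  expected_rank <- match.arg(expected_rank, TAXONOMIC_RANKS)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  lineage <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(lineage)) stop("duplicated taxon_id in profile file")
  if (any(mat < 0, na.rm = TRUE)) stop("negative abundance in profile file")
  ranks <- rank_from_lineage(lineage)
  bad <- is.na(ranks)
  if (any(bad)) {
    warning(sum(bad), " rows failed lineage parsing and were dropped")
    lineage <- lineage[!bad]; mat <- mat[!bad, , drop = FALSE]
    ranks <- ranks[!bad]
  }
  keep <- ranks == expected_rank
  lineage <- lineage[keep]; mat <- mat[keep, , drop = FALSE]
  # percent vs fraction dialect, decided on the rank-restricted columns
  if (median(colSums(mat)) > 2) mat <- mat / 100
  mat <- t(mat)  # samples x taxa
  empty <- rowSums(mat) == 0
  if (renormalize) {
    rs <- rowSums(mat)
    mat[!empty, ] <- mat[!empty, , drop = FALSE] / rs[!empty]
  }
  taxa <- data.frame(taxon_id = lineage,
                     rank = expected_rank,
                     lineage = lineage,
                     domain = lineage_domain(lineage),
                     name = display_name(lineage),
                     stringsAsFactors = FALSE)
  out <- taxon_profile_table(mat, taxa, normalized = renormalize)
  attr(out, "empty_samples") <- rownames(mat)[empty]
  out
}

#' Write a profile table as MetaPhlAn-style TSV
#'
#' Inverse of [read_profile_table()]: lineages in column 1, one sample
#' per column, fractional abundances. A header comment records provenance.
#'
#' @param table a [taxon_profile_table()].
#' @param path output path.
#' @param seed optional seed to record in the header comment.
#' @export
write_profile_table <- function(table, path, seed = NULL) {
  stopifnot(inherits(table, "taxon_profile_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment("profile", seed), con)
  df <- data.frame(clade_name = table$taxa$lineage,
                   t(table$relabund), check.names = FALSE)
  colnames(df)[-1] <- table$sample_ids
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

header_comment <- function(kind, seed = NULL) {
  sprintf("# urobiome %s v%s%s", kind,
          as.character(utils::packageVersion("urobiome")),
          if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
}
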