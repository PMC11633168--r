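SAMPLE_ROLES <- c("study", "mock_extraction", "mock_library", "negative")

#' Per-sample metadata sheet
#'
#' Holds the per-sample roles (study vs mock/negative controls), 96-well
#' plate membership, library PCR concentration, demographics and any
#' number of extra phenotype columns.
#'
#' @param df data.frame with at least `sample_id` and `role`; study
#'   samples must carry `plate_id`. Optional standard columns:
#'   `pcr_concentration` (ng/uL), `sex` (`"female"`/`"male"`), `age`,
#'   `bmi`, `total_read_count`. Remaining columns are treated as
#'   phenotypes.
#' @return a data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  stopifnot(is.data.frame(df), all(c("sample_id", "role") %in% names(df)))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$role %in% SAMPLE_ROLES))
    stop("unknown role; expected one of ", paste(SAMPLE_ROLES, collapse = ", "))
  study <- df$role == "study"
  if (is.null(df$plate_id)) df$plate_id <- NA_character_
  if (any(study & (is.na(df$plate_id) | df$plate_id == "")))
    stop("every study sample needs a plate_id")
  if (!is.null(df$pcr_concentration)) {
    df$pcr_concentration <- as.numeric(df$pcr_concentration)
    if (any(df$pcr_concentration <= 0, na.rm = TRUE))
      stop("pcr_concentration must be > 0 where measured")
  }
  if (!is.null(df$sex) && !all(is.na(df$sex) | df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Names of the free-form phenotype columns of a sample sheet
#' @param sheet a [sample_sheet()].
#' @return character vector of column names.
#' @export
phenotype_columns <- function(sheet) {
  std <- c("sample_id", "role", "plate_id", "pcr_concentration", "sex",
           "age", "bmi", "total_read_count")
  setdiff(names(sheet), std)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with a header; columns beyond the standard set are
#'   kept as phenotypes. `NA`/empty cells become missing values.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  sh <- sample_sheet(df)
  if (!is.null(sh$pcr_concentration)) {
    ctrl <- sh$role != "study" & sh$role != "negative"
    if (any(ctrl & is.na(sh$pcr_concentration)))
      warning("mock control(s) with missing pcr_concentration")
  }
  sh
}

#' Write a sample sheet TSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @export
write_sample_sheet <- function(sheet, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment("samples", seed), con)
  utils::write.table(as.data.frame(sheet), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
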