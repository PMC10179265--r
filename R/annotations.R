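#' Read a per-variant annotation table
#'
#' Tab-separated with a header row and a `variant_id` key column
#' (`chrom:pos:ref:alt`). Frequency columns are named `freq_<db>` (e.g.
#' `freq_gnomad`, `freq_internal`), in-silico scores `score_<tool>` (e.g.
#' `score_spliceai`, `score_ada`), and tissue expression `tpm`. Empty
#' cells, `"."` and `"NA"` are missing; a missing frequency means "not
#' observed" and is distinct from 0 in storage (it only counts as 0 at
#' filter time).
#'
#' @param path TSV file path.
#' @return data frame of annotations keyed by `variant_id`.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("", ".", "NA"),
                           check.names = FALSE, quote = "")
  if (!"variant_id" %in% names(ann)) stop("annotation table needs a variant_id column")
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  for (col in grep("^freq_", names(ann), value = TRUE)) {
    f <- ann[[col]]
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("frequency outside [0,1] in column ", col)
    }
  }
  if (!is.null(ann$tpm) && any(!is.na(ann$tpm) & ann$tpm < 0)) stop("negative tpm")
  invisible(ann)
}

#' Write an annotation table (round-trips through [read_annotation_table()])
#' @param ann annotation data frame.
#' @param path output TSV path.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read an allele-frequency table
#'
#' TSV with header: `variant_id` plus one column per database, values in
#' [0, 1] or missing. Column names may be bare db names (`gnomad`) or
#' already prefixed (`freq_gnomad`); the returned table always uses the
#' `freq_<db>` convention.
#'
#' @param path TSV file path.
#' @return data frame with `variant_id` and `freq_<db>` columns.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("", ".", "NA"),
                           check.names = FALSE, quote = "")
  if (!"variant_id" %in% names(tab)) stop("frequency table needs a variant_id column")
  dbcols <- setdiff(names(tab), "variant_id")
  names(tab)[match(dbcols, names(tab))] <-
    ifelse(grepl("^freq_", dbcols), dbcols, paste0("freq_", dbcols))
  validate_annotations(tab)
  tab
}

# Look up allele frequencies for filtering: absent entry/NA counts as 0.
freq_at_filter <- function(ann, ids, db) {
  col <- paste0("freq_", db)
  if (!col %in% names(ann)) stop("unknown db name: ", db)
  f <- ann[[col]][match(ids, ann$variant_id)]
  f[is.na(f)] <- 0
  f
}

#' Read a gene panel (one gene symbol per line)
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of unique gene symbols.
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(genes)
}

#' Write a gene panel
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @export
write_panel <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write a prioritization report
#'
#' One TSV row per surviving variant (plus any tier / path annotation
#' columns already joined onto `records`), followed by the filter trace as
#' `#trace` comment lines so a single file carries both the survivors and
#' the cascade audit.
#'
#' @param records data frame of surviving variant rows.
#' @param trace a [filter_trace()].
#' @param path output path.
#' @export
write_report <- function(records, trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(records, con, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = ".")
  for (i in seq_len(nrow(trace))) {
    writeLines(sprintf("#trace\t%s\t%d\t%d", trace$stage[i],
                       trace$count_in[i], trace$count_out[i]), con)
  }
  invisible(path)
}
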