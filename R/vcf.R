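#' Read a multi-sample VCF into a variant cohort
#'
#' Parses a VCFv4.2 file (only the GT FORMAT field is used), splits
#' multi-allelic sites into biallelic records (other alternate alleles
#' count as reference on each split record), normalizes indels to minimal
#' representation, and maps genotypes to dosages. If the header declares
#' the INFO fields `GENE` and `CSQ` they populate the `gene` and
#' `consequence` columns.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param pedigree optional [pedigree()]; if given, every VCF sample must
#'   be a pedigree id.
#' @return a [var_cohort()].
#' @export
read_cohort_vcf <- function(path, pedigree = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  samples <- colnames(vcf)
  if (!is.null(pedigree) && length(samples) > 0L) {
    extra <- setdiff(samples, pedigree$id)
    if (length(extra) > 0L) {
      stop("sample in VCF absent from pedigree: ", paste(extra, collapse = ", "))
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt) && length(samples) > 0L) stop("VCF has no GT field")
  inf <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(inf)) as.character(inf$GENE) else rep(NA_character_, length(pos))
  csq <- if ("CSQ" %in% names(inf)) as.character(inf$CSQ) else rep(NA_character_, length(pos))

  rows <- list()
  genos <- list()
  k <- 0L
  for (i in seq_along(pos)) {
    alts <- as.character(alt_list[[i]])
    for (a in seq_along(alts)) {
      if (alts[a] %in% c("", "*") || grepl("[<>\\[\\]]", alts[a])) next
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                              alt = alts[a], gene = gene[i], consequence = csq[i],
                              stringsAsFactors = FALSE)
      genos[[k]] <- if (length(samples) > 0L) geno_from_gt(gt[i, ], allele = a) else integer(0)
    }
  }
  if (k == 0L) {
    return(var_cohort(data.frame(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0)),
                      matrix(integer(0), 0, length(samples),
                             dimnames = list(NULL, samples))))
  }
  variants <- do.call(rbind, rows)
  gm <- do.call(rbind, genos)
  colnames(gm) <- samples
  var_cohort(variants, gm)
}

#' Write a variant cohort as a VCF file
#'
#' Emits a minimal VCFv4.2 with GT as the only FORMAT field and the
#' `gene`/`consequence` columns in the INFO fields `GENE`/`CSQ`.
#' [read_cohort_vcf()] round-trips its output.
#'
#' @param cohort a [var_cohort()].
#' @param path output file path.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  samples <- colnames(cohort$geno)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0L) c("FORMAT", samples)), collapse = "\t")
  )
  info <- ifelse(is.na(v$gene) & is.na(v$consequence), ".",
                 paste0(ifelse(is.na(v$gene), "", paste0("GENE=", v$gene)),
                        ifelse(is.na(v$gene) | is.na(v$consequence), "", ";"),
                        ifelse(is.na(v$consequence), "", paste0("CSQ=", v$consequence))))
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    fields <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", info[i])
    if (length(samples) > 0L) {
      fields <- c(fields, "GT", geno_to_gt(cohort$geno[i, ]))
    }
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
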