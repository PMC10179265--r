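#' Construct a variant cohort
#'
#' The canonical in-memory container for multi-sample calls: a variant
#' table plus a variants x individuals dosage matrix. Sites are normalized
#' to minimal representation, must be biallelic, and are sorted by
#' (chrom, pos, ref, alt).
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `gene`, `consequence`.
#' @param geno integer matrix (variants x individuals) of dosages, with
#'   column names the individual ids; may have zero columns.
#' @return An object of class `var_cohort`: list with elements `variants`
#'   (with a `variant_id` column `chrom:pos:ref:alt`) and `geno`.
#' @export
var_cohort <- function(variants, geno = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(variants$gene)) variants$gene <- rep(NA_character_, nrow(variants))
  if (is.null(variants$consequence)) {
    variants$consequence <- rep(NA_character_, nrow(variants))
  }
  if (nrow(variants) > 0L) {
    norm <- normalize_alleles(variants$pos, variants$ref, variants$alt)
    variants$pos <- norm$pos; variants$ref <- norm$ref; variants$alt <- norm$alt
    if (any(variants$ref == variants$alt)) stop("alt equals ref after normalization")
  }
  variants$variant_id <- variant_id(variants)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]), collapse = ", "))
  }
  if (is.null(geno)) {
    geno <- matrix(integer(0), nrow = nrow(variants), ncol = 0)
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants)) stop("geno rows must match variants")
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno))) stop("invalid dosage in geno")
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(variants) <- NULL
  rownames(geno) <- variants$variant_id
  structure(list(variants = variants, geno = geno), class = "var_cohort")
}

variant_id <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Normalize alleles to minimal representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing `pos`),
#' keeping at least one base on each allele. This is left alignment by
#' minimal representation; no reference genome is consulted.
#'
#' @param pos,ref,alt parallel vectors describing the sites.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]; a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' @export
print.var_cohort <- function(x, ...) {
  cat(sprintf("var_cohort: %d variants x %d individuals\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' Subset a cohort by variant ids
#' @param cohort a [var_cohort()].
#' @param ids variant ids to keep (order preserved from the cohort).
#' @return a [var_cohort()].
#' @export
subset_cohort <- function(cohort, ids) {
  keep <- cohort$variants$variant_id %in% ids
  out <- cohort
  out$variants <- cohort$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$geno <- cohort$geno[keep, , drop = FALSE]
  out
}

#' Number of variants in a cohort
#' @param cohort a [var_cohort()].
#' @return integer count.
#' @export
n_variants <- function(cohort) nrow(cohort$variants)
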