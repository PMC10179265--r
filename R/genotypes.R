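# Genotypes are stored as integer alternate-allele dosages:
#   0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing.

#' Convert VCF GT strings to dosage codes
#'
#' Accepts unphased ("0/1") and phased ("0|1") diploid GT strings. Any GT
#' containing "." is missing. For records produced by multi-allelic
#' splitting, `allele` selects which alternate allele is counted; other
#' alternate alleles count as reference on the split record.
#'
#' @param gt character vector of VCF GT strings.
#' @param allele integer index of the counted ALT allele (default 1).
#' @return integer vector of dosages (0/1/2/NA).
#' @export
geno_from_gt <- function(gt, allele = 1L) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  vapply(strsplit(gt, "/", fixed = TRUE), function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_integer_)
    if (!all(grepl("^[0-9]+$", a))) stop("malformed GT: ", paste(a, collapse = "/"))
    sum(as.integer(a) == allele)
  }, integer(1))
}

#' Convert dosage codes to VCF GT strings
#' @param geno integer vector of dosages (0/1/2/NA).
#' @return character vector of GT strings ("0/0", "0/1", "1/1", "./.").
#' @export
geno_to_gt <- function(geno) {
  out <- c("0/0", "0/1", "1/1")[geno + 1L]
  out[is.na(geno)] <- "./."
  out
}

#' Convert segregation-table symbols to dosage codes
#'
#' Symbols follow the convention used in family genotyping tables:
#' "+/+" normal (hom_ref), "-/+" heterozygote, "-/-" homozygote for the
#' variation. Both the ASCII hyphen and the Unicode minus are accepted;
#' empty strings and "NA" are missing.
#'
#' @param sym character vector of symbols.
#' @return integer vector of dosages.
#' @export
geno_from_symbol <- function(sym) {
  sym <- gsub("−", "-", trimws(sym))
  map <- c("+/+" = 0L, "-/+" = 1L, "+/-" = 1L, "-/-" = 2L)
  out <- map[sym]
  out[sym %in% c("", "NA", ".")] <- NA_integer_
  if (any(is.na(out) & !(sym %in% c("", "NA", ".")))) {
    stop("unknown genotype symbol: ",
         paste(unique(sym[is.na(out) & !(sym %in% c("", "NA", "."))]), collapse = ", "))
  }
  unname(out)
}

#' Convert dosage codes to segregation-table symbols
#' @param geno integer vector of dosages.
#' @return character vector of "+/+", "-/+", "-/-", "NA".
#' @export
geno_to_symbol <- function(geno) {
  out <- c("+/+", "-/+", "-/-")[geno + 1L]
  out[is.na(geno)] <- "NA"
  out
}
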