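# Worked-example fixtures: a reconstruction of a published consanguineous
# thyroid-cancer kindred (two branches, dominant inheritance with incomplete
# penetrance) and its candidate-variant genotype matrix, annotations, gene
# panels and interaction subnetwork. The pedigree connectivity beyond the
# genotyped members is a synthetic reconstruction from the published
# simplified drawing; it is bundled for worked examples and tests.

#' Reconstructed two-branch kindred pedigree
#'
#' 24 individuals over four generations. Affected means papillary thyroid
#' carcinoma; benign multinodular goiter and unexamined members carry the
#' phenotype `"unknown"`, so they contribute no segregation evidence.
#' 17 members are flagged sampled (DNA available) and the five exome-
#' sequenced patients used for the shared-variant intersection are flagged
#' sequenced.
#'
#' @return a [pedigree()].
#' @export
example_kindred_pedigree <- function() {
  df <- data.frame(stringsAsFactors = FALSE, rbind(
    c("I1",     NA,     NA,      "male",   "unknown"),
    c("I2",     NA,     NA,      "female", "unknown"),
    c("II1",    "I1",   "I2",    "male",   "unknown"),
    c("IIW1",   NA,     NA,      "female", "unknown"),
    c("II2",    "I1",   "I2",    "female", "affected"),
    c("II3",    NA,     NA,      "male",   "unknown"),
    c("III1",   "II1",  "IIW1",  "female", "affected"),
    c("III2",   "II1",  "IIW1",  "male",   "unaffected"),
    c("III3",   "II1",  "IIW1",  "female", "unknown"),
    c("III4",   "II1",  "IIW1",  "female", "unaffected"),
    c("III5",   "II1",  "IIW1",  "male",   "affected"),
    c("III6",   "II1",  "IIW1",  "male",   "unaffected"),
    c("III7",   "II1",  "IIW1",  "male",   "unknown"),
    c("III8",   "II1",  "IIW1",  "male",   "affected"),
    c("III9",   "II1",  "IIW1",  "female", "unknown"),
    c("III10",  "II1",  "IIW1",  "female", "affected"),
    c("IIIS1",  NA,     NA,      "male",   "unknown"),
    c("XFIII1", "II3",  "II2",   "male",   "affected"),
    c("XFIII2", "II3",  "II2",   "female", "unknown"),
    c("XFIII3", "II3",  "II2",   "male",   "unknown"),
    c("XFIII4", "II3",  "II2",   "male",   "affected"),
    c("XFIII5", "II3",  "II2",   "female", "affected"),
    c("IVA5",   "IIIS1", "III1", "female", "affected"),
    c("IVA8",   "IIIS1", "III1", "female", "unknown")))
  names(df) <- c("id", "father_id", "mother_id", "sex", "phenotype")
  sampled <- c(paste0("III", 1:10), paste0("XFIII", 1:5), "IVA5", "IVA8")
  sequenced <- c("III8", "III10", "IVA5", "XFIII4", "XFIII5")
  pedigree(df$id, df$father_id, df$mother_id, df$sex, df$phenotype,
           sequenced = df$id %in% sequenced, sampled = df$id %in% sampled)
}

#' Candidate-variant genotype matrix (4 variants x 11 individuals)
#'
#' The four germline candidates that survived the filter cascade, with
#' the Sanger-verified genotypes of the 11 informative family members.
#'
#' @return a [var_cohort()].
#' @export
example_candidate_cohort <- function() {
  variants <- data.frame(
    chrom = c("5", "17", "14", "17"),
    pos = c(73048875L, 18661699L, 92953131L, 19459316L),
    ref = c("A", "ACAT", "A", "G"),
    alt = c("G", "A", "G", "A"),
    gene = c("ARHGEF28", "FBXW10", "SLC24A4", "SLC47A1"),
    consequence = c("missense_variant", "inframe_deletion",
                    "splice_region_variant", "missense_variant"),
    stringsAsFactors = FALSE)
  ids <- c("III1", "III2", "III4", "III5", "III6", "III8", "III10", "IVA5",
           "XFIII1", "XFIII4", "XFIII5")
  sym <- rbind(
    c("-/+", "+/+", "+/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/-"),
    c("-/+", "-/+", "+/+", "-/+", "+/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/+"),
    c("-/+", "+/+", "-/+", "-/+", "+/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/+"),
    c("-/+", "-/+", "+/+", "-/-", "+/+", "-/+", "-/+", "-/+", "-/+", "-/+", "-/+"))
  geno <- matrix(geno_from_symbol(sym), nrow = 4,
                 dimnames = list(NULL, ids))
  var_cohort(variants, geno)
}

#' Annotations for the four germline candidates
#'
#' Internal-cohort allele frequencies are converted from the published
#' carrier proportions as het/2 + hom; the four public population
#' databases are recorded absent (the candidates passed a < 1% screen and
#' no numeric value is published). Expression is thyroid TPM; splice
#' scores exist only for the splice-region candidate.
#'
#' @return annotation data frame (see [read_annotation_table()]).
#' @export
example_candidate_annotations <- function() {
  co <- example_candidate_cohort()
  ids <- co$variants$variant_id[match(c("ARHGEF28", "FBXW10", "SLC24A4", "SLC47A1"),
                                      co$variants$gene)]
  data.frame(
    variant_id = ids,
    gene = c("ARHGEF28", "FBXW10", "SLC24A4", "SLC47A1"),
    freq_1kg = NA_real_, freq_evs = NA_real_, freq_exac = NA_real_,
    freq_gnomad = NA_real_,
    freq_internal = c(0.0057 / 2 + 0.0006, 0.0128 / 2, NA, 0.0147 / 2 + 0.0006),
    score_sift = c(0.14, NA, NA, 0.83),
    score_cadd = c(10.71, NA, 4.68, 22),
    score_polyphen = c(0.02, NA, NA, 0.73),
    score_spliceai = c(NA, NA, 0.17, NA),
    score_ada = c(NA, NA, 0.005, NA),
    tpm = c(19.44, 1.22, 0.20, 7.45),
    stringsAsFactors = FALSE)
}

#' 13-gene somatic panel of recurrently altered thyroid-cancer genes
#' @return character vector of 13 gene symbols.
#' @export
somatic_gene_panel <- function() {
  c("NRAS", "HRAS", "KRAS", "THADA", "PIK3CA", "BRAF", "TERT", "PAX8/PPARG",
    "PTEN", "DICER1", "EIF1AX", "TSHR", "TP53")
}

#' Germline thyroid-cancer susceptibility gene panel
#'
#' Genes reported as non-syndromic susceptibility or candidate genes for
#' familial non-medullary thyroid cancer; assembled from the main-text
#' gene lists of the source study (its full appendix panel is not
#' published).
#'
#' @return character vector of 19 gene symbols.
#' @export
susceptibility_gene_panel <- function() {
  c("NKX2.1", "FOXE1", "HABP2", "RTFC", "MYH9", "CHEK2", "MYO1F", "DICER1",
    "SRRM2", "MAP2K5", "SPRY4", "RASAL1", "SRGAP1", "BRCA1", "BRCA2", "ATM",
    "XRCC1", "PAX8", "HHEX")
}

#' Curated interaction subnetwork around the candidate genes
#'
#' The five experimentally supported edges linking the top candidate to
#' known thyroid-cancer genes: ARHGEF28-SQSTM1 (affinity chromatography),
#' SQSTM1-TP53 (affinity capture / reconstituted complex), ARHGEF28-MYH9
#' (cross-linking mass spectrometry), MYH9-PTCSC2 (lncRNA binding) and
#' PTCSC2-FOXE1 (regulatory target).
#'
#' @return an [interaction_graph()].
#' @export
example_ppi_edges <- function() {
  interaction_graph(data.frame(
    gene_a = c("ARHGEF28", "SQSTM1", "ARHGEF28", "MYH9", "PTCSC2"),
    gene_b = c("SQSTM1", "TP53", "MYH9", "PTCSC2", "FOXE1"),
    evidence = c("affinity_chromatography", "affinity_capture_western",
                 "cross_linking_MS", "lncRNA_binding", "regulatory_target"),
    stringsAsFactors = FALSE))
}

#' Paired tumor/germline fixture with planted somatic candidates
#'
#' A single-patient pair: the germline call set holds the patient's four
#' candidate-variant genotypes; the tumor call set adds the two published
#' somatic candidates (XRCC1 19:44047825 A>C, HRAS 11:533875 C>A) plus 22
#' decoys - 11 rare variants in genes outside both panels and 11 common
#' variants (10% in gnomAD) inside panel genes - together with one site
#' shared by tumor and germline and one tumor site whose germline
#' genotype is missing. Only the two planted candidates survive the
#' somatic cascade.
#'
#' @return list with `tumor`, `germline` (single-sample [var_cohort()]s
#'   for patient III8), `annotations`, and `expected` (the two planted
#'   variant ids).
#' @export
example_somatic_fixture <- function() {
  germ_v <- example_candidate_cohort()
  g8 <- germ_v$geno[, "III8", drop = FALSE]
  germ <- var_cohort(germ_v$variants[, c("chrom", "pos", "ref", "alt", "gene",
                                         "consequence")], g8)

  planted <- data.frame(
    chrom = c("19", "11"), pos = c(44047825L, 533875L),
    ref = c("A", "C"), alt = c("C", "A"),
    gene = c("XRCC1", "HRAS"),
    consequence = c("missense_variant", "missense_variant"),
    stringsAsFactors = FALSE)
  rare_decoys <- data.frame(
    chrom = as.character(1:11), pos = 5000000L + (1:11) * 1000L,
    ref = "A", alt = "T", gene = sprintf("DCY%02d", 1:11),
    consequence = "missense_variant", stringsAsFactors = FALSE)
  panel_genes <- c("TP53", "BRAF", "NRAS", "KRAS", "PTEN", "TSHR", "TERT",
                   "PIK3CA", "THADA", "MYH9", "CHEK2")
  common_decoys <- data.frame(
    chrom = as.character(1:11), pos = 7000000L + (1:11) * 1000L,
    ref = "G", alt = "C", gene = panel_genes,
    consequence = "missense_variant", stringsAsFactors = FALSE)
  # a site present in both tumor and germline (removed by subtraction) and
  # a tumor site with a missing germline call (conservatively removed)
  shared <- data.frame(chrom = "2", pos = 9000001L, ref = "C", alt = "G",
                       gene = "TP53", consequence = "missense_variant",
                       stringsAsFactors = FALSE)
  nocall <- data.frame(chrom = "3", pos = 9100001L, ref = "T", alt = "A",
                       gene = "BRAF", consequence = "missense_variant",
                       stringsAsFactors = FALSE)

  tum_v <- rbind(germ$variants[, names(planted)], planted, rare_decoys,
                 common_decoys, shared, nocall)
  tum_g <- matrix(c(germ$geno[, 1], rep(1L, nrow(planted) + nrow(rare_decoys) +
                                          nrow(common_decoys)), 1L, 1L),
                  ncol = 1, dimnames = list(NULL, "III8"))
  tumor <- var_cohort(tum_v, tum_g)

  germ_plus <- var_cohort(rbind(germ$variants[, names(planted)], shared, nocall),
                          matrix(c(germ$geno[, 1], 1L, NA_integer_), ncol = 1,
                                 dimnames = list(NULL, "III8")))

  ann <- data.frame(variant_id = tumor$variants$variant_id,
                    gene = tumor$variants$gene, stringsAsFactors = FALSE)
  for (db in c("1kg", "evs", "exac", "gnomad", "internal")) {
    ann[[paste0("freq_", db)]] <- NA_real_
  }
  ann$freq_gnomad[ann$gene %in% panel_genes] <- 0.10
  ann$freq_internal[ann$gene == "XRCC1"] <- 0.04
  ann$freq_gnomad[startsWith(ann$gene, "DCY")] <- 0.001
  validate_annotations(ann)

  pl_ids <- variant_id(planted)
  list(tumor = tumor, germline = germ_plus, annotations = ann,
       expected = pl_ids)
}
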