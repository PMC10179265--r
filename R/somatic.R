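#' Subtract germline calls from a tumor call set
#'
#' Retains tumor records carrying at least one alternate allele whose
#' matched (chrom, pos, ref, alt) germline genotype is homozygous
#' reference. A site entirely absent from the germline call set is treated
#' as homozygous reference (variant-only call sets do not list reference
#' sites), whereas a germline genotype explicitly missing ("./.") excludes
#' the site — a conservative choice that avoids calling somatic variants
#' in germline coverage gaps.
#'
#' @param tumor,germline [var_cohort()]s for the same individual.
#' @param individual the sample id present in both cohorts.
#' @return the somatic [var_cohort()] (tumor records only).
#' @export
subtract_germline <- function(tumor, germline, individual) {
  for (co in list(tumor = tumor, germline = germline)) {
    if (!individual %in% colnames(co$geno)) {
      stop("sample-id mismatch: ", individual, " not present in both call sets")
    }
  }
  tg <- tumor$geno[, individual]
  idx <- match(tumor$variants$variant_id, germline$variants$variant_id)
  gg <- ifelse(is.na(idx), 0L, germline$geno[idx, individual])
  keep <- !is.na(tg) & tg >= 1L & !is.na(gg) & gg == 0L
  subset_cohort(tumor, tumor$variants$variant_id[keep])
}

#' Population-frequency filter for somatic candidates
#'
#' Identical logic to [filter_population_frequency()] with the somatic
#' default threshold of 5%.
#'
#' @inheritParams filter_population_frequency
#' @param threshold allele-frequency cutoff (default 0.05).
#' @return the filtered [var_cohort()].
#' @export
filter_somatic_frequency <- function(cohort, annotations, dbs,
                                     threshold = 0.05) {
  filter_population_frequency(cohort, annotations, dbs, threshold)
}

#' Restrict somatic candidates to disease gene panels
#'
#' Keeps records whose gene is in the somatic panel (genes recurrently
#' altered in the tumor type) or the susceptibility panel (germline
#' predisposition genes); membership is pure set lookup. A gene in both
#' panels is labelled `somatic_panel`.
#'
#' @param cohort a [var_cohort()].
#' @param somatic_panel,susceptibility_panel nonempty character vectors of
#'   gene symbols.
#' @return data frame of somatic candidates with a `panel_hit` column
#'   (`"somatic_panel"` or `"susceptibility_panel"`).
#' @export
apply_panel <- function(cohort, somatic_panel, susceptibility_panel) {
  if (length(somatic_panel) == 0L || length(susceptibility_panel) == 0L) {
    stop("empty panel")
  }
  v <- cohort$variants
  hit <- ifelse(v$gene %in% somatic_panel, "somatic_panel",
                ifelse(v$gene %in% susceptibility_panel, "susceptibility_panel",
                       "none"))
  out <- v[hit != "none", , drop = FALSE]
  out$panel_hit <- hit[hit != "none"]
  rownames(out) <- NULL
  out
}

#' Scan candidate genes for somatic second hits
#'
#' For each candidate (germline-susceptibility) gene, lists the
#' tumor-only variants by zygosity and enumerates all distinct pairs of
#' heterozygous sites as potential compound heterozygotes, per the
#' two-hit model of tumor suppressor inactivation.
#'
#' @param somatic a [var_cohort()] of tumor-only records (e.g. the output
#'   of [subtract_germline()]).
#' @param candidate_genes gene symbols to scan.
#' @param individual sample id whose genotypes define zygosity.
#' @return named list (one entry per gene) with `homozygous_hits`,
#'   `heterozygous_hits` (variant ids) and `compound_het_pairs` (2-column
#'   matrix of variant ids).
#' @export
second_hit_scan <- function(somatic, candidate_genes, individual) {
  g <- somatic$geno[, individual]
  lapply(stats::setNames(candidate_genes, candidate_genes), function(gene) {
    in_gene <- !is.na(somatic$variants$gene) & somatic$variants$gene == gene
    ids <- somatic$variants$variant_id
    hom <- ids[in_gene & !is.na(g) & g == 2L]
    het <- ids[in_gene & !is.na(g) & g == 1L]
    pairs <- if (length(het) >= 2L) t(utils::combn(het, 2L)) else
      matrix(character(0), 0, 2)
    colnames(pairs) <- c("site_a", "site_b")
    list(gene = gene, homozygous_hits = hom, heterozygous_hits = het,
         compound_het_pairs = pairs)
  })
}

#' Run the tumor-analysis cascade
#'
#' Tumor-minus-germline subtraction, population-frequency filter at the
#' somatic threshold, and panel restriction, with a chained filter trace;
#' optionally scans candidate susceptibility genes for second hits.
#'
#' @inheritParams subtract_germline
#' @param annotations annotation/frequency data frame.
#' @param dbs population database names.
#' @param threshold somatic frequency cutoff (default 0.05).
#' @param somatic_panel,susceptibility_panel gene panels.
#' @param candidate_genes optional genes for [second_hit_scan()].
#' @return list with `candidates` (data frame with `panel_hit`), `trace`,
#'   and `second_hits`.
#' @export
run_somatic_cascade <- function(tumor, germline, individual, annotations,
                                dbs = c("1kg", "evs", "exac", "gnomad"),
                                threshold = 0.05, somatic_panel,
                                susceptibility_panel,
                                candidate_genes = character(0)) {
  trace <- filter_trace()
  n0 <- n_variants(tumor)
  s1 <- subtract_germline(tumor, germline, individual)
  trace <- add_stage(trace, "tumor-only (absent in germline)", n0, n_variants(s1))
  s2 <- filter_somatic_frequency(s1, annotations, dbs, threshold)
  trace <- add_stage(trace, sprintf("population databases < %g", threshold),
                     n_variants(s1), n_variants(s2))
  cand <- apply_panel(s2, somatic_panel, susceptibility_panel)
  trace <- add_stage(trace, "disease gene panels", n_variants(s2), nrow(cand))
  hits <- if (length(candidate_genes) > 0L) {
    second_hit_scan(s1, candidate_genes, individual)
  } else list()
  list(candidates = cand, trace = trace, second_hits = hits)
}
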