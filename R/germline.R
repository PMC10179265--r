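#' Retain variants carried by every member of a carrier set
#'
#' The first stage of the germline cascade: keep exactly the records in
#' which every listed individual carries at least one alternate allele
#' (het or hom-alt); a missing genotype fails the test.
#'
#' @param cohort a [var_cohort()].
#' @param carrier_ids individual ids (all must be sequenced if a pedigree
#'   is supplied).
#' @param pedigree optional [pedigree()] used to check the sequenced flag.
#' @return the filtered [var_cohort()].
#' @export
intersect_shared <- function(cohort, carrier_ids, pedigree = NULL) {
  if (length(carrier_ids) == 0L) stop("carrier_ids must be nonempty")
  if (n_variants(cohort) > 0L) {
    missing_cols <- setdiff(carrier_ids, colnames(cohort$geno))
    if (length(missing_cols) > 0L) {
      stop("carrier not genotyped in cohort: ", paste(missing_cols, collapse = ", "))
    }
  }
  if (!is.null(pedigree)) {
    unseq <- carrier_ids[!carrier_ids %in% pedigree$id[pedigree$sequenced]]
    if (length(unseq) > 0L) {
      stop("carrier id not sequenced: ", paste(unseq, collapse = ", "))
    }
  }
  if (n_variants(cohort) == 0L) return(cohort)
  g <- cohort$geno[, carrier_ids, drop = FALSE]
  keep <- apply(g, 1L, function(r) all(!is.na(r) & r >= 1L))
  subset_cohort(cohort, cohort$variants$variant_id[keep])
}

#' Filter on population database allele frequencies
#'
#' Keeps records whose allele frequency is below `threshold` in *every*
#' listed database; a variant at or above the threshold in any one
#' database is removed. A database entry that is absent counts as 0
#' ("never observed").
#'
#' @param cohort a [var_cohort()].
#' @param annotations annotation/frequency data frame (see
#'   [read_annotation_table()]).
#' @param dbs database names (column `freq_<db>` must exist).
#' @param threshold allele-frequency cutoff in (0, 1].
#' @return the filtered [var_cohort()].
#' @export
filter_population_frequency <- function(cohort, annotations, dbs,
                                        threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- cohort$variants$variant_id
  keep <- rep(TRUE, length(ids))
  for (db in dbs) {
    keep <- keep & (freq_at_filter(annotations, ids, db) < threshold)
  }
  subset_cohort(cohort, ids[keep])
}

#' Filter on the internal cohort allele frequency
#'
#' Single-database version of [filter_population_frequency()], for an
#' in-house exome collection matched to the family's population of origin.
#'
#' @inheritParams filter_population_frequency
#' @param db internal database name (default `"internal"`).
#' @return the filtered [var_cohort()].
#' @export
filter_internal_cohort <- function(cohort, annotations, threshold = 0.01,
                                   db = "internal") {
  filter_population_frequency(cohort, annotations, dbs = db,
                              threshold = threshold)
}

#' Tier surviving candidates by splice prediction and tissue expression
#'
#' A splice-region variant predicted benign by both splice models
#' (spliceAI score below `splice_rules$spliceai_benign` *and* dbscSNV-Ada
#' below `splice_rules$ada_benign`) is excluded. Retained variants are
#' `primary` when the gene's expression in the target tissue is at least
#' `tpm_threshold` TPM (boundary inclusive), else `secondary`. A missing
#' score never fires a rule and never excludes; the reason string records
#' what was (or could not be) evaluated.
#'
#' @param cohort a [var_cohort()].
#' @param annotations annotation data frame with `score_spliceai`,
#'   `score_ada` and `tpm` columns as available.
#' @param splice_rules list with `spliceai_benign` (default 0.2) and
#'   `ada_benign` (default 0.6).
#' @param tpm_threshold expression cutoff in TPM (default 10).
#' @return data frame with `variant_id`, `gene`, `tier`
#'   (primary/secondary/excluded) and `reason`.
#' @export
tier_candidates <- function(cohort, annotations,
                            splice_rules = list(spliceai_benign = 0.2,
                                                ada_benign = 0.6),
                            tpm_threshold = 10) {
  v <- cohort$variants
  idx <- match(v$variant_id, annotations$variant_id)
  spliceai <- if ("score_spliceai" %in% names(annotations)) annotations$score_spliceai[idx] else rep(NA_real_, nrow(v))
  ada <- if ("score_ada" %in% names(annotations)) annotations$score_ada[idx] else rep(NA_real_, nrow(v))
  tpm <- if ("tpm" %in% names(annotations)) annotations$tpm[idx] else rep(NA_real_, nrow(v))

  tier <- character(nrow(v)); reason <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    splice_site <- !is.na(v$consequence[i]) && grepl("splice", v$consequence[i], ignore.case = TRUE)
    if (splice_site && !is.na(spliceai[i]) && !is.na(ada[i]) &&
        spliceai[i] < splice_rules$spliceai_benign && ada[i] < splice_rules$ada_benign) {
      tier[i] <- "excluded"
      reason[i] <- sprintf("splice-benign: spliceAI %.3g < %.3g and Ada %.3g < %.3g",
                           spliceai[i], splice_rules$spliceai_benign,
                           ada[i], splice_rules$ada_benign)
      next
    }
    if (is.na(tpm[i])) {
      tier[i] <- "secondary"
      reason[i] <- "tissue expression missing; not promoted to primary"
    } else if (tpm[i] >= tpm_threshold) {
      tier[i] <- "primary"
      reason[i] <- sprintf("expressed in target tissue (%.4g TPM >= %.4g)", tpm[i], tpm_threshold)
    } else {
      tier[i] <- "secondary"
      reason[i] <- sprintf("low target-tissue expression (%.4g TPM < %.4g)", tpm[i], tpm_threshold)
    }
    if (splice_site && (is.na(spliceai[i]) || is.na(ada[i]))) {
      reason[i] <- paste0(reason[i], "; splice rule not evaluated (missing score)")
    }
  }
  data.frame(variant_id = v$variant_id, gene = v$gene, tier = tier,
             reason = reason, stringsAsFactors = FALSE)
}

#' Run the full germline prioritization cascade
#'
#' Composes, in order: shared-carrier intersection, population-database
#' frequency filter, internal-cohort frequency filter, and familial
#' segregation filter; then tiers the survivors. The returned filter
#' trace has one row per cascade stage with exactly chained counts.
#'
#' @param cohort a [var_cohort()].
#' @param pedigree a [pedigree()].
#' @param annotations annotation data frame.
#' @param config list with elements `carriers` (ids), `dbs` (population
#'   database names), `pop_threshold` (default 0.01), `internal_threshold`
#'   (default 0.01), `models` (list of [inheritance_model()]; default
#'   dominant with incomplete penetrance), `splice_rules`, `tpm_threshold`.
#' @return list with `cohort` (survivors), `tiers`, `trace`,
#'   `segregation` (per-variant results).
#' @export
run_germline_cascade <- function(cohort, pedigree, annotations, config) {
  if (is.null(config$carriers)) stop("config$carriers is required")
  dbs <- config$dbs %||% c("1kg", "evs", "exac", "gnomad")
  pop_thr <- config$pop_threshold %||% 0.01
  int_thr <- config$internal_threshold %||% 0.01
  models <- config$models %||%
    list(inheritance_model("dominant", allow_incomplete_penetrance = TRUE))

  trace <- filter_trace()
  n0 <- n_variants(cohort)
  s1 <- intersect_shared(cohort, config$carriers, pedigree)
  trace <- add_stage(trace, "shared among carriers", n0, n_variants(s1))
  s2 <- filter_population_frequency(s1, annotations, dbs, pop_thr)
  trace <- add_stage(trace, sprintf("population databases < %g", pop_thr),
                     n_variants(s1), n_variants(s2))
  s3 <- filter_internal_cohort(s2, annotations, int_thr)
  trace <- add_stage(trace, sprintf("internal cohort < %g", int_thr),
                     n_variants(s2), n_variants(s3))
  seg <- segregation_filter(s3, pedigree, models)
  trace <- add_stage(trace, "familial segregation", n_variants(s3),
                     n_variants(seg$cohort))
  tiers <- tier_candidates(seg$cohort, annotations,
                           splice_rules = config$splice_rules %||%
                             list(spliceai_benign = 0.2, ada_benign = 0.6),
                           tpm_threshold = config$tpm_threshold %||% 10)
  list(cohort = seg$cohort, tiers = tiers, trace = trace,
       segregation = seg$results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
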