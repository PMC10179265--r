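#' Specify an inheritance model for segregation classification
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param allow_incomplete_penetrance if `TRUE`, unaffected carriers are
#'   recorded as non-penetrant rather than counted as violations
#'   (dominant mode).
#' @param allow_pseudo_dominant recessive mode only: accept the
#'   pseudo-dominant transmission pattern (an affected homozygote mating a
#'   heterozygote, so affecteds appear in successive generations). This
#'   relaxes the generational expectation only; it grants no genotype
#'   exemptions.
#' @return an object of class `inheritance_model`.
#' @export
inheritance_model <- function(mode = c("dominant", "recessive"),
                              allow_incomplete_penetrance = FALSE,
                              allow_pseudo_dominant = FALSE) {
  mode <- match.arg(mode)
  if (allow_pseudo_dominant && mode != "recessive") {
    stop("allow_pseudo_dominant requires recessive mode")
  }
  structure(list(mode = mode,
                 allow_incomplete_penetrance = allow_incomplete_penetrance,
                 allow_pseudo_dominant = allow_pseudo_dominant),
            class = "inheritance_model")
}

#' @export
format.inheritance_model <- function(x, ...) {
  paste0(x$mode,
         if (x$allow_incomplete_penetrance) "+incomplete_penetrance" else "",
         if (x$allow_pseudo_dominant) "+pseudo_dominant" else "")
}

#' @export
print.inheritance_model <- function(x, ...) {
  cat("inheritance model:", format(x), "\n")
  invisible(x)
}

new_seg_result <- function(model, compatible, non_penetrant, violators,
                           n_informative) {
  structure(list(model = model, compatible = compatible,
                 non_penetrant_carriers = sort(non_penetrant),
                 violators = sort(violators),
                 n_informative = n_informative),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("segregation [%s]: %s (informative n = %d)\n", format(x$model),
              if (x$compatible) "compatible" else "incompatible",
              x$n_informative))
  if (length(x$non_penetrant_carriers)) {
    cat("  non-penetrant carriers:", paste(x$non_penetrant_carriers, collapse = ", "), "\n")
  }
  if (length(x$violators)) {
    cat("  violators:", paste(x$violators, collapse = ", "), "\n")
  }
  invisible(x)
}

seg_evidence <- function(genotypes, pedigree) {
  g <- genotypes[match(pedigree$id, names(genotypes))]
  names(g) <- pedigree$id
  typed <- !is.na(g)
  list(g = g,
       affected = pedigree$id[pedigree$phenotype == "affected" & typed],
       unaffected = pedigree$id[pedigree$phenotype == "unaffected" & typed],
       n_informative = sum(typed & pedigree$phenotype != "unknown"))
}

#' Classify a variant against autosomal dominant segregation
#'
#' Compatible iff every genotyped affected individual carries at least one
#' alternate allele (het or hom-alt; an affected homozygote still
#' segregates). A genotyped unaffected carrier is a violator under strict
#' penetrance, or a recorded non-penetrant carrier when
#' `allow_incomplete = TRUE`. Individuals with unknown phenotype or
#' missing genotype contribute nothing.
#'
#' @param genotypes named integer dosage vector (names are individual ids).
#' @param pedigree a [pedigree()].
#' @param allow_incomplete allow unaffected carriers (incomplete
#'   penetrance).
#' @return a `seg_result`: `compatible`, `non_penetrant_carriers`,
#'   `violators`, `n_informative`.
#' @export
classify_dominant <- function(genotypes, pedigree, allow_incomplete = TRUE) {
  ev <- seg_evidence(genotypes, pedigree)
  if (length(ev$affected) == 0L) stop("no genotyped affected individual")
  g <- ev$g
  affected_noncarrier <- ev$affected[g[ev$affected] == 0L]
  unaffected_carrier <- ev$unaffected[g[ev$unaffected] >= 1L]
  violators <- affected_noncarrier
  non_penetrant <- character(0)
  if (allow_incomplete) {
    non_penetrant <- unaffected_carrier
  } else {
    violators <- c(violators, unaffected_carrier)
  }
  new_seg_result(
    inheritance_model("dominant", allow_incomplete_penetrance = allow_incomplete),
    compatible = length(violators) == 0L,
    non_penetrant = non_penetrant, violators = violators,
    n_informative = ev$n_informative
  )
}

#' Classify a variant against autosomal recessive segregation
#'
#' Compatible iff every genotyped affected individual is homozygous for
#' the alternate allele, no genotyped unaffected individual is
#' homozygous-alt, and no affected homozygote has a genotyped homozygous-
#' reference parent (an outright Mendelian impossibility regardless of the
#' pseudo-dominant flag).
#'
#' @inheritParams classify_dominant
#' @param allow_pseudo_dominant recorded on the model; see
#'   [inheritance_model()].
#' @return a `seg_result`.
#' @export
classify_recessive <- function(genotypes, pedigree, allow_pseudo_dominant = FALSE) {
  ev <- seg_evidence(genotypes, pedigree)
  if (length(ev$affected) == 0L) stop("no genotyped affected individual")
  g <- ev$g
  violators <- c(ev$affected[g[ev$affected] != 2L],
                 ev$unaffected[g[ev$unaffected] == 2L])
  # affected hom-alt child with a genotyped hom-ref parent: impossible
  for (child in ev$affected[g[ev$affected] == 2L]) {
    row <- pedigree[pedigree$id == child, ]
    for (par in c(row$father_id, row$mother_id)) {
      if (!is.na(par) && !is.na(g[par]) && g[par] == 0L) {
        violators <- c(violators, par)
      }
    }
  }
  violators <- unique(violators)
  new_seg_result(
    inheritance_model("recessive", allow_pseudo_dominant = allow_pseudo_dominant),
    compatible = length(violators) == 0L,
    non_penetrant = character(0), violators = violators,
    n_informative = ev$n_informative
  )
}

#' Flag Mendelian-impossible genotype combinations in trios
#'
#' Checks every parent-offspring trio in which father, mother and child
#' are all genotyped against biallelic Mendelian transmission (each parent
#' transmits one of their two alleles).
#'
#' @inheritParams classify_dominant
#' @return data frame with one row per violation: `child`, `father`,
#'   `mother` and their dosages.
#' @export
check_mendelian <- function(genotypes, pedigree) {
  g <- genotypes[match(pedigree$id, names(genotypes))]
  names(g) <- pedigree$id
  gametes <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    child <- pedigree$id[i]
    fa <- pedigree$father_id[i]; mo <- pedigree$mother_id[i]
    if (is.na(fa) || is.na(mo)) next
    if (is.na(g[child]) || is.na(g[fa]) || is.na(g[mo])) next
    possible <- unique(outer(gametes[[as.character(g[fa])]],
                             gametes[[as.character(g[mo])]], `+`))
    if (!(g[child] %in% possible)) {
      out[[length(out) + 1L]] <- data.frame(
        child = child, father = fa, mother = mo,
        child_geno = unname(g[child]), father_geno = unname(g[fa]),
        mother_geno = unname(g[mo]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(child = character(0), father = character(0),
                      mother = character(0), child_geno = integer(0),
                      father_geno = integer(0), mother_geno = integer(0)))
  }
  do.call(rbind, out)
}

#' Segregation filter over a cohort
#'
#' A record survives if it is compatible with at least one of the supplied
#' inheritance models; the per-record results are retained for reporting.
#'
#' @param cohort a [var_cohort()].
#' @param pedigree a [pedigree()].
#' @param models nonempty list of [inheritance_model()].
#' @return list with `cohort` (survivors), `results` (per variant, a list
#'   of `seg_result` named by model), and `stage` (a one-row
#'   [filter_trace()] fragment).
#' @export
segregation_filter <- function(cohort, pedigree, models) {
  if (length(models) == 0L) stop("empty model list")
  ids <- cohort$variants$variant_id
  results <- stats::setNames(vector("list", length(ids)), ids)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    gen <- cohort$geno[i, ]
    res <- lapply(models, function(m) {
      if (m$mode == "dominant") {
        classify_dominant(gen, pedigree, allow_incomplete = m$allow_incomplete_penetrance)
      } else {
        classify_recessive(gen, pedigree, allow_pseudo_dominant = m$allow_pseudo_dominant)
      }
    })
    names(res) <- vapply(models, format, character(1))
    results[[i]] <- res
    keep[i] <- any(vapply(res, `[[`, logical(1), "compatible"))
  }
  surv <- subset_cohort(cohort, ids[keep])
  stage <- add_stage(filter_trace(), "familial segregation",
                     length(ids), sum(keep))
  list(cohort = surv, results = results, stage = stage)
}
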