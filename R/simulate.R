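#' Simulate a multi-branch, multi-generation pedigree
#'
#' Builds a three-generation pedigree: a founder couple, `n_branches`
#' of their children each married to an unrelated spouse, `sibs_per_branch`
#' grandchildren per branch, and optionally a fourth generation under the
#' first grandchild of branch 1. With `consanguineous = TRUE` that fourth
#' generation instead descends from a first-cousin mating (the first
#' grandchildren of branches 1 and 2), creating exactly one mating pair
#' sharing a grandparent. Structure is deterministic; the seed fixes the
#' random offspring sexes.
#'
#' @param spec list with `n_branches` (default 2), `sibs_per_branch`
#'   (default 5, recycled across branches), `n_gen4` (default 2),
#'   `consanguineous` (default FALSE).
#' @param seed integer RNG seed.
#' @return a [pedigree()] with all members flagged sequenced and sampled.
#' @export
simulate_pedigree <- function(spec = list(), seed = 1) {
  n_branches <- spec$n_branches %||% 2L
  sibs <- rep_len(spec$sibs_per_branch %||% 5L, n_branches)
  n_gen4 <- spec$n_gen4 %||% 2L
  consang <- isTRUE(spec$consanguineous)
  if (consang && (n_branches < 2L || any(sibs[1:2] < 1L))) {
    stop("consanguineous mating needs two branches with children")
  }
  id <- character(0); fa <- character(0); mo <- character(0); sex <- character(0)
  add <- function(i, f, m, s) {
    id <<- c(id, i); fa <<- c(fa, f); mo <<- c(mo, m); sex <<- c(sex, s)
  }
  set.seed(seed)
  add("I1", NA, NA, "male"); add("I2", NA, NA, "female")
  for (b in seq_len(n_branches)) {
    bs <- sample(c("male", "female"), 1)
    add(sprintf("II%d", b), "I1", "I2", bs)
    add(sprintf("II%dS", b), NA, NA, if (bs == "male") "female" else "male")
    pa <- if (bs == "male") sprintf("II%d", b) else sprintf("II%dS", b)
    ma <- if (bs == "male") sprintf("II%dS", b) else sprintf("II%d", b)
    for (k in seq_len(sibs[b])) {
      add(sprintf("III%d_%d", b, k), pa, ma, sample(c("male", "female"), 1))
    }
  }
  if (n_gen4 > 0L) {
    p1 <- "III1_1"
    sex[id == p1] <- "male"
    if (consang) {
      p2 <- "III2_1"
      sex[id == p2] <- "female"
    } else {
      p2 <- "III1_1S"
      add(p2, NA, NA, "female")
    }
    for (k in seq_len(n_gen4)) {
      add(sprintf("IV_%d", k), p1, p2, sample(c("male", "female"), 1))
    }
  }
  pedigree(id, fa, mo, sex, phenotype = "unknown", sequenced = TRUE,
           sampled = TRUE)
}

#' Simulate rare background variant sites
#'
#' Site frequencies follow a rare-skewed Beta(0.5, 5) spectrum truncated
#' to `freq_range` (resampling), unless a fixed `freq` vector is given.
#'
#' @param n number of sites.
#' @param seed RNG seed.
#' @param freq optional fixed allele-frequency vector (length `n`).
#' @param freq_range truncation interval (default `c(1e-4, 0.5)`).
#' @return data frame with `gene`, `chrom`, `pos`, `ref`, `alt`, `freq`.
#' @export
simulate_background_sites <- function(n, seed = 1, freq = NULL,
                                      freq_range = c(1e-4, 0.5)) {
  set.seed(seed)
  if (is.null(freq)) {
    freq <- numeric(0)
    while (length(freq) < n) {
      draw <- stats::rbeta(n, 0.5, 5)
      freq <- c(freq, draw[draw >= freq_range[1] & draw <= freq_range[2]])
    }
    freq <- freq[seq_len(n)]
  }
  stopifnot(length(freq) == n, all(freq > 0 & freq < 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(
    gene = sprintf("BG%04d", seq_len(n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1e6, n) * 50L + sample(49L, n, replace = TRUE),
    ref = ref, alt = unname(alt), freq = freq, stringsAsFactors = FALSE)
}

#' Assign phenotypes from causal-genotype dosages
#'
#' Each individual is affected with probability `f[dosage + 1]` under the
#' model's penetrance vector, independently.
#'
#' @param dosage integer vector of causal-site dosages (0/1/2).
#' @param model a [disease_model()].
#' @return character vector of `"affected"` / `"unaffected"`.
#' @export
sample_phenotypes <- function(dosage, model) {
  p <- model$f[dosage + 1L]
  ifelse(stats::runif(length(dosage)) < p, "affected", "unaffected")
}

#' Gene-drop a variant cohort through a pedigree
#'
#' Founders draw two alleles per site at Hardy-Weinberg from the site's
#' population frequency; children inherit one allele from each parent
#' uniformly at random. One designated causal site uses the disease
#' model's allele frequency, with the first founder forced to carry at
#' least one copy so the family actually segregates the allele.
#' Phenotypes are then drawn from the causal dosage via the penetrance
#' vector, and the whole drop is rejected and redrawn until at least
#' `min_affected` members are affected (family studies are ascertained
#' through affected members; set `min_affected = 0` to disable). Finally
#' genotypes are masked missing at `missing_rate`.
#'
#' @param pedigree a [pedigree()].
#' @param model a [disease_model()].
#' @param background data frame of background sites (see
#'   [simulate_background_sites()]).
#' @param seed RNG seed; the output is fully reproducible given the seed.
#' @param missing_rate per-call missingness probability in [0, 1].
#' @param min_affected ascertainment condition (default 2).
#' @param max_tries rejection-sampling cap (default 1000).
#' @return list with `cohort` (a [var_cohort()] over all pedigree
#'   members), `pedigree` (phenotypes filled in), `causal_id` (variant id
#'   of the planted site).
#' @export
gene_drop <- function(pedigree, model, background, seed = 1,
                      missing_rate = 0, min_affected = 2L, max_tries = 1000L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  if (model$q <= 0 || model$q >= 1) stop("causal allele frequency outside (0,1)")
  set.seed(seed)
  causal <- data.frame(gene = "CAUSAL1", chrom = "1", pos = 1000000L,
                       ref = "A", alt = "G", freq = model$q,
                       stringsAsFactors = FALSE)
  sites <- rbind(causal, background)
  n_site <- nrow(sites)
  ids <- pedigree$id
  ord <- topo_order(pedigree)
  founder1 <- ids[is.na(pedigree$father_id) & is.na(pedigree$mother_id)][1]

  for (try in seq_len(max_tries)) {
    # allele matrices: n_site x n_ind, paternal and maternal copies
    al1 <- matrix(NA_integer_, n_site, length(ids), dimnames = list(NULL, ids))
    al2 <- al1
    for (i in ord) {
      who <- ids[i]
      fa <- pedigree$father_id[i]; mo <- pedigree$mother_id[i]
      if (is.na(fa) && is.na(mo)) {
        al1[, who] <- stats::rbinom(n_site, 1, sites$freq)
        al2[, who] <- stats::rbinom(n_site, 1, sites$freq)
      } else {
        pick1 <- stats::runif(n_site) < 0.5
        pick2 <- stats::runif(n_site) < 0.5
        al1[, who] <- ifelse(pick1, al1[, fa], al2[, fa])
        al2[, who] <- ifelse(pick2, al1[, mo], al2[, mo])
      }
      if (who == founder1 && al1[1, who] + al2[1, who] == 0L) al1[1, who] <- 1L
    }
    geno <- al1 + al2
    phen <- sample_phenotypes(geno[1, ], model)
    if (sum(phen == "affected") >= min_affected) {
      if (missing_rate > 0) {
        geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
      }
      ped <- pedigree
      ped$phenotype <- phen
      vtab <- sites[, c("chrom", "pos", "ref", "alt", "gene")]
      vtab$sim_freq <- sites$freq
      cohort <- var_cohort(vtab, geno)
      causal_id <- variant_id(causal)
      cohort$variants$sim_freq[cohort$variants$variant_id == causal_id] <- NA_real_
      return(list(cohort = cohort, pedigree = ped, causal_id = causal_id))
    }
  }
  stop("ascertainment condition not met in ", max_tries, " tries")
}

topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed &
      (is.na(ped$father_id) | ped$father_id %in% ped$id[placed]) &
      (is.na(ped$mother_id) | ped$mother_id %in% ped$id[placed]))
    if (length(ready) == 0L) stop("pedigree is not acyclic")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  ord
}

#' Annotation table for a simulated cohort
#'
#' Background sites carry their generating allele frequency in every
#' listed database column; the planted causal site is absent everywhere
#' (never observed in any database). Expression is set high for the
#' causal gene and low elsewhere so tiering promotes the causal variant.
#'
#' @param drop result of [gene_drop()].
#' @param dbs database names to populate.
#' @return annotation data frame.
#' @export
simulated_annotations <- function(drop, dbs = c("1kg", "evs", "exac", "gnomad",
                                                "internal")) {
  v <- drop$cohort$variants
  ann <- data.frame(variant_id = v$variant_id, gene = v$gene,
                    stringsAsFactors = FALSE)
  for (db in dbs) ann[[paste0("freq_", db)]] <- v$sim_freq
  ann$tpm <- ifelse(v$variant_id == drop$causal_id, 25, 5)
  ann
}

#' Spike somatic variants into a germline sample
#'
#' Copies one individual's germline calls and adds heterozygous somatic
#' variants in the specified genes at positions absent from the germline
#' call set, emulating a tumor exome from the same patient.
#'
#' @param germline a [var_cohort()].
#' @param individual sample id to copy.
#' @param somatic_spec list with `genes` (symbols, recycled) and
#'   `n_spikes` (count).
#' @param seed RNG seed.
#' @return single-sample tumor [var_cohort()].
#' @export
spike_tumor <- function(germline, individual, somatic_spec, seed = 1) {
  if (!individual %in% colnames(germline$geno)) {
    stop("individual not in germline cohort: ", individual)
  }
  set.seed(seed)
  n <- somatic_spec$n_spikes %||% 0L
  v <- germline$variants[, c("chrom", "pos", "ref", "alt", "gene", "consequence")]
  g <- germline$geno[, individual, drop = FALSE]
  if (n > 0L) {
    genes <- rep_len(somatic_spec$genes, n)
    bases <- c("A", "C", "G", "T")
    repeat {
      pos <- sample(2e6, n) * 37L + sample(36L, n, replace = TRUE)
      chrom <- as.character(sample(1:22, n, replace = TRUE))
      if (!any(paste(chrom, pos) %in% paste(v$chrom, v$pos))) break
    }
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    spikes <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                         gene = genes, consequence = "missense_variant",
                         stringsAsFactors = FALSE)
    v <- rbind(v, spikes)
    g <- rbind(g, matrix(1L, n, 1))
  }
  colnames(g) <- individual
  var_cohort(v, g)
}

#' Write a complete plain-text fixture suite
#'
#' Emits, under `outdir`: the reconstructed kindred PED, the candidate
#' genotype-matrix VCF and its annotation TSV, the somatic and
#' susceptibility gene panels, the interaction edge list, a simulated
#' gene-dropped cohort (PED + VCF + annotation TSV), and a spiked tumor
#' VCF with its matched germline VCF. Regenerating with the same seed is
#' byte-identical, and every file loads back through the package readers.
#'
#' @param outdir output directory (created if needed).
#' @param seed RNG seed for the simulated components.
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture_suite <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    kindred_ped = p("kindred.ped"), candidates_vcf = p("candidates.vcf"),
    candidate_annotations = p("candidate_annotations.tsv"),
    somatic_panel = p("somatic_panel.txt"),
    susceptibility_panel = p("susceptibility_panel.txt"),
    ppi_edges = p("ppi_edges.tsv"),
    sim_ped = p("sim.ped"), sim_vcf = p("sim_cohort.vcf"),
    sim_annotations = p("sim_annotations.tsv"),
    germline_vcf = p("somatic_germline.vcf"), tumor_vcf = p("somatic_tumor.vcf"),
    somatic_annotations = p("somatic_annotations.tsv"))

  write_ped(example_kindred_pedigree(), paths["kindred_ped"])
  write_vcf(example_candidate_cohort(), paths["candidates_vcf"])
  write_annotation_table(example_candidate_annotations(),
                         paths["candidate_annotations"])
  write_panel(somatic_gene_panel(), paths["somatic_panel"])
  write_panel(susceptibility_gene_panel(), paths["susceptibility_panel"])
  write_edges(example_ppi_edges(), paths["ppi_edges"])

  sim_ped <- simulate_pedigree(seed = seed)
  bg <- simulate_background_sites(50, seed = seed + 1)
  drop <- gene_drop(sim_ped, disease_model("dominant", 0.9), bg,
                    seed = seed + 2)
  ann <- simulated_annotations(drop)
  write_ped(drop$pedigree, paths["sim_ped"])
  write_vcf(drop$cohort, paths["sim_vcf"])
  write_annotation_table(ann, paths["sim_annotations"])

  som <- example_somatic_fixture()
  write_vcf(som$germline, paths["germline_vcf"])
  write_vcf(som$tumor, paths["tumor_vcf"])
  write_annotation_table(som$annotations, paths["somatic_annotations"])
  invisible(paths)
}
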