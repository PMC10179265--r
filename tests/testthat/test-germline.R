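carriers <- c("III8", "III10", "IVA5", "XFIII4", "XFIII5")

random_cohort <- function(n, ids, seed) {
  set.seed(seed)
  variants <- data.frame(chrom = "1", pos = seq_len(n) * 10L, ref = "A",
                         alt = "G", gene = sprintf("G%04d", seq_len(n)))
  geno <- matrix(sample(c(0L, 1L, 2L, NA), n * length(ids), TRUE,
                        prob = c(.5, .3, .1, .1)),
                 n, length(ids), dimnames = list(NULL, ids))
  var_cohort(variants, geno)
}

test_that("intersect_shared keeps exactly the records carried by all carriers", {
  co <- example_candidate_cohort()
  kept <- intersect_shared(co, carriers, example_kindred_pedigree())
  expect_equal(n_variants(kept), 4L)

  # break one carrier's genotype
  co$geno[1, "III10"] <- 0L
  kept <- intersect_shared(co, carriers)
  expect_equal(n_variants(kept), 3L)

  # 1000 simulated records vs record-by-record brute force
  big <- random_cohort(1000, c(carriers, "III2"), seed = 11)
  kept <- intersect_shared(big, carriers)
  brute <- vapply(seq_len(1000), function(i) {
    all(vapply(carriers, function(id) {
      g <- big$geno[i, id]; !is.na(g) && g >= 1L
    }, logical(1)))
  }, logical(1))
  expect_setequal(kept$variants$variant_id, big$variants$variant_id[brute])

  expect_error(intersect_shared(co, c(carriers, "III6"),
                                example_kindred_pedigree()),
               "not sequenced")
  expect_error(intersect_shared(co, character(0)), "nonempty")
})

test_that("population frequency filter is keep-if-rare-in-every-db", {
  co <- random_cohort(3, "III8", seed = 1)
  ids <- co$variants$variant_id
  ann <- data.frame(variant_id = ids,
                    freq_gnomad = c(0.02, NA, 0.001),
                    freq_exac = c(NA, NA, 0.002))
  kept <- filter_population_frequency(co, ann, c("gnomad", "exac"), 0.01)
  expect_setequal(kept$variants$variant_id, ids[2:3])
  expect_error(filter_population_frequency(co, ann, "nosuchdb", 0.01),
               "unknown db")

  # random table vs exhaustive re-check
  big <- random_cohort(400, "III8", seed = 2)
  set.seed(3)
  dbs <- c("1kg", "evs", "exac", "gnomad")
  ann <- data.frame(variant_id = big$variants$variant_id)
  for (db in dbs) {
    f <- stats::runif(400, 0, 0.05)
    f[stats::runif(400) < 0.3] <- NA
    ann[[paste0("freq_", db)]] <- f
  }
  kept <- filter_population_frequency(big, ann, dbs, 0.01)
  brute <- vapply(seq_len(400), function(i) {
    all(vapply(dbs, function(db) {
      f <- ann[[paste0("freq_", db)]][i]
      is.na(f) || f < 0.01
    }, logical(1)))
  }, logical(1))
  expect_setequal(kept$variants$variant_id, big$variants$variant_id[brute])
})

test_that("internal-cohort filter keeps the rare and drops the 4% variant", {
  co <- random_cohort(3, "III8", seed = 4)
  ids <- co$variants$variant_id
  ann <- data.frame(variant_id = ids,
                    freq_internal = c(0.0057, 0.04, NA))
  kept <- filter_internal_cohort(co, ann, threshold = 0.01)
  expect_setequal(kept$variants$variant_id, ids[c(1, 3)])
  expect_equal(n_variants(filter_internal_cohort(co, ann, threshold = 1.0)), 3L)
})

test_that("the two frequency filters commute", {
  big <- random_cohort(200, "III8", seed = 5)
  set.seed(6)
  ann <- data.frame(variant_id = big$variants$variant_id,
                    freq_gnomad = stats::runif(200, 0, 0.03),
                    freq_internal = stats::runif(200, 0, 0.03))
  a <- filter_internal_cohort(filter_population_frequency(big, ann, "gnomad", 0.01), ann)
  b <- filter_population_frequency(filter_internal_cohort(big, ann), ann, "gnomad", 0.01)
  expect_equal(a$variants$variant_id, b$variants$variant_id)
})

test_that("tiering reproduces the worked example and its boundaries", {
  co <- example_candidate_cohort()
  ann <- example_candidate_annotations()
  tiers <- tier_candidates(co, ann)
  expect_equal(tiers$tier[tiers$gene == "SLC24A4"], "excluded")
  expect_match(tiers$reason[tiers$gene == "SLC24A4"], "splice-benign")
  expect_equal(tiers$tier[tiers$gene == "ARHGEF28"], "primary")
  expect_setequal(tiers$gene[tiers$tier == "secondary"],
                  c("FBXW10", "SLC47A1"))

  # boundary: no splice scores, TPM exactly at threshold -> primary
  ann2 <- ann
  ann2$score_spliceai <- NA_real_; ann2$score_ada <- NA_real_
  ann2$tpm <- 10
  tiers2 <- tier_candidates(co, ann2, tpm_threshold = 10)
  expect_true(all(tiers2$tier == "primary"))
  # a splice-region variant with missing scores records the unfired rule
  expect_match(tiers2$reason[tiers2$gene == "SLC24A4"], "not evaluated")

  # missing TPM never excludes; it demotes with a reason
  ann3 <- ann; ann3$tpm <- NA_real_
  tiers3 <- tier_candidates(co, ann3)
  expect_equal(tiers3$tier[tiers3$gene == "ARHGEF28"], "secondary")
  expect_match(tiers3$reason[tiers3$gene == "ARHGEF28"], "missing")
})

test_that("the full cascade composes the stages with a chained trace", {
  ped <- example_kindred_pedigree()
  co <- example_candidate_cohort()
  ann <- example_candidate_annotations()
  res <- run_germline_cascade(co, ped, ann, list(carriers = carriers))
  expect_equal(n_variants(res$cohort), 4L)
  expect_equal(nrow(res$trace), 4L)
  expect_equal(res$trace$count_in[-1], res$trace$count_out[-4])
  expect_equal(sum(res$tiers$tier == "excluded"), 1L)
  expect_equal(sum(res$tiers$tier == "primary"), 1L)
  expect_equal(sum(res$tiers$tier == "secondary"), 2L)
})

test_that("a planted variant survives among decoys and the trace decreases", {
  ped <- simulate_pedigree(seed = 21)
  set.seed(20)
  bg <- simulate_background_sites(500, seed = 22,
                                  freq = stats::runif(500, 0.02, 0.5))
  drop <- gene_drop(ped, disease_model("dominant", 0.9), bg, seed = 23)
  ann <- simulated_annotations(drop)
  aff <- drop$pedigree$id[drop$pedigree$phenotype == "affected"]
  res <- run_germline_cascade(drop$cohort, drop$pedigree, ann,
                              list(carriers = aff))
  expect_true(drop$causal_id %in% res$cohort$variants$variant_id)
  expect_true(all(diff(c(res$trace$count_in[1], res$trace$count_out)) <= 0))
  expect_lt(res$trace$count_out[4], res$trace$count_in[1])
})

test_that("an empty cohort flows through as four 0 -> 0 stages", {
  empty <- var_cohort(data.frame(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0)))
  ped <- example_kindred_pedigree()
  res <- run_germline_cascade(empty, ped, example_candidate_annotations(),
                              list(carriers = carriers))
  expect_equal(res$trace$count_in, rep(0L, 4))
  expect_equal(res$trace$count_out, rep(0L, 4))
})

test_that("cascade output equals the naive conjunction of all predicates", {
  ped <- simulate_pedigree(seed = 31)
  bg <- simulate_background_sites(300, seed = 32)
  drop <- gene_drop(ped, disease_model("dominant", 0.9), bg, seed = 33,
                    missing_rate = 0.05)
  ann <- simulated_annotations(drop)
  aff <- drop$pedigree$id[drop$pedigree$phenotype == "affected"]
  res <- run_germline_cascade(drop$cohort, drop$pedigree, ann,
                              list(carriers = aff))
  dbs <- c("1kg", "evs", "exac", "gnomad")
  brute <- vapply(seq_len(n_variants(drop$cohort)), function(i) {
    g <- drop$cohort$geno[i, ]
    id <- drop$cohort$variants$variant_id[i]
    shared <- all(!is.na(g[aff]) & g[aff] >= 1L)
    freqs <- vapply(c(dbs, "internal"), function(db) {
      f <- ann[[paste0("freq_", db)]][match(id, ann$variant_id)]
      if (is.na(f)) 0 else f
    }, numeric(1))
    seg <- oracle_dominant(g, drop$pedigree, allow_incomplete = TRUE)
    shared && all(freqs < 0.01) && seg$compatible
  }, logical(1))
  expect_setequal(res$cohort$variants$variant_id,
                  drop$cohort$variants$variant_id[brute])
})
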