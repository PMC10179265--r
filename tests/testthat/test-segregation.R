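# a five-member nuclear family used for exhaustive truth-table checks
truth_ped <- pedigree(
  id = c("F", "M", "C1", "C2", "C3"),
  father_id = c(NA, NA, "F", "F", "F"),
  mother_id = c(NA, NA, "M", "M", "M"),
  sex = c("male", "female", "male", "female", "male"),
  phenotype = c("affected", "unaffected", "affected", "unaffected", "unknown"))

test_that("the candidate genotype matrix segregates dominantly with one
           non-penetrant carrier each, and fails strict penetrance", {
  ped <- example_kindred_pedigree()
  co <- example_candidate_cohort()
  expected_np <- c(ARHGEF28 = "III6", FBXW10 = "III2", SLC24A4 = "III4",
                   SLC47A1 = "III2")
  for (gene in names(expected_np)) {
    g <- co$geno[co$variants$variant_id[co$variants$gene == gene], ]
    res <- classify_dominant(g, ped, allow_incomplete = TRUE)
    expect_true(res$compatible, label = gene)
    expect_equal(res$non_penetrant_carriers, unname(expected_np[gene]))
    expect_equal(res$n_informative, 11L)

    strict <- classify_dominant(g, ped, allow_incomplete = FALSE)
    expect_false(strict$compatible)
    expect_equal(strict$violators, unname(expected_np[gene]))
  }
})

test_that("an affected homozygote still counts as a segregating carrier", {
  ped <- example_kindred_pedigree()
  co <- example_candidate_cohort()
  g <- co$geno[co$variants$variant_id[co$variants$gene == "SLC47A1"], ]
  expect_equal(unname(g["III5"]), 2L)
  res <- classify_dominant(g, ped, allow_incomplete = TRUE)
  expect_true(res$compatible)
  expect_equal(res$non_penetrant_carriers, "III2")
})

test_that("recessive classification rejects het affecteds and accepts hom ones", {
  ped <- example_kindred_pedigree()
  co <- example_candidate_cohort()
  g <- co$geno[co$variants$variant_id[co$variants$gene == "ARHGEF28"], ]
  res <- classify_recessive(g, ped)
  expect_false(res$compatible)
  expect_true(all(c("III1", "III8") %in% res$violators))

  g2 <- setNames(c(2L, 1L, 2L, 0L, 1L), truth_ped$id)
  expect_true(classify_recessive(g2, truth_ped)$compatible)
  # a hom-ref parent of an affected homozygote is an outright violation
  g3 <- setNames(c(0L, 1L, 2L, 0L, NA), truth_ped$id)
  res3 <- classify_recessive(g3, truth_ped, allow_pseudo_dominant = TRUE)
  expect_false(res3$compatible)
  expect_true("F" %in% res3$violators)
})

test_that("classifiers match exhaustive truth-table oracles over 4^5 vectors", {
  states <- c(0L, 1L, 2L, NA)
  grid <- expand.grid(F = states, M = states, C1 = states, C2 = states,
                      C3 = states)
  for (i in seq_len(nrow(grid))) {
    g <- setNames(as.integer(grid[i, ]), truth_ped$id)
    if (all(is.na(g[c("F", "C1")]))) next  # no genotyped affected
    for (allow in c(TRUE, FALSE)) {
      got <- classify_dominant(g, truth_ped, allow_incomplete = allow)
      exp <- oracle_dominant(g, truth_ped, allow_incomplete = allow)
      expect_identical(got$compatible, exp$compatible)
      expect_identical(got$violators, exp$violators)
      expect_identical(got$non_penetrant_carriers, exp$non_penetrant_carriers)
    }
    gotr <- classify_recessive(g, truth_ped)
    expr <- oracle_recessive(g, truth_ped)
    expect_identical(gotr$compatible, expr$compatible)
    expect_identical(gotr$violators, expr$violators)
  }
})

test_that("an individual of unknown phenotype never changes a verdict", {
  set.seed(40)
  for (rep in 1:50) {
    g <- setNames(sample(c(0L, 1L, 2L, NA), 5, TRUE), truth_ped$id)
    if (all(is.na(g[c("F", "C1")]))) next
    base <- classify_dominant(g, truth_ped)
    ped2 <- rbind(as.data.frame(truth_ped),
                  data.frame(id = "EXTRA", father_id = "F", mother_id = "M",
                             sex = "male", phenotype = "unknown",
                             sequenced = TRUE, sampled = TRUE))
    class(ped2) <- c("pedigree", "data.frame")
    with_extra <- classify_dominant(c(g, EXTRA = sample(c(0L, 1L, 2L), 1)), ped2)
    expect_identical(base$compatible, with_extra$compatible)
    expect_identical(base$violators, with_extra$violators)
  }
})

test_that("masking a genotype never turns compatible into incompatible", {
  set.seed(41)
  for (rep in 1:100) {
    g <- setNames(sample(c(0L, 1L, 2L, NA), 5, TRUE), truth_ped$id)
    if (all(is.na(g[c("F", "C1")]))) next
    res <- classify_dominant(g, truth_ped, allow_incomplete = FALSE)
    if (!res$compatible) next
    for (mask in truth_ped$id[!is.na(g)]) {
      g2 <- g; g2[mask] <- NA
      if (all(is.na(g2[c("F", "C1")]))) next
      expect_true(classify_dominant(g2, truth_ped, FALSE)$compatible)
    }
  }
})

test_that("check_mendelian matches gamete enumeration on all 27 trios", {
  trio <- pedigree(id = c("F", "M", "C"), father_id = c(NA, NA, "F"),
                   mother_id = c(NA, NA, "M"),
                   sex = c("male", "female", "male"))
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    g <- c(F = gf, M = gm, C = gc)
    viol <- check_mendelian(g, trio)
    expect_identical(nrow(viol) == 0L, oracle_trio_possible(gf, gm, gc),
                     label = paste(gf, gm, gc))
  }
  # explicit cases
  expect_equal(nrow(check_mendelian(c(F = 0L, M = 0L, C = 1L), trio)), 1L)
  for (gc in 0:2) {
    expect_equal(nrow(check_mendelian(c(F = 1L, M = 1L, C = gc), trio)), 0L)
  }
  # incomplete trios are not checked
  expect_equal(nrow(check_mendelian(c(F = 0L, M = NA, C = 2L), trio)), 0L)
})

test_that("segregation_filter keeps records compatible with any model", {
  ped <- example_kindred_pedigree()
  co <- example_candidate_cohort()
  dom_inc <- list(inheritance_model("dominant", allow_incomplete_penetrance = TRUE))
  res <- segregation_filter(co, ped, dom_inc)
  expect_equal(n_variants(res$cohort), 4L)
  np <- vapply(res$results, function(r)
    length(r[[1]]$non_penetrant_carriers), integer(1))
  expect_true(all(np == 1L))

  strict <- segregation_filter(co, ped, list(inheritance_model("dominant")))
  expect_equal(n_variants(strict$cohort), 0L)

  both <- segregation_filter(co, ped,
                             list(inheritance_model("dominant"),
                                  inheritance_model("recessive",
                                                    allow_pseudo_dominant = TRUE)))
  expect_equal(n_variants(both$cohort), 0L)
  expect_error(segregation_filter(co, ped, list()), "empty model")
})

test_that("model constructor enforces the pseudo-dominant constraint", {
  expect_error(inheritance_model("dominant", allow_pseudo_dominant = TRUE),
               "recessive")
})
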