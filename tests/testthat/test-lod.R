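# phase-known fully penetrant dominant family: grandparents fix the phase of
# the affected father; each genotyped child is an informative meiosis
phase_known_family <- function(m) {
  ids <- c("GF", "GM", "FA", "MO", paste0("C", seq_len(m)))
  ped <- pedigree(ids,
    father_id = c(NA, NA, "GF", NA, rep("FA", m)),
    mother_id = c(NA, NA, "GM", NA, rep("MO", m)),
    sex = c("male", "female", "male", "female", rep("male", m)),
    phenotype = c("affected", "unaffected", "affected", "unaffected",
                  rep(c("affected", "unaffected"), length.out = m)))
  g <- setNames(c(1L, 0L, 1L, 0L, rep(c(1L, 0L), length.out = m)), ids)
  list(ped = ped, g = g)
}

test_that("a lone genotyped individual with unknown phenotype scores 0", {
  p1 <- pedigree("A", sex = "male")
  dm <- disease_model("dominant", 0.9)
  expect_equal(pedigree_likelihood(p1, c(A = 1L), dm, theta = 0,
                                   normalize = "conditional"), 0)
})

test_that("lod at theta = 0.5 is exactly 0", {
  ped <- example_kindred_pedigree()
  g <- example_candidate_cohort()$geno["5:73048875:A:G", ]
  lr <- two_point_lod(ped, g, disease_model("dominant", 0.9), theta = 0.5,
                      marker_allele_freq = 0.00345)
  expect_identical(lr$lod, 0)
})

test_that("fully penetrant phase-known families give m * log10(2)", {
  dm <- disease_model("dominant", 1, phenocopy = 0, disease_allele_freq = 0.001)
  for (m in c(4L, 10L)) {
    fam <- phase_known_family(m)
    lr <- two_point_lod(fam$ped, fam$g, dm, theta = 0,
                        marker_allele_freq = 0.01)
    expect_equal(lr$lod, m * log10(2), tolerance = 1e-9)
  }
})

test_that("an obligate recombinant at theta 0 is incompatible, not an error", {
  fam <- phase_known_family(3)
  g <- fam$g
  g["C1"] <- 0L  # affected child without the linked allele
  dm <- disease_model("dominant", 1, phenocopy = 0)
  lr <- two_point_lod(fam$ped, g, dm, theta = 0)
  expect_true(lr$incompatible_at_theta)
  expect_identical(lr$lod, -Inf)
  expect_error(pedigree_likelihood(fam$ped, g, dm, theta = 0),
               "inconsistent data")
})

test_that("data impossible under any theta raise inconsistent-data errors", {
  trio <- pedigree(c("F", "M", "C"), father_id = c(NA, NA, "F"),
                   mother_id = c(NA, NA, "M"))
  g <- c(F = 0L, M = 0L, C = 2L)  # Mendelian marker violation
  expect_error(two_point_lod(trio, g, disease_model("dominant", 0.9)),
               "inconsistent data")
})

test_that("peeling equals full enumeration on random small pedigrees", {
  dm <- disease_model("dominant", 0.9, phenocopy = 0.01,
                      disease_allele_freq = 0.05)
  for (s in 1:25) {
    rp <- random_small_pedigree(s, max_members = 7L, p_alt = 0.25)
    theta <- c(0, 0.1, 0.3, 0.5)[(s %% 4) + 1]
    a <- pedigree_likelihood(rp$ped, rp$geno, dm, theta = theta,
                             marker_allele_freq = 0.25, on_zero = "neginf")
    b <- oracle_pedigree_loglik(rp$ped, rp$geno, dm, theta, 0.25)
    if (is.infinite(a) || is.infinite(b)) {
      expect_identical(is.infinite(a), is.infinite(b))
    } else {
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
})

test_that("consanguineous loops peel exactly (first-cousin mating)", {
  ped <- pedigree(
    id = c("G1", "G2", "P1", "P2", "S1", "S2", "C1", "C2", "K1"),
    father_id = c(NA, NA, "G1", "G1", NA, NA, "P1", "P2", "C1"),
    mother_id = c(NA, NA, "G2", "G2", NA, NA, "S1", "S2", "C2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "female", "male"),
    phenotype = c("unknown", "affected", "affected", "unaffected",
                  "unknown", "unknown", "affected", "unknown", "affected"))
  g <- setNames(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L), ped$id)
  dm <- disease_model("dominant", 0.9, phenocopy = 0.005,
                      disease_allele_freq = 0.02)
  for (theta in c(0, 0.2)) {
    a <- pedigree_likelihood(ped, g, dm, theta = theta,
                             marker_allele_freq = 0.25, on_zero = "neginf")
    b <- oracle_pedigree_loglik(ped, g, dm, theta, 0.25)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to relabeling and row order", {
  fam <- phase_known_family(5)
  dm <- disease_model("dominant", 0.9, disease_allele_freq = 0.01)
  base <- pedigree_likelihood(fam$ped, fam$g, dm, theta = 0.1,
                              marker_allele_freq = 0.2)
  # permute rows
  set.seed(5)
  perm <- sample(nrow(fam$ped))
  ped2 <- fam$ped[perm, ]
  class(ped2) <- c("pedigree", "data.frame")
  expect_equal(pedigree_likelihood(ped2, fam$g, dm, 0.1,
                                   marker_allele_freq = 0.2), base,
               tolerance = 1e-12)
  # rename ids
  map <- setNames(sprintf("ID%02d", seq_len(nrow(fam$ped))), fam$ped$id)
  ped3 <- fam$ped
  ped3$id <- unname(map[ped3$id])
  ped3$father_id <- ifelse(is.na(ped3$father_id), NA, map[ped3$father_id])
  ped3$mother_id <- ifelse(is.na(ped3$mother_id), NA, map[ped3$mother_id])
  g3 <- setNames(fam$g, map[names(fam$g)])
  expect_equal(pedigree_likelihood(ped3, g3, dm, 0.1,
                                   marker_allele_freq = 0.2), base,
               tolerance = 1e-12)
})

test_that("lod is non-increasing in theta on co-segregating data", {
  fam <- phase_known_family(6)
  dm <- disease_model("dominant", 0.9, disease_allele_freq = 0.001)
  lods <- vapply(c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5), function(th)
    two_point_lod(fam$ped, fam$g, dm, theta = th,
                  marker_allele_freq = 0.01)$lod, numeric(1))
  expect_true(all(diff(lods) <= 1e-12))
  expect_equal(lods[length(lods)], 0)
})

test_that("disease model constructor validates penetrance structure", {
  dm <- disease_model("recessive", penetrance = 0.8, phenocopy = 0.01)
  expect_equal(dm$f, c(0.01, 0.01, 0.8))
  expect_error(disease_model("dominant", penetrance = 0.1, phenocopy = 0.5),
               "non-decreasing")
  expect_error(disease_model("dominant", disease_allele_freq = 0),
               "disease_allele_freq")
})
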