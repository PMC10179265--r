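#' Specify a parametric disease model for linkage analysis
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param penetrance probability that a susceptible genotype (>= 1 disease
#'   allele for dominant, 2 for recessive) is affected.
#' @param phenocopy probability that a non-susceptible genotype is
#'   affected.
#' @param disease_allele_freq population frequency q of the disease
#'   allele, in (0, 1).
#' @return object of class `disease_model` with the penetrance vector
#'   `f = (f0, f1, f2)` (probability affected given 0/1/2 disease
#'   alleles).
#' @export
disease_model <- function(mode = c("dominant", "recessive"), penetrance = 0.9,
                          phenocopy = 0, disease_allele_freq = 0.001) {
  mode <- match.arg(mode)
  stopifnot(penetrance >= 0, penetrance <= 1, phenocopy >= 0, phenocopy <= 1,
            disease_allele_freq > 0, disease_allele_freq < 1)
  f <- if (mode == "dominant") c(phenocopy, penetrance, penetrance)
       else c(phenocopy, phenocopy, penetrance)
  if (is.unsorted(f)) stop("penetrance vector must be non-decreasing")
  structure(list(mode = mode, f = f, q = disease_allele_freq),
            class = "disease_model")
}

# --- two-locus state space -------------------------------------------------
# A haplotype pairs one allele at the (unobserved) disease locus with one at
# the marker: h in 1..4 encodes (d, m), d = disease allele (0/1), m = marker
# allele (0 = ref, 1 = alt), h = 2 d + m + 1. An individual's state is an
# ordered (paternal, maternal) haplotype pair, s in 1..16.

hap_d <- function(h) (h - 1L) %/% 2L
hap_m <- function(h) (h - 1L) %% 2L
state_hp <- function(s) (s - 1L) %/% 4L + 1L
state_hm <- function(s) (s - 1L) %% 4L + 1L

# 16 x 4 transmission matrix: P(transmit haplotype t | parent state s) with
# recombination fraction theta between disease locus and marker.
transmission_matrix <- function(theta) {
  T <- matrix(0, 16L, 4L)
  for (s in 1:16) {
    a <- state_hp(s); b <- state_hm(s)
    r1 <- 2L * hap_d(a) + hap_m(b) + 1L   # disease from paternal, marker from maternal
    r2 <- 2L * hap_d(b) + hap_m(a) + 1L
    T[s, a] <- T[s, a] + (1 - theta) / 2
    T[s, b] <- T[s, b] + (1 - theta) / 2
    T[s, r1] <- T[s, r1] + theta / 2
    T[s, r2] <- T[s, r2] + theta / 2
  }
  T
}

# Per-state evidence weight: indicator of the observed marker dosage times
# the phenotype probability under the penetrance vector.
state_evidence <- function(marker_geno, phenotype, f) {
  s <- 1:16
  md <- hap_m(state_hp(s)) + hap_m(state_hm(s))
  dd <- hap_d(state_hp(s)) + hap_d(state_hm(s))
  w <- rep(1, 16)
  if (!is.na(marker_geno)) w <- w * as.numeric(md == marker_geno)
  if (phenotype == "affected") w <- w * f[dd + 1L]
  if (phenotype == "unaffected") w <- w * (1 - f[dd + 1L])
  w
}

# --- factor algebra for variable elimination -------------------------------

fac <- function(vars, vals) list(vars = vars, vals = vals)

fac_expand <- function(f, U, dims) {
  extra <- setdiff(U, f$vars)
  arr <- array(f$vals, dim = c(dims[f$vars], dims[extra]))
  aperm(arr, match(U, c(f$vars, extra)))
}

fac_mult <- function(f1, f2, dims) {
  U <- union(f1$vars, f2$vars)
  fac(U, fac_expand(f1, U, dims) * fac_expand(f2, U, dims))
}

fac_sum_out <- function(f, v, dims) {
  p <- which(f$vars == v)
  others <- setdiff(seq_along(f$vars), p)
  if (length(others) == 0L) return(fac(character(0), sum(f$vals)))
  arr <- aperm(array(f$vals, dim = dims[f$vars]), c(others, p))
  od <- dims[f$vars[others]]
  vals <- rowSums(matrix(arr, nrow = prod(od)))
  fac(f$vars[others], array(vals, dim = od))
}

# add implicit unknown founders so every individual has 0 or 2 parents
complete_parents <- function(ped) {
  df <- ped
  class(df) <- "data.frame"
  half <- which(xor(is.na(df$father_id), is.na(df$mother_id)))
  for (i in half) {
    nid <- paste0("..unk_parent_", df$id[i])
    df <- rbind(df, data.frame(id = nid, father_id = NA_character_,
                               mother_id = NA_character_,
                               sex = if (is.na(df$father_id[i])) "male" else "female",
                               phenotype = "unknown", sequenced = FALSE,
                               sampled = FALSE))
    if (is.na(df$father_id[i])) df$father_id[i] <- nid else df$mother_id[i] <- nid
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Two-point pedigree log10-likelihood by generalized peeling
#'
#' Computes log10 P(phenotypes, marker genotypes | model, theta) for a
#' candidate variant treated as a marker linked to an unobserved biallelic
#' disease locus at recombination fraction `theta`. Founder haplotypes are
#' drawn at Hardy-Weinberg and linkage equilibrium (disease allele
#' frequency from the model, marker alternate-allele frequency
#' `marker_allele_freq`); marker genotype calls are treated as exact.
#' The sum over unobserved disease genotypes and phases is carried out by
#' exact variable elimination over per-individual haplotype-pair states
#' (leaf-first on tree pedigrees; consanguinity loops are handled exactly
#' without loop breakers), with per-step rescaling for numerical
#' stability.
#'
#' @param pedigree a [pedigree()] (acyclic; loops from shared ancestry are
#'   fine).
#' @param genotypes named dosage vector of observed marker genotypes
#'   (individuals absent from the vector, or `NA`, are unobserved).
#' @param model a [disease_model()].
#' @param theta recombination fraction in [0, 0.5].
#' @param marker_allele_freq founder frequency of the marker alternate
#'   allele (default 0.01).
#' @param normalize `"joint"` (default) returns the joint likelihood of
#'   phenotypes and marker data; `"conditional"` divides by the marker-
#'   only likelihood, so a pedigree with no phenotype evidence scores
#'   exactly 0.
#' @param on_zero `"error"` raises "inconsistent data" when no genotype
#'   configuration has positive probability; `"neginf"` returns `-Inf`.
#' @return log10 likelihood (scalar).
#' @export
pedigree_likelihood <- function(pedigree, genotypes, model, theta,
                                marker_allele_freq = 0.01,
                                normalize = c("joint", "conditional"),
                                on_zero = c("error", "neginf")) {
  normalize <- match.arg(normalize)
  on_zero <- match.arg(on_zero)
  stopifnot(theta >= 0, theta <= 0.5,
            marker_allele_freq > 0, marker_allele_freq < 1)
  ped <- complete_parents(pedigree)
  ll <- peel_loglik(ped, genotypes, model$f, model$q, theta, marker_allele_freq)
  if (normalize == "conditional") {
    flat <- ped; flat$phenotype <- "unknown"
    ll <- ll - peel_loglik(flat, genotypes, model$f, model$q, theta,
                           marker_allele_freq)
  }
  if (!is.finite(ll) && on_zero == "error") stop("inconsistent data")
  ll
}

peel_loglik <- function(ped, genotypes, f, q, theta, p_alt) {
  n <- nrow(ped)
  ids <- ped$id
  g <- genotypes[match(ids, names(genotypes))]
  prior16 <- {
    pd <- c(1 - q, q); pm <- c(1 - p_alt, p_alt)
    ph <- pd[hap_d(1:4) + 1L] * pm[hap_m(1:4) + 1L]
    ph[state_hp(1:16)] * ph[state_hm(1:16)]
  }
  Tm <- transmission_matrix(theta)

  support <- vector("list", n)
  dims <- integer(n); names(dims) <- ids
  factors <- list()
  for (i in seq_len(n)) {
    w <- state_evidence(g[i], ped$phenotype[i], f)
    if (is.na(ped$father_id[i])) w <- w * prior16
    support[[i]] <- which(w > 0)
    if (length(support[[i]]) == 0L) return(-Inf)
    dims[i] <- length(support[[i]])
    factors[[length(factors) + 1L]] <- fac(ids[i], w[support[[i]]])
  }
  names(support) <- ids
  for (i in seq_len(n)) {
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    if (is.na(fa)) next
    sc <- support[[ids[i]]]; sf <- support[[fa]]; sm <- support[[mo]]
    arr <- array(0, dim = c(length(sc), length(sf), length(sm)))
    for (ci in seq_along(sc)) {
      hp <- state_hp(sc[ci]); hm <- state_hm(sc[ci])
      arr[ci, , ] <- outer(Tm[sf, hp], Tm[sm, hm])
    }
    factors[[length(factors) + 1L]] <- fac(c(ids[i], fa, mo), arr)
  }

  logscale <- 0
  remaining <- ids
  while (length(remaining) > 0L) {
    # greedy elimination: pick the variable whose combined factor is smallest
    cost <- vapply(remaining, function(v) {
      vars <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      prod(dims[vars])
    }, numeric(1))
    v <- remaining[which.min(cost)]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prodf <- Reduce(function(a, b) fac_mult(a, b, dims), factors[touch])
    newf <- fac_sum_out(prodf, v, dims)
    m <- max(newf$vals)
    if (m == 0) return(-Inf)
    newf$vals <- newf$vals / m
    logscale <- logscale + log10(m)
    factors <- c(factors[!touch], list(newf))
    remaining <- setdiff(remaining, v)
  }
  const <- prod(vapply(factors, function(f) as.numeric(f$vals), numeric(1)))
  if (const == 0) return(-Inf)
  logscale + log10(const)
}

#' Two-point LOD score between a candidate variant and the phenotype
#'
#' `lod = log10 L(theta) - log10 L(0.5)`, both terms from
#' [pedigree_likelihood()]. Data impossible at the tested `theta` but
#' possible under free recombination yield `lod = -Inf` with
#' `incompatible_at_theta = TRUE` (an obligate recombinant at theta = 0).
#'
#' @inheritParams pedigree_likelihood
#' @param theta recombination fraction tested (default 0, full linkage).
#' @return object of class `linkage_result`: `lod`,
#'   `log10_likelihood_linked`, `log10_likelihood_unlinked`, `theta`,
#'   `incompatible_at_theta`.
#' @export
two_point_lod <- function(pedigree, genotypes, model, theta = 0,
                          marker_allele_freq = 0.01) {
  ll0 <- pedigree_likelihood(pedigree, genotypes, model, theta = theta,
                             marker_allele_freq = marker_allele_freq,
                             on_zero = "neginf")
  ll5 <- pedigree_likelihood(pedigree, genotypes, model, theta = 0.5,
                             marker_allele_freq = marker_allele_freq,
                             on_zero = "error")
  structure(list(lod = ll0 - ll5, log10_likelihood_linked = ll0,
                 log10_likelihood_unlinked = ll5, theta = theta,
                 incompatible_at_theta = !is.finite(ll0)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  if (x$incompatible_at_theta) {
    cat(sprintf("two-point LOD: incompatible at theta = %g (lod = -Inf)\n", x$theta))
  } else {
    cat(sprintf("two-point LOD = %.4f at theta = %g (L1 = %.4f, L0 = %.4f)\n",
                x$lod, x$theta, x$log10_likelihood_linked,
                x$log10_likelihood_unlinked))
  }
  invisible(x)
}
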