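# Independent brute-force oracles. These deliberately re-derive each
# predicate from first principles (loops, truth tables, exhaustive
# enumeration) and never call the implementation paths they check.

# dominant compatibility by direct truth table over individuals
oracle_dominant <- function(geno, ped, allow_incomplete) {
  compatible <- TRUE
  violators <- character(0)
  non_pen <- character(0)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    g <- geno[id]
    if (is.na(g)) next
    ph <- ped$phenotype[i]
    if (ph == "affected" && g == 0L) {
      compatible <- FALSE; violators <- c(violators, id)
    }
    if (ph == "unaffected" && g > 0L) {
      if (allow_incomplete) non_pen <- c(non_pen, id)
      else { compatible <- FALSE; violators <- c(violators, id) }
    }
  }
  list(compatible = compatible, violators = sort(violators),
       non_penetrant_carriers = sort(non_pen))
}

oracle_recessive <- function(geno, ped) {
  compatible <- TRUE
  violators <- character(0)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]; g <- geno[id]
    if (is.na(g)) next
    ph <- ped$phenotype[i]
    if (ph == "affected" && g != 2L) { compatible <- FALSE; violators <- c(violators, id) }
    if (ph == "unaffected" && g == 2L) { compatible <- FALSE; violators <- c(violators, id) }
    if (ph == "affected" && g == 2L) {
      for (par in c(ped$father_id[i], ped$mother_id[i])) {
        if (!is.na(par) && !is.na(geno[par]) && geno[par] == 0L) {
          compatible <- FALSE; violators <- c(violators, par)
        }
      }
    }
  }
  list(compatible = compatible, violators = sort(unique(violators)))
}

# Mendelian trio check by explicit gamete enumeration
oracle_trio_possible <- function(gf, gm, gc) {
  alleles <- function(g) switch(g + 1L, list(c(0L, 0L)), list(c(0L, 1L)), list(c(1L, 1L)))[[1]]
  for (a in alleles(gf)) for (b in alleles(gm)) {
    if (a + b == gc) return(TRUE)
  }
  FALSE
}

# somatic subtraction predicate, re-derived per genotype pair
oracle_subtract_keep <- function(tumor_g, germ_g) {
  if (is.na(tumor_g) || tumor_g < 1L) return(FALSE)
  if (is.na(germ_g)) return(FALSE)
  germ_g == 0L
}

# exhaustive simple-path enumeration by recursive DFS over an edge list
oracle_paths <- function(edges, src, targets, max_edges) {
  adj <- list()
  adde <- function(a, b) adj[[a]] <<- union(adj[[a]] %||% character(0), b)
  for (i in seq_len(nrow(edges))) {
    adde(edges$gene_a[i], edges$gene_b[i]); adde(edges$gene_b[i], edges$gene_a[i])
  }
  found <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) > 1L && last %in% targets) found[[length(found) + 1L]] <<- path
    if (length(path) - 1L == max_edges) return()
    for (nb in setdiff(adj[[last]] %||% character(0), path)) walk(c(path, nb))
  }
  walk(src)
  if (src %in% targets) found <- c(list(src), found)
  unique(found)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full enumeration of the two-locus pedigree likelihood: every individual
# takes one of up to 16 ordered haplotype-pair states; probabilities are
# multiplied factor by factor over the explicit assignment grid (chunked).
oracle_pedigree_loglik <- function(ped, geno, model, theta, p_alt,
                                   chunk = 200000L) {
  q <- model$q; f <- model$f
  hap_d <- function(h) (h - 1L) %/% 2L
  hap_m <- function(h) (h - 1L) %% 2L
  shp <- function(s) (s - 1L) %/% 4L + 1L
  shm <- function(s) (s - 1L) %% 4L + 1L
  Tm <- matrix(0, 16L, 4L)
  for (s in 1:16) {
    a <- shp(s); b <- shm(s)
    r1 <- 2L * hap_d(a) + hap_m(b) + 1L
    r2 <- 2L * hap_d(b) + hap_m(a) + 1L
    Tm[s, a] <- Tm[s, a] + (1 - theta) / 2
    Tm[s, b] <- Tm[s, b] + (1 - theta) / 2
    Tm[s, r1] <- Tm[s, r1] + theta / 2
    Tm[s, r2] <- Tm[s, r2] + theta / 2
  }
  ph <- c(1 - q, q)[hap_d(1:4) + 1L] * c(1 - p_alt, p_alt)[hap_m(1:4) + 1L]
  prior16 <- ph[shp(1:16)] * ph[shm(1:16)]

  n <- nrow(ped)
  ids <- ped$id
  g <- geno[match(ids, names(geno))]
  ev <- matrix(1, 16L, n)
  for (i in seq_len(n)) {
    md <- hap_m(shp(1:16)) + hap_m(shm(1:16))
    dd <- hap_d(shp(1:16)) + hap_d(shm(1:16))
    w <- rep(1, 16)
    if (!is.na(g[i])) w <- w * as.numeric(md == g[i])
    if (ped$phenotype[i] == "affected") w <- w * f[dd + 1L]
    if (ped$phenotype[i] == "unaffected") w <- w * (1 - f[dd + 1L])
    ev[, i] <- w
  }
  supp <- lapply(seq_len(n), function(i) which(ev[, i] > 0))
  sizes <- lengths(supp)
  if (any(sizes == 0L)) return(-Inf)
  total <- prod(sizes)
  fa_idx <- match(ped$father_id, ids)
  mo_idx <- match(ped$mother_id, ids)

  SHP <- shp(1:16); SHM <- shm(1:16)
  acc <- 0
  done <- 0
  while (done < total) {
    m <- min(chunk, total - done)
    lin <- done + seq_len(m) - 1
    states <- matrix(0L, m, n)
    rem <- lin
    for (i in seq_len(n)) {
      states[, i] <- supp[[i]][(rem %% sizes[i]) + 1L]
      rem <- rem %/% sizes[i]
    }
    p <- rep(1, m)
    for (i in seq_len(n)) {
      si <- states[, i]
      p <- p * ev[si + (i - 1L) * 16L]
      if (is.na(fa_idx[i])) {
        p <- p * prior16[si]
      } else {
        p <- p * Tm[states[, fa_idx[i]] + (SHP[si] - 1L) * 16L] *
          Tm[states[, mo_idx[i]] + (SHM[si] - 1L) * 16L]
      }
    }
    acc <- acc + sum(p)
    done <- done + m
  }
  if (acc == 0) -Inf else log10(acc)
}

# random nuclear-family pedigree with gene-dropped marker genotypes,
# sized so that full enumeration stays tractable
random_small_pedigree <- function(seed, max_members = 8L, p_alt = 0.3) {
  set.seed(seed)
  n_child <- sample(2:(max_members - 2L), 1)
  ids <- c("F", "M", paste0("C", seq_len(n_child)))
  ped <- pedigree(
    id = ids,
    father_id = c(NA, NA, rep("F", n_child)),
    mother_id = c(NA, NA, rep("M", n_child)),
    sex = c("male", "female", sample(c("male", "female"), n_child, TRUE)),
    phenotype = "unknown")
  a1 <- c(stats::rbinom(2, 1, p_alt), rep(NA, n_child))
  a2 <- c(stats::rbinom(2, 1, p_alt), rep(NA, n_child))
  for (k in seq_len(n_child)) {
    a1[2 + k] <- if (stats::runif(1) < .5) a1[1] else a2[1]
    a2[2 + k] <- if (stats::runif(1) < .5) a1[2] else a2[2]
  }
  geno <- stats::setNames(as.integer(a1 + a2), ids)
  # random phenotypes and a few missing genotypes (missingness is kept low:
  # each untyped member multiplies the enumeration grid by 16)
  ped$phenotype <- sample(c("affected", "unaffected", "unknown"),
                          nrow(ped), TRUE, prob = c(.35, .45, .2))
  geno[stats::runif(length(geno)) < 0.05] <- NA_integer_
  list(ped = ped, geno = geno)
}
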