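# Diversity and differentiation statistics: per-population summaries,
# Weir-Cockerham (1984) pairwise and global per-locus F_ST, and the
# Weir-Goudet matching-proportion population-specific F_ST (beta).

#' Per-population diversity statistics
#'
#' Per SNP and population, over non-missing calls: observed heterozygosity
#' (heterozygote fraction), expected heterozygosity He = 2p(1-p) without
#' small-sample correction, nucleotide diversity at variant sites
#' pi = n/(n-1) * 2p(1-p) with n the local allele count, and
#' F_IS = 1 - Ho/He where He > 0 (undefined sites excluded from the mean).
#' Values are averaged over sites. Private alleles (Pa) count the SNPs at
#' which an allele segregates (frequency > 0) in the focal population and is
#' absent among the non-missing calls of every other population; a population
#' with all calls missing at a SNP counts as "absent" there.
#'
#' @param G a [genotype_matrix()].
#' @param popmap population map.
#' @return data.frame with one row per population: `population`, `n`
#'   (individuals), `pa`, `ho`, `he`, `pi`, `fis`, and `beta`
#'   (population-specific F_ST from [population_specific_fst()]).
#' @export
per_pop_stats <- function(G, popmap) {
  pop <- pop_factor(G, popmap)
  if (any(table(pop) == 0)) stop("empty population")
  af <- pop_allele_freq(G, popmap)
  p <- af$freq          # pops x SNPs, NaN when no calls
  n <- af$n             # non-missing genotype counts
  ho <- af$het
  he <- 2 * p * (1 - p)
  nal <- 2 * n
  pi <- ifelse(nal > 1, nal / (nal - 1) * he, NA)
  fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA)

  # private alleles: alt allele private iff p_i > 0 and p_j == 0 elsewhere;
  # ref allele private iff p_i < 1 and p_j == 1 elsewhere (over called pops)
  called <- n > 0
  pa <- integer(nlevels(pop))
  for (i in seq_len(nlevels(pop))) {
    others <- which(seq_len(nlevels(pop)) != i)
    p_oth <- p[others, , drop = FALSE]
    c_oth <- called[others, , drop = FALSE]
    alt_absent <- colSums(c_oth & p_oth > 0) == 0
    ref_absent <- colSums(c_oth & p_oth < 1) == 0
    alt_private <- called[i, ] & p[i, ] > 0 & alt_absent
    ref_private <- called[i, ] & p[i, ] < 1 & ref_absent
    pa[i] <- sum(alt_private | ref_private)
  }

  beta <- population_specific_fst(G, popmap)
  data.frame(population = levels(pop),
             n = as.integer(table(pop)),
             pa = pa,
             ho = rowMeans(ho, na.rm = TRUE),
             he = rowMeans(he, na.rm = TRUE),
             pi = rowMeans(pi, na.rm = TRUE),
             fis = rowMeans(fis, na.rm = TRUE),
             beta = beta[levels(pop)],
             row.names = NULL)
}

# Weir-Cockerham (1984) variance components a (among populations),
# b (among individuals within populations) and c (within individuals),
# per locus, for an arbitrary number of populations. Inputs are
# per-population alternate-allele frequencies, heterozygote proportions and
# sample sizes (individuals) at each locus; loci where fewer than two
# populations have data, or that are monomorphic across the included
# populations, yield NA components.
wc_components <- function(p, h, n) {
  # p, h, n: pops x loci matrices
  use <- n >= 1 & !is.na(p)
  r <- colSums(use)
  n_use <- ifelse(use, n, 0)
  nbar <- colSums(n_use) / r
  nsum <- colSums(n_use)
  nc <- (nsum - colSums(n_use^2) / nsum) / (r - 1)
  pbar <- colSums(n_use * ifelse(use, p, 0)) / nsum
  s2 <- colSums(n_use * (ifelse(use, p, pbar[col(p)]) -
                           rep(pbar, each = nrow(p)))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_use * ifelse(use, h, 0)) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  ok <- r >= 2 & poly & nbar > 1
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  list(a = a, b = b, c = cc, ok = ok)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' The 1984 theta estimator, combined across loci as a ratio of averages
#' (sum of `a` over sum of `a + b + c`). Sites monomorphic across a pair are
#' skipped for that pair. Pairs with no co-typed polymorphic sites get `NA`
#' with a warning.
#'
#' @inheritParams per_pop_stats
#' @return symmetric populations x populations matrix, diagonal 0.
#' @export
pairwise_fst <- function(G, popmap) {
  af <- pop_allele_freq(G, popmap)
  pops <- rownames(af$freq)
  if (length(pops) < 2) stop("need at least two populations")
  K <- length(pops)
  fst <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      sel <- c(i, j)
      comp <- wc_components(af$freq[sel, , drop = FALSE],
                            af$het[sel, , drop = FALSE],
                            af$n[sel, , drop = FALSE])
      num <- sum(comp$a[comp$ok])
      den <- sum((comp$a + comp$b + comp$c)[comp$ok])
      if (!any(comp$ok) || den == 0) {
        warning("no usable sites for pair ", pops[i], " / ", pops[j])
        fst[i, j] <- fst[j, i] <- NA
      } else {
        fst[i, j] <- fst[j, i] <- num / den
      }
    }
  }
  fst
}

#' Global per-locus Weir-Cockerham F_ST
#'
#' Multi-population theta per locus: `a / (a + b + c)`. Loci monomorphic
#' across all populations yield `NA`.
#'
#' @inheritParams per_pop_stats
#' @return numeric vector, one value per SNP (named by site id).
#' @export
global_per_locus_fst <- function(G, popmap) {
  af <- pop_allele_freq(G, popmap)
  comp <- wc_components(af$freq, af$het, af$n)
  theta <- comp$a / (comp$a + comp$b + comp$c)
  names(theta) <- colnames(af$freq)
  theta
}

#' Population-specific F_ST (Weir-Goudet beta)
#'
#' The matching-proportion estimator: per locus, the within-population
#' allele-matching proportion for population i is
#' `M_i = sum_a x_a (x_a - 1) / (n (n - 1))` over allele counts `x_a` with
#' `n` total alleles (matching without replacement), and the mean
#' between-population matching is `M_B = mean_{i != j} sum_a p_ia p_ja`.
#' `beta_i = (M_i - M_B) / (1 - M_B)`, combined across loci as a ratio of
#' averages. All populations fixed for the same allele everywhere
#' (`M_B = 1`) is flagged as undefined.
#'
#' @inheritParams per_pop_stats
#' @return named numeric vector of per-population beta values.
#' @export
population_specific_fst <- function(G, popmap) {
  af <- pop_allele_freq(G, popmap)
  p <- af$freq
  n_al <- 2 * af$n
  K <- nrow(p)
  if (K < 2) stop("need at least two populations")
  x_alt <- p * n_al
  # within matching without replacement
  Mi <- (x_alt * (x_alt - 1) + (n_al - x_alt) * (n_al - x_alt - 1)) /
    (n_al * (n_al - 1))
  Mi[n_al < 2] <- NA
  # between matching, averaged over ordered pairs i != j, per locus
  MB <- matrix(NA_real_, K, ncol(p))
  for (l in seq_len(ncol(p))) {
    pl <- p[, l]
    ok <- !is.na(pl) & n_al[, l] > 0
    if (sum(ok) < 2) next
    match_lm <- outer(pl[ok], pl[ok]) + outer(1 - pl[ok], 1 - pl[ok])
    MB[, l][ok] <- (sum(match_lm) - sum(diag(match_lm))) /
      (sum(ok) * (sum(ok) - 1))
  }
  num <- rowSums(Mi - MB, na.rm = TRUE)
  den <- rowSums(1 - MB, na.rm = TRUE)
  if (all(den == 0, na.rm = TRUE)) {
    stop("all populations fixed identical: beta undefined")
  }
  beta <- num / den
  stats::setNames(beta, rownames(p))
}
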