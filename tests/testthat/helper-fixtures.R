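# Shared fixtures, built in code. The reference simulation (the package's
# default study conditions) is computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small simulation reused across test files: 20 populations, moderate SNP
# count, defaults otherwise.
small_sim <- function(n_snps = 300, seed = 7, ...) {
  key <- paste0("sim_", n_snps, "_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- simulate_metapopulation(sim_config(n_snps = n_snps, seed = seed, ...))
  .fixture_cache[[key]] <- sim
  sim
}

# Hand-built genotype matrix: 4 individuals x 5 SNPs over 2 loci, with one
# missing call and per-genotype depths.
tiny_G <- function() {
  g <- rbind(i1 = c(0L, 1L, 2L, 0L, 1L),
             i2 = c(0L, 1L, 2L, 1L, NA),
             i3 = c(1L, 2L, 0L, 2L, 1L),
             i4 = c(2L, 0L, 1L, 0L, 0L))
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                      pos = c(100L, 250L, 400L, 50L, 90L),
                      locus = c("L1", "L1", "L2", "L3", "L4"),
                      ref = "A", alt = "G",
                      depth = c(15, 12, 22, 9, 35))
  dp <- matrix(10L, 4, 5, dimnames = list(rownames(g), NULL))
  genotype_matrix(g, sites, dp = dp)
}

tiny_popmap <- function(G = tiny_G()) {
  data.frame(individual = rownames(G$geno),
             population = c("p1", "p1", "p2", "p2"),
             lake = c("lakeA", "lakeA", "lakeB", "lakeB"),
             hydrometric_area = c("HA1", "HA1", "HA2", "HA2"),
             ecotype = "unimodal",
             replicate_group = NA_character_)
}

# Genotype matrix built directly from a dosage matrix (individuals x SNPs),
# one SNP per locus, sequential positions.
make_G <- function(g, depth = NA_real_) {
  S <- ncol(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  sites <- data.frame(chrom = "chr1", pos = seq_len(S) * 10L,
                      locus = paste0("L", seq_len(S)), ref = "A", alt = "G",
                      depth = rep_len(depth, S))
  genotype_matrix(g, sites)
}

make_popmap <- function(G, pop) {
  data.frame(individual = rownames(G$geno), population = pop,
             lake = pop, hydrometric_area = pop, ecotype = "unimodal",
             replicate_group = NA_character_)
}

# Independent scalar implementation of the Weir-Cockerham (1984) theta,
# ratio of averages, written as plain per-locus loops against the textbook
# component formulas. Inputs: list of per-population dosage matrices.
wc_theta_oracle <- function(pop_genos) {
  r_all <- length(pop_genos)
  S <- ncol(pop_genos[[1]])
  num <- den <- 0
  for (l in seq_len(S)) {
    ns <- ps <- hs <- numeric(0)
    for (k in seq_len(r_all)) {
      gl <- pop_genos[[k]][, l]
      gl <- gl[!is.na(gl)]
      if (length(gl) == 0) next
      ns <- c(ns, length(gl))
      ps <- c(ps, sum(gl) / (2 * length(gl)))
      hs <- c(hs, mean(gl == 1))
    }
    r <- length(ns)
    if (r < 2) next
    nbar <- mean(ns)
    if (nbar <= 1) next
    pbar <- sum(ns * ps) / sum(ns)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hs) / sum(ns)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Independently coded two-level AMOVA (populations, individuals within),
# classical unbalanced one-way variance components from squared Euclidean
# distances.
two_level_amova_oracle <- function(g, pop) {
  pops <- unique(pop)
  N <- nrow(g)
  P <- length(pops)
  grand <- colMeans(g)
  ss_within <- 0
  ss_among <- 0
  for (p in pops) {
    sub <- g[pop == p, , drop = FALSE]
    m <- colMeans(sub)
    ss_within <- ss_within + sum(sweep(sub, 2, m)^2)
    ss_among <- ss_among + nrow(sub) * sum((m - grand)^2)
  }
  ns <- table(pop)[pops]
  n0 <- (N - sum(ns^2) / N) / (P - 1)
  ms_within <- ss_within / (N - P)
  ms_among <- ss_among / (P - 1)
  c(among = (ms_among - ms_within) / n0, within = ms_within)
}

# Constructed clean turnover signal: lakes spread along one climate variable,
# SNP minor-allele frequencies stepping at locations spread over its range.
step_signal_fixture <- function(n_lakes = 24, n_snps = 40, seed = 2) {
  withr::with_seed(seed, {
    env <- data.frame(lake = paste0("lake", sprintf("%02d", seq_len(n_lakes))),
                      scenario = "current")
    for (v in paste0("bio", 1:19)) env[[v]] <- rnorm(n_lakes, 50, 10)
    env$bio1 <- seq(5, 12, length.out = n_lakes)
    env$latitude <- seq(59, 55, length.out = n_lakes)
    step_at <- runif(n_snps, 5.5, 11.5)
    f <- sapply(seq_len(n_snps), function(s) {
      pmin(pmax(ifelse(env$bio1 > step_at[s], 0.45, 0.05) +
                  rnorm(n_lakes, 0, 0.01), 0), 0.5)
    })
    dimnames(f) <- list(env$lake, paste0("s", seq_len(n_snps)))
    list(env = env, freqs = f, step_at = step_at)
  })
}
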