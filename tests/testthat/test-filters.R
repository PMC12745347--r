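# Brute-force per-SNP recounts for the presence rule.
presence_oracle <- function(G, pop, min_prop) {
  vapply(seq_len(n_sites(G)), function(j) {
    called <- !is.na(G$geno[, j])
    if (mean(called) < min_prop) return(FALSE)
    all(vapply(unique(pop), function(p) {
      mean(called[pop == p]) >= min_prop
    }, logical(1)))
  }, logical(1))
}

test_that("presence filter matches a brute-force recount across thresholds", {
  sim <- small_sim(n_snps = 200, seed = 7)
  G <- sim$genotypes
  pop <- sim$popmap$population
  for (thr in c(0.5, 0.66, 0.9, 1)) {
    res <- filter_presence(G, sim$popmap, min_prop = thr)
    keep <- presence_oracle(G, pop, thr)
    expect_equal(res$report$snps_out, sum(keep))
    expect_equal(site_ids(res$genotypes$sites),
                 site_ids(G$sites)[keep])
  }
  # a SNP missing in half of one population is removed at 0.66
  g <- matrix(2L, 6, 2)
  g[1:2, 1] <- NA  # 50% called in p1
  Gm <- make_G(g)
  pm <- make_popmap(Gm, rep(c("p1", "p2"), c(4, 2)))
  out <- filter_presence(Gm, pm, 0.66)
  expect_equal(out$report$snps_removed, 1)
  # complete matrix: nothing removed
  expect_equal(filter_presence(make_G(matrix(1L, 4, 3)),
                               make_popmap(make_G(matrix(1L, 4, 3)),
                                           rep("p1", 4)))$report$snps_removed,
               0)
})

test_that("MAF, heterozygosity and first-SNP-per-locus rules apply literally", {
  # 1 alt allele among 200: MAF 0.005 < 0.01 removed; MAF 0.01 retained
  g <- matrix(0L, 100, 3)
  g[1, 1] <- 1L                      # MAF 0.005
  g[1:2, 2] <- 1L                    # MAF 0.01
  g[, 3] <- rep(c(0L, 2L), 50)       # MAF 0.5
  res <- filter_maf(make_G(g), 0.01)
  expect_equal(res$report$snps_removed, 1)
  expect_equal(res$genotypes$sites$locus, c("L2", "L3"))

  # every individual heterozygous -> removed at max_ho 0.5
  g2 <- cbind(rep(1L, 20), rep(c(0L, 1L, 2L, 0L), 5))
  res2 <- filter_max_het(make_G(g2), 0.5)
  expect_equal(res2$report$snps_removed, 1)

  # three SNPs on one locus: the lowest-position SNP is kept
  G3 <- tiny_G()
  res3 <- first_snp_per_locus(G3)
  expect_equal(res3$genotypes$sites$pos[res3$genotypes$sites$locus == "L1"],
               100L)
  expect_equal(res3$report$snps_out, 4)
})

test_that("exact HWE test matches expectations and calibrates", {
  # perfect 1:2:1 at p = 0.5 is retained
  expect_gt(hwe_exact_test(5, 10, 5), 0.5)
  # an all-heterozygote sample of 20 is strongly rejected
  expect_lt(hwe_exact_test(0, 20, 0), 1e-4)
  # exact-test enumeration oracle: p equals the tail sum of the conditional
  # distribution computed by direct enumeration with choose()
  hwe_oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    n_a <- 2 * n_aa + n_ab
    probs <- sapply(0:n, function(h) {
      hom_a <- (n_a - h) / 2
      if (h > n_a || hom_a != round(hom_a) || hom_a < 0 ||
          n - h - hom_a < 0) return(0)
      choose(n, h) * choose(n - h, hom_a) * 2^h /
        choose(2 * n, n_a)
    })
    probs <- probs / sum(probs)
    sum(probs[probs <= probs[n_ab + 1] + 1e-12])
  }
  for (cnt in list(c(3, 5, 2), c(0, 10, 0), c(8, 1, 1), c(2, 2, 6))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # calibration: under HWE sampling, rejections at alpha are rare
  pvals <- withr::with_seed(11, {
    replicate(300, {
      p <- runif(1, 0.2, 0.8)
      g <- rbinom(30, 2, p)
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    })
  })
  expect_lt(mean(pvals < 0.05), 0.08)  # exact test is conservative
  # per-population filter removes the all-heterozygote SNP
  g <- cbind(rep(1L, 20), rbinom(20, 2, 0.5))
  Gh <- make_G(g)
  pm <- make_popmap(Gh, rep("p1", 20))
  res <- filter_hwe_per_pop(Gh, pm, alpha = 0.001)
  expect_equal(res$report$snps_removed, 1)
})

test_that("depth filter bounds are inclusive and match a recount", {
  G <- tiny_G()   # depths 15, 12, 22, 9, 35
  res <- filter_depth(G, 10, 30)
  expect_equal(res$genotypes$sites$depth, c(15, 12, 22))
  # boundary values retained
  Gb <- make_G(matrix(1L, 3, 4), depth = c(10, 30, 9.99, 30.01))
  expect_equal(filter_depth(Gb)$genotypes$sites$depth, c(10, 30))
  # random depths vs recount
  Gr <- make_G(matrix(1L, 2, 50),
               depth = withr::with_seed(3, runif(50, 5, 40)))
  resr <- filter_depth(Gr, 10, 30)
  expect_equal(site_ids(resr$genotypes$sites),
               site_ids(Gr$sites)[Gr$sites$depth >= 10 &
                                    Gr$sites$depth <= 30])
  # absent depth: skipped with a warning
  expect_warning(res0 <- filter_depth(make_G(matrix(1L, 2, 3))), "skipped")
  expect_equal(res0$report$snps_removed, 0)
})

test_that("replicate error estimation is exact on constructed pairs", {
  # identical replicates -> rate 0; 3 mismatches / 100 co-called -> 0.03
  g_src <- matrix(rep(c(0L, 1L, 2L), length.out = 100), 1, 100)
  g_rep <- g_src
  g_rep[1, 1:3] <- (g_src[1, 1:3] + 1L) %% 3L
  g <- rbind(a = g_src[1, ], a_rep = g_rep[1, ],
             b = g_src[1, ], b_rep = g_src[1, ])
  G <- make_G(g)
  pm <- data.frame(individual = rownames(g),
                   population = "p1", lake = "l1", hydrometric_area = "h1",
                   ecotype = "unimodal",
                   replicate_group = c("a", "a", "b", "b"))
  er <- estimate_replicate_error(G, pm)
  expect_equal(sort(er$pair_rates$rate), c(0, 0.03))
  expect_equal(er$overall_rate, 0.015)
  # the three planted SNPs appear with one discordant pair each
  expect_equal(unname(er$snp_mismatch_pairs[1:3]), rep(1L, 3))

  # a SNP discordant in two pairs is dropped, one pair is tolerated
  g2 <- g
  g2["b_rep", 1] <- (g2["b", 1] + 1L) %% 3L   # SNP1 now discordant twice
  er2 <- estimate_replicate_error(make_G(g2), pm)
  expect_equal(unname(er2$snp_mismatch_pairs[1]), 2L)
  res <- drop_mismatch_snps(make_G(g2), er2, max_pairs = 1)
  expect_equal(res$report$snps_removed, 1)
  expect_false("chr1:10" %in% site_ids(res$genotypes$sites))

  # re-estimating after the drop never increases the overall rate
  er3 <- estimate_replicate_error(res$genotypes, pm)
  expect_lte(er3$overall_rate, er2$overall_rate)
})

test_that("the higher-coverage replicate is the one retained", {
  g <- rbind(a = c(0L, 1L, 2L, NA), a_rep = c(0L, 1L, 2L, 0L))
  G <- make_G(g)
  pm <- data.frame(individual = c("a", "a_rep"), population = "p1",
                   lake = "l1", hydrometric_area = "h1", ecotype = "unimodal",
                   replicate_group = "a")
  out <- drop_replicates(G, pm)
  expect_equal(rownames(out$genotypes$geno), "a_rep")
  expect_true(all(is.na(out$popmap$replicate_group)))
})

test_that("non-neutral removal takes the union of candidates and top F_ST", {
  sim <- small_sim(n_snps = 200, seed = 7)
  G <- sim$genotypes
  fst <- global_per_locus_fst(G, sim$popmap)
  cand <- site_ids(G$sites)[c(3, 50, 120)]
  res <- remove_nonneutral(G, sim$popmap, candidate_ids = cand, fst = fst,
                           top_fst_prop = 0.05)
  # brute-force union oracle
  k <- ceiling(0.05 * n_sites(G))
  ord <- order(-fst, G$sites$chrom, G$sites$pos)
  top_ids <- site_ids(G$sites)[ord[1:k]]
  expected_removed <- union(cand, top_ids)
  expect_equal(res$report$snps_removed, length(expected_removed))
  expect_true(!any(expected_removed %in% site_ids(res$genotypes$sites)))
  # candidates inside the top set do not double count
  res2 <- remove_nonneutral(G, sim$popmap, candidate_ids = top_ids[1:2],
                            fst = fst, top_fst_prop = 0.05)
  expect_equal(res2$report$snps_removed, k)
  # empty candidates: exactly ceiling(0.05 S) removed
  res3 <- remove_nonneutral(G, sim$popmap, fst = fst)
  expect_equal(res3$report$snps_removed, k)
})

test_that("complete-case filter equals a column recount", {
  sim <- small_sim(n_snps = 150, seed = 7)
  res <- complete_cases(sim$genotypes)
  expect_equal(res$report$snps_out,
               sum(colSums(is.na(sim$genotypes$geno)) == 0))
  expect_false(anyNA(res$genotypes$geno))
  # one missing cell removes exactly that SNP
  g <- matrix(1L, 3, 4)
  g[2, 3] <- NA
  res2 <- complete_cases(make_G(g))
  expect_equal(res2$report$snps_removed, 1)
  expect_equal(res2$genotypes$sites$locus, c("L1", "L2", "L4"))
})

test_that("the cascade telescopes and every filter is idempotent", {
  cfg <- sim_config(n_snps = 300, seed = 19, missing_rate = 0.08)
  sim <- simulate_replicates(simulate_metapopulation(cfg), cfg)
  G <- sim$genotypes
  pm <- sim$popmap

  s1 <- filter_presence(G, pm)
  s2 <- filter_maf(s1$genotypes)
  s3 <- filter_max_het(s2$genotypes)
  s4 <- first_snp_per_locus(s3$genotypes)
  s5 <- filter_hwe_per_pop(s4$genotypes, pm)
  s6 <- filter_depth(s5$genotypes)
  er <- estimate_replicate_error(s6$genotypes, pm)
  s7 <- drop_mismatch_snps(s6$genotypes, er)
  rep <- bind_filter_reports(list(s1$report, s2$report, s3$report,
                                  s4$report, s5$report, s6$report, s7$report))
  expect_equal(rep$snps_out, rep$snps_in - rep$snps_removed)
  expect_equal(rep$snps_in[-1], rep$snps_out[-nrow(rep)])
  expect_equal(rep$stage,
               c("presence", "maf", "max_het", "first_snp_per_locus",
                 "hwe", "depth", "replicate_mismatch"))

  # idempotence
  expect_equal(filter_presence(s1$genotypes, pm)$report$snps_removed, 0)
  expect_equal(filter_maf(s2$genotypes)$report$snps_removed, 0)
  expect_equal(filter_max_het(s3$genotypes)$report$snps_removed, 0)
  expect_equal(first_snp_per_locus(s4$genotypes)$report$snps_removed, 0)
  expect_equal(filter_hwe_per_pop(s5$genotypes, pm)$report$snps_removed, 0)
  expect_equal(filter_depth(s6$genotypes)$report$snps_removed, 0)
  er7 <- estimate_replicate_error(s7$genotypes, pm)
  expect_equal(drop_mismatch_snps(s7$genotypes, er7)$report$snps_removed, 0)
})
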