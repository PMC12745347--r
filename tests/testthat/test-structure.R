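test_that("PCA matches an SVD oracle and elementary geometry", {
  sim <- small_sim(n_snps = 100, seed = 7)
  res <- snp_pca(sim$genotypes)
  # oracle: mean-imputed, centered matrix -> eigen of covariance
  g <- sim$genotypes$geno
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  x <- scale(g, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)
  k <- length(res$eigenvalues)
  expect_equal(res$eigenvalues, ev$values[seq_len(k)], tolerance = 1e-8)
  expect_equal(unname(abs(res$scores[, 1])),
               abs(as.numeric(x %*% ev$vectors[, 1])), tolerance = 1e-8)
  # eigenvalues non-increasing; percent variance matches eigenvalue ratios
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_equal(res$percent_var,
               100 * res$eigenvalues / sum(res$eigenvalues))

  # duplicated individual -> identical coordinates
  gi <- withr::with_seed(4, matrix(rbinom(5 * 30, 2, 0.5), 5, 30))
  g2 <- rbind(gi, dup = gi[5, ])
  res2 <- snp_pca(make_G(g2))
  expect_equal(unname(res2$scores[5, ]), unname(res2$scores[6, ]),
               tolerance = 1e-10)

  # two clusters of identical individuals: EV1 separates, explains 100%
  gc <- rbind(matrix(0L, 4, 20), matrix(2L, 4, 20))
  res3 <- snp_pca(make_G(gc))
  expect_equal(res3$percent_var[1], 100)
  expect_equal(length(unique(sign(res3$scores[, 1]))), 2)
})

test_that("genetic distances follow the definitions on toys", {
  # identical populations -> 0; fixed opposite -> 1
  g <- rbind(matrix(c(0L, 2L), 4, 6), matrix(c(0L, 2L), 4, 6))
  G <- make_G(g)
  D <- genetic_distance(G, make_popmap(G, rep(c("a", "b"), each = 4)))
  expect_equal(D["a", "b"], 0)
  gf <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  Gf <- make_G(gf)
  Df <- genetic_distance(Gf, make_popmap(Gf, rep(c("a", "b"), each = 4)))
  expect_equal(Df["a", "b"], 1)

  # 3-population, 4-SNP hand computation (Prevosti = mean |p_i - p_j|)
  ga <- rbind(c(0L, 2L, 1L, 0L), c(2L, 2L, 1L, 0L))  # p_a = .5, 1, .5, 0
  gb <- rbind(c(0L, 0L, 2L, 1L), c(0L, 2L, 2L, 1L))  # p_b = 0, .5, 1, .5
  gc2 <- rbind(c(2L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L)) # p_c = 1, 1, 0, 0
  Gh <- make_G(rbind(ga, gb, gc2))
  Dh <- genetic_distance(Gh, make_popmap(Gh, rep(c("a", "b", "c"), each = 2)))
  expect_equal(Dh["a", "b"], mean(c(.5, .5, .5, .5)))
  expect_equal(Dh["a", "c"], mean(c(.5, 0, .5, 0)))
  expect_equal(Dh["b", "c"], mean(c(1, .5, 1, .5)))
  # Nei distance is 0 for identical and positive otherwise
  Dn <- genetic_distance(Gh, make_popmap(Gh, rep(c("a", "b", "c"), each = 2)),
                         metric = "nei")
  expect_true(all(Dn[upper.tri(Dn)] > 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4-taxon additive matrix with known topology ((A,B),(C,D))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # branch lengths: A=2, B=3, C=4, D=5, internal=6
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 12
  D["A", "D"] <- D["D", "A"] <- 13
  D["B", "C"] <- D["C", "B"] <- 13
  D["B", "D"] <- D["D", "B"] <- 14
  D["C", "D"] <- D["D", "C"] <- 9
  tr <- neighbor_joining(D)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D),
                                                           rownames(D)]),
               unname(D), tolerance = 1e-10)
  expect_equal(sort(tr$edge.length), sort(c(2, 3, 4, 5, 6)))

  # property: random additive metrics from random trees, up to 12 taxa
  withr::with_seed(21, {
    for (rep in 1:5) {
      nt <- sample(4:12, 1)
      t0 <- ape::rtree(nt, rooted = FALSE)
      t0$edge.length <- runif(length(t0$edge.length), 0.1, 2)
      D0 <- as.matrix(ape::cophenetic.phylo(t0))
      tr0 <- neighbor_joining(D0)
      expect_equal(ape::dist.topo(ape::unroot(t0), tr0)[1], 0)
      expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr0))[rownames(D0),
                                                                colnames(D0)]),
                   unname(D0), tolerance = 1e-8)
    }
  })

  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  lens <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(lens[["x"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["y"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["z"]], (4 + 5 - 3) / 2)

  # tip order permutation leaves the tree invariant
  perm <- c(3, 1, 4, 2)
  trp <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(tr, trp)[1], 0)
  expect_error(neighbor_joining(D3[1:2, 1:2]), "three taxa")
  Dbad <- D3
  Dbad[1, 2] <- 99
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("bootstrap supports are deterministic and sensible", {
  # two clearly separated clades
  cfg <- sim_config(n_snps = 150, seed = 51, missing_rate = 0,
                    n_ha_per_region = 1, n_lakes_per_ha = 3,
                    ecotype_lake_fraction = 0,
                    fst_levels = c(region = 0.4, ha = 0.01, lake = 0.01,
                                   ecotype = 0.01))
  sim <- simulate_metapopulation(cfg)
  bs <- bootstrap_support(sim$genotypes, sim$popmap, B = 50, seed = 3)
  # the region split bipartition should be near-unanimous
  expect_gt(max(bs$support), 95)
  bs2 <- bootstrap_support(sim$genotypes, sim$popmap, B = 50, seed = 3)
  expect_identical(bs$support, bs2$support)
  bs1 <- bootstrap_support(sim$genotypes, sim$popmap, B = 1, seed = 9)
  expect_true(all(bs1$support %in% c(0, 100)))
})

test_that("AMOVA partitions variance correctly", {
  sim <- small_sim(n_snps = 100, seed = 7)
  pm <- sim$popmap
  strata <- data.frame(group = sub("\\..*", "", pm$hydrometric_area),
                       ha = pm$hydrometric_area, population = pm$population)
  res <- amova(sim$genotypes, strata)
  expect_equal(sum(res$percent), 100, tolerance = 1e-6)

  # all individuals identical -> all components 0
  gi <- matrix(1L, 12, 5)
  Gi <- make_G(gi)
  sti <- data.frame(group = rep(c("g1", "g2"), each = 6),
                    ha = rep(c("h1", "h1", "h2", "h3", "h4", "h4"), each = 2),
                    population = rep(paste0("p", 1:6), each = 2))
  resi <- amova(Gi, sti)
  expect_equal(resi$sigma2, rep(0, 4), tolerance = 1e-10)

  # two-level agreement with the independent oracle to 1e-8
  g <- withr::with_seed(12, matrix(rbinom(40 * 60, 2, runif(60, .2, .8)),
                                   40, 60))
  # make population means differ
  g[1:10, 1:20] <- pmin(g[1:10, 1:20] + 1L, 2L)
  G2 <- make_G(g)
  pop <- rep(paste0("p", 1:4), each = 10)
  st2 <- data.frame(group = "all", ha = "one", population = pop)
  res2 <- amova(G2, st2)
  oracle <- two_level_amova_oracle(apply(g, 2, as.numeric), pop)
  expect_equal(res2$sigma2[res2$level == "within_pop"],
               unname(oracle["within"]), tolerance = 1e-8)
  expect_equal(res2$sigma2[res2$level == "among_pop_within_ha"],
               unname(oracle["among"]), tolerance = 1e-8)

  # permuted population labels -> among-population component near zero
  withr::with_seed(33, {
    gperm <- matrix(rbinom(60 * 50, 2, 0.5), 60, 50)
    Gp <- make_G(gperm)
    stp <- data.frame(group = "all", ha = "one",
                      population = sample(rep(paste0("p", 1:6), each = 10)))
    resp <- amova(Gp, stp)
    expect_lt(abs(resp$percent[resp$level == "among_pop_within_ha"]), 5)
    expect_gt(resp$percent[resp$level == "within_pop"], 95)
  })

  # permutation p-values: structured data give small p for the pop level
  resp2 <- amova(G2, st2, n_perm = 49, seed = 4)
  expect_lt(resp2$p_value[3], 0.05)
  expect_error(amova(Gi, data.frame(group = rep(c("g1", "g2"), 6),
                                    ha = rep(c("h1", "h2"), each = 6),
                                    population = rep(c("p1", "p2"), each = 6))),
               "not nested")
})

test_that("F_ST-threshold clustering finds planted groups", {
  pops <- paste0("p", 1:9)
  fst <- matrix(0.4, 9, 9, dimnames = list(pops, pops))
  diag(fst) <- 0
  block <- function(i) fst[i, i] <<- 0.02
  block(1:3); block(4:6); block(7:9)
  diag(fst) <- 0
  cl <- cluster_populations(fst, 0.1)
  expect_equal(length(unique(cl)), 3)
  expect_equal(length(unique(cl[1:3])), 1)
  # extremes
  expect_equal(length(unique(cluster_populations(fst, 1e-9))), 9)
  expect_equal(length(unique(cluster_populations(fst, 1))), 1)
})
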