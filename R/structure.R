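# Population-structure analyses: genotype PCA, population distance matrices,
# neighbor-joining with locus bootstrap, hierarchical AMOVA, and an
# F_ST-threshold single-linkage clustering used as an admixture surrogate.

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are replaced with the SNP's mean across all individuals
#' (mean allele-frequency imputation), columns are centered, and the
#' eigendecomposition is taken of the individual covariance. Axis signs are
#' fixed by making the largest-magnitude SNP loading on each axis positive.
#'
#' @param G a [genotype_matrix()].
#' @return list with `scores` (individuals x axes), `loadings` (SNPs x axes),
#'   `eigenvalues` (non-increasing) and `percent_var`.
#' @export
snp_pca <- function(G) {
  if (n_ind(G) < 2) stop("need at least two individuals")
  g <- G$geno
  mu <- colMeans(g, na.rm = TRUE)
  if (any(is.nan(mu))) stop("SNP with all genotypes missing; filter first")
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  x <- sweep(g, 2, colMeans(g))
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-9)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k),
                 function(a) sign(v[which.max(abs(v[, a])), a]), numeric(1))
  u <- sweep(u, 2, flip, `*`)
  v <- sweep(v, 2, flip, `*`)
  eig <- d^2 / (nrow(x) - 1)
  scores <- sweep(u, 2, d, `*`)
  dimnames(scores) <- list(rownames(g), paste0("EV", seq_len(k)))
  dimnames(v) <- list(colnames(g), paste0("EV", seq_len(k)))
  list(scores = scores, loadings = v, eigenvalues = eig,
       percent_var = 100 * eig / sum(eig))
}

#' Between-population genetic distance
#'
#' Computed from population allele frequencies on complete-case SNPs only
#' (SNPs with any missing genotype are dropped first, mirroring the
#' phylogeny-input convention). `prevosti` is the mean absolute
#' allele-frequency difference over loci (for biallelic loci
#' `|p_i - p_j|`); `nei` is Nei's standard distance.
#'
#' @inheritParams per_pop_stats
#' @param metric `"prevosti"` (default) or `"nei"`.
#' @return symmetric populations x populations distance matrix.
#' @export
genetic_distance <- function(G, popmap, metric = c("prevosti", "nei")) {
  metric <- match.arg(metric)
  Gc <- complete_cases(G)$genotypes
  if (n_sites(Gc) == 0) stop("no complete-case SNPs")
  p <- pop_allele_freq(Gc, popmap)$freq
  K <- nrow(p)
  D <- matrix(0, K, K, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      if (metric == "prevosti") {
        d <- mean(abs(p[i, ] - p[j, ]))
      } else {
        jxy <- mean(p[i, ] * p[j, ] + (1 - p[i, ]) * (1 - p[j, ]))
        jx <- mean(p[i, ]^2 + (1 - p[i, ])^2)
        jy <- mean(p[j, ]^2 + (1 - p[j, ])^2)
        d <- -log(jxy / sqrt(jx * jy))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Unrooted neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via `ape::nj`) with the standard negative-branch
#' fix: each negative branch is clamped to zero and its deficit moved to the
#' adjacent branch below, preserving path lengths through the node.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an unrooted `ape::phylo` tree over the row names of `D`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least three taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tree <- ape::nj(as.dist(D))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    below <- which(tree$edge[, 1] == child)
    if (length(below)) {
      tree$edge.length[below] <- tree$edge.length[below] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Canonical bipartition keys for the internal edges of an unrooted tree:
# each internal edge splits the tips; the side not containing the first tip
# label (alphabetically) is sorted and pasted.
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  n_tip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > n_tip)
  keys <- character(0)
  edges <- integer(0)
  for (e in internal) {
    node <- tree$edge[e, 2]
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (anchor %in% clade) setdiff(tree$tip.label, clade) else clade
    if (length(side) < 2 || length(side) > n_tip - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    edges <- c(edges, e)
  }
  list(keys = keys, edges = edges)
}

#' Bootstrap support for a neighbor-joining population tree
#'
#' Resamples loci (SNP columns) with replacement `B` times, rebuilds the
#' distance matrix and tree, and reports the percentage of replicates in
#' which each internal bipartition of the full-data tree recurs. Supports are
#' attached as internal node labels.
#'
#' @inheritParams genetic_distance
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return list with `tree` (full-data tree, node labels = support %) and
#'   `support` (named vector of bipartition support percentages).
#' @export
bootstrap_support <- function(G, popmap, metric = "prevosti", B = 1000,
                              seed = 1) {
  Gc <- complete_cases(G)$genotypes
  full <- neighbor_joining(genetic_distance(Gc, popmap, metric))
  bp <- bipartitions(full)
  counts <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n_sites(Gc), replace = TRUE)
      # re-index resampled columns so site positions stay strictly increasing
      sites_b <- Gc$sites[idx, , drop = FALSE]
      sites_b$chrom <- "boot"
      sites_b$pos <- seq_along(idx)
      Gb <- genotype_matrix(Gc$geno[, idx, drop = FALSE], sites_b)
      tb <- neighbor_joining(genetic_distance(Gb, popmap, metric))
      kb <- bipartitions(tb)$keys
      hit <- bp$keys %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / B
  n_tip <- length(full$tip.label)
  labels <- rep(NA_character_, full$Nnode)
  node_of_edge <- full$edge[bp$edges, 2] - n_tip
  labels[node_of_edge] <- format(round(support), trim = TRUE)
  full$node.label <- labels
  list(tree = full, support = support)
}

# Block-averaging projector for a factor: (J)_{ij} = 1/n_g if i,j share level.
block_projector <- function(f) {
  f <- as.factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  sweep(Z, 2, colSums(Z), `/`) %*% t(Z)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared-Euclidean genotype distances across nested strata
#' (group / Hydrometric Area / population / within-population). Sums of
#' squares are the classical nested quadratic forms; expected-mean-square
#' coefficients are computed exactly for unbalanced designs from traces of
#' the quadratic forms against the strata block structure, and the
#' method-of-moments system is solved for the variance components.
#' Missing dosages are mean-imputed first. Components may be negative
#' (estimator property); percentages are of the raw component total and sum
#' to 100. Optional permutation p-values shuffle labels at each level.
#'
#' @param G a [genotype_matrix()].
#' @param strata data.frame with one row per individual of `G` (same order as
#'   genotype rows) and columns `group`, `ha`, `population`; the strata must
#'   be nested (population within ha within group).
#' @param n_perm permutations per level for p-values (0 = skip).
#' @param seed permutation seed.
#' @return data.frame with one row per level: `sigma2`, `percent`, `df`,
#'   and `p_value` (NA when `n_perm = 0`).
#' @export
amova <- function(G, strata, n_perm = 0, seed = 1) {
  stopifnot(all(c("group", "ha", "population") %in% names(strata)),
            nrow(strata) == n_ind(G))
  # nestedness check
  if (any(rowSums(table(strata$population, strata$ha) > 0) > 1) ||
      any(rowSums(table(strata$ha, strata$group) > 0) > 1)) {
    stop("strata are not nested (population within ha within group)")
  }
  g <- G$geno
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]

  comp <- amova_components(g, strata$group, strata$ha, strata$population)
  out <- comp$table
  out$p_value <- NA_real_
  if (n_perm > 0) {
    obs <- out$sigma2
    hits <- numeric(3)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        # level 1: permute group assignment among HAs (relabel HA blocks)
        st1 <- strata
        ha_tab <- unique(strata[, c("ha", "group")])
        ha_tab$group <- sample(ha_tab$group)
        st1$group <- ha_tab$group[match(st1$ha, ha_tab$ha)]
        # level 2: permute HA assignment among populations within groups
        st2 <- strata
        pop_tab <- unique(strata[, c("population", "ha", "group")])
        for (gr in unique(pop_tab$group)) {
          i <- pop_tab$group == gr
          pop_tab$ha[i] <- sample(pop_tab$ha[i])
        }
        st2$ha <- pop_tab$ha[match(st2$population, pop_tab$population)]
        # level 3: permute individuals among populations within HAs
        st3 <- strata
        for (h in unique(strata$ha)) {
          i <- which(strata$ha == h)
          st3$population[i] <- strata$population[sample(i)]
        }
        p1 <- amova_components(g, st1$group, st1$ha, st1$population)$table
        p2 <- amova_components(g, st2$group, st2$ha, st2$population)$table
        p3 <- amova_components(g, st3$group, st3$ha, st3$population)$table
        hits[1] <- hits[1] + (p1$sigma2[1] >= obs[1])
        hits[2] <- hits[2] + (p2$sigma2[2] >= obs[2])
        hits[3] <- hits[3] + (p3$sigma2[3] >= obs[3])
      }
    })
    out$p_value[1:3] <- (hits + 1) / (n_perm + 1)
  }
  out
}

# Core AMOVA computation shared by amova() and its permutation loop.
amova_components <- function(g, group, ha, population) {
  N <- nrow(g)
  J_all <- matrix(1 / N, N, N)
  J_g <- block_projector(group)
  J_h <- block_projector(interaction(group, ha, drop = TRUE))
  J_p <- block_projector(interaction(group, ha, population, drop = TRUE))
  Q <- list(among_group = J_g - J_all,
            among_ha_within_group = J_h - J_g,
            among_pop_within_ha = J_p - J_h,
            within_pop = diag(N) - J_p)
  same_block <- function(f) (outer(f, f, `==`)) * 1
  K <- list(group = same_block(as.character(group)),
            ha = same_block(paste(group, ha, sep = "\r")),
            pop = same_block(paste(group, ha, population, sep = "\r")),
            e = diag(N))
  G2 <- tcrossprod(g)   # N x N gram matrix; SS_i = sum(Q_i * G2)
  ss <- vapply(Q, function(q) sum(q * G2), numeric(1))
  df <- c(length(unique(group)) - 1,
          nrow(unique(cbind(group, ha))) - length(unique(group)),
          nrow(unique(cbind(group, ha, population))) -
            nrow(unique(cbind(group, ha))),
          N - nrow(unique(cbind(group, ha, population))))
  # degenerate levels (df = 0, e.g. a single group) are dropped from the
  # method-of-moments system; their component is 0 by construction
  active <- df > 0
  coefs <- matrix(0, 4, 4, dimnames = list(names(Q), names(K)))
  for (i in 1:4) for (j in 1:4) coefs[i, j] <- sum(Q[[i]] * K[[j]])
  sigma2 <- numeric(4)
  sigma2[active] <- solve(coefs[active, active, drop = FALSE], ss[active])
  tab <- data.frame(level = names(Q), df = df, ss = ss,
                    sigma2 = sigma2,
                    percent = 100 * sigma2 / sum(sigma2),
                    row.names = NULL)
  list(table = tab)
}

#' Cluster populations by an F_ST threshold
#'
#' Single-linkage merging: populations joined whenever their pairwise F_ST is
#' strictly below `threshold`; connected components become clusters. A crude
#' surrogate for model-based admixture clustering.
#'
#' @param fst symmetric pairwise F_ST matrix.
#' @param threshold merge threshold.
#' @return named integer vector of cluster labels.
#' @export
cluster_populations <- function(fst, threshold) {
  fst <- as.matrix(fst)
  K <- nrow(fst)
  pops <- rownames(fst)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      if (!is.na(fst[i, j]) && fst[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))
  labels <- match(roots, unique(roots))
  stats::setNames(labels, pops)
}
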