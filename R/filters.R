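# SNP-retention cascade: presence -> MAF -> max Ho -> first SNP per locus ->
# HWE -> depth -> replicate-mismatch. Each filter returns the reduced matrix
# plus a one-row filter report; reports chain so the cascade telescopes.

new_filter_report <- function(stage, n_in, keep) {
  data.frame(stage = stage, snps_in = n_in,
             snps_removed = n_in - sum(keep), snps_out = sum(keep))
}

apply_site_filter <- function(G, keep, stage) {
  rep <- new_filter_report(stage, n_sites(G), keep)
  list(genotypes = subset_sites(G, keep), report = rep)
}

#' Combine per-stage filter reports into one cascade report
#' @param ... one-row filter reports (or a list of them).
#' @return data.frame, stages in order, with `snps_out = snps_in -
#'   snps_removed` at each stage and `snps_in` chaining from the previous
#'   stage's `snps_out`.
#' @export
bind_filter_reports <- function(...) {
  reps <- list(...)
  if (length(reps) == 1 && is.list(reps[[1]]) && !is.data.frame(reps[[1]])) {
    reps <- reps[[1]]
  }
  do.call(rbind, reps)
}

#' Presence (call-rate) filter
#'
#' Retains SNPs genotyped in at least `min_prop` of the individuals within
#' every population and at least `min_prop` of all individuals overall.
#'
#' @param G a [genotype_matrix()].
#' @param popmap population map.
#' @param min_prop minimum call proportion (default 0.66).
#' @return list(`genotypes`, `report`).
#' @export
filter_presence <- function(G, popmap, min_prop = 0.66) {
  pop <- pop_factor(G, popmap)
  called <- !is.na(G$geno)
  overall <- colMeans(called) >= min_prop
  per_pop <- vapply(levels(pop), function(p) {
    colMeans(called[pop == p, , drop = FALSE]) >= min_prop
  }, logical(n_sites(G)))
  if (is.null(dim(per_pop))) per_pop <- matrix(per_pop, nrow = 1)
  keep <- overall & apply(per_pop, 1, all)
  apply_site_filter(G, keep, "presence")
}

#' Minor-allele-frequency filter
#'
#' MAF is computed over all non-missing alleles pooled across individuals.
#' SNPs with MAF strictly below `min_maf` are removed.
#'
#' @inheritParams filter_presence
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return list(`genotypes`, `report`).
#' @export
filter_maf <- function(G, min_maf = 0.01) {
  n_alleles <- 2 * colSums(!is.na(G$geno))
  alt <- colSums(G$geno, na.rm = TRUE)
  p <- ifelse(n_alleles > 0, alt / n_alleles, 0)
  maf <- pmin(p, 1 - p)
  apply_site_filter(G, maf >= min_maf, "maf")
}

#' Maximum observed-heterozygosity filter
#'
#' Observed heterozygosity is the heterozygote proportion over all non-missing
#' individuals pooled. SNPs with Ho strictly above `max_ho` are removed
#' (a hard cap that flags paralogous RAD loci).
#'
#' @inheritParams filter_presence
#' @param max_ho maximum observed heterozygosity (default 0.5).
#' @return list(`genotypes`, `report`).
#' @export
filter_max_het <- function(G, max_ho = 0.5) {
  n <- colSums(!is.na(G$geno))
  ho <- ifelse(n > 0, colSums(G$geno == 1, na.rm = TRUE) / n, 0)
  apply_site_filter(G, ho <= max_ho, "max_het")
}

#' Keep the first SNP per RAD locus
#'
#' Per locus id, only the SNP at the lowest position is retained.
#'
#' @inheritParams filter_presence
#' @return list(`genotypes`, `report`).
#' @export
first_snp_per_locus <- function(G) {
  ord <- order(G$sites$locus, G$sites$chrom, G$sites$pos)
  first <- ord[!duplicated(G$sites$locus[ord])]
  keep <- seq_len(n_sites(G)) %in% first
  apply_site_filter(G, keep, "first_snp_per_locus")
}

#' Exact Hardy-Weinberg test (biallelic, single sample)
#'
#' Exact conditional test on heterozygote counts given the minor-allele count
#' (Wigginton et al. style): the p-value sums the probabilities of all
#' heterozygote counts no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  het_values <- seq(rare %% 2, rare, by = 2)
  # unnormalised probabilities via log factorials, conditioning on rare count
  logp <- vapply(het_values, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, het_values)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Per-population Hardy-Weinberg filter
#'
#' Runs the exact HWE test per SNP per population (on non-missing genotypes)
#' and removes a SNP when it is rejected at `alpha` in more than
#' `max_reject_prop` of the populations in which it was testable.
#'
#' @inheritParams filter_presence
#' @param alpha per-test significance level (default 0.001).
#' @param max_reject_prop tolerated fraction of rejecting populations
#'   (default 0.5; removal requires strictly more).
#' @return list(`genotypes`, `report`).
#' @export
filter_hwe_per_pop <- function(G, popmap, alpha = 0.001,
                               max_reject_prop = 0.5) {
  pop <- pop_factor(G, popmap)
  S <- n_sites(G)
  reject <- matrix(NA, nlevels(pop), S)
  for (i in seq_len(nlevels(pop))) {
    sub <- G$geno[pop == levels(pop)[i], , drop = FALSE]
    n0 <- colSums(sub == 0, na.rm = TRUE)
    n1 <- colSums(sub == 1, na.rm = TRUE)
    n2 <- colSums(sub == 2, na.rm = TRUE)
    testable <- (n0 + n1 + n2) > 0
    pv <- rep(NA_real_, S)
    pv[testable] <- vapply(which(testable), function(j) {
      hwe_exact_test(n0[j], n1[j], n2[j])
    }, numeric(1))
    reject[i, ] <- pv < alpha
  }
  n_tested <- colSums(!is.na(reject))
  n_reject <- colSums(reject, na.rm = TRUE)
  keep <- n_tested == 0 | (n_reject / pmax(n_tested, 1)) <= max_reject_prop
  apply_site_filter(G, keep, "hwe")
}

#' Mean read-depth filter
#'
#' Retains SNPs whose site mean depth lies within `[min_dp, max_dp]`
#' (inclusive bounds: only strict violations are removed). When no depth
#' information is present the stage is skipped with a warning.
#'
#' @inheritParams filter_presence
#' @param min_dp,max_dp inclusive mean-depth bounds (defaults 10 and 30,
#'   the latter being ~2x a typical 15x average depth).
#' @return list(`genotypes`, `report`).
#' @export
filter_depth <- function(G, min_dp = 10, max_dp = 30) {
  d <- G$sites$depth
  if (all(is.na(d))) {
    warning("no depth information; depth filter skipped")
    return(apply_site_filter(G, rep(TRUE, n_sites(G)), "depth"))
  }
  keep <- !is.na(d) & d >= min_dp & d <= max_dp
  apply_site_filter(G, keep, "depth")
}

#' Estimate genotyping error from technical replicate pairs
#'
#' For each replicate pair, discordance is the number of discordant called
#' sites over the number of sites called in both members; the overall rate is
#' the mean over pairs. Per-SNP counts of discordant pairs are tabulated for
#' [drop_mismatch_snps()]. Pairs with zero co-called sites are excluded with
#' a warning.
#'
#' @inheritParams filter_presence
#' @return list with `pair_rates` (data.frame: source, replicate, n_co_called,
#'   n_discordant, rate), `overall_rate`, and `snp_mismatch_pairs` (integer
#'   per-SNP count of discordant pairs).
#' @export
estimate_replicate_error <- function(G, popmap) {
  popmap <- align_popmap(popmap, G)
  rg <- popmap$replicate_group
  groups <- split(popmap$individual, rg)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) stop("no replicate pairs in popmap")
  S <- n_sites(G)
  mismatch <- integer(S)
  rows <- list()
  for (g in groups) {
    # pair = first two members of the replicate group
    a <- G$geno[g[1], ]
    b <- G$geno[g[2], ]
    co <- !is.na(a) & !is.na(b)
    if (!any(co)) {
      warning("replicate pair (", g[1], ", ", g[2],
              ") has no co-called sites; excluded")
      next
    }
    dis <- co & a != b
    mismatch <- mismatch + dis
    rows[[length(rows) + 1]] <-
      data.frame(source = g[1], replicate = g[2], n_co_called = sum(co),
                 n_discordant = sum(dis), rate = sum(dis) / sum(co))
  }
  if (!length(rows)) stop("all replicate pairs lacked co-called sites")
  pair_rates <- do.call(rbind, rows)
  list(pair_rates = pair_rates,
       overall_rate = mean(pair_rates$rate),
       snp_mismatch_pairs = mismatch)
}

#' Remove SNPs discordant in more than `max_pairs` replicate pairs
#'
#' @inheritParams filter_presence
#' @param error_report result of [estimate_replicate_error()] computed on the
#'   same matrix.
#' @param max_pairs tolerated number of discordant pairs (default 1; removal
#'   requires strictly more).
#' @return list(`genotypes`, `report`).
#' @export
drop_mismatch_snps <- function(G, error_report, max_pairs = 1) {
  counts <- error_report$snp_mismatch_pairs
  if (length(counts) != n_sites(G)) {
    stop("error report does not match this genotype matrix")
  }
  apply_site_filter(G, counts <= max_pairs, "replicate_mismatch")
}

#' Drop technical replicate individuals, keeping the higher-coverage member
#'
#' "Higher coverage" is the larger count of non-missing genotypes (ties keep
#' the source individual, i.e. the first member of the group).
#'
#' @inheritParams filter_presence
#' @return list(`genotypes`, `popmap`) with one member kept per replicate
#'   group (its `replicate_group` cleared).
#' @export
drop_replicates <- function(G, popmap) {
  popmap <- align_popmap(popmap, G)
  rg <- popmap$replicate_group
  drop <- character(0)
  for (g in split(popmap$individual, rg)) {
    if (length(g) < 2) next
    cov <- rowSums(!is.na(G$geno[g, , drop = FALSE]))
    keep <- g[which.max(cov)]
    drop <- c(drop, setdiff(g, keep))
  }
  keep_rows <- !(popmap$individual %in% drop)
  G2 <- subset_inds(G, popmap$individual[keep_rows])
  pm2 <- popmap[keep_rows, , drop = FALSE]
  pm2$replicate_group <- NA_character_
  rownames(pm2) <- NULL
  list(genotypes = G2, popmap = pm2)
}

#' Remove putatively non-neutral SNPs
#'
#' Removes the union of an explicit candidate set (e.g. the RDA candidates)
#' and the SNPs in the top `top_fst_prop` quantile of per-locus global F_ST.
#' The top set is the first `ceiling(top_fst_prop * S)` SNPs after ranking by
#' F_ST descending, ties broken by (chrom, pos).
#'
#' @inheritParams filter_presence
#' @param candidate_ids character vector of SNP ids (`chrom:pos`) to remove.
#' @param fst per-SNP global F_ST (from [global_per_locus_fst()]); computed
#'   from `G` and `popmap` when `NULL`.
#' @param top_fst_prop proportion of top-F_ST SNPs to remove (default 0.05).
#' @return list(`genotypes`, `report`).
#' @export
remove_nonneutral <- function(G, popmap, candidate_ids = character(0),
                              fst = NULL, top_fst_prop = 0.05) {
  if (is.null(fst)) fst <- global_per_locus_fst(G, popmap)
  S <- n_sites(G)
  k <- ceiling(top_fst_prop * S)
  ord <- order(-fst, G$sites$chrom, G$sites$pos)
  top <- ord[seq_len(min(k, S))]
  ids <- site_ids(G$sites)
  remove <- ids %in% candidate_ids | seq_len(S) %in% top
  apply_site_filter(G, !remove, "nonneutral")
}

#' Keep only SNPs with no missing genotypes
#'
#' @inheritParams filter_presence
#' @return list(`genotypes`, `report`).
#' @export
complete_cases <- function(G) {
  keep <- colSums(is.na(G$geno)) == 0
  apply_site_filter(G, keep, "complete_cases")
}
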