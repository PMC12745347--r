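#' Construct a genotype matrix
#'
#' The central data container of the package: a biallelic SNP genotype matrix
#' coded as alternate-allele dosage (0, 1, 2) with `NA` for missing calls,
#' together with per-site metadata and, optionally, a per-genotype read-depth
#' matrix.
#'
#' @param geno integer matrix, individuals in rows (rownames are individual
#'   ids) and SNPs in columns. Entries must be 0, 1, 2 or `NA`.
#' @param sites data.frame with one row per SNP and columns `chrom`, `pos`
#'   (1-based), `locus`, `ref`, `alt`, `depth` (mean read depth, may be `NA`).
#' @param dp optional integer matrix of per-genotype read depths, same
#'   dimensions as `geno`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, dp = NULL) {
  stopifnot(is.matrix(geno), is.data.frame(sites))
  if (ncol(geno) != nrow(sites)) {
    stop("`geno` has ", ncol(geno), " columns but `sites` has ", nrow(sites),
         " rows")
  }
  required <- c("chrom", "pos", "locus", "ref", "alt", "depth")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("`sites` is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  }
  # positions strictly increasing within each chromosome
  if (nrow(sites) > 1) {
    by_chrom <- split(sites$pos, sites$chrom)
    if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1)))) {
      stop("site positions must be strictly increasing within each chromosome")
    }
  }
  sites$chrom <- as.character(sites$chrom)
  sites$locus <- as.character(sites$locus)
  rownames(sites) <- NULL
  colnames(geno) <- site_ids(sites)
  if (!is.null(dp)) {
    stopifnot(is.matrix(dp), all(dim(dp) == dim(geno)))
    dimnames(dp) <- dimnames(geno)
  }
  structure(list(geno = geno, sites = sites, dp = dp),
            class = "genotype_matrix")
}

#' Canonical SNP identifiers (`chrom:pos`) for a site table
#' @param sites the `sites` data.frame of a [genotype_matrix()].
#' @return character vector of ids.
#' @export
site_ids <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " SNPs\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%; chromosomes: %d; depth: %s\n",
              100 * miss, length(unique(x$sites$chrom)),
              if (is.null(x$dp)) "absent" else "per-genotype"))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype matrix
#' @param G a `genotype_matrix`
#' @return integer count.
#' @export
n_ind <- function(G) nrow(G$geno)

#' @rdname n_ind
#' @export
n_sites <- function(G) ncol(G$geno)

#' Subset a genotype matrix by SNPs or individuals
#'
#' @param G a `genotype_matrix`
#' @param keep logical or integer index over SNP columns (`subset_sites`) or
#'   individual rows (`subset_inds`).
#' @return a new `genotype_matrix`.
#' @export
subset_sites <- function(G, keep) {
  genotype_matrix(G$geno[, keep, drop = FALSE], G$sites[keep, , drop = FALSE],
                  dp = if (is.null(G$dp)) NULL else G$dp[, keep, drop = FALSE])
}

#' @rdname subset_sites
#' @export
subset_inds <- function(G, keep) {
  genotype_matrix(G$geno[keep, , drop = FALSE], G$sites,
                  dp = if (is.null(G$dp)) NULL else G$dp[keep, , drop = FALSE])
}

#' Validate a population map against a genotype matrix
#'
#' A population map is a data.frame with one row per individual and columns
#' `individual`, `population`, `lake`, `hydrometric_area`, `ecotype`,
#' `replicate_group` (NA when the individual is not a technical replicate).
#' Optional columns `latitude` and `longitude` carry the lake coordinates.
#' Individuals present in the map but absent from the matrix are dropped with
#' a warning; individuals genotyped but unmapped are an error.
#'
#' @param popmap data.frame as described.
#' @param G a `genotype_matrix`.
#' @return the population map restricted (and reordered) to the individuals of
#'   `G`.
#' @export
align_popmap <- function(popmap, G) {
  required <- c("individual", "population", "lake", "hydrometric_area",
                "ecotype")
  missing_cols <- setdiff(required, names(popmap))
  if (length(missing_cols)) {
    stop("popmap is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"replicate_group" %in% names(popmap)) popmap$replicate_group <- NA
  inds <- rownames(G$geno)
  extra <- setdiff(popmap$individual, inds)
  if (length(extra)) {
    warning(length(extra), " individual(s) in popmap absent from genotypes; ",
            "dropped: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  unmapped <- setdiff(inds, popmap$individual)
  if (length(unmapped)) {
    stop("genotyped individual(s) missing from popmap: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  out <- popmap[match(inds, popmap$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Population factor in the row order of G, validated.
pop_factor <- function(G, popmap) {
  popmap <- align_popmap(popmap, G)
  factor(popmap$population, levels = unique(popmap$population))
}

#' Per-population alternate-allele frequencies and call counts
#'
#' @param G a `genotype_matrix`.
#' @param popmap population map (see [align_popmap()]).
#' @return list with `freq` (populations x SNPs matrix of alternate-allele
#'   frequencies over non-missing calls; `NaN` where a population has no
#'   calls), `n` (populations x SNPs matrix of non-missing genotype counts)
#'   and `het` (populations x SNPs observed-heterozygote proportions).
#' @export
pop_allele_freq <- function(G, popmap) {
  pop <- pop_factor(G, popmap)
  g <- G$geno
  pops <- levels(pop)
  idx <- lapply(pops, function(p) which(pop == p))
  n    <- matrix(0, length(pops), ncol(g), dimnames = list(pops, colnames(g)))
  freq <- n
  het  <- n
  for (i in seq_along(pops)) {
    sub <- g[idx[[i]], , drop = FALSE]
    ni  <- colSums(!is.na(sub))
    n[i, ]    <- ni
    freq[i, ] <- colSums(sub, na.rm = TRUE) / (2 * ni)
    het[i, ]  <- colSums(sub == 1, na.rm = TRUE) / ni
  }
  list(freq = freq, n = n, het = het)
}

# Deterministic seed substreams: one global seed, deterministic offsets per
# named stage. Keeps every derived seed inside 32-bit integer range.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}
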