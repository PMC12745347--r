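#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x with diploid GT (DP per genotype optional). Multi-allelic
#' and non-SNP records are skipped with a message reporting the count. Missing
#' genotypes (`./.`) become `NA`. The VCF ID column is taken as the RAD locus
#' id (several SNPs may share one locus).
#'
#' @param path path to a (plain or gzipped) VCF.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(genotype_matrix(
      matrix(integer(0), nrow = max(0L, ncol(v@gt) - 1L), ncol = 0,
             dimnames = list(setdiff(colnames(v@gt), "FORMAT"), NULL)),
      data.frame(chrom = character(0), pos = integer(0), locus = character(0),
                 ref = character(0), alt = character(0), depth = numeric(0))))
  }
  alt <- ifelse(is.na(fix$ALT), "", fix$ALT)
  snp <- !grepl(",", alt) & nchar(fix$REF) == 1 & nchar(alt) == 1
  if (any(!snp)) {
    message(sum(!snp), " multi-allelic or non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", ifelse(is.na(gt), "./.", gt))
  alleles <- strsplit(as.vector(gt_clean), "/", fixed = TRUE)
  if (any(lengths(alleles) != 2)) stop("non-diploid genotype encountered")
  dosage <- vapply(alleles, function(a) {
    if (any(a == ".")) NA_integer_ else sum(a != "0")
  }, integer(1))
  geno <- t(matrix(dosage, nrow = nrow(gt_clean), ncol = ncol(gt_clean),
                   dimnames = dimnames(gt_clean)))
  dp <- NULL
  fmt <- v@gt[snp, "FORMAT"]
  if (length(fmt) && any(grepl("DP", fmt))) {
    dpv <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                             as.numeric = TRUE))
    dp <- t(dpv[snp, , drop = FALSE])
    storage.mode(dp) <- "integer"
  }
  id <- fix$ID[snp]
  sites <- data.frame(chrom = fix$CHROM[snp],
                      pos = as.integer(fix$POS[snp]),
                      locus = ifelse(is.na(id) | id == ".",
                                     paste0("L", seq_len(sum(snp))), id),
                      ref = fix$REF[snp], alt = alt[snp],
                      depth = if (is.null(dp)) NA_real_
                              else round(colMeans(dp, na.rm = TRUE), 2))
  genotype_matrix(geno, sites, dp = dp)
}

#' Write a genotype matrix as VCF
#'
#' Deterministic plain-text VCF v4.2 writer: fixed row (site) and column
#' (individual) order, GT (and DP when present) per genotype, locus id in the
#' ID column. `read_vcf(write_vcf(G))` reproduces `G` exactly when `G` carries
#' integer per-genotype depths.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=charrcu",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">'),
             con)
  inds <- rownames(G$geno)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[G$geno + 1L],
                   nrow = nrow(G$geno), ncol = ncol(G$geno))
  gt_str[is.na(G$geno)] <- "./."
  has_dp <- !is.null(G$dp)
  if (has_dp) {
    dp_str <- ifelse(is.na(G$dp), ".", as.character(G$dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"),
                     nrow = nrow(gt_str))
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  s <- G$sites
  lines <- vapply(seq_len(ncol(G$geno)), function(j) {
    paste(c(s$chrom[j], s$pos[j], s$locus[j], s$ref[j], s$alt[j], ".", "PASS",
            ".", fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a tab-delimited population map
#'
#' Requires columns `individual`, `population`, `lake`, `hydrometric_area`,
#' `ecotype`; `replicate_group`, `latitude`, `longitude` are optional.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual", "population", "lake", "hydrometric_area",
                "ecotype")
  missing_cols <- setdiff(required, names(pm))
  if (length(missing_cols)) {
    stop("popmap is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"replicate_group" %in% names(pm)) pm$replicate_group <- NA_character_
  pm
}

#' Write a population map
#' @param popmap data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-lake environment table
#'
#' Tab-delimited, one row per lake x scenario, with columns `lake`,
#' `scenario`, the 19 bioclim variables and the bathymetric/geographic
#' variables. Checks that bathymetric values are identical across scenarios
#' for each lake, that depths and areas are non-negative, and (optionally)
#' that every lake has rows for a set of required scenarios.
#'
#' @param path path to the TSV.
#' @param require_scenarios character vector of scenarios every lake must
#'   cover (hard error naming the lake otherwise).
#' @return data.frame.
#' @export
read_env <- function(path, require_scenarios = NULL) {
  env <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("lake", "scenario") %in% names(env))) {
    stop("environment table needs `lake` and `scenario` columns")
  }
  validate_env(env, require_scenarios)
  env
}

validate_env <- function(env, require_scenarios = NULL) {
  for (v in c("max_depth", "mean_depth", "surface_area")) {
    if (v %in% names(env) && any(env[[v]] < 0, na.rm = TRUE)) {
      stop("negative values in `", v, "`")
    }
  }
  bathy <- intersect(bathymetric_vars(), names(env))
  for (lk in unique(env$lake)) {
    rows <- env[env$lake == lk, bathy, drop = FALSE]
    if (nrow(rows) > 1 &&
        any(vapply(rows, function(x) length(unique(x)) > 1, logical(1)))) {
      stop("bathymetric values differ across scenarios for lake ", lk)
    }
    if (!is.null(require_scenarios)) {
      have <- env$scenario[env$lake == lk]
      miss <- setdiff(require_scenarios, have)
      if (length(miss)) {
        stop("lake ", lk, " is missing environment rows for scenario(s): ",
             paste(miss, collapse = ", "))
      }
    }
  }
  invisible(env)
}

#' Write an environment table
#' @param env data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_env <- function(env, path) {
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of feature intervals
#'
#' Standard BED: 0-based half-open `[start, end)` with at least
#' chrom/start/end and an optional name column. A VCF 1-based position `p`
#' overlaps `[s, e)` iff `s < p <= e`.
#'
#' @param path path to the BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]),
                    name = if (ncol(bed) >= 4) as.character(bed[[4]])
                           else paste0("feature", seq_len(nrow(bed))))
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end at line ",
         which(out$start >= out$end)[1])
  }
  out
}

#' Write a phylogenetic tree in newick format
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
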