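# Genotype-environment association via redundancy analysis (RDA):
# collinearity pruning of predictors, modal-genotype imputation, an
# own least-squares + SVD RDA (optionally partial, conditioning on structure
# covariates), per-axis permutation tests, loading-based candidate SNP
# detection, and interval annotation of candidates.

#' Greedy collinearity pruning of environment variables
#'
#' Scans variables in priority order; a variable is dropped when its absolute
#' Pearson correlation with any already-retained variable is `>= rho_max`.
#' Constant variables (undefined correlation) are dropped with a warning.
#'
#' @param env data.frame of candidate predictor columns (numeric), or a full
#'   environment table (non-numeric columns such as `lake`/`scenario` are
#'   ignored).
#' @param rho_max correlation threshold (default 0.7).
#' @param priority character vector giving the scan order; defaults to column
#'   order.
#' @return list with `retained` (character vector) and `dropped`
#'   (data.frame: variable, because_of).
#' @export
prune_collinear <- function(env, rho_max = 0.7, priority = NULL) {
  num <- env[vapply(env, is.numeric, logical(1))]
  if (is.null(priority)) priority <- names(num)
  stopifnot(all(priority %in% names(num)), length(priority) >= 2)
  retained <- character(0)
  dropped <- data.frame(variable = character(0), because_of = character(0))
  for (v in priority) {
    x <- num[[v]]
    if (stats::sd(x) == 0) {
      warning("constant variable dropped: ", v)
      dropped <- rbind(dropped,
                       data.frame(variable = v, because_of = "<constant>"))
      next
    }
    conflict <- NULL
    for (r in retained) {
      if (abs(stats::cor(x, num[[r]])) >= rho_max) { conflict <- r; break }
    }
    if (is.null(conflict)) {
      retained <- c(retained, v)
    } else {
      dropped <- rbind(dropped,
                       data.frame(variable = v, because_of = conflict))
    }
  }
  list(retained = retained, dropped = dropped)
}

#' Impute missing genotypes with the modal genotype
#'
#' Per SNP, missing cells are set to the most common genotype code across all
#' individuals; ties are broken toward the lower dosage.
#'
#' @param G a [genotype_matrix()].
#' @return a [genotype_matrix()] without missing genotypes.
#' @export
impute_most_common <- function(G) {
  g <- G$geno
  for (j in which(colSums(is.na(g)) > 0)) {
    counts <- tabulate(g[, j] + 1L, nbins = 3L)
    g[is.na(g[, j]), j] <- which.max(counts) - 1L  # which.max takes first tie
  }
  genotype_matrix(g, G$sites, dp = G$dp)
}

#' Redundancy analysis of genotypes on environment predictors
#'
#' `X` is standardised to zero mean / unit variance and `Y` centered. With a
#' conditioning matrix `Z` (partial RDA), both `Y` and `X` are first replaced
#' by their residuals from least-squares projection on `(1, Z)`. The fitted
#' values `X (X'X)^-1 X' Y` are decomposed by SVD into constrained axes.
#' Rank-deficient predictor sets have surplus columns dropped with a warning.
#'
#' @param Y numeric matrix, rows = individuals (or populations), columns =
#'   SNP dosages (or frequencies). No missing values (see
#'   [impute_most_common()]).
#' @param X data.frame or matrix of predictors, rows aligned with `Y`.
#' @param Z optional conditioning covariates (e.g. admixture proportions).
#' @return an `rda_model`: `scores` (row scores per constrained axis),
#'   `loadings` (SNP loadings), `eigenvalues`, `total_inertia`,
#'   `constrained_prop`, `X` (standardised predictors), `Y_resid`, plus
#'   bookkeeping for [axis_significance()].
#' @export
rda_fit <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  storage.mode(X) <- "double"
  if (any(is.na(Y)) || any(is.na(X))) stop("Y and X must be complete")
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0)) {
    warning("constant predictor(s) dropped: ",
            paste(colnames(X)[sdx == 0], collapse = ", "))
    X <- X[, sdx > 0, drop = FALSE]
    sdx <- sdx[sdx > 0]
  }
  Xs <- scale(X)
  total <- sum(Yc^2) / (n - 1)
  conditioned <- 0
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    fitz <- stats::lm.fit(cbind(1, Z), Yc)
    Yr <- as.matrix(fitz$residuals)
    conditioned <- (sum(Yc^2) - sum(Yr^2)) / (n - 1)
    Yc <- Yr
    Xs <- as.matrix(stats::lm.fit(cbind(1, Z), Xs)$residuals)
  }
  qrx <- qr(Xs)
  if (qrx$rank < ncol(Xs)) {
    drop_cols <- colnames(Xs)[qrx$pivot[seq(qrx$rank + 1, ncol(Xs))]]
    warning("rank-deficient predictors; dropped: ",
            paste(drop_cols, collapse = ", "))
    Xs <- Xs[, setdiff(colnames(Xs), drop_cols), drop = FALSE]
    qrx <- qr(Xs)
  }
  Yhat <- qr.fitted(qrx, Yc)
  sv <- svd(Yhat)
  k <- sum(sv$d > max(sv$d, 1e-300) * 1e-8)
  k <- min(k, qrx$rank)
  d <- sv$d[seq_len(k)]
  eig <- d^2 / (n - 1)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, d, `*`)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(Y), paste0("RDA", seq_len(k)))
  dimnames(loadings) <- list(colnames(Y), paste0("RDA", seq_len(k)))
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 total_inertia = total, conditioned_inertia = conditioned,
                 constrained_inertia = sum(eig),
                 unconstrained_inertia = total - conditioned - sum(eig),
                 constrained_prop = sum(eig) / total,
                 X = Xs, Y_resid = Yc, n = n),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat("rda_model: ", x$n, " rows, ", ncol(x$loadings), " constrained axes\n",
      sep = "")
  cat(sprintf("  inertia: total %.3f | constrained %.3f (%.1f%%)\n",
              x$total_inertia, x$constrained_inertia,
              100 * x$constrained_prop))
  invisible(x)
}

#' Permutation significance of constrained RDA axes
#'
#' Permutes the rows of the (residualised) predictor matrix, refits, and
#' compares each axis eigenvalue against its permutation distribution
#' (marginal, axis-by-axis): `p_k = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param model an `rda_model` from [rda_fit()].
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @return numeric vector of per-axis p-values.
#' @export
axis_significance <- function(model, n_perm = 999, seed = 1) {
  obs <- model$eigenvalues
  k <- length(obs)
  exceed <- numeric(k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- model$X[sample.int(model$n), , drop = FALSE]
      Yhat <- qr.fitted(qr(Xp), model$Y_resid)
      d <- svd(Yhat, nu = 0, nv = 0)$d
      ev <- (d^2 / (model$n - 1))[seq_len(k)]
      ev[is.na(ev)] <- 0
      exceed <- exceed + (ev >= obs)
    }
  })
  stats::setNames((exceed + 1) / (n_perm + 1),
                  colnames(model$loadings))
}

#' Candidate SNP detection from RDA loadings
#'
#' Per significant axis, flags SNPs whose loading lies more than `sd_cut`
#' standard deviations from that axis's loading mean; candidates are combined
#' across axes (union by default, intersection optionally). Each candidate's
#' strongest predictor is the environment variable maximising the absolute
#' correlation with its dosage column.
#'
#' @param model an `rda_model`.
#' @param axes indices of significant axes (e.g. from [axis_significance()]).
#' @param sd_cut loading threshold in SD units (default 3).
#' @param combine `"union"` (default) or `"intersection"` across axes.
#' @param Y,X the matrices passed to [rda_fit()]; used to attribute the
#'   strongest predictor (optional: when omitted, attribution is skipped).
#' @return data.frame with `snp`, `axis` (axis of maximal |standardised
#'   loading|), `max_abs_loading_sd`, and `strongest_predictor` (NA when not
#'   attributed).
#' @export
candidate_snps <- function(model, axes = seq_along(model$eigenvalues),
                           sd_cut = 3, combine = c("union", "intersection"),
                           Y = NULL, X = NULL) {
  combine <- match.arg(combine)
  L <- model$loadings[, axes, drop = FALSE]
  zl <- scale(L)
  flagged <- abs(zl) > sd_cut
  sel <- if (combine == "union") rowSums(flagged) > 0
         else rowSums(flagged) == ncol(flagged)
  if (!any(sel)) {
    return(data.frame(snp = character(0), axis = character(0),
                      max_abs_loading_sd = numeric(0),
                      strongest_predictor = character(0)))
  }
  zsel <- abs(zl[sel, , drop = FALSE])
  best_axis <- colnames(zsel)[max.col(zsel, ties.method = "first")]
  out <- data.frame(snp = rownames(L)[sel], axis = best_axis,
                    max_abs_loading_sd = apply(zsel, 1, max),
                    strongest_predictor = NA_character_)
  if (!is.null(Y) && !is.null(X)) {
    X <- as.matrix(X)
    cors <- abs(stats::cor(as.matrix(Y)[, out$snp, drop = FALSE], X))
    out$strongest_predictor <- colnames(X)[max.col(cors, ties.method = "first")]
  }
  rownames(out) <- NULL
  out
}

#' Annotate candidate SNPs against gene / QTL intervals
#'
#' Reports SNP-feature pairs where the SNP position falls inside the feature
#' interval expanded by `window` bases on both sides (window edges
#' inclusive). Features use BED convention (0-based half-open), SNPs are
#' 1-based; a SNP at position `p` overlaps `[s, e)` iff `s < p <= e`.
#' `rel_pos` is 0 for SNPs inside the unexpanded feature, otherwise the
#' signed distance to the nearest feature edge.
#'
#' @param snps data.frame with `chrom` and `pos` columns (e.g. the `sites`
#'   rows of candidate SNPs).
#' @param features interval data.frame from [read_bed()].
#' @param window expansion in bp (1000 for genes, 1e5 for QTLs).
#' @return data.frame: `snp`, `feature`, `chrom`, `pos`, `rel_pos`.
#' @export
annotate_candidates <- function(snps, features, window = 1000) {
  if (!length(intersect(unique(snps$chrom), unique(features$chrom)))) {
    warning("no shared chromosome names between SNPs and features")
  }
  feat <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(start = pmax(1L, features$start + 1L - as.integer(window)),
                     end = features$end + as.integer(window)))
  snp_r <- GenomicRanges::GRanges(snps$chrom,
                                  IRanges::IRanges(snps$pos, snps$pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_r, feat))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    return(data.frame(snp = character(0), feature = character(0),
                      chrom = character(0), pos = integer(0),
                      rel_pos = integer(0)))
  }
  pos <- snps$pos[qi]
  s1 <- features$start[si] + 1L  # 1-based first covered position
  e1 <- features$end[si]
  rel <- ifelse(pos < s1, pos - s1, ifelse(pos > e1, pos - e1, 0L))
  data.frame(snp = paste(snps$chrom[qi], pos, sep = ":"),
             feature = features$name[si],
             chrom = snps$chrom[qi], pos = pos, rel_pos = as.integer(rel),
             row.names = NULL)
}

#' Population-level allele-frequency RDA response matrix
#'
#' Convenience builder for the population-frequency analysis mode: rows are
#' populations, columns SNP alternate-allele frequencies over non-missing
#' calls (populations without calls at a SNP get the across-population mean).
#'
#' @inheritParams per_pop_stats
#' @return numeric matrix populations x SNPs.
#' @export
pop_freq_matrix <- function(G, popmap) {
  p <- pop_allele_freq(G, popmap)$freq
  for (j in which(colSums(is.nan(p)) > 0)) {
    p[is.nan(p[, j]), j] <- mean(p[, j], na.rm = TRUE)
  }
  p
}
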