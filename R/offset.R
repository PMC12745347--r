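# Gradient-forest-style turnover model and genetic offset. A from-scratch
# regression-tree ensemble: per SNP, trees are fitted on bootstrap samples of
# lakes with random predictor subsetting per split; every split donates its
# impurity reduction at its threshold location to that predictor's importance
# profile, weighted by the SNP's out-of-bag R^2. Accumulated profiles are
# binned and integrated into monotone cumulative-importance functions used to
# transform climate space; genetic offset is the Euclidean distance between
# transformed current and future climates.

#' Drop SNPs with low allele-frequency variation across populations
#'
#' Retains SNPs showing more than `min_distinct - 1` distinct minor-allele
#' frequency values across populations (i.e. at least `min_distinct`),
#' distinctness evaluated after rounding to `digits` decimal places.
#'
#' @param freqs populations x SNPs matrix of alternate-allele frequencies
#'   (each SNP is folded to its globally minor allele internally).
#' @param min_distinct minimum number of distinct MAF values (default 6,
#'   i.e. SNPs with 5 or fewer are removed).
#' @param digits rounding precision before the distinctness count (default 6).
#' @return character vector of retained SNP ids (column names).
#' @export
low_variation_filter <- function(freqs, min_distinct = 6, digits = 6) {
  maf <- round(fold_to_minor(freqs), digits)
  n_distinct <- apply(maf, 2, function(x) length(unique(x[!is.na(x)])))
  colnames(freqs)[n_distinct >= min_distinct]
}

# Frequency of the globally minor allele: one allele choice per SNP (the
# allele rarer on average across populations), so each column stays a
# monotone transform of the input and can exceed 0.5 locally.
fold_to_minor <- function(freqs) {
  flip <- colMeans(freqs, na.rm = TRUE) > 0.5
  freqs[, flip] <- 1 - freqs[, flip, drop = FALSE]
  freqs
}

# Grow one regression tree on rows `boot` (bootstrap sample, with
# multiplicity); rows `oob` are routed alongside and receive leaf means.
# Splits are appended to `acc` (an environment collecting var/threshold/
# improvement); OOB predictions accumulate into acc$oob_sum / acc$oob_n.
grow_tree <- function(x, y, boot, oob, mtry, min_leaf, acc) {
  n <- length(boot)
  yb <- y[boot]
  if (n < 2 * min_leaf || stats::var(yb) == 0) {
    if (length(oob)) {
      acc$oob_sum[oob] <- acc$oob_sum[oob] + mean(yb)
      acc$oob_n[oob] <- acc$oob_n[oob] + 1
    }
    return(invisible())
  }
  ss_node <- sum((yb - mean(yb))^2)
  vars <- sample.int(ncol(x), mtry)
  best <- list(imp = 0)
  for (v in vars) {
    xv <- x[boot, v]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- yb[ord]
    cs <- cumsum(ys)
    tot <- cs[n]
    k <- seq_len(n - 1)
    # left child = first k sorted rows; valid where both children >= min_leaf
    # and the split value actually separates distinct x values
    valid <- k >= min_leaf & k <= n - min_leaf & xs[k] < xs[k + 1]
    if (!any(valid)) next
    ss_red <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
    ss_red[!valid] <- -Inf
    kbest <- which.max(ss_red)
    if (ss_red[kbest] > best$imp) {
      best <- list(imp = unname(ss_red[kbest]), var = v,
                   thr = unname((xs[kbest] + xs[kbest + 1]) / 2))
    }
  }
  if (best$imp <= 0) {
    if (length(oob)) {
      acc$oob_sum[oob] <- acc$oob_sum[oob] + mean(yb)
      acc$oob_n[oob] <- acc$oob_n[oob] + 1
    }
    return(invisible())
  }
  acc$splits[[length(acc$splits) + 1]] <-
    c(var = best$var, thr = best$thr, imp = best$imp)
  left_b <- boot[x[boot, best$var] <= best$thr]
  right_b <- boot[x[boot, best$var] > best$thr]
  left_o <- oob[x[oob, best$var] <= best$thr]
  right_o <- oob[x[oob, best$var] > best$thr]
  grow_tree(x, y, left_b, left_o, mtry, min_leaf, acc)
  grow_tree(x, y, right_b, right_o, mtry, min_leaf, acc)
  invisible()
}

#' Fit a turnover model of allele-frequency change along climate gradients
#'
#' For each SNP, `n_trees` regression trees are fitted on bootstrap samples
#' of the rows (lakes/populations), with responses the SNP's minor-allele
#' frequency and predictors the climate variables; `mtry = ceiling(v/3)`
#' predictors are considered per split and leaves hold at least `min_leaf`
#' rows. Each split's impurity reduction accrues to its predictor at the
#' split threshold, weighted by the SNP's forest out-of-bag R^2; SNPs with
#' non-positive out-of-bag R^2 contribute nothing. Importance mass is binned
#' on each predictor's observed range (`n_bins` equal bins) and integrated
#' into non-decreasing cumulative-importance functions anchored at 0 at the
#' range minimum.
#'
#' @param freqs populations x SNPs matrix of allele frequencies (rows aligned
#'   with `env`); each SNP is folded to its globally minor allele internally.
#' @param env data.frame aligned with `freqs` rows; the climate predictors
#'   used are `predictors` (default: its bioclim columns).
#' @param n_trees trees per SNP (default 250).
#' @param seed integer seed.
#' @param predictors character vector of predictor columns.
#' @param min_leaf minimum rows per leaf (default 2).
#' @param n_bins importance bins per predictor (default 50).
#' @return a `turnover_model`: per predictor `edges` (bin edges) and `cum`
#'   (cumulative importance at each edge), `importance` (per-predictor
#'   totals), `r2` (per-SNP out-of-bag R^2) and fitting metadata.
#' @export
fit_turnover <- function(freqs, env, n_trees = 250, seed = 1,
                         predictors = intersect(names(env), bioclim_names()),
                         min_leaf = 2, n_bins = 50) {
  freqs <- as.matrix(freqs)
  if (!length(predictors)) stop("no climate predictor columns found")
  x <- as.matrix(env[, predictors, drop = FALSE])
  stopifnot(nrow(x) == nrow(freqs))
  n <- nrow(x)
  if (n < 5) stop("need at least five lakes/populations")
  if (n < 2 * min_leaf) stop("fewer rows than the minimum node size allows")
  if (ncol(freqs) < 2) stop("need at least two SNPs after filtering")
  maf <- fold_to_minor(freqs)
  mtry <- max(1L, ceiling(ncol(x) / 3))
  v <- ncol(x)
  edges <- lapply(seq_len(v), function(j) {
    r <- range(x[, j])
    if (r[1] == r[2]) r[2] <- r[1] + 1e-9
    seq(r[1], r[2], length.out = n_bins + 1)
  })
  names(edges) <- predictors
  mass <- matrix(0, n_bins, v, dimnames = list(NULL, predictors))
  r2 <- stats::setNames(numeric(ncol(maf)), colnames(maf))

  with_seed(substream_seed(seed, "turnover"), {
    for (s in seq_len(ncol(maf))) {
      y <- maf[, s]
      acc <- new.env(parent = emptyenv())
      acc$splits <- list()
      acc$oob_sum <- numeric(n)
      acc$oob_n <- numeric(n)
      for (t in seq_len(n_trees)) {
        boot <- sample.int(n, replace = TRUE)
        oob <- setdiff(seq_len(n), boot)
        grow_tree(x, y, boot, oob, mtry, min_leaf, acc)
      }
      seen <- acc$oob_n > 0
      if (!any(seen) || stats::var(y[seen]) == 0) next
      pred <- acc$oob_sum[seen] / acc$oob_n[seen]
      r2_s <- 1 - sum((y[seen] - pred)^2) /
        sum((y[seen] - mean(y[seen]))^2)
      r2[s] <- r2_s
      if (r2_s <= 0 || !length(acc$splits)) next
      sp <- do.call(rbind, acc$splits)
      w <- r2_s * sp[, "imp"] / sum(sp[, "imp"])
      for (i in seq_len(nrow(sp))) {
        j <- sp[i, "var"]
        b <- findInterval(sp[i, "thr"], edges[[j]], rightmost.closed = TRUE)
        b <- min(max(b, 1L), n_bins)
        mass[b, j] <- mass[b, j] + w[i]
      }
    }
  })

  cum <- lapply(seq_len(v), function(j) c(0, cumsum(mass[, j])))
  names(cum) <- predictors
  structure(list(predictors = predictors, edges = edges, cum = cum,
                 importance = stats::setNames(colSums(mass), predictors),
                 r2 = r2, n_trees = n_trees, seed = seed,
                 snps = colnames(maf), n_rows = n),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("turnover_model: ", length(x$snps), " SNPs, ", x$n_rows, " rows, ",
      x$n_trees, " trees per SNP\n", sep = "")
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  top predictors:",
      paste(utils::head(names(imp), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Transform climate values through a turnover model
#'
#' Maps each predictor value through its cumulative-importance step function
#' (values beyond the fitted range clamp to the boundary values, so the
#' transform is 0 at/below the fitted minimum and the total importance
#' at/above the maximum).
#'
#' @param model a `turnover_model`.
#' @param env data.frame (or single row) with the model's predictor columns.
#' @return numeric matrix rows x predictors of transformed values.
#' @export
transform_env <- function(model, env) {
  env <- as.data.frame(env)
  out <- matrix(0, nrow(env), length(model$predictors),
                dimnames = list(NULL, model$predictors))
  for (j in model$predictors) {
    e <- model$edges[[j]]
    idx <- findInterval(env[[j]], e)
    idx <- pmin(pmax(idx, 1L), length(e))
    out[, j] <- model$cum[[j]][idx]
  }
  out
}

#' Per-lake genetic offset between current and future climate
#'
#' The Euclidean distance, per lake, between the turnover-transformed current
#' and future climate vectors. A single score per lake: ecotype populations
#' sharing a lake share its offset.
#'
#' @param model a `turnover_model`.
#' @param env_current,env_future environment tables covering the same lakes
#'   (`lake` column plus the model predictors).
#' @return data.frame `lake`, `offset`.
#' @export
genetic_offset <- function(model, env_current, env_future) {
  miss <- setdiff(env_current$lake, env_future$lake)
  if (length(miss)) {
    stop("lake(s) missing from the future scenario: ",
         paste(miss, collapse = ", "))
  }
  fut <- env_future[match(env_current$lake, env_future$lake), , drop = FALSE]
  tc <- transform_env(model, env_current)
  tf <- transform_env(model, fut)
  data.frame(lake = env_current$lake,
             offset = sqrt(rowSums((tc - tf)^2)),
             row.names = NULL)
}
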