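#' Configuration for the metapopulation simulator
#'
#' Defines the study conditions the simulator emulates: a two-region
#' (east/west) x Hydrometric-Area x lake hierarchy with strong per-lake drift,
#' sympatric ecotype pairs in a fraction of lakes, environment-associated
#' (adaptive) loci, technical replicate pairs with a known genotyping-error
#' rate, missingness and per-genotype read depth. The defaults define the
#' package's reference simulation: 2 regions x 4 Hydrometric Areas x 2 lakes
#' (16 lakes, 4 of them with an ecotype pair, i.e. 20 populations), 2000 SNPs
#' of which 20 track an environmental gradient, a 2.6% replicate discordance
#' rate and ~5% missing data at ~15x depth.
#'
#' @param n_regions number of top-level regions (drainage sides).
#' @param n_ha_per_region Hydrometric Areas per region.
#' @param n_lakes_per_ha lakes per Hydrometric Area.
#' @param ecotype_lake_fraction fraction of lakes holding a sympatric ecotype
#'   pair (two populations sharing one lake and its environment).
#' @param n_ind_per_pop individuals per unimodal population.
#' @param n_ecotype_ind individuals per ecotype population.
#' @param n_snps number of biallelic SNPs.
#' @param fst_levels named vector of Balding-Nichols drift intensities in
#'   (0,1) for levels `region`, `ha`, `lake`, `ecotype`.
#' @param n_adaptive number of environment-associated loci.
#' @param gea_effect logit-scale slope per unit of standardised environment
#'   for adaptive loci.
#' @param error_rate per-genotype replicate discordance probability.
#' @param n_replicate_pairs number of technical replicate pairs appended by
#'   [simulate_replicates()].
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean mean per-genotype read depth (Poisson).
#' @param seed integer seed driving all randomness; sub-streams are derived
#'   deterministically per stage.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_regions = 2, n_ha_per_region = 4, n_lakes_per_ha = 2,
                       ecotype_lake_fraction = 0.25, n_ind_per_pop = 10,
                       n_ecotype_ind = 5, n_snps = 2000,
                       fst_levels = c(region = 0.05, ha = 0.05, lake = 0.2,
                                      ecotype = 0.02),
                       n_adaptive = 20, gea_effect = 2, error_rate = 0.026,
                       n_replicate_pairs = 10, missing_rate = 0.05,
                       depth_mean = 15, seed = 1) {
  cfg <- list(n_regions = n_regions, n_ha_per_region = n_ha_per_region,
              n_lakes_per_ha = n_lakes_per_ha,
              ecotype_lake_fraction = ecotype_lake_fraction,
              n_ind_per_pop = n_ind_per_pop, n_ecotype_ind = n_ecotype_ind,
              n_snps = n_snps, fst_levels = fst_levels,
              n_adaptive = n_adaptive, gea_effect = gea_effect,
              error_rate = error_rate, n_replicate_pairs = n_replicate_pairs,
              missing_rate = missing_rate, depth_mean = depth_mean,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_regions < 1 || n_ha_per_region < 1 || n_lakes_per_ha < 1) {
      stop("degenerate configuration: need at least one region, HA and lake")
    }
    if (n_snps < 1) stop("degenerate configuration: n_snps must be >= 1")
    stopifnot(length(fst_levels) == 4,
              all(c("region", "ha", "lake", "ecotype") %in% names(fst_levels)))
    if (any(fst_levels <= 0) || any(fst_levels >= 1)) {
      stop("fst_levels must lie strictly in (0, 1)")
    }
    for (p in c(ecotype_lake_fraction, missing_rate, error_rate)) {
      if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
    }
    if (n_adaptive > n_snps) stop("n_adaptive must not exceed n_snps")
  })
  invisible(cfg)
}

# Balding-Nichols draw: child frequencies around ancestral p with intensity F.
balding_nichols <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

bioclim_names <- function() paste0("bio", 1:19)

#' Names of the bathymetric / geographic (non-climate) environment variables
#'
#' These are fixed lake properties: future climate scenarios never alter them.
#' @return character vector.
#' @export
bathymetric_vars <- function() {
  c("altitude", "max_depth", "mean_depth", "surface_area", "littoral_pct",
    "distance_to_sea", "latitude", "longitude")
}

#' Simulate a hierarchically structured lake metapopulation
#'
#' Ancestral allele frequencies are drawn per SNP from Uniform(0.05, 0.95) and
#' pushed down the region -> Hydrometric Area -> lake -> ecotype hierarchy by
#' Balding-Nichols beta draws with the configured drift intensity at each
#' level. Adaptive loci additionally shift each population's frequency on the
#' logit scale by `gea_effect` per unit of the lake's standardised driver
#' variable (bio1, which carries a latitudinal gradient). Frequencies are
#' clipped to [0.001, 0.999] before binomial genotype draws so no locus is
#' forced to fixation. Genotypes are Binomial(2, p) with independent
#' missingness and Poisson read depths. The environment table contains the 19
#' bioclim variables (bio6 deliberately collinear with bio1, |rho| > 0.7, to
#' exercise pruning), bathymetry, altitude and distance to sea for the
#' `current` scenario.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]), `popmap`,
#'   `env` (current-scenario environment table) and `truth` (adaptive SNP ids,
#'   true per-population frequencies, the env driver and slopes, planted
#'   cluster labels).
#' @export
simulate_metapopulation <- function(config) {
  validate_sim_config(config)
  cfg <- config

  lakes <- with_seed(substream_seed(cfg$seed, "lakes"), {
    lk <- expand.grid(lake_i = seq_len(cfg$n_lakes_per_ha),
                      ha_i = seq_len(cfg$n_ha_per_region),
                      region_i = seq_len(cfg$n_regions))
    lk$region <- paste0("R", lk$region_i)
    lk$ha <- paste0("HA", lk$region_i, ".", lk$ha_i)
    lk$lake <- paste0("lake", sprintf("%02d", seq_len(nrow(lk))))
    n <- nrow(lk)
    # a latitudinal gradient spanning lakes of both regions: the regional
    # split is a (longitudinal) drainage divide, so latitude is assigned
    # independently of the hierarchy (evenly spaced, shuffled, jittered)
    lk$latitude <- sample(55 + 4 * (seq_len(n) - 1) / max(1, n - 1)) +
      stats::rnorm(n, 0, 0.15)
    lk$longitude <- ifelse(lk$region_i == 1, -5, -3.5) + stats::rnorm(n, 0, 0.4)
    n_eco <- round(cfg$ecotype_lake_fraction * n)
    eco_lakes <- if (n_eco > 0) sample(lk$lake, n_eco) else character(0)
    lk$has_ecotypes <- lk$lake %in% eco_lakes
    lk
  })

  env <- with_seed(substream_seed(cfg$seed, "env"), {
    n <- nrow(lakes)
    z_lat <- as.numeric(scale(lakes$latitude))
    e <- data.frame(lake = lakes$lake, scenario = "current")
    # bio1 (annual mean temperature) declines with latitude; bio6 is the
    # deliberately collinear partner (|rho| > 0.7 with bio1)
    e$bio1 <- 9 - 1.5 * z_lat + stats::rnorm(n, 0, 0.5)
    e$bio6 <- e$bio1 - 7 + stats::rnorm(n, 0, 0.6)
    for (v in setdiff(bioclim_names(), c("bio1", "bio6"))) {
      e[[v]] <- stats::rnorm(n, mean = 50, sd = 10)
    }
    e$altitude <- round(exp(stats::rnorm(n, log(80), 0.9)))
    e$max_depth <- round(exp(stats::rnorm(n, log(30), 0.8)), 1)
    e$mean_depth <- round(0.4 * e$max_depth, 1)
    e$surface_area <- round(exp(stats::rnorm(n, log(40), 1)), 1)
    e$littoral_pct <- round(stats::runif(n, 5, 80), 1)
    e$distance_to_sea <- round(stats::runif(n, 1, 100), 1)
    e$latitude <- lakes$latitude
    e$longitude <- lakes$longitude
    e
  })

  # populations: one per unimodal lake, two per ecotype lake
  pops <- do.call(rbind, lapply(seq_len(nrow(lakes)), function(i) {
    lk <- lakes[i, ]
    if (lk$has_ecotypes) {
      data.frame(population = paste0(lk$lake, c("_bn", "_pl")),
                 lake = lk$lake, ha = lk$ha, region = lk$region,
                 ecotype = c("benthivore", "planktivore"),
                 n_ind = cfg$n_ecotype_ind)
    } else {
      data.frame(population = lk$lake, lake = lk$lake, ha = lk$ha,
                 region = lk$region, ecotype = "unimodal",
                 n_ind = cfg$n_ind_per_pop)
    }
  }))

  freqs <- with_seed(substream_seed(cfg$seed, "freqs"), {
    S <- cfg$n_snps
    p0 <- stats::runif(S, 0.05, 0.95)
    f <- cfg$fst_levels
    p_region <- t(vapply(seq_len(cfg$n_regions),
                         function(i) balding_nichols(p0, f[["region"]]),
                         numeric(S)))
    rownames(p_region) <- paste0("R", seq_len(cfg$n_regions))
    has <- unique(lakes[, c("ha", "region")])
    p_ha <- t(vapply(seq_len(nrow(has)), function(i) {
      balding_nichols(p_region[has$region[i], ], f[["ha"]])
    }, numeric(S)))
    rownames(p_ha) <- has$ha
    p_lake <- t(vapply(seq_len(nrow(lakes)), function(i) {
      balding_nichols(p_ha[lakes$ha[i], ], f[["lake"]])
    }, numeric(S)))
    rownames(p_lake) <- lakes$lake
    p_pop <- t(vapply(seq_len(nrow(pops)), function(i) {
      if (pops$ecotype[i] == "unimodal") p_lake[pops$lake[i], ]
      else balding_nichols(p_lake[pops$lake[i], ], f[["ecotype"]])
    }, numeric(S)))
    rownames(p_pop) <- pops$population

    adaptive <- if (cfg$n_adaptive > 0) sort(sample.int(S, cfg$n_adaptive))
                else integer(0)
    z_env <- as.numeric(scale(env$bio1))
    names(z_env) <- env$lake
    if (length(adaptive)) {
      z_pop <- z_env[pops$lake]
      shifted <- stats::plogis(
        stats::qlogis(p_pop[, adaptive, drop = FALSE]) +
          cfg$gea_effect * z_pop)
      p_pop[, adaptive] <- shifted
    }
    p_pop <- pmin(pmax(p_pop, 0.001), 0.999)
    list(p_pop = p_pop, adaptive = adaptive, p0 = p0)
  })

  sim <- with_seed(substream_seed(cfg$seed, "genotypes"), {
    S <- cfg$n_snps
    ind_pop <- rep(pops$population, pops$n_ind)
    ids <- unlist(lapply(seq_len(nrow(pops)), function(i) {
      paste0(pops$population[i], "_i", seq_len(pops$n_ind[i]))
    }))
    N <- length(ids)
    g <- matrix(stats::rbinom(N * S, 2,
                              rep(freqs$p_pop[ind_pop, ], 1)),
                nrow = N, ncol = S, dimnames = list(ids, NULL))
    if (cfg$missing_rate > 0) {
      # heterogeneous per-SNP missingness emulating RAD locus dropout: a
      # fraction of loci genotype completely, the rest have exponentially
      # distributed dropout rates (capped at 1/3); mean equals missing_rate
      complete_frac <- 0.3
      rate <- ifelse(stats::runif(S) < complete_frac, 0,
                     pmin(stats::rexp(S, (1 - complete_frac) /
                                           cfg$missing_rate), 1 / 3))
      g[matrix(stats::runif(N * S), N, S) <
          matrix(rate, N, S, byrow = TRUE)] <- NA
    }
    dp <- matrix(stats::rpois(N * S, cfg$depth_mean), N, S,
                 dimnames = list(ids, NULL))
    list(g = g, dp = dp, ind_pop = ind_pop, ids = ids)
  })

  n_chrom <- min(10L, cfg$n_snps)
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), cfg$n_snps))
  chrom <- sort(chrom)  # contiguous blocks, positions increasing within each
  pos <- unlist(lapply(split(seq_len(cfg$n_snps), chrom),
                       function(i) seq_along(i) * 1000L), use.names = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos,
                      locus = paste0("L", seq_len(cfg$n_snps)),
                      ref = "A", alt = "G",
                      depth = round(colMeans(sim$dp), 2))
  G <- genotype_matrix(sim$g, sites, dp = sim$dp)

  popmap <- data.frame(individual = sim$ids,
                       population = sim$ind_pop,
                       lake = pops$lake[match(sim$ind_pop, pops$population)],
                       hydrometric_area =
                         pops$ha[match(sim$ind_pop, pops$population)],
                       ecotype =
                         pops$ecotype[match(sim$ind_pop, pops$population)],
                       replicate_group = NA_character_)
  popmap$latitude <- lakes$latitude[match(popmap$lake, lakes$lake)]
  popmap$longitude <- lakes$longitude[match(popmap$lake, lakes$lake)]

  truth <- list(adaptive_snp_ids = site_ids(sites)[freqs$adaptive],
                adaptive_index = freqs$adaptive,
                pop_freq = freqs$p_pop,
                ancestral_freq = freqs$p0,
                env_driver = "bio1",
                gea_effect = cfg$gea_effect,
                cluster = stats::setNames(pops$population, pops$population),
                replicate_pairs = NULL)

  list(genotypes = G, popmap = popmap, env = env, truth = truth,
       config = cfg)
}

#' Append technical replicate individuals with injected genotyping error
#'
#' Duplicates `n_replicate_pairs` individuals (spread across populations);
#' each replicate differs from its source at Bernoulli(`error_rate`) of the
#' co-called sites, flipping to one of the other two genotype codes. Missing
#' calls stay missing. Pairings are recorded through the popmap
#' `replicate_group` column (shared by source and replicate).
#'
#' @param sim result of [simulate_metapopulation()].
#' @param config the same [sim_config()] (uses `error_rate`,
#'   `n_replicate_pairs`, `depth_mean`, `seed`).
#' @return `sim` with replicates appended to `genotypes` and `popmap`, and
#'   `truth$replicate_pairs` filled in.
#' @export
simulate_replicates <- function(sim, config) {
  cfg <- config
  if (cfg$error_rate < 0 || cfg$error_rate > 1) {
    stop("error_rate must lie in [0, 1]")
  }
  G <- sim$genotypes
  if (cfg$n_replicate_pairs > n_ind(G)) {
    stop("n_replicate_pairs exceeds the number of individuals")
  }
  if (cfg$n_replicate_pairs == 0) return(sim)
  with_seed(substream_seed(cfg$seed, "replicates"), {
    src <- sort(sample.int(n_ind(G), cfg$n_replicate_pairs))
    g_rep <- G$geno[src, , drop = FALSE]
    flip <- !is.na(g_rep) &
      matrix(stats::runif(length(g_rep)) < cfg$error_rate,
             nrow(g_rep), ncol(g_rep))
    if (any(flip)) {
      old <- g_rep[flip]
      # flip to one of the two other codes, uniformly
      shift <- sample(1:2, sum(flip), replace = TRUE)
      g_rep[flip] <- (old + shift) %% 3
    }
    rep_ids <- paste0(rownames(G$geno)[src], "_rep")
    rownames(g_rep) <- rep_ids
    dp_rep <- if (is.null(G$dp)) NULL else {
      d <- matrix(stats::rpois(length(g_rep), cfg$depth_mean),
                  nrow(g_rep), ncol(g_rep))
      rownames(d) <- rep_ids
      d
    }
    geno <- rbind(G$geno, g_rep)
    dp <- if (is.null(G$dp)) NULL else rbind(G$dp, dp_rep)
    G2 <- genotype_matrix(geno, G$sites, dp = dp)

    pm <- sim$popmap
    src_ids <- rownames(G$geno)[src]
    pm$replicate_group[match(src_ids, pm$individual)] <- src_ids
    pm_rep <- pm[match(src_ids, pm$individual), , drop = FALSE]
    pm_rep$individual <- rep_ids
    pm_rep$replicate_group <- src_ids
    pm2 <- rbind(pm, pm_rep)
    rownames(pm2) <- NULL

    sim$genotypes <- G2
    sim$popmap <- pm2
    sim$truth$replicate_pairs <- data.frame(source = src_ids,
                                            replicate = rep_ids)
    sim
  })
}

#' Shift climate variables to create a future scenario
#'
#' Returns a scenario-labelled copy of the environment table with the given
#' per-variable displacements added to the climate columns. Bathymetric and
#' geographic variables are fixed lake properties and may not be shifted.
#'
#' @param env environment table (rows: lake x scenario).
#' @param displacement named numeric vector of shifts, keyed by climate
#'   variable names (subset of `bio1` ... `bio19`). A displacement may also be
#'   a vector of per-lake shifts (recycled against lakes in row order).
#' @param scenario label for the new scenario (e.g. `"future_A"`).
#' @param from scenario to displace (default `"current"`).
#' @return environment table rows for the new scenario.
#' @export
simulate_future_climate <- function(env, displacement, scenario = "future_A",
                                    from = "current") {
  bad <- intersect(names(displacement), bathymetric_vars())
  if (length(bad)) {
    stop("displacement applied to bathymetric/geographic variable(s): ",
         paste(bad, collapse = ", "))
  }
  unknown <- setdiff(names(displacement), bioclim_names())
  if (length(unknown)) {
    stop("unknown climate variable(s): ", paste(unknown, collapse = ", "))
  }
  cur <- env[env$scenario == from, , drop = FALSE]
  if (!nrow(cur)) stop("no rows for scenario '", from, "'")
  fut <- cur
  fut$scenario <- scenario
  for (v in names(displacement)) {
    fut[[v]] <- fut[[v]] + rep_len(displacement[[v]], nrow(fut))
  }
  rownames(fut) <- NULL
  fut
}
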