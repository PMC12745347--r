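# Lake-sensitivity scoring, the multi-metric vulnerability table, offset
# regressions, and rule-based delineation of management units (MUs) and
# evolutionarily significant units (ESUs).

#' Composite lake-sensitivity score
#'
#' Bins maximum depth (deep lakes buffer warming: < 10 m = 4, 10-30 m = 3,
#' 30-100 m = 2, > 100 m = 1), surface area (small lakes carry small
#' populations: < 10 ha = 3, 10-30 ha = 2, > 30 ha = 1) and altitude (high
#' lakes are cooler: < 10 m = 4, 10-50 m = 3, 50-200 m = 2, > 200 m = 1).
#' Bin boundaries are lower-inclusive (10-30 means [10, 30)). The composite
#' is the sum, from 3 (least concern) to 11 (highest concern).
#'
#' @param max_depth_m maximum lake depth in metres (> 0).
#' @param surface_area_ha lake surface area in hectares (> 0).
#' @param altitude_m lake altitude in metres (>= 0).
#' @return data.frame with `depth_score`, `area_score`, `altitude_score`,
#'   `composite` (vectorised over the inputs).
#' @export
sensitivity_score <- function(max_depth_m, surface_area_ha, altitude_m) {
  if (any(max_depth_m <= 0) || any(surface_area_ha <= 0)) {
    stop("depth and surface area must be positive")
  }
  if (any(altitude_m < 0)) stop("altitude must be non-negative")
  depth_score <- 4L - findInterval(max_depth_m, c(10, 30, 100))
  area_score <- 3L - findInterval(surface_area_ha, c(10, 30))
  altitude_score <- 4L - findInterval(altitude_m, c(10, 50, 200))
  data.frame(depth_score, area_score, altitude_score,
             composite = depth_score + area_score + altitude_score)
}

#' Assemble the per-population vulnerability table
#'
#' Joins the three vulnerability metrics: genetic offset (higher = more
#' vulnerable), lake-sensitivity composite (higher = more vulnerable) and
#' observed heterozygosity (lower = more vulnerable). Lake-level metrics
#' (offset, sensitivity) repeat across ecotype populations of a lake.
#' Populations lacking a metric are kept with `NA` and excluded from the
#' pairwise Pearson correlation matrix; constant metrics give `NA`
#' correlations with a warning.
#'
#' @param stats per-population statistics from [per_pop_stats()].
#' @param offsets data.frame `lake`, `offset` from [genetic_offset()], or
#'   `NULL`.
#' @param env current-scenario environment table (for the sensitivity score).
#' @param popmap population map (links populations to lakes).
#' @return list with `table` (population, lake, offset, ho, sensitivity) and
#'   `correlations` (3 x 3 matrix).
#' @export
assemble_vulnerability <- function(stats, offsets, env, popmap) {
  pops <- unique(popmap[, c("population", "lake")])
  tab <- data.frame(population = pops$population, lake = pops$lake)
  tab$offset <- if (is.null(offsets)) NA_real_
                else offsets$offset[match(tab$lake, offsets$lake)]
  tab$ho <- stats$ho[match(tab$population, stats$population)]
  cur <- env[env$scenario == "current", , drop = FALSE]
  sens <- sensitivity_score(cur$max_depth, cur$surface_area, cur$altitude)
  tab$sensitivity <- sens$composite[match(tab$lake, cur$lake)]
  metrics <- tab[, c("offset", "ho", "sensitivity")]
  const <- vapply(metrics, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), logical(1))
  if (any(const)) {
    warning("constant or empty metric(s): ",
            paste(names(metrics)[const], collapse = ", "),
            "; correlations undefined")
  }
  cors <- suppressWarnings(stats::cor(metrics,
                                      use = "pairwise.complete.obs"))
  list(table = tab, correlations = cors)
}

#' Simple regressions of genetic offset on geography
#'
#' Ordinary least squares of offset on latitude and on distance to sea,
#' separately, with the two-sided slope test.
#'
#' @param offsets data.frame `lake`, `offset`.
#' @param env current-scenario environment table with `latitude` and
#'   `distance_to_sea`.
#' @return data.frame per covariate: `slope`, `r_squared`, `p_value`.
#' @export
offset_regressions <- function(offsets, env) {
  cur <- env[env$scenario == "current", , drop = FALSE]
  d <- merge(offsets, cur[, c("lake", "latitude", "distance_to_sea")],
             by = "lake")
  one <- function(v) {
    if (stats::var(d$offset) == 0) {
      return(data.frame(covariate = v, slope = 0, r_squared = 0,
                        p_value = NA_real_))
    }
    fit <- stats::lm(d$offset ~ d[[v]])
    sm <- summary(fit)
    slope <- stats::coef(fit)[2]
    p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA
    data.frame(covariate = v, slope = unname(slope),
               r_squared = sm$r.squared, p_value = unname(p))
  }
  out <- rbind(one("latitude"), one("distance_to_sea"))
  rownames(out) <- NULL
  out
}

#' Delineate conservation units (MUs and ESUs)
#'
#' Builds a merge graph over populations and takes connected components as
#' units. Two populations are linked when (a) their lakes lie within
#' `proximity_km` great-circle kilometres of each other AND their pairwise
#' F_ST is below `gene_flow_fst` (proximity alone never merges strongly
#' differentiated lakes), (b) they share a translocation group, or (c) they
#' share a shared-history group. A unit is an ESU when any member carries the
#' diverged-ecotype flag or is the sole extant population of its Hydrometric
#' Area; otherwise it is an MU. Criterion tags record why each unit got its
#' type and which merge mechanisms formed it.
#'
#' @param meta data.frame, one row per population, with columns `population`,
#'   `ecotype_esu` (logical: diverged-ecotype population, including
#'   parapatric-divergence members), `sole_ha` (logical: only extant
#'   population in its Hydrometric Area), and optionally `lake`, `latitude`,
#'   `longitude`, `translocation_group`, `shared_history_group` (NA = none).
#' @param fst optional pairwise F_ST matrix over the populations; when `NULL`
#'   the proximity/gene-flow rule is skipped and only explicit links merge.
#' @param proximity_km proximity threshold in km (default 20).
#' @param gene_flow_fst pairwise F_ST below which gene flow is deemed notable
#'   (default 0.05).
#' @return a `conservation_units` object: data.frame `units` (unit id, type,
#'   criteria, members) and per-population assignment `membership`.
#' @export
delineate_units <- function(meta, fst = NULL, proximity_km = 20,
                            gene_flow_fst = 0.05) {
  stopifnot(all(c("population", "ecotype_esu", "sole_ha") %in% names(meta)))
  n <- nrow(meta)
  pops <- meta$population
  if (n == 0) {
    return(structure(list(
      units = data.frame(unit = integer(0), type = character(0),
                         criteria = character(0), members = character(0),
                         n_populations = integer(0)),
      membership = data.frame(population = character(0), unit = integer(0),
                              type = character(0))),
      class = "conservation_units"))
  }
  for (col in c("translocation_group", "shared_history_group")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  edges <- matrix(FALSE, n, n, dimnames = list(pops, pops))
  mech <- matrix("", n, n)
  link_group <- function(col, tag) {
    grp <- meta[[col]]
    for (g in unique(grp[!is.na(grp) & grp != ""])) {
      i <- which(grp == g)
      for (a in i) for (b in i) if (a != b) {
        edges[a, b] <<- TRUE
        mech[a, b] <<- paste0(mech[a, b], tag, ";")
      }
    }
  }
  link_group("translocation_group", "merged_translocation")
  link_group("shared_history_group", "merged_shared_history")
  if (!is.null(fst)) {
    if (!all(c("latitude", "longitude") %in% names(meta)) ||
        any(is.na(meta$latitude) | is.na(meta$longitude))) {
      stop("population(s) missing coordinates; proximity rule needs them")
    }
    fst <- as.matrix(fst)[pops, pops]
    km <- geosphere::distHaversine(
      cbind(rep(meta$longitude, each = n), rep(meta$latitude, each = n)),
      cbind(rep(meta$longitude, n), rep(meta$latitude, n))) / 1000
    km <- matrix(km, n, n)
    near <- km < proximity_km & !is.na(fst) & fst < gene_flow_fst
    diag(near) <- FALSE
    # populations in the same lake are only merged by explicit links:
    # sympatric ecotypes are kept distinct unless flagged together
    if ("lake" %in% names(meta)) {
      same_lake <- outer(meta$lake, meta$lake, `==`)
      near[same_lake] <- FALSE
    }
    mech[near & !edges] <- "merged_proximity;merged_gene_flow;"
    edges <- edges | near
  }
  # connected components (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (edges[i, j]) { ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # deterministic, order-independent unit ids: sorted first member name
  comp <- split(seq_len(n), roots)
  first_member <- vapply(comp, function(i) min(pops[i]), character(1))
  comp <- comp[order(first_member)]
  units <- do.call(rbind, lapply(seq_along(comp), function(u) {
    i <- comp[[u]]
    tags <- character(0)
    if (any(meta$ecotype_esu[i])) tags <- c(tags, "diverged_ecotype")
    if (any(meta$sole_ha[i])) tags <- c(tags, "sole_HA_population")
    merge_tags <- unique(unlist(strsplit(paste0(mech[i, i, drop = FALSE],
                                                collapse = ""), ";")))
    merge_tags <- merge_tags[merge_tags != ""]
    type <- if (length(intersect(tags, c("diverged_ecotype",
                                         "sole_HA_population")))) "ESU"
            else "MU"
    data.frame(unit = u, type = type,
               criteria = paste(sort(unique(c(tags, merge_tags))),
                                collapse = ";"),
               members = paste(sort(pops[i]), collapse = ","),
               n_populations = length(i))
  }))
  unit_of <- integer(n)
  for (u in seq_along(comp)) unit_of[comp[[u]]] <- u
  membership <- data.frame(population = pops, unit = unit_of,
                           type = units$type[unit_of])
  structure(list(units = units, membership = membership),
            class = "conservation_units")
}

#' @export
print.conservation_units <- function(x, ...) {
  s <- summarize_units(x)
  cat("conservation_units: ", nrow(x$units), " units over ",
      nrow(x$membership), " populations\n", sep = "")
  cat(sprintf("  ESU: %d units (%d populations); MU: %d units (%d populations)\n",
              s$n_esu_units, s$n_esu_populations, s$n_mu_units,
              s$n_mu_populations))
  invisible(x)
}

#' Count units and member populations by type
#'
#' @param units a `conservation_units` object from [delineate_units()].
#' @return one-row data.frame: `n_esu_units`, `n_mu_units`,
#'   `n_esu_populations`, `n_mu_populations`.
#' @export
summarize_units <- function(units) {
  u <- units$units
  data.frame(n_esu_units = sum(u$type == "ESU"),
             n_mu_units = sum(u$type == "MU"),
             n_esu_populations = sum(u$n_populations[u$type == "ESU"]),
             n_mu_populations = sum(u$n_populations[u$type == "MU"]))
}

#' Bundled Arctic charr population summaries (64 populations)
#'
#' Published diversity summaries for 64 Arctic charr populations from
#' Britain and Ireland: coordinates, sample size, private alleles (`pa`),
#' observed/expected heterozygosity, nucleotide diversity and
#' population-specific F_ST.
#'
#' @return data.frame with one row per population.
#' @export
charr_population_summary <- function() {
  utils::read.delim(system.file("extdata", "charr_population_summary.tsv",
                                package = "charrcu"),
                    stringsAsFactors = FALSE)
}

#' Bundled conservation-unit input metadata for the Scottish populations
#'
#' Encodes, for the 58 Scottish Arctic charr populations, the delineation
#' inputs: diverged-ecotype and sole-Hydrometric-Area flags, explicit
#' translocation and shared-history merge links, coordinates, and the
#' recorded unit classification (`unit_type`) used for validation.
#'
#' @return data.frame with one row per population.
#' @export
charr_unit_metadata <- function() {
  m <- utils::read.delim(system.file("extdata", "charr_unit_metadata.tsv",
                                     package = "charrcu"),
                         stringsAsFactors = FALSE)
  m$ecotype_esu <- as.logical(m$ecotype_esu)
  m$sole_ha <- as.logical(m$sole_ha)
  m
}
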