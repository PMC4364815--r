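#' Simulation configuration
#'
#' Parameters of the forward-time Wright-Fisher stepping-stone simulator of
#' microsatellite evolution under stepwise mutation. Demes sit on a 1-D
#' chain (or a single panmictic deme split into pseudo-populations);
#' migration is gametic: each inherited gene is drawn from a neighbouring
#' deme with probability `migration` per neighbour. Mutation changes the
#' repeat count by +/-1 with probability `mutation_rate`, reflecting at 1.
#'
#' @param demes number of demes (default 8).
#' @param deme_size diploid N per deme (default 50).
#' @param layout `"chain"` (stepping-stone, default) or `"island"` (every
#'   deme exchanges migrants with every other at the same total rate).
#' @param migration chain layout: per-neighbour migration rate, a scalar or
#'   a vector of per-edge rates (length `demes - 1`) for heterogeneous
#'   connectivity (e.g. reduced flow across a group boundary). Island
#'   layout: the total emigration rate, split evenly over the other demes.
#' @param loci number of loci (default 10, the typical panel size).
#' @param mutation_rate per-locus per-generation stepwise mutation rate
#'   (default 5e-4, microsatellite-typical).
#' @param generations burn-in length (default `10 * deme_size`).
#' @param sample_sizes individuals sampled per deme (scalar or per-deme
#'   vector).
#' @param missing_rate per-genotype dropout probability (default 0).
#' @param spacing inter-deme distance in meters for site coordinates
#'   (default 25000).
#' @param pseudo_pops with `demes = 1`, split the single deme's sample into
#'   this many pseudo-populations laid out on the transect (panmictic null;
#'   default 1 = no split).
#' @param groups optional character vector, one group label per deme (or
#'   per pseudo-population), for hierarchical analyses.
#' @param founder_allele initial repeat count of every gene (default 10).
#' @param seed integer seed; the simulation is byte-reproducible given it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(demes = 8, deme_size = 50, layout = "chain",
                              migration = 0.01,
                              loci = 10, mutation_rate = 5e-4,
                              generations = 10 * deme_size,
                              sample_sizes = 20, missing_rate = 0,
                              spacing = 25000, pseudo_pops = 1,
                              groups = NULL, founder_allele = 10, seed = 1) {
  layout <- match.arg(layout, c("chain", "island"))
  if (deme_size < 2) stop("deme_size must be >= 2")
  if (layout == "island" && length(migration) != 1L) {
    stop("island layout takes a single total migration rate")
  }
  if (any(migration < 0) || any(migration > 0.5)) {
    stop("per-neighbour migration must lie in [0, 0.5]")
  }
  if (mutation_rate < 0 || mutation_rate > 0.1) {
    stop("mutation_rate must lie in [0, 0.1]")
  }
  n_sites <- if (demes == 1L) pseudo_pops else demes
  sample_sizes <- rep_len(sample_sizes, n_sites)
  if (demes == 1L && sum(sample_sizes) > deme_size) {
    stop("total sample size exceeds deme_size")
  }
  if (demes > 1L && any(sample_sizes > deme_size)) {
    stop("sample size exceeds deme_size")
  }
  if (demes > 1L && layout == "chain") {
    migration <- rep_len(migration, demes - 1L)
    if (any(2 * migration > 1)) stop("total outgoing migration exceeds 1")
  }
  if (!is.null(groups)) groups <- rep_len(as.character(groups), n_sites)
  structure(list(demes = as.integer(demes), deme_size = as.integer(deme_size),
                 layout = layout,
                 migration = migration, loci = as.integer(loci),
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 sample_sizes = as.integer(sample_sizes),
                 missing_rate = missing_rate, spacing = spacing,
                 pseudo_pops = as.integer(pseudo_pops), groups = groups,
                 founder_allele = as.integer(founder_allele),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Forward-time stepping-stone simulation of microsatellite genotypes
#'
#' Wright-Fisher reproduction per deme: every offspring gene is drawn
#' uniformly from the previous generation's gene pool of its source deme
#' (the deme itself, or a chain neighbour with the configured migration
#' probability per gene), then mutates +/-1 repeat with probability
#' `mutation_rate`, reflecting at repeat count 1. After the burn-in,
#' `sample_sizes` diploid individuals are drawn without replacement per
#' deme and dropout is applied independently per genotype.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_dataset()] with sites on a linear transect (see
#'   [simulate_landscape()] for coordinates/climate).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, "wf"), {
    d <- config$demes; n2 <- 2L * config$deme_size; L <- config$loci
    mu <- config$mutation_rate
    ncolumns <- d * L  # one column per deme x locus pool
    A <- matrix(config$founder_allele, nrow = n2, ncol = ncolumns)
    deme_of_col <- rep(seq_len(d), times = L)
    island <- identical(config$layout, "island") && d > 1L
    if (d > 1L && !island) {
      m_left <- c(0, config$migration)   # edge to deme-1
      m_right <- c(config$migration, 0)  # edge to deme+1
      pl <- m_left[deme_of_col]; pr <- m_right[deme_of_col]
    } else {
      pl <- pr <- rep(0, ncolumns)
    }
    ng <- n2 * ncolumns
    PL <- rep(pl, each = n2); PR <- rep(pr, each = n2)
    col_idx <- rep(seq_len(ncolumns), each = n2)
    deme_idx <- rep(deme_of_col, each = n2)
    for (gen in seq_len(config$generations)) {
      u <- stats::runif(ng)
      src_col <- col_idx
      if (island) {
        mig <- u < config$migration
        offset <- sample.int(d - 1L, sum(mig), replace = TRUE)
        src_deme <- (deme_idx[mig] - 1L + offset) %% d + 1L
        src_col[mig] <- src_col[mig] + (src_deme - deme_idx[mig])
      } else {
        src_col[u < PL] <- src_col[u < PL] - 1L
        go_r <- u >= PL & u < PL + PR
        src_col[go_r] <- src_col[go_r] + 1L
      }
      gidx <- sample.int(n2, ng, replace = TRUE)
      Anew <- A[cbind(gidx, src_col)]
      if (mu > 0) {
        v <- stats::runif(ng)
        Anew[v < mu / 2] <- Anew[v < mu / 2] - 1L
        up <- v >= mu / 2 & v < mu
        Anew[up] <- Anew[up] + 1L
        Anew[Anew == 0L] <- 2L  # reflect at 1
      }
      A <- matrix(Anew, nrow = n2, ncol = ncolumns)
    }
    # sample diploid individuals (gene-slot pairs) per deme
    n_sites <- if (d == 1L) config$pseudo_pops else d
    site_ids <- sprintf("site%02d", seq_len(n_sites))
    ss <- config$sample_sizes
    if (d == 1L) {
      slots <- sample.int(config$deme_size, sum(ss))
      deme_of_site <- rep(1L, n_sites)
      slot_list <- split(slots, rep(seq_len(n_sites), times = ss))
    } else {
      deme_of_site <- seq_len(d)
      slot_list <- lapply(seq_len(d), function(i)
        sample.int(config$deme_size, ss[i]))
    }
    n_ind <- sum(ss)
    alleles <- array(NA_integer_, dim = c(n_ind, 2L, L))
    pop <- character(n_ind)
    ids <- character(n_ind)
    row <- 0L
    for (s in seq_len(n_sites)) {
      dm <- deme_of_site[s]
      for (slot in slot_list[[s]]) {
        row <- row + 1L
        pop[row] <- site_ids[s]
        ids[row] <- sprintf("%s_i%03d", site_ids[s], slot)
        for (l in seq_len(L)) {
          col <- (l - 1L) * d + dm
          alleles[row, , l] <- A[c(2L * slot - 1L, 2L * slot), col]
        }
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(n_ind * L) < config$missing_rate, n_ind, L)
      for (l in seq_len(L)) alleles[drop[, l], , l] <- NA_integer_
    }
    sites <- simulate_landscape(config)$sites
    genotype_dataset(sprintf("locus%02d", seq_len(L)), ids, pop, alleles, sites)
  })
}

#' Emulated landscape: site coordinates, climate scalars, raster, features
#'
#' Lays the demes (or pseudo-populations) out on a linear coastal transect
#' in UTM-like meters, generates site-level climate scalars as a linear
#' spatial gradient plus noise (so climate dissimilarity rank-correlates
#' with distance, as the landscape models assume), and builds a toy
#' coastline feature plus a habitat cost raster consistent with the sites.
#'
#' @param config a [simulation_config()].
#' @param climate_slope gradient of annual precipitation in mm per km along
#'   the transect (default 2).
#' @param climate_noise_sd s.d. of site-level noise in mm (default 10).
#' @param buffer_km suitable-habitat buffer around the coastline feature
#'   (default 10).
#' @param resolution raster cell size in meters (default `spacing / 5`).
#' @return list `sites` (data frame with coordinates, group, precipitation,
#'   isothermality), `raster` (a [cost_raster()]), `features` (named list
#'   of coordinate matrices).
#' @export
simulate_landscape <- function(config, climate_slope = 2,
                               climate_noise_sd = 10, buffer_km = 10,
                               resolution = config$spacing / 5) {
  n_sites <- if (config$demes == 1L) config$pseudo_pops else config$demes
  site_ids <- sprintf("site%02d", seq_len(n_sites))
  x0 <- 300000; y0 <- 7500000
  easting <- x0 + (seq_len(n_sites) - 1L) * config$spacing
  northing <- rep(y0, n_sites)
  with_seed(derive_seed(config$seed, "landscape"), {
    precip <- 400 + climate_slope * (easting - x0) / 1000 +
      stats::rnorm(n_sites, sd = climate_noise_sd)
    precip <- pmax(precip, 0)
    iso <- 50 - 0.5 * climate_slope * (easting - x0) / 1000 / 10 +
      stats::rnorm(n_sites, sd = climate_noise_sd / 20)
    iso <- pmax(iso, 1)
    groups <- config$groups %||%
      rep(c("north", "south"), c(ceiling(n_sites / 2), floor(n_sites / 2)))
    sites <- data.frame(id = site_ids, easting = easting, northing = northing,
                        group = groups, precipitation = precip,
                        isothermality = iso, stringsAsFactors = FALSE)
    # coastline running along the transect, slightly south of the sites
    coast_x <- seq(x0 - config$spacing, max(easting) + config$spacing,
                   by = resolution / 2)
    coast <- cbind(x = coast_x, y = y0 - 2 * resolution)
    extent <- c(x0 - config$spacing, max(easting) + config$spacing,
                y0 - buffer_km * 1000 * 2, y0 + buffer_km * 1000 * 2)
    rule <- habitat_rule(list(coastline = coast), buffer_km = buffer_km,
                         outside_penalty = 100)
    raster <- build_cost_raster(rule, extent, resolution)
    list(sites = sites, raster = raster, features = list(coastline = coast))
  })
}

#' Expected island-model F_ST (closed form)
#'
#' Finite-island equilibrium approximation
#' \deqn{F_{ST} \approx \frac{1}{1 + 4N(m + \mu)\,[d/(d-1)]^2}}
#' used only as a coarse oracle band for the simulator (drift variance
#' around it is large).
#'
#' @param deme_size diploid N per deme.
#' @param migration total migration rate m.
#' @param mutation_rate mutation rate mu.
#' @param demes number of demes d (>= 2).
#' @return expected F_ST.
#' @export
expected_fst_island <- function(deme_size, migration, mutation_rate, demes) {
  if (demes < 2) stop("island expectation needs at least 2 demes")
  a <- (demes / (demes - 1))^2
  1 / (1 + 4 * deme_size * (migration + mutation_rate) * a)
}

#' Scenario presets
#'
#' Three canonical study conditions mirroring the qualitative contrasts the
#' pipeline is meant to resolve:
#' \describe{
#'   \item{panmixia}{one large deme sampled into 8 pseudo-populations along
#'     the transect: no genetic structure, the null for every test.}
#'   \item{strong_IBD}{8 demes in a chain, nearest-neighbour migration
#'     m = 0.01, N = 50, mu = 5e-4, 10 loci, 20 sampled per deme:
#'     differentiation increases with distance.}
#'   \item{hierarchical_watersheds}{two groups of 4 demes; migration within
#'     groups 0.05, across the single between-group edge 0.005 (10x lower):
#'     watershed-style vicariant structure detectable as F_CT > 0.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed stored in the config.
#' @return a [simulation_config()]; for `hierarchical_watersheds` the config
#'   carries the group map in `$groups`.
#' @export
scenario_preset <- function(name = c("panmixia", "strong_IBD",
                                     "hierarchical_watersheds"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    panmixia = simulation_config(
      demes = 1, deme_size = 200, loci = 10, mutation_rate = 5e-4,
      generations = 2000, sample_sizes = 10, pseudo_pops = 8, seed = seed),
    strong_IBD = simulation_config(
      demes = 8, deme_size = 50, migration = 0.01, loci = 10,
      mutation_rate = 5e-4, generations = 500, sample_sizes = 20,
      seed = seed),
    hierarchical_watersheds = simulation_config(
      demes = 8, deme_size = 50,
      migration = c(0.05, 0.05, 0.05, 0.005, 0.05, 0.05, 0.05),
      loci = 10, mutation_rate = 5e-4, generations = 500, sample_sizes = 20,
      groups = rep(c("west", "east"), each = 4), seed = seed))
}

#' Write a simulated scenario to disk in the pipeline's input formats
#'
#' Emits the Genepop genotype file, the site-metadata table, the ESRI ASCII
#' cost raster and the feature-layer coordinates — exactly the files the
#' readers consume.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_genotypes(config)
  land <- simulate_landscape(config)
  paths <- list(
    genotypes = file.path(dir, "genotypes.gen"),
    sites = file.path(dir, "sites.csv"),
    raster = file.path(dir, "cost.asc"),
    features = file.path(dir, "coastline.csv"))
  write_genepop(ds, paths$genotypes)
  write_site_metadata(land$sites, paths$sites)
  write_esri_ascii(land$raster, paths$raster)
  utils::write.table(as.data.frame(land$features$coastline), paths$features,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
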