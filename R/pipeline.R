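#' Pipeline run configuration
#'
#' Declarative configuration for a full comparative analysis of one cohort
#' (species): inputs, enabled stages, numeric settings and the master seed.
#' All inputs for enabled stages are validated up front (fail fast).
#'
#' @param genotypes a [genotype_dataset()] or path to a Genepop file.
#' @param sites site data frame or path to a metadata table (may be `NULL`
#'   if `genotypes` is a dataset that already carries sites).
#' @param raster a [cost_raster()] or path to an ESRI ASCII grid (required
#'   only for the landscape IBD stage).
#' @param stages character vector among `diversity`, `hwe`, `fst`, `amova`,
#'   `ibd_euclidean`, `ibd_landscape` (default: all, in the standard order
#'   diversity, HWE, F_ST, AMOVA, Euclidean IBD, landscape IBD).
#' @param label cohort label carried into reports.
#' @param rarefaction_genes rarefaction size (default 4).
#' @param hwe_dememorization,hwe_batches,hwe_iterations HWE chain settings
#'   (defaults 10000, 1000, 10000).
#' @param alpha significance level (default 0.05).
#' @param fst_permutations pairwise F_ST permutations (default 100).
#' @param amova_permutations AMOVA permutations (default 10000).
#' @param mrmpa_permutations MRMPA permutations (default 10000).
#' @param climate_variables site columns used as climate predictors
#'   (default `c("precipitation", "isothermality")`).
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir optional output directory; when given, every stage table
#'   is written there along with a machine-readable `summary.json`.
#' @return object of class `run_config`.
#' @export
run_config <- function(genotypes, sites = NULL, raster = NULL,
                       stages = c("diversity", "hwe", "fst", "amova",
                                  "ibd_euclidean", "ibd_landscape"),
                       label = "cohort",
                       rarefaction_genes = 4,
                       hwe_dememorization = 10000, hwe_batches = 1000,
                       hwe_iterations = 10000, alpha = 0.05,
                       fst_permutations = 100, amova_permutations = 10000,
                       mrmpa_permutations = 10000,
                       climate_variables = c("precipitation", "isothermality"),
                       seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

resolve_inputs <- function(config) {
  problems <- character(0)
  ds <- config$genotypes
  sites <- config$sites
  if (is.character(sites)) {
    if (!file.exists(sites)) problems <- c(problems, paste("missing site file:", sites))
    else sites <- read_site_metadata(sites)
  }
  if (is.character(ds)) {
    if (!file.exists(ds)) {
      problems <- c(problems, paste("missing genotype file:", ds))
      ds <- NULL
    } else {
      ds <- read_genepop(ds, pop_names = if (is.data.frame(sites)) sites$id else NULL,
                         sites = if (is.data.frame(sites)) sites else NULL)
    }
  } else if (is.data.frame(sites)) {
    ds <- genotype_dataset(ds$loci, ds$ind_id, as.character(ds$pop),
                           ds$alleles, sites)
  }
  raster <- config$raster
  if (is.character(raster)) {
    if (!file.exists(raster)) problems <- c(problems, paste("missing raster file:", raster))
    else raster <- read_esri_ascii(raster)
  }
  needs_coords <- any(c("ibd_euclidean", "ibd_landscape") %in% config$stages)
  if (!is.null(ds) && needs_coords &&
      !all(c("easting", "northing") %in% names(ds$sites))) {
    problems <- c(problems, "IBD stages need site coordinates (easting/northing)")
  }
  if ("ibd_landscape" %in% config$stages) {
    if (is.null(raster)) problems <- c(problems, "ibd_landscape stage needs a cost raster")
    if (!is.null(ds) &&
        !all(config$climate_variables %in% names(ds$sites))) {
      problems <- c(problems, paste("missing climate variable(s):",
        paste(setdiff(config$climate_variables, names(ds$sites)), collapse = ", ")))
    }
  }
  if ("amova" %in% config$stages && !is.null(ds) &&
      (is.null(ds$sites$group) || anyNA(ds$sites$group))) {
    problems <- c(problems, "amova stage needs a complete `group` column in site metadata")
  }
  if (length(problems)) {
    stop("pipeline inputs unresolvable:\n  - ", paste(problems, collapse = "\n  - "))
  }
  list(ds = ds, raster = raster)
}

#' Run the full comparative analysis
#'
#' Executes the enabled stages in the standard order (diversity, HWE exact
#' tests, pairwise F_ST, hierarchical AMOVA, Euclidean isolation by
#' distance, landscape isolation by distance), each consuming the previous
#' stages' artifacts. Warnings (skipped populations, undefined statistics,
#' unreachable pairs) are collected as data in the report. Re-running with
#' the same configuration and seed reproduces every number exactly.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: stage tables plus a `summary` list
#'   (settings, seed, counts, warnings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  ds <- inputs$ds
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  report <- list(label = config$label)
  st <- config$stages

  if ("diversity" %in% st) {
    report$diversity <- withCallingHandlers(
      diversity_table(ds, g = config$rarefaction_genes, label = config$label),
      warning = function(w) { note("diversity: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  }
  if ("hwe" %in% st) {
    report$hwe <- hwe_test_all(
      ds, scope = "island",
      dememorization = config$hwe_dememorization,
      batches = config$hwe_batches, iterations = config$hwe_iterations,
      alpha = config$alpha, seed = derive_seed(config$seed, "hwe"))
    nt <- sum(!report$hwe$testable)
    if (nt) note("hwe: %d locus/unit combinations not testable", nt)
  }
  fst_res <- NULL
  if (any(c("fst", "ibd_euclidean", "ibd_landscape") %in% st)) {
    fst_res <- fst_matrix(ds, permutations = config$fst_permutations,
                          seed = derive_seed(config$seed, "fst"))
    report$fst <- fst_res
    if (anyNA(fst_res$fst[lower.tri(fst_res$fst)])) {
      note("fst: %d pair(s) with no shared typed locus",
           sum(is.na(fst_res$fst[lower.tri(fst_res$fst)])))
    }
  }
  if ("amova" %in% st) {
    report$amova <- amova_three_level(
      ds, permutations = config$amova_permutations,
      seed = derive_seed(config$seed, "amova"))
  }
  log_warnings <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      note("%s: %s", stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  if ("ibd_euclidean" %in% st) {
    eu <- euclidean_matrix(ds$sites)
    prob <- matrix_regression_problem(fst_res$fst,
                                      list(euclidean = eu),
                                      pair_weights(ds))
    report$ibd_euclidean <- log_warnings("ibd_euclidean", model_average(
      prob, B = config$mrmpa_permutations,
      seed = derive_seed(config$seed, "ibd_euclidean")))
  }
  if ("ibd_landscape" %in% st) {
    cwdd <- withCallingHandlers(
      least_cost_matrix(inputs$raster, ds$sites),
      warning = function(w) { note("landscape: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    preds <- list(cwdd = cwdd)
    for (v in config$climate_variables) {
      preds[[v]] <- bray_curtis_matrix(ds$sites, v)
    }
    prob <- matrix_regression_problem(fst_res$fst, preds, pair_weights(ds))
    report$ibd_landscape <- log_warnings("ibd_landscape", model_average(
      prob, B = config$mrmpa_permutations,
      seed = derive_seed(config$seed, "ibd_landscape")))
  }

  report$summary <- list(
    label = config$label, seed = config$seed, stages = st,
    n_individuals = length(ds$ind_id), n_loci = length(ds$loci),
    n_populations = nlevels(ds$pop),
    settings = config[c("rarefaction_genes", "hwe_dememorization",
                        "hwe_batches", "hwe_iterations", "alpha",
                        "fst_permutations", "amova_permutations",
                        "mrmpa_permutations")],
    warnings = warnings_log)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report's tables to a directory
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    format(as.data.frame(df), digits = 10, trim = TRUE),
    file.path(dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$diversity)) wt(report$diversity, "diversity.tsv")
  if (!is.null(report$hwe)) wt(report$hwe, "hwe.tsv")
  if (!is.null(report$fst)) {
    write_pairwise_matrix(report$fst$fst, file.path(dir, "fst.tsv"))
    write_pairwise_matrix(report$fst$p_value, file.path(dir, "fst_p.tsv"))
  }
  if (!is.null(report$amova)) write_amova_report(report$amova, file.path(dir, "amova.tsv"))
  if (!is.null(report$ibd_euclidean)) {
    write_mrmpa_report(report$ibd_euclidean, file.path(dir, "mrmpa_euclidean.tsv"))
  }
  if (!is.null(report$ibd_landscape)) {
    write_mrmpa_report(report$ibd_landscape, file.path(dir, "mrmpa_landscape.tsv"))
  }
  s <- report$summary
  lines <- c(
    sprintf("label: %s", s$label), sprintf("seed: %d", s$seed),
    sprintf("stages: %s", paste(s$stages, collapse = ", ")),
    sprintf("n_individuals: %d", s$n_individuals),
    sprintf("n_loci: %d", s$n_loci),
    sprintf("n_populations: %d", s$n_populations),
    "settings:",
    vapply(names(s$settings), function(k)
      sprintf("  %s: %s", k, format(s$settings[[k]])), character(1)),
    "warnings:",
    if (length(s$warnings)) paste0("  - ", s$warnings) else "  []")
  writeLines(lines, file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report '%s': stages %s\n", x$label,
              paste(x$summary$stages, collapse = ", ")))
  cat(sprintf("  %d individuals, %d loci, %d populations; seed %d\n",
              x$summary$n_individuals, x$summary$n_loci,
              x$summary$n_populations, x$summary$seed))
  if (length(x$summary$warnings)) {
    cat("  warnings:\n"); cat(paste0("    - ", x$summary$warnings, "\n"))
  }
  invisible(x)
}

#' Side-by-side comparison of cohort (species) reports
#'
#' Tabulates per-cohort means +/- SE of A, A_R, H_O and uH_E across
#' populations, and counts of loci deviating from HWE (raw and
#' Holm-corrected), mirroring the standard interspecific comparison.
#' Purely tabulation: no inferential model is fitted.
#'
#' @param reports list of `run_report` objects with diversity tables.
#' @return data frame, one row per cohort.
#' @export
compare_species <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports to compare")
  panels <- lapply(reports, function(r) {
    if (is.null(r$diversity)) stop("report '", r$label, "' has no diversity table")
    unique(r$hwe$locus)
  })
  common <- Reduce(intersect, panels[!vapply(panels, is.null, logical(1))])
  if (length(unique(vapply(panels, length, integer(1)))) > 1 ||
      any(vapply(panels, function(p) !setequal(p, common), logical(1)))) {
    warning("locus panels differ among cohorts; HWE counts use the intersection")
  }
  rows <- lapply(reports, function(r) {
    d <- r$diversity
    agg <- d[d$population == "mean", ]
    hwe <- r$hwe
    if (!is.null(hwe)) hwe <- hwe[hwe$locus %in% common, ]
    data.frame(label = r$label,
               n_populations = sum(d$population != "mean"),
               n_individuals = agg$n,
               A = agg$A, A_se = agg$A_se, A_R = agg$A_R, A_R_se = agg$A_R_se,
               H_O = agg$H_O, H_O_se = agg$H_O_se,
               uH_E = agg$uH_E, uH_E_se = agg$uH_E_se,
               hwe_dev_raw = if (is.null(hwe)) NA_integer_ else sum(hwe$significant_raw),
               hwe_dev_holm = if (is.null(hwe)) NA_integer_ else sum(hwe$significant_holm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
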