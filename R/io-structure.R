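#' Read a STRUCTURE-format genotype matrix
#'
#' Whitespace-delimited matrix with one column for the individual label, one
#' for the population, and either two columns per locus (one row per
#' individual) or one column per locus with two rows per individual.
#' `-9` encodes a missing allele; both alleles of a genotype must be missing
#' together.
#'
#' @param path path to the file.
#' @param one_row_per_individual `TRUE` for the two-columns-per-locus layout,
#'   `FALSE` for the two-rows-per-individual layout.
#' @param loci optional locus names; defaults to `locus1`, `locus2`, ...
#' @param pop_col column index of the population label (default 2). Set to
#'   `NULL` if the file has no population column, in which case `site_map`
#'   is required.
#' @param site_map optional named character vector mapping individual label
#'   to population id (required when `pop_col` is `NULL`).
#' @param sites optional site-metadata data frame attached to the dataset.
#' @return a [genotype_dataset()].
#' @export
read_structure_table <- function(path, one_row_per_individual = TRUE,
                                 loci = NULL, pop_col = 2L,
                                 site_map = NULL, sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("STRUCTURE parse error: ragged rows (widths ",
         paste(unique(widths), collapse = ", "), ")")
  }
  if (is.null(pop_col) && is.null(site_map)) {
    stop("no population column: supply `site_map` mapping individuals to sites")
  }
  meta_cols <- if (is.null(pop_col)) 1L else 2L
  L_cols <- widths[1L] - meta_cols
  if (L_cols < 1L) stop("STRUCTURE parse error: no genotype columns")
  m <- do.call(rbind, rows)

  if (one_row_per_individual) {
    if (L_cols %% 2L != 0L) {
      stop("STRUCTURE parse error: odd number of allele columns in one-row layout")
    }
    L <- L_cols %/% 2L
    ids <- m[, 1L]
    a_raw <- m[, (meta_cols + 1L):ncol(m), drop = FALSE]
    n <- nrow(m)
    alleles <- array(NA_integer_, dim = c(n, 2L, L))
    for (j in seq_len(L)) {
      alleles[, 1L, j] <- decode_structure_allele(a_raw[, 2L * j - 1L])
      alleles[, 2L, j] <- decode_structure_allele(a_raw[, 2L * j])
    }
  } else {
    if (nrow(m) %% 2L != 0L) {
      stop("STRUCTURE parse error: odd row count in two-row layout")
    }
    L <- L_cols
    n <- nrow(m) %/% 2L
    ids <- m[2L * seq_len(n) - 1L, 1L]
    ids2 <- m[2L * seq_len(n), 1L]
    if (!all(ids == ids2)) {
      stop("STRUCTURE parse error: paired rows carry different individual labels")
    }
    alleles <- array(NA_integer_, dim = c(n, 2L, L))
    for (j in seq_len(L)) {
      col <- decode_structure_allele(m[, meta_cols + j])
      alleles[, 1L, j] <- col[2L * seq_len(n) - 1L]
      alleles[, 2L, j] <- col[2L * seq_len(n)]
    }
  }
  half <- xor(is.na(alleles[, 1L, , drop = FALSE]), is.na(alleles[, 2L, , drop = FALSE]))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("STRUCTURE parse error: half-missing genotype (individual '%s', locus %d)",
                 ids[bad[1L]], bad[3L]))
  }
  pop <- if (!is.null(pop_col)) {
    if (one_row_per_individual) m[, pop_col] else m[2L * seq_len(n) - 1L, pop_col]
  } else {
    mapped <- site_map[ids]
    if (anyNA(mapped)) {
      stop("site_map lacks entries for: ",
           paste(unique(ids[is.na(mapped)]), collapse = ", "))
    }
    unname(mapped)
  }
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  if (length(loci) != L) stop("`loci` length != locus count ", L)
  if (!is.null(sites)) genotype_dataset(loci, ids, pop, alleles, sites)
  else genotype_dataset(loci, ids, pop, alleles)
}

decode_structure_allele <- function(x) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) stop("STRUCTURE parse error: non-integer allele '",
                     x[which(is.na(v))[1L]], "'")
  v[v == -9L] <- NA_integer_
  if (any(v <= 0L, na.rm = TRUE)) {
    stop("STRUCTURE parse error: allele value must be positive or -9 (missing)")
  }
  v
}

#' Write a dataset as a STRUCTURE-format matrix
#'
#' One row per individual, two columns per locus, `-9` for missing alleles;
#' columns: label, population, then alleles.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(ds, path) {
  n <- length(ds$ind_id)
  L <- length(ds$loci)
  a <- ds$alleles
  a[is.na(a)] <- -9L
  cols <- matrix(0L, n, 2L * L)
  for (j in seq_len(L)) {
    cols[, 2L * j - 1L] <- a[, 1L, j]
    cols[, 2L * j] <- a[, 2L, j]
  }
  out <- cbind(ds$ind_id, as.character(ds$pop), cols)
  writeLines(apply(out, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Read site metadata (coordinates, groups, climate)
#'
#' Delimited table (comma or tab, auto-detected) with columns `id`,
#' `easting`, `northing` (planar meters in one UTM zone), optionally `group`
#' (e.g. watershed label), and any further numeric columns taken as
#' site-level climate variables (e.g. annual precipitation in mm,
#' isothermality).
#'
#' @param path path to the table.
#' @return data frame of sites, row order preserved (it fixes population
#'   order in all downstream matrices).
#' @export
read_site_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("id", "easting", "northing")
  if (!all(need %in% names(df))) {
    stop("site metadata must have columns: ", paste(need, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate site id: ", df$id[duplicated(df$id)][1L])
  }
  for (col in c("easting", "northing")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric %s for site '%s'", col, df$id[which(is.na(v))[1L]]))
    }
    df[[col]] <- v
  }
  if (!is.null(df$group)) {
    df$group <- as.character(df$group)
    df$group[!nzchar(trimws(df$group))] <- NA_character_
  }
  df
}

#' Write site metadata
#' @param sites data frame as returned by [read_site_metadata()].
#' @param path output path (comma-separated).
#' @return `path`, invisibly.
#' @export
write_site_metadata <- function(sites, path) {
  utils::write.table(sites, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
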