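#' Read a Genepop-format genotype file
#'
#' Supports the standard dialect: a title line, locus names (one per line or
#' comma-separated), blocks introduced by a line reading `POP` (any case),
#' and individual lines `label , tok tok ...` with 2- or 3-digit allele
#' encoding. `00`/`000` encodes a missing allele; a genotype is treated as
#' missing only when both halves are missing.
#'
#' Genepop carries no population names, so blocks are labelled `pop1`,
#' `pop2`, ... in file order unless `pop_names` supplies labels.
#'
#' @param path path to a Genepop text file.
#' @param pop_names optional character vector naming the POP blocks in order.
#' @param sites optional site-metadata data frame (see [read_site_metadata()])
#'   attached to the dataset; its `id`s must cover the population labels.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, pop_names = NULL, sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("not a Genepop file: fewer than 3 lines")
  lines <- lines[-1L]  # title
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a Genepop file: no POP line")
  locus_lines <- trimws(lines[seq_len(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], "\\s*,\\s*"))
  loci <- trimws(loci)
  if (!length(loci)) stop("no locus names before first POP line")
  body <- lines[first_pop:length(lines)]
  pop_idx <- cumsum(toupper(trimws(body)) == "POP")
  ind_lines <- body[toupper(trimws(body)) != "POP" & nzchar(trimws(body))]
  ind_pop <- pop_idx[toupper(trimws(body)) != "POP" & nzchar(trimws(body))]
  npop <- max(pop_idx)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(npop))
  if (length(pop_names) != npop) stop("pop_names length != number of POP blocks")

  n <- length(ind_lines)
  L <- length(loci)
  ids <- character(n)
  alleles <- array(NA_integer_, dim = c(n, 2L, L))
  digits <- NA_integer_
  for (i in seq_len(n)) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("Genepop parse error: no comma separating label on line '%s'",
                   ind_lines[i]))
    }
    ids[i] <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(toks) != L) {
      stop(sprintf("Genepop parse error: individual '%s' has %d genotype tokens, expected %d",
                   ids[i], length(toks), L))
    }
    for (j in seq_len(L)) {
      tok <- toks[j]
      nc <- nchar(tok)
      if (nc == 4L) d <- 2L
      else if (nc == 6L) d <- 3L
      else stop(sprintf("Genepop parse error: token '%s' (individual '%s', locus '%s') has odd length %d",
                        tok, ids[i], loci[j], nc))
      if (is.na(digits)) digits <- d
      if (d != digits) {
        stop(sprintf("Genepop parse error: mixed %d- and %d-digit encoding at token '%s'",
                     digits, d, tok))
      }
      a1 <- suppressWarnings(as.integer(substr(tok, 1L, d)))
      a2 <- suppressWarnings(as.integer(substr(tok, d + 1L, 2L * d)))
      if (is.na(a1) || is.na(a2)) {
        stop(sprintf("Genepop parse error: non-numeric token '%s'", tok))
      }
      if (xor(a1 == 0L, a2 == 0L)) {
        stop(sprintf("Genepop parse error: half-missing genotype '%s' (individual '%s', locus '%s')",
                     tok, ids[i], loci[j]))
      }
      if (a1 > 0L) alleles[i, , j] <- c(a1, a2)
    }
  }
  if (!is.null(sites)) {
    genotype_dataset(loci, ids, pop_names[ind_pop], alleles, sites)
  } else {
    genotype_dataset(loci, ids, pop_names[ind_pop], alleles)
  }
}

#' Write a dataset in Genepop format
#'
#' Uses 3-digit allele encoding when any allele exceeds 99, else 2-digit.
#' Population block order follows the dataset's site order.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "popcompare export") {
  maxa <- suppressWarnings(max(ds$alleles, na.rm = TRUE))
  if (!is.finite(maxa)) maxa <- 1L
  if (maxa > 999L) stop("allele value ", maxa, " cannot be encoded in 3 digits")
  d <- if (maxa > 99L) 3L else 2L
  fmt <- paste0("%0", d, "d%0", d, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, ds$loci), con)
  for (p in populations(ds)) {
    writeLines("POP", con)
    idx <- which(ds$pop == p)
    for (i in idx) {
      a <- ds$alleles[i, , , drop = FALSE]
      toks <- vapply(seq_along(ds$loci), function(j) {
        if (is.na(a[1L, 1L, j])) sprintf(fmt, 0L, 0L)
        else sprintf(fmt, a[1L, 1L, j], a[1L, 2L, j])
      }, character(1))
      writeLines(paste0(ds$ind_id[i], " , ", paste(toks, collapse = " ")), con)
    }
  }
  invisible(path)
}
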