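#' Euclidean distance matrix between sites
#'
#' Straight-line planar distance in meters between site coordinates
#' (a single UTM zone is assumed; no geodesic correction).
#'
#' @param sites data frame with `id`, `easting`, `northing`.
#' @return a [pairwise_matrix()] in meters.
#' @export
euclidean_matrix <- function(sites) {
  if (nrow(sites) < 2) stop("need at least 2 sites")
  if (!all(is.finite(sites$easting)) || !all(is.finite(sites$northing))) {
    stop("non-finite site coordinates")
  }
  d <- as.matrix(stats::dist(cbind(sites$easting, sites$northing)))
  dimnames(d) <- list(sites$id, sites$id)
  pairwise_matrix(d)
}

#' Bray-Curtis dissimilarity matrix of a site-level climate scalar
#'
#' For scalars, the Bray-Curtis dissimilarity reduces to
#' \eqn{|x - y| / (x + y)}, bounded in `[0, 1]`; two zero values give 0.
#' Negative values are rejected (the index is undefined for them).
#'
#' @param sites site data frame carrying the variable as a column.
#' @param variable column name (e.g. `"precipitation"`, `"isothermality"`).
#' @return a [pairwise_matrix()], unitless.
#' @export
bray_curtis_matrix <- function(sites, variable) {
  x <- sites[[variable]]
  if (is.null(x)) stop("sites have no climate variable '", variable, "'")
  if (any(!is.finite(x))) stop("non-finite values in '", variable, "'")
  if (any(x < 0)) stop("Bray-Curtis undefined for negative values in '", variable, "'")
  k <- length(x)
  num <- abs(outer(x, x, "-"))
  den <- outer(x, x, "+")
  bc <- ifelse(den == 0, 0, num / den)
  dimnames(bc) <- list(sites$id, sites$id)
  pairwise_matrix(bc)
}

#' Habitat suitability rule for cost rasters
#'
#' Describes dispersal habitat as the union of buffers around landscape
#' features (e.g. "within 10 km of the coast", "within 75 km of major rivers
#' and the coast"). Cells inside any buffer cost 1 (suitable); all other
#' cells carry a penalty multiplier.
#'
#' @param feature_layers named list of coordinate matrices/data frames with
#'   columns `x`, `y` (meters); lines are supplied as densely sampled points.
#' @param buffer_km numeric, one value per layer (recycled if scalar):
#'   buffer distance in kilometers.
#' @param outside_penalty cost multiplier (> 1) outside all buffers;
#'   `Inf` makes unsuitable habitat an absolute barrier.
#' @return object of class `habitat_rule`.
#' @export
habitat_rule <- function(feature_layers, buffer_km, outside_penalty = 100) {
  if (!length(feature_layers)) stop("need at least one feature layer")
  if (any(buffer_km <= 0)) stop("buffer_km must be positive")
  if (outside_penalty <= 1) stop("outside_penalty must exceed 1")
  buffer_km <- rep_len(buffer_km, length(feature_layers))
  layers <- lapply(feature_layers, function(f) {
    f <- as.matrix(as.data.frame(f)[, 1:2])
    colnames(f) <- c("x", "y")
    f
  })
  structure(list(feature_layers = layers, buffer_km = buffer_km,
                 outside_penalty = outside_penalty),
            class = "habitat_rule")
}

#' Construct a cost raster
#'
#' Grid-backed traversal-cost surface: cell centers within `buffer_km` of
#' any feature layer (minimum planar distance to the layer's geometry) get
#' cost 1; all other cells get the rule's outside penalty.
#'
#' @param rule a [habitat_rule()].
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in meters; must cover
#'   every site to be connected.
#' @param resolution cell size in meters; should not exceed half the
#'   smallest buffer so corridors are resolved.
#' @return object of class `cost_raster`: `origin` (lower-left corner),
#'   `resolution`, `grid` (matrix, row 1 = northernmost row, `NA` = nodata).
#' @export
build_cost_raster <- function(rule, extent, resolution) {
  if (resolution <= 0) stop("resolution must be positive")
  if (resolution > min(rule$buffer_km) * 1000 / 2) {
    warning("resolution coarser than half the smallest buffer; corridors may be unresolved")
  }
  ncols <- max(1L, ceiling((extent[2] - extent[1]) / resolution))
  nrows <- max(1L, ceiling((extent[4] - extent[3]) / resolution))
  cx <- extent[1] + (seq_len(ncols) - 0.5) * resolution
  cy <- extent[3] + (nrows - seq_len(nrows) + 0.5) * resolution  # row 1 = top
  suitable <- matrix(FALSE, nrows, ncols)
  for (li in seq_along(rule$feature_layers)) {
    f <- rule$feature_layers[[li]]
    lim <- (rule$buffer_km[li] * 1000)^2
    dx2 <- outer(f[, "x"], cx, "-")^2  # features x cols, reused per row
    for (r in seq_len(nrows)) {
      d2 <- dx2 + (f[, "y"] - cy[r])^2
      mins <- if (nrow(f) == 1L) d2[1L, ] else apply(d2, 2L, min)
      suitable[r, ] <- suitable[r, ] | (mins <= lim)
    }
  }
  grid <- matrix(rule$outside_penalty, nrows, ncols)
  grid[suitable] <- 1
  cost_raster(origin = c(extent[1], extent[3]), resolution = resolution,
              grid = grid)
}

#' Cost raster constructor
#' @param origin `c(easting, northing)` of the lower-left corner (meters).
#' @param resolution cell size, meters.
#' @param grid numeric matrix of traversal costs (>= 1 or `NA` for nodata);
#'   row 1 is the northernmost row, as in the ESRI ASCII layout.
#' @return object of class `cost_raster`.
#' @export
cost_raster <- function(origin, resolution, grid) {
  if (resolution <= 0) stop("resolution must be positive")
  grid <- as.matrix(grid)
  if (any(grid < 1, na.rm = TRUE)) stop("cell costs must be >= 1 (or NA)")
  structure(list(origin = as.numeric(origin), resolution = as.numeric(resolution),
                 grid = grid),
            class = "cost_raster")
}

#' @export
print.cost_raster <- function(x, ...) {
  cat(sprintf("cost_raster: %d x %d cells, %.6g m resolution, origin (%.6g, %.6g)\n",
              nrow(x$grid), ncol(x$grid), x$resolution, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Read an ESRI ASCII grid as a cost raster
#' @param path path to an `.asc` file (ncols/nrows/xllcorner/yllcorner/
#'   cellsize/NODATA_value header).
#' @return a [cost_raster()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("ESRI ASCII header incomplete")
  if (is.null(hdr$xllcorner)) hdr$xllcorner <- 0
  if (is.null(hdr$yllcorner)) hdr$yllcorner <- 0
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) grid[grid == hdr$nodata_value] <- NA
  cost_raster(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, grid)
}

#' Write a cost raster as an ESRI ASCII grid
#' @param raster a [cost_raster()].
#' @param path output path.
#' @param nodata sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  g[is.na(g)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(g)),
               sprintf("nrows %d", nrow(g)),
               sprintf("xllcorner %.10g", raster$origin[1]),
               sprintf("yllcorner %.10g", raster$origin[2]),
               sprintf("cellsize %.10g", raster$resolution),
               sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(g, 1L, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             con)
  invisible(path)
}

# map site coordinates to (row, col); ties toward the lower cell index
snap_sites <- function(raster, sites) {
  nr <- nrow(raster$grid); nc <- ncol(raster$grid); res <- raster$resolution
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  out <- matrix(NA_integer_, nrow(sites), 2L,
                dimnames = list(sites$id, c("row", "col")))
  for (s in seq_len(nrow(sites))) {
    cx <- x0 + (seq_len(nc) - 0.5) * res
    cy <- y0 + (nr - seq_len(nr) + 0.5) * res
    if (sites$easting[s] < x0 || sites$easting[s] > x0 + nc * res ||
        sites$northing[s] < y0 || sites$northing[s] > y0 + nr * res) {
      stop("site '", sites$id[s], "' falls outside the raster extent")
    }
    dc <- abs(cx - sites$easting[s]); dr <- abs(cy - sites$northing[s])
    col <- which(dc == min(dc))[1L]; row <- which(dr == min(dr))[1L]
    if (is.na(raster$grid[row, col])) {
      stop("site '", sites$id[s], "' falls in a nodata cell")
    }
    out[s, ] <- c(row, col)
  }
  out
}

#' Least-cost dispersal distance matrix
#'
#' Minimum accumulated cost between site cells over 8-connected lattice
#' paths, with step cost `resolution * (c_i + c_j) / 2`, scaled by
#' `sqrt(2)` for diagonal steps (the standard cost-distance convention).
#' On a unit-cost raster the result is path length in meters. Shortest
#' paths are computed with Dijkstra's algorithm (via igraph).
#'
#' @param raster a [cost_raster()].
#' @param sites site data frame (`id`, `easting`, `northing`); every site
#'   must fall in a non-nodata cell.
#' @return a [pairwise_matrix()] in cost-weighted meters; pairs separated by
#'   a nodata barrier get `NA` with a warning.
#' @export
least_cost_matrix <- function(raster, sites) {
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g); res <- raster$resolution
  snap <- snap_sites(raster, sites)
  idx <- function(r, c) (r - 1L) * nc + c
  # 8-neighbourhood edge list (right, down, down-right, down-left)
  edges <- list()
  w <- list()
  add_edges <- function(r1, c1, r2, c2, diag) {
    a <- g[cbind(r1, c1)]; b <- g[cbind(r2, c2)]
    ok <- !is.na(a) & !is.na(b) & is.finite(a) & is.finite(b)
    if (!any(ok)) return(NULL)
    list(from = idx(r1, c1)[ok], to = idx(r2, c2)[ok],
         w = res * (a[ok] + b[ok]) / 2 * (if (diag) sqrt(2) else 1))
  }
  rc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  steps <- list(c(0L, 1L, FALSE), c(1L, 0L, FALSE), c(1L, 1L, TRUE), c(1L, -1L, TRUE))
  for (s in steps) {
    r2 <- rc$r + s[[1L]]; c2 <- rc$c + s[[2L]]
    keep <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    e <- add_edges(rc$r[keep], rc$c[keep], r2[keep], c2[keep], as.logical(s[[3L]]))
    if (!is.null(e)) { edges[[length(edges) + 1L]] <- e }
  }
  from <- unlist(lapply(edges, `[[`, "from"))
  to <- unlist(lapply(edges, `[[`, "to"))
  wt <- unlist(lapply(edges, `[[`, "w"))
  gr <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(from, to))
  igraph::E(gr)$weight <- wt
  vs <- idx(snap[, "row"], snap[, "col"])
  d <- igraph::distances(gr, v = vs, to = vs, algorithm = "dijkstra")
  dimnames(d) <- list(sites$id, sites$id)
  if (any(is.infinite(d[upper.tri(d)]))) {
    warning("some site pairs are separated by a nodata barrier (NA distance)")
    d[is.infinite(d)] <- NA_real_
  }
  pairwise_matrix(d)
}
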