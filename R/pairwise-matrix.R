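#' Labelled symmetric pairwise matrix
#'
#' All pairwise quantities in the pipeline (F_ST, distances, dissimilarities,
#' weights) travel as plain numeric matrices with population ids on both
#' dimnames, zero diagonal, and enforced symmetry, so that matrix order is
#' always checkable against the site metadata.
#'
#' @param values square numeric matrix.
#' @param labels population ids (defaults to existing dimnames).
#' @return matrix of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (is.null(labels)) stop("pairwise matrix needs population labels")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("label length != matrix dimension")
  asym <- abs(values - t(values))
  if (any(asym > 1e-8, na.rm = TRUE)) stop("pairwise matrix not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("pairwise_matrix", "matrix")
  values
}

#' @export
print.pairwise_matrix <- function(x, digits = 4, ...) {
  y <- unclass(x)
  print(round(y, digits), ...)
  invisible(x)
}

#' Unroll the lower triangle of pairwise matrices into vectors
#'
#' Pairs are ordered column-major over the lower triangle of the label order:
#' (2,1), (3,1), ..., (k,1), (3,2), ... — the same fixed order for every
#' matrix, so response, predictors and weights always align.
#'
#' @param m a [pairwise_matrix()] (or plain labelled symmetric matrix).
#' @param labels optional label order to enforce before unrolling.
#' @return data frame with columns `a`, `b` (labels) and `value`.
#' @export
lower_triangle <- function(m, labels = NULL) {
  if (!is.null(labels)) {
    if (!setequal(rownames(m), labels)) stop("matrix labels do not match")
    m <- m[labels, labels]
  }
  k <- nrow(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  data.frame(a = rownames(m)[idx[, 1L]], b = colnames(m)[idx[, 2L]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Write a pairwise matrix as a labelled delimited lower triangle
#' @param m a [pairwise_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_matrix <- function(m, path) {
  df <- lower_triangle(m)
  utils::write.table(format(df, digits = 12, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pairwise matrix written by [write_pairwise_matrix()]
#' @param path path to the file.
#' @param labels optional explicit label order; defaults to order of first
#'   appearance in the file.
#' @return a [pairwise_matrix()].
#' @export
read_pairwise_matrix <- function(path, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(labels)) labels <- unique(c(rbind(df$b, df$a)))
  k <- length(labels)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  ia <- match(df$a, labels); ib <- match(df$b, labels)
  if (anyNA(ia) || anyNA(ib)) stop("matrix file contains labels outside `labels`")
  m[cbind(ia, ib)] <- df$value
  m[cbind(ib, ia)] <- df$value
  pairwise_matrix(m)
}

# deterministic per-stage seed stream derived from one master seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 1) %% 2147483647)
}
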