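#' Assemble a matrix-regression problem
#'
#' Bundles the response (genetic differentiation), named predictor matrices
#' (e.g. cost-weighted dispersal distance, climate dissimilarities, or
#' Euclidean distance alone) and a pair-weight matrix, all sharing labels
#' and order.
#'
#' @param response a [pairwise_matrix()] (typically F_ST).
#' @param predictors named list of [pairwise_matrix()] objects.
#' @param weights a [pairwise_matrix()] of pair weights (> 0), typically
#'   from [pair_weights()]; `NULL` for unweighted (all 1).
#' @return object of class `matrix_regression_problem`.
#' @export
matrix_regression_problem <- function(response, predictors, weights = NULL) {
  labels <- rownames(response)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stop("predictors must be a named list")
  }
  for (nm in names(predictors)) {
    if (!setequal(rownames(predictors[[nm]]), labels)) {
      stop("predictor '", nm, "' labels do not match the response")
    }
    predictors[[nm]] <- predictors[[nm]][labels, labels]
  }
  if (is.null(weights)) {
    weights <- matrix(1, length(labels), length(labels),
                      dimnames = list(labels, labels))
    diag(weights) <- 0
    weights <- pairwise_matrix(weights)
  } else {
    if (!setequal(rownames(weights), labels)) stop("weight labels do not match")
    weights <- weights[labels, labels]
    if (any(weights[lower.tri(weights)] <= 0, na.rm = TRUE)) {
      stop("pair weights must be positive")
    }
  }
  structure(list(response = response, predictors = predictors,
                 weights = weights, labels = labels),
            class = "matrix_regression_problem")
}

#' Pair weight matrix from per-site sample sizes
#'
#' Weight of pair (i, j) = n_i + n_j, the total number of samples behind
#' that pairwise comparison; down-weights F_ST values estimated from small
#' sites. (`min(n_i, n_j)` is available via `combine = "min"`.)
#'
#' @param ds a [genotype_dataset()].
#' @param combine `"sum"` (default) or `"min"`.
#' @return a [pairwise_matrix()] of weights.
#' @export
pair_weights <- function(ds, combine = c("sum", "min")) {
  combine <- match.arg(combine)
  n <- as.numeric(table(ds$pop))
  w <- if (combine == "sum") outer(n, n, "+") else outer(n, n, pmin)
  dimnames(w) <- list(populations(ds), populations(ds))
  diag(w) <- 0
  pairwise_matrix(w)
}

#' Unroll a matrix-regression problem into vectors
#'
#' Lower-triangle unrolling in the fixed column-major pair order of
#' [lower_triangle()]. Pairs with `NA` in the response or any requested
#' predictor are dropped listwise (count recorded in attribute
#' `n_dropped`).
#'
#' @param problem a [matrix_regression_problem()].
#' @param model character vector of predictor names (default: all).
#' @return list `y`, `X` (matrix without intercept column), `w`,
#'   `pairs` (data frame a/b), with attribute `n_dropped`.
#' @export
vectorize_problem <- function(problem, model = names(problem$predictors)) {
  lt <- lower_triangle(problem$response, problem$labels)
  y <- lt$value
  X <- vapply(model, function(nm)
    lower_triangle(problem$predictors[[nm]], problem$labels)$value,
    numeric(length(y)))
  X <- matrix(X, nrow = length(y), ncol = length(model),
              dimnames = list(NULL, model))
  w <- lower_triangle(problem$weights, problem$labels)$value
  ok <- is.finite(y) & is.finite(w) & rowSums(!is.finite(X)) == 0
  n_dropped <- sum(!ok)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; w <- w[ok]
  if (length(y) < length(model) + 2L) {
    stop("model unidentifiable: ", length(y), " usable pairs for ",
         length(model), " predictors")
  }
  out <- list(y = y, X = X, w = w, pairs = lt[ok, c("a", "b")])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Weighted least squares fit
#'
#' Minimises the weighted residual sum of squares with an intercept always
#' included. Weights are normalised to mean 1 before fitting so AICc values
#' are invariant to rescaling the weights.
#'
#' @param y response vector.
#' @param X predictor matrix (no intercept column).
#' @param w positive weights.
#' @return list: `coefficients`, `se` (slope-aligned), `rss_w` (weighted
#'   RSS under mean-1 weights), `residuals`, `w_norm`, `n`, `k_slopes`.
#' @export
wls_fit <- function(y, X, w) {
  X <- as.matrix(X)
  n <- length(y)
  w <- w / mean(w)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi * sqrt(w))
  if (qr_x$rank < ncol(Xi)) {
    drop_idx <- qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xi))]
    stop("rank-deficient design: collinear column(s) ",
         paste(colnames(Xi)[drop_idx], collapse = ", "))
  }
  beta <- qr.coef(qr_x, y * sqrt(w))
  resid <- y - drop(Xi %*% beta)
  rss_w <- sum(w * resid^2)
  sigma2 <- rss_w / (n - ncol(Xi))
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(0, diag(xtx_inv)) * sigma2)
  names(se) <- colnames(Xi)
  list(coefficients = beta, se = se, rss_w = rss_w, residuals = resid,
       w_norm = w, n = n, k_slopes = ncol(X))
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = n \ln(RSS_w / n) + 2k + \frac{2k(k+1)}{n - k - 1}}
#' with k counting the intercept, the slopes, and the error variance.
#'
#' @param rss_w weighted residual sum of squares (mean-1 weights).
#' @param n number of observations.
#' @param k parameter count (slopes + intercept + error variance).
#' @return AICc value; `-Inf`-like saturation (RSS = 0) returns `NA` with a
#'   warning ("saturated" models are excluded from averaging).
#' @export
aicc <- function(rss_w, n, k) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1 (n = ", n,
                       ", k = ", k, ")")
  if (rss_w <= 0) {
    warning("saturated model (RSS = 0); AICc undefined")
    return(NA_real_)
  }
  n * log(rss_w / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

fit_model_aicc <- function(problem, model) {
  v <- vectorize_problem(problem, model)
  if (length(model) == 0L) {
    # intercept-only
    w <- v$w / mean(v$w)
    mu <- sum(w * v$y) / sum(w)
    rss_w <- sum(w * (v$y - mu)^2)
    fit <- list(coefficients = c(`(Intercept)` = mu), se = NA,
                rss_w = rss_w, residuals = v$y - mu, w_norm = w,
                n = length(v$y), k_slopes = 0L)
  } else {
    fit <- wls_fit(v$y, v$X, v$w)
  }
  k <- fit$k_slopes + 2L
  list(fit = fit, aicc = aicc(fit$rss_w, fit$n, k), v = v)
}

#' Permutation significance of a matrix-regression model
#'
#' Permutes one designated predictor matrix by a random population-label
#' permutation applied to rows and columns together (so only the pairing
#' with the other matrices changes, never the matrix's internal structure),
#' refits, and compares AICc: p = (#\{AICc_perm < AICc_obs\} + 1) / (B + 1).
#' With `exhaustive = TRUE` all k! label permutations are enumerated and
#' p is the fraction of permutations (identity included, ties counted)
#' whose AICc does not exceed the observed.
#'
#' @param problem a [matrix_regression_problem()].
#' @param model character vector of predictor names in the model.
#' @param focal name of the predictor to permute (default: first of
#'   `model`).
#' @param B number of random permutations (default 10000).
#' @param seed integer seed.
#' @param exhaustive enumerate all label permutations (feasible for <= 8
#'   populations).
#' @param plus_one use the (b+1)/(B+1) estimator (default); `FALSE` gives
#'   the raw proportion b/B.
#' @return p-value; `NA` with a warning if the focal predictor is constant
#'   over pairs.
#' @export
permutation_test <- function(problem, model, focal = model[1L], B = 10000,
                             seed = 1, exhaustive = FALSE, plus_one = TRUE) {
  if (!length(model)) stop("model needs at least one predictor")
  if (!focal %in% model) stop("focal predictor must be in the model")
  fm <- problem$predictors[[focal]]
  if (max(abs(fm[lower.tri(fm)] - fm[lower.tri(fm)][1L]), na.rm = TRUE) < 1e-300) {
    warning("focal predictor is constant over pairs; permutation p undefined")
    return(NA_real_)
  }
  obs <- fit_model_aicc(problem, model)$aicc
  if (is.na(obs)) return(NA_real_)
  k <- length(problem$labels)
  refit_perm <- function(perm) {
    pp <- problem
    pp$predictors[[focal]] <- pairwise_matrix(unclass(fm)[perm, perm],
                                              labels = problem$labels)
    fit_model_aicc(pp, model)$aicc
  }
  if (exhaustive) {
    perms <- all_permutations(k)
    vals <- vapply(perms, refit_perm, numeric(1))
    tol <- 1e-9 * (1 + abs(obs))
    return(sum(vals <= obs + tol, na.rm = TRUE) / length(perms))
  }
  hits <- with_seed(derive_seed(seed, paste0("mrmpa:", focal)), {
    sum(vapply(seq_len(B), function(b) {
      val <- refit_perm(sample.int(k))
      !is.na(val) && val < obs - 1e-12
    }, logical(1)))
  })
  if (plus_one) (hits + 1) / (B + 1) else hits / B
}

# Akaike weights w_m = exp(-delta_m/2) / sum_j exp(-delta_j/2); NA entries
# (saturated/unfittable models) get weight 0
akaike_weights <- function(aicc_values) {
  usable <- !is.na(aicc_values)
  delta <- aicc_values - min(aicc_values[usable])
  w <- ifelse(usable, exp(-delta / 2), 0)
  w / sum(w)
}

all_permutations <- function(k) {
  if (k > 8L) stop("exhaustive enumeration supported for <= 8 populations")
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (s in sub) for (pos in seq_len(k)) {
    i <- i + 1L
    out[[i]] <- append(s, k, after = pos - 1L)
  }
  out
}

#' All-subsets AICc model comparison with Akaike-weight model averaging
#'
#' Fits every non-empty subset of the predictors plus the intercept-only
#' model, computes AICc and Akaike weights
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2)}, attaches a
#' permutation p-value to each model (its predictors permuted in turn), and
#' summarises per predictor: total AICc weight (sum of weights of models
#' containing it), conditionally model-averaged beta, the
#' unconditional-variance adjusted SE
#' \eqn{\widehat{SE} = \sum_m w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2} /
#' \sum_m w_m}, z = |beta|/SE and a two-sided normal p. The per-predictor
#' permutation p is from permuting that predictor under the full model.
#' Residual normality (Shapiro-Wilk) is reported for the AICc-best model.
#'
#' @param problem a [matrix_regression_problem()].
#' @param B permutations per test (default 10000).
#' @param seed integer seed.
#' @param conditional average betas only over models containing the
#'   predictor (default); `FALSE` zero-fills absent models.
#' @param plus_one permutation p estimator, see [permutation_test()].
#' @return object of class `mrmpa_result` with elements `models` (data
#'   frame: model, k, AICc, delta, weight, perm p per predictor),
#'   `predictors` (data frame: total weight, averaged beta, adjusted SE, z,
#'   p, permutation p), `diagnostics` (Shapiro-Wilk on the best model),
#'   `best_model`.
#' @export
model_average <- function(problem, B = 10000, seed = 1, conditional = TRUE,
                          plus_one = TRUE) {
  preds <- names(problem$predictors)
  if (!length(preds)) stop("empty model set")
  subsets <- unlist(lapply(seq_along(preds), function(m)
    utils::combn(preds, m, simplify = FALSE)), recursive = FALSE)
  subsets <- c(list(character(0)), subsets)
  fits <- lapply(subsets, function(s) {
    tryCatch(suppressWarnings(fit_model_aicc(problem, s)),
             error = function(e) {
               warning(sprintf("model {%s} dropped from the set: %s",
                               paste(s, collapse = ", "),
                               conditionMessage(e)), call. = FALSE)
               list(fit = NULL, aicc = NA_real_)
             })
  })
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  usable <- !is.na(aiccs)
  if (!any(usable)) stop("no model has a defined AICc")
  delta <- aiccs - min(aiccs[usable])
  wts <- akaike_weights(aiccs)

  model_label <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = " + ") else "(intercept only)",
    character(1))
  perm_p <- lapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    if (!length(s) || !usable[i]) return(stats::setNames(numeric(0), character(0)))
    vapply(s, function(f)
      permutation_test(problem, s, focal = f, B = B,
                       seed = derive_seed(seed, paste0("mm:", model_label[i], ":", f)),
                       plus_one = plus_one),
      numeric(1))
  })
  models <- data.frame(model = model_label,
                       k = vapply(subsets, length, integer(1)) + 2L,
                       AICc = aiccs, delta = delta, weight = wts,
                       stringsAsFactors = FALSE)
  models$perm_p <- vapply(seq_along(perm_p), function(i) {
    if (!length(perm_p[[i]])) NA_real_ else max(perm_p[[i]])
  }, numeric(1))

  pred_rows <- lapply(preds, function(px) {
    has <- vapply(subsets, function(s) px %in% s, logical(1)) & usable
    total_w <- sum(wts[has])
    betas <- vapply(which(has), function(i) fits[[i]]$fit$coefficients[[px]],
                    numeric(1))
    ses <- vapply(which(has), function(i) fits[[i]]$fit$se[[px]], numeric(1))
    wm <- wts[has]
    if (conditional) {
      bbar <- sum(wm * betas) / sum(wm)
      se_adj <- sum(wm * sqrt(ses^2 + (betas - bbar)^2)) / sum(wm)
    } else {
      bbar <- sum(wm * betas)  # absent models contribute beta = 0
      se_adj <- sum(wm * sqrt(ses^2 + (betas - bbar)^2)) +
        (1 - sum(wm)) * abs(bbar)
    }
    z <- abs(bbar) / se_adj
    full_p <- tryCatch(
      permutation_test(problem, preds, focal = px, B = B,
                       seed = derive_seed(seed, paste0("full:", px)),
                       plus_one = plus_one),
      error = function(e) NA_real_)
    data.frame(predictor = px, total_weight = total_w,
               beta = bbar, adjusted_se = se_adj, z = z,
               p_value = 2 * stats::pnorm(-z), perm_p_full = full_p,
               stringsAsFactors = FALSE)
  })
  predictors <- do.call(rbind, pred_rows)

  best <- which.min(ifelse(usable, aiccs, Inf))
  diagnostics <- residual_normality(fits[[best]]$fit)
  structure(list(models = models, predictors = predictors,
                 diagnostics = diagnostics, best_model = model_label[best],
                 n_pairs = fits[[best]]$fit$n,
                 settings = list(B = B, seed = seed, conditional = conditional,
                                 plus_one = plus_one)),
            class = "mrmpa_result")
}

#' Shapiro-Wilk normality check of weighted residuals
#'
#' @param fit a fit as returned by [wls_fit()] (or an element of a
#'   [model_average()] result).
#' @return list `W`, `p_value`; `NA`s if residuals are constant.
#' @export
residual_normality <- function(fit) {
  r <- fit$residuals * sqrt(fit$w_norm)
  if (length(r) < 3) stop("Shapiro-Wilk requires at least 3 residuals")
  if (length(r) > 5000) stop("Shapiro-Wilk supports at most 5000 residuals")
  if (stats::sd(r) < 1e-300) return(list(W = NA_real_, p_value = NA_real_))
  sw <- stats::shapiro.test(r)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' @export
print.mrmpa_result <- function(x, ...) {
  cat("MRMPA: weighted matrix regression with AICc permutation\n")
  cat(sprintf("  %d pairs; best model: %s\n", x$n_pairs, x$best_model))
  m <- x$models
  m$AICc <- round(m$AICc, 2); m$delta <- round(m$delta, 2)
  m$weight <- round(m$weight, 3); m$perm_p <- round(m$perm_p, 4)
  print(m, row.names = FALSE)
  cat("per-predictor (model-averaged):\n")
  p <- x$predictors
  for (col in c("total_weight", "z", "p_value", "perm_p_full")) p[[col]] <- round(p[[col]], 4)
  print(p, row.names = FALSE)
  if (!is.na(x$diagnostics$W)) {
    cat(sprintf("best-model residual normality: W = %.3f, p = %.3f\n",
                x$diagnostics$W, x$diagnostics$p_value))
  }
  invisible(x)
}

#' Write the model-averaged predictor report
#' @param res an `mrmpa_result`.
#' @param path output path (tab-separated; per-predictor total AICc weight,
#'   model-averaged beta, adjusted SE, z, p, plus the per-model table below).
#' @return `path`, invisibly.
#' @export
write_mrmpa_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-predictor (model-averaged)", con)
  utils::write.table(format(res$predictors, digits = 10, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# per-model", con)
  utils::write.table(format(res$models, digits = 10, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
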