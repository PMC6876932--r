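#' Fisher ratio of two one-dimensional class distributions
#'
#' The separation criterion maximized by Fisher discriminant analysis in
#' one dimension: squared mean difference over the summed class
#' variances, \eqn{(\mu_1-\mu_2)^2 / (\sigma_1^2 + \sigma_2^2)}.
#' Degenerate inputs with zero total variance return `Inf` when the
#' means differ (perfect separation) and 0 when they coincide.
#'
#' @param mu1,mu2 Class means.
#' @param var1,var2 Non-negative class variances.
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' fisher_ratio(0, 2, 1, 1)  # 2
#' @export
fisher_ratio <- function(mu1, mu2, var1, var2) {
  if (var1 < 0 || var2 < 0) stop("variances must be non-negative")
  denom <- var1 + var2
  if (denom == 0) {
    return(if (mu1 == mu2) 0 else Inf)
  }
  (mu1 - mu2)^2 / denom
}

#' Within- and between-class scatter matrices
#'
#' The multivariate generalization of the Fisher ratio's numerator and
#' denominator: `within` is the summed within-class cross-product
#' \eqn{S_W = \sum_c \sum_{i \in c} (x_i-\mu_c)(x_i-\mu_c)^T} and
#' `between` the weighted between-class scatter
#' \eqn{S_B = \sum_c n_c (\mu_c-\mu)(\mu_c-\mu)^T} about the grand mean
#' \eqn{\mu}. Their sum is the total scatter about the grand mean, and
#' `between` has rank at most `C - 1` for `C` classes.
#'
#' @param X Numeric matrix, rows = observations.
#' @param y Class labels, one per row; at least two classes, each with
#'   at least two rows.
#' @return Object of class `scatter_matrices`: `within`, `between`,
#'   `class_means`, `class_variances`, `class_counts`, `grand_mean`,
#'   `n_classes`, `n_features`.
#' @export
compute_scatter <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X))) stop("X must be finite")
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2L) stop("at least two classes required")
  counts <- table(y)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    stop("class(es) with fewer than two rows: ",
         paste(small, collapse = ", "))
  }
  p <- ncol(X)
  grand <- colMeans(X)
  within <- matrix(0, p, p)
  between <- matrix(0, p, p)
  class_means <- matrix(NA_real_, length(classes), p,
                        dimnames = list(classes, colnames(X)))
  class_vars <- matrix(NA_real_, length(classes), p,
                       dimnames = list(classes, colnames(X)))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    mu_c <- colMeans(Xc)
    centred <- sweep(Xc, 2L, mu_c)
    within <- within + crossprod(centred)
    dvec <- mu_c - grand
    between <- between + nrow(Xc) * tcrossprod(dvec)
    class_means[cl, ] <- mu_c
    class_vars[cl, ] <- colSums(centred^2) / nrow(Xc)
  }
  structure(list(
    within = (within + t(within)) / 2,
    between = (between + t(between)) / 2,
    class_means = class_means,
    class_variances = class_vars,
    class_counts = as.integer(counts[classes]),
    grand_mean = grand,
    n_classes = length(classes),
    n_features = p
  ), class = "scatter_matrices")
}

# Ledoit-Wolf shrinkage of the within-class scatter: the class-centered
# covariance is shrunk toward (tr(S)/p) I with the closed-form intensity
# of Ledoit & Wolf (2004), then rescaled to scatter units
.lw_shrunk_scatter <- function(Xs, y, sc) {
  y <- as.character(y)
  Z <- Xs
  for (cl in rownames(sc$class_means)) {
    idx <- y == cl
    Z[idx, ] <- sweep(Xs[idx, , drop = FALSE], 2L, sc$class_means[cl, ])
  }
  n <- nrow(Z)
  p <- ncol(Z)
  S <- crossprod(Z) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - m * diag(p))^2) / p
  if (d2 <= 0) return(sc$within + 1e-6 * m * n * diag(p))
  sq_norms <- rowSums(Z^2)
  zSz <- rowSums((Z %*% S) * Z)
  b2 <- (sum(sq_norms^2) - 2 * sum(zSz) + n * sum(S^2)) / (n^2 * p)
  rho <- min(b2, d2) / d2
  n * ((1 - rho) * S + rho * m * diag(p))
}

# fixed sign convention: first component of each column exceeding tol in
# magnitude is made positive (eigenvectors are sign-ambiguous)
.fix_signs <- function(W, tol = 1e-12) {
  for (j in seq_len(ncol(W))) {
    nz <- which(abs(W[, j]) > tol)
    if (length(nz) > 0L && W[nz[1L], j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Fit a Fisher discriminant projection
#'
#' Solves the generalized eigenproblem of \eqn{S_W^{-1} S_B} on the
#' (z-scored, regularized) training data and retains the leading
#' `k <= C - 1` discriminant directions, the subspace in which the
#' projected between/within scatter ratio is maximal. For binary
#' classification this is a single direction; a four-class problem
#' yields at most three.
#'
#' Numerical treatment: features are standardized with training means
#' and sds (stored in the projection so held-out data is transformed
#' with training statistics only); `S_W` receives shrinkage
#' regularization \eqn{S_W + \epsilon\,\mathrm{tr}(S_W)/p\,I}
#' (default `epsilon = 1e-6`) so singular within-scatter never crashes
#' the solve; the eigenproblem is computed in symmetrized form
#' \eqn{S_W^{-1/2} S_B S_W^{-1/2}}; eigenvalues below `1e-10` times the
#' largest are treated as zero and never retained; each direction is
#' unit-norm with the first nonzero component positive.
#'
#' With the default near-zero shrinkage the solution is the exact
#' Fisher discriminant — its projected between/within ratio is maximal
#' over all directions. When the sample size is close to the feature
#' count (40 subjects, 26 features in the per-vowel experiments) the
#' exact solve overfits the noisy within-scatter estimate; passing
#' `shrinkage = "ledoit_wolf"` instead shrinks the within-class
#' covariance toward a scaled identity with the analytically estimated
#' Ledoit-Wolf intensity, the standard regularized-discriminant remedy.
#' The classifier pipeline ([nn_lda_factory()]) uses this estimator.
#'
#' @param X Training feature matrix.
#' @param y Class labels.
#' @param k Number of discriminant directions, or `"auto"` for
#'   `min(C - 1, rank(S_B))`.
#' @param scale Standardize features with training statistics first
#'   (default `TRUE`).
#' @param shrinkage Numeric shrinkage coefficient \eqn{\epsilon} for
#'   `S_W`, or `"ledoit_wolf"` for the estimated-intensity shrinkage.
#' @return Object of class `lda_projection`: `directions` (p x k),
#'   `eigenvalues`, `k`, `center`, `scale`, `feature_names`.
#' @seealso [lda_transform()]
#' @export
fit_projection <- function(X, y, k = "auto", scale = TRUE,
                           shrinkage = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  n_classes <- length(unique(as.character(y)))
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k < 1L || k > n_classes - 1L) {
      stop("k must lie in 1..C-1 (C-1 = ", n_classes - 1L, ")")
    }
  }
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, p)
    scl <- rep(1, p)
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  sc <- compute_scatter(Xs, y)

  if (identical(shrinkage, "ledoit_wolf")) {
    Sw <- .lw_shrunk_scatter(Xs, y, sc)
  } else {
    Sw <- sc$within + shrinkage * (sum(diag(sc$within)) / p) * diag(p)
  }
  ew <- eigen(Sw, symmetric = TRUE)
  wvals <- pmax(ew$values, max(ew$values) * 1e-12)
  W_inv_half <- ew$vectors %*% (t(ew$vectors) / sqrt(wvals))
  M <- W_inv_half %*% sc$between %*% W_inv_half
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  vals <- pmax(em$values, 0)
  nonzero <- sum(vals > 1e-10 * max(vals, .Machine$double.eps))
  k_max <- min(n_classes - 1L, nonzero)
  k_use <- if (identical(k, "auto")) k_max else min(k, k_max)
  if (k_use < 1L) stop("no discriminant direction with nonzero separation")
  dirs <- W_inv_half %*% em$vectors[, seq_len(k_use), drop = FALSE]
  dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), `/`)
  dirs <- .fix_signs(dirs)
  rownames(dirs) <- colnames(X)
  structure(list(
    directions = dirs,
    eigenvalues = vals[seq_len(k_use)],
    k = k_use,
    n_classes = n_classes,
    center = ctr,
    scale = scl,
    feature_names = colnames(X)
  ), class = "lda_projection")
}

#' @export
print.lda_projection <- function(x, ...) {
  cat(sprintf("Fisher discriminant projection: %d feature(s) -> %d dimension(s)\n",
              nrow(x$directions), x$k))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project data through a fitted discriminant
#'
#' Applies the training standardization stored in the projection, then
#' the linear map onto the discriminant directions. Linear and
#' deterministic.
#'
#' @param proj An [fit_projection()] result.
#' @param X Matrix with the same number of columns the projection was
#'   fitted on.
#' @return `n x k` matrix of discriminant scores.
#' @export
lda_transform <- function(proj, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(proj$directions)) {
    stop("X has ", ncol(X), " columns; projection was fitted on ",
         nrow(proj$directions))
  }
  Xs <- sweep(sweep(X, 2L, proj$center), 2L, proj$scale, `/`)
  Xs %*% proj$directions
}

#' @export
predict.lda_projection <- function(object, newdata, ...) {
  lda_transform(object, newdata)
}

#' Projected between/within scatter ratio along a direction
#'
#' Rayleigh-quotient form of the multivariate Fisher criterion,
#' \eqn{w^T S_B w / w^T S_W w}, used to compare a fitted discriminant
#' against arbitrary candidate directions.
#'
#' @param scatter A [compute_scatter()] result.
#' @param w Direction vector (any nonzero scale).
#' @return Non-negative scalar (possibly `Inf` for zero within-scatter).
#' @export
projected_scatter_ratio <- function(scatter, w) {
  w <- as.numeric(w)
  num <- drop(t(w) %*% scatter$between %*% w)
  den <- drop(t(w) %*% scatter$within %*% w)
  if (den <= 0) {
    return(if (num <= .Machine$double.eps) 0 else Inf)
  }
  num / den
}

#' Serialize / restore a discriminant projection as JSON
#'
#' @param proj An `lda_projection`.
#' @param path Output (input) file path.
#' @return `projection_to_json()` returns `path` invisibly;
#'   `projection_from_json()` an `lda_projection`.
#' @export
projection_to_json <- function(proj, path) {
  jsonlite::write_json(
    list(directions = proj$directions, eigenvalues = proj$eigenvalues,
         k = proj$k, n_classes = proj$n_classes, center = proj$center,
         scale = proj$scale, feature_names = proj$feature_names),
    path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname projection_to_json
#' @export
projection_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirs <- matrix(as.numeric(x$directions), ncol = x$k)
  rownames(dirs) <- x$feature_names
  structure(list(
    directions = dirs,
    eigenvalues = as.numeric(x$eigenvalues),
    k = as.integer(x$k),
    n_classes = as.integer(x$n_classes),
    center = as.numeric(x$center),
    scale = as.numeric(x$scale),
    feature_names = x$feature_names
  ), class = "lda_projection")
}
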