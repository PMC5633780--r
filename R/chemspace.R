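# Chemical-space mapping: autoscaling + PCA of physicochemical descriptor
# tables, and a descriptive overlap summary between score clouds.

#' Autoscale a descriptor matrix
#'
#' Centres each column to mean 0 and scales to unit variance (the usual
#' preprocessing for PCA of incommensurate physicochemical properties).
#' Missing cells are imputed by the column mean before scaling, with a
#' message giving the count; a constant column cannot be scaled and becomes
#' all zeros with a warning.  The returned transform record allows exact
#' inversion.
#'
#' @param x Numeric matrix (or data frame), compounds in rows, descriptors
#'   in columns; at least 2 rows, no all-missing column.
#' @return List with `scaled` (matrix), `center`, `scale` (named vectors)
#'   and `n_imputed`.
#' @export
standardize_descriptors <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("descriptor matrix must be numeric", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least two compounds to standardize",
                         call. = FALSE)
  if (any(colSums(!is.na(x)) == 0L)) {
    stop("all-missing descriptor column", call. = FALSE)
  }
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
    message(sprintf("imputed %d missing descriptor cell(s) by column mean",
                    n_imputed))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  if (any(scl == 0)) {
    warning("constant descriptor column(s) scaled to zero: ",
            paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
    scl[scl == 0] <- 1  # centred constant column is already all zeros
  }
  scaled <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  list(scaled = scaled, center = ctr, scale = scl, n_imputed = n_imputed)
}

#' Invert [standardize_descriptors()]
#'
#' @param scaled Standardized matrix.
#' @param transform The transform record (`center`, `scale`).
#' @return The original-scale matrix.
#' @export
unstandardize_descriptors <- function(scaled, transform) {
  sweep(sweep(as.matrix(scaled), 2L, transform$scale, "*"), 2L,
        transform$center, "+")
}

#' Principal component analysis of a chemical descriptor matrix
#'
#' Thin wrapper over [stats::prcomp()] on an already-standardized matrix,
#' adding the conventions a reproducible chemical-space map needs: explained
#' variance fractions relative to the total variance of the input,
#' components ordered by decreasing variance, and a deterministic sign
#' convention (the largest-magnitude loading of each component is made
#' positive, so score plots do not flip between runs).
#'
#' @param x Standardized numeric matrix (see [standardize_descriptors()]).
#' @param n_components Number of components to keep; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return A `chem_pca` object: `loadings` (components x descriptors),
#'   `scores` (compounds x components), `variance_fraction`, and `sdev`
#'   over all computable components.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 50, 4)
#' fit <- chem_pca(standardize_descriptors(m)$scaled, 3)
#' sum(fit$all_variance_fraction)  # 1
#' @export
chem_pca <- function(x, n_components = min(nrow(x) - 1L, ncol(x))) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1L || n_components > kmax) {
    stop("n_components must be in [1, ", kmax, "]", call. = FALSE)
  }
  fit <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  rot <- fit$rotation
  scores <- fit$x
  # sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = t(rot[, seq_len(n_components), drop = FALSE]),
                 scores = scores[, seq_len(n_components), drop = FALSE],
                 variance_fraction = frac[seq_len(n_components)],
                 all_variance_fraction = frac,
                 sdev = fit$sdev,
                 n_components = n_components),
            class = "chem_pca")
}

#' @export
print.chem_pca <- function(x, ...) {
  cat(sprintf("PCA of chemical space: %d component(s) kept\n",
              x$n_components))
  vf <- round(x$variance_fraction, 3L)
  cat("  variance fractions:", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Project new compounds onto a fitted chemical-space PCA
#'
#' @param object A `chem_pca` fit.
#' @param newdata Matrix on the same standardized descriptor scale as the
#'   training matrix.
#' @param ... Unused.
#' @return Score matrix (rows x kept components).
#' @export
predict.chem_pca <- function(object, newdata, ...) {
  as.matrix(newdata) %*% t(object$loadings)
}

#' Overlap between two score clouds in chemical space
#'
#' A purely descriptive comparison of two sets of PCA scores from the same
#' fit (e.g. herbal ingredients vs known drugs): per component, the fraction
#' of set-a points lying inside the \[min, max\] interval of set b, plus the
#' Euclidean distance between the two centroids.
#'
#' @param scores_a,scores_b Score matrices with the same number of columns.
#' @param k Number of leading components to compare (default: all shared).
#' @return List with `containment` (per-component fraction of a inside b's
#'   range) and `centroid_distance`.
#' @export
overlap_summary <- function(scores_a, scores_b,
                            k = min(ncol(scores_a), ncol(scores_b))) {
  scores_a <- as.matrix(scores_a)
  scores_b <- as.matrix(scores_b)
  if (!nrow(scores_a) || !nrow(scores_b)) {
    stop("empty score set", call. = FALSE)
  }
  if (k < 1L || k > min(ncol(scores_a), ncol(scores_b))) {
    stop("invalid number of components", call. = FALSE)
  }
  containment <- vapply(seq_len(k), function(j) {
    rng <- range(scores_b[, j])
    mean(scores_a[, j] >= rng[1L] & scores_a[, j] <= rng[2L])
  }, numeric(1L))
  names(containment) <- paste0("PC", seq_len(k))
  ca <- colMeans(scores_a[, seq_len(k), drop = FALSE])
  cb <- colMeans(scores_b[, seq_len(k), drop = FALSE])
  list(containment = containment,
       centroid_distance = sqrt(sum((ca - cb)^2)))
}
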