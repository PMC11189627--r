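#' Variance-thresholded principal component reduction
#'
#' Standardizes columns to zero mean / unit variance (layers have
#' heterogeneous units), drops zero-variance columns with a warning, runs a
#' PCA and retains the smallest number of components whose cumulative
#' explained variance reaches the threshold. Loading signs follow a fixed
#' convention (largest-magnitude element of each loading vector is positive)
#' so scores are reproducible.
#'
#' @param x numeric matrix, cells x variables (>= 2 rows, finite values).
#' @param variance_threshold cumulative explained-variance target, default
#'   0.80.
#' @return object of class `pca_reduction`: list with `loadings`
#'   (orthonormal columns), `explained_fraction`, `retained`, `scores`
#'   (cells x retained), `center`, `scale`, `dropped` (names of
#'   zero-variance columns).
#' @export
pca_reduce <- function(x, variance_threshold = 0.80) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_config("PCA needs at least 2 rows")
  if (!all(is.finite(x))) stop_config("PCA input must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0) stop_config("no non-constant columns left for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  retained <- which(cumsum(expl) >= variance_threshold - 1e-12)[1]
  # Sign convention: largest-|loading| element positive, per component.
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = rot, explained_fraction = expl,
                 retained = retained,
                 scores = scores[, seq_len(retained), drop = FALSE],
                 center = pc$center, scale = pc$scale, dropped = dropped,
                 variance_threshold = variance_threshold),
            class = "pca_reduction")
}

#' Assemble the per-cell predictor matrix
#'
#' Binds retained principal-component scores, additional continuous layers
#' (by default the elevation range) and categorical region indicator columns
#' into the predictor matrix the model consumes. Column names are stable:
#' `PC1..PCk`, the layer names, then `region_<level>` indicators.
#'
#' @param landscape an `sdm_landscape`.
#' @param pca a [pca_reduce()] result whose scores have one row per cell
#'   (or a bare score matrix), or `NULL`.
#' @param region_flags factor of length `n_cells` with biogeographic region
#'   labels (e.g. sides of a dispersal barrier), or `NULL`. A k-level factor
#'   adds k - 1 indicator columns (first level is the reference).
#' @param extra_layers names of landscape layers appended as continuous
#'   predictors.
#' @return numeric matrix, `n_rows * n_cols` rows, with attribute
#'   `categorical` naming the indicator columns.
#' @export
assemble_predictors <- function(landscape, pca = NULL, region_flags = NULL,
                                extra_layers = "elev_range") {
  n_cells <- landscape$n_rows * landscape$n_cols
  parts <- list()
  if (!is.null(pca)) {
    scores <- if (inherits(pca, "pca_reduction")) pca$scores else as.matrix(pca)
    if (nrow(scores) != n_cells) stop_config("PCA scores rows != landscape cells")
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    parts$pca <- scores
  }
  if (length(extra_layers)) parts$layers <- landscape_matrix(landscape, extra_layers)
  cat_cols <- character(0)
  if (!is.null(region_flags)) {
    region_flags <- as.factor(region_flags)
    if (length(region_flags) != n_cells) {
      stop_config("region_flags length != landscape cells")
    }
    lv <- levels(region_flags)
    if (length(lv) > 1) {
      ind <- vapply(lv[-1], function(l) as.numeric(region_flags == l),
                    numeric(n_cells))
      if (is.null(dim(ind))) ind <- matrix(ind, ncol = length(lv) - 1)
      colnames(ind) <- paste0("region_", lv[-1])
      cat_cols <- colnames(ind)
      parts$region <- ind
    }
  }
  if (!length(parts)) stop_config("no predictors to assemble")
  out <- do.call(cbind, unname(parts))
  attr(out, "categorical") <- cat_cols
  out
}
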