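#' Feature class specification
#'
#' Continuous predictors are expanded into linear, quadratic and hinge
#' features (the classes used by MaxEnt-style presence-background models);
#' categorical predictors pass through as indicators. Hinge knots are placed
#' at empirical quantiles of the training data; each knot contributes a
#' forward hinge `max(0, (x - k) / (xmax - k))` and a reverse hinge
#' `max(0, (k - x) / (k - xmin))`. All features are min-max scaled to
#' \[0, 1\] using training ranges.
#'
#' @param classes subset of `c("linear", "quadratic", "hinge")`; at least
#'   one.
#' @param hinge_knots knots per continuous predictor (>= 2), default 50.
#' @param clamp clamp prediction-time predictor values to training ranges
#'   (default TRUE).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "hinge"),
                         hinge_knots = 50, clamp = TRUE) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (!length(classes)) stop_config("at least one feature class is required")
  if ("hinge" %in% classes && hinge_knots < 2) stop_config("hinge_knots must be >= 2")
  structure(list(classes = classes, hinge_knots = as.integer(hinge_knots),
                 clamp = isTRUE(clamp)),
            class = "feature_spec")
}

scale01 <- function(v, lo, hi) {
  if (hi > lo) pmin(1, pmax(0, (v - lo) / (hi - lo))) else v * 0
}

#' Build the model design matrix from predictor rows
#'
#' In training mode (`manifest = NULL`) the function derives and stores a
#' manifest: per-variable training range and hinge knots, per-feature class
#' labels and scaling ranges, and observed categorical levels. In prediction
#' mode the stored manifest is re-applied, optionally clamping predictors to
#' their training ranges; an unseen categorical level is an error naming the
#' level.
#'
#' Constant continuous predictors emit all-zero linear/quadratic columns with
#' a warning and no hinges.
#'
#' @param x numeric predictor matrix (cells/points x predictors); columns
#'   named. Categorical indicator columns are declared via `categorical` or
#'   the matrix's `categorical` attribute.
#' @param spec a [feature_spec()].
#' @param manifest a manifest from a previous training call, or `NULL`.
#' @param categorical names of categorical indicator columns.
#' @return design matrix with attributes `manifest` and `feature_class`
#'   (one of linear/quadratic/hinge/categorical per column).
#' @export
build_features <- function(x, spec = feature_spec(), manifest = NULL,
                           categorical = attr(x, "categorical") %||% character(0)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop_config("predictor matrix must be finite")
  training <- is.null(manifest)
  if (training) {
    manifest <- list(spec = spec, categorical = categorical, vars = list())
    cont <- setdiff(colnames(x), categorical)
    for (v in cont) {
      lo <- min(x[, v]); hi <- max(x[, v])
      knots <- numeric(0)
      if ("hinge" %in% spec$classes && hi > lo) {
        k <- spec$hinge_knots
        knots <- unique(as.numeric(
          stats::quantile(x[, v], probs = seq_len(k) / (k + 1), names = FALSE)))
      }
      manifest$vars[[v]] <- list(min = lo, max = hi, knots = knots,
                                 q_lo = if (hi > lo) min(x[, v])^2 else 0,
                                 constant = hi <= lo)
    }
    for (v in categorical) {
      manifest$vars[[v]] <- list(levels_seen = sort(unique(x[, v])))
    }
  } else {
    spec <- manifest$spec
    categorical <- manifest$categorical
  }
  missing <- setdiff(names(manifest$vars), colnames(x))
  if (length(missing)) {
    stop_config("predictor column(s) missing: %s", paste(missing, collapse = ", "))
  }

  cols <- list(); classes <- character(0)
  for (v in setdiff(names(manifest$vars), categorical)) {
    m <- manifest$vars[[v]]
    xv <- x[, v]
    if (m$constant) {
      if (training) warning(sprintf("predictor '%s' is constant; features zeroed", v))
      if ("linear" %in% spec$classes) { cols[[paste0(v, "_lin")]] <- xv * 0; classes <- c(classes, "linear") }
      if ("quadratic" %in% spec$classes) { cols[[paste0(v, "_quad")]] <- xv * 0; classes <- c(classes, "quadratic") }
      next
    }
    if (spec$clamp && !training) xv <- pmin(m$max, pmax(m$min, xv))
    if ("linear" %in% spec$classes) {
      cols[[paste0(v, "_lin")]] <- scale01(xv, m$min, m$max)
      classes <- c(classes, "linear")
    }
    if ("quadratic" %in% spec$classes) {
      cols[[paste0(v, "_quad")]] <- scale01(xv^2, min(m$min^2, m$max^2, m$min * m$max),
                                            max(m$min^2, m$max^2))
      classes <- c(classes, "quadratic")
    }
    if ("hinge" %in% spec$classes) {
      for (k in m$knots) {
        if (m$max > k) {
          cols[[sprintf("%s_hf_%.6g", v, k)]] <- pmax(0, (xv - k) / (m$max - k))
          classes <- c(classes, "hinge")
        }
        if (k > m$min) {
          cols[[sprintf("%s_hr_%.6g", v, k)]] <- pmax(0, (k - xv) / (k - m$min))
          classes <- c(classes, "hinge")
        }
      }
    }
  }
  for (v in intersect(names(manifest$vars), categorical)) {
    lv <- manifest$vars[[v]]$levels_seen
    unseen <- setdiff(unique(x[, v]), lv)
    if (length(unseen) && !training) {
      stop_config("unseen level(s) %s in categorical predictor '%s'",
                  paste(unseen, collapse = ", "), v)
    }
    cols[[v]] <- x[, v]
    classes <- c(classes, "categorical")
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  attr(out, "manifest") <- manifest
  attr(out, "feature_class") <- classes
  out
}
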