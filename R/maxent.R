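# Per-class base regularization weights, interpolated by presence sample
# size, following the published MaxEnt defaults.
REG_TABLES <- list(
  linear = list(n = c(10, 30, 100), w = c(1.0, 0.2, 0.05)),
  quadratic = list(n = c(0, 10, 17, 30, 100), w = c(1.3, 0.8, 0.5, 0.25, 0.05)),
  hinge = list(n = c(0, 1), w = c(0.5, 0.5)),
  categorical = list(n = c(0, 10, 17), w = c(0.65, 0.5, 0.25))
)

base_reg_weight <- function(class, n_presence) {
  tb <- REG_TABLES[[class]]
  stats::approx(tb$n, tb$w, xout = n_presence, rule = 2)$y
}

#' Fit a MaxEnt-style penalized background-contrast model
#'
#' Implements the maximum-entropy presence-background model as an
#' L1-penalized, heavily background-weighted logistic regression contrasting
#' presence feature vectors against background feature vectors — the
#' standard reformulation of MaxEnt as penalized regression. Optimization is
#' delegated to glmnet's coordinate descent along a decreasing lambda path
#' whose final value encodes the absolute penalty scale.
#'
#' The per-feature penalty is `reg_multiplier x class base weight x
#' sd(feature at presences) / sqrt(n_presence)`, with class base weights
#' interpolated by presence sample size from the published MaxEnt defaults
#' (hinge 0.5; linear, quadratic and categorical tables). The default
#' multiplier 2.5 sits in the commonly recommended 1.5-4 range.
#'
#' @param x_presence,x_background predictor matrices (not yet feature
#'   expanded) with identical columns; at least one row each. Feature
#'   construction (ranges, knots) uses the pooled rows.
#' @param spec a [feature_spec()].
#' @param reg_multiplier global penalty multiplier, default 2.5. As it grows
#'   all non-intercept coefficients shrink to exactly zero.
#' @param categorical names of categorical indicator columns.
#' @param seed integer seed stored as training metadata (the fit itself is
#'   deterministic).
#' @param add_samples_to_background also use the presence rows as background
#'   (default TRUE, matching common practice for this model family); this
#'   bounds the likelihood and prevents coefficient divergence under
#'   quasi-separation.
#' @param exact if TRUE, the weighted-logistic warm start is polished by
#'   proximal-gradient descent into the exact optimum of the penalized
#'   Gibbs objective (the one [maxent_objective()] evaluates). The default
#'   FALSE keeps the weighted-logistic solution, the standard practical
#'   equivalent used by the field's tooling.
#' @param thresh,maxit glmnet convergence tolerance (relative objective
#'   change, default 1e-7) and iteration cap.
#' @return object of class `maxent_model`: feature manifest, named
#'   coefficient vector `beta`, normalizer `alpha` (so relative suitability
#'   `exp(eta + alpha)` sums to 1 over the training background), background
#'   entropy (used by the cloglog link), penalty bookkeeping and training
#'   metadata.
#' @export
fit_maxent <- function(x_presence, x_background, spec = feature_spec(),
                       reg_multiplier = 2.5,
                       categorical = attr(x_presence, "categorical") %||% character(0),
                       seed = 1L, add_samples_to_background = TRUE,
                       exact = FALSE, thresh = 1e-7, maxit = 1e5) {
  x_presence <- as.matrix(x_presence); x_background <- as.matrix(x_background)
  if (nrow(x_presence) < 1 || nrow(x_background) < 1) {
    stop_config("need at least one presence and one background row")
  }
  if (!identical(colnames(x_presence), colnames(x_background))) {
    stop_config("presence and background predictor columns differ")
  }
  if (!all(is.finite(x_presence)) || !all(is.finite(x_background))) {
    stop_config("non-finite predictor values")
  }
  if (add_samples_to_background) {
    x_background <- rbind(x_background, x_presence)
  }
  np <- nrow(x_presence); nb <- nrow(x_background)
  pooled <- rbind(x_presence, x_background)
  attr(pooled, "categorical") <- categorical
  mm <- build_features(pooled, spec, categorical = categorical)
  manifest <- attr(mm, "manifest")
  fclass <- attr(mm, "feature_class")

  # Per-feature penalties after the published MaxEnt defaults: class base
  # weight (interpolated by presence sample size) times the presence-site
  # standard deviation over sqrt(np), floored by 0.001 x feature range and,
  # for hinges, by a minimum-deviance term that stops rarely-active hinge
  # columns from escaping regularization.
  mm_pres <- mm[seq_len(np), , drop = FALSE]
  sds <- apply(mm_pres, 2, stats::sd)
  base <- vapply(fclass, base_reg_weight, numeric(1), n_presence = np)
  reg <- sds * base / sqrt(np)
  rng <- apply(mm, 2, max) - apply(mm, 2, min)
  hmin <- ifelse(fclass == "hinge",
                 pmax(sds, 1 / sqrt(np)) * 0.5 / sqrt(np), 0)
  reg <- reg_multiplier * pmax(reg, 0.001 * rng, hmin, 1e-9)

  y <- c(rep(1, np), rep(0, nb))
  w <- c(rep(1, np), rep(100, nb))
  lambda <- 10^(seq(4, 0, length.out = 200)) * mean(reg) * np / sum(w)
  # Coordinate descent can cycle between near-collinear hinge features at the
  # tightest tolerance; retry with a mildly relaxed tolerance before giving up.
  fit <- NULL
  for (th in unique(pmax(c(thresh, 1e-6, 1e-5), thresh))) {
    cand <- suppressWarnings(
      glmnet::glmnet(x = mm, y = y, family = "binomial", weights = w,
                     standardize = FALSE, penalty.factor = reg,
                     lambda = lambda, thresh = th, maxit = maxit))
    if (ncol(cand$beta) == length(lambda)) {
      if (th > thresh) {
        warning(sprintf("fit converged at relaxed tolerance %g (requested %g)",
                        th, thresh))
      }
      fit <- cand
      break
    }
    fit <- cand
  }
  if (ncol(fit$beta) < length(lambda)) {
    stop_config("glmnet did not converge along the full path (%d of %d steps; see maxit/thresh)",
                ncol(fit$beta), length(lambda))
  }
  beta <- as.numeric(fit$beta[, length(lambda)])
  names(beta) <- colnames(mm)
  a0 <- as.numeric(fit$a0[length(lambda)])

  if (exact) {
    # Polish the weighted-logistic warm start into the exact optimum of the
    # penalized Gibbs (MaxEnt) objective with per-feature penalties `reg`.
    mm_b <- mm[np + seq_len(nb), , drop = FALSE]
    pol <- ista_polish(beta, mm_pres, mm_b, lam = reg, tol = thresh,
                       maxit = 10000)
    beta <- stats::setNames(pol$beta, colnames(mm))
  }

  eta_b <- drop(mm[np + seq_len(nb), , drop = FALSE] %*% beta)
  alpha <- -logsumexp(eta_b)
  q <- exp(eta_b + alpha)
  entropy <- -sum(q * log(pmax(q, 1e-300)))

  structure(list(spec = spec, manifest = manifest, beta = beta, a0 = a0,
                 add_samples_to_background = add_samples_to_background,
                 alpha = alpha, entropy = entropy,
                 reg_multiplier = reg_multiplier, penalty = reg,
                 lambda = lambda[length(lambda)],
                 n_presence = np, n_background = nb, seed = seed),
            class = "maxent_model")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Negative penalized Gibbs objective pieces: smooth part
#   f(beta) = -(1/np) sum_p eta + logsumexp(eta_b)
# and its gradient; the L1 part is sum(lam_j |beta_j|).
gibbs_f <- function(beta, mm_p, mm_b) {
  -mean(mm_p %*% beta) + logsumexp(drop(mm_b %*% beta))
}

gibbs_grad <- function(beta, mm_p, mm_b, xbar_p) {
  eta_b <- drop(mm_b %*% beta)
  q <- exp(eta_b - logsumexp(eta_b))
  drop(crossprod(mm_b, q)) - xbar_p
}

# Proximal-gradient (ISTA with backtracking) minimization of
# f(beta) + sum(lam |beta|), warm-started from the glmnet estimate.
ista_polish <- function(beta, mm_p, mm_b, lam, tol = 1e-7, maxit = 10000) {
  xbar_p <- colMeans(mm_p)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  obj <- function(b) gibbs_f(b, mm_p, mm_b) + sum(lam * abs(b))
  t_step <- 1
  o_cur <- obj(beta)
  f_cur <- gibbs_f(beta, mm_p, mm_b)
  for (it in seq_len(maxit)) {
    g <- gibbs_grad(beta, mm_p, mm_b, xbar_p)
    repeat {
      cand <- soft(beta - t_step * g, t_step * lam)
      d <- cand - beta
      f_cand <- gibbs_f(cand, mm_p, mm_b)
      if (f_cand <= f_cur + sum(g * d) + sum(d^2) / (2 * t_step) + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    o_new <- gibbs_f(cand, mm_p, mm_b) + sum(lam * abs(cand))
    if (o_new > o_cur) break               # no further progress possible
    moved <- abs(o_cur - o_new) / max(1, abs(o_cur))
    beta <- cand
    f_cur <- gibbs_f(beta, mm_p, mm_b)
    o_cur <- o_new
    if (moved < tol) break
    t_step <- min(t_step * 2, 1e3)         # cautious step recovery
  }
  list(beta = beta, objective = o_cur, iterations = it)
}

#' Predict habitat suitability from a fitted model
#'
#' `raw` gives relative suitability `exp(eta + alpha)` (normalized so the
#' training background sums to 1); `cloglog` gives
#' `1 - exp(-exp(entropy + eta + alpha))` in (0, 1). Both are strictly
#' increasing in the linear predictor, so rankings — and hence the Boyce
#' index — are identical across links.
#'
#' @param model a [fit_maxent()] result.
#' @param x predictor rows matching the training columns.
#' @param link `"cloglog"` (default) or `"raw"`.
#' @return numeric vector of suitabilities, one per row of `x`.
#' @export
predict_suitability <- function(model, x, link = c("cloglog", "raw")) {
  link <- match.arg(link)
  stopifnot(inherits(model, "maxent_model"))
  mm <- build_features(as.matrix(x), manifest = model$manifest)
  mm <- mm[, names(model$beta), drop = FALSE]
  eta <- drop(mm %*% model$beta)
  if (link == "raw") exp(eta + model$alpha)
  else 1 - exp(-exp(model$entropy + eta + model$alpha))
}

#' Penalized MaxEnt objective (for optimality spot-checks)
#'
#' Evaluates the penalized Gibbs log-likelihood the fit maximizes,
#' `mean(eta_presence) - log(sum(exp(eta_background))) -
#' sum(penalty_j |beta_j|)`, for an arbitrary coefficient vector on the
#' model's own feature expansion. Used to verify the fitted optimum
#' dominates random coefficient draws.
#'
#' @param model a [fit_maxent()] result.
#' @param x_presence,x_background predictor matrices.
#' @param beta coefficient vector (default: the fitted one).
#' @return scalar objective value (larger is better).
#' @export
maxent_objective <- function(model, x_presence, x_background,
                             beta = model$beta) {
  mm_p <- build_features(as.matrix(x_presence), manifest = model$manifest)
  mm_b <- build_features(as.matrix(x_background), manifest = model$manifest)
  mm_p <- mm_p[, names(model$beta), drop = FALSE]
  mm_b <- mm_b[, names(model$beta), drop = FALSE]
  if (isTRUE(model$add_samples_to_background)) mm_b <- rbind(mm_b, mm_p)
  -gibbs_f(unname(beta), mm_p, mm_b) - sum(model$penalty * abs(beta))
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a [fit_maxent()] result.
#' @param path file path.
#' @return `maxent_from_json()` returns the restored `maxent_model`.
#' @export
maxent_to_json <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  obj <- unclass(model)
  obj$spec <- unclass(obj$spec)
  obj$manifest$spec <- unclass(obj$manifest$spec)
  obj$beta <- as.list(obj$beta)  # keep coefficient names (atomic vectors drop them)
  obj$penalty <- unname(obj$penalty)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname maxent_to_json
#' @export
maxent_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spec <- structure(as.list(obj$spec), class = "feature_spec")
  obj$spec$classes <- as.character(obj$spec$classes)
  obj$manifest$spec <- obj$spec
  obj$manifest$categorical <- as.character(obj$manifest$categorical %||% character(0))
  obj$manifest$vars <- lapply(obj$manifest$vars, function(v) {
    v$knots <- as.numeric(v$knots %||% numeric(0))
    v
  })
  obj$beta <- unlist(obj$beta)
  structure(obj, class = "maxent_model")
}
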