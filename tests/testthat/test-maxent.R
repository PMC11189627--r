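test_that("feature expansion has the documented combinatorial structure", {
  x <- matrix(seq(0, 1, length.out = 50), ncol = 1,
              dimnames = list(NULL, "v"))
  mm <- build_features(x, feature_spec(hinge_knots = 3))
  expect_equal(ncol(mm), 1 + 1 + 6)
  expect_setequal(unique(attr(mm, "feature_class")),
                  c("linear", "quadratic", "hinge"))
  # x at its minimum: all forward hinges zero, linear zero
  fwd <- grepl("_hf_", colnames(mm))
  expect_true(all(mm[1, fwd] == 0))
  expect_true(all(mm >= 0 & mm <= 1))
  # at a knot, its own forward and reverse hinges are both zero
  k <- attr(mm, "manifest")$vars$v$knots[1]
  i <- which.min(abs(x[, 1] - k))
  expect_equal(unname(mm[i, fwd][1]), max(0, (x[i, 1] - k) / (1 - k)))
})

test_that("constant predictors are zeroed with a warning", {
  x <- cbind(v = rnorm(20), k = rep(3, 20))
  expect_warning(mm <- build_features(x, feature_spec(hinge_knots = 3)), "constant")
  expect_true(all(mm[, grepl("^k_", colnames(mm))] == 0))
  expect_false(any(grepl("^k_hf", colnames(mm))))
})

test_that("prediction-time manifests clamp and reject unseen levels", {
  set.seed(51)
  x <- cbind(v = rnorm(100), g = rep(c(0, 1), 50))
  attr(x, "categorical") <- "g"
  mm <- build_features(x, feature_spec(hinge_knots = 5), categorical = "g")
  man <- attr(mm, "manifest")
  x_new <- cbind(v = c(-100, 100), g = c(0, 1))
  mm_new <- build_features(x_new, manifest = man)
  expect_true(all(mm_new >= 0 & mm_new <= 1))
  x_bad <- cbind(v = 0, g = 7)
  expect_error(build_features(x_bad, manifest = man), "unseen level.*7")
})

sim_1d <- function(n_pres = 1000, n_bg = 5000, seed = 52) {
  # logit-quadratic truth on a 1-D gradient
  set.seed(seed)
  grid <- seq(-3, 3, length.out = 2000)
  s <- plogis(1 + 1.5 * grid - 1.2 * grid^2)
  pres <- sample(grid, n_pres, replace = TRUE, prob = s)
  bg <- runif(n_bg, -3, 3)
  list(grid = grid, s = s,
       xp = matrix(pres, ncol = 1, dimnames = list(NULL, "v")),
       xb = matrix(bg, ncol = 1, dimnames = list(NULL, "v")))
}

test_that("an extreme penalty multiplier kills all coefficients", {
  d <- sim_1d(200, 500)
  m <- fit_maxent(d$xp, d$xb, feature_spec(hinge_knots = 5),
                  reg_multiplier = 1e9)
  expect_true(all(m$beta == 0))
  pred <- predict_suitability(m, matrix(d$grid, ncol = 1,
                                        dimnames = list(NULL, "v")))
  expect_equal(diff(range(pred)), 0)
})

test_that("a null model (presence = background distribution) stays near-flat", {
  set.seed(53)
  xp <- matrix(runif(2000, -1, 1), ncol = 1, dimnames = list(NULL, "v"))
  xb <- matrix(runif(2000, -1, 1), ncol = 1, dimnames = list(NULL, "v"))
  m <- fit_maxent(xp, xb, feature_spec(hinge_knots = 10))
  pred <- predict_suitability(m, xb, link = "raw")
  expect_lt(stats::sd(pred) / mean(pred), 0.25)
})

test_that("the model recovers a 1-D logit-quadratic suitability (rho > 0.9)", {
  d <- sim_1d()
  m <- fit_maxent(d$xp, d$xb)
  pred <- predict_suitability(m, matrix(d$grid, ncol = 1,
                                        dimnames = list(NULL, "v")))
  rho <- cor(pred, d$s, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("links are monotone, bounded and rank-identical", {
  d <- sim_1d(300, 800, seed = 54)
  m <- fit_maxent(d$xp, d$xb, feature_spec(hinge_knots = 10))
  gx <- matrix(d$grid, ncol = 1, dimnames = list(NULL, "v"))
  p_raw <- predict_suitability(m, gx, link = "raw")
  p_clg <- predict_suitability(m, gx, link = "cloglog")
  expect_true(all(p_clg > 0 & p_clg < 1))
  expect_equal(rank(p_raw), rank(p_clg))
})

test_that("coefficient L1 norms shrink monotonically in the multiplier", {
  d <- sim_1d(400, 1000, seed = 55)
  norms <- sapply(c(1, 2.5, 5, 10, 25, 100), function(rm) {
    sum(abs(fit_maxent(d$xp, d$xb, feature_spec(hinge_knots = 10),
                       reg_multiplier = rm)$beta))
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("the fitted optimum dominates random coefficient draws", {
  set.seed(56)
  xp <- cbind(a = rnorm(15, 1), b = rnorm(15, -0.5))
  xb <- cbind(a = rnorm(15), b = rnorm(15))
  m <- fit_maxent(xp, xb, feature_spec(classes = c("linear", "quadratic")),
                  exact = TRUE)
  obj_fit <- maxent_objective(m, xp, xb)
  draws <- replicate(1000, {
    beta <- m$beta + rnorm(length(m$beta), 0, 0.5)
    maxent_objective(m, xp, xb, beta = beta)
  })
  expect_true(all(obj_fit >= draws - 1e-6))
})

test_that("JSON serialization round-trips predictions", {
  d <- sim_1d(200, 500, seed = 57)
  m <- fit_maxent(d$xp, d$xb, feature_spec(hinge_knots = 5))
  path <- tempfile(fileext = ".json")
  maxent_to_json(m, path)
  m2 <- maxent_from_json(path)
  gx <- matrix(d$grid[1:100], ncol = 1, dimnames = list(NULL, "v"))
  expect_equal(predict_suitability(m2, gx), predict_suitability(m, gx),
               tolerance = 1e-8)
})
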