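rec_at <- function(row, col, ...) {
  r <- make_records(1, ...)
  r$row <- row; r$col <- col; r$cell <- row * 100L + col
  r
}

test_that("the block split is exhaustive, disjoint and closed-low/open-high", {
  blk <- spatial_block(2, 5, 2, 5)
  recs <- do.call(rbind, Map(rec_at,
                             row = c(2, 5, 2, 4, 0, 6, 3, 4, 1, 7),
                             col = c(2, 2, 5, 4, 0, 6, 3, 2, 1, 7),
                             prefix = paste0("r", 1:10)))
  sp <- split_by_block(recs, blk)
  expect_equal(nrow(sp$train) + nrow(sp$test_pool), 10)
  expect_equal(nrow(sp$test_pool), 4)      # (2,2),(4,4),(3,3),(4,2)
  expect_true("r10001" %in% sp$test_pool$record_id)   # on the low boundary
  expect_false("r20001" %in% sp$test_pool$record_id)  # on the high boundary
  empty_blk <- spatial_block(50, 50, 50, 50)
  expect_warning(sp2 <- split_by_block(recs, empty_blk), "all or none")
  expect_equal(nrow(sp2$train), 10)
})

test_that("p_tp follows the closed form and its monotonicity", {
  expect_equal(p_true_presence(0.91, 2), 1 - 0.09^2)
  expect_equal(p_true_presence(0.91, 1), 0.91)
  expect_equal(p_true_presence(1, 1), 1)
  ptp <- p_true_presence(0.5, 1:10)
  expect_true(all(diff(ptp) > 0))
})

test_that("consensus validation applies the 99% rule per (species, cell)", {
  recs <- rbind(
    make_records(2, user = c("u1", "u2"), cell = 10L, prefix = "a"),
    make_records(1, user = "u1", cell = 11L, prefix = "b"),
    make_records(3, user = c("u1", "u1", "u2"), cell = 12L, prefix = "c"))
  out <- consensus_validate(recs, c(bird = 0.91))
  # cell 10: 2 users -> 0.9919 > 0.99 accepted; cell 11: 1 user -> 0.91 rejected
  # cell 12: 2 distinct users -> accepted
  expect_setequal(out$cell, c(10L, 12L))
  expect_equal(out$n_users[out$cell == 12], 2)
  expect_equal(out$p_tp[out$cell == 10], 1 - 0.09^2)
  # p_valid above threshold lets single-user cells through
  out2 <- consensus_validate(recs, c(bird = 0.995))
  expect_true(11L %in% out2$cell)
  expect_error(consensus_validate(recs, c(fish = 0.9)), "bird")
})

test_that("the dominant freshwater sub-source is downsampled to parity", {
  mk <- function(n_fresh, n_other) {
    rbind(make_records(n_fresh, source = "traditional_freshwater",
                       user = "survey", prefix = "f"),
          make_records(n_other, source = "traditional", user = "survey",
                       prefix = "o"))
  }
  out <- balance_traditional(mk(1000, 200), seed = 1)
  expect_equal(sum(out$source == "traditional_freshwater"), 200)
  expect_equal(sum(out$source == "traditional"), 200)
  expect_equal(nrow(balance_traditional(mk(50, 200))), 250)
  expect_equal(nrow(balance_traditional(mk(0, 200))), 200)
})

test_that("the composite test set hits the 25/75 community share", {
  comm <- data.frame(species_id = "sp1", taxon = "bird",
                     cell = 1:50, n_users = 2, p_tp = 0.999)
  trad <- make_records(500, species = "sp1", cell = 100:599,
                       source = "traditional", user = "survey", prefix = "t")
  out <- assemble_test(comm, trad, seed = 2)
  expect_equal(sum(out$source == "community"), 50)
  expect_equal(sum(out$source == "traditional"), 150)
  expect_equal(mean(out$source == "community"), 0.25, tolerance = 0.01)
  expect_identical(out, assemble_test(comm, trad, seed = 2))
  expect_warning(out2 <- assemble_test(comm[0, ], trad), "one test source")
  expect_true(all(out2$source == "traditional"))
})

test_that("test presences are deduplicated per (species, cell)", {
  comm <- data.frame(species_id = "sp1", taxon = "bird", cell = c(1L, 2L),
                     n_users = 2, p_tp = 0.999)
  trad <- make_records(8, species = "sp1",
                       cell = c(1L, 2L, 3L, 3L, 4L, 5L, 6L, 7L),
                       source = "traditional", user = "survey", prefix = "t")
  out <- assemble_test(comm, trad, community_fraction = 0.25, seed = 3)
  expect_false(any(duplicated(out[, c("species_id", "cell")])))
  # cells 1 and 2 belong to the community side only
  expect_false(any(out$cell %in% c(1L, 2L) & out$source == "traditional"))
})

# Independent brute-force Boyce oracle: literal windows, no shared code.
boyce_oracle <- function(eval_s, pres_s, n_windows = 101, frac = 0.1) {
  lo <- min(eval_s); hi <- max(eval_s); w <- frac * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  pe <- mid_keep <- c()
  for (m in mids) {
    P <- sum(pres_s >= m - w / 2 & pres_s <= m + w / 2) / length(pres_s)
    E <- sum(eval_s >= m - w / 2 & eval_s <= m + w / 2) / length(eval_s)
    if (E > 0) { pe <- c(pe, P / E); mid_keep <- c(mid_keep, m) }
  }
  cor(pe, mid_keep, method = "spearman")
}

test_that("boyce_index agrees with the brute-force oracle", {
  set.seed(71)
  eval_s <- runif(3000)
  pres_s <- sample(eval_s, 400, prob = eval_s^2)
  b <- boyce_index(eval_s, pres_s)
  expect_equal(b$bi, boyce_oracle(eval_s, pres_s))
  expect_true(b$valid)
})

test_that("perfect and inverted rankings give BI = +1 / -1", {
  # presence density an exact strictly-increasing transform of suitability
  eval_s <- seq(0, 1, length.out = 500)
  pres_s <- rep(eval_s, times = pmax(1, round(exp(6 * eval_s))))
  expect_equal(boyce_index(eval_s, pres_s)$bi, 1)
  expect_equal(boyce_index(1 - eval_s, 1 - pres_s)$bi, -1)
})

test_that("BI is invariant under strictly monotone transforms of suitability", {
  set.seed(73)
  eval_s <- runif(2000)
  pres_s <- sample(eval_s, 300, prob = eval_s)
  b1 <- boyce_index(eval_s, pres_s)$bi
  f <- function(x) plogis(5 * x - 2)
  b2 <- boyce_index(f(eval_s), f(pres_s))$bi
  expect_equal(b1, b2, tolerance = 0.05)
})

test_that("random suitability centres BI on zero (permutation null)", {
  set.seed(74)
  eval_s <- runif(2000)
  bis <- replicate(200, boyce_index(eval_s, sample(eval_s, 1000))$bi)
  expect_lt(abs(mean(bis)), 0.1)
})

test_that("degenerate inputs are flagged invalid, not mis-scored", {
  b <- boyce_index(rep(0.5, 100), runif(60))
  expect_false(b$valid)
  expect_true(is.na(b$bi))
  b2 <- boyce_index(runif(1000), runif(10))
  expect_false(b2$valid)   # fewer than 50 presences
  expect_match(b2$reason, "50")
})
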