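test_that("blended assemblies hold the community share at exactly 50%", {
  comm <- make_records(100, species = "fam1.gen1.sp1", prefix = "c")
  trad <- make_records(300, species = "fam1.gen1.sp1", source = "traditional",
                       user = "survey", prefix = "t")
  a <- assemble_dataset(comm, trad, "blended", seed = 1)
  expect_equal(nrow(a$records), 200)
  expect_equal(sum(a$records$source == "community"), 100)
  expect_equal(a$community_fraction, 0.5)
  expect_message(sk <- assemble_dataset(comm[0, ], trad, "blended"), "skipped")
  expect_null(sk)
  t_only <- assemble_dataset(comm, trad, "traditional")
  expect_equal(nrow(t_only$records), 300)
  expect_true(all(t_only$records$source != "community"))
  expect_equal(t_only$community_fraction, 0)
})

test_that("the downsampling grid is geometric with the stated endpoints", {
  g <- downsampling_grid()
  expect_equal(g[1], 20)
  expect_equal(g[length(g)], 20000)
  expect_lte(length(g), 123)
  expect_equal(downsampling_grid(n_conditions = 3), c(20, 632, 20000))
  g500 <- downsampling_grid(available = 500)
  expect_true(all(g500 <= 500))
  expect_true(all(diff(g) > 0))
})

test_that("records_to_threshold finds first crossings and summarises", {
  runs <- expand.grid(species_id = c("s1", "s2"), type = "blended",
                      n_records = c(20, 100, 300, 1000), replicate = 1,
                      stringsAsFactors = FALSE)
  runs$bi <- with(runs, ifelse(species_id == "s1",
                               c(0.2, 0.85, 0.93, 0.91)[match(n_records, c(20, 100, 300, 1000))],
                               c(0.2, 0.95, 0.93, 0.91)[match(n_records, c(20, 100, 300, 1000))]))
  runs$taxon <- "bird"; runs$valid <- TRUE
  rt <- records_to_threshold(runs, 0.9)
  expect_equal(rt$per_species$n_at_threshold[rt$per_species$species_id == "s1"], 300)
  expect_equal(rt$per_species$n_at_threshold[rt$per_species$species_id == "s2"], 100)
  expect_equal(rt$summary$mean, 200)
  expect_equal(rt$summary$sd, sd(c(100, 300)))
  # a series never reaching the threshold is undefined, and raising the
  # threshold never lowers the crossing
  rt99 <- records_to_threshold(runs, 0.99)
  expect_true(all(is.na(rt99$per_species$n_at_threshold)))
  rt85 <- records_to_threshold(runs, 0.85)
  expect_true(all(rt85$per_species$n_at_threshold <=
                    rt$per_species$n_at_threshold, na.rm = TRUE))
})

simulate_runs_df <- function(n_species = 20, sizes = c(20, 63, 200, 632, 2000),
                             b0 = 0.5, b_type = 0, b_n = 0.1, b_int = 0.05,
                             sd_species = 0.2, sd_noise = 0.1, seed = 1) {
  # Generative model on the Fisher-z scale, used as a recovery oracle.
  set.seed(seed)
  sp <- sprintf("s%02d", seq_len(n_species))
  re <- rnorm(n_species, 0, sd_species)
  grid <- expand.grid(species_id = sp, type = c("traditional", "blended"),
                      n_records = sizes, stringsAsFactors = FALSE)
  ty <- as.numeric(grid$type == "blended")
  z <- b0 + b_type * ty + b_n * log10(grid$n_records) +
    b_int * ty * log10(grid$n_records) + re[match(grid$species_id, sp)] +
    rnorm(nrow(grid), 0, sd_noise)
  grid$replicate <- 1
  grid$bi <- tanh(z)
  grid$taxon <- "bird"; grid$valid <- TRUE
  grid
}

test_that("the mixed model recovers a known interaction coefficient", {
  runs <- simulate_runs_df(seed = 11)
  fit <- fit_mixed_model(runs)
  co <- fit$coefficients
  inter <- co[grepl(":", co$term), ]
  expect_lt(abs(inter$estimate - 0.05), 2.5 * inter$std_error)
  expect_equal(nrow(co), 4)
  expect_true(all(co$p >= 0 & co$p <= 1))
  expect_gt(fit$random_intercept_sd, 0)
})

test_that("the mixed model rejects inestimable designs and clips |BI| = 1", {
  runs <- simulate_runs_df(n_species = 1, seed = 12)
  expect_error(fit_mixed_model(runs), "2 species")
  runs2 <- simulate_runs_df(seed = 13)
  runs2$bi[1] <- 1   # would be atanh(1) = Inf without clipping
  expect_silent(fit <- fit_mixed_model(runs2))
  expect_true(all(is.finite(fit$coefficients$estimate)))
})

small_world <- function(seed = 5) {
  suppressWarnings(suppressMessages(
    build_experiment_world(n_species = 2, config = landscape_config(30, 30),
                           n_community = 1500, n_traditional = 1500,
                           n_background = 500, seed = seed)))
}

test_that("run_experiment bookkeeping, determinism and invariants", {
  w <- small_world()
  runs <- run_experiment(w$assemblies, c(80, 200), replicates = 2, w$cfg,
                         seed = 9)
  expect_lte(nrow(runs), 2 * 2 * 2 * 2)
  expect_true(all(runs$type %in% c("traditional", "blended")))
  expect_true(all(runs$n_records %in% c(80, 200)))
  runs2 <- run_experiment(w$assemblies, c(80, 200), replicates = 2, w$cfg,
                          seed = 9)
  expect_identical(runs, runs2)
  expect_true(all(is.na(runs$bi) | (runs$bi >= -1 & runs$bi <= 1)))
})

test_that("the world builder produces a coherent pipeline state", {
  w <- small_world(seed = 6)
  expect_gt(length(w$certified), 0)
  expect_true(all(w$p_valid >= 0 & w$p_valid <= 1))
  expect_lt(nrow(w$filtered), nrow(w$community))
  # training records sit outside the block, test presences inside
  expect_true(all(w$test_presences$cell %in% w$cfg$block_cells))
  expect_false(any(w$train_traditional$cell %in% w$cfg$block_cells))
})
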