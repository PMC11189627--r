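# Records table with a controlled species-abundance structure: per taxon,
# `n_rare` species with 10 records each and `n_common` species with 100.
abundance_fixture <- function(taxa, n_rare = 20, n_common = 4) {
  pieces <- lapply(seq_along(taxa), function(ti) {
    tx <- taxa[ti]
    sp_r <- sprintf("fam%d.gen%d.sp%d", ti, 1:n_rare, 1:n_rare)
    sp_c <- sprintf("fam%d.gen%d.sp%d", ti, n_rare + 1:n_common, n_rare + 1:n_common)
    make_records(species = c(rep(sp_r, each = 10), rep(sp_c, each = 100)),
                 taxon = tx, prefix = paste0("t", ti, "x"))
  })
  do.call(rbind, pieces)
}

test_that("stratification applies the <=10 rule and the top-15% quota", {
  recs <- make_records(species = rep(sprintf("fam1.gen%d.sp%d", 1:20, 1:20),
                                     times = 1:20),
                       taxon = "bird", prefix = "s")
  st <- stratify_species(recs)
  cls <- setNames(st$class, st$n_records)
  # ceil(0.15 * 20) = 3 -> counts 18, 19, 20 are common
  expect_setequal(st$species_id[st$class == "common"],
                  sprintf("fam1.gen%d.sp%d", 18:20, 18:20))
  expect_true(all(st$class[st$n_records <= 10] == "rare"))
  expect_equal(st$class[st$n_records == 11], "neither")
  expect_equal(st$class[st$n_records == 10], "rare")
})

test_that("the audit sample matches the stated design: 2(2x145 + 6x70) = 1420", {
  taxa <- c("seed_plant", "insect", "bird", "fish", "mammal", "amphibian",
            "reptile", "mollusc")
  recs <- abundance_fixture(taxa)
  st <- stratify_species(recs)
  smp <- draw_audit_sample(recs, st, seed = 1)
  expect_equal(nrow(smp), 1420)
  tab <- table(smp$taxon, smp$rarity)
  expect_true(all(tab[c("seed_plant", "insect"), ] == 145))
  expect_true(all(tab[setdiff(taxa, c("seed_plant", "insect")), ] == 70))
  expect_identical(smp, draw_audit_sample(recs, st, seed = 1))
  expect_false(identical(smp$record_id,
                         draw_audit_sample(recs, st, seed = 2)$record_id))
})

test_that("an exhausted stratum is taken whole with a warning", {
  recs <- abundance_fixture("bird", n_rare = 5, n_common = 4)  # 50 rare records
  st <- stratify_species(recs)
  expect_warning(smp <- draw_audit_sample(recs, st, seed = 1),
                 "holds 50 < 70")
  expect_equal(sum(smp$rarity == "rare"), 50)
  expect_equal(sum(smp$rarity == "common"), 70)
})

test_that("audit metrics count wild fractions and hierarchical accuracies", {
  truth <- "fam1.gen1.sp1"
  recs <- make_records(
    species = c(rep(truth, 6),            # wild, species correct
                "fam1.gen1.sp9",          # wild, genus correct only
                "fam1.gen9.sp1",          # wild, family correct only
                rep(truth, 2)),           # non-wild
    wild = c(rep(TRUE, 8), FALSE, FALSE),
    true_species = truth, taxon = "bird", prefix = "m")
  m <- audit_metrics(recs)
  row <- m[m$taxon == "bird" & m$rarity == "total", ]
  expect_equal(row$n, 10)
  expect_equal(row$frac_wild, 0.8)
  expect_equal(row$acc_species, 0.75)
  expect_equal(row$acc_genus, 0.875)
  expect_equal(row$acc_family, 1.0)
  # all-correct limit
  m2 <- audit_metrics(make_records(5, prefix = "z"))
  expect_true(all(m2[, c("frac_wild", "acc_species", "acc_genus",
                         "acc_family")] == 1))
  # zero wild records: accuracies undefined
  m3 <- audit_metrics(make_records(4, wild = FALSE, prefix = "w"))
  expect_true(all(is.na(m3$acc_species)))
})

test_that("acc_species <= acc_genus <= acc_family on every stratum", {
  ls <- tiny_landscape()
  cal <- contamination_from_quality("seed_plant")
  pool <- observer_pool(4, 0, 0, misid_rates = list(expert = cal$misid_rate,
                                                    casual = 0, sloppy = 0))
  sp <- virtual_species("fam2.gen3.sp4", "seed_plant", coef = c(urban = 0))
  r <- simulate_occurrences(ls, sp, pool, "community", 2000,
                            cal$contamination, seed = 31)
  m <- audit_metrics(r)
  ok <- !is.na(m$acc_species)
  expect_true(all(m$acc_species[ok] <= m$acc_genus[ok] + 1e-12))
  expect_true(all(m$acc_genus[ok] <= m$acc_family[ok] + 1e-12))
})

test_that("audit recovers configured bird-level generator rates (n = 1000)", {
  ls <- tiny_landscape()
  cal <- contamination_from_quality("bird")   # wild 0.986, species acc 0.986
  pool <- observer_pool(4, 0, 0,
                        misid_rates = list(expert = cal$misid_rate, casual = 0,
                                           sloppy = 0),
                        omission_rates = list(expert = 1, casual = 1, sloppy = 1))
  r <- simulate_occurrences(ls, flat_species("bird"), pool, "community", 1000,
                            cal$contamination, seed = 32)
  m <- audit_metrics(r)
  row <- m[m$taxon == "bird", ]
  ci_wild <- stats::binom.test(sum(r$is_wild_true), 1000)$conf.int
  expect_true(ci_wild[1] <= 0.986 && 0.986 <= ci_wild[2])
  wild <- r[r$is_wild_true, ]
  ci_acc <- stats::binom.test(sum(wild$species_id_reported == wild$species_id_true),
                              nrow(wild))$conf.int
  expect_true(ci_acc[1] <= 0.986 && 0.986 <= ci_acc[2])
  expect_equal(row$frac_wild, mean(r$is_wild_true))
  expect_equal(row$acc_species,
               mean(wild$species_id_reported == wild$species_id_true))
})

test_that("p_valid is the wild x species-accuracy product", {
  m <- data.frame(taxon = c("bird", "fish"), rarity = "total", n = 100,
                  frac_wild = c(1, 0.816), acc_species = c(1, 0.91),
                  acc_genus = 1, acc_family = 1)
  p <- estimate_p_valid(m)
  expect_equal(unname(p["bird"]), 1)
  expect_equal(unname(p["fish"]), 0.816 * 0.91)
  expect_equal(unname(round(p["fish"], 4)), 0.7426)
  m$frac_wild[1] <- 0
  expect_equal(unname(estimate_p_valid(m)["bird"]), 0)
  expect_error(estimate_p_valid(m, "reptile"), "reptile")
})
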