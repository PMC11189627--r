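test_that("profile_users computes public-record statistics", {
  recs <- rbind(make_records(25, user = "alice", prefix = "a"),
                make_records(5, user = "bob", private = TRUE, prefix = "b"))
  sugg <- make_suggestions(c("a0001", "a0002"), "carol", "fam2.gen9.sp9")
  prof <- profile_users(recs, sugg)
  alice <- prof$users[prof$users$user_id == "alice", ]
  expect_equal(alice$n_public_records, 25)
  expect_equal(alice$frac_suggested_misid, 0.08)
  expect_equal(alice$frac_inappropriate, 0)
  bob <- prof$users[prof$users$user_id == "bob", ]
  expect_equal(bob$n_public_records, 0)
  expect_equal(bob$frac_suggested_misid, 0)
})

test_that("a record with several differing suggestions counts once", {
  recs <- make_records(25, user = "alice", prefix = "a")
  sugg <- make_suggestions(c("a0001", "a0001"), c("u9", "u8"), "fam2.gen9.sp9")
  prof <- profile_users(recs, sugg)
  expect_equal(prof$users$frac_suggested_misid[prof$users$user_id == "alice"],
               1 / 25)
  # agreeing suggestions and self-suggestions do not count
  sugg2 <- make_suggestions(c("a0001", "a0002"), c("u9", "alice"),
                            c("fam1.gen1.sp1", "fam2.gen9.sp9"))
  prof2 <- profile_users(recs, sugg2)
  expect_equal(prof2$users$frac_suggested_misid, 0)
})

test_that("suggestions referencing unknown records are an integrity error", {
  recs <- make_records(3, prefix = "a")
  expect_error(profile_users(recs, make_suggestions("zzz", "u9", "x")),
               "unknown record")
})

test_that("certification applies strict inequalities at the boundaries", {
  mk <- function(frac_sugg, frac_inap, n_pub) {
    structure(list(users = data.frame(user_id = "u", n_public_records = n_pub,
                                      frac_suggested_misid = frac_sugg,
                                      frac_inappropriate = frac_inap),
                   taxon = data.frame()),
              class = "user_profiles")
  }
  expect_equal(certify_users(mk(0.08, 0.0, 25)), "u")
  expect_equal(certify_users(mk(0.15, 0.0, 25)), character(0))
  expect_equal(certify_users(mk(0.08, 0.0, 20)), character(0))
  expect_equal(certify_users(mk(0.08, 0.005, 25)), character(0))
  expect_equal(certify_users(mk(0.1499, 0.0049, 21)), "u")
})

test_that("specialists need >30 taxon contributions and below-mean fractions", {
  prof <- structure(list(
    users = data.frame(user_id = c("a", "b", "c"),
                       n_public_records = c(40, 40, 40),
                       frac_suggested_misid = c(0.02, 0.05, 0.08),
                       frac_inappropriate = 0),
    taxon = data.frame(user_id = c("a", "b", "c"),
                       taxon = "bird",
                       n_records_or_suggestions = c(31, 31, 31),
                       frac_suggested = c(0.02, 0.05, 0.08),
                       accuracy = c(0.98, 0.95, 0.92))),
    class = "user_profiles")
  cert <- c("a", "b", "c")
  # mean fraction = 0.05: only a (0.02 < 0.05) qualifies; b is at the mean
  expect_equal(identify_specialists(prof, cert, "bird"), "a")
  # boundary on contributions: exactly 30 is not enough
  prof$taxon$n_records_or_suggestions <- c(30, 31, 31)
  expect_equal(identify_specialists(prof, cert, "bird"), character(0))
  expect_warning(out <- identify_specialists(prof, character(0), "bird"),
                 "no certified")
  expect_equal(out, character(0))
})

test_that("the 8-record rule fixture yields exactly the enumerated survivors", {
  fx <- rule_fixture()
  out <- filter_records(fx$records, fx$suggestions, fx$certified)
  expect_equal(nrow(out), 3)
  expect_setequal(out$record_id, c("k0001", "k0002", "s0001"))
  # certified suggestion overrides the reported identification
  expect_equal(out$species_id_accepted[out$record_id == "s0001"],
               "fam1.gen1.spB")
  expect_equal(nrow(filter_records(make_records(0), certified = "u")), 0)
})

test_that("the latest certified suggestion wins conflicts", {
  recs <- make_records(1, user = "nobody", species = "spA", prefix = "s")
  sugg <- rbind(
    make_suggestions("s0001", "cert1", "spB", as.Date("2022-06-10")),
    make_suggestions("s0001", "cert2", "spC", as.Date("2022-06-20")),
    make_suggestions("s0001", "uncert", "spD", as.Date("2022-06-30")))
  out <- filter_records(recs, sugg, certified = c("cert1", "cert2"))
  expect_equal(out$species_id_accepted, "spC")
})

test_that("filtering is idempotent and monotone in the certified set", {
  set.seed(42)
  recs <- make_records(200, user = sample(paste0("u", 1:8), 200, TRUE),
                       private = runif(200) < 0.1,
                       reported = runif(200) < 0.05,
                       labeled_nonwild = runif(200) < 0.1, prefix = "m")
  sugg <- make_suggestions(sample(recs$record_id, 40),
                           sample(paste0("u", 1:8), 40, TRUE), "spZ")
  small <- c("u1", "u2"); big <- c("u1", "u2", "u3", "u4")
  f_small <- filter_records(recs, sugg, small)
  f_big <- filter_records(recs, sugg, big)
  expect_true(all(f_small$record_id %in% f_big$record_id))
  again <- filter_records(f_small, sugg, small)
  expect_equal(again, f_small)
})

test_that("filtering lowers the true misidentification rate on synthetic data", {
  ls <- tiny_landscape(20, 20)
  pool <- observer_pool(5, 10, 10)
  raw <- simulate_occurrences(ls, flat_species(), pool, "community", 5000,
                              contamination_config(nonwild_fraction = 0.1,
                                                   private_fraction = 0.05),
                              seed = 21)
  sugg <- simulate_suggestions(raw, pool, seed = 22)
  prof <- profile_users(raw, sugg)
  cert <- certify_users(prof)
  expect_gt(length(cert), 0)
  kept <- filter_records(raw, sugg, cert)
  expect_gt(nrow(kept), 0)
  misid_raw <- mean(raw$species_id_reported != raw$species_id_true)
  misid_kept <- mean(kept$species_id_accepted != kept$species_id_true)
  expect_lt(misid_kept, misid_raw)
})
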