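# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

tiny_landscape <- function(n_rows = 12, n_cols = 12, seed = 1, ...) {
  generate_landscape(landscape_config(n_rows, n_cols, autocorr_range = 3,
                                      allow_small = TRUE, ...), seed = seed)
}

# A species with constant suitability 0.5 everywhere (zero coefficients).
flat_species <- function(taxon = "bird") {
  virtual_species("fam1.gen1.sp1", taxon, coef = c(urban = 0))
}

# Hand-built occurrence records with sensible defaults; all arguments are
# recycled to the longest length.
make_records <- function(n = NULL, species = "fam1.gen1.sp1", taxon = "bird",
                         user = "u1", cell = 0L, wild = TRUE,
                         labeled_nonwild = FALSE, private = FALSE,
                         reported = FALSE, cultural = FALSE,
                         true_species = species, source = "community",
                         timestamp = as.Date("2022-06-01"), prefix = "r") {
  if (is.null(n)) {
    n <- max(lengths(list(species, taxon, user, cell, wild, labeled_nonwild,
                          private, reported, cultural, true_species, source)))
  }
  cell <- as.integer(rep_len(cell, n))
  df <- data.frame(
    record_id = sprintf("%s%04d", prefix, seq_len(n)),
    species_id_reported = rep_len(species, n),
    species_id_true = rep_len(true_species, n),
    taxon = rep_len(taxon, n),
    row = cell %/% 100L, col = cell %% 100L, cell = cell,
    timestamp = rep_len(timestamp, n),
    user_id = rep_len(user, n),
    source = rep_len(source, n),
    is_wild_true = rep_len(wild, n),
    labeled_nonwild = rep_len(labeled_nonwild, n),
    is_private = rep_len(private, n),
    is_reported = rep_len(reported, n),
    at_cultural_center = rep_len(cultural, n)
  )
  class(df) <- c("occurrence_records", "data.frame")
  df
}

make_suggestions <- function(record_id, user_id, suggested,
                             timestamp = as.Date("2022-06-10")) {
  n <- max(lengths(list(record_id, user_id, suggested)))
  data.frame(record_id = rep_len(record_id, n),
             user_id = rep_len(user_id, n),
             suggested_species_id = rep_len(suggested, n),
             timestamp = rep_len(timestamp, n))
}

# Rook-contiguity Moran's I on a matrix (independent oracle for spatial
# autocorrelation).
morans_i <- function(m) {
  z <- m - mean(m)
  num <- sum(z[, -1] * z[, -ncol(z)]) + sum(z[-1, ] * z[-nrow(z), ])
  w <- (nrow(z) * (ncol(z) - 1) + (nrow(z) - 1) * ncol(z))
  (length(z) / w) * num / sum(z^2)
}

# Effort surface built directly from given per-cell counts.
surface_from_counts <- function(counts, landscape) {
  recs <- make_records(cell = rep(seq_along(counts) - 1L, counts),
                       prefix = "e")
  effort_all_taxa(recs, landscape)
}

# Canonical 8-record filtering-rule fixture: exactly 3 records survive.
rule_fixture <- function() {
  recs <- rbind(
    make_records(1, user = "cert1", private = TRUE, prefix = "p"),
    make_records(1, user = "cert1", reported = TRUE, prefix = "q"),
    make_records(1, user = "cert1", labeled_nonwild = TRUE, prefix = "w"),
    make_records(1, user = "cert1", cultural = TRUE, prefix = "x"),
    make_records(2, user = "cert1", prefix = "k"),
    make_records(1, user = "nobody1", prefix = "n"),
    make_records(1, user = "nobody2", species = "fam1.gen1.spA", prefix = "s"))
  sugg <- make_suggestions("s0001", "cert2", "fam1.gen1.spB")
  list(records = recs, suggestions = sugg, certified = c("cert1", "cert2"))
}

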