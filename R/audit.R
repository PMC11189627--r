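#' Audit design configuration
#'
#' Rare species are those with at most `rare_max_occurrences` records in the
#' community dataset; common species are the top `common_top_fraction` of
#' species by record count within their taxon. The audit draws
#' `sample_size_large_taxa` records per rarity class for the two
#' record-dominant taxa (seed plants and insects) and
#' `sample_size_other_taxa` for the rest, giving 2 x (2 x 145 + 6 x 70) =
#' 1420 audited records under the defaults with all eight taxa.
#'
#' @param rare_max_occurrences maximum record count of a rare species.
#' @param common_top_fraction top fraction of species (by count, per taxon)
#'   classed common.
#' @param sample_size_large_taxa per-stratum sample size for `large_taxa`.
#' @param sample_size_other_taxa per-stratum sample size for other taxa.
#' @param large_taxa taxa audited at the larger sample size.
#' @return object of class `audit_config`.
#' @export
audit_config <- function(rare_max_occurrences = 10, common_top_fraction = 0.15,
                         sample_size_large_taxa = 145,
                         sample_size_other_taxa = 70,
                         large_taxa = c("seed_plant", "insect")) {
  stopifnot(rare_max_occurrences > 0, common_top_fraction > 0,
            common_top_fraction < 1, sample_size_large_taxa > 0,
            sample_size_other_taxa > 0)
  structure(list(rare_max_occurrences = rare_max_occurrences,
                 common_top_fraction = common_top_fraction,
                 sample_size_large_taxa = sample_size_large_taxa,
                 sample_size_other_taxa = sample_size_other_taxa,
                 large_taxa = large_taxa),
            class = "audit_config")
}

audit_species_col <- function(records) {
  if ("species_id_accepted" %in% names(records)) "species_id_accepted"
  else "species_id_reported"
}

#' Stratify species into rare / common / neither
#'
#' Rare: record count <= `rare_max_occurrences`. Common: within the top
#' `common_top_fraction` of species by record count in the taxon, with a
#' ceiling quota (`ceiling(fraction * n_species)`); ties broken by count rank.
#' A species qualifying for both (possible in tiny taxa) is classed common.
#'
#' @param records `occurrence_records` (non-empty).
#' @param config an [audit_config()].
#' @return data.frame with `species_id`, `taxon`, `n_records`, `class`.
#' @export
stratify_species <- function(records, config = audit_config()) {
  if (nrow(records) == 0) stop_config("cannot stratify an empty record set")
  sp_col <- audit_species_col(records)
  counts <- stats::aggregate(list(n_records = records$record_id),
                             by = list(species_id = records[[sp_col]],
                                       taxon = records$taxon),
                             FUN = length)
  counts$class <- "neither"
  for (tx in unique(counts$taxon)) {
    i <- which(counts$taxon == tx)
    quota <- ceiling(config$common_top_fraction * length(i))
    ord <- i[order(-counts$n_records[i], counts$species_id[i])]
    common <- ord[seq_len(min(quota, length(ord)))]
    counts$class[common] <- "common"
    rare <- i[counts$n_records[i] <= config$rare_max_occurrences]
    counts$class[setdiff(rare, common)] <- "rare"
  }
  rownames(counts) <- NULL
  counts
}

#' Draw the audit sample
#'
#' Per taxon and rarity class, draws the configured number of records
#' uniformly without replacement from records of species in that class. A
#' stratum holding fewer records than requested is taken whole, with a
#' warning.
#'
#' @param records `occurrence_records`.
#' @param strata a [stratify_species()] result.
#' @param config an [audit_config()].
#' @param seed integer seed.
#' @return the sampled records with a `rarity` column.
#' @export
draw_audit_sample <- function(records, strata, config = audit_config(),
                              seed = 1L) {
  sp_col <- audit_species_col(records)
  with_seed(seed, {
    pieces <- list()
    for (tx in sort(unique(records$taxon))) {
      want <- if (tx %in% config$large_taxa) config$sample_size_large_taxa
              else config$sample_size_other_taxa
      for (cls in c("rare", "common")) {
        sp <- strata$species_id[strata$taxon == tx & strata$class == cls]
        pool <- records[records$taxon == tx & records[[sp_col]] %in% sp, ,
                        drop = FALSE]
        if (nrow(pool) == 0) {
          warning(sprintf("empty %s stratum in taxon '%s'", cls, tx))
          next
        }
        if (nrow(pool) < want) {
          warning(sprintf("stratum %s/%s holds %d < %d records; taking all",
                          tx, cls, nrow(pool), want))
          take <- pool
        } else {
          take <- pool[sample.int(nrow(pool), want), , drop = FALSE]
        }
        take$rarity <- cls
        pieces[[paste(tx, cls)]] <- take
      }
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

metrics_row <- function(d, taxon, rarity) {
  sp_col <- audit_species_col(d)
  wild <- d[d$is_wild_true, , drop = FALSE]
  acc <- function(level_fn) {
    if (nrow(wild) == 0) return(NA_real_)
    mean(level_fn(wild[[sp_col]]) == level_fn(wild$species_id_true))
  }
  data.frame(taxon = taxon, rarity = rarity, n = nrow(d),
             frac_wild = if (nrow(d)) mean(d$is_wild_true) else NA_real_,
             acc_species = acc(identity), acc_genus = acc(genus_of),
             acc_family = acc(family_of))
}

#' Audit quality metrics
#'
#' Computes, per taxon and rarity class (plus per-taxon and overall totals),
#' the fraction of audited records documenting wild individuals and the
#' identification accuracy at species, genus and family level among wild
#' records (species are identified only for wild individuals, so accuracies
#' condition on wildness). With zero wild records the accuracies are
#' reported as `NA`.
#'
#' Requires truth fields (`species_id_true`, `is_wild_true`), which synthetic
#' data carries; for real data these would come from expert reidentification.
#'
#' @param sample audited records (ideally from [draw_audit_sample()]; any
#'   record set with truth fields works). A missing `rarity` column is
#'   treated as a single `"total"` stratum.
#' @return data.frame of metrics rows; satisfies
#'   `acc_species <= acc_genus <= acc_family` on every stratum.
#' @export
audit_metrics <- function(sample) {
  assert_columns(sample, c("species_id_true", "is_wild_true", "taxon"))
  if (!"rarity" %in% names(sample)) sample$rarity <- "total"
  rows <- list()
  for (tx in c(sort(unique(sample$taxon)))) {
    d_tx <- sample[sample$taxon == tx, , drop = FALSE]
    rows[[paste(tx, "total")]] <- metrics_row(d_tx, tx, "total")
    for (cls in intersect(c("rare", "common"), unique(d_tx$rarity))) {
      rows[[paste(tx, cls)]] <-
        metrics_row(d_tx[d_tx$rarity == cls, , drop = FALSE], tx, cls)
    }
  }
  rows[["total total"]] <- metrics_row(sample, "total", "total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-taxon valid-record probability
#'
#' A record is valid when it documents a wild individual that is correctly
#' identified at species level, so `p_valid = frac_wild * acc_species`,
#' taken from each taxon's `total` metrics row. This is the quantity the
#' consensus test-set rule consumes.
#'
#' @param metrics an [audit_metrics()] result.
#' @param taxa taxa to return (default: all in `metrics` except the overall
#'   `"total"` row).
#' @return named numeric vector of probabilities in \[0, 1\].
#' @export
estimate_p_valid <- function(metrics, taxa = NULL) {
  tot <- metrics[metrics$rarity == "total" & metrics$taxon != "total", ,
                 drop = FALSE]
  if (is.null(taxa)) taxa <- tot$taxon
  i <- match(taxa, tot$taxon)
  if (anyNA(i)) {
    stop_config("no audit metrics for taxon/taxa: %s",
                paste(taxa[is.na(i)], collapse = ", "))
  }
  p <- tot$frac_wild[i] * tot$acc_species[i]
  p[tot$frac_wild[i] == 0] <- 0  # no wild records: nothing can be valid
  stats::setNames(p, taxa)
}
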