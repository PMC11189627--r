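#' Certification thresholds for community observers
#'
#' Defaults mirror the operational rules of the data-collection platform:
#' a certified observer has < 15% of public records suggested as
#' misidentified by other users, < 0.5% of public records flagged as
#' inappropriate, and > 20 public records; a specialist is a certified
#' observer with > 30 records-or-suggestions in a taxon and a below-average
#' suggested-as-misidentified fraction there. All inequalities are strict.
#'
#' @param max_frac_suggested upper bound (exclusive) on the fraction of
#'   public records suggested as misidentified.
#' @param max_frac_inappropriate upper bound (exclusive) on the fraction of
#'   public records flagged.
#' @param min_public_records lower bound (exclusive) on public record count.
#' @param specialist_min_contributions lower bound (exclusive) on per-taxon
#'   records + suggestions for specialist status.
#' @return object of class `certification_config`.
#' @export
certification_config <- function(max_frac_suggested = 0.15,
                                 max_frac_inappropriate = 0.005,
                                 min_public_records = 20,
                                 specialist_min_contributions = 30) {
  stopifnot(max_frac_suggested > 0, max_frac_inappropriate > 0,
            min_public_records > 0, specialist_min_contributions > 0)
  structure(list(max_frac_suggested = max_frac_suggested,
                 max_frac_inappropriate = max_frac_inappropriate,
                 min_public_records = min_public_records,
                 specialist_min_contributions = specialist_min_contributions),
            class = "certification_config")
}

# A record counts as "suggested as misidentified" if at least one suggestion
# from a different user proposes a species other than the reported one;
# multiplicity of suggestions on one record does not matter.
suggested_misid_record_ids <- function(records, suggestions) {
  if (is.null(suggestions) || nrow(suggestions) == 0) return(character(0))
  m <- merge(suggestions,
             records[, c("record_id", "species_id_reported", "user_id")],
             by = "record_id", suffixes = c("", ".author"))
  m <- m[m$user_id != m$user_id.author &
           m$suggested_species_id != m$species_id_reported, , drop = FALSE]
  unique(m$record_id)
}

#' Profile community observers from their records and suggestions
#'
#' Computes, per distinct community observer, the statistics that
#' certification consumes: public record count, the fraction of public
#' records that received a differing identification suggestion from another
#' user, the fraction flagged as inappropriate, and per-taxon contribution
#' counts (records plus suggestions made) with per-taxon suggested fractions.
#'
#' Private records are excluded from all "public" counts. Observers with zero
#' public records get proportions of 0 (they cannot be certified anyway,
#' given the record-count threshold).
#'
#' @param records community `occurrence_records`.
#' @param suggestions suggestion table as from [simulate_suggestions()];
#'   every `record_id` must exist in `records`.
#' @return object of class `user_profiles`: list with `users` (one row per
#'   observer) and `taxon` (one row per observer x taxon).
#' @export
profile_users <- function(records, suggestions = NULL) {
  assert_columns(records, c("record_id", "species_id_reported", "taxon",
                            "user_id", "source", "is_private", "is_reported"))
  records <- records[records$source == "community", , drop = FALSE]
  if (!is.null(suggestions) && nrow(suggestions)) {
    unknown <- setdiff(suggestions$record_id, records$record_id)
    if (length(unknown)) {
      stop_config("suggestion(s) reference unknown record(s): %s",
                  paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  users <- unique(records$user_id)
  pub <- records[!records$is_private, , drop = FALSE]
  misid_ids <- suggested_misid_record_ids(records, suggestions)
  pub$suggested <- pub$record_id %in% misid_ids

  agg <- function(v, f, default = 0) {
    out <- stats::setNames(rep(default, length(users)), users)
    if (length(v)) {
      t <- tapply(v, f, mean)
      out[names(t)] <- t
    }
    out
  }
  n_public <- stats::setNames(rep(0L, length(users)), users)
  tb <- table(pub$user_id)
  n_public[names(tb)] <- as.integer(tb)
  prof <- data.frame(
    user_id = users,
    n_public_records = as.integer(n_public[users]),
    frac_suggested_misid = as.numeric(agg(pub$suggested, pub$user_id)[users]),
    frac_inappropriate = as.numeric(agg(pub$is_reported, pub$user_id)[users]),
    row.names = NULL
  )

  # Per-taxon contributions: the observer's public records in the taxon plus
  # the suggestions they made on records of the taxon.
  rec_tab <- as.data.frame(table(user_id = pub$user_id, taxon = pub$taxon),
                           stringsAsFactors = FALSE)
  names(rec_tab)[3] <- "n_records"
  if (!is.null(suggestions) && nrow(suggestions)) {
    sugg_tax <- merge(suggestions, records[, c("record_id", "taxon")],
                      by = "record_id")
    sug_tab <- as.data.frame(table(user_id = sugg_tax$user_id,
                                   taxon = sugg_tax$taxon),
                             stringsAsFactors = FALSE)
    names(sug_tab)[3] <- "n_suggestions"
  } else {
    sug_tab <- data.frame(user_id = character(0), taxon = character(0),
                          n_suggestions = integer(0))
  }
  tax <- merge(rec_tab, sug_tab, by = c("user_id", "taxon"), all = TRUE)
  tax$n_records[is.na(tax$n_records)] <- 0
  tax$n_suggestions[is.na(tax$n_suggestions)] <- 0
  tax$n_records_or_suggestions <- tax$n_records + tax$n_suggestions
  tax <- tax[tax$n_records_or_suggestions > 0 & tax$user_id %in% users, ,
             drop = FALSE]
  key <- paste(pub$user_id, pub$taxon)
  fs <- tapply(pub$suggested, key, mean)
  tax$frac_suggested <- as.numeric(fs[paste(tax$user_id, tax$taxon)])
  tax$frac_suggested[is.na(tax$frac_suggested)] <- 0
  tax$accuracy <- 1 - tax$frac_suggested
  rownames(tax) <- NULL

  structure(list(users = prof, taxon = tax), class = "user_profiles")
}

#' Certify observers
#'
#' An observer is certified iff `frac_suggested_misid < 0.15`,
#' `frac_inappropriate < 0.005` and `n_public_records > 20` (strict
#' inequalities; thresholds from `config`).
#'
#' @param profiles a [profile_users()] result.
#' @param config a [certification_config()].
#' @return character vector of certified user ids.
#' @export
certify_users <- function(profiles, config = certification_config()) {
  stopifnot(inherits(profiles, "user_profiles"))
  u <- profiles$users
  u$user_id[u$frac_suggested_misid < config$max_frac_suggested &
              u$frac_inappropriate < config$max_frac_inappropriate &
              u$n_public_records > config$min_public_records]
}

#' Identify specialist observers for a taxon
#'
#' A specialist is a certified observer with strictly more than
#' `specialist_min_contributions` records-or-suggestions in the taxon and a
#' per-taxon suggested-as-misidentified fraction strictly below the mean of
#' certified observers active in that taxon.
#'
#' @param profiles a [profile_users()] result.
#' @param certified character vector from [certify_users()].
#' @param taxon taxon name.
#' @param config a [certification_config()].
#' @return character vector of specialist user ids (empty, with a warning,
#'   when the taxon has no certified observers).
#' @export
identify_specialists <- function(profiles, certified, taxon,
                                 config = certification_config()) {
  stopifnot(inherits(profiles, "user_profiles"))
  tx <- profiles$taxon[profiles$taxon$taxon == taxon, , drop = FALSE]
  tx <- tx[tx$user_id %in% certified, , drop = FALSE]
  if (nrow(tx) == 0) {
    warning(sprintf("no certified observers active in taxon '%s'", taxon))
    return(character(0))
  }
  mean_frac <- mean(tx$frac_suggested)
  tx$user_id[tx$n_records_or_suggestions > config$specialist_min_contributions &
               tx$frac_suggested < mean_frac]
}

#' Filter community occurrence records
#'
#' Applies the automatic exclusion rules for community-sourced records:
#' drops records that are flagged/reported, private, labelled non-wild, or
#' located at cultural-centre cells (zoos, botanical gardens, aquariums, pet
#' stores; `masked_cells` plus the `at_cultural_center` flag); of the
#' remainder, keeps a record only if its author is certified or it carries at
#' least one identification suggestion from a certified observer. When a
#' certified observer's suggestion differs from the reported species, the
#' accepted identification follows the certified suggestion (most recent
#' certified suggestion wins on conflicts).
#'
#' The operation is idempotent and its survivor set grows monotonically with
#' the certified set.
#'
#' @param records community `occurrence_records`.
#' @param suggestions suggestion table (may be `NULL`).
#' @param certified character vector of certified user ids.
#' @param masked_cells integer cell ids to exclude (cultural centres etc.).
#' @return the surviving records with a `species_id_accepted` column.
#' @export
filter_records <- function(records, suggestions = NULL, certified = character(0),
                           masked_cells = integer(0)) {
  if (nrow(records) == 0) {
    out <- records
    out$species_id_accepted <- character(0)
    return(out)
  }
  assert_columns(records, c("record_id", "species_id_reported", "user_id",
                            "cell", "labeled_nonwild", "is_private",
                            "is_reported", "at_cultural_center"))
  keep <- !records$is_reported & !records$is_private &
    !records$labeled_nonwild & !records$at_cultural_center &
    !(records$cell %in% masked_cells)
  out <- records[keep, , drop = FALSE]

  cert_sugg <- NULL
  if (!is.null(suggestions) && nrow(suggestions)) {
    cert_sugg <- suggestions[suggestions$user_id %in% certified, , drop = FALSE]
  }
  has_cert_sugg <- if (!is.null(cert_sugg) && nrow(cert_sugg)) {
    out$record_id %in% cert_sugg$record_id
  } else {
    rep(FALSE, nrow(out))
  }
  out <- out[out$user_id %in% certified | has_cert_sugg, , drop = FALSE]

  # Accepted identification: certified suggestions override the author.
  out$species_id_accepted <- out$species_id_reported
  if (!is.null(cert_sugg) && nrow(cert_sugg)) {
    cs <- cert_sugg[cert_sugg$record_id %in% out$record_id, , drop = FALSE]
    if (nrow(cs)) {
      cs <- cs[order(cs$timestamp), , drop = FALSE]
      latest <- cs[!duplicated(cs$record_id, fromLast = TRUE), , drop = FALSE]
      i <- match(out$record_id, latest$record_id)
      hit <- !is.na(i)
      out$species_id_accepted[hit] <- latest$suggested_species_id[i[hit]]
    }
  }
  rownames(out) <- NULL
  out
}
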