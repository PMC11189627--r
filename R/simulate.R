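#' Contamination configuration for the synthetic observation process
#'
#' Controls how simulated occurrence records deviate from the truth:
#' non-wild individuals (cultivated/captive organisms photographed where
#' people live), misidentifications (reported species differs from the true
#' one, at per-observer rates), and record-level flags (private records,
#' records reported as inappropriate by other users).
#'
#' Non-wild records are placed with probability proportional to the `urban`
#' layer: cultivated and captive individuals occur where people are.
#' Misidentified records get a decoy id at a taxonomic distance drawn from
#' `misid_level_probs` (within genus / within family / outside family), which
#' is what makes genus- and family-level audit accuracies meaningful.
#'
#' @param nonwild_fraction probability a record documents a non-wild
#'   individual.
#' @param misid_level_probs length-3 numeric (genus, family, outside) summing
#'   to 1: taxonomic distance of a misidentification.
#' @param private_fraction probability a community record is private.
#' @param reported_fraction probability a record is flagged as inappropriate.
#' @param traditional_misid_rate misidentification rate applied to survey
#'   (traditional) records, which carry no per-observer rates.
#' @return object of class `contamination_config`.
#' @export
contamination_config <- function(nonwild_fraction = 0,
                                 misid_level_probs = c(genus = 0.3, family = 0.35, outside = 0.35),
                                 private_fraction = 0,
                                 reported_fraction = 0,
                                 traditional_misid_rate = 0) {
  stopifnot(nonwild_fraction >= 0, nonwild_fraction <= 1,
            length(misid_level_probs) == 3,
            abs(sum(misid_level_probs) - 1) < 1e-8)
  structure(list(nonwild_fraction = nonwild_fraction,
                 misid_level_probs = misid_level_probs,
                 private_fraction = private_fraction,
                 reported_fraction = reported_fraction,
                 traditional_misid_rate = traditional_misid_rate),
            class = "contamination_config")
}

#' Contamination calibrated to a taxon's measured record quality
#'
#' Converts the per-taxon wild fractions and identification accuracies of
#' [taxon_quality_defaults()] into generator parameters: the non-wild
#' fraction, the per-record misidentification rate among wild records, and
#' the taxonomic-distance mixture of misidentifications implied by the gap
#' between species-, genus- and family-level accuracy.
#'
#' @param taxon taxon name.
#' @param quality optionally, a data.frame shaped like
#'   [taxon_quality_defaults()].
#' @return list with `contamination` (a [contamination_config()]) and
#'   `misid_rate` (per-record misidentification probability to assign to
#'   observers).
#' @export
contamination_from_quality <- function(taxon, quality = taxon_quality_defaults()) {
  row <- quality[quality$taxon == taxon, ]
  if (nrow(row) != 1) stop_config("unknown taxon '%s'", taxon)
  m <- 1 - row$acc_species
  if (m > 0) {
    p_genus <- max(0, (row$acc_genus - row$acc_species) / m)
    p_family <- max(0, (row$acc_family - row$acc_genus) / m)
    p_out <- max(0, 1 - p_genus - p_family)
    probs <- c(genus = p_genus, family = p_family, outside = p_out)
    probs <- probs / sum(probs)
  } else {
    probs <- c(genus = 0.3, family = 0.35, outside = 0.35)
  }
  list(contamination = contamination_config(
         nonwild_fraction = 1 - row$frac_wild,
         misid_level_probs = probs),
       misid_rate = m)
}

misid_decoy <- function(species_id, level) {
  # Decoy ids share the true genus/family as dictated by `level`, and are
  # guaranteed to differ from the truth at the requested level.
  g <- genus_of(species_id)
  f <- family_of(species_id)
  switch(level,
    genus = paste0(g, ".sp", 9000L + sample.int(99L, 1L)),
    family = paste0(f, ".gen", 9000L + sample.int(99L, 1L), ".sp1"),
    outside = sprintf("fam%d.gen1.sp1", 9000L + sample.int(99L, 1L)))
}

empty_records <- function() {
  data.frame(record_id = character(0), species_id_reported = character(0),
             species_id_true = character(0), taxon = character(0),
             row = integer(0), col = integer(0), cell = integer(0),
             timestamp = as.Date(character(0)), user_id = character(0),
             source = character(0), is_wild_true = logical(0),
             labeled_nonwild = logical(0), is_private = logical(0),
             is_reported = logical(0), at_cultural_center = logical(0))
}

#' Simulate occurrence records under a biased observation process
#'
#' Draws presence records of a virtual species under one of two effort
#' models mirroring the empirical contrast between survey programmes and
#' smartphone-app data: `traditional` effort is biased towards natural areas
#' (`effort(cell) proportional to natural(cell)^gamma`, default `gamma = 2`),
#' while `community` effort is near-uniform along the urban-natural gradient
#' (`natural(cell)^community_exponent`, default exponent 0). A presence
#' record's cell is drawn with probability proportional to
#' `effort(cell) * s_true(cell)`.
#'
#' Community records are attributed to observers from `pool` (sampled by
#' activity weight); each observer misidentifies with their own `misid_rate`
#' and omits the non-wild label with their own omission rate. Traditional
#' records are attributed to a survey source; a configurable fraction come
#' from a massive freshwater-like sub-source (`traditional_freshwater`).
#'
#' @param landscape an `sdm_landscape`.
#' @param species a [virtual_species()].
#' @param pool an [observer_pool()]; required when `effort_model =
#'   "community"`.
#' @param effort_model `"community"` or `"traditional"`.
#' @param n_records number of records to draw (>= 0).
#' @param contamination a [contamination_config()].
#' @param seed integer seed; full determinism under fixed seeds.
#' @param gamma naturalness-bias exponent for traditional effort.
#' @param community_exponent naturalness exponent for community effort
#'   (0 = uniform).
#' @param freshwater_fraction fraction of traditional records tagged
#'   `traditional_freshwater` (calibrated to the dominance of freshwater
#'   census records among survey data).
#' @param effort_multiplier optional per-cell effort multiplier (length
#'   `n_cells`), typically a spatially clustered human-activity field shared
#'   across species: community recording concentrates where people are
#'   active even though it spans the whole urban-natural gradient.
#' @param n_sites for the traditional effort model only: number of fixed
#'   survey stations, or an integer vector of 0-based station cells (so one
#'   station network can be shared across species). The freshwater-census
#'   sub-source draws its records exclusively on stations (fixed plots
#'   resampled repeatedly, hence heavy within-site redundancy), while the
#'   remaining traditional records (museum specimens, scattered surveys)
#'   keep the continuous naturalness-biased effort surface. `NULL` (the
#'   default) makes all traditional records use the continuous surface.
#' @param cultural_cells integer cell ids of zoos/botanical gardens etc.;
#'   records falling there are flagged.
#' @param dates length-2 Date vector; timestamps drawn uniformly in between.
#' @return data.frame of class `occurrence_records`; one row per record with
#'   reported and true species ids, cell coordinates, observer, source and
#'   flag columns.
#' @export
simulate_occurrences <- function(landscape, species, pool = NULL,
                                 effort_model = c("community", "traditional"),
                                 n_records,
                                 contamination = contamination_config(),
                                 seed = 1L, gamma = 2, community_exponent = 0,
                                 freshwater_fraction = 0.7,
                                 effort_multiplier = NULL, n_sites = NULL,
                                 cultural_cells = integer(0),
                                 dates = as.Date(c("2022-01-01", "2022-12-31"))) {
  effort_model <- match.arg(effort_model)
  stopifnot(inherits(landscape, "sdm_landscape"),
            inherits(species, "virtual_species"), n_records >= 0)
  if (effort_model == "community" && (is.null(pool) || nrow(pool) == 0)) {
    stop_config("community effort model requires a non-empty observer pool")
  }
  if (n_records == 0) return(structure(empty_records(),
                                       class = c("occurrence_records", "data.frame")))
  with_seed(seed, {
    nat <- as.vector(t(landscape$layers$natural))
    urb <- as.vector(t(landscape$layers$urban))
    effort <- if (effort_model == "traditional") nat^gamma else nat^community_exponent
    if (!is.null(effort_multiplier)) {
      stopifnot(length(effort_multiplier) == length(effort),
                all(effort_multiplier >= 0))
      effort <- effort * effort_multiplier
    }
    if (!all(is.finite(effort))) stop_config("effort weights must be finite")
    s <- true_suitability(species, landscape)
    pw <- effort * s
    if (sum(pw) <= 0) stop_config("effort x suitability is zero everywhere")
    n_cells <- length(pw)

    is_fresh <- logical(n_records)
    if (effort_model == "traditional") {
      is_fresh <- stats::runif(n_records) < freshwater_fraction
    }
    cells0 <- integer(n_records)
    scatter <- !is_fresh
    if (any(scatter)) {
      cells0[scatter] <- sample.int(n_cells, sum(scatter), replace = TRUE,
                                    prob = pw) - 1L
    }
    if (any(is_fresh)) {
      pw_site <- pw
      if (!is.null(n_sites)) {
        sites <- if (length(n_sites) > 1L) {
          as.integer(n_sites) + 1L      # explicit 0-based station cells
        } else {
          sample.int(n_cells, min(n_sites, n_cells), prob = effort)
        }
        pw_site <- numeric(n_cells)
        pw_site[sites] <- pw[sites]
        if (sum(pw_site) <= 0) pw_site <- pw
      }
      cells0[is_fresh] <- sample.int(n_cells, sum(is_fresh), replace = TRUE,
                                     prob = pw_site) - 1L
    }

    wild <- stats::runif(n_records) >= contamination$nonwild_fraction
    if (any(!wild)) {
      # Non-wild individuals sit where people are: re-place those records
      # with probability proportional to the urban fraction.
      uw <- urb + 1e-9
      cells0[!wild] <- sample.int(n_cells, sum(!wild), replace = TRUE, prob = uw) - 1L
    }

    if (effort_model == "community") {
      idx <- sample.int(nrow(pool), n_records, replace = TRUE,
                        prob = pool$activity_weight)
      user_id <- pool$user_id[idx]
      misid_p <- pool$misid_rate[idx]
      omit_p <- pool$nonwild_label_omission_rate[idx]
      source <- rep("community", n_records)
    } else {
      user_id <- rep("survey", n_records)
      misid_p <- rep(contamination$traditional_misid_rate, n_records)
      omit_p <- rep(0, n_records)
      source <- ifelse(is_fresh, "traditional_freshwater", "traditional")
    }

    misid <- stats::runif(n_records) < misid_p
    reported <- rep(species$species_id, n_records)
    if (any(misid)) {
      lv <- sample(names(contamination$misid_level_probs), sum(misid),
                   replace = TRUE, prob = contamination$misid_level_probs)
      reported[misid] <- vapply(lv, function(l) misid_decoy(species$species_id, l),
                                character(1))
    }

    labeled_nonwild <- !wild & (stats::runif(n_records) >= omit_p)
    rc <- cell_to_rowcol(cells0, landscape)
    out <- data.frame(
      record_id = sprintf("%s-%s-%06d", substr(effort_model, 1, 1),
                          species$species_id, seq_len(n_records)),
      species_id_reported = reported,
      species_id_true = species$species_id,
      taxon = species$taxon,
      row = rc$row, col = rc$col, cell = cells0,
      timestamp = dates[1] + floor(stats::runif(n_records) *
                                     (as.numeric(dates[2] - dates[1]) + 1)),
      user_id = user_id, source = source,
      is_wild_true = wild, labeled_nonwild = labeled_nonwild,
      is_private = source == "community" &
        stats::runif(n_records) < contamination$private_fraction,
      is_reported = stats::runif(n_records) < contamination$reported_fraction,
      at_cultural_center = cells0 %in% cultural_cells
    )
    structure(out, class = c("occurrence_records", "data.frame"))
  })
}

#' Simulate identification suggestions from other observers
#'
#' Emulates the community-review loop: other observers (experts with higher
#' probability) look at a record and suggest a different identification.
#' Misidentified records are caught with probability `detect_rate` (the
#' suggestion then carries the true species); correct records attract a
#' spurious differing suggestion with probability `false_rate`.
#'
#' @param records community `occurrence_records`.
#' @param pool an [observer_pool()].
#' @param detect_rate probability a misidentified record receives a
#'   corrective suggestion.
#' @param false_rate probability a correct record receives a (wrong)
#'   suggestion.
#' @param seed integer seed.
#' @return data.frame with columns `record_id`, `user_id`,
#'   `suggested_species_id`, `timestamp`.
#' @export
simulate_suggestions <- function(records, pool, detect_rate = 0.8,
                                 false_rate = 0.02, seed = 1L) {
  assert_columns(records, c("record_id", "species_id_reported",
                            "species_id_true", "user_id", "timestamp"))
  with_seed(seed, {
    misid <- records$species_id_reported != records$species_id_true
    gets <- ifelse(misid, stats::runif(nrow(records)) < detect_rate,
                   stats::runif(nrow(records)) < false_rate)
    idx <- which(gets)
    if (!length(idx)) {
      return(data.frame(record_id = character(0), user_id = character(0),
                        suggested_species_id = character(0),
                        timestamp = as.Date(character(0))))
    }
    # Experts review disproportionately often.
    w <- ifelse(pool$type == "expert", 5, 1) * pool$activity_weight
    sugg_user <- pool$user_id[sample.int(nrow(pool), length(idx),
                                         replace = TRUE, prob = w)]
    suggested <- ifelse(misid[idx], records$species_id_true[idx],
                        vapply(records$species_id_true[idx], misid_decoy,
                               character(1), level = "genus"))
    data.frame(record_id = records$record_id[idx], user_id = sugg_user,
               suggested_species_id = suggested,
               timestamp = records$timestamp[idx] + sample(1:14, length(idx),
                                                           replace = TRUE))
  })
}
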