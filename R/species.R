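VALID_TAXA <- c("seed_plant", "insect", "bird", "fish", "mammal",
                "amphibian", "reptile", "mollusc")

#' Define a virtual species
#'
#' A virtual species has a known habitat suitability surface
#' `s(cell) = plogis(intercept + sum coef_l * layer_l(cell))`, linear and
#' quadratic terms allowed. Because the truth is known, downstream models can
#' be validated by parameter/suitability recovery rather than by faith.
#'
#' @param species_id identifier. The convention `fam<f>.gen<g>.sp<s>` encodes
#'   a family/genus hierarchy that the audit module uses to score genus- and
#'   family-level identification accuracy (see [genus_of()]).
#' @param taxon one of `r paste(VALID_TAXA, collapse = ", ")`.
#' @param coef named numeric vector of linear coefficients on layer names.
#' @param coef2 named numeric vector of quadratic coefficients (optional).
#' @param intercept real intercept on the logit scale.
#' @param prevalence_target nominal prevalence in (0, 1); carried as metadata.
#' @return object of class `virtual_species`.
#' @export
virtual_species <- function(species_id, taxon, coef, coef2 = numeric(0),
                            intercept = 0, prevalence_target = 0.3) {
  taxon <- match.arg(taxon, VALID_TAXA)
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  if (length(coef2)) stopifnot(is.numeric(coef2), !is.null(names(coef2)))
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop_config("prevalence_target must be in (0, 1)")
  }
  structure(list(species_id = species_id, taxon = taxon, coef = coef,
                 coef2 = coef2, intercept = intercept,
                 prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' True suitability of a virtual species over a landscape
#'
#' @param species a [virtual_species()].
#' @param landscape an `sdm_landscape`.
#' @return numeric vector of suitabilities in \[0, 1\], one per cell in
#'   0-based row-major order.
#' @export
true_suitability <- function(species, landscape) {
  stopifnot(inherits(species, "virtual_species"))
  lay <- unique(c(names(species$coef), names(species$coef2)))
  X <- landscape_matrix(landscape, lay)
  eta <- rep(species$intercept, nrow(X))
  for (nm in names(species$coef)) eta <- eta + species$coef[[nm]] * X[, nm]
  for (nm in names(species$coef2)) eta <- eta + species$coef2[[nm]] * X[, nm]^2
  stats::plogis(eta)
}

#' Taxon-level record quality defaults
#'
#' Per-taxon calibration of the synthetic observation process: the fraction of
#' records documenting wild individuals and identification accuracy at
#' species, genus and family level, as measured for a large community-sourced
#' dataset in Japan (audited totals per taxon). Used as generator defaults so
#' that audit metrics on synthetic data land near realistic values.
#'
#' @return data.frame with columns `taxon`, `frac_wild`, `acc_species`,
#'   `acc_genus`, `acc_family`.
#' @export
taxon_quality_defaults <- function() {
  data.frame(
    taxon = c("seed_plant", "mollusc", "insect", "fish",
              "amphibian", "reptile", "bird", "mammal"),
    frac_wild = c(0.862, 0.879, 1.000, 0.736, 0.936, 0.914, 0.986, 0.807),
    acc_species = c(0.896, 0.902, 0.834, 0.874, 0.962, 0.977, 0.986, 0.956),
    acc_genus = c(0.944, 0.911, 0.869, 0.932, 0.962, 1.000, 0.993, 0.956),
    acc_family = c(0.972, 0.967, 0.941, 0.961, 0.985, 1.000, 0.993, 0.965)
  )
}

#' Build an observer pool
#'
#' @param n_experts,n_casual,n_sloppy number of observers of each type.
#'   Experts rarely misidentify and always label non-wild individuals; casual
#'   users have moderate error; sloppy users have high error and often omit
#'   the non-wild label.
#' @param misid_rates named list overriding per-type misidentification rates.
#' @param omission_rates named list overriding per-type non-wild label
#'   omission rates.
#' @param activity_weights named list overriding per-type relative activity.
#' @return data.frame of class `observer_pool` with columns `user_id`, `type`,
#'   `misid_rate`, `nonwild_label_omission_rate`, `activity_weight`.
#' @export
observer_pool <- function(n_experts = 5, n_casual = 20, n_sloppy = 5,
                          misid_rates = list(expert = 0.02, casual = 0.10, sloppy = 0.30),
                          omission_rates = list(expert = 0.0, casual = 0.2, sloppy = 0.6),
                          activity_weights = list(expert = 3, casual = 1, sloppy = 1)) {
  types <- rep(c("expert", "casual", "sloppy"), c(n_experts, n_casual, n_sloppy))
  n <- length(types)
  if (n == 0) stop_config("observer pool must contain at least one user")
  pool <- data.frame(
    user_id = sprintf("u%03d", seq_len(n)),
    type = types,
    misid_rate = unlist(misid_rates)[types],
    nonwild_label_omission_rate = unlist(omission_rates)[types],
    activity_weight = unlist(activity_weights)[types],
    row.names = NULL
  )
  bad <- pool$misid_rate < 0 | pool$misid_rate > 1 |
    pool$nonwild_label_omission_rate < 0 | pool$nonwild_label_omission_rate > 1 |
    pool$activity_weight <= 0
  if (any(bad)) stop_config("observer rates must be in [0,1] and weights > 0")
  class(pool) <- c("observer_pool", "data.frame")
  pool
}

#' Taxonomic levels encoded in synthetic species ids
#'
#' Synthetic species ids follow `fam<f>.gen<g>.sp<s>`; genus and family are
#' recovered by stripping trailing components. Ids not following the
#' convention are returned unchanged (they compare equal only to themselves).
#'
#' @param species_id character vector of species ids.
#' @return character vector of genus (family) identifiers.
#' @export
genus_of <- function(species_id) {
  sub("\\.sp[^.]*$", "", species_id)
}

#' @rdname genus_of
#' @export
family_of <- function(species_id) {
  sub("\\.gen[^.]*\\.sp[^.]*$", "", species_id)
}

#' Construct a synthetic species id
#'
#' @param family,genus,species integer indices.
#' @return character id `fam<f>.gen<g>.sp<s>`.
#' @export
make_species_id <- function(family, genus, species) {
  sprintf("fam%d.gen%d.sp%d", family, genus, species)
}
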