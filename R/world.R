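#' Draw a set of virtual species with controlled prevalence
#'
#' Species respond linearly to the two climate fields, mildly to the urban
#' fraction, and carry a negative quadratic climate term (a niche optimum);
#' the intercept is solved numerically so mean true suitability equals the
#' prevalence target. Taxa are assigned by cycling through `taxa`.
#'
#' @param n_species number of species.
#' @param landscape an `sdm_landscape` (used to calibrate intercepts).
#' @param taxa taxa to cycle through.
#' @param prevalence mean suitability target.
#' @param climate_coef_sd spread of the linear climate responses; small
#'   values give near-generalists.
#' @param urban_coef_mean,urban_coef_sd distribution of the urban-response
#'   coefficient. The default is negative on average: the modelled guild is
#'   wild terrestrial taxa, for which urbanised land is mostly (not
#'   uniformly) poorer habitat; a minority of species come out
#'   urban-tolerant.
#' @param seed integer seed.
#' @return list of [virtual_species()].
#' @export
draw_virtual_species <- function(n_species, landscape,
                                 taxa = c("seed_plant", "insect", "bird", "amphibian"),
                                 prevalence = 0.25, climate_coef_sd = 1,
                                 urban_coef_mean = -1.5,
                                 urban_coef_sd = 0.75, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      coef <- c(climate1 = stats::rnorm(1, 0, climate_coef_sd),
                climate2 = stats::rnorm(1, 0, climate_coef_sd),
                urban = stats::rnorm(1, urban_coef_mean, urban_coef_sd))
      # Distinct climatic optima: narrow niches make response-curve
      # estimation genuinely data-hungry, as with real species.
      coef2 <- c(climate1 = -abs(stats::rnorm(1, 0, 1.2 * climate_coef_sd)),
                 climate2 = -abs(stats::rnorm(1, 0, 1.2 * climate_coef_sd)))
      sp <- virtual_species(make_species_id((i - 1) %/% 5 + 1, i, i),
                            taxa[(i - 1) %% length(taxa) + 1],
                            coef = coef, coef2 = coef2, intercept = 0,
                            prevalence_target = prevalence)
      X <- landscape_matrix(landscape, c("climate1", "climate2", "urban"))
      eta <- X %*% c(coef) + coef2[["climate1"]] * X[, "climate1"]^2
      f <- function(b) mean(stats::plogis(eta + b)) - prevalence
      sp$intercept <- stats::uniroot(f, c(-30, 30))$root
      sp
    })
  })
}

#' Build a complete synthetic blending-experiment world
#'
#' Wires every pipeline stage together on simulated data with known truth:
#' generates a landscape; transforms its monthly climate into bioclim
#' variables and variance-thresholded principal components; draws virtual
#' species; simulates community records (near-uniform effort, observer pool
#' with contamination) and traditional survey records (naturalness-biased
#' effort, dominant freshwater sub-source); profiles, certifies and filters
#' the community records; audits filtered records against the synthetic
#' truth to estimate per-taxon validity; splits all records by the spatial
#' block; builds the consensus-validated 25/75 test set; and computes the
#' two effort surfaces.
#'
#' The returned object feeds [run_experiment()] directly.
#'
#' @param n_species number of virtual species, default 20.
#' @param config a [landscape_config()].
#' @param pool an [observer_pool()].
#' @param n_community,n_traditional records simulated per species and
#'   source.
#' @param block a [spatial_block()]; default: a central vertical band (all
#'   rows, 40% of the columns), so the held-out region spans the landscape's
#'   full environmental range — the real evaluation block likewise covers
#'   alpine to coastal and metropolitan to intact environments — and holds
#'   enough cells for a stable windowed Boyce profile on a small grid.
#' @param gamma naturalness-bias exponent of traditional effort, default 2.
#' @param traditional_sites number of fixed survey stations for the
#'   traditional process, drawn once (naturalness-biased) and shared by all
#'   species as in a real census network; 10% of cells by default. `NULL`
#'   for a continuous effort surface.
#' @param taxa taxa cycled over species.
#' @param community_effort_sd log-scale spread of the shared community
#'   effort field: community recording clusters spatially around human
#'   activity (a log-Gaussian field independent of the urban-natural
#'   gradient, so coverage along the gradient stays even). 0 gives uniform
#'   effort. This heterogeneity is what the all-taxa background surface is
#'   designed to correct.
#' @param n_effort_species,n_effort_records number of unmodelled common
#'   generalist species in the community record stream and records per such
#'   species. Community platforms are dominated by ubiquitous generalists
#'   recorded wherever people go, which is what makes all-taxa record
#'   counts a proxy for search effort rather than for any one species'
#'   habitat; with only the focal species in the stream that premise fails.
#'   These species enter filtering, the audit and the effort surfaces but
#'   are never modelled.
#' @param hinge_knots hinge knots per predictor for experiment fits (kept
#'   small for speed on synthetic grids).
#' @param n_background background points per fit (scaled to the synthetic
#'   grid; the protocol default 10,000 applies to full-scale landscapes).
#' @param seed integer master seed.
#' @return list with the landscape, species list, predictor matrix, record
#'   tables, certification outputs, `p_valid`, effort surfaces, test
#'   presences, `assemblies` and a ready `blend_eval_config` in `$cfg`.
#' @export
build_experiment_world <- function(n_species = 20,
                                   config = landscape_config(50, 50,
                                                             autocorr_range = 4),
                                   pool = observer_pool(),
                                   n_community = 3000, n_traditional = 600,
                                   block = NULL, gamma = 2,
                                   traditional_sites = round(0.06 * config$n_rows * config$n_cols),
                                   community_effort_sd = 1,
                                   n_effort_species = 40, n_effort_records = 2000,
                                   taxa = c("seed_plant", "insect", "bird", "amphibian"),
                                   hinge_knots = 8, n_background = 2000,
                                   seed = 1L) {
  landscape <- generate_landscape(config, seed = child_seed(seed, "landscape"))
  if (is.null(block)) {
    c0 <- floor(landscape$n_cols * 0.3)
    block <- spatial_block(0, landscape$n_rows,
                           c0, c0 + ceiling(landscape$n_cols * 0.4))
  }
  bcells <- block_cells(block, landscape)

  bio <- compute_bioclim(monthly_matrix(landscape, "tmean"),
                         monthly_matrix(landscape, "tmin"),
                         monthly_matrix(landscape, "tmax"),
                         monthly_matrix(landscape, "precip"))
  pca <- suppressWarnings(pca_reduce(bio, variance_threshold = 0.80))
  predictors <- assemble_predictors(landscape, pca = pca,
                                    extra_layers = c("urban", "elev_range"))

  species <- draw_virtual_species(n_species, landscape, taxa = taxa,
                                  seed = child_seed(seed, "species"))

  # One station network shared by all species, like a real census programme.
  # Stations are placed with a milder naturalness bias than the per-record
  # effort: census networks (river stations, forest plots) span the whole
  # gradient even though visit intensity concentrates in natural areas.
  sites <- NULL
  if (!is.null(traditional_sites)) {
    nat <- as.vector(t(landscape$layers$natural))
    sites <- with_seed(child_seed(seed, "sites"), {
      sample.int(length(nat), min(traditional_sites, length(nat)),
                 prob = nat^(gamma / 2)) - 1L
    })
  }

  # Shared human-activity field driving where community users record.
  activity <- with_seed(child_seed(seed, "activity"), {
    exp(as.vector(t(gaussian_field(landscape$n_rows, landscape$n_cols,
                                   config$autocorr_range,
                                   community_effort_sd))))
  })

  # Ubiquitous generalists fill out the community record stream.
  effort_species <- if (n_effort_species > 0) {
    draw_virtual_species(n_effort_species, landscape, taxa = taxa,
                         prevalence = 0.4, climate_coef_sd = 0.3,
                         urban_coef_mean = 0, urban_coef_sd = 0.3,
                         seed = child_seed(seed, "generalists"))
  } else {
    list()
  }
  effort_species <- lapply(seq_along(effort_species), function(i) {
    sp <- effort_species[[i]]
    sp$species_id <- sub("^fam", "gfam", sp$species_id)
    sp
  })

  comm <- list(); trad <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    cal <- contamination_from_quality(sp$taxon)
    ccfg <- cal$contamination
    ccfg$private_fraction <- 0.05
    ccfg$reported_fraction <- 0.002
    comm[[i]] <- simulate_occurrences(landscape, sp, pool, "community",
                                      n_community, ccfg,
                                      seed = child_seed(seed, paste0("c", i)),
                                      effort_multiplier = activity)
    trad[[i]] <- simulate_occurrences(landscape, sp, NULL, "traditional",
                                      n_traditional, contamination_config(),
                                      seed = child_seed(seed, paste0("t", i)),
                                      gamma = gamma, n_sites = sites)
  }
  for (i in seq_along(effort_species)) {
    sp <- effort_species[[i]]
    cal <- contamination_from_quality(sp$taxon)
    cal$contamination$private_fraction <- 0.05
    comm[[length(comm) + 1L]] <-
      simulate_occurrences(landscape, sp, pool, "community",
                           n_effort_records, cal$contamination,
                           seed = child_seed(seed, paste0("g", i)),
                           effort_multiplier = activity)
  }
  community <- do.call(rbind, comm)
  traditional <- do.call(rbind, trad)

  suggestions <- simulate_suggestions(community, pool,
                                      seed = child_seed(seed, "sugg"))
  profiles <- profile_users(community, suggestions)
  certified <- certify_users(profiles)
  specialists <- lapply(stats::setNames(nm = unique(taxa)), function(tx) {
    identify_specialists(profiles, certified, tx)
  })
  filtered <- filter_records(community, suggestions, certified)

  metrics <- audit_metrics(filtered)
  p_valid <- estimate_p_valid(metrics)

  split_c <- split_by_block(filtered, block)
  split_t <- split_by_block(traditional, block)

  accepted <- consensus_validate(split_c$test_pool, p_valid)
  balanced <- balance_traditional(split_t$test_pool,
                                  seed = child_seed(seed, "bal"))
  test_presences <- suppressWarnings(
    assemble_test(accepted, balanced, seed = child_seed(seed, "test")))

  all_surface <- effort_all_taxa(split_c$train, landscape)
  specialist_surfaces <- lapply(stats::setNames(nm = unique(taxa)), function(tx) {
    effort_specialist_taxon(split_c$train, specialists[[tx]],
                            split_t$train, tx, landscape)
  })
  # Survey-only models never see community data, not even in their
  # background: their per-taxon effort surface counts traditional records
  # alone.
  traditional_surfaces <- lapply(stats::setNames(nm = unique(taxa)), function(tx) {
    effort_specialist_taxon(split_c$train[0, , drop = FALSE], character(0),
                            split_t$train, tx, landscape)
  })

  assemblies <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    c_sp <- split_c$train[split_c$train$species_id_accepted == sp$species_id, ,
                          drop = FALSE]
    t_sp <- split_t$train[split_t$train$species_id_true == sp$species_id, ,
                          drop = FALSE]
    for (ty in c("traditional", "blended")) {
      assemblies[[paste(sp$species_id, ty)]] <-
        assemble_dataset(c_sp, t_sp, ty,
                         seed = child_seed(seed, paste0("a", i, ty)))
    }
  }

  cfg <- blend_eval_config(
    predictors = predictors,
    spec = feature_spec(hinge_knots = hinge_knots),
    all_surface = all_surface, specialist_surfaces = specialist_surfaces,
    traditional_surfaces = traditional_surfaces,
    block_cells = bcells, test_presences = test_presences,
    n_background = n_background, replace = TRUE)

  list(landscape = landscape, block = block, species = species,
       predictors = predictors, pca = pca, community = community,
       traditional = traditional, suggestions = suggestions,
       profiles = profiles, certified = certified, specialists = specialists,
       filtered = filtered, metrics = metrics, p_valid = p_valid,
       train_community = split_c$train, train_traditional = split_t$train,
       test_presences = test_presences, assemblies = assemblies, cfg = cfg)
}
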