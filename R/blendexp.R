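#' Assemble a training dataset of a given type
#'
#' `traditional` passes the survey records through. `blended` draws equal
#' numbers of community and traditional records (uniformly, without
#' replacement), so the community share is fixed at 50% and the assembly
#' size is `2 * min(available community, available traditional)`. A species
#' with zero community records cannot be blended and yields `NULL` with a
#' message (the species is skipped).
#'
#' @param community_records filtered community `occurrence_records` of one
#'   species.
#' @param traditional_records traditional `occurrence_records` of the same
#'   species.
#' @param type `"traditional"` or `"blended"`.
#' @param seed integer seed.
#' @return object of class `dataset_assembly` (list with `species_id`,
#'   `taxon`, `type`, `community_fraction`, `records`), or `NULL` when
#'   skipped.
#' @export
assemble_dataset <- function(community_records, traditional_records,
                             type = c("traditional", "blended"), seed = 1L) {
  type <- match.arg(type)
  ensure_accepted <- function(r) {
    if (!"species_id_accepted" %in% names(r)) {
      r$species_id_accepted <- r$species_id_reported
    }
    r
  }
  community_records <- ensure_accepted(community_records)
  traditional_records <- ensure_accepted(traditional_records)
  ref <- if (nrow(traditional_records)) traditional_records else community_records
  if (nrow(ref) == 0) stop_config("no records to assemble")
  species <- ref$species_id_true[1] %||% NA_character_
  taxon <- ref$taxon[1]
  if (type == "traditional") {
    records <- traditional_records
  } else {
    nc <- nrow(community_records); nt <- nrow(traditional_records)
    if (nc == 0) {
      message(sprintf("species %s skipped: no community records to blend", species))
      return(NULL)
    }
    n <- min(nc, nt)
    records <- with_seed(seed, rbind(
      community_records[sample.int(nc, n), , drop = FALSE],
      traditional_records[sample.int(nt, n), , drop = FALSE]))
  }
  rownames(records) <- NULL
  structure(list(species_id = species, taxon = taxon, type = type,
                 community_fraction = if (type == "blended") 0.5 else 0,
                 records = records),
            class = "dataset_assembly")
}

#' Training-size grid for the downsampling experiment
#'
#' Geometrically spaced integer sizes from `min` to `max` (inclusive),
#' deduplicated after rounding and truncated to sizes not exceeding the
#' species' available record count.
#'
#' @param min,max grid endpoints, defaults 20 and 20000.
#' @param n_conditions number of grid points before deduplication, default
#'   123.
#' @param available cap on usable sizes (default unbounded).
#' @return increasing integer vector.
#' @export
downsampling_grid <- function(min = 20, max = 20000, n_conditions = 123,
                              available = Inf) {
  if (min >= max) stop_config("grid needs min < max")
  sizes <- unique(round(exp(seq(log(min), log(max),
                                length.out = n_conditions))))
  sizes[sizes <= available]
}

#' Evaluation configuration for experiment runs
#'
#' Bundles everything a single model run needs: the per-cell predictor
#' matrix, the feature specification, the two effort surfaces, the test
#' block, the test presences and the background-sampling settings.
#'
#' @param predictors cells x predictors matrix (0-based row-major cell
#'   order), e.g. from [assemble_predictors()].
#' @param spec a [feature_spec()].
#' @param all_surface all-taxa community `effort_surface`.
#' @param specialist_surfaces named list of per-taxon `effort_surface`s
#'   (specialist community + traditional records), used as the second
#'   approach in blended mode.
#' @param traditional_surfaces named list of per-taxon `effort_surface`s
#'   built from traditional records only, used in traditional-only mode
#'   (community data plays no part in survey-only models, including their
#'   background). Defaults to `specialist_surfaces` when not supplied.
#' @param block_cells integer cell ids of the test block (also the
#'   evaluation region).
#' @param test_presences data.frame `species_id`, `cell` of test presences.
#' @param n_background total background points per fit.
#' @param replace background sampling with replacement (needed when the
#'   grid is small relative to `n_background`).
#' @param reg_multiplier penalty multiplier passed to [fit_maxent()].
#' @param min_presences Boyce validity floor.
#' @return object of class `blend_eval_config`.
#' @export
blend_eval_config <- function(predictors, spec = feature_spec(),
                              all_surface, specialist_surfaces, block_cells,
                              test_presences, n_background = 10000,
                              replace = FALSE, reg_multiplier = 2.5,
                              min_presences = 50,
                              traditional_surfaces = specialist_surfaces) {
  structure(list(predictors = predictors, spec = spec,
                 all_surface = all_surface,
                 specialist_surfaces = specialist_surfaces,
                 traditional_surfaces = traditional_surfaces,
                 block_cells = as.integer(block_cells),
                 test_presences = test_presences,
                 n_background = n_background, replace = replace,
                 reg_multiplier = reg_multiplier,
                 min_presences = min_presences),
            class = "blend_eval_config")
}

sample_training <- function(assembly, n) {
  rec <- assembly$records
  if (assembly$type == "blended") {
    comm <- which(rec$source == "community")
    trad <- which(rec$source != "community")
    half <- floor(n / 2)
    idx <- c(sample(comm, min(half, length(comm))),
             sample(trad, min(n - half, length(trad))))
  } else {
    idx <- sample.int(nrow(rec), min(n, nrow(rec)))
  }
  rec[idx, , drop = FALSE]
}

#' Run the blending/downsampling experiment
#'
#' For every (assembly, training size, replicate): downsample the training
#' records (keeping the 50% community share for blended assemblies), sample
#' effort-weighted background points in the matching mode (`blended` merges
#' the two effort surfaces, `traditional` uses the specialist+survey surface
#' alone), fit the penalized background-contrast model, predict suitability
#' over the test-block cells and score the continuous Boyce index against
#' the species' test presences. Runs are independently seeded from `seed`;
#' identical inputs give an identical run table.
#'
#' @param assemblies list of [assemble_dataset()] results (NULLs allowed;
#'   they are skipped).
#' @param sizes integer training sizes (per species truncated to
#'   availability).
#' @param replicates runs per condition, default 3.
#' @param cfg a [blend_eval_config()].
#' @param seed integer master seed.
#' @return data.frame of class `evaluation_runs`: `species_id`, `taxon`,
#'   `type`, `n_records`, `replicate`, `bi`, `n_test_presences`, `valid`.
#'   Invalid Boyce results carry `bi = NA`.
#' @export
run_experiment <- function(assemblies, sizes, replicates = 3, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "blend_eval_config"))
  assemblies <- Filter(Negate(is.null), assemblies)
  rows <- list()
  for (a in assemblies) {
    avail <- nrow(a$records)
    sz <- sizes[sizes <= avail]
    tp <- cfg$test_presences[cfg$test_presences$species_id == a$species_id, ,
                             drop = FALSE]
    for (n in sz) {
      for (rep in seq_len(replicates)) {
        rs <- child_seed(seed, paste(a$species_id, a$type, n, rep))
        bi_row <- with_seed(rs, {
          train <- sample_training(a, n)
          pres_cells <- unique(train$cell)
          bg <- sample_background(
            all_surface = cfg$all_surface,
            specialist_surface = if (a$type == "blended") {
              cfg$specialist_surfaces[[a$taxon]]
            } else {
              cfg$traditional_surfaces[[a$taxon]]
            },
            exclusions = union(pres_cells, cfg$block_cells),
            n_total = cfg$n_background,
            mode = if (a$type == "blended") "blended" else "traditional_only",
            replace = cfg$replace, seed = rs + 1L)
          model <- fit_maxent(cfg$predictors[pres_cells + 1L, , drop = FALSE],
                              cfg$predictors[bg$cell + 1L, , drop = FALSE],
                              spec = cfg$spec,
                              reg_multiplier = cfg$reg_multiplier,
                              categorical = attr(cfg$predictors, "categorical") %||% character(0),
                              seed = rs)
          suit_eval <- predict_suitability(
            model, cfg$predictors[cfg$block_cells + 1L, , drop = FALSE])
          suit_pres <- suit_eval[match(tp$cell, cfg$block_cells)]
          b <- boyce_index(suit_eval, suit_pres[!is.na(suit_pres)],
                           min_presences = cfg$min_presences)
          data.frame(species_id = a$species_id, taxon = a$taxon, type = a$type,
                     n_records = n, replicate = rep,
                     bi = if (b$valid) b$bi else NA_real_,
                     n_test_presences = b$n_test_presences, valid = b$valid)
        })
        rows[[length(rows) + 1L]] <- bi_row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_runs", "data.frame")
  out
}

mean_bi_table <- function(runs) {
  agg <- stats::aggregate(list(bi = runs$bi),
                          by = list(species_id = runs$species_id,
                                    type = runs$type,
                                    n_records = runs$n_records),
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg$bi[is.nan(agg$bi)] <- NA_real_
  agg
}

#' Records needed to reach a Boyce-index threshold
#'
#' Per species and dataset type, the smallest training size whose
#' across-replicate mean Boyce index reaches the threshold (default 0.9),
#' `NA` when never reached; plus a mean +/- SD summary over species with a
#' defined crossing (the number of undefined species is reported).
#'
#' @param runs an `evaluation_runs` table.
#' @param threshold Boyce-index threshold, default 0.9.
#' @return list with `per_species` and `summary` data.frames.
#' @export
records_to_threshold <- function(runs, threshold = 0.9) {
  agg <- mean_bi_table(runs)
  combos <- unique(agg[, c("species_id", "type")])
  combos$n_at_threshold <- vapply(seq_len(nrow(combos)), function(i) {
    d <- agg[agg$species_id == combos$species_id[i] &
               agg$type == combos$type[i], , drop = FALSE]
    d <- d[order(d$n_records), , drop = FALSE]
    hit <- which(!is.na(d$bi) & d$bi >= threshold)
    if (length(hit)) d$n_records[hit[1]] else NA_real_
  }, numeric(1))
  summary <- do.call(rbind, lapply(unique(combos$type), function(ty) {
    v <- combos$n_at_threshold[combos$type == ty]
    data.frame(type = ty, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               n_species = sum(!is.na(v)), n_undefined = sum(is.na(v)))
  }))
  list(per_species = combos, summary = summary)
}

#' Mixed model for the blending effect on model accuracy
#'
#' Per-condition mean Boyce indices are Fisher z-transformed
#' (`z = atanh(BI)`, BI clipped to +/-(1 - 1e-8)) and modelled as
#' `z ~ type * log10(n_records) + (1 | species)` by REML. The interaction
#' term asks whether accuracy grows faster with record count for blended
#' data than for survey-only data. p values use the normal approximation on
#' the t statistic (no Satterthwaite correction), which is accurate at the
#' residual degrees of freedom these run tables carry.
#'
#' @param runs an `evaluation_runs` table (>= 2 species, >= 2 sizes, both
#'   types).
#' @return object of class `blend_mixed_model`: list with `coefficients`
#'   (estimate, std_error, t, p per fixed effect), `random_intercept_sd`,
#'   `fit` (the underlying `lmerMod`).
#' @export
fit_mixed_model <- function(runs) {
  agg <- mean_bi_table(runs)
  agg <- agg[!is.na(agg$bi), , drop = FALSE]
  if (length(unique(agg$species_id)) < 2) {
    stop_config("mixed model needs at least 2 species (random effect inestimable)")
  }
  if (length(unique(agg$type)) < 2 || length(unique(agg$n_records)) < 2) {
    stop_config("mixed model needs both dataset types and >= 2 sizes")
  }
  agg$z <- atanh(pmin(pmax(agg$bi, -1 + 1e-8), 1 - 1e-8))
  agg$log_n <- log10(agg$n_records)
  agg$type <- stats::relevel(factor(agg$type), ref = "traditional")
  fit <- lme4::lmer(z ~ type * log_n + (1 | species_id), data = agg,
                    REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      std_error = sm[, "Std. Error"], t = sm[, "t value"],
                      p = 2 * stats::pnorm(-abs(sm[, "t value"])),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 random_intercept_sd = vc$sdcor[vc$grp == "species_id"],
                 n_conditions = nrow(agg), fit = fit),
            class = "blend_mixed_model")
}
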