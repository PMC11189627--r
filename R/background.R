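new_effort_surface <- function(counts, landscape, provenance) {
  structure(list(counts = counts, weight = log(counts + 1.2),
                 n_rows = landscape$n_rows, n_cols = landscape$n_cols,
                 provenance = provenance),
            class = "effort_surface")
}

cell_counts <- function(cells, n_cells) {
  counts <- numeric(n_cells)
  if (length(cells)) {
    tb <- table(factor(cells, levels = 0:(n_cells - 1)))
    counts <- as.numeric(tb)
  }
  counts
}

#' Sampling-effort surface from all community records
#'
#' The picking weight of a cell is `log(n + 1.2)` where `n` counts community
#' records of any taxon in the cell. The +1.2 offset keeps cells with zero
#' or one record selectable at low probability (log 1.2 > 0), so background
#' points can fall in under-sampled places.
#'
#' @param records community `occurrence_records`.
#' @param landscape an `sdm_landscape`.
#' @return object of class `effort_surface` with per-cell `counts` and
#'   `weight` vectors (0-based row-major cell order).
#' @export
effort_all_taxa <- function(records, landscape) {
  assert_columns(records, c("cell", "source"))
  cells <- records$cell[records$source == "community"]
  new_effort_surface(cell_counts(cells, landscape$n_rows * landscape$n_cols),
                     landscape, "all_taxa_community")
}

#' Sampling-effort surface from specialists and survey data, per taxon
#'
#' Counts only (a) community records authored by specialist observers and
#' (b) all traditional survey records, both restricted to the focal taxon,
#' then applies the same `log(n + 1.2)` weighting. This is the target-group
#' background surface for survey-biased effort.
#'
#' @param community_records community `occurrence_records`.
#' @param specialists character vector of specialist user ids (from
#'   [identify_specialists()]).
#' @param traditional_records traditional `occurrence_records` (sources
#'   `traditional` / `traditional_freshwater`).
#' @param taxon focal taxon.
#' @param landscape an `sdm_landscape`.
#' @return an `effort_surface`.
#' @export
effort_specialist_taxon <- function(community_records, specialists,
                                    traditional_records, taxon, landscape) {
  if (!taxon %in% VALID_TAXA) stop_config("unknown taxon '%s'", taxon)
  comm <- community_records[community_records$source == "community" &
                              community_records$taxon == taxon &
                              community_records$user_id %in% specialists, ,
                            drop = FALSE]
  trad <- traditional_records[traditional_records$source != "community" &
                                traditional_records$taxon == taxon, ,
                              drop = FALSE]
  cells <- c(comm$cell, trad$cell)
  new_effort_surface(cell_counts(cells, landscape$n_rows * landscape$n_cols),
                     landscape, "specialist_plus_traditional_taxon")
}

#' Sample effort-weighted pseudo-absence (background) cells
#'
#' Draws background cells with probability proportional to the effort
#' surface weight over eligible cells, excluding focal-species presence
#' cells and the test-block cells. In `blended` mode, half the points come
#' from the all-taxa community surface and half from the specialist+survey
#' taxon surface, merged with duplicates retained; in `traditional_only`
#' mode all points come from the specialist+survey surface. Defaults follow
#' the standard protocol: 10,000 points as 5,000 + 5,000.
#'
#' Within each approach, cells are drawn without replacement by default; if
#' eligible cells are fewer than requested this errors with a suggestion to
#' set `replace = TRUE` (appropriate on small synthetic grids).
#'
#' @param all_surface `effort_surface` from [effort_all_taxa()] (required in
#'   blended mode).
#' @param specialist_surface `effort_surface` from
#'   [effort_specialist_taxon()].
#' @param exclusions integer cell ids never returned (focal presence cells,
#'   test block cells).
#' @param n_total total number of background points, default 10000.
#' @param mode `"blended"` or `"traditional_only"`.
#' @param replace sample with replacement within each approach.
#' @param seed integer seed.
#' @return data.frame with `cell`, `weight`, `approach`.
#' @export
sample_background <- function(all_surface = NULL, specialist_surface,
                              exclusions = integer(0), n_total = 10000,
                              mode = c("blended", "traditional_only"),
                              replace = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(specialist_surface, "effort_surface"))
  if (mode == "blended" && !inherits(all_surface, "effort_surface")) {
    stop_config("blended mode needs the all-taxa community effort surface")
  }
  n_cells <- length(specialist_surface$weight)
  eligible <- setdiff(0:(n_cells - 1), as.integer(exclusions))
  draw <- function(surface, n, approach) {
    if (n == 0) return(NULL)
    w <- surface$weight[eligible + 1]
    if (!replace && length(eligible) < n) {
      stop_config(paste("only %d eligible cells for %d background points;",
                        "set replace = TRUE to sample with replacement"),
                  length(eligible), n)
    }
    idx <- sample(seq_along(eligible), n, replace = replace, prob = w)
    data.frame(cell = eligible[idx], weight = w[idx], approach = approach)
  }
  with_seed(seed, {
    out <- if (mode == "blended") {
      n1 <- floor(n_total / 2)
      rbind(draw(all_surface, n1, "all_taxa_community"),
            draw(specialist_surface, n_total - n1, "specialist_plus_traditional_taxon"))
    } else {
      draw(specialist_surface, n_total, "specialist_plus_traditional_taxon")
    }
    rownames(out) <- NULL
    out
  })
}
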