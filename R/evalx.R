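#' Define a rectangular spatial block
#'
#' Grid-coordinate rectangle used to split records into training (outside)
#' and test pool (inside). The boundary convention is closed-low / open-high:
#' a record at `row_min`/`col_min` is inside, one at `row_max`/`col_max` is
#' outside.
#'
#' @param row_min,row_max,col_min,col_max 0-based grid bounds.
#' @return object of class `spatial_block`.
#' @export
spatial_block <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_max >= row_min, col_max >= col_min)
  structure(list(row_min = row_min, row_max = row_max,
                 col_min = col_min, col_max = col_max),
            class = "spatial_block")
}

#' Cells covered by a spatial block
#'
#' @param block a [spatial_block()].
#' @param landscape an `sdm_landscape`.
#' @return integer vector of 0-based cell ids inside the block.
#' @export
block_cells <- function(block, landscape) {
  rows <- seq(max(0, block$row_min), min(landscape$n_rows, block$row_max) - 1)
  cols <- seq(max(0, block$col_min), min(landscape$n_cols, block$col_max) - 1)
  if (!length(rows) || !length(cols)) return(integer(0))
  as.integer(outer(rows * landscape$n_cols, cols, "+"))
}

in_block <- function(records, block) {
  records$row >= block$row_min & records$row < block$row_max &
    records$col >= block$col_min & records$col < block$col_max
}

#' Split records by a spatial block
#'
#' Records inside the block form the test pool; records outside form the
#' training set. The partition is exhaustive and disjoint. A block covering
#' all records or none triggers a warning.
#'
#' @param records `occurrence_records` with `row`/`col` columns.
#' @param block a [spatial_block()].
#' @return list with `train` and `test_pool` data.frames.
#' @export
split_by_block <- function(records, block) {
  stopifnot(inherits(block, "spatial_block"))
  inside <- in_block(records, block)
  if (nrow(records) > 0 && (all(inside) || !any(inside))) {
    warning("spatial block covers all or none of the records")
  }
  list(train = records[!inside, , drop = FALSE],
       test_pool = records[inside, , drop = FALSE])
}

#' True-presence probability under multi-observer consensus
#'
#' `p_tp = 1 - (1 - p_valid)^n_users`: the probability that at least one of
#' `n_users` independent observers' records of the species in a cell is
#' valid. Strictly increasing in `n_users` for `0 < p_valid < 1`, and equal
#' to `p_valid` at `n_users = 1`.
#'
#' @param p_valid per-record validity probability in \[0, 1\].
#' @param n_users number of distinct observers (>= 1).
#' @return numeric probability in \[0, 1\].
#' @export
p_true_presence <- function(p_valid, n_users) {
  stopifnot(all(p_valid >= 0 & p_valid <= 1), all(n_users >= 1))
  1 - (1 - p_valid)^n_users
}

#' Consensus-validate community presences for the test set
#'
#' Community records enter the test set only where multiple observers
#' corroborate each other: records are grouped by (species, cell), the
#' number of distinct observers is counted, and the cell is accepted iff
#' `p_tp = 1 - (1 - p_valid)^n_users` exceeds the threshold (default 99%).
#' Single-observer cells can pass only if `p_valid` itself exceeds the
#' threshold.
#'
#' @param records community test-pool `occurrence_records`.
#' @param p_valid named vector of per-taxon validity probabilities (from
#'   [estimate_p_valid()]); every taxon present must be covered.
#' @param threshold acceptance threshold on `p_tp`, default 0.99 (strict
#'   `>`).
#' @return data.frame of accepted presence cells: `species_id`, `taxon`,
#'   `cell`, `n_users`, `p_tp`.
#' @export
consensus_validate <- function(records, p_valid, threshold = 0.99) {
  sp_col <- audit_species_col(records)
  records <- records[records$source == "community", , drop = FALSE]
  if (nrow(records) == 0) {
    return(data.frame(species_id = character(0), taxon = character(0),
                      cell = integer(0), n_users = integer(0),
                      p_tp = numeric(0)))
  }
  missing <- setdiff(unique(records$taxon), names(p_valid))
  if (length(missing)) {
    stop_config("no p_valid for taxon/taxa: %s", paste(missing, collapse = ", "))
  }
  grp <- stats::aggregate(list(n_users = records$user_id),
                          by = list(species_id = records[[sp_col]],
                                    taxon = records$taxon,
                                    cell = records$cell),
                          FUN = function(u) length(unique(u)))
  grp$p_tp <- p_true_presence(p_valid[grp$taxon], grp$n_users)
  out <- grp[grp$p_tp > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance the dominant survey sub-source in the test pool
#'
#' The freshwater-census-like sub-source (`traditional_freshwater`) dwarfs
#' the remaining survey records; it is randomly downsampled to the size of
#' the remaining traditional records. Other records pass through untouched.
#'
#' @param records traditional test-pool `occurrence_records`.
#' @param seed integer seed.
#' @return the balanced records.
#' @export
balance_traditional <- function(records, seed = 1L) {
  fresh <- records$source == "traditional_freshwater"
  n_other <- sum(!fresh)
  if (sum(fresh) <= n_other) return(records)
  with_seed(seed, {
    keep_fresh <- sample(which(fresh), n_other)
    out <- records[sort(c(keep_fresh, which(!fresh))), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Assemble the composite test presence set
#'
#' Combines consensus-validated community presence cells with balanced
#' traditional test records so that community records make up
#' `community_fraction` (default 25%) of the final set, downsampling the
#' over-represented source. Presences are deduplicated to one per
#' (species, cell) — the analysis unit is the grid cell. If one source is
#' empty the other is used whole, with a warning.
#'
#' @param community_cells accepted cells from [consensus_validate()].
#' @param traditional_records balanced traditional records (see
#'   [balance_traditional()]).
#' @param community_fraction target community share, default 0.25.
#' @param seed integer seed.
#' @return data.frame of test presences: `species_id`, `cell`, `source`.
#' @export
assemble_test <- function(community_cells, traditional_records,
                          community_fraction = 0.25, seed = 1L) {
  sp_col <- audit_species_col(traditional_records)
  comm <- unique(data.frame(species_id = community_cells$species_id,
                            cell = community_cells$cell))
  trad <- unique(data.frame(species_id = traditional_records[[sp_col]],
                            cell = traditional_records$cell))
  with_seed(seed, {
    pieces <- lapply(unique(c(comm$species_id, trad$species_id)), function(sp) {
      c_sp <- comm[comm$species_id == sp, , drop = FALSE]
      t_sp <- trad[trad$species_id == sp, , drop = FALSE]
      nc <- nrow(c_sp); nt <- nrow(t_sp)
      f <- community_fraction
      if (nc == 0 || nt == 0) {
        warning(sprintf("species %s: only one test source available", sp))
      } else {
        # Select the community share first, then dedup the traditional pool
        # against the SELECTED community cells only: a community cell that is
        # dropped by the 25% cap stays eligible as a traditional presence, so
        # the cap does not strip shared (typically high-suitability) cells
        # from the test set altogether.
        c_target <- min(nc, round(f / (1 - f) * nt))
        c_sp <- c_sp[sample.int(nc, c_target), , drop = FALSE]
        t_sp <- t_sp[!t_sp$cell %in% c_sp$cell, , drop = FALSE]
        t_target <- round((1 - f) / f * nrow(c_sp))
        if (nrow(t_sp) > t_target) {
          t_sp <- t_sp[sample.int(nrow(t_sp), t_target), , drop = FALSE]
        } else if (nrow(t_sp) < t_target && nrow(c_sp) > 0) {
          c_keep <- round(f / (1 - f) * nrow(t_sp))
          c_sp <- c_sp[seq_len(min(nrow(c_sp), max(c_keep, 1))), , drop = FALSE]
        }
      }
      rbind(cbind(c_sp, source = rep("community", nrow(c_sp))),
            cbind(t_sp, source = rep("traditional", nrow(t_sp))))
    })
    out <- do.call(rbind, pieces)
    out <- out[!duplicated(out[, c("species_id", "cell")]), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
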