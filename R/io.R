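DWC_MAP <- c(record_id = "occurrenceID", species_id_reported = "scientificName",
             species_id_true = "verbatimIdentification", taxon = "taxonGroup",
             row = "gridRow", col = "gridCol", cell = "cellID",
             timestamp = "eventDate", user_id = "recordedBy",
             source = "datasetName", is_wild_true = "isWild",
             labeled_nonwild = "labeledNonWild", is_private = "isPrivate",
             is_reported = "isFlagged", at_cultural_center = "atCulturalCenter",
             species_id_accepted = "acceptedScientificName")

#' Read / write occurrence records as Darwin-Core-flavoured CSV
#'
#' Column headers follow Darwin Core where a term exists (occurrenceID,
#' scientificName, eventDate, recordedBy, ...) with documented extensions
#' for grid coordinates, flags and the synthetic truth fields.
#'
#' @param records `occurrence_records` data.frame.
#' @param path CSV file path.
#' @return `read_records_csv()` returns an `occurrence_records` data.frame.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  names(out) <- ifelse(names(out) %in% names(DWC_MAP),
                       DWC_MAP[names(out)], names(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  rev_map <- stats::setNames(names(DWC_MAP), DWC_MAP)
  names(x) <- ifelse(names(x) %in% names(rev_map), rev_map[names(x)], names(x))
  if ("timestamp" %in% names(x)) x$timestamp <- as.Date(x$timestamp)
  structure(x, class = c("occurrence_records", "data.frame"))
}

#' Read / write a landscape as CSV in long format
#'
#' One row per (layer, cell): `layer`, `gridRow`, `gridCol`, `value`, plus
#' a header comment-free shape encoded in the coordinates. A documented
#' plain-text alternative to raster formats for synthetic landscapes.
#'
#' @param landscape an `sdm_landscape`.
#' @param path CSV file path.
#' @return `read_landscape_csv()` returns an `sdm_landscape`.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "sdm_landscape"))
  rows <- lapply(names(landscape$layers), function(nm) {
    m <- landscape$layers[[nm]]
    data.frame(layer = nm,
               gridRow = rep(0:(nrow(m) - 1), each = ncol(m)),
               gridCol = rep(0:(ncol(m) - 1), nrow(m)),
               value = as.vector(t(m)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  x <- utils::read.csv(path)
  assert_columns(x, c("layer", "gridRow", "gridCol", "value"), "landscape CSV")
  n_rows <- max(x$gridRow) + 1L
  n_cols <- max(x$gridCol) + 1L
  layers <- lapply(split(x, x$layer), function(d) {
    m <- matrix(NA_real_, n_rows, n_cols)
    m[cbind(d$gridRow + 1L, d$gridCol + 1L)] <- d$value
    m
  })
  out <- structure(list(n_rows = n_rows, n_cols = n_cols,
                        layers = layers[unique(x$layer)]),
                   class = "sdm_landscape")
  validate_landscape(out)
  out
}

#' @importFrom stats aggregate approx cor plogis pnorm prcomp quantile rnorm runif sd setNames relevel uniroot
#' @importFrom utils head read.csv write.csv
NULL
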