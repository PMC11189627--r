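#' Compute the 19 standard bioclimatic variables
#'
#' Transforms monthly climatologies into the standard BIO1..BIO19 summaries.
#' Quarters are any 3 consecutive months with December-January wrap-around,
#' selected by the usual max/min rules (ties resolved to the earliest
#' window). Identities guaranteed to machine precision: `BIO7 = BIO5 - BIO6`,
#' `BIO12 = sum of monthly precipitation`, `BIO4 >= 0`, `BIO15 >= 0`.
#'
#' Definitions: BIO1 annual mean temperature; BIO2 mean diurnal range
#' (mean of monthly tmax - tmin); BIO3 isothermality (100 x BIO2/BIO7, 0 when
#' BIO7 = 0); BIO4 temperature seasonality (100 x SD of monthly means); BIO5
#' max temperature of warmest month; BIO6 min temperature of coldest month;
#' BIO7 annual range; BIO8/BIO9 mean temperature of wettest/driest quarter;
#' BIO10/BIO11 mean temperature of warmest/coldest quarter; BIO12 annual
#' precipitation; BIO13/BIO14 precipitation of wettest/driest month; BIO15
#' precipitation seasonality (100 x SD / (mean + 1)); BIO16/BIO17
#' precipitation of wettest/driest quarter; BIO18/BIO19 precipitation of
#' warmest/coldest quarter.
#'
#' @param tmean,tmin,tmax monthly mean/min/max temperature (deg C), each a
#'   cells x 12 matrix (or length-12 vector for a single cell).
#' @param precip monthly precipitation (mm), cells x 12.
#' @return numeric matrix, cells x 19, columns `BIO1`..`BIO19`.
#' @export
compute_bioclim <- function(tmean, tmin, tmax, precip) {
  as12 <- function(x, nm) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != 12) {
      stop_config("%s must have 12 monthly columns; missing month(s): %s", nm,
                  paste(setdiff(1:12, seq_len(ncol(x))), collapse = ", "))
    }
    x
  }
  tmean <- as12(tmean, "tmean"); tmin <- as12(tmin, "tmin")
  tmax <- as12(tmax, "tmax"); precip <- as12(precip, "precip")
  stopifnot(nrow(tmean) == nrow(tmin), nrow(tmean) == nrow(tmax),
            nrow(tmean) == nrow(precip))
  if (any(tmin > tmax + 1e-9)) stop_config("tmin exceeds tmax")

  n <- nrow(tmean)
  # Quarter (3-month wrap-around window) aggregates: 12 windows.
  wins <- lapply(1:12, function(m) ((m - 1):(m + 1)) %% 12 + 1)
  q_sum <- function(x) vapply(wins, function(w) rowSums(x[, w, drop = FALSE]),
                              numeric(n))
  pq <- q_sum(precip)                 # cells x 12 window precip totals
  tq <- q_sum(tmean) / 3              # cells x 12 window mean temps
  if (n == 1) { pq <- matrix(pq, 1); tq <- matrix(tq, 1) }

  pick <- function(mat, idx) mat[cbind(seq_len(n), idx)]
  wet_q <- max.col(pq, ties.method = "first")
  dry_q <- max.col(-pq, ties.method = "first")
  warm_q <- max.col(tq, ties.method = "first")
  cold_q <- max.col(-tq, ties.method = "first")

  out <- matrix(NA_real_, n, 19, dimnames = list(NULL, paste0("BIO", 1:19)))
  out[, "BIO1"] <- rowMeans(tmean)
  out[, "BIO2"] <- rowMeans(tmax - tmin)
  out[, "BIO4"] <- 100 * apply(tmean, 1, stats::sd)
  out[, "BIO5"] <- apply(tmax, 1, max)
  out[, "BIO6"] <- apply(tmin, 1, min)
  out[, "BIO7"] <- out[, "BIO5"] - out[, "BIO6"]
  out[, "BIO3"] <- ifelse(out[, "BIO7"] == 0, 0,
                          100 * out[, "BIO2"] / out[, "BIO7"])
  out[, "BIO8"] <- pick(tq, wet_q)
  out[, "BIO9"] <- pick(tq, dry_q)
  out[, "BIO10"] <- pick(tq, warm_q)
  out[, "BIO11"] <- pick(tq, cold_q)
  out[, "BIO12"] <- rowSums(precip)
  out[, "BIO13"] <- apply(precip, 1, max)
  out[, "BIO14"] <- apply(precip, 1, min)
  out[, "BIO15"] <- 100 * apply(precip, 1, stats::sd) / (rowMeans(precip) + 1)
  out[, "BIO16"] <- pick(pq, wet_q)
  out[, "BIO17"] <- pick(pq, dry_q)
  out[, "BIO18"] <- pick(pq, warm_q)
  out[, "BIO19"] <- pick(pq, cold_q)
  out
}
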