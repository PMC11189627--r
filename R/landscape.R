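#' Landscape generator configuration
#'
#' Describes the synthetic 1-km-analog grid world: its dimensions, the spatial
#' autocorrelation range of the continuous fields, and the climatology used to
#' build monthly temperature and precipitation stacks.
#'
#' @param n_rows,n_cols grid dimensions; `n_rows * n_cols` must be >= 100
#'   unless `allow_small = TRUE` (degenerate grids are handy in tests).
#' @param autocorr_range Gaussian smoothing length (in cells) of the random
#'   fields; larger values give smoother landscapes. Must be > 0.
#' @param n_climate_fields number of generic spatially autocorrelated climate
#'   fields (at least 2) exposed as layers `climate1`, `climate2`, ...
#' @param field_sd marginal standard deviation of the autocorrelated fields;
#'   0 collapses every field to a constant (useful degenerate case).
#' @param urban_scale steepness of the logistic squashing that turns a random
#'   field into the `urban` fraction in \[0, 1\].
#' @param urban_climate_cor correlation between the urban field and the
#'   first climate field (warm lowlands carry the cities, uplands stay
#'   natural and cool), mirroring how the urban-natural axis of real
#'   landscapes loads jointly on land use, topography and climate. 0
#'   decouples them.
#' @param temp_mean annual mean temperature (deg C) at the landscape centre.
#' @param temp_seasonal_amplitude half-range of the seasonal temperature cycle
#'   (deg C), peaking in August.
#' @param temp_spatial_sd spatial standard deviation (deg C) added to monthly
#'   temperatures from the first climate field.
#' @param diurnal_range mean monthly tmax - tmin spread (deg C); must be >= 0
#'   so tmin <= tmean <= tmax holds everywhere.
#' @param precip_mean mean monthly precipitation (mm).
#' @param precip_seasonality relative amplitude (0..1) of the seasonal
#'   precipitation cycle.
#' @param allow_small permit grids with fewer than 100 cells.
#' @return an object of class `landscape_config`.
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(n_rows = 50, n_cols = 50, autocorr_range = 10,
                             n_climate_fields = 2, field_sd = 1,
                             urban_scale = 1.5, urban_climate_cor = 0.6,
                             temp_mean = 12,
                             temp_seasonal_amplitude = 10, temp_spatial_sd = 3,
                             diurnal_range = 8, precip_mean = 120,
                             precip_seasonality = 0.5, allow_small = FALSE) {
  if (n_rows <= 0 || n_cols <= 0) {
    stop_config("landscape dimensions must be positive (got %d x %d)",
                n_rows, n_cols)
  }
  if (!allow_small && n_rows * n_cols < 100) {
    stop_config("landscape must have at least 100 cells; use allow_small = TRUE for degenerate grids")
  }
  if (autocorr_range <= 0) stop_config("autocorr_range must be > 0")
  if (n_climate_fields < 2) stop_config("need at least 2 climate fields")
  if (diurnal_range < 0) stop_config("diurnal_range must be >= 0")
  if (abs(urban_climate_cor) > 1) stop_config("urban_climate_cor must be in [-1, 1]")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    autocorr_range = autocorr_range, n_climate_fields = as.integer(n_climate_fields),
    field_sd = field_sd, urban_scale = urban_scale,
    urban_climate_cor = urban_climate_cor, temp_mean = temp_mean,
    temp_seasonal_amplitude = temp_seasonal_amplitude,
    temp_spatial_sd = temp_spatial_sd, diurnal_range = diurnal_range,
    precip_mean = precip_mean, precip_seasonality = precip_seasonality
  ), class = "landscape_config")
}

# Gaussian random field on a torus: white noise smoothed with an isotropic
# Gaussian kernel via FFT, then standardized to mean 0 / sd 1. `sd = 0`
# returns a constant zero field.
gaussian_field <- function(n_rows, n_cols, range, sd = 1) {
  if (sd == 0) return(matrix(0, n_rows, n_cols))
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range > 0 && (n_rows > 1 || n_cols > 1)) {
    di <- outer(pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))^2,
                pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))^2, "+")
    kern <- exp(-di / (2 * range^2))
    kern <- kern / sum(kern)
    sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (n_rows * n_cols)
    z <- sm
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- (z - mean(z)) / s
  z * sd
}

#' Generate a synthetic landscape
#'
#' Builds the gridded world every other module consumes: an urban/natural
#' gradient, spatially autocorrelated climate fields, monthly mean/min/max
#' temperature and precipitation stacks, and an elevation-range layer.
#' Continuous fields are Gaussian random fields obtained by FFT smoothing of
#' white noise on a torus, so autocorrelation is controlled by a single range
#' parameter and output is fully reproducible from `(config, seed)`.
#'
#' Layer invariants (validated on construction): all layers share the grid
#' shape, `urban + natural == 1` per cell, precipitation is non-negative and
#' `tmin <= tmean <= tmax` in every month.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   layers.
#' @return an object of class `sdm_landscape`: a list with `n_rows`, `n_cols`
#'   and `layers` (named list of `n_rows x n_cols` matrices). Cells are
#'   addressed by 0-based row-major ids; see [rowcol_to_cell()].
#' @examples
#' ls <- generate_landscape(landscape_config(20, 20, allow_small = TRUE), seed = 1)
#' names(ls$layers)[1:6]
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(seed, {
    nr <- config$n_rows; nc <- config$n_cols
    layers <- list()
    for (k in seq_len(config$n_climate_fields)) {
      layers[[paste0("climate", k)]] <-
        gaussian_field(nr, nc, config$autocorr_range, config$field_sd)
    }
    # Urbanisation concentrates in the warm lowlands: the urban field mixes
    # the first climate field with an independent component.
    rho <- config$urban_climate_cor
    u_field <- rho * layers$climate1 / max(config$field_sd, 1e-12) +
      sqrt(1 - rho^2) * gaussian_field(nr, nc, config$autocorr_range,
                                       config$field_sd) / max(config$field_sd, 1e-12)
    if (config$field_sd == 0) u_field <- matrix(0, nr, nc)
    layers$urban <- stats::plogis(config$urban_scale * u_field * config$field_sd)
    layers$natural <- 1 - layers$urban
    layers$elev_range <- exp(gaussian_field(nr, nc, config$autocorr_range,
                                            config$field_sd) * 0.5)
    # Monthly climate: shared seasonal cycle + spatial anomaly from climate1.
    anom <- layers$climate1 * config$temp_spatial_sd
    wetf <- layers$climate2
    for (m in 1:12) {
      season <- config$temp_mean +
        config$temp_seasonal_amplitude * cos(2 * pi * (m - 8) / 12)
      tm <- season + anom
      layers[[sprintf("tmean_%02d", m)]] <- tm
      layers[[sprintf("tmax_%02d", m)]] <- tm + config$diurnal_range / 2
      layers[[sprintf("tmin_%02d", m)]] <- tm - config$diurnal_range / 2
      pseason <- 1 + config$precip_seasonality * sin(2 * pi * (m - 5) / 12)
      # pmax with the matrix first: a scalar first argument would drop dims
      layers[[sprintf("precip_%02d", m)]] <-
        pmax(config$precip_mean * pseason * exp(0.4 * wetf), 0)
    }
    out <- structure(list(n_rows = nr, n_cols = nc, layers = layers),
                     class = "sdm_landscape")
    validate_landscape(out)
    out
  })
}

validate_landscape <- function(x) {
  stopifnot(inherits(x, "sdm_landscape"))
  dims <- vapply(x$layers, function(l) all(dim(l) == c(x$n_rows, x$n_cols)),
                 logical(1))
  if (!all(dims)) stop_config("landscape layers differ in shape")
  if (max(abs(x$layers$urban + x$layers$natural - 1)) > 1e-12) {
    stop_config("urban + natural must equal 1 in every cell")
  }
  for (m in 1:12) {
    p <- x$layers[[sprintf("precip_%02d", m)]]
    if (any(p < 0)) stop_config("negative precipitation in month %d", m)
    tm <- x$layers[[sprintf("tmean_%02d", m)]]
    if (any(x$layers[[sprintf("tmin_%02d", m)]] > tm + 1e-9) ||
        any(tm > x$layers[[sprintf("tmax_%02d", m)]] + 1e-9)) {
      stop_config("tmin <= tmean <= tmax violated in month %d", m)
    }
  }
  invisible(x)
}

#' Cell id conversions
#'
#' Cells are addressed by 0-based row-major ids: cell `= row * n_cols + col`
#' with `row`, `col` 0-based.
#'
#' @param row,col 0-based grid coordinates.
#' @param cell 0-based row-major cell id.
#' @param landscape an `sdm_landscape` (only `n_cols` is used).
#' @return `rowcol_to_cell()` returns integer cell ids; `cell_to_rowcol()`
#'   returns a data.frame with `row` and `col`.
#' @export
rowcol_to_cell <- function(row, col, landscape) {
  as.integer(row) * landscape$n_cols + as.integer(col)
}

#' @rdname rowcol_to_cell
#' @export
cell_to_rowcol <- function(cell, landscape) {
  cell <- as.integer(cell)
  data.frame(row = cell %/% landscape$n_cols, col = cell %% landscape$n_cols)
}

#' Flatten landscape layers to a cells-by-layers matrix
#'
#' @param landscape an `sdm_landscape`.
#' @param layers character vector of layer names (default: all).
#' @return numeric matrix with one row per cell in 0-based row-major order and
#'   one named column per layer.
#' @export
landscape_matrix <- function(landscape, layers = names(landscape$layers)) {
  missing <- setdiff(layers, names(landscape$layers))
  if (length(missing)) stop_config("unknown layer(s): %s", paste(missing, collapse = ", "))
  # t() because R matrices are column-major but cell ids are row-major.
  out <- vapply(layers, function(nm) as.vector(t(landscape$layers[[nm]])),
                numeric(landscape$n_rows * landscape$n_cols))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, layers))
  out
}

#' Extract a monthly climate stack as a cells-by-12 matrix
#'
#' @param landscape an `sdm_landscape`.
#' @param prefix one of `"tmean"`, `"tmin"`, `"tmax"`, `"precip"`.
#' @return numeric matrix, cells (row-major order) by 12 months.
#' @export
monthly_matrix <- function(landscape, prefix = c("tmean", "tmin", "tmax", "precip")) {
  prefix <- match.arg(prefix)
  landscape_matrix(landscape, sprintf("%s_%02d", prefix, 1:12))
}
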