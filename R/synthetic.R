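#' Configuration for the synthetic lake generator
#'
#' Defines the study conditions the generator emulates: a shallow tropical
#' basin (depths under `basin_max_depth`) drained through a deeper channel
#' (up to `channel_max_depth`) at an outlet on the southern shore; water
#' clarity (Secchi depth) increasing linearly with distance from the
#' outlet; total nitrogen, phosphorus and chlorophyll declining from the
#' outlet (south) towards the north; light-limited submerged vegetation;
#' and a seasonal water-level amplitude of about 2.5 m.
#'
#' @param nx,ny Grid dimensions in cells (>= 8).
#' @param cell_size Cell edge, metres (default 16).
#' @param basin_max_depth Maximum depth of the open basin, m (default 5).
#' @param channel_max_depth Maximum depth of the outlet channel, m
#'   (default 9); must exceed `basin_max_depth`.
#' @param outlet_xy Planar coordinates of the outlet, m; default is on the
#'   southern shore at mid-width.
#' @param secchi_slope,secchi_intercept Linear clarity model: Secchi depth
#'   (m) = intercept + slope * distance-to-outlet (km). Defaults 0.073 and
#'   0.69.
#' @param secchi_noise_sd Gaussian noise on station Secchi readings, m
#'   (default 0.05; 0 disables).
#' @param chem_south_means,chem_north_means Named vectors `c(tn=, tp=,
#'   tchl=)` in ug/L giving zone means next to the outlet and at the far
#'   (north) end; station chemistry is interpolated between them along the
#'   distance axis.
#' @param chem_noise_cv Coefficient of variation of additive Gaussian
#'   chemistry noise (default 0.15; 0 disables).
#' @param biovolume_fp_rate Fraction of dark (light-starved) wet cells
#'   given spurious biovolume by the simulated sonar (default 0.03).
#' @param biovolume_fn_rate Fraction of lit cells where vegetation goes
#'   undetected (default 0.15).
#' @param biovolume_jitter SD of additive jitter on detected biovolume,
#'   percentage points (default 5; 0 disables).
#' @param truth_light_fraction Bottom light fraction above which the
#'   synthetic lake actually grows vegetation (default 0.15).
#' @param seasonal_amplitude Seasonal water-level range, m (default 2.5).
#' @param flat_depth If non-NULL, disable the random basin field and the
#'   channel and give every wet cell this constant depth (m); used for
#'   degenerate-geometry checks.
#' @param seed Integer seed; identical seeds give identical lakes.
#' @return A `lake_sim_config` list.
#' @export
lake_sim_config <- function(nx = 128, ny = 128, cell_size = 16,
                            basin_max_depth = 5, channel_max_depth = 9,
                            outlet_xy = NULL,
                            secchi_slope = 0.073, secchi_intercept = 0.69,
                            secchi_noise_sd = 0.05,
                            chem_south_means = c(tn = 398.9, tp = 40.6, tchl = 29.9),
                            chem_north_means = c(tn = 327.5, tp = 25.1, tchl = 15.2),
                            chem_noise_cv = 0.15,
                            biovolume_fp_rate = 0.03,
                            biovolume_fn_rate = 0.15,
                            biovolume_jitter = 5,
                            truth_light_fraction = 0.15,
                            seasonal_amplitude = 2.5,
                            flat_depth = NULL,
                            seed = 1L) {
  if (nx < 8 || ny < 8) stop_config("Grid dimensions must be at least 8 x 8 cells.")
  if (cell_size <= 0) stop_config("`cell_size` must be positive.")
  if (basin_max_depth < 0 || channel_max_depth < 0) {
    stop_config("Depth caps must be non-negative.")
  }
  if (channel_max_depth <= basin_max_depth) {
    stop_config("`channel_max_depth` must exceed `basin_max_depth`.")
  }
  if (biovolume_fp_rate < 0 || biovolume_fp_rate > 1 ||
      biovolume_fn_rate < 0 || biovolume_fn_rate > 1) {
    stop_config("Biovolume noise rates must lie in [0, 1].")
  }
  for (v in list(chem_south_means, chem_north_means)) {
    if (!all(c("tn", "tp", "tchl") %in% names(v))) {
      stop_config("Chemistry means need named entries `tn`, `tp`, `tchl`.")
    }
  }
  if (is.null(outlet_xy)) {
    outlet_xy <- c(nx * cell_size / 2, 1.5 * cell_size)
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), cell_size = cell_size,
    basin_max_depth = basin_max_depth, channel_max_depth = channel_max_depth,
    outlet_xy = as.numeric(outlet_xy),
    secchi_slope = secchi_slope, secchi_intercept = secchi_intercept,
    secchi_noise_sd = secchi_noise_sd,
    chem_south_means = chem_south_means, chem_north_means = chem_north_means,
    chem_noise_cv = chem_noise_cv,
    biovolume_fp_rate = biovolume_fp_rate,
    biovolume_fn_rate = biovolume_fn_rate,
    biovolume_jitter = biovolume_jitter,
    truth_light_fraction = truth_light_fraction,
    seasonal_amplitude = seasonal_amplitude,
    flat_depth = flat_depth,
    seed = as.integer(seed)
  ), class = "lake_sim_config")
}

#' Simulate a bathymetric grid
#'
#' Builds an elliptical basin with a smooth low-order random depth field
#' clipped to `[0, basin_max_depth]`, plus a deeper channel corridor
#' running from the interior to the outlet, where depth ramps up to
#' `channel_max_depth`. Cells outside the shoreline (or whose depth falls
#' to zero or below after the random field) are land, encoded as `NA`
#' depth. The returned grid has layers `depth` (m) and `channel`
#' (logical), and carries the outlet location in the `outlet_xy`
#' attribute.
#'
#' @param config A [lake_sim_config()].
#' @return A [new_lake_grid()] with `depth` and `channel` layers.
#' @export
simulate_bathymetry <- function(config) {
  stopifnot(inherits(config, "lake_sim_config"))
  nx <- config$nx; ny <- config$ny; cs <- config$cell_size
  lx <- nx * cs; ly <- ny * cs
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  x <- (ix - 0.5) * cs
  y <- (iy - 0.5) * cs
  cx <- lx / 2; cy <- ly / 2
  # elliptical shoreline: dome of unit height, land where it vanishes
  r2 <- ((x - cx) / (0.46 * lx))^2 + ((y - cy) / (0.46 * ly))^2
  dome <- 1 - r2

  if (!is.null(config$flat_depth)) {
    depth <- ifelse(dome > 0, config$flat_depth, NA_real_)
    channel <- rep(FALSE, nx * ny)
  } else {
    field <- withr::with_seed(config$seed, {
      # low-order cosine field: smooth, seeded, mean-zero
      modes <- 4L
      a <- rnorm(modes, 0, 0.12)
      p <- sample(1:2, modes, replace = TRUE)
      q <- sample(1:2, modes, replace = TRUE)
      ph <- runif(modes, 0, 2 * pi)
      f <- rep(0, length(x))
      for (j in seq_len(modes)) {
        f <- f + a[j] * cos(2 * pi * (p[j] * x / lx + q[j] * y / ly) + ph[j])
      }
      f
    })
    depth <- config$basin_max_depth * pmin(pmax(dome + field, 0), 1)
    depth[dome <= 0] <- NA_real_
    depth[!is.na(depth) & depth <= 0] <- NA_real_

    # channel: straight corridor from the outlet northwards into the basin
    ox <- config$outlet_xy[1]; oy <- config$outlet_xy[2]
    chan_len <- 0.35 * ly
    halfwidth <- 1.5 * cs
    s <- y - oy                                   # along-channel distance
    channel <- abs(x - ox) <= halfwidth & s >= 0 & s <= chan_len
    ramp <- config$basin_max_depth +
      (config$channel_max_depth - config$basin_max_depth) * (1 - s / chan_len)
    depth[channel] <- pmax(depth[channel], ramp[channel], na.rm = TRUE)
    channel <- channel & !is.na(depth)
  }

  g <- new_lake_grid(
    tibble::tibble(x = x, y = y, depth = depth, channel = channel),
    origin = c(0, 0), cell_size = cs, nx = nx, ny = ny
  )
  attr(g, "outlet_xy") <- config$outlet_xy
  g
}

#' Simulate station water-sampling records
#'
#' Scatters stations over the wet cells of a simulated lake, stratified by
#' distance to the outlet so they span the clarity gradient, and draws
#' monthly chemistry and Secchi readings. True Secchi depth is
#' `intercept + slope * distance_km` plus truncated Gaussian noise;
#' TN/TP/TChl are interpolated between the south (outlet) and north zone
#' means along the distance axis, plus truncated Gaussian noise. All
#' values are kept positive.
#'
#' @param config A [lake_sim_config()].
#' @param n_stations Number of stations (>= 2; default 18).
#' @param n_months Number of monthly visits starting in May (default 4).
#' @param bathy Optional pre-computed bathymetry from
#'   [simulate_bathymetry()]; regenerated from `config` if missing.
#' @return A tibble of station-month records with columns `station_id`,
#'   `x`, `y`, `zone`, `date`, `distance_km`, `tn`, `tp`, `tchl`,
#'   `secchi`.
#' @export
simulate_stations <- function(config, n_stations = 18, n_months = 4,
                              bathy = NULL) {
  stopifnot(inherits(config, "lake_sim_config"))
  if (n_stations < 2) stop_config("`n_stations` must be at least 2.")
  if (n_months < 1) stop_config("`n_months` must be at least 1.")
  if (is.null(bathy)) bathy <- simulate_bathymetry(config)

  wet <- which(!is.na(bathy$depth))
  d_km <- sqrt((bathy$x - config$outlet_xy[1])^2 +
               (bathy$y - config$outlet_xy[2])^2)[wet] / 1000

  withr::with_seed(config$seed + 1L, {
    # stratified placement: one random wet cell per distance band
    bands <- cut(rank(d_km, ties.method = "first"),
                 breaks = n_stations, labels = FALSE)
    cells <- vapply(seq_len(n_stations), function(b) {
      cand <- wet[bands == b]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    dist_km <- sqrt((bathy$x[cells] - config$outlet_xy[1])^2 +
                    (bathy$y[cells] - config$outlet_xy[2])^2) / 1000
    zone <- cut(dist_km, breaks = stats::quantile(dist_km, c(0, 1/3, 2/3, 1)),
                labels = c("south", "middle", "north"), include.lowest = TRUE)

    months <- sprintf("2016-%02d", 4 + seq_len(n_months))
    grid <- tidyr::expand_grid(station = seq_len(n_stations), date = months)

    w <- dist_km / max(dist_km)          # 0 at outlet, 1 at far end
    chem_mean <- function(var) {
      config$chem_south_means[[var]] +
        (config$chem_north_means[[var]] - config$chem_south_means[[var]]) * w
    }
    draw_chem <- function(var) {
      mu <- chem_mean(var)[grid$station]
      pmax(mu + rnorm(nrow(grid), 0, config$chem_noise_cv * mu), 0.1)
    }
    secchi_true <- config$secchi_intercept + config$secchi_slope * dist_km
    tibble::tibble(
      station_id = sprintf("S%02d", grid$station),
      x = bathy$x[cells][grid$station],
      y = bathy$y[cells][grid$station],
      zone = as.character(zone)[grid$station],
      date = grid$date,
      distance_km = dist_km[grid$station],
      tn = draw_chem("tn"),
      tp = draw_chem("tp"),
      tchl = draw_chem("tchl"),
      secchi = pmax(secchi_true[grid$station] +
                      rnorm(nrow(grid), 0, config$secchi_noise_sd), 0.05)
    )
  })
}

#' Simulate an observed (sonar-detected) biovolume raster
#'
#' The synthetic lake grows vegetation wherever the bottom receives at
#' least `truth_light_fraction` of surface irradiance; biovolume scales
#' from 10% at that light level to 100% in full light, so it decreases
#' with depth. Detection noise then (a) jitters detected biovolume, (b)
#' zeroes a fraction of vegetated cells (false negatives), and (c) gives a
#' fraction of dark cells spurious moderate biovolume (false positives).
#' With all noise off, observed presence is exactly the set of lit cells.
#'
#' @param bathy Bathymetry grid from [simulate_bathymetry()].
#' @param secchi_surface Aligned `lake_grid` with a `secchi` layer (m),
#'   e.g. from [predict_secchi_surface()].
#' @param config A [lake_sim_config()].
#' @return A `lake_grid` with a `biovolume` layer in percent (0-100; `NA`
#'   on land).
#' @export
simulate_observed_sav <- function(bathy, secchi_surface, config) {
  stopifnot(inherits(config, "lake_sim_config"))
  check_aligned(bathy, secchi_surface)
  check_columns(bathy, "depth", "bathy")
  check_columns(secchi_surface, "secchi", "secchi_surface")

  params <- light_params()
  frac <- percent_irradiance(bathy$depth, secchi_surface$secchi, params)
  thr <- config$truth_light_fraction
  lit <- !is.na(frac) & frac >= thr
  bio <- rep(NA_real_, nrow(bathy))
  wet <- !is.na(bathy$depth)
  bio[wet] <- 0
  bio[lit] <- 10 + 90 * (frac[lit] - thr) / (1 - thr)

  withr::with_seed(config$seed + 2L, {
    if (config$biovolume_jitter > 0 && any(lit)) {
      bio[lit] <- pmin(pmax(
        bio[lit] + rnorm(sum(lit), 0, config$biovolume_jitter), 0), 100)
    }
    if (config$biovolume_fn_rate > 0 && any(lit)) {
      idx <- which(lit)
      drop <- idx[runif(length(idx)) < config$biovolume_fn_rate]
      bio[drop] <- 0
    }
    dark <- wet & !lit
    if (config$biovolume_fp_rate > 0 && any(dark)) {
      idx <- which(dark)
      ghost <- idx[runif(length(idx)) < config$biovolume_fp_rate]
      bio[ghost] <- runif(length(ghost), 10, 26)
    }
  })
  grid_with_layer(bathy, "biovolume", bio)
}
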