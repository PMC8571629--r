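# Shared fixtures and independent brute-force oracles.

small_config <- function(..., nx = 48, ny = 48, seed = 11) {
  lake_sim_config(nx = nx, ny = ny, seed = seed, ...)
}

noise_off_config <- function(..., seed = 11) {
  small_config(secchi_noise_sd = 0, chem_noise_cv = 0,
               biovolume_jitter = 0, biovolume_fn_rate = 0,
               biovolume_fp_rate = 0, seed = seed, ...)
}

# brute-force outlier flags: pooled mean/sd, single pass
brute_outlier_flags <- function(x, k) {
  ok <- !is.na(x)
  mu <- mean(x[ok]); sigma <- sd(x[ok])
  flags <- rep(FALSE, length(x))
  if (is.finite(k) && sigma > 0) {
    for (i in seq_along(x)) {
      if (ok[i] && abs(x[i] - mu) > k * sigma) flags[i] <- TRUE
    }
  }
  flags
}

# brute-force OLS via normal equations
brute_ols <- function(X, y) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force mean-binning of points onto a snapped grid (no fill)
brute_rasterize <- function(points, cell_size) {
  x0 <- floor(min(points$x) / cell_size) * cell_size
  y0 <- floor(min(points$y) / cell_size) * cell_size
  nx <- max(1, ceiling((max(points$x) - x0) / cell_size))
  ny <- max(1, ceiling((max(points$y) - y0) / cell_size))
  m <- matrix(NA_real_, ny, nx)
  cnt <- matrix(0, ny, nx)
  for (i in seq_len(nrow(points))) {
    ix <- min(floor((points$x[i] - x0) / cell_size) + 1, nx)
    iy <- min(floor((points$y[i] - y0) / cell_size) + 1, ny)
    if (is.na(m[iy, ix])) m[iy, ix] <- 0
    m[iy, ix] <- m[iy, ix] + points$value[i]
    cnt[iy, ix] <- cnt[iy, ix] + 1
  }
  m / ifelse(cnt == 0, NA, cnt)
}

# brute-force four-way confusion tally
brute_confusion <- function(obs, prd) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(obs)) {
    if (is.na(obs[i]) || is.na(prd[i])) next
    if (obs[i] == 1 && prd[i] == 1) tp <- tp + 1L
    else if (obs[i] == 1 && prd[i] == 0) fn <- fn + 1L
    else if (obs[i] == 0 && prd[i] == 1) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# brute-force per-cell morphometry accumulation
brute_morphometry <- function(depth, cell_size) {
  area <- 0; volume <- 0
  for (d in depth) {
    if (!is.na(d)) {
      area <- area + cell_size^2
      volume <- volume + d * cell_size^2
    }
  }
  c(area_m2 = area, volume_m3 = volume)
}

# random small wet/dry presence grid as a lake_grid
random_presence_grid <- function(nx, ny, p_na = 0.2, p_pres = 0.3,
                                 cell_size = 16) {
  n <- nx * ny
  vals <- ifelse(runif(n) < p_na, NA_integer_,
                 as.integer(runif(n) < p_pres))
  g <- lake_grid_from_matrix(matrix(vals, ny, nx, byrow = TRUE),
                             layer = "presence", cell_size = cell_size)
  g
}
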