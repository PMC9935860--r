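# Seeded synthetic fixtures: every input the simulator and tests need,
# generated in code (no downloads, no bundled observational data).

#' Generate a synthetic tidal constituent set
#'
#' Builds an M2 + S2 pair (optionally plus minor constituents) whose
#' fortnightly beat envelope hits prescribed spring and neap high-water
#' levels: amplitudes solve A_M2 + A_S2 = spring_high and
#' A_M2 - A_S2 = neap_high. Defaults emulate the study-site forcing
#' (spring high ~ +2.5 m, neap high ~ +2.0 m AMSL).
#'
#' @param spring_high Spring high water, m AMSL.
#' @param neap_high Neap high water, m AMSL (must be positive and below
#'   `spring_high`).
#' @param minors Optional data frame of extra constituents (columns `name`,
#'   `amplitude_m`, `phase_deg`, `omega_rad_s`) appended as-is.
#' @param seed Optional seed; only used to draw random phases when
#'   `random_phases = TRUE`.
#' @param random_phases Logical; draw M2/S2 phases uniformly instead of 0.
#' @return A [tide_constituents()] object.
#' @export
gen_constituents <- function(spring_high = 2.5, neap_high = 2.0,
                             minors = NULL, seed = NULL,
                             random_phases = FALSE) {
  if (!(spring_high >= neap_high && neap_high > 0))
    stop("need spring_high >= neap_high > 0")
  a_m2 <- (spring_high + neap_high) / 2
  a_s2 <- (spring_high - neap_high) / 2
  omega_m2 <- 2 * pi / (12.4206012 * 3600)
  omega_s2 <- 2 * pi / (12.0 * 3600)
  ph <- c(0, 0)
  if (random_phases) {
    if (!is.null(seed)) set.seed(seed)
    ph <- stats::runif(2, 0, 360)
  }
  cs <- tide_constituents(c("M2", "S2"), c(a_m2, a_s2), ph,
                          c(omega_m2, omega_s2))
  if (!is.null(minors)) {
    cs <- tide_constituents(c(cs$name, minors$name),
                            c(cs$amplitude_m, minors$amplitude_m),
                            c(cs$phase_deg, minors$phase_deg),
                            c(cs$omega_rad_s, minors$omega_rad_s))
  }
  cs
}

#' Generate a synthetic suspended-sediment decay series
#'
#' Samples the quiescent settling decay C(t) = C_s0 exp(-t w_s / h) at
#' uniform times and adds Gaussian noise truncated at zero.
#'
#' @param ws Settling velocity, m s^-1 (default 1e-4, i.e. 0.1 mm s^-1).
#' @param h Flow depth, m (default 0.30).
#' @param c_s0 Initial concentration, kg m^-3 (default 0.10).
#' @param noise_sd Noise standard deviation, kg m^-3.
#' @param n_points Number of samples.
#' @param t_max Duration, s; default spans two e-folding times.
#' @param seed Seed for the noise draw.
#' @return A `tss_series` data frame with `time_s`, `conc_kg_m3` and the
#'   generating parameters as attributes.
#' @export
gen_tss_series <- function(ws = 1e-4, h = 0.30, c_s0 = 0.10,
                           noise_sd = 0, n_points = 25,
                           t_max = 2 * h / ws, seed = NULL) {
  stopifnot(ws > 0, h > 0, c_s0 > 0, noise_sd >= 0, n_points >= 3)
  tt <- seq(0, t_max, length.out = n_points)
  conc <- c_s0 * exp(-tt * ws / h)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    conc <- pmax(0, conc + stats::rnorm(n_points, 0, noise_sd))
  }
  structure(data.frame(time_s = tt, conc_kg_m3 = conc),
            class = c("tss_series", "data.frame"),
            ws = ws, h = h, c_s0 = c_s0, noise_sd = noise_sd, seed = seed)
}

#' Generate a miniature creekshed domain for fast solver tests
#'
#' A shrunken version of the standard creekshed preserving its zone
#' topology: seaward channel, central creek ending short of the landward
#' boundary, creekhead band with optional mounds, levee and levee-adjacent
#' strips scaled down proportionally.
#'
#' @param width_m Long-shore extent, m (default 10).
#' @param length_m Landward extent, m (default 40).
#' @param cover Mussel cover fraction of the creekhead band.
#' @param cell Cell size, m (uniform; default 1).
#' @param vegetated Logical.
#' @return A `marsh_domain` (same structure as [build_paper_domain()]).
#' @export
gen_mini_domain <- function(width_m = 10, length_m = 40, cover = 0.10,
                            cell = 1, vegetated = TRUE) {
  scale <- length_m / 207
  channel_len <- max(2 * cell, round(20 * scale / cell) * cell)
  head_len <- max(2 * cell, round(50 * scale / cell) * cell)
  if (width_m / cell != round(width_m / cell) ||
      length_m / cell != round(length_m / cell))
    stop(sprintf("extents (%g x %g m) must be divisible by the cell size %g m",
                 width_m, length_m, cell))
  n_cols <- as.integer(width_m / cell)
  n_rows <- as.integer(length_m / cell)
  dy <- rep(cell, n_rows)
  y_edge <- c(0, cumsum(dy))
  y_center <- (y_edge[-1] + y_edge[-(n_rows + 1)]) / 2
  x_center <- seq(cell / 2, width_m - cell / 2, by = cell)
  mid_len <- length_m - channel_len - head_len
  if (mid_len < 2 * cell) stop("domain too short for channel + creek + creekhead")

  zone <- matrix(match("PLATFORM", ZONE_LEVELS), n_rows, n_cols)
  zb <- matrix(0.79, n_rows, n_cols)
  creek_cols <- max(1L, n_cols %/% 2)
  levee_w <- max(cell, round(5 * scale / cell) * cell)
  adj_w <- max(cell, round(10 * scale / cell) * cell)
  for (j in seq_len(n_rows)) {
    y <- y_center[j]
    if (y < channel_len) {
      zone[j, ] <- match("CHANNEL", ZONE_LEVELS)
      zb[j, ] <- -6 + (y / channel_len) * 6
    } else if (y < channel_len + mid_len) {
      zone[j, creek_cols] <- match("CREEK", ZONE_LEVELS)
      frac <- (channel_len + mid_len - y) / mid_len
      zb[j, creek_cols] <- 0.79 - frac * 1.79
      for (i in seq_len(n_cols)) {
        if (i == creek_cols) next
        d <- min(y - channel_len, abs(x_center[i] - x_center[creek_cols]) - cell / 2)
        if (d < levee_w) {
          zone[j, i] <- match("LEVEE", ZONE_LEVELS); zb[j, i] <- 0.94
        } else if (d < levee_w + adj_w) {
          zone[j, i] <- match("LEVEE_ADJACENT", ZONE_LEVELS)
        }
      }
    } else {
      zone[j, ] <- match("CREEKHEAD", ZONE_LEVELS)
    }
  }
  area_mat <- outer(dy, rep(cell, n_cols))
  head_mask <- zone == match("CREEKHEAD", ZONE_LEVELS)
  pm <- place_mounds(head_mask, cover, mound_area = 0.25, cell_area = area_mat)
  zone[pm$mask] <- match("MUSSEL_MOUND", ZONE_LEVELS)
  veg <- vegetation_classes()
  veg_class <- matrix(1L, n_rows, n_cols)
  if (vegetated) {
    veg_class[zone == match("LEVEE", ZONE_LEVELS)] <- match("tall", veg$class)
    veg_class[zone == match("LEVEE_ADJACENT", ZONE_LEVELS)] <- match("intermediate", veg$class)
    veg_class[zone %in% match(c("PLATFORM", "CREEKHEAD", "MUSSEL_MOUND"),
                              ZONE_LEVELS)] <- match("short", veg$class)
    veg_class[zb <= 0] <- 1L
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, dx = cell, dy = dy,
                 x_center = x_center, y_center = y_center,
                 cell_area = area_mat, zb = zb, zone = zone,
                 veg = veg, veg_class = veg_class,
                 mound_frac = pm$frac, rho_mm_eff = 177 * pm$frac,
                 mound_count = pm$count, mussel_cover = cover,
                 vegetated = vegetated, cell_scale = cell / 0.5,
                 rho_mm = 177, zone_levels = ZONE_LEVELS),
            class = "marsh_domain")
}

#' Generate a straight sloping flume domain (solver validation)
#'
#' A 1-D open channel: uniform bed slope dropping seaward, uniform cells,
#' no vegetation, no zones beyond CHANNEL. Used for uniform-flow and
#' advection-dispersion checks against closed forms.
#'
#' @param n_rows Number of cells along the flume.
#' @param n_cols Number of cells across (default 1).
#' @param cell Cell size, m.
#' @param slope Bed slope (positive = bed rises landward).
#' @param zb0 Bed elevation of the seaward cell centre, m AMSL.
#' @return A `marsh_domain`.
#' @export
flume_domain <- function(n_rows = 100, n_cols = 1, cell = 1,
                         slope = 1e-4, zb0 = -2) {
  dy <- rep(cell, n_rows)
  y_center <- seq(cell / 2, n_rows * cell - cell / 2, by = cell)
  x_center <- seq(cell / 2, n_cols * cell - cell / 2, by = cell)
  zb <- matrix(zb0 + slope * y_center, n_rows, n_cols)
  zone <- matrix(match("CHANNEL", ZONE_LEVELS), n_rows, n_cols)
  veg <- vegetation_classes()
  structure(list(n_rows = n_rows, n_cols = n_cols, dx = cell, dy = dy,
                 x_center = x_center, y_center = y_center,
                 cell_area = outer(dy, rep(cell, n_cols)),
                 zb = zb, zone = zone, veg = veg,
                 veg_class = matrix(1L, n_rows, n_cols),
                 mound_frac = matrix(0, n_rows, n_cols),
                 rho_mm_eff = matrix(0, n_rows, n_cols),
                 mound_count = 0L, mussel_cover = 0, vegetated = FALSE,
                 cell_scale = cell / 0.5, rho_mm = 177,
                 zone_levels = ZONE_LEVELS),
            class = "marsh_domain")
}

#' Read / write a TSS decay series
#'
#' Delimited text with header `time_s,conc_kg_m3`.
#' @param path File path.
#' @export
read_tss_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "conc_kg_m3") %in% names(df)))
    stop("TSS table must have columns time_s, conc_kg_m3")
  structure(df[c("time_s", "conc_kg_m3")],
            class = c("tss_series", "data.frame"))
}

#' @rdname read_tss_series
#' @param series A `tss_series`.
#' @export
write_tss_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("time_s", "conc_kg_m3")], path,
                   row.names = FALSE)
  invisible(path)
}
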