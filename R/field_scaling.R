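#' Creekhead areal coverage from creekhead density
#'
#' Scales a creekhead count density (creeks per square kilometre of
#' contiguous marsh) to the percent of marsh creekshed area occupied by
#' creekheads, assuming each creekhead zone of influence covers a fixed area
#' (default 0.0025 km^2, i.e. a 50 m x 50 m square at the point where the
#' creek debouches onto the platform).
#'
#' @param density Creekhead density, creeks km^-2. Vectorised.
#' @param creekhead_area Area of one creekhead zone, km^2 (default 0.0025).
#' @param creekshed_area Reference creekshed area, km^2 (default 1).
#' @return Coverage in percent.
#' @examples
#' creekhead_areal_coverage(110.2) # ~27.6 %
#' @export
creekhead_areal_coverage <- function(density, creekhead_area = 0.0025,
                                     creekshed_area = 1) {
  stopifnot(all(density >= 0), creekhead_area > 0, creekshed_area > 0)
  100 * creekhead_area * density / creekshed_area
}

#' Creekshed-scale mussel coverage
#'
#' Product of the percent of the creekshed occupied by creekheads and the
#' fraction of creekhead area occupied by mussel aggregations.
#'
#' @param creekhead_cover Creekhead coverage, percent (0-100).
#' @param mussel_fraction Fraction of creekhead area occupied by mussels
#'   (0-1).
#' @return Mussel areal coverage of the creekshed, percent.
#' @examples
#' creekshed_mussel_coverage(27.6, 0.103) # ~2.8 %
#' @export
creekshed_mussel_coverage <- function(creekhead_cover, mussel_fraction) {
  stopifnot(all(creekhead_cover >= 0), all(creekhead_cover <= 100),
            all(mussel_fraction >= 0), all(mussel_fraction <= 1))
  creekhead_cover * mussel_fraction
}

#' Estimate marsh platform elevation from mussel-mound heights
#'
#' Mature mussel aggregations grow to a regional height ceiling (m AMSL);
#' the platform elevation under a mature mound is then the ceiling minus the
#' mound height above the platform. Returns per-mound elevations and, when
#' grouping labels are supplied, a transect-level summary: the creek-level
#' mean is the mean of the transect means (not the pooled per-mound mean).
#'
#' @param heights Mound heights above the platform, m. Either a numeric
#'   vector or a data frame with columns `height_m` and optionally
#'   `transect` and `creek`.
#' @param ceiling Mound growth ceiling, m AMSL (default 0.84).
#' @return A list with `elevation` (per-mound, m AMSL), `mean`, `sd`,
#'   `outliers` (indices with height exceeding ceiling + 1 m), and, when
#'   grouping is present, data frames `by_transect` and `by_creek` (creek
#'   mean taken over transect means).
#' @export
platform_elevation_from_mounds <- function(heights, ceiling = 0.84) {
  if (is.data.frame(heights)) {
    df <- heights
    stopifnot("height_m" %in% names(df))
    h <- df$height_m
  } else {
    df <- data.frame(height_m = as.numeric(heights))
    h <- df$height_m
  }
  stopifnot(all(h >= 0), is.finite(ceiling))
  outliers <- which(h > ceiling + 1)
  elev <- ceiling - h
  out <- list(elevation = elev,
              mean = mean(elev), sd = stats::sd(elev),
              outliers = outliers)
  if (!is.null(df$transect)) {
    bt <- stats::aggregate(elev, by = list(transect = df$transect,
                                           creek = if (is.null(df$creek)) rep("all", length(elev)) else df$creek),
                           FUN = mean)
    names(bt)[names(bt) == "x"] <- "mean_elevation"
    out$by_transect <- bt
    bc <- stats::aggregate(bt$mean_elevation, by = list(creek = bt$creek), FUN = mean)
    names(bc)[names(bc) == "x"] <- "mean_elevation"
    bc$sd_elevation <- stats::aggregate(bt$mean_elevation,
                                        by = list(creek = bt$creek),
                                        FUN = stats::sd)$x
    out$by_creek <- bc
  }
  out
}

#' Fit a settling velocity to a suspended-sediment decay series
#'
#' Fits the quiescent exponential settling decay
#' \eqn{C(t) = C_{s0} e^{-t w_s / h}} to an observed concentration series by
#' least squares in \eqn{w_s}. The initial concentration can be held fixed
#' or co-estimated (profiled in closed form for each candidate \eqn{w_s}).
#'
#' @param series A data frame with columns `time_s` and `conc_kg_m3` (a
#'   `tss_series` from [gen_tss_series()] works directly).
#' @param h Flow depth, m (default 0.30, a mean-high-tide water depth).
#' @param c_s0 Initial concentration, kg m^-3. If `NULL` (default) it is
#'   co-estimated; otherwise held fixed.
#' @param ws_range Search bracket for the settling velocity, m s^-1.
#' @return A list with `ws` (m s^-1), `c_s0`, `mae` and `rmse` (kg m^-3),
#'   and `fitted` values.
#' @export
fit_settling_velocity <- function(series, h = 0.30, c_s0 = NULL,
                                  ws_range = c(1e-7, 1e-2)) {
  stopifnot(is.data.frame(series), nrow(series) >= 3, h > 0)
  t <- series$time_s
  conc <- series$conc_kg_m3
  stopifnot(!is.unsorted(t, strictly = TRUE), all(conc >= 0))
  if (all(conc == 0)) stop("all concentrations are zero; nothing to fit")

  sse <- function(ws) {
    decay <- exp(-t * ws / h)
    c0 <- if (is.null(c_s0)) sum(conc * decay) / sum(decay^2) else c_s0
    sum((conc - c0 * decay)^2)
  }
  # optimise on log(ws): the decay rate spans orders of magnitude
  opt <- stats::optimize(function(lw) sse(exp(lw)), log(ws_range), tol = 1e-12)
  ws <- exp(opt$minimum)
  decay <- exp(-t * ws / h)
  c0 <- if (is.null(c_s0)) sum(conc * decay) / sum(decay^2) else c_s0
  fitted <- c0 * decay
  resid <- conc - fitted
  list(ws = ws, c_s0 = c0,
       mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)),
       fitted = fitted)
}

#' Convert a surface deposition flux to a vertical accretion rate
#'
#' Transparent dimensional calculator: a dry-mass flux collected on the
#' marsh surface (g cm^-2 d^-1) divided by the dry bulk density of the
#' deposit (g cm^-3) gives a thickness rate, scaled to a year and by the
#' fraction of days on which the site is actually flooded. All assumptions
#' are arguments and are echoed in the result.
#'
#' @param flux Deposition flux, g cm^-2 d^-1. Vectorised.
#' @param dry_density Dry bulk density of the deposit, g cm^-3 (default 0.8).
#' @param flooding_factor Fraction of days with depositional flooding
#'   (default 1).
#' @param days_per_year Days per year (default 365.25).
#' @return A data frame with the inputs and `accretion_cm_yr`.
#' @examples
#' deposition_to_accretion(1e-3, 0.8, 1) # 0.457 cm/yr
#' @export
deposition_to_accretion <- function(flux, dry_density = 0.8,
                                    flooding_factor = 1,
                                    days_per_year = 365.25) {
  stopifnot(all(flux >= 0), dry_density > 0,
            flooding_factor >= 0, flooding_factor <= 1)
  data.frame(flux_g_cm2_d = flux,
             dry_density_g_cm3 = dry_density,
             flooding_factor = flooding_factor,
             accretion_cm_yr = flux / dry_density * days_per_year * flooding_factor)
}
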