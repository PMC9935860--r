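# Scenario engine: crossed vegetation x mussel-cover experiments on the
# standard creekshed, multi-scale aggregation, baseline comparison and
# sensitivity variants.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario configuration
#'
#' The baseline study scenario is vegetated, 10 % mussel cover, no
#' resuspension.
#'
#' @param vegetated Logical.
#' @param mussel_cover Fraction of creekhead area under mounds (0-1).
#' @param resuspension Enable erosion of mound deposits (sensitivity).
#' @param cell_scale Grid coarsening factor (see [build_paper_domain()];
#'   default 4, i.e. 2 m cells).
#' @param duration Simulation window, s (default 16 days).
#' @param sediment A [sediment_params()] object.
#' @param bivalves A [bivalve_params()] object.
#' @param veg A [vegetation_classes()] table.
#' @param constituents Tidal forcing constituents; default
#'   [gen_constituents()] (spring high +2.5 m, neap high +2.0 m).
#' @param window Optional `c(t_start, t_end)` s into the tidal record; by
#'   default the representative spring-neap window is selected from a
#'   synthesized year.
#' @param dt Solver step, s; default CFL-derived via [cfl_dt()].
#' @param bc_dt Boundary sampling step, s (default 60).
#' @param domain Optional prebuilt `marsh_domain` overriding the standard
#'   geometry (miniature test domains).
#' @param seed Seed recorded in the result; the pipeline is deterministic.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(vegetated = TRUE, mussel_cover = 0.10,
                            resuspension = FALSE, cell_scale = 4,
                            duration = 16 * 86400,
                            sediment = sediment_params(),
                            bivalves = bivalve_params(),
                            veg = vegetation_classes(),
                            constituents = NULL, window = NULL,
                            dt = NULL, bc_dt = 60, domain = NULL,
                            seed = 1L) {
  structure(list(vegetated = vegetated, mussel_cover = mussel_cover,
                 resuspension = resuspension, cell_scale = cell_scale,
                 duration = duration, sediment = sediment,
                 bivalves = bivalves, veg = veg,
                 constituents = constituents, window = window,
                 dt = dt, bc_dt = bc_dt, domain = domain, seed = seed),
            class = "scenario_config")
}

#' Location-type masks of a domain
#'
#' The five local marsh location types: levee crest, levee-adjacent,
#' mussel aggregation, aggregation-adjacent (ring of cells within 1 m of a
#' mound, not itself a mound) and non-mussel platform; plus the creekhead
#' (2500 m^2 band incl. mounds) and whole-domain masks.
#'
#' @param domain A `marsh_domain`.
#' @return A named list of logical matrices.
#' @export
location_masks <- function(domain) {
  z <- domain$zone
  lv <- domain$zone_levels
  mound <- z == match("MUSSEL_MOUND", lv)
  # ring within 1 m of a mound: dilate by ceiling(1 m / cell dimension)
  rx <- max(1L, ceiling(1 / domain$dx))
  ry <- max(1L, ceiling(1 / min(domain$dy)))
  dil <- mound
  if (any(mound)) {
    for (sft in seq_len(ry)) {
      dil[-(1:sft), ] <- dil[-(1:sft), ] | mound[1:(nrow(mound) - sft), ]
      dil[1:(nrow(mound) - sft), ] <- dil[1:(nrow(mound) - sft), ] | mound[-(1:sft), ]
    }
    m2 <- dil
    for (sft in seq_len(rx)) {
      dil[, -(1:sft)] <- dil[, -(1:sft)] | m2[, 1:(ncol(m2) - sft)]
      dil[, 1:(ncol(m2) - sft)] <- dil[, 1:(ncol(m2) - sft)] | m2[, -(1:sft)]
    }
  }
  list(levee = z == match("LEVEE", lv),
       levee_adjacent = z == match("LEVEE_ADJACENT", lv),
       mound = mound,
       mound_adjacent = dil & !mound,
       platform = z == match("PLATFORM", lv),
       creekhead = matrix(z %in% match(c("CREEKHEAD", "MUSSEL_MOUND"), lv),
                          nrow(z), ncol(z)),
       marsh = z != match("CHANNEL", lv),
       domain = matrix(TRUE, domain$n_rows, domain$n_cols))
}

.location_stats <- function(acc, dep_m3, masks, area) {
  types <- c("levee", "levee_adjacent", "mound", "mound_adjacent", "platform")
  do.call(rbind, lapply(types, function(ty) {
    m <- masks[[ty]]
    data.frame(type = ty, n_cells = sum(m), area_m2 = sum(area[m]),
               mean_accretion_cm_yr = if (any(m)) mean(acc[m]) else NA_real_,
               sd_accretion_cm_yr = if (sum(m) > 1) stats::sd(acc[m]) else NA_real_,
               deposition_m3_yr = sum(dep_m3[m]))
  }))
}

#' Run one vegetation x mussel-cover scenario
#'
#' Couples tidal forcing, shallow-water flow, sediment transport and the
#' mussel filtration sink over a representative 16-day spring-neap window,
#' then annualises. Deterministic for a given configuration.
#'
#' @param config A [scenario_config()].
#' @param c_boundary Optional boundary concentration override, kg m^-3
#'   (e.g. a calibrated value); defaults to `config$sediment$c_boundary`.
#' @return A `scenario_result`: the domain, per-cell `accretion_cm_yr`,
#'   `dep_m_yr` (deposition depth, m yr^-1) and `deposition_m3_yr`
#'   matrices, process-split ledgers, `location_stats`, `creekhead` and
#'   `domain_totals` aggregates, budget diagnostics, and the tide window
#'   used.
#' @export
run_scenario <- function(config, c_boundary = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  domain <- config$domain %||%
    build_paper_domain(cell_scale = config$cell_scale,
                       mussel_cover = config$mussel_cover,
                       vegetated = config$vegetated, veg = config$veg)
  cons <- config$constituents %||% gen_constituents()
  if (is.null(config$window)) {
    year <- synthesize_tide(cons, 0, 365 * 86400, 600)
    win <- select_tide_window(year, period_length_s = config$duration)
  } else {
    win <- list(t_start = config$window[1], t_end = config$window[2])
  }
  times <- seq(win$t_start, win$t_start + config$duration, by = config$bc_dt)
  levels <- eval_tide(cons, times)
  dt <- config$dt %||% default_dt(domain, max(levels))
  sed <- config$sediment
  if (!is.null(c_boundary)) sed$c_boundary <- c_boundary

  state <- step_sediment(domain, levels, config$duration, dt,
                         params = sed, bivalves = config$bivalves,
                         erosion = config$resuspension, bc_dt = config$bc_dt)
  ann <- accretion_rate(state, domain, config$duration)
  masks <- location_masks(domain)
  res <- list(domain = domain, config = config,
              c_boundary = sed$c_boundary,
              dt = dt, window = c(win$t_start, win$t_start + config$duration),
              dz_settling = state$dz_settling,
              dz_filtration = state$dz_filtration,
              dz_erosion = state$dz_erosion,
              accretion_cm_yr = ann$accretion_cm_yr,
              dep_m_yr = ann$accretion_cm_yr / 100,
              deposition_m3_yr = ann$deposition_m3_yr,
              annual_factor = ann$annual_factor,
              location_stats = .location_stats(ann$accretion_cm_yr,
                                               ann$deposition_m3_yr, masks,
                                               domain$cell_area),
              creekhead = list(
                deposition_m3_yr = sum(ann$deposition_m3_yr[masks$creekhead]),
                accretion_cm_yr = mean(ann$accretion_cm_yr[masks$creekhead])),
              domain_totals = list(
                deposition_m3_yr = sum(ann$deposition_m3_yr),
                accretion_cm_yr = mean(ann$accretion_cm_yr)),
              budget = state[c("vol_in", "vol_out", "sed_in", "sed_out",
                               "suspended_kg", "max_vol_resid",
                               "max_mass_resid", "clamp_mass_kg",
                               "clamp_vol_m3")])
  class(res) <- "scenario_result"
  res
}

# exact linear rescaling of a (no-erosion) result in the boundary
# concentration; used by the calibration shortcut
.scale_result <- function(res, f) {
  for (nm in c("dz_settling", "dz_filtration", "dz_erosion",
               "accretion_cm_yr", "dep_m_yr", "deposition_m3_yr"))
    res[[nm]] <- res[[nm]] * f
  res$location_stats$mean_accretion_cm_yr <-
    res$location_stats$mean_accretion_cm_yr * f
  res$location_stats$sd_accretion_cm_yr <-
    res$location_stats$sd_accretion_cm_yr * f
  res$location_stats$deposition_m3_yr <-
    res$location_stats$deposition_m3_yr * f
  res$creekhead <- lapply(res$creekhead, `*`, f)
  res$domain_totals <- lapply(res$domain_totals, `*`, f)
  res$c_boundary <- res$c_boundary * f
  res
}

#' Calibrate the boundary concentration against a platform accretion target
#'
#' The transport-deposition system is linear in the boundary concentration
#' (flow does not feel the sediment), so a single baseline run determines
#' the calibrated value exactly: c_cal = c_0 * target / accretion(c_0).
#'
#' @param config Baseline [scenario_config()] (erosion must be off; erosion
#'   caps would break linearity).
#' @param target Platform mean annual accretion to match, cm yr^-1
#'   (default 0.9).
#' @param baseline_run Optional precomputed `scenario_result` for `config`,
#'   to avoid re-running.
#' @return A list: `c_boundary` (calibrated, kg m^-3), `factor`, and
#'   `baseline` (the baseline result rescaled to the calibrated value).
#' @export
calibrate_c_boundary <- function(config, target = 0.9, baseline_run = NULL) {
  stopifnot(!config$resuspension)
  res <- baseline_run %||% run_scenario(config)
  acc <- res$location_stats$mean_accretion_cm_yr[
    res$location_stats$type == "platform"]
  if (!is.finite(acc) || acc <= 0)
    stop("baseline platform accretion is not positive; cannot calibrate")
  f <- target / acc
  list(c_boundary = res$c_boundary * f, factor = f,
       baseline = .scale_result(res, f))
}

#' Compare a scenario with the baseline
#'
#' All location types are evaluated on the baseline's masks (so mound
#' locations keep their identity in a removal scenario). Percent changes
#' are reported two ways: `pct_change_mean` (change of the location-type
#' mean) and `pct_change_cellwise` (mean over cells of the per-cell percent
#' change); zero-deposition baseline cells are excluded and counted.
#'
#' @param result,baseline `scenario_result` objects sharing grid geometry.
#' @return A list: `by_location` data frame, `creekhead` and `domain` delta
#'   lists (`d_deposition_m3_yr`, `d_accretion_cm_yr`).
#' @export
compare_scenarios <- function(result, baseline) {
  stopifnot(all(dim(result$accretion_cm_yr) == dim(baseline$accretion_cm_yr)))
  masks <- location_masks(baseline$domain)
  types <- c("levee", "levee_adjacent", "mound", "mound_adjacent", "platform")
  by_loc <- do.call(rbind, lapply(types, function(ty) {
    m <- masks[[ty]]
    if (!any(m))
      return(data.frame(type = ty, n_cells = 0, n_zero_baseline = 0,
                        pct_change_mean = NA_real_,
                        pct_change_cellwise = NA_real_))
    vb <- baseline$dep_m_yr[m]; vv <- result$dep_m_yr[m]
    ok <- vb != 0
    data.frame(type = ty, n_cells = sum(m), n_zero_baseline = sum(!ok),
               pct_change_mean = 100 * (mean(vv) - mean(vb)) / mean(vb),
               pct_change_cellwise = mean(100 * (vv[ok] - vb[ok]) / vb[ok]))
  }))
  ch <- masks$creekhead
  list(by_location = by_loc,
       creekhead = list(
         d_deposition_m3_yr = sum(result$deposition_m3_yr[ch]) -
           sum(baseline$deposition_m3_yr[ch]),
         d_accretion_cm_yr = mean(result$accretion_cm_yr[ch]) -
           mean(baseline$accretion_cm_yr[ch])),
       domain = list(
         d_deposition_m3_yr = sum(result$deposition_m3_yr) -
           sum(baseline$deposition_m3_yr),
         d_accretion_cm_yr = mean(result$accretion_cm_yr) -
           mean(baseline$accretion_cm_yr)))
}

#' Mussel-attributable extra deposition
#'
#' Total domain deposition of a mussel scenario minus the matching
#' zero-cover run: the deposition the mounds add to the system.
#'
#' @param with_mussels,without_mussels `scenario_result` objects differing
#'   only in mussel cover.
#' @return A list: `extra_m3_yr` (domain total), `extra_creekhead_m3_yr`,
#'   and `creekhead_share` (fraction of the extra deposition inside the
#'   creekhead mask).
#' @export
extra_deposition <- function(with_mussels, without_mussels) {
  ch <- location_masks(with_mussels$domain)$creekhead
  d <- with_mussels$deposition_m3_yr - without_mussels$deposition_m3_yr
  list(extra_m3_yr = sum(d),
       extra_creekhead_m3_yr = sum(d[ch]),
       creekhead_share = sum(d[ch]) / sum(d))
}

#' Run a named set of sensitivity variants
#'
#' Each variant reruns the mussel and the matching zero-cover scenario
#' under a perturbed configuration and reports the percent change in
#' mussel-attributable extra deposition relative to the unperturbed pair.
#'
#' Built-in variants: `ws_plus_50` (settling velocity x 1.5), `cell_fine`
#' (cell_scale halved), `resuspension` (erosion on mounds),
#' `double_density` (mussel density x 2), `null` (no change).
#'
#' @param base_config Baseline [scenario_config()] (its `mussel_cover` is
#'   the "with mussels" case).
#' @param variants Character vector of variant names, or a named list of
#'   functions `function(config) config` transforming the configuration.
#' @param c_boundary Calibrated boundary concentration shared by all runs.
#' @param base_pair Optional precomputed list(with, without) for the
#'   unperturbed pair.
#' @return A data frame: variant, extra deposition before/after (m^3
#'   yr^-1), `delta_pct`.
#' @export
sensitivity_suite <- function(base_config, variants = c("ws_plus_50"),
                              c_boundary = NULL, base_pair = NULL) {
  builtin <- list(
    ws_plus_50 = function(cf) { cf$sediment$ws <- cf$sediment$ws * 1.5; cf },
    cell_fine = function(cf) { cf$cell_scale <- max(1, cf$cell_scale / 2); cf },
    resuspension = function(cf) { cf$resuspension <- TRUE; cf },
    double_density = function(cf) {
      cf$bivalves <- bivalve_params(rho_mm = cf$bivalves$rho_mm * 2,
                                    f_mm = cf$bivalves$f_mm,
                                    f_mm_unit = cf$bivalves$f_mm_unit); cf },
    null = function(cf) cf)
  if (is.character(variants)) {
    bad <- setdiff(variants, names(builtin))
    if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "))
    variants <- builtin[variants]
  }
  pair <- function(cf) {
    cf0 <- cf; cf0$mussel_cover <- 0
    list(with = run_scenario(cf, c_boundary),
         without = run_scenario(cf0, c_boundary))
  }
  base <- base_pair %||% pair(base_config)
  extra0 <- extra_deposition(base$with, base$without)$extra_m3_yr
  out <- lapply(names(variants), function(nm) {
    cf <- variants[[nm]](base_config)
    pr <- if (identical(variants[[nm]], builtin$null)) base else pair(cf)
    ex <- extra_deposition(pr$with, pr$without)$extra_m3_yr
    data.frame(variant = nm, extra_base_m3_yr = extra0,
               extra_variant_m3_yr = ex,
               delta_pct = 100 * (ex - extra0) / extra0)
  })
  do.call(rbind, out)
}

#' Write scenario summaries to delimited text
#'
#' Writes the location-type summary and the multi-scale totals as CSV, and
#' the per-cell annualised fields as long-format TSV.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_scenario_result <- function(result, dir, prefix = "scenario") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$location_stats,
                   file.path(dir, paste0(prefix, "_locations.csv")),
                   row.names = FALSE)
  totals <- data.frame(
    scale = c("creekhead", "domain"),
    area_m2 = c(sum(result$domain$cell_area[location_masks(result$domain)$creekhead]),
                sum(result$domain$cell_area)),
    deposition_m3_yr = c(result$creekhead$deposition_m3_yr,
                         result$domain_totals$deposition_m3_yr),
    accretion_cm_yr = c(result$creekhead$accretion_cm_yr,
                        result$domain_totals$accretion_cm_yr))
  utils::write.csv(totals, file.path(dir, paste0(prefix, "_totals.csv")),
                   row.names = FALSE)
  d <- result$domain
  df <- expand.grid(row = seq_len(d$n_rows), col = seq_len(d$n_cols))
  df$dz_settling_m <- result$dz_settling[cbind(df$row, df$col)]
  df$dz_filtration_m <- result$dz_filtration[cbind(df$row, df$col)]
  df$dz_erosion_m <- result$dz_erosion[cbind(df$row, df$col)]
  df$accretion_cm_yr <- result$accretion_cm_yr[cbind(df$row, df$col)]
  utils::write.table(df, file.path(dir, paste0(prefix, "_cells.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
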