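# R surface over the compiled shallow-water / sediment stepper.

#' Sediment transport parameters
#'
#' @param ws Settling velocity, m s^-1 (default 1e-4, i.e. 0.1 mm s^-1).
#' @param rho_sed_dry Dry bed density, kg m^-3 (default 800).
#' @param c_boundary Suspended concentration carried by flood water at the
#'   seaward boundary, kg m^-3 (default 0.05; the calibration knob).
#' @param diffusivity Horizontal eddy diffusivity, m^2 s^-1 (default 1, a
#'   grid-scale dispersion coefficient for metre-scale cells).
#' @param tau_ce Critical shear stress for erosion on mounds, N m^-2
#'   (default 1; only used when erosion is enabled).
#' @param m_erod Erodibility, kg m^-2 s^-1 (default 1e-4).
#' @return A `sediment_params` list.
#' @export
sediment_params <- function(ws = 1e-4, rho_sed_dry = 800, c_boundary = 0.05,
                            diffusivity = 1, tau_ce = 1, m_erod = 1e-4) {
  stopifnot(ws >= 0, rho_sed_dry > 0, c_boundary >= 0, diffusivity >= 0,
            tau_ce > 0, m_erod >= 0)
  structure(list(ws = ws, rho_sed_dry = rho_sed_dry,
                 c_boundary = c_boundary, diffusivity = diffusivity,
                 tau_ce = tau_ce, m_erod = m_erod),
            class = "sediment_params")
}

#' CFL-limited time step for the explicit solver
#'
#' dt = factor * min(cell dimension) / sqrt(g * h_max), where h_max is the
#' largest possible depth (highest boundary level minus deepest bed).
#'
#' @param domain A `marsh_domain`.
#' @param eta_max Highest water level reached by the forcing, m AMSL.
#' @param factor Safety factor (default 0.4).
#' @param dt_max Upper bound, s (default 0.6, the reference-resolution step).
#' @return Time step, s.
#' @export
cfl_dt <- function(domain, eta_max, factor = 0.4, dt_max = 0.6) {
  h_max <- max(eta_max - min(domain$zb), 0.1)
  min(dt_max, factor * min(domain$dx, min(domain$dy)) / sqrt(9.81 * h_max))
}

#' Default time step for a scheme
#'
#' The explicit scheme is bound by the gravity-wave CFL ([cfl_dt()]). The
#' ADI scheme treats the free surface implicitly, so its step is bound by
#' the (explicit) advective Courant number: dt = factor * min(cell
#' dimension) / u_ref with a reference current speed u_ref (default
#' 2 m s^-1, above the strongest creek currents the standard forcing
#' drives).
#'
#' @inheritParams cfl_dt
#' @param scheme `"adi"` or `"explicit"`.
#' @param u_ref Reference maximum current speed, m s^-1.
#' @param factor Courant safety factor for the ADI limit (default 0.9).
#' @return Time step, s.
#' @export
default_dt <- function(domain, eta_max, scheme = c("adi", "explicit"),
                       u_ref = 2, factor = 0.9) {
  scheme <- match.arg(scheme)
  if (scheme == "explicit") return(cfl_dt(domain, eta_max))
  min(1, factor * min(domain$dx, min(domain$dy)) / u_ref)
}

# common driver over the compiled stepper
.simulate <- function(domain, boundary_level, duration, dt,
                      bc_dt = NULL, land_level = NULL,
                      params = sediment_params(),
                      bivalves = bivalve_params(),
                      sediment = TRUE, erosion = FALSE,
                      advection = TRUE, viscosity = 0.1, h_dry = 0.01,
                      sed_stride = NULL, scheme = c("adi", "explicit"),
                      theta = 0.55, init = list()) {
  scheme <- match.arg(scheme)
  if (is.null(sed_stride)) sed_stride <- max(1L, floor(2.4 / dt))
  stopifnot(inherits(domain, "marsh_domain"), duration > 0, dt > 0)
  if (is.null(bc_dt)) {
    bc_dt <- if (length(boundary_level) > 1) duration / (length(boundary_level) - 1) else duration
  }
  if (length(boundary_level) == 1)
    boundary_level <- rep(boundary_level, 2)
  veg_n <- matrix(domain$veg$n[domain$veg_class],
                  domain$n_rows, domain$n_cols)
  veg_hv <- matrix(domain$veg$h_v[domain$veg_class],
                   domain$n_rows, domain$n_cols)
  empty <- matrix(numeric(0), 0, 0)
  res <- cpp_simulate(domain$zb, domain$dx, domain$dy,
                      veg_n, veg_hv,
                      attr(domain$veg, "c_b"), attr(domain$veg, "c_d"),
                      domain$rho_mm_eff, bivalves$f_mm_si,
                      boundary_level,
                      if (is.null(land_level)) numeric(0) else
                        if (length(land_level) == 1) rep(land_level, 2) else land_level,
                      bc_dt, duration, dt,
                      if (sediment) params$ws else 0,
                      params$rho_sed_dry, params$c_boundary,
                      params$diffusivity, viscosity, h_dry,
                      advection, as.integer(sed_stride), sediment,
                      erosion, params$tau_ce, params$m_erod,
                      if (is.null(init$eta)) empty else init$eta,
                      if (is.null(init$u)) empty else init$u,
                      if (is.null(init$v)) empty else init$v,
                      if (is.null(init$conc)) empty else init$conc,
                      if (scheme == "adi") 1L else 0L, theta)
  res$h <- pmax(res$eta - domain$zb, 0)
  res$wet <- res$h > h_dry
  class(res) <- "sim_state"
  res
}

#' Advance the shallow-water flow (no sediment)
#'
#' Staggered-grid continuity and momentum update with vegetated Chezy
#' friction, a prescribed seaward water level, closed lateral and landward
#' walls (optionally an open landward level for flume configurations) and
#' threshold wetting/drying. Water volume change matches the boundary flux
#' to round-off.
#'
#' @param domain A `marsh_domain`.
#' @param boundary_level Seaward water level: a scalar or a vector sampled
#'   every `bc_dt` seconds, m AMSL.
#' @param duration Simulated time, s.
#' @param dt Time step, s (must satisfy the gravity-wave CFL condition; see
#'   [cfl_dt()]).
#' @param state Optional initial state (a previous `sim_state`, or a list
#'   with `eta`, `u`, `v` matrices).
#' @param land_level Optional landward boundary level (opens the landward
#'   wall; used by flume validation tests).
#' @param advection Include momentum advection (default TRUE).
#' @param viscosity Horizontal eddy viscosity, m^2 s^-1 (default 0.1).
#' @param bc_dt Sampling interval of `boundary_level`, s.
#' @param scheme Time integrator: `"adi"` (directionally split
#'   semi-implicit free surface; default) or `"explicit"` (gravity-wave
#'   CFL bound).
#' @param theta Implicitness weight of the split scheme (>= 0.5).
#' @return A `sim_state`: `eta`, `u`, `v`, `conc`, `h`, `wet`, bed-change
#'   ledgers and volume/mass budget diagnostics (`vol_in`, `vol_out`,
#'   `max_vol_resid`, ...).
#' @export
step_flow <- function(domain, boundary_level, duration, dt,
                      state = NULL, land_level = NULL, advection = TRUE,
                      viscosity = 0.1, bc_dt = NULL,
                      scheme = c("adi", "explicit"), theta = 0.55) {
  .simulate(domain, boundary_level, duration, dt, bc_dt = bc_dt,
            land_level = land_level, sediment = FALSE,
            advection = advection, viscosity = viscosity,
            scheme = scheme, theta = theta,
            init = if (is.null(state)) list() else state)
}

#' Advance coupled flow and suspended-sediment transport
#'
#' Adds to [step_flow()] the suspended-sediment advection-diffusion with
#' donor-cell (positivity-limited) advection, explicit horizontal
#' diffusion, unconditional implicit settling on wet cells, implicit mussel
#' filtration on mound cells, and optional shear-threshold erosion of mound
#' deposits. Flood water entering the seaward boundary carries
#' `params$c_boundary`; ebb water leaves with the interior concentration.
#' The process-split bed ledger (`dz_settling`, `dz_filtration`,
#' `dz_erosion`, m) accumulates over the run and the full mass ledger
#' (suspended + bed - net boundary import) closes to round-off
#' (`max_mass_resid`).
#'
#' @inheritParams step_flow
#' @param params A [sediment_params()] object.
#' @param bivalves A [bivalve_params()] object.
#' @param erosion Enable erosion on mound cells (default FALSE, the base
#'   configuration).
#' @param sed_stride Hydrodynamic steps per sediment step (default 5).
#' @return A `sim_state` (see [step_flow()]).
#' @export
step_sediment <- function(domain, boundary_level, duration, dt,
                          params = sediment_params(),
                          bivalves = bivalve_params(),
                          state = NULL, land_level = NULL, erosion = FALSE,
                          advection = TRUE, viscosity = 0.1,
                          sed_stride = NULL, bc_dt = NULL,
                          scheme = c("adi", "explicit"), theta = 0.55) {
  res <- .simulate(domain, boundary_level, duration, dt, bc_dt = bc_dt,
                   land_level = land_level, params = params,
                   bivalves = bivalves, sediment = TRUE, erosion = erosion,
                   advection = advection, viscosity = viscosity,
                   sed_stride = sed_stride, scheme = scheme, theta = theta,
                   init = if (is.null(state)) list() else state)
  if (res$max_mass_resid > 1e-6)
    stop(sprintf("sediment mass ledger failed to close (relative residual %.3g); limiter failure",
                 res$max_mass_resid))
  res
}

#' Shear-threshold erosion of mound deposits (single explicit step)
#'
#' Partheniades-type pickup on mound cells: E = M (tau/tau_ce - 1) for
#' tau > tau_ce, capped by the mass previously deposited on the cell.
#' Eroded mass returns to suspension; the ledger is debited under the
#' erosion process. The compiled stepper applies the same rule in-line;
#' this pure-R form exposes it for direct use and testing.
#'
#' @param dz_ledger List of matrices `dz_settling`, `dz_filtration`,
#'   `dz_erosion` (m).
#' @param conc Suspended concentration matrix, kg m^-3.
#' @param h Depth matrix, m.
#' @param tau Bed shear stress matrix, N m^-2.
#' @param params A [sediment_params()] object (uses `tau_ce`, `m_erod`,
#'   `rho_sed_dry`).
#' @param mound_mask Logical matrix; erosion acts only there.
#' @param dt Step, s.
#' @return List with updated `conc` and `dz_erosion`.
#' @export
erode_mounds <- function(dz_ledger, conc, h, tau, params, mound_mask, dt) {
  stopifnot(dt > 0)
  e <- params$m_erod * pmax(tau / params$tau_ce - 1, 0) * dt  # kg m^-2
  e[!mound_mask] <- 0
  avail <- pmax(dz_ledger$dz_settling + dz_ledger$dz_filtration +
                dz_ledger$dz_erosion, 0) * params$rho_sed_dry
  e <- pmin(e, avail)
  e[h <= 0] <- 0
  conc_new <- conc + ifelse(h > 0, e / h, 0)
  list(conc = conc_new,
       dz_erosion = dz_ledger$dz_erosion - e / params$rho_sed_dry)
}

#' Annualised accretion and deposition from a finished run
#'
#' Scales the cumulative bed-level change of a simulation window to a year:
#' with the standard 16-day spring-neap window the annual factor is
#' 365.25/16 ~ 22.83 cycles.
#'
#' @param state A `sim_state` with bed ledgers.
#' @param domain The `marsh_domain` the run used.
#' @param duration Simulated duration, s.
#' @param annual_factor Cycles per year; default `365.25 * 86400 / duration`.
#' @return A list: `accretion_cm_yr` (matrix), `dz_total` (m over the
#'   window), `deposition_m3_yr` (matrix of per-cell annual deposition
#'   volume), and the process-split annualised volumes.
#' @export
accretion_rate <- function(state, domain, duration,
                           annual_factor = NULL) {
  if (is.null(annual_factor)) annual_factor <- 365.25 * 86400 / duration
  dz <- state$dz_settling + state$dz_filtration + state$dz_erosion
  list(accretion_cm_yr = dz * annual_factor * 100,
       dz_total = dz,
       deposition_m3_yr = dz * domain$cell_area * annual_factor,
       annual_factor = annual_factor)
}
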