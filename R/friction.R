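# Vegetation-dependent Chezy friction (rigid-cylinder vegetation drag
# superposed on bed roughness) and bed shear stress.

#' Chezy coefficient of a vegetated bed
#'
#' For emergent vegetation (depth h <= stem height h_v):
#' \deqn{C = \left[\frac{1}{C_b^2} + \frac{C_D n h}{2 g}\right]^{-1/2}}
#' For submerged vegetation (h > h_v) the canopy resistance saturates at
#' h_v and a logarithmic overflow profile is added:
#' \deqn{C = \left[\frac{1}{C_b^2} + \frac{C_D n h_v}{2 g}\right]^{-1/2} +
#'   \frac{\sqrt{g}}{\kappa}\ln\frac{h}{h_v}, \quad \kappa = 0.41}
#' Unvegetated cells (n = 0) return the bare-bed Chezy `c_b`.
#'
#' @param h Water depth, m (> 0). Vectorised.
#' @param n Vegetation density m^-1 (stems m^-2 times stem diameter m).
#' @param h_v Stem height, m (ignored where n = 0).
#' @param c_b Bare-bed Chezy coefficient, m^1/2 s^-1 (default 45).
#' @param c_d Drag coefficient (default 1.65).
#' @return Chezy coefficient, m^1/2 s^-1.
#' @export
chezy_vegetated <- function(h, n, h_v, c_b = 45, c_d = 1.65) {
  stopifnot(all(h > 0), all(n >= 0), c_b > 0, c_d > 0)
  g <- 9.81; kappa <- 0.41
  hv_eff <- pmin(h, ifelse(n > 0, h_v, Inf))
  cc <- 1 / sqrt(1 / c_b^2 + c_d * n * hv_eff / (2 * g))
  submerged <- n > 0 & h > h_v
  cc[submerged] <- cc[submerged] +
    sqrt(g) / kappa * log(h[submerged] / h_v[submerged])
  cc
}

#' Bed shear stress from depth-averaged speed and Chezy coefficient
#'
#' \eqn{\tau = \rho_w g (u^2 + v^2) / C^2}; zero where the bed is dry.
#'
#' @param u,v Depth-averaged velocity components, m s^-1.
#' @param chezy Chezy coefficient, m^1/2 s^-1 (> 0).
#' @param rho_w Water density, kg m^-3 (default 1025).
#' @param wet Logical (recycled); `FALSE` forces tau = 0.
#' @return Bed shear stress, N m^-2.
#' @export
bed_shear <- function(u, v, chezy, rho_w = 1025, wet = TRUE) {
  stopifnot(all(chezy > 0))
  tau <- rho_w * 9.81 * (u^2 + v^2) / chezy^2
  tau * as.numeric(wet)
}
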