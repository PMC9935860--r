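---
title: "A bivalve-augmented creekshed model of salt-marsh accretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bivalve-augmented creekshed model of salt-marsh accretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(marshmussel)
```

## The system and the question

Ribbed mussels (*Geukensia demissa*) aggregate into mounds near the heads of
tidal creeks on southeastern US salt marshes. Each mussel filters suspended
sediment out of the water column and expels it as cohesive biodeposits that
stay on the mound, so aggregations act as spatially concentrated sediment
sinks. `marshmussel` simulates how this faunal engineering redistributes
sediment deposition and vertical accretion across a marsh creekshed, at the
scale of a single mound (1 m²), the creekhead (2500 m²) and the whole
domain (10,350 m²), and under crossed vegetation × mussel-cover scenarios.

## Model structure

The model couples four components over a representative 16-day spring–neap
window:

1. **Tidal forcing.** Water level is a harmonic sum
   $\eta(t) = \sum_i A_i \cos(\omega_i t - \phi_i)$. Tidal ranges
   (consecutive low-to-high excursions) are classified by the empirical
   quartiles of their distribution — below Q25 neap, above Q75 spring — and
   the year is partitioned into spring-onset-to-spring-onset periods. The
   period whose mean spring and mean neap ranges lie jointly closest (sum of
   absolute differences) to the annual means is the representative window.
2. **Hydrodynamics.** Depth-averaged shallow-water flow on a staggered
   rectangular grid with threshold wetting/drying (1 cm), a prescribed
   seaward water level, closed lateral and landward walls, and
   vegetation-dependent Chézy friction:
   emergent canopies ($h \le h_v$) give
   $C = [C_b^{-2} + C_D n h/(2g)]^{-1/2}$ and submerged ones add a
   logarithmic overflow layer
   $C = [C_b^{-2} + C_D n h_v/(2g)]^{-1/2} + (\sqrt{g}/\kappa)\ln(h/h_v)$,
   with $n$ the stem density × diameter (m⁻¹), $C_b = 45$ m$^{1/2}$s$^{-1}$,
   $C_D = 1.65$, $\kappa = 0.41$.
3. **Sediment transport.** Depth-averaged advection–diffusion of suspended
   sediment with donor-cell advection on the hydrodynamic face fluxes,
   explicit (subcycled) horizontal diffusion, and unconditional implicit
   settling at velocity $w_s$ on wet cells. Flood water entering the
   seaward boundary carries a prescribed concentration; ebb water exports
   the interior concentration. There is no critical shear stress for
   deposition; erosion is available only as the mound-resuspension
   sensitivity (Partheniades pickup $E = M(\tau/\tau_{c,e} - 1)$, capped by
   the previously deposited mass).
4. **Bivalve filtration.** On mound cells, mussels at density
   $\rho_{MM}$ (mussels m⁻²) each filtering $f_{MM}$ (m³ per mussel per
   unit time) remove sediment through an implicit sink,
   $C^{+} = C / (1 + \rho_{MM} f_{MM}\,\Delta t / h)$,
   which cannot produce negative concentrations; the removed mass
   $(C - C^{+})\,h$ accretes the mound as
   $\Delta z = (C - C^{+})\,h / \rho_{sed,dry}$. In the small-step limit
   this reduces to the explicit increment
   $\Delta z = \rho_{MM} f_{MM} C \Delta t / \rho_{sed,dry}$, and the mass
   removed from suspension equals the mass added to the bed exactly.

Per-cell bed change is accumulated in a process-split ledger (settling,
filtration, erosion) and annualised by the number of 16-day cycles per year
(365.25/16 ≈ 22.83); bed changes do not feed back into the bathymetry
within a window (accretion ≪ depth; a morphodynamic coupling switch exists
but defaults off).

## The synthetic creekshed

The standard domain is a 50 m × 207 m rectangle: a 20 m deep-water channel
band (bed 0 → −6 m AMSL seaward), a 2 m wide central creek ending 50 m
short of the landward edge (bed 0.79 → −1 m at the junction), and the
50 m × 50 m creekhead band landward of the creek. Levees (0.94 m AMSL, 5 m,
tall cordgrass) and levee-adjacent strips (10 m, intermediate cordgrass)
line the channel and creek; everything else is platform at 0.79 m AMSL
under short cordgrass; cells at or below mean sea level are bare. Mussel
mounds (0.25 m² each, 177 mussels m⁻²) tile a deterministic alternate-row
lattice covering 0/10/20 % of the creekhead. At the reference resolution
(0.5 m cells in the creekhead band, 0.5 × 1 m elsewhere) each mound is one
cell; on coarsened grids the physical mound count is preserved and cells
carry a mound-area fraction which scales the effective mussel density.
The creekhead occupies 26.7 % and the mounds 2.7 % of the marsh
(non-channel) area at 10 % cover.

Coarsening (`cell_scale`) must keep the 50 m cross-shore extent and the
creekhead band divisible; the 137 m mid-marsh band uses the nearest
integer row count with exactly equal row heights so the total extent stays
50 × 207 m. The creek never coarsens below one column.

## Tunable parameters

| parameter | default | unit | meaning / basis |
|---|---|---|---|
| `ws` | 1e-4 | m s⁻¹ | settling velocity (0.1 mm s⁻¹), the best-fit value of the exponential decay calibration |
| `rho_sed_dry` | 800 | kg m⁻³ | dry bed density of fresh deposits |
| `c_boundary` | 0.05 | kg m⁻³ | flood-water concentration at the seaward boundary; the calibration knob (see below) |
| `diffusivity` | 1 | m² s⁻¹ | horizontal eddy diffusivity; grid-scale dispersion for metre-scale cells, standing in for unresolved creekhead jet spreading |
| `rho_mm` | 177 | mussels m⁻² | mussel density on mound area |
| `f_mm` | 0.115 | m³ per `f_mm_unit` | per-mussel clearance rate |
| `f_mm_unit` | `"per_day"` | — | time base of `f_mm` (see below) |
| `tau_ce`, `m_erod` | 1, 1e-4 | N m⁻², kg m⁻² s⁻¹ | mound erosion threshold and erodibility (resuspension sensitivity only) |
| `viscosity` | 0.1 | m² s⁻¹ | horizontal eddy viscosity |
| vegetation classes | tall 1.5 m / inter 0.8 m / short 0.4 m | — | editable placeholders for local survey values; densities `n = m_stems × D_s` of 2.0 / 1.5 / 1.0 m⁻¹ |

**The clearance-rate unit.** A literature-style value of
0.115 m³ s⁻¹ mussel⁻¹ is physically impossible (≈ 414 m³ h⁻¹ per animal)
and turns every mound into a perfect sink whose deposition is limited only
by grid-scale delivery. Read per day, 0.115 m³ d⁻¹ ≈ 4.8 L h⁻¹ per mussel
is a plausible clearance rate, and it gives a mound uptake velocity
$\rho_{MM} f_{MM} = 2.36\times10^{-4}$ m s⁻¹ whose ratio to the settling
velocity (≈ 2.4) reproduces the observed mound-versus-platform accretion
contrast (≈ 3.4×) and the ≈ −67 % effect of mussel removal at mound
locations. The per-day reading is therefore the default; all three
readings (`per_second`, `per_hour`, `per_day`) are selectable, and the
per-second one triggers a start-up warning.

**Calibration.** The boundary concentration is calibrated so that the
baseline (vegetated, 10 % cover) non-mussel platform accretes
0.9 cm yr⁻¹. Because flow does not feel the sediment, every deposition
field is exactly linear in the boundary concentration, so one run
determines the calibrated value in closed form
(`calibrate_c_boundary()`); no iterative search is needed, and all
cross-scenario comparisons reuse the single calibrated value.

## Numerical choices

* **Grid and variables.** Arakawa-C staggering: water level and
  concentration at cell centres, velocities at faces; row 1 is the seaward
  boundary. Face depths are upwind (by the face velocity, else the higher
  water level), which keeps a lake at rest exactly at rest on any
  bathymetry.
* **Time integration.** Two schemes share all physics:
  an explicit scheme (gravity-wave CFL bound,
  $\Delta t \le 0.4\,\min\Delta x/\sqrt{g h_{max}}$, point-implicit
  friction) used as the reference, and the default directionally split
  semi-implicit scheme, in which each step advances the x- then the
  y-subsystem (continuity + that direction's momentum) as a 1-D
  θ-scheme (θ = 0.55) with the sweep order alternating between steps.
  The split scheme is unconditionally stable for the linearised
  subsystems, so its step is bound by the explicit advective Courant
  number instead; the scenario default is
  $\Delta t = \min(1, 0.9\,\min\Delta/u_{ref})$ s with $u_{ref} = 2$
  m s⁻¹ (creek currents peak near 1 m s⁻¹). On the 2 m scenario grid the
  two schemes agree on cumulative deposition to within a few percent.
* **Positivity and conservation.** Continuity is in flux form and every
  cell's outgoing fluxes are scaled to its available volume, so depths
  never go negative and the water-volume budget closes against boundary
  fluxes to round-off. Sediment mass moves with the same limited face
  volumes (donor-cell upwind), with the donor concentration referenced to
  the pre-export volume so exports can never exceed the mass held; the
  suspended + bed − boundary ledger closes to round-off and the run aborts
  if it ever exceeds 10⁻⁶ relative. First-order upwind advection carries
  numerical diffusion of order $u\Delta x/2$; the advection–dispersion
  validation test is run at sediment Courant ≈ 0.98 where that term nearly
  vanishes, and in scenario runs it simply adds to the (larger) prescribed
  eddy diffusivity.
* **Diffusion** is explicit and subcycled to a diffusion number ≤ 0.2,
  exchanging through the shallower of the two cell depths so film-thin
  cells cannot destabilise the exchange.
* **Drying cells** strand their suspended load on the bed (credited to
  settling), conserving mass through wet/dry cycles.
* **Quantile convention** for spring/neap classification is linear
  interpolation of order statistics (type 7), configurable; extrema
  detection enforces an 8 h same-kind peak separation, removing
  opposite-kind wiggle pairs closer than 4 h.
* **Ties** in the representative-window search break to the earliest
  period; periods lacking either a spring or a neap phase are excluded and
  reported.

## What the fixtures emulate — and what they do not

`gen_constituents()` builds an M2+S2 pair whose fortnightly envelope hits
prescribed spring (+2.5 m) and neap (+2.0 m) high waters, matching the
deployment-tide levels of the study system; optional minor constituents
and randomised phases support property tests. `gen_tss_series()` samples
the quiescent decay law with zero-truncated Gaussian noise. The miniature
creekshed preserves zone topology for fast solver tests. None of these
reproduce observed records: real tides carry many more constituents and
meteorological residuals, real concentration series have autocorrelated
errors, and the synthetic creekshed is far more regular than a natural
marsh. Passing tests therefore demonstrate internal correctness and
order-of-magnitude realism, not site-specific prediction.

## Problem sizes used by the shipped tests

The simulation-reproduction tests and the acceptance script run the
creekshed at `cell_scale = 4` (2 m cells, 25 × 64 grid) with the split
scheme at Δt = 1.2 s over one representative 16-day window — the
configuration the package treats as its desk-scale reference. The solver
validation suite uses the miniature creekshed and 1-D flumes.

## Known limitations

* Single layer: the filtration sink acts on the whole water column rather
  than a near-bed layer. This makes mound uptake — and its competition
  with settling — track the depth-averaged concentration. One consequence
  is a stronger sensitivity of the mussel-attributable extra deposition to
  the settling velocity than a layered model shows, and a weaker
  redistribution compensation when mound cover is doubled; the removal
  magnitudes and the mound/platform accretion contrast are reproduced.
* No waves, no salinity, no Coriolis, no flocculation, one grain-size
  class, no bed consolidation.
* No biology beyond the filtration sink: no mussel growth or seasonality,
  and none of the indirect effects (plant stimulation, sediment
  stabilisation) that field manipulations show to be substantial — the
  model quantifies direct biodeposition only.
* Morphodynamic feedback is off by default; multi-year evolution under
  sea-level rise is out of scope.
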