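---
title: "From segmented tissue images to morphogen transport models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmented tissue images to morphogen transport models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemodel)
```

`tissuemodel` turns a preprocessed (already segmented or hand-drawn) 2D
tissue image into a quantitative structural model and embeds that model
into a system of ODEs for morphogen dynamics. This vignette explains the
procedures, the conventions and tunable parameters, the numerical
choices, and what the synthetic fixtures do and do not demonstrate.

## 1. The structural model

### Pixel classes and indexing

The input raster classifies every pixel as *wall*, *interior*, or
*excluded* (tissue present in the image but left out of the simulation).
The default grayscale convention is 0 = wall, 255 = interior,
128 = excluded; any other value mapping can be passed to
`load_layout_image()`. Interior components are found with
4-connectivity, so cells cannot leak diagonally through one-pixel walls;
wall-pixel groupings use 8-connectivity so thin diagonal walls stay
connected.

Indices follow a fixed scheme: every interior component touching the
image border is the external environment and receives index 1 (several
such components are merged — the exterior is whatever surrounds the
tissue); every excluded component receives index 2; the remaining N
components are the cells and receive 3..N+2 in raster-scan order of each
component's first pixel. Raster-scan assignment is an arbitrary but
deterministic choice: re-running the extraction on the same image is
bit-identical.

### Coordinate convention

Image coordinates are x = column, y = height − 1 − row, both 0-based, so
y increases *upward* and "top" means larger y. Angles are measured
counter-clockwise from the x-axis. Nothing in the pipeline depends on
which convention is chosen as long as it is applied consistently; the
y-up choice makes the top/bottom vocabulary of wall orientation match
the on-screen appearance of the image.

### Geometric features

Per region the package computes the pixel count area (× pixel_size²),
the crack-length perimeter (the number of unit pixel edges between
region and non-region pixels — exact and parameter-free; a single pixel
has perimeter 4), the centroid, the axis-aligned bounding rectangle of
pixel centers, and the characteristic ellipse with the same normalized
second central moments as the region. Each pixel contributes the 1/12
central moment of its own unit square, so a single pixel or a
one-pixel-wide wall still has a non-degenerate ellipse (axes
4·√(1/12) ≈ 1.155 px); without this correction the minor axis of thin
walls would collapse to zero and their axis angle would be numerically
unstable. The ellipse angle is reported in (−90°, 90°].

### Wall segments

A real wall lattice is one big connected component, so it must be split
into per-pair segments. Each wall pixel is assigned the two distinct
region indices nearest to it by Euclidean distance to region pixels;
ties at equal distance resolve to the smallest indices
(lexicographically smallest pair). All pixels assigned to the same pair
\{i, j\} form one wall record; disjoint contact patches between the same
two cells are merged because the output matrices hold one scalar per
pair — the record's length sums the patch lengths, other features are
computed on the union.

Wall length is the extent of the pixel centers projected on the wall's
own ellipse major axis, plus one pixel; width is area/length clamped
below at one pixel. Both estimators are exact on straight axis-aligned
walls (the test oracle) and stable on curved ones. One consequence of
the nearest-two rule worth knowing: when two diagonal cells come within
a junction's width of each other (possible in strongly jittered
layouts), the junction pixels between them form a genuine 1–2 px
"hairline" wall record. This is a faithful description of pixel-level
contact, not an extraction error; models that want to ignore such
contacts can filter wall records by length.

Walls toward regions 1 and 2 are recorded like any others so that
boundary conditions can refer to them.

## 2. Wall orientation

The orientation code of wall (i, j) names the side of cell i on which
the wall lies — equivalently the direction from i toward j: 1 top,
2 bottom, 3 right, 4 left. The matrix entry (j, i) always holds the
opposite code. Three direct geometric rules are evaluated per wall:

1. **Extent**: if the wall's y-extent lies strictly between the two
   centroids' y-coordinates while the x-extent does not (or vice versa),
   the wall separates the cells in that axis and the centroid order
   fixes the side.
2. **Axis angle**: a wall whose ellipse-axis angle exceeds 45° in
   absolute value is vertical, so the wall is right/left by centroid
   x-order; below 45° it is horizontal, top/bottom by y-order. Exactly
   45° decides nothing.
3. **Rectangle**: if one centroid lies strictly beyond one side of the
   wall's bounding rectangle and the other centroid strictly beyond the
   opposite side, that separation fixes the side.

A wall is directly oriented when at least one rule fires and all firing
rules agree. Requiring *all three* to fire would fail on common curved
walls whose extent rule is silent, so agreement-of-firing-rules is the
chosen quorum.

Walls still undetermined are resolved through common neighbours, swept
in lexicographic pair order until a fixpoint: if both walls to a common
neighbour q are vertical, the undetermined wall is perpendicular to them
(top/bottom by centroid order), symmetrically for horizontal; in the
mixed configuration the codes of the known walls combined with the
centroid order can force the code directly. The mixed-configuration
clauses are implemented literally, including the pairing of left/right
codes with centroid x-order; on stretched geometries two clauses can
imply different codes — such pairs, and pairs whose different neighbours
disagree, are flagged ambiguous and left unresolved rather than decided
by vote, because silent majority voting could hide segmentation errors.
The manual-correction table (`apply_corrections()`) exists precisely for
this remainder, and permissive mode (the default) returns a report
naming the survivors; strict mode errors on them. Resolution never
overwrites an already-assigned code, so the direct verdicts are stable
under the neighbour sweeps.

On every rectangular grid fixture the direct rules alone orient 100 % of
cell–cell walls correctly. The merged L-shaped wall a *corner* cell
shares with the exterior is genuinely ambiguous (its ellipse angle is
exactly ±45°) and is reported unresolved; with closed boundaries this
has no downstream effect.

## 3. The ODE embedding

`model_spec()` declares substances (mobile or not), cell types, reaction
terms per (type, substance), transport parameters, boundary handling and
initial concentrations; `compile_rhs()` binds it to an annotated,
oriented structural model. For mobile substance A in cell i:

dA_i/dt = Σ reactions + (1/V_i) Σ_j [ P·s_ij·(A_j − A_i) +
k_act·s_ij·(c_ji·A_j − c_ij·A_i) ]

* V_i is the cell's cross-sectional area (µm²), the 2D volume proxy.
  Dividing the wall fluxes by V_i makes conservation exact: with closed
  boundaries and no reactions, Σ V_i·A_i is constant to solver accuracy
  (the flux operator has zero column sums by construction).
* s_ij is the shared wall *length* (µm); wall width does not enter the
  default flux laws. P is a permeability (µm/time), k_act a mass-action
  rate constant, and c_ij the carrier concentration of cell i on its
  (i, j) wall, resolved from a `(cell type, wall side)` placement map.
  A carrier may instead name an immobile substance, making it a dynamic
  per-cell variable (uniformly placed).
* Boundaries toward regions 1 and 2 are closed (zero flux) by default —
  the safest assumption; a fixed-concentration boundary makes the region
  act as a neighbour at constant concentration (with active efflux into
  it when a carrier sits on that wall).
* Carrier placement needs wall orientations; compiling a spec whose
  carriers touch an unresolved wall is an error naming the walls, so
  unresolved orientation cannot silently change transport.

The reaction-term library composes constant synthesis, linear decay,
Michaelis–Menten conversion and Generalized Hill factors
((x/K)^h/(1+(x/K)^h) for activation, its complement for repression,
products over multiple regulators scaled by one Vmax). Inside the
compiled right-hand side regulator concentrations are clamped at zero so
the tiny negative excursions a stiff solver can produce remain
evaluable; the exported kinetics functions keep their domain errors.

The state vector is substances-outermost, cells ascending by id —
deterministic and readable in dumps.

### Units

Geometry is measured in pixels times `pixel_size` (µm/px).
`rescale_units()` multiplies lengths by a factor and areas by its
square, so a model built in pixel units can be moved to physical units
at any point before compilation; a factor of 1 is the identity.

## 4. Numerics

* **Integrator**: the stiff variable-order BDF method (`deSolve::ode`,
  `method = "bdf"`), the standard choice when transport and reaction
  timescales differ sharply; any other `deSolve` method can be selected.
  Defaults rtol 1e-6, atol 1e-9.
* **Steady state**: integrate over doubling windows (1, 2, 4, … time
  units, capped at t_max = 1e6) until ‖rhs(y)‖∞ < tol_rel ·
  max(‖y‖∞, atol), default tol_rel 1e-8. The residual test needs no
  root-finding and is robust for stiff relaxation; a divergence guard
  errors when the state norm passes 1e12. On the demo model the reported
  steady state moves by less than 1e-4 relative when tolerances tighten
  from 1e-6 to 1e-8 (checked in the test suite).
* **Rendering**: concentrations are normalized per render (min → max
  across cells) onto a 256-colour palette (`hcl.colors`, default
  viridis), with an optional fixed range for comparing states; wall
  pixels are black, regions 1 and 2 neutral gray. Rendering is
  deterministic, byte-for-byte.

## 5. Synthetic fixtures and what they show

`make_grid_layout()` rasterizes rows × cols rectangular cells
(defaults: 20 px cells, 2 px walls, 3 px exterior margin — comfortably
above the one-pixel regime where geometry degenerates) from a junction
lattice; `make_jittered_layout()` displaces the internal junctions by a
seeded uniform offset up to `jitter_frac`·cell_px (≤ 0.3) before
rasterizing straight wall segments, preserving topology by construction
and retrying with a derived seed if a displacement ever merges or
disconnects a cell. Both return exhaustive ground truth — ids,
neighbour pairs, true orientation codes — computed from the generator's
own quadrilaterals, independently of the extraction pipeline, which is
what makes the round-trip tests genuine oracles. All randomness flows
through the explicit seed and the session RNG state is restored
afterwards.

`make_roottip_layout()` stacks column-typed files (default epidermis |
cortex | vascular | cortex | epidermis, mirror-symmetric) on a bottom
"columella" cap of `cap_rows` rows — a full rectangle of
(rows + cap_rows) × columns cells. This emulates the *organization* of
a root tip (files plus cap), not its curved geometry.

The jittered generator emulates irregular cell shapes and wall angles;
it does **not** emulate curved organ axes, variable wall thickness,
segmentation noise (gaps, over/under-segmentation) or non-convex cells.
Passing the fixture suite therefore demonstrates correctness of the
algorithms under topology-preserving geometric distortion, not
robustness to imperfect segmentations — those are expected to need the
manual-correction path.

### The demonstration transport model

`demo_polar_transport_spec()` wires a minimal reflected-flow auxin
model: constant synthesis (0.1) and linear decay (0.01) in every cell,
passive permeability P = 1, mass-action efflux with k_act = 0.5, and
carrier placement by type — vascular cells pump toward their bottom
walls, epidermis and cortex toward their top walls, columella cells
toward left and right. Carrier strengths are type-specific: vascular
2.0, epidermis/cortex 0.2, columella 0.3. The asymmetry matters: with
equal strengths everywhere and a fully closed shootward boundary, the
upward-pumping outer files simply pile auxin up at the top image corners
(their chains end blindly), whereas real root tips pump rootward in the
stele much more strongly than shootward in the outer files. With the
type-specific strengths the steady state from uniform initial data
places the global maximum in an interior columella cell directly under
the vascular files — the self-organized interior maximum characteristic
of reflected-flow wirings — with a clear margin over every
boundary-adjacent cell. The demo is *not* a published auxin model; it is
the smallest wiring on which that qualitative behaviour is testable.

```{r demo, eval = FALSE}
rt <- make_roottip_layout()
model <- annotate_cell_types(orient_all(extract_structural_model(rt$grid)),
                             rt$truth$types)
sys <- compile_rhs(demo_polar_transport_spec(rt$truth), model)
ss <- find_steady_state(sys)
render_concentrations(model, ss, system = sys, substance = "auxin",
                      out_path = "auxin.png")
```

## 6. Problem sizes and known limitations

The test and acceptance workloads use 8×8 grids with 20 px cells
(≈ 180×180 px images, 64 cells), ten 6×6 jittered layouts, and the
5×10-cell root-tip demo — sizes chosen so the full validation cycle
completes in well under a minute while still exercising every code
path; the extraction pipeline itself is vectorized and handles images of
a few megapixels.

Limitations, by design: no segmentation of raw micrographs (the input
is a clean layout drawing); no sub-pixel boundary geometry; no
skeletonized arc length for strongly curved walls (the projection
estimator underestimates them); orientation is defined in the image
frame only, not along curved organ axes; no cell growth or division;
and no parameter fitting.
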