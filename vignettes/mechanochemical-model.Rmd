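---
title: "The mechano-chemical bone-healing model: methods and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechano-chemical bone-healing model: methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bmpheal` simulates healing of a fracture gap or segmental defect in a
fixated rat femur under combined mechanical and biochemical regulation:
a mechanoregulated tissue-differentiation algorithm whose cellular rates
are amplified by dose-dependent BMP-2 modulation curves, with the BMP-2
delivered from a degrading alginate hydrogel implanted in the defect.
This vignette describes the governing equations, the numerical methods,
and the reasoning behind the frozen default parameters.

## 1. Domain and scenarios

The femur is idealized as a cylinder and modeled as one 2D longitudinal
half-section (plane strain, unit thickness, symmetry axis at $y = 0$):
20 mm of shaft, 2 mm outer radius, 0.7 mm cortical wall, and 0.2 mm
periosteal and endosteal progenitor strips. A mid-shaft band of width
`gap_mm` is the wound:

* **2 mm gap** — a regular fracture: the gap starts as granulation
  hematoma, the periosteum is intact, and an outer callus band is
  meshed over a 10 mm extent.
* **8 mm defect** — critical size: the periosteum over the gap is
  resected and there is no callus band. The gap is void (untreated) or
  filled with alginate (`gel_present = TRUE`) optionally loaded with a
  BMP-2 dose spread uniformly over the gel volume.

All scalar fields live on a structured grid of control volumes
(default edge `h = 0.25` mm) that coincides with the bilinear
quadrilateral (Q4) finite element mesh used by the mechanics.

## 2. Governing processes

### BMP-2 (two pools)

The free concentration $g$ (ng/cm³) obeys

$$\partial_t g = \nabla\!\cdot(D(a)\nabla g)
  \;-\; \lambda g
  \;-\; \frac{V_{max}\, g}{K_{m} + g}
  \;+\; \frac{\alpha\,(c_s + c_b)}{\gamma g + \gamma_0}
  \;+\; \text{release} \;-\; \text{event sink},$$

with half-life decay $\lambda = \ln 2 / 0.42\ \mathrm{d}^{-1}$,
Michaelis–Menten consumption by MSCs and bone cells
($V_{max} = (c_s + c_b)\,v_{cell}$, $K_m = 11.01$), and production that
is inversely related to the ambient level — so populated tissue
self-maintains a *homeostatic* concentration `homeostatic_g(c)` inside
the physiological band $[0.008, 0.05]$ ng/cm³. Diffusivity blends
linearly between the in-gel and in-vivo endpoints with the gel fraction
$a$. The encapsulated pool $g_{gel}$ decays with the in-gel half-life
(3.25 d) and is released to the free pool at rate
$\lambda_{rel}(a) = \lambda_{rel,0}(1-a)$: release accelerates as
degradation exposes gel surface. Chondro-/osteogenic differentiation
events drain local free BMP-2 to exactly $g_{min}$.

### Alginate

$\dot a = -(\lambda_{bulk} + c\,\lambda_{cell})\,a$ — slow bulk
hydrolysis ($5\times10^{-4}\,\mathrm{d}^{-1}$; an acellular implant
retains 95.9 % after 84 days, i.e. "nearly intact") plus cell-driven
destabilisation of the ionic cross-links. The cell-driven term carries
the same $g \ge g_{min}$ activity gate as every other cellular rule:
quiescent cells that merely seep into the gel do not remodel it.
Degraded gel volume is replaced by granulation tissue — invading
tissue does the degrading, it does not leave a cavity.

### MSC migration

A conservative finite-volume Keller–Segel flux
$-D(a)\nabla c_s + c_s\,\chi_{e\!f\!f}\nabla g$ with
$D = D_0(1-a) + \varepsilon D_0 a$ and
$\chi_{e\!f\!f} = \chi_0 (1-a) \cdot \text{chemotaxis\_fold}(g)$.
Chemotactic drift is integrated explicitly with donor-cell upwinding
under a CFL sub-cycle and a saturation cap on the face drift speed
(~2 mm/day); random motility is implicit (unconditionally stable,
positivity-preserving M-matrix). Faces touching a void cell or a cell
whose mineralized fraction exceeds 50 % carry no flux. The periosteal
and endosteal strips are progenitor niches replenished daily to the
source density; they supply MSCs but are exempt from differentiation.

### BMP-2 dose modulation

Four fold-increase curves (monotone shape-preserving cubics on
$\log_{10} g$ through experimental anchors, clamped outside) multiply
the baseline cellular rates: proliferation (2× at 10–200 ng/cm³),
MSC and osteoblast chemotaxis (bell-shaped, 3.5× and 2.2× at 1 ng/cm³),
chondrocyte hypertrophy (2× at 3, saturating 3.8× at 30) and
bone-matrix production (2.3× at 10, 5.5× at 200, osterix anchoring).
Every curve is pinned to 1-fold across the physiological range:
exogenous BMP-2 amplifies behaviour, its absence does not suppress it.

### Mechanics and differentiation

Each day a linear elastic plane-strain solve is performed: distal face
fixed, symmetry at the axis, proximal face tied to a rigid platen that
carries the 14.4 N axial gait load, with the external fixator as a
277 N/mm grounded spring on the platen. Element properties are
fraction-weighted arithmetic means of the constituent tissue properties
renormalized over solids (rule of mixtures; 100 % woven bone gives
E = 982.48 MPa). The stimulus is $\psi = \sqrt{J_2}$ of the deviatoric
strain. Where $g \ge g_{min}$, MSCs commit at rate `r_diff` to the fate
of the local stimulus band — bone ($\psi \le 0.01$), cartilage
($\psi \le 0.06$), fibrous tissue above — then differentiated cells
produce matrix in place (woven bone, cartilage, fibrous tissue);
chondrocytes hypertrophy and their matrix calcifies and is replaced by
woven bone (endochondral route). MSC proliferation is an exact-update
logistic with space competition: the carrying capacity available to
MSCs is reduced by resident differentiated cells.

## 3. Daily macro-loop

1. homogenize → FE solve → $\psi$;
2. MSC transport; replenish source strips;
3. differentiation (BMP-2-gated, niche-exempt), proliferation,
   maturation and matrix production;
4. BMP-2 step (release, event sink, sub-cycled reactions at
   $\Delta t \le 0.05$ d, implicit diffusion);
5. gated alginate degradation with granulation replacement;
6. record the summary row.

The model is deterministic for a given configuration.

## 4. Calibration of the frozen defaults

Most constants are physical/kinetic values carried by the model
(half-lives, $K_m$, consumption and production rates, tissue properties,
load and fixator stiffness). Three groups are genuine calibration
constants, frozen after scanning scenario outcomes:

* **Motility** `D0 = 0.022` mm²/day, `chi0 = 0.02` mm²·day⁻¹·(ng/cm³)⁻¹ —
  unconstrained by the source data; they set the speed of the
  front-like colonization of the gel. During the release burst the
  invasion front self-sustains (cells ignite the gel rim, proliferate,
  degrade the gel); after the burst the front stalls where ambient
  in-gel BMP-2 falls below $g_{min}$ (the gel is a BMP-2 sink), leaving
  a residual alginate islet. The chosen point gives ~12 % residual gel
  and ~87 % bone at day 84 and sits away from the "complete sweep"
  cliff where the islet vanishes.
* **Cell densities** `c_max = c_source = 1.2e6` cells/cm³ — the
  homeostatic concentration of tissue at carrying density must clear
  the $g_{min}$ gate with margin, which controls both the width of the
  gate-closed annulus around the residual gel and whether late-stage
  defect tissue stays inside the physiological band.
* **`psi_resorb_min = 0`** — the arithmetic homogenization
  strain-shields elements once a few percent woven bone forms; with a
  positive dormancy floor ossification would self-arrest. Bone
  resorption/remodeling is outside the model's scope, so arbitrarily
  low strains remain osteogenic (the floor stays configurable).

With these defaults (`h = 0.25` mm): the 2 mm fracture bridges (95 %
bone by day 42); the untreated and gel-only 8 mm defects form no bone
(gel-only keeps 95.9 % of the implant — the acellular closed form,
because gate-closed cells never erode it); the 5 µg scenario reaches
87.5 % bone with 12 % residual alginate; day-84 bone is monotone in
dose over 0–5 µg; and defect-tissue BMP-2 is supra-physiological for
the first two weeks, then inside the physiological band from week 6.
Halving the mesh (h = 0.125) changes day-84 bone by 4.6 points and
moves residual alginate to 9.3 % — the bone outcome is mesh-robust,
the residual-gel fraction (a front-stall position) is the most
mesh-sensitive output, and `h = 0.25` is part of the frozen default
configuration.

## 5. Numerical notes and limitations

* Structured grid + Q4 elements instead of unstructured triangles: the
  matched FV/FE pair gives exactly conservative transport, an M-matrix
  implicit diffusion (positivity), and an assembly that passes the
  patch test — all in pure R at desk scale.
* Drained linear elasticity is solved once per day of loading;
  poroelastic permeabilities are carried and reported but not used by
  the solver.
* No remodeling/resorption, no endosteal contribution to cortex
  regeneration, no 3D effects, no vascularity.
* The 10 % bone crossing occurs near week 2 rather than week 4: the
  release burst drives early woven deposition harder than in vivo.
  Endpoint composition, not early kinetics, was prioritized in the
  calibration.

```{r example}
library(bmpheal)
sim <- simulate_healing(scenario(8, TRUE, 5, 84))
summary(sim)
plot(sim)
```
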