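---
title: "Two-step IMRT segmentation and MU-preserving adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step IMRT segmentation and MU-preserving adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adapt2step)
```

## The problem

In image-guided IMRT of the prostate, the clinical target deforms between
the planning CT and the day of treatment: rectum and bladder filling push
the prostate around, the seminal vesicles compress, and the high-dose
Boost volume can change by several per cent (rarely tens of per cent).
The routine clinical answer is a rigid couch correction — *isocenter
relocation* — which restores the position but not the shape of the MLC
apertures, degrading both target coverage and rectum sparing.

`adapt2step` implements a geometric alternative built on *two-step
segmentation*. Every beam direction delivers three fluence steps per
target:

* **S0** — an aperture conformal to the target's beam's-eye-view (BEV)
  silhouette, setting the overall dose level;
* **S1** — the same aperture with the organ-at-risk (OAR) shadow removed;
  an interior block splits the opening into a left and a right one-sided
  segment, because one leaf pair carries one interval;
* **S2** — narrow strips hugging the block edges that compensate the
  target underdosage caused by the sparing.

Because each segment has a clear geometric role, a plan can be *adapted*
to the geometry of the day by regenerating the apertures and carrying the
monitor units (MU) over unchanged — an attractive property for quality
assurance, since MU-preserving adaptation leaves the delivery weights
untouched and only reshapes leaves.

## The blocked-rotation model and $\beta^*$

The width of the S2 strips comes from an idealized, analytically tractable
model: a continuous coplanar rotation around concentric circles — target
ring of radius $R_{PTV}$, central OAR of radius $R_{OAR}$, gap $g$ — under
a unit-fluence, no-attenuation ("exposure fraction") beam. With
$\rho = r/R_{PTV}$, $\rho_{OAR} = R_{OAR}/R_{PTV}$, $\gamma = g/R_{PTV}$,
the OAR-sparing rotation delivers

$$D_{S1}(\rho) = 1 - \tfrac{2}{\pi}\arcsin\!\big(\min(1, \rho_{OAR}/\rho)\big),$$

and a strip rotation open on $\rho_{OAR} \le |x| \le \rho_{OAR}+\beta$
delivers

$$D_{S2}(\rho) = \tfrac{2}{\pi}\Big[\arcsin\!\big(\min(1, (\rho_{OAR}+\beta)/\rho)\big) - \arcsin\!\big(\min(1, \rho_{OAR}/\rho)\big)\Big].$$

The composite dose is $D_{S1} + \omega D_{S2}$ with the strip weight
$\omega$. The optimal pair $(\omega_{opt}, \beta_{opt})$ minimizes the
homogeneity objective

$$f^2 = \sigma_D^2 + (\bar D - D_0)^2 = \langle (D - D_0)^2 \rangle,$$

the area-weighted ($2\pi\rho\,d\rho$) mean-square deviation over the
target annulus $\rho \in [\rho_{OAR}+\gamma,\, 1]$. The normalization
$D_0$ is not dictated by the model; we set $D_0 = 1$, the mean of an
unblocked rotation, so that "homogeneous at the unblocked level" is the
ideal. The product $\beta^* = \omega_{opt}\beta_{opt}$ characterizes the
optimum and depends only weakly on $\gamma$; the package samples it over
a $(\gamma, \rho_{OAR})$ grid, fits a fourth-order polynomial in
$\rho_{OAR}$ per $\gamma$ node (through the origin, since
$\beta^*(\gamma, 0) = 0$), and interpolates linearly across $\gamma$.
How the fourth-order parameterization should be organized across the two
variables is a genuinely open choice; one polynomial per $\gamma$ node
with linear interpolation keeps the fit local and the weak
$\gamma$-dependence visible in the stored table.

Two details of the optimizer deserve a note.

* **Search box.** The exposure-fraction model has no penumbra, so the
  unconstrained joint optimum degenerates: $\beta \to 0$,
  $\omega \to \infty$ with $\omega\beta$ nearly constant — a
  millimetre-wide strip at many times the sparing segment's weight, which
  no MLC delivers usefully. The joint search therefore runs over the
  deliverable box $\omega \in [0.2, 3]$, $\beta \in [0.005, 0.3]$
  (weights within a clinically sensible factor of the S1 weight, widths
  up to 30% of the target radius). Since $f^2$ is exactly quadratic in
  $\omega$, the search is a profile scan over $\beta$ with the
  box-clamped closed-form $\omega$, refined by golden-section and a
  bounded quasi-Newton polish; tests verify it against a literal
  brute-force grid.
* **Two table modes.** Plan *generation* uses the joint optimum evaluated
  at $\omega = 1$ (the strips get the S1 weight and width $\beta^*$).
  Width *adaptation* must respect MU preservation, i.e. frozen weights,
  so a second table column stores the $\omega$-frozen optimum
  ($\beta^*_{adapt} = \beta_{opt}|_{\omega=1}$). Whether the original
  clinical lookup tables distinguished the two uses cannot be settled
  here; both modes are exposed, and the adaptation uses the frozen-weight
  mode.

## The adaptation protocol

Given a planned ("native") geometry CT1 and a geometry of the day CT2:

1. **Isocenter relocation** (the clinical baseline, also kept as the
   comparison plan): the rigid shift maximizing summed PTV/Boost overlap,
   found by centroid alignment plus exhaustive refinement on a 1 mm
   in-plane grid within ±10 mm. The z component is probed at whole slices
   — contours only exist at the slice pitch (2.5 mm), so a finer z search
   would interpolate information that is not there. Ties break to the
   smallest shift norm, then lexicographically.
2. **Regeneration with MU transfer**: fresh S0/S1/S2 generation on CT2 at
   the relocated isocenter; each segment receives the MU of the CT1
   segment with the same structural key (gantry angle, step type, target,
   sidedness). A key mismatch aborts with the offending keys listed: the
   method presumes similar segment sets, and silently redistributing MU
   would disguise a situation the operator must see.
3. **S2 width adaptation**: every strip width is rescaled by
   $\beta^*_{adapt}(\gamma_2, \rho_2) / \beta^*_{adapt}(\gamma_1, \rho_1)$
   of its leaf pair's measured geometries and re-clipped against the CT2
   target opening. MUs untouched.
4. **Fine-tuning imitation**: the inverse fine-tuning stage (below)
   records, per segment and leaf pair, the net leaf shifts it introduced
   on CT1; these shifts are replayed onto the CT2 apertures, with each
   CT2 pair mapped to the CT1 pair at the same fractional position within
   the target's BEV vertical extent (nearest-pair rounding), so a target
   that grew or shrank along the patient axis still receives the right
   edge features.

Steps 2–4 copy MU once and then touch only geometry, so the adapted total
MU equals the planned total *exactly, by construction* — the tests assert
bit-level equality.

When the estimated native MU requirement of CT2 (planned MU scaled by the
prescription-to-achieved-mean ratio of the transferred plan) differs from
the planned MU by more than 10%, the geometry change is outside the
small-change regime the method assumes, and `adapt_plan()` warns
prominently while still adapting: beyond that regime either coverage or
sparing must give.

## Dose engine, DVH metrics, scoring

The dose engine is deliberately idealized: a voxel receives a segment's
MU whenever its parallel-beam BEV projection falls inside the open leaf
interval of the covering pair; dose is the calibrated sum over segments.
No attenuation, scatter, penumbra or divergence. This matches the
idealization in which the $\beta^*$ analysis is derived, and the discrete
engine provably converges to the closed-form blocked-rotation dose as the
beam count grows (the suite checks < 1% RMS over the target annulus at
360 beams). Consequences: absolute Gy values away from flat-field
conditions should not be compared against a clinical dose engine, and
leaf-edge effects at the millimetre scale are sharper than reality.

Calibration is one scalar per plan, chosen so the native plan's mean dose
in its highest-prescription target equals the prescription; MU-preserving
comparisons (relocated, adapted, per-step plans) reuse the native
calibration, making the Gy axis commensurable across the group.

Cumulative DVHs are computed per structure from voxel samples
(point-in-polygon membership at voxel centres, even-odd rule for ring
structures). $D_{x\%}$ — the minimum dose to the hottest $x\%$ — is an
inverse-cumulative lookup with linear interpolation on the sorted voxel
doses (a type-7 quantile at $1 - x/100$); published values from
commercial systems may differ at the 0.1 Gy level from interpolation-rule
differences. $V_{p\%}$ is the absolute volume in cm³ above $p\%$ of the
reference dose, which defaults to 76.2 Gy so that $V_{95\%}$ is the
volume above 72.4 Gy, the rectal-bleeding surrogate the evaluation
reports. The quality score

$$S_D = \sum_j \max(0,\; R_j^{lo} - A_j,\; A_j - R_j^{up})$$

sums the violations of the required dose ranges (Boost
$D_{mean}, D_{99\%}, D_{95\%}, D_{1\%}$; PTV-minus-Boost
$D_{99\%}, D_{95\%}$; defaults hard-code the protocol column of the
reference evaluation and are fully overridable in the config).

## The fine-tuning stand-in

Clinical two-step plans are post-processed by a proprietary inverse
optimizer; the adaptation only needs that stage's *interface* — the MU
weights it settles on and the leaf shifts it introduces — not its
algorithm. The package therefore provides documented monotone-descent
procedures: projected-gradient MU optimization (25 steps by default,
backtracking line search, so the composite objective value never
increases) and greedy single-leaf fine-tuning (± step moves accepted only
when the COV drops, shifts recorded per segment and pair). The COV is the
weighted sum of volume-normalized one-sided quadratic DVH-point
penalties; the default objective template mirrors the clinical counts
(paired min/max objectives for the PTV plateau, three for the Boost, four
shaping the rectum DVH, a 0.1-weight healthy-tissue ceiling) with weights
spanning 0.1–100. Weight optimization never moves leaves and leaf
fine-tuning never changes MU — the same separation the MU-preserving
adaptation relies on. Segment count is frozen through fine-tuning.

## Synthetic geometries

No patient data ships with the package; two generators produce the study
geometries.

* **Horseshoe phantom** (`generate_quasimodo()`): a ring target almost
  enclosing a central cylindrical OAR in an elliptical body — the classic
  coplanar IMRT benchmark. The canonical phantom's dimensions are not
  published with the method, so the defaults (body 300×200 mm, $R_{PTV}$
  60 mm, $R_{OAR}$ 24 mm, gap 6 mm, 60° opening, eight 2.5 mm slices) are
  package choices, configurable and documented as non-canonical. The
  paired generator shrinks the OAR by $\Delta\rho$ (default 0.05, the
  magnitude of typical interfractional change) with the target inner edge
  following at constant gap, and identical isocenters — so the relocation
  step of the protocol is exercised as an exact zero.
* **Synthetic prostate** (`generate_prostate_case()`): a spherical CTV
  (prostate plus vesicle base) anterior to a tubular rectum; PTV = CTV +
  10 mm (7 mm posterior), Boost = CTV + 5 mm minus rectum, per the
  clinical margin protocol. Deformations: rigid posterior/inferior push,
  rectum caliber change, and a Boost volume shrink whose scale factor is
  solved on the discretized contours, so the requested ratio (5% in the
  small regime, 25% in the hard regime) is met on the geometry as
  generated. Everything is seeded and bit-reproducible. What the
  generator does **not** emulate: non-ellipsoidal prostate shapes, rectum
  folding, bladder, seminal-vesicle anatomy as a separate lobe, or
  observer contouring variability — so green tests on these geometries
  demonstrate the mechanics and invariants of the method, not clinical
  dose accuracy.

## Numerical choices and degenerate inputs

* Margin expansion is per-slice 2D dilation (raster shift-OR at the set's
  in-plane resolution, polygonized back with contour tracing at the 0.5
  level) plus cross-slice extension by the margin rounded to whole
  slices; boundary placement is accurate to about one resolution cell.
  The forbidden structure is grown by one cell before subtraction so the
  traced boundary cannot touch it. A slice whose expansion is swallowed
  entirely is omitted with a message.
* The OAR-target gap $g$ is measured as the signed minimum edge-to-edge
  distance between the boundaries in the slice plane; when the OAR bulges
  into the target (a posterior PTV routinely overlaps the rectum) the gap
  is negative and the pair is flagged. The $\beta^*$ lookup clamps such
  geometries to its domain boundary — benign, because $\beta^*$ depends
  weakly on $\gamma$ — and the segment generators summarize the clamping
  in one warning.
* Leaf pairs are indexed along the patient axis with pair 0 centred on
  the isocenter; a 4 mm pair spans one or two 2.5 mm slices, whose
  measured geometries are averaged.
* Gantry convention: coplanar rotation in the axial plane, parallel
  projection, angle 0° projecting onto the patient x axis, BEV x
  increasing with patient x at 0°.
* Degenerate apertures (interval collapsed by adaptation or shifting) are
  dropped at re-validation; the MU of a segment is never redistributed.

## Problem sizes

The shipped tests and examples run the full chain at deliberately modest
sizes — the 36-beam, eight-slice phantom for the adaptation studies, 8–12
beam synthetic prostate cases at 2–4 mm dose sampling, a 48-point
$\beta^*$ grid — which reproduce every qualitative result of the method
(three-step DVH pattern, MU conservation, fixed-point behaviour,
convergence to the closed form) in minutes on one CPU. All sizes scale up
through the configuration object.

## Known limitations

* The dose model is the analysis idealization, not a clinical engine;
  absolute DVH statistics of deformed anatomies are indicative only.
* Only one OAR participates in S1/S2 generation; multi-OAR strip
  interaction is out of scope.
* Deliverability constraints (tongue-and-groove, interdigitation, leaf
  speed) are not modelled.
* MU-modifying adaptation — the published escape hatch for large
  geometry changes — is not implemented; the package warns when a case
  crosses the ~10% equivalent-MU threshold where MU preservation stops
  being adequate.
* Dose accumulation across fractions and deformable registration are out
  of scope.
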