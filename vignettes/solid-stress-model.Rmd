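---
title: "Modeling growth-induced solid stress around gel-embedded spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling growth-induced solid stress around gel-embedded spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the question

A macrophage suspended as a single cell in molten agarose is trapped, after
gelation, inside an elastic cage it cannot degrade or remodel. As the cell
proliferates in place, the growing aggregate — a spheroid — must displace gel
to make room for itself, and the displaced gel pushes back. The mechanical
footprint of that growth, the *growth-induced solid stress*, is the quantity
this package models and measures around. Four experimental readouts feed the
analysis: unconfined compression of cell-free gel disks (how stiff is the
cage), phase-contrast morphometry of day-3 spheroids (how large did the
aggregate get), live/dead staining (did confinement kill the cells), and
relative qPCR (how did expression respond). The computational core converts an
observed final spheroid outline into the displacement, strain and stress field
it must have produced in the surrounding gel.

## The elastic growth model

The gel is treated as a homogeneous, isotropic, linear elastic solid in **2-D
plane strain**. Plane strain (rather than plane stress) is appropriate because
the gel slab is millimetres thick while spheroids are tens of micrometres: the
out-of-plane dimension is effectively constrained. The model domain is the
annular region between

* the **seed circle** of radius $a_0 = 5\ \mu m$ — the single founding cell —
  and
* a fixed **outer circle** of radius $R$, default $20\times$ the equivalent
  final radius $\sqrt{A/\pi}$.

The spheroid interior is excluded: the model estimates the deformation of the
gel adjacent to the spheroid, not the stress state inside the aggregate, and
because the boundary conditions are displacement-driven the spheroid's own
stiffness never enters.

Growth is imposed as a Dirichlet condition: each point of the cavity boundary
at polar angle $\theta$ about the seed center is mapped along the ray at
$\theta$ to the point where that ray crosses the observed final outline, and
the prescribed displacement is the difference. This *radial ray map* is the
simplest correspondence consistent with growth from a point; it requires the
final outline to be star-shaped about the seed center, which is checked at
problem construction. The outer boundary is fully fixed ($u = 0$).

The solver uses linear (constant-strain) triangles on a structured annular
mesh whose element size grows proportionally to radius, so triangles stay
near-isotropic from the 1 µm elements at the cavity out to the far boundary.
The assembled system is symmetric positive definite and is solved with a
sparse Cholesky factorization; the relative residual is checked below
$10^{-10}$. Stress follows from the plane-strain constitutive matrix, and the
out-of-plane component $\sigma_{zz} = \nu(\sigma_{xx}+\sigma_{yy})$ enters the
von Mises summary.

### The closed-form oracle

For circular growth the problem is the classical pressurized-annulus (Lamé)
problem with displacement boundary data, whose axisymmetric solution is

$$ u(r) = A\,r + B/r, \qquad A = \frac{u_a\,a}{a^2 - R^2}, \qquad B = -A R^2, $$

satisfying $u(a) = u_a$, $u(R) = 0$ for *every* admissible Poisson ratio. This
solution is implemented independently of the solver (`analytic_annulus()`) and
anchors the verification suite: at the default cavity resolution
($h = a_0/5$) the finite-element radial displacement agrees with it to well
under 1% in relative $L_\infty$, and the error falls monotonically under mesh
refinement. The solver is additionally checked against the structural laws a
pure-Dirichlet linear problem must obey exactly — displacement independent of
$E$, stress proportional to $E$, linearity in $u_a$, the patch test to machine
precision — none of which depend on meshing choices.

### Fidelity limitations, stated up front

The displacement from a 5 µm seed to a 40+ µm spheroid is geometrically large,
yet the model performs **one linear solve on the reference configuration**.
This mirrors the modeling idealization of the study design rather than
attempting a finite-strain or incremental-growth treatment, and the absolute
strain and stress magnitudes near the cavity should be read accordingly; the
far-field decay shape and the comparisons across gel stiffness are the
meaningful outputs. A useful consequence of the Dirichlet-driven formulation
is that the displacement *field* is independent of $E$ entirely — stiffness
matters for stress, not displacement — so the headline displacement summaries
are insensitive to uncertainty in gel modulus. The "discoid" case is a thin
ellipse (aspect ratio ≥ 5) standing in for a gel microcrack; no fracture
mechanics is attempted.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `seed_radius` | 5 µm | founding-cell radius; sets the decay length of the far field |
| `nu` | 0.45 | gel Poisson ratio; unreported for these gels, so the near-incompressible value is used — the axisymmetric displacement is provably ν-independent, and tests confirm ν = 0.2 vs 0.45 changes the field by < 1% |
| `outer_radius` | 20 × equivalent final radius | far-boundary placement; halving it to the 10× validity floor moves near-cavity displacements by well under 1% (the $r/R^2$ correction term) |
| `h_cavity` | `seed_radius / 5` | cavity element size; drives the oracle error below 1% |
| `E` | per condition | 2000 / 19830 / 99596 Pa for 0.5/1/2% gels in the modeling stage — literature calibration values, deliberately distinct from the measured day-1 moduli (3.8/12.1/44.8 kPa) extracted by the rheology module. The two are treated as independent inputs and never reconciled. |

## Compression analytics

Records are converted with the engineering conventions (stress $F/A_0$,
strain $\Delta h/h_0$) for 6 mm diameter, 2 mm thick punched disks compressed
to 50%. Because real records begin with a compliant toe (imperfect platen
contact), the linear region is found automatically: all contiguous windows of
strain width ≥ 0.1 on a 50 × 50 onset-by-width grid are scored by OLS $R^2$,
the best window wins, and ties break toward the widest then latest-onset
window. A floor of $R^2 \ge 0.5$ turns flat or pure-noise curves into an
explicit degenerate-fit error instead of a meaningless slope. The modulus is
the OLS slope over the chosen window with a free intercept, so any residual
toe offset is absorbed. The synthetic generator builds exactly this shape — a
quadratic toe joining a linear segment continuously in value and slope — so
recovery is testable: noiseless curves return the true modulus exactly, and at
1% stress noise the median recovery error over 100 seeded curves stays below
2%.

## Morphometry

Segmentation follows the particle-analysis convention: global threshold
(Otsu by default, with a fixed-value override), 8-connected components,
minimum-area rejection (default 50 px, standing in for the exclusion of
singlet/doublet cells), pixel-count areas converted by `um_per_px`², and
boundary tracing to polygons for downstream geometry use. Solidity uses the
convex hull of the component (with a half-pixel dilation correction) and
eccentricity the moment-equivalent ellipse. Touching spheroids merge — there
is deliberately no watershed split, and the synthetic placement keeps objects
separated so count-recovery tests are exact. The live/dead pipeline is maximum
projection → rolling-ball-style background subtraction (grayscale opening with
a disc) → threshold → particle count per channel. One guard is added to the
automatic path: Otsu's method assumes a bimodal histogram and fails on a
channel containing no cells, so the automatic threshold is floored at 0.2 in
normalized intensity; channels with cells sit far above the floor and are
unaffected.

Coordinates are documented once and used everywhere: pixels are 0-based,
origin top-left, stored `img[x+1, y+1]`; physical coordinates are µm with y
up, via $x_{um} = (x+0.5)\,s$, $y_{um} = (H-y-0.5)\,s$ for pixel size $s$.

## qPCR quantification

Per sample, $\Delta Ct = Ct_{target} - Ct_{reference}$; one control-condition
sample anchors the table ($\Delta\Delta Ct = \Delta Ct - \Delta Ct_{anchor}$)
and folds are $2^{-\Delta\Delta Ct}$, making the anchor's fold exactly 1. The
anchor is the lexicographically first control sample id — the analysis
software the assay community uses picks "one control sample" without
documenting how, so this package picks a deterministic, reproducible rule and
allows an explicit override. Condition summaries use the geometric mean
(folds are log-scale quantities); the arithmetic mean and SEM are reported
alongside for parity with common practice. Grubbs rejection (two-sided,
single pass, α = 0.05, on the $\Delta\Delta Ct$ scale within each
condition × gene group) is available and off by default. No multiple-testing
correction is applied across genes, matching the per-gene reporting
convention of the assay design.

The group tests are implemented in-package and cross-checked against
independent references in the tests: Mann–Whitney U with midranks, exact by
dynamic programming when tie-free and $n_x n_y \le 400$, exact by full
permutation enumeration for small tied samples, tie-corrected normal
otherwise; Kruskal–Wallis with tie correction and Dunn's z on mean ranks with
Bonferroni adjustment. One caveat the noise model exposes: per-sample folds
inherit the anchor sample's own measurement noise (≈ $\sqrt2 \cdot$ Ct noise),
so ground-truth recovery at realistic noise is assessed on the ratio of
condition geometric means, which cancels the anchor term.

## What the synthetic data do and do not emulate

The generator produces every input with known latent truth: lognormal spheroid
areas (areas are positive and right-skewed; the reported data constrain only
condition means, so the coefficient of variation is a free parameter fixed
once at 0.5), near-circular to discoid outlines, non-overlap placement by
rejection sampling (budget 1000 tries per object), binary-foreground renders
with additive Gaussian intensity noise, toe-plus-linear compression curves,
and Ct tables built by inverting the ΔΔCt transform. It deliberately omits
optics (PSF blur), Poisson shot noise, uneven illumination, out-of-focus
structure and touching/overlapping aggregates — segmentation logic, not
denoising, is what downstream tests exercise. Passing recovery tests on these
images therefore validates the measurement chain, not robustness to real
microscopy artifacts. All generator randomness flows from one explicit integer
seed per call and never touches the global RNG stream.

## Problem sizes used by the validation suite

The test and acceptance workloads are sized for precision, not spectacle: the
area-recovery pipeline uses 480 spheroids per condition (16 rendered fields of
30), giving the lognormal sample mean a standard error of ≈ 2.3% of the mean;
viability uses a 1000-cell stack at the printed 95.1% composition with
3-radius minimum separation, where particle counting is exact; the oracle
comparison runs at cavity element sizes 1, 0.5 and 0.25 µm; the Mann–Whitney
size check uses 10⁴ null simulations at n = 6 vs 6. The full suite runs in
well under a minute on one CPU.

## Known limitations

* One-shot linear kinematics at geometrically large growth (above).
* Manual outline tracing and manual thresholds of the original assay are
  replaced by Otsu defaults — the validation target is synthetic ground
  truth, not human agreement.
* The discoid/microcrack case shares the star-shaped-outline requirement, so
  crack geometries more complex than a thin ellipse are out of reach.
* Where the gel concentrations' reported peak displacements depend on
  specific unpublished day-4 image geometries, this package reports its own
  simulated summaries rather than reproducing those figures.
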