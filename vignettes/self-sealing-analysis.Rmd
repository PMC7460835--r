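---
title: "Methods: self-sealing kinematics, rank statistics and leaf biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-sealing kinematics, rank statistics and leaf biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafseal)
```

## The biological problem

Succulent *Delosperma* leaves store water in a central hydrenchyma wrapped
by chlorenchyma, a peripheral net of vascular bundles and the epidermis,
with a single central vascular strand running along the axis. When a ring
incision cuts the outer tissues around the circumference, the pre-stressed
tissue assembly relaxes and water evaporates from the wound: over roughly
an hour the whole leaf contracts along its axis until the wound edges meet
(self-sealing). The strength of this contraction differs between species
and with ambient relative humidity (RH), and is thought to trace back to
differences in tissue mechanics, above all the flexibility of the central
vascular strand.

`leafseal` implements the complete quantitative chain used to compare the
response of a straight-leaved, terete species and a recurved, triquetrous
species under a crossed species x RH design: trajectory simulation,
segment-wise contraction kinematics, rank-based factorial statistics,
cross-section morphometry, and tensile-property extraction with a
turgor-based parenchyma modulus.

## Contraction kinematics

Seventeen markers `p1`..`p17` lie along the leaf mid-line; painted markers
sit at the apex (`p1`), 2 mm above (`p5`) and below (`p9`) the incision
(itself at one third of leaf length from the apex), at the base (`p17`)
and halfway between `p9` and `p17` (`p13`). The leaf is divided into three
contiguous segments: apex (`p1`->`p5`), incision (`p5`->`p9`) and base
(`p9`->`p17`).

For a segment $i$ with length $L_i(t)$, the package computes the
*absolute contraction*

$$\varepsilon_i(t) = \frac{L_i(t) - L_i(t_0)}{L_i(t_0)}$$

(dimensionless, exactly zero at $t_0$, negative for shortening) and the
*relative contraction*

$$\varepsilon_i^*(t) = \varepsilon_i(t)\,\frac{L_i(t)}{L_{\mathrm{total}}(t)},$$

which weights each segment by its share of the whole leaf so that
differently sized leaves are comparable. Both are stored signed;
magnitudes are a presentation choice.

Segment length is measured in one of two modes:

* **Y-spacing** (straight leaves, held vertically): the absolute Y
  distance between the segment's boundary markers.
* **Arc length** (recurved leaves): per frame, the marker cloud is rotated
  so its principal axis becomes the abscissa, a least-squares polynomial
  $y(x)$ (default degree 3, configurable; the suite exercises degrees 3-5)
  is fitted to all markers, the boundary markers are projected onto the
  curve (nearest point), and
  $\int \sqrt{1 + y'(x)^2}\,dx$ is evaluated by adaptive quadrature at a
  relative tolerance of $10^{-8}$.

Design choices where the procedure was genuinely open:

* *Per-frame fitting.* The polynomial is refitted in every frame rather
  than fitted once to a reference frame; this makes no assumption about
  how tracking noise propagates through time.
* *Principal-axis rotation.* Fitting $y(x)$ directly would fail for
  strongly recurved leaves with near-vertical tangents; rotating each
  frame's cloud to its principal axis removes that failure mode and makes
  the fit rotation-invariant.
* *Marker projection.* Painted markers are mapped to the fitted curve by
  nearest distance; with noiseless markers the projection is exact.
* *Sign convention.* Contraction values stay negative internally.
* *Endpoint summary.* A leaf/segment is summarised by the median
  contraction over the last `window_frames` frames (default 5); the median
  suppresses frame-level tracking noise without modelling it.

A finite-degree polynomial cannot represent a circular arc exactly, so the
arc-length mode carries a small systematic error for recurved leaves. On
noiseless synthetic leaves the endpoint contraction is recovered to
machine precision for straight mid-lines and to better than $10^{-3}$
(measured: about $7\times10^{-6}$ at degree 3) for the default recurved
geometry — far below the biological signal of a few percent.

## The synthetic generator

Raw experiments are videos; the analysis consumes tracked coordinates. The
generator emulates exactly that interface so every stage is testable
without downloads:

* 1/6 Hz sampling over 60 min (601 frames), matching the experimental
  acquisition; configurable.
* Straight mid-lines of 45.5 mm and recurved (circular-arc) mid-lines of
  27.4 mm, the reported mean leaf lengths of the two species. The arc
  radius defaults to 50 mm — experimental leaves were preselected against
  pronounced curvature, and a 27 mm leaf on a 50 mm arc bends by about
  31 degrees.
* Each segment's arc length follows a saturating exponential
  $L_i(t) = L_i(0)\,(1 + \varepsilon_{\infty,i}(1 - e^{-t/\tau}))$ with
  $\tau = 10$ min, so the contraction effectively saturates within the
  observation hour. The published record shows saturating median curves
  but no functional form; the exponential is the simplest
  hydraulic-relaxation surrogate and is a config-visible choice.
* Contraction scales arc length uniformly within each segment about its
  proximal (basal) boundary, with the leaf base fixed at the origin; the
  intra-segment strain profile is unreported.
* Tracking noise is isotropic Gaussian per coordinate per frame
  (default sd 0.02 mm — an assumption; the error structure of the tracking
  software is unreported).
* Cohorts draw per-leaf plateaus from a normal distribution around group
  means (between-leaf sd 0.01, truncated to $(-1, 0]$ by redrawing) and
  derive per-leaf seeds from the cohort seed by a fixed splitting rule, so
  cohorts are reproducible leaf by leaf.
* Default group plateau means follow the reported qualitative ordering
  (incision of the straight species strongest, low RH stronger than high
  RH); their magnitudes are assumptions, since per-leaf plateaus are not
  tabulated.

What passing tests on synthetic data do *not* show: robustness to
non-Gaussian tracking failures (marker swaps, occlusion), to leaf bending
out of plane, to gravity acting differently on the two mounting
orientations, or to deviations from the exponential time course. They do
show that the kinematic pipeline is an unbiased, noise-stable estimator of
the generating contraction under the stated model.

## Rank-based statistics

Endpoint contractions are analysed with the Scheirer-Ray-Hare (SRH) test:
responses are replaced by mid-ranks over the whole dataset, a two-way
ANOVA is computed on the ranks, and each effect's statistic
$H = SS_{\mathrm{effect}} / MS_{\mathrm{total}}$ (with
$MS_{\mathrm{total}} = SS_{\mathrm{total}}/(N-1)$) is referred to a
chi-square distribution at the effect's degrees of freedom. Because
published analyses sometimes report the ordinary rank-ANOVA F with its
denominator degrees of freedom, both conventions are returned. Balanced
designs use closed-form sums of squares; unbalanced designs fall back to
type-II sums of squares via nested model comparisons (balanced data are
unaffected by the distinction). A constant response makes $H$ undefined;
the implementation reports $H = 0$, $p = 1$ with a warning rather than
failing.

Post-hoc comparisons are two-sided Wilcoxon rank-sum tests over all group
pairs with Bonferroni adjustment $p_{adj} = \min(1, m\,p)$. The exact null
distribution is used when both samples have at most 12 observations and no
ties; otherwise the normal approximation with tie-corrected variance and
continuity correction. `W` is reported as the rank sum of the first sample
minus its minimum (the Mann-Whitney U of the first sample) — conventions
differ across software, so the choice is documented rather than implied.
The test suite checks the exact branch against full enumeration of all
labelings for group sizes up to 8, and the SRH decomposition against an
independent rank-ANOVA oracle and a 5000-replicate null simulation
(type-I error of each effect within [0.04, 0.06] at $\alpha = 0.05$).

Significance bands are inclusive as conventionally printed:
$p \le 0.05$ `*`, $p \le 0.01$ `**`, $p \le 0.001$ `***`, otherwise `ns`.

## Morphometry

The cross-section is five concentric layers; a layer's thickness is its
outer radius (or outer intercept along a measurement line) minus the
radius of the adjacent inner tissue, so thicknesses telescope back to the
outer intercept. Terete sections measure along the minor/major diameters
(the section is treated as centro-symmetric); triquetrous sections measure
along the three interior angle bisectors $r_1$-$r_3$ and one side bisector
$r_4$ (the perpendicular from the designated side's midpoint to the
opposite boundary; which side carries $r_4$ is configurable because the
mounting convention is not fully specified). Embedding shrinkage
$\gamma = 100\,(\mathrm{fresh}-\mathrm{embedded})/\mathrm{fresh}$ and its
exact inverse correction are provided.

For surface-area-to-volume comparisons the leaf shapes are idealized as a
cone (terete; base radius = mean of the semi-axes) and an irregular
tetrahedron from four vertex coordinates (triquetrous). The closed forms
are validated against an independent Cayley-Menger/Heron oracle rather
than against published figures, which depend on unpublished shape
parameters.

## Biomechanics

* **Elastic modulus**: slope of the best linear region of the pre-peak
  stress-strain trace, found by sliding a window of at least 20% of the
  pre-peak points and maximizing $R^2$ (ties resolve to the earliest
  window; traces whose best window stays below $R^2 = 0.9$ are rejected
  with diagnostics). The window fraction and threshold are conventional
  and exposed in the interface.
* **Tensile strength**: the maximum stress attained.
* **Poisson's ratio**: minus the least-squares slope of lateral versus
  axial strain.
* **Turgor-based parenchyma modulus**: hydrenchyma and chlorenchyma cannot
  be clamped in a tensile machine, so their moduli are computed from cell
  geometry and turgor with the linear-in-turgor relation
  $$E = c_w\,E_{cw}\,\frac{t_{cw}}{d_c} + c_P\,P,$$
  a cell-wall term (membrane stiffness of a thin-walled closed cell scales
  with the wall-thickness to cell-diameter ratio) plus turgor stiffening.
  The defaults $c_w = 4$ and $c_P = 3.4$ are calibrated so that the four
  published tissue moduli (0.26/0.26 MPa for the recurved species'
  hydrenchyma/chlorenchyma, 0.23/0.27 MPa for the straight species') are
  reproduced at the published two-decimal precision from the published
  inputs; both coefficients are arguments, so the relation can be
  re-calibrated if an independent formulation is preferred. The measured
  tissue Poisson's ratio is accepted and validated for admissibility
  ($0 \le \nu \le 0.5$), but across the narrow physiological range covered
  by the calibration data (0.29-0.35) its influence is not identifiable,
  and it does not enter the calibrated relation — an openly stated
  limitation.
* **Comparison table**: interspecific ratios of property medians, rounded
  to two decimals *half away from zero* (base R rounds half to even, which
  disagrees with printed tables; `round_half_away()` is used throughout).

There is no full unit system; units are documented per argument, and the
mixed-unit entry points carry plausibility checks (for example, cell
dimensions passed in millimetres instead of micrometres raise an error
instead of silently mis-scaling).

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate`, relative tolerance $10^{-8}$; arc-length
  bounds may exceed the fit domain by at most 2.5% of its width.
* Mid-line fits require `degree + 1` distinct abscissa values after
  rotation; rank-deficient designs raise an explicit error.
* The principal-axis orientation is made deterministic by a fixed sign
  rule, so fits are reproducible across platforms.
* Missing markers or non-increasing frame times are errors (naming frame
  and marker), never interpolated.
* Ties take mid-ranks everywhere; tie-corrected variances in normal
  approximations.
* All RNG flows through explicit seeds; child seeds derive from parent
  seeds by a fixed rule and stay within the 32-bit integer range.

## Problem sizes in the shipped checks

The test-suite simulations are sized to be decisive yet quick: the SRH
null calibration uses 5000 replicates of a 2x2 design with 10 observations
per cell; cohort parameter recovery uses 20 cohorts of 10 straight leaves
at full 1/6 Hz resolution; recurved-leaf oracle checks run single
noiseless leaves at 1-min sampling across fit degrees 3-5; power contrasts
use 80 reduced-resolution cohorts per condition. These are the package's
own choices of experiment size, stated here so that readers know what the
reported error rates were estimated from.

## Known limitations

* The exponential contraction time course and the noise and between-leaf
  variance magnitudes are assumptions; conclusions about the real
  experiments inherit them only insofar as the pipeline is agnostic to the
  exact saturating shape.
* Virtual markers are defined by arc-length proportionality between
  painted markers; the original tracking software's definition is not
  public.
* The turgor-based modulus is a calibrated two-coefficient relation, not a
  transcription of the original micromechanical derivation.
* Leaves are treated as independent replicates; no repeated-measures or
  mixed-model structure is fitted.
* No image processing: the package starts from tracked coordinates.
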