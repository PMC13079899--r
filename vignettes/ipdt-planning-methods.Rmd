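---
title: "Light-dose planning and delivery-uncertainty analysis for interstitial PDT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-dose planning and delivery-uncertainty analysis for interstitial PDT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdtplan)
```

## The planning problem

In interstitial photodynamic therapy (iPDT) light is delivered inside the
target tissue through implanted fibre diffusers — cylindrical diffusers
modelled as thin line sources emitting radially over a finite length, and
spherical diffusers modelled as isotropic point sources. The controllable
dose surrogate is the fluence $\phi_i$ (J/mm²) received by each tetrahedral
tissue element $i$. An element of the tumour is adequately treated when
$\phi_i \ge d_{\min,i}$; an element of an organ at risk (OAR — grey and
white matter here) is damaged when $\phi_i \ge d_{\max,i}$. The main
outcome metric is $v_{100}$: the tumour volume fraction (in %) at or above
threshold, and for each OAR the absolute over-threshold volume in mm³.

Because fluence is linear in the source powers, a single forward
simulation per source at 1 W suffices: the dose matrix $G$ stores the
per-element fluence of each unit-power source, and any plan evaluates as
$\phi = G x$ for the power vector $x$. Power selection is a linear
program:

$$\min_x f(x) \quad \text{s.t. } A x \le p_{\max},\; x \ge 0,$$

where each under-dosed tumour element contributes
$w_i t_i (d_{\min,i} - g_i \cdot x)$ to $f$, each over-dosed OAR element
contributes $w_i t_i (g_i \cdot x - d_{\max,i})$, and all other elements
contribute zero ($t_i$ is the element volume, $w_i$ its weight). The
default constraint set is the single aggregate row
$\sum_i x_i \le 1\,\mathrm{W}$, guarding against tissue heating.

Two uncertainty-aware objectives address source-power miscalibration of
relative size $\eta$: $f_{\text{max+min}}(x) = f(x(1+\eta)) +
f(x(1-\eta))$, and $f_{\min}(x) = f(x(1-\eta))$, which optimizes against
the minimum deliverable power — the extreme at which tumour coverage is
lost. Worst-case delivered-power bounds are simply $x(1\pm\eta)$, with
$\eta \in \{5\%, 10\%, 20\%\}$ as the study levels.

## How the LP is solved

Only `boot::simplex` is available as an LP backend in the supported
environment, and the epigraph form of the objective (one slack per element
and power extreme) is far too large for a dense pure-R tableau. The
package therefore solves the equivalent low-dimensional problem — $f$ is
piecewise-linear convex in the handful of source powers — with a
level-bundle cutting-plane method:

* each iterate contributes an exact subgradient cut of $f$;
* a small simplex master LP over (powers, epigraph variable) yields a
  certified lower bound;
* the next iterate is the projection of the incumbent onto the level set
  $\{\hat f(x) \le \ell\}$, $\ell = \mathrm{lb} + 0.3(\mathrm{ub} -
  \mathrm{lb})$, a strictly convex QP solved by `quadprog`.

Iteration stops when the gap $\mathrm{ub} - \mathrm{lb}$ falls below a
relative $10^{-9}$ (default), i.e. at the LP optimum up to that tolerance.
Cut rows are sup-normalized before entering the simplex tableau (row
scaling leaves the LP unchanged) because `boot::simplex` is numerically
fragile; on a simplex failure the oldest cuts are dropped once and the
master retried. The tests cross-check this solver against both a
brute-force power grid at 0.001 W resolution and the full epigraph LP
handed directly to the simplex on a small toy — two independent routes to
the same optimum.

Exact prefilters keep the cut evaluations cheap: an OAR element whose
best-case dose $\max_j g_{ij} \cdot P_{\text{total}}$ cannot reach its
threshold contributes an identically zero cost term and is dropped from
the LP before solving.

### The 98% coverage target

Planning practice constrains tumour $v_{100}$ at 98%. The mechanism by
which a planner enforces this is an open design choice; here it is an
optional outer loop that doubles the tumour element weights (up to 20
rounds) until the nominal-power coverage reaches the target, then stops.
On an infeasible geometry the loop simply exhausts and reports the
achieved coverage. It is enabled by default (`coverage_target = 0.98`)
and disabled with `coverage_target = NULL` wherever a pure LP optimum is
wanted (all oracle comparisons in the tests do this).

## Forward light transport

Two engines stand behind the same dose-matrix surface:

* **Analytic (default).** The infinite-medium diffusion kernel
  $\phi(r) = e^{-\mu_{\text{eff}} r} / (4 \pi D r)$ per unit emitted
  energy, with $\mu_s' = \mu_s(1-g)$, $D = 1/3(\mu_a + \mu_s')$,
  $\mu_{\text{eff}} = \sqrt{3\mu_a(\mu_a+\mu_s')}$. Line diffusers are
  integrated along their axis by Gauss–Legendre quadrature (32 nodes per
  cm, configurable); the node count is exercised against a 10⁴-point
  trapezoid oracle in the tests. Because the kernel is infinite-medium
  only, the analytic engine assumes one homogeneous effective medium
  (the tumour's optical properties by default). Evaluation distances are
  clamped at 0.5 mm — the physical fibre radius scale — to keep the
  kernel finite next to a source. This engine drives the LP/annealing
  inner loops and the deflection libraries.
* **Voxel Monte Carlo.** Photon packets take exponential optical-depth
  steps across the phantom's voxel grid with per-region properties,
  deposit $w \mu_a/\mu_t$ at interaction sites, scatter by
  Henyey–Greenstein sampling, and undergo Russian roulette below a weight
  of $10^{-4}$ with survival probability 0.1. Boundaries are matched (no
  Fresnel reflection) — boundary physics is not the subject here. Line
  diffusers emit radially (direction perpendicular to the axis, uniform
  azimuth, uniform position along the emitting length); point diffusers
  emit isotropically. Fluence is scored per voxel by the absorbed-energy
  estimator $E_{\text{abs}}/(\mu_a V)$, falling back to the track-length
  estimator $\sum w\ell / V$ in (near-)transparent regions where the
  absorption estimator is undefined. Weight is conserved exactly in the
  tallies (absorbed + escaped + net roulette balance = launched), which
  the tests assert to $10^{-6}$.

The engine-equivalence oracle runs both engines on a homogeneous phantom
and requires agreement within 10% over radii of 5–15 mm at $10^6$
packets. That check uses a reduced-scattering similarity medium
($\mu_s = \mu_s' = 2\,\mathrm{mm^{-1}}$, $g = 0$): its diffusion
parameters equal the tumour defaults while the transport mean free path
stays long enough for the check to run in about 90 s on one CPU. With the
clinical $g = 0.9$, $\mu_s = 20\,\mathrm{mm^{-1}}$ optics each packet
undergoes thousands of scattering events and the same check would take
over an hour; the diffusion limit being tested is identical by the
similarity relation.

One scoring difference from tetrahedral research codes is documented
rather than reconciled: those codes score energy crossing tetrahedron
faces, whereas this package scores volume-averaged fluence per element.

## The synthetic phantom world

Patient-derived tetrahedral head meshes are external data; the package
generates layered brain-like phantoms instead. A box domain (80 mm cube
by default) carries concentric layers from every face — skull 4 mm, CSF
2 mm, grey matter 6 mm, white matter interior — with an ellipsoidal (or
multi-sphere) tumour embedded in the core; the default semi-axes
(19, 19, 22) mm give a ~33 cm³ tumour, mid-range for glioblastoma
planning studies. Each voxel is split into six Kuhn tetrahedra labelled
by the region at their centroid, matching the tetrahedral data model of
patient meshes while partitioning the domain volume exactly. The default
4 mm pitch (48K tetrahedra) is a desk-scale compromise; 2 mm reproduces
clinical mesh density (384K tetrahedra).

What the generator does not emulate: anatomical curvature (layers follow
the box, not a skull surface), heterogeneous optical properties within a
region, infiltrative tumour margins, and CSF channels. A green test on
these phantoms therefore establishes the correctness and the qualitative
behaviour of the planning machinery, not clinical dose accuracy on any
patient geometry.

Default optical properties are representative of brain tissue at PDT
wavelengths (~630–665 nm) and were chosen once so that each
scattering-dominated region has an effective attenuation depth
$1/\mu_{\text{eff}}$ inside the 2–5 mm range quoted for PDT in tissue;
CSF is a low-scattering clear layer. They are a documented, replaceable
table (`default_optical_properties()`), not a claim about any specific
patient.

### Units and thresholds

Fluence is J/mm² throughout. The treatment duration converting source
power (W) into emitted energy (J) is an explicit scalar, default 1 s, so
the default dose matrix is "fluence per W-second". Thresholds must live
on the same scale, and only the ratio threshold/duration matters (both
sides of every comparison are linear in duration). The default tumour
threshold of $1.5\times10^{-4}$ J/mm² per W·s corresponds to a real
prescription of about 25 J/cm² delivered over a ~2800 s session at the
1 W cap — a typical clinical order of magnitude. The nominal OAR death
threshold defaults to 20× the tumour prescription with the standard 0.1×
guardband applied to grey and white matter, making the effective OAR
limit twice the tumour threshold; on the default phantom this yields
OAR damage volumes of hundreds to a few thousand mm³, the scale planning
studies report. These are stated-world calibrations, made once and
documented here, not fitted quantities.

### Heuristic placement

Initial plans follow the clinical heuristic: parallel line diffusers on a
regular grid aligned with the tumour's longest principal axis, 10 mm
centre-to-centre, outermost axes kept 8–10 mm inside the tumour boundary,
lengths drawn from the commercial 5 mm-increment set. The lateral
orientation of the grid is not prescribed anywhere; this implementation
aligns it with the tumour's principal axes (PCA of the tumour element
centroids) and documents that choice. Point diffusers fill tumour pockets
farther than 7 mm from every line axis (greedy farthest-first, at most
4); a tumour too small for any diffuser receives a single central point
source. The injection constraint — the disc on the outer surface through
which every trajectory must pass — is constructed to encircle all
axis/surface intersection points, and point sources (whose trajectory is
unobserved) take the disc centre as their injection point.

## Position uncertainty

Insertion error is modelled as an angular deflection about the injection
point: insertion length and emission length are held constant (both are
precisely controlled in the procedure), and the worst-case angle comes
from the isosceles triangle whose equal sides are the insertion length
$L$ and whose base is the 3 mm tip-displacement tolerance:
$\theta_{\max} = 2\arcsin(d/2L)$, so the chord at $\theta_{\max}$ is
exactly $d$.

The angular space is discretized: 8 principal directions at 45° in the
plane normal to the source axis (Dir1 seeded-random), and 10 angle
quantiles at fractions 0.05, 0.15, …, 0.95 of $\theta_{\max}$ — giving
$1 + 8 + 8\times10 = 89$ forward simulations per source, precomputed into
a deflection library. Outcomes for any sampled configuration are then a
superposition of library columns, so 10,000-sample histograms cost no
further transport.

Two samplers drive the analysis. **Worst case**: every source deflects by
the full 3 mm in a uniformly random principal direction. **Truncated
Gaussian**: per source, an axis is drawn from Dir 1–4, a magnitude from
$N(0, \sigma)$ with $\sigma = 3/1.96$ mm (so ~95% of raw draws lie within
3 mm) redrawn until inside the bound, the sign selects Dir 1–4 vs Dir
5–8, and the magnitude snaps to the nearest quantile bin. The
nearest-bin rule is this package's choice — only 89 fields exist per
source and the mapping from continuous magnitude to bin is not otherwise
specified. The 4-axis-plus-sign construction is distributionally
identical to an 8-way uniform direction draw with unsigned magnitudes;
the signed form is implemented because it is how the deflection
histograms are constructed.

Power re-optimization models the clinical option of measuring the
realized source positions after insertion: the dose matrix is reassembled
from the realized library columns and the LP re-run on it, independent of
the nominal plan. By LP optimality the re-optimized powers never cost
more on the realized geometry than the nominal powers do, and with the
coverage loop they restore the 98% tumour target whenever the realized
geometry can reach it.

Sample counts default to 10,000 (1,000 when every sample carries a
re-optimization); the test suite and worked examples run 200-sample
versions of the same protocol to stay inside desk-scale budgets, which is
sufficient for every qualitative assertion made (direction of mean
shifts, spread orderings) though not for publication-grade histograms.

## Simulated-annealing placement

Source locations are optimized by simulated annealing with the LP as the
inner evaluator: propose a perturbation of one source (lateral
translation, depth change, 5 mm length step, optional point/line toggle),
validate it (pairwise clearance ≥ 2 mm, emitting segment inside the
tumour, axis through the injection disc), LP-optimize its powers, and
accept by the Metropolis rule — always when cost improves, with
probability $e^{-\Delta\text{cost}/T}$ otherwise. A printed form of this
rejection probability that is negative for worsening moves is treated as
a typographical slip for the standard Metropolis rule.

The annealing constants are heuristic by nature and are this package's
own: $T_0 = 0.2\,|$initial cost$|$ (floored at $10^{-9}$), geometric
cooling ×0.95 every $20\times$(source count) proposals, termination at
$T < 10^{-3} T_0$ or after 10 stages without improvement. The move menu
is likewise this package's definition; the sources' count and injection
surface are preserved exactly, matching the comparison protocol of
placement studies.

## Numerical choices and degenerate inputs

* Threshold comparison is inclusive (an element exactly at threshold is
  treated) so element counts are reproducible.
* $\Delta v_{100}$ aggregation across models geometric-averages the
  per-model spreads (rather than differencing the averaged extremes);
  both are computable and the difference is small, but the per-model
  spread is the quantity with a physical reading per model.
* A zero-variance paired difference makes the t statistic degenerate:
  all-zero differences report $p = 1$, anything else errors rather than
  fabricating a p-value. No multiple-comparisons correction is applied.
* The LP returns its certified bounds; a degenerate optimum may be
  attained at different vertices depending on row scaling, which is why
  tests compare costs, not power vectors.
* Relative change $\Delta v_{100}^{\%}$ is undefined at zero nominal
  $v_{100}$ and reported as missing.
* Phantom configs whose tumour touches the skull/CSF shell are rejected
  at construction.

## Known limitations

The analytic engine ignores tissue heterogeneity and boundaries; the MC
engine scores on the voxel grid, not per tetrahedron; optical-property
and photosensitizer uncertainty are out of scope (they are the dominant
outcome-variability contributors in the wider literature and a natural
extension); annealing cannot add or remove sources; and all quantitative
defaults describe a synthetic stated world, not a patient.
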