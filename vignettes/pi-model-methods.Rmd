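---
title: "Methods: the Proliferation-Invasion model and its clinical derivatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Proliferation-Invasion model and its clinical derivatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliopi)
```

## The model

gliopi implements the Proliferation-Invasion (PI) description of diffuse
glioma growth: the tumor cell density $c(\mathbf{x}, t)$ (cells/mm$^3$)
obeys

$$\frac{\partial c}{\partial t} = \nabla \cdot (D \nabla c)
  + \rho\, c \left(1 - \frac{c}{K}\right),$$

with net invasion rate $D$ (mm$^2$/year), net proliferation rate $\rho$
(1/year) and carrying capacity $K$ (cells/mm$^3$). Two consequences of this
equation carry all of the clinical content:

* an established tumor invades as a traveling front with asymptotic
  velocity $v = 2\sqrt{D\rho}$, so the imaging radius grows linearly in
  time;
* the front's leading edge decays over the gradient length
  $\lambda = \sqrt{D/\rho}$, so a proliferation-dominated ("nodular",
  high $\rho/D$) tumor has a sharp edge and an invasion-dominated
  ("diffuse", low $\rho/D$) tumor a shallow one.

MRI enters through density thresholds: the T1Gd-visible lesion edge is
taken at a cell density of $f_{T1} K$ and the larger T2/FLAIR abnormality
at $f_{T2} K$, with defaults $f_{T1} = 0.80$ and $f_{T2} = 0.16$ following
the established calibration convention. All radii are equivalent spherical
radii; `radius_from_volume()` converts segmented volumes. Every reported
quantity is invariant to the absolute value of $K$ (densities enter only as
fractions of $K$), so the default $K = 10^5$ cells/mm$^3$ is a convention,
not a fitted value.

Geometry is spherically symmetric: the solver evolves $c(r, t)$ under
$\frac{1}{r^2}\partial_r (r^2 D\, \partial_r c)$. This is the assumption
under which the (D, rho) calibration from two scalar radii is exactly
determined; anatomical 3-D simulation is out of scope.

## Numerical scheme

The solver (`pi_simulate()`) uses a conservative finite-volume
discretization on a uniform radial grid: node $i$ owns the shell between
face radii midway to its neighbours, the diffusive flux through a face is
$4\pi r_f^2 D\, \Delta c / \Delta r$, and zero-flux closures hold at $r = 0$
and $r = r_{max}$. The vanishing face area at the origin regularizes the
$r \to 0$ singularity of the spherical Laplacian — the finite-volume
counterpart of the usual symmetric-limit treatment — and summing cell
volume times density gives a total cell number that pure diffusion
conserves to linear-solver precision (measured: $\sim 10^{-15}$ relative
per run, versus the $10^{-6}$ contract).

Time stepping is Strang splitting: a half-step of the reaction, a full
implicit (backward-Euler) diffusion step via a cached sparse Cholesky
factorization, and another reaction half-step. The reaction is advanced by
the *exact* logistic map
$c \mapsto K c e^{\rho \Delta t} / (K + c(e^{\rho \Delta t} - 1))$, whose
flow property makes the two half-steps compose exactly; in the $D \to 0$
limit the scheme therefore reproduces the closed-form logistic solution to
rounding error at any $\Delta t$. The implicit diffusion matrix is an
M-matrix, so densities remain in $[0, K]$ structurally; the solver asserts
the bounds each step (tolerance $10^{-8} K$) and aborts rather than
silently clipping, because clipped negativity masks instability. An
explicit (forward-Euler) scheme is available behind the same interface;
its stability bound $\Delta t \le \Delta r^2 / (2D)$ is checked before
stepping and violations are rejected up front.

Defaults $\Delta r = 0.25$ mm and $\Delta t = 0.5$ d resolve gradient
lengths down to $\lambda \approx 1$ mm; analyses of sharper fronts scale
$\Delta r$ with $\lambda$ (the resection sweep below uses
$\Delta r = \min(0.25, \lambda/4)$ mm).

Fisher-KPP fronts are *pulled*: they approach $2\sqrt{D\rho}$ slowly from
below, with a transient that decays like $1/(\rho t)$. Two devices keep
measured speeds honest and cheap: simulations start from the numerically
computed steady wave profile (see below) rather than a point seed, and
`wavefront_speed()` fits only the last third of the trajectory while
refusing windows whose front is within 5 % of the outer boundary. With run
lengths of $\rho t \approx 25$, measured speeds sit within 1 % of
$2\sqrt{D\rho}$ across $D/\rho \in [0.5, 10]$ mm$^2$ (the acceptance
script's grid: $D \in \{12, 30, 60\}$, $\rho \in \{6, 12, 24\}$).

## The canonical front profile

Several operations need the shape of the steady traveling wave: the
dimensionless critical Fisher-KPP profile $U(\xi)$ solving
$U'' + 2U' + U(1-U) = 0$. It is integrated once per session along the
unstable manifold of $U = 1$ (with deSolve, rtol $10^{-10}$) and cached.
`front_profile_field()` scales it by $\lambda$ to build initial conditions
with a prescribed imaging radius.

The same profile decides a calibration design question. The textbook
inversion of the T2-T1Gd size gap assumes a pure exponential tail,
$\lambda = (r_{T2} - r_{T1}) / \ln(f_{T1}/f_{T2})$. But between the 0.80 K
and 0.16 K levels the pulled front is far wider than its asymptotic tail:
the measured width is $6.106\,\lambda$, not $\ln 5 = 1.609\,\lambda$ — a
3.8-fold bias that would propagate directly into $D$ and $\rho$.
`gradient_length_from_paired_radii()` therefore defaults to the
profile-width inverter (`method = "profile"`), dividing the gap by the
numerically computed width `front_width(f_t1, f_t2)`; the tail formula is
retained as `method = "tail"` for comparison. A useful side effect: because
the physical gap is $\approx 6\lambda$, millimetre-scale radius noise
perturbs $\hat\lambda$ far less than the tail formula would suggest.

Calibration combines $\hat v$ (ordinary least squares on the serial T1Gd
radii — T1Gd because it is the surgical target lesion; T2 is used only for
the gap) with $\bar\lambda$ (mean over all paired timepoints) via
$D = v\lambda/2$, $\rho = v/(2\lambda)$. Shrinking series are flagged, not
silently inverted: a growth model cannot be calibrated from a non-growing
lesion. Acceptance-scale results: noiseless synthetic series recover both
parameters within 8 % across the grid; with 1 mm radius noise and four
scans the pooled median absolute error is ~7 % over 200 replicates per
tested patient.

## UVC and Days Gained

The untreated virtual control is the model's prediction of growth with no
therapy, anchored at a pre-treatment scan (by default the last one — an
explicit, configurable convention). Simulated mode starts a front *behind*
the anchor, lets it relax onto the discrete traveling wave for
`relax_days` (120 d default), and time-shifts the radius curve through the
anchor exactly. Without this pre-roll a freshly constructed profile
travels a few percent slow while the pulled front re-establishes, which
alone would bias Days Gained by 2-3 days; with it, an untreated virtual
patient scored against its own UVC returns $0 \pm 1$ day. Linear mode
($r(t) = r_0 + v(t - t_0)$) agrees with simulated mode within a few
percent for established fronts and is used where thousands of evaluations
matter.

Days Gained is the horizontal (time-axis) distance from the UVC curve to
the post-treatment point: $DG = t_{post} - t^*$ with
$r_{UVC}(t^*) = r_{post}$, interpolated on the earliest crossing. Scans
below the anchor radius saturate at the elapsed time (flagged); scans above
the UVC give negative scores, which are reported rather than floored —
hyper-progression is information. The responder cutoff has *no default*:
no validated threshold exists, and forcing the caller to state one avoids
baking an unstated clinical decision into the package.

## Radiation (PIRT)

Fractionated radiotherapy enters as instantaneous events at each delivery
time: with linear-quadratic surviving fraction
$S(d) = e^{-\alpha d - \beta d^2}$, $\beta = \alpha / (\alpha/\beta)$, a
fraction maps $c \mapsto c - (1 - S)\, c\, (1 - c/K)$. The $(1 - c/K)$
factor ties kill to proliferative activity — saturated, quiescent regions
respond less — mirroring the proliferation-radiosensitivity link that makes
$\rho$ the imaging correlate of $\alpha$. The event-based form (rather
than a continuous loss term) was chosen for testability: with an empty
plan the code path is identical to untreated simulation, and the
per-fraction arithmetic is directly checkable against the LQ formula
(e.g. $S(2\,\mathrm{Gy}) = 0.4422$ at $\alpha = 0.340$/Gy and $0.9623$ at
$\alpha = 0.016$/Gy with $\alpha/\beta = 10$ Gy). The $\alpha/\beta$ ratio
defaults to 10 Gy, the conventional tumor-tissue value, and is
configurable. `standard_rt_plan()` builds the conventional 2 Gy x 5
weekdays x 6 weeks = 60 Gy course. Post-course radii are non-increasing in
$\alpha$; note that the standard course *eradicates* the visible lesion of
the default virtual patient for $\alpha \gtrsim 0.1$/Gy, so analyses that
need graded responses should use $\alpha$ below that or larger tumors.

## Resection and the survival surrogate

Resection zeroes the density inside a margin (optionally down to a
configurable residual fraction): GTR resects to the T1Gd-visible radius,
STR to 0.75 of it (both conventions configurable; the extent definitions
are qualitative in the source literature), biopsy removes nothing.
`margin_for_fraction_removed()` inverts the cumulative volume-weighted
mass sub-grid (exact for piecewise-constant profiles) — with
`fraction = 0.99` this is the margin required to remove 99 % of all tumor
cells, which hugs the visible edge for nodular tumors and extends far
beyond it for diffuse ones. Survival surrogates assume a uniform fatal
T1Gd-equivalent radius, default 35 mm (the uniform-fatal-size assumption
is standard in this model family; the specific value is a configurable
convention), with censoring at the simulation horizon.

One genuine model limitation deserves emphasis. Because resection leaves
the infiltrative tail beyond the margin untouched, and Fisher-KPP fronts
are pulled by that tail, the re-established front rejoins the untreated
trajectory almost immediately: the time-to-fatal-radius benefit of virtual
GTR over biopsy is under ~1 day for every tumor in the package's sweeps,
and is marginally *larger* for diffuse tumors (more rebuild work at the
shoulder). The tip-of-the-iceberg content of the model — that GTR removes a
much larger *fraction of all tumor cells* from nodular (high $\rho/D$)
tumors than from diffuse ones (0.15 to 0.73 across
$\rho/D \in [0.1, 4]$ mm$^{-2}$ at a fixed 15 mm visible radius) — is
robust and tested. But the clinically observed survival benefit of GTR in
high-$\rho/D$ patients is an empirical cohort finding that this
fatal-radius surrogate does not, and cannot, reproduce: within the pure PI
equation any resection that spares the leading tail is asymptotically
invisible to the front. Capturing that benefit would need mechanisms
outside this model (cell-count-dependent mortality, post-surgical therapy
interactions, mass effect), which we deliberately do not invent.

## Stratification

$\rho/D$ (1/mm$^2$) is dimensionally a reciprocal area and invariant to
joint time-unit changes. `fit_threshold()` scans the midpoints of adjacent
sorted unique values (plus the minimum, so degenerate inputs report
$J = 0$) and maximizes Youden's $J$ — the criterion is our choice, as the
source literature reports operating characteristics without naming one —
with ties broken toward the lower threshold and the low-$\rho/D$ side
assigned to the label with the smaller mean (IDH1-mutant-like) unless
overridden. The scan is verified against an independently coded
brute-force enumeration on random cohorts. Strata default to cohort
tertiles with the half-open convention low $< c_1 \le$ moderate
$< c_2 \le$ high, because no published cutpoints exist for the
low/moderate/high grouping. Kaplan-Meier curves and log-rank tests are
thin wrappers over the survival package: standard statistics are bought,
not rebuilt.

## The virtual cohort

`cohort_spec()` defines the synthetic population: $D$ and $\rho$ are drawn
independently from log-normal distributions (positive, right-skewed, the
shape seen in imaging-calibrated cohorts) with default medians 25 mm$^2$/yr
and 16 /yr — a median velocity of 40 mm/yr, representative of reported GBM
kinetics but explicitly a placeholder, not a fit to any cohort. Scans
follow a quarterly schedule (0/90/180/270 d) from a 10 mm initial T1Gd
radius; measurement noise is additive Gaussian on the radius (default
1 mm, the scale of segmentation error), truncated at zero, with draws
violating T2 $\ge$ T1Gd resampled. A single integer seed fixes every draw,
and `run_virtual_trial()` output is byte-identical across reruns.

What the generator emulates: serial two-modality radii from PI growth,
mm-scale measurement error, and therapy arms acting on a common patient
set. What it does not: real segmentation error structure (correlated
across sequences and time), non-spherical lesions, treatment-era imaging
artifacts such as pseudoprogression, inter-scan schedule variability, and
any correlation between $D$ and $\rho$. Green tests therefore demonstrate
internal consistency of the method chain on model-faithful data, not
clinical performance.

## Problem sizes

The test suite and acceptance script run, by design, at: a 3x3 (D, rho)
grid with $\rho t = 25$ front runs for wave speeds; 200 noise replicates
per patient on three grid points for calibration; 21 virtual patients for
the resection sweep; 100 random cohorts for the threshold oracle; and a
4-patient, 2-arm trial for determinism. These sizes were chosen to give
stable estimates of each property at desk scale; all are parameters, not
limits.
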