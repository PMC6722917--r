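---
title: "From single nanofibers to membrane stress: the micromechanical model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single nanofibers to membrane stress: the micromechanical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomech)
```

## The problem

Electrospun nanofibrous membranes — here silk-fibroin/poly(e-caprolactone)
(SF/PCL) blend mats used as tissue-engineering scaffolds — are layered
deposits of essentially continuous, randomly oriented nanofibers. Their
uniaxial tensile response is what a scaffold designer needs, but testing
single nanofibers is far easier to standardise than testing whole mats.
`nanomech` implements a geometric micromechanical model that predicts the
membrane stress–strain curve from three measurable ingredients:

1. the tensile law of *single* nanofibers,
2. the fiber diameter distribution (SEM-based), and
3. the membrane's porosity and lateral shrinkage behaviour.

## Model assumptions

The model inherits the idealisations of classical nonwoven micromechanics:

* fibers are straight, continuous filaments, randomly oriented in-plane;
* layers deposit independently; there is no inter-fiber adhesion or contact
  mechanics, so each fiber responds independently;
* loading is quasi-static — no strain-rate dependence, no relaxation;
* deformation is *affine*: a circle of fibers through a common intersection
  deforms into an ellipse, each fiber's endpoints following the macroscopic
  field.

Because real mats violate the first two assumptions (wavy fibers, weak
spots, unloaded fibers), measured membrane stress tends to sit somewhat
*below* the model — the model is an upper envelope for an ideal mat.

## The pieces

### Single-fiber law

Single-fiber tensile records are well described by the logarithmic law

$$\sigma(\varepsilon) = a - b\,\ln(\varepsilon + c), \qquad c > 0,$$

with stress in MPa (`b` is negative for a hardening fiber and is stored
exactly as fitted). `fit_fiber_law()` estimates $(a, b, c)$ by
Levenberg–Marquardt with $c \ge 10^{-8}$: as $c \to 0$ the Jacobian columns
for $a$ and $c$ become nearly collinear and the bound keeps both the
logarithm and the solver well behaved. The default start is
$a = \max\sigma$, $b = -\Delta\sigma / \ln(\Delta\varepsilon)$,
$c = 10^{-3}$; the fit is deterministic given data and start.

For every realistic parameter set the raw law is *negative* at
$\varepsilon = 0$ (e.g. about $-3.1$ MPa for the 100/0 SF blend). A fiber
cannot transmit negative tensile stress, so the package clamps the law at
zero by default; the raw law stays available via `clamp = FALSE`, and $R^2$
is always computed against the unclamped law because published fits
evidently were. Units of $a$ and $b$ are taken as MPa — consistent with
typical electrospun-fiber strength scales — since the fitted constants are
dimensionally tied to the stress axis.

### Diameter statistics

`diameter_statistics()` reports arithmetic, root-mean-square and harmonic
means. The model itself uses only the harmonic mean $D = n / \sum 1/d_i$:
it enters the diameter correction $\tfrac12(1 + d/D)$ applied to a tested
fiber of diameter $d$, and the fiber count. The AM–QM–HM inequality
(harmonic ≤ arithmetic ≤ RMS) is asserted on every sample.

### Kinematics

Under membrane strain $\varepsilon$ the axial scale factor is
$\lambda_y = 1 + \varepsilon$; the transverse factor $\lambda_x$ is set by
the shrinkage coefficient $v$ under one of two conventions:

* **literal-eq2** (default): $\lambda_x = v$ — $v$ acts directly as the
  multiplicative transverse factor, exactly as it appears inside the
  reorientation formula
  $\theta' = \arctan[(1+\varepsilon)\sin\theta / (v\cos\theta)]$;
* **strain-ratio**: $v$ read as the transverse-to-axial strain ratio,
  $\lambda_x = 1 + v\varepsilon$.

Both are implemented because the two readings of $v$ give different
numbers; neither is silently corrected into the other, and every run log
records which was used. The affine map then fixes everything else:

$$r' = r_0\sqrt{\lambda_x^2\cos^2\theta + \lambda_y^2\sin^2\theta},
\qquad \varepsilon_f = r'/r_0 - 1,$$

which reproduces the reorientation formula identically
($\tan\theta'\,\lambda_x\cos\theta = \lambda_y\sin\theta$ to machine
precision) — it is the unique linear deformation consistent with the
circle-to-ellipse picture. The same ambiguity exists for the
projection-strain relation: dividing the change of a fiber's axial
projection by the *deformed* projection gives
$\varepsilon/(1+\varepsilon)$ for an axis-aligned fiber, while dividing by
the *reference* projection recovers $\varepsilon$ exactly.
`projection_strain()` defaults to the reference denominator (the
self-consistent choice) and keeps the deformed-denominator variant behind a
flag.

Orientations live on $[0, \pi/2]$; the random layup is symmetric, so
full-plane angles fold in.

### Orientation average and membrane stress

A fiber at initial angle $\theta$ contributes
$f_y = \tfrac{\pi}{4}d^2\,\bar\sigma_f\,\sin\theta'$ along the stretch
axis. The membrane average is

$$\bar f_y = \frac{2}{\pi}\int_0^{\pi/2} f_y(\theta)\,d\theta, \qquad
F_y = n\,\bar f_y, \qquad
n = \frac{2V(1-p)}{r_0\,\pi D^2},$$

where $n$ is exactly the count that makes the total fiber volume equal the
solid volume $V(1-p)$ (asserted to $10^{-12}$ relative in the tests).

Two aggregation choices were genuinely open:

* **Which diameter enters the average.** The $\tfrac12(1+d/D)$ correction
  is defined for a *tested* fiber of diameter $d$; for a membrane
  prediction there is no single $d$. The default evaluates at $d = D$
  (correction factor 1), the only choice under which the force sum and the
  fiber-count conservation identity stay mutually consistent. The
  population-expected factor $\tfrac12(1+\bar d/D)$ is available via
  `correction = "expected"`.
* **Force-to-stress conversion.** Nothing in the model fixes the volume
  over which $F_y$ acts. The package adopts a slab unit cell $V = A\,2r_0$
  — one fiber-length thick — so every fiber in the cell crosses the
  mid-plane and $\sigma_\text{membrane} = F_y/A$ needs no
  orientation-dependent crossing correction. Stress is intensive in $A$ and
  invariant under halving $D$ at fixed porosity (count $\times 4$,
  per-fiber force $\times \tfrac14$), both verified numerically.

Fibers whose axial strain is non-positive are treated as buckled and carry
zero force, consistent with clamping the law.

### Numerics

The integrand is smooth except where the clamp activates. The fiber strain
is monotone in $\theta$, so the clamp boundaries (zero fiber strain; zero
of the raw law) map to at most two angles, found by root bracketing; the
integral is evaluated panel-by-panel with 64-point Gauss–Legendre rules.
Just above the clamp angle the law rises with slope
$|b|/(\varepsilon_0 + c)$ — a boundary layer a few $10^{-4}$ wide in fiber
strain because the logarithm's branch point sits that close — so panels are
additionally subdivided adaptively until bisection changes the panel value
by less than $10^{-13}$ of the integral's scale. Every call also recomputes
the integral at doubled order and fails loudly if the two disagree beyond
$10^{-6}$ relative; in practice order doubling moves the result by less
than $10^{-8}$.

## The discrete Monte-Carlo oracle

`build_network()` + `simulate_tension()` implement the same physics with no
integral: $N$ explicit fibers, orientations uniform on $[0, \pi/2]$,
diameters lognormal (positive support and right skew, the shape SEM
diameter histograms of electrospun mats typically show; the distribution
itself is a modelling choice — only summary diameters are usually
reported). Each fiber is deformed, clamped and projected individually and
the unit-cell force is the literal sum scaled by $n/N$. The simulator
reports a per-point Monte-Carlo standard error.

One deliberate asymmetry: the simulator applies each fiber's *own* diameter
in the $\tfrac12(1+d/D)$ factor — the literal per-fiber reading — so under
diameter dispersion its expectation exceeds the analytic $d = D$ model
(by $\tfrac12(\mathbb E d^2 + \mathbb E d^3/D)/D^2$ relative to 1). The
tests therefore check exact statistical agreement on equal-diameter
networks ($\sigma_{\ln} = 0$), where the two routes share an expectation,
and separately assert the *sign* of the dispersion effect. The agreement
checks use 20 random (spec, law, strain) draws spanning all five blend
parameter sets at $N = 10^5$ fibers, within three standard errors.

## Synthetic data: what it does and does not emulate

`generate_synthetic_fiber_curve()` produces clamped-law curves with i.i.d.
Gaussian noise (default study conditions: 50 points on strain
$[0.01, 1.0]$, noise sd 0.1 MPa — the scale of single-fiber force
transducer scatter relative to ~10–30 MPa stresses);
`generate_diameter_sample()` produces lognormal diameter samples at the
60–100 nm means typical of these mats. These fixtures exercise fitting,
statistics and the full prediction chain, but they do not emulate fiber
waviness, diameter measurement bias, heteroscedastic noise near fracture,
or membrane non-uniformity — so passing tests demonstrate correctness of
the *model implementation*, not accuracy of the model for real mats.

Porosity and shrinkage are inputs, not estimates: where an example needs
values the package uses $p = 0.8$ and $v = 0.9$, typical for electrospun
mats, as stated assumptions.

## Worked example

```{r example}
tab <- sfpcl_fiber_params()
params <- fiber_law(tab$a[1], tab$b[1], tab$c[1])   # SF/PCL = 100/0
spec <- membrane_spec(porosity = 0.8, r0_nm = 1000, area_nm2 = 1e6,
                      shrinkage_v = 0.9,
                      harmonic_d_nm = sfpcl_diameter_summaries()$harmonic_nm[1])
pred <- predict_stress_strain(spec, params, seq(0, 0.5, by = 0.1))
pred

# cross-check one point against the discrete simulator
net <- build_network(1e5, mu_ln = log(spec$D), sigma_ln = 0, seed = 42)
sim <- simulate_tension(net, spec, params, 0.3)
c(analytic = pred$stress_mpa[which.min(abs(pred$strain - 0.3))],
  monte_carlo = sim$stress_mpa, se = sim$se_mpa)
```

## Known limitations

* No fracture criterion or post-peak softening; predictions are meaningful
  only up to the experimental fracture strain.
* No viscoelasticity — outside the model's quasi-static scope.
* The literal shrinkage convention makes $\lambda_x = v$ at *zero* strain,
  i.e. the transverse contraction is not continuous at $\varepsilon = 0$
  unless $v = 1$; this is the printed formula's behaviour, and the
  strain-ratio convention is provided for users who prefer a continuous
  deformation path.
* Predicted membrane stress scales with assumed porosity through $(1-p)$;
  uncertainty in $p$ propagates linearly.
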