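# nanomech

Micromechanical prediction of the uniaxial tensile response of electrospun
nanofibrous membranes from single-fiber measurements.

Electrospun mats — e.g. silk-fibroin/poly(e-caprolactone) (SF/PCL)
scaffolds for tissue engineering — are layered networks of randomly
oriented nanofibers. `nanomech` predicts the membrane stress–strain curve
σ(ε) from three measurable inputs: the tensile law of single nanofibers,
the fiber diameter distribution, and the membrane's porosity and lateral
shrinkage.

## The model

Single fibers follow the logarithmic law

    σ_f(ε_f) = a − b · ln(ε_f + c)        [MPa, b < 0 for hardening fibers]

fitted by `fit_fiber_law()` (Levenberg–Marquardt, c bounded below; negative
law values are clamped to zero stress). Under membrane strain ε the fiber
population deforms affinely (circle → ellipse): a fiber at inclination θ
rotates to

    θ′ = arctan[ (1 + ε) sinθ / (λx cosθ) ],

stretches to fiber strain ε_f = sqrt(λx² cos²θ + (1+ε)² sin²θ) − 1
(λx set by the shrinkage coefficient v), and contributes an axial force
f_y = (π/4) d² σ̄_f sinθ′. The membrane stress is the orientation average

    f̄_y = (2/π) ∫₀^{π/2} f_y(θ) dθ,   F_y = n f̄_y,
    n = 2V(1 − p) / (r0 π D²),         σ_membrane = F_y / A,

with p the porosity, D the harmonic mean fiber diameter, and V = A·2r0 the
slab unit cell. The integral is evaluated by adaptive Gauss–Legendre
quadrature split at the clamp boundaries; an independent discrete-fiber
Monte-Carlo simulator (`simulate_tension()`) reproduces the same numbers by
brute-force summation and serves as the cross-check oracle throughout the
test suite.

## Worked example

```r
library(nanomech)

tab <- sfpcl_fiber_params()                    # built-in single-fiber fits
params <- fiber_law(tab$a[1], tab$b[1], tab$c[1])   # SF/PCL = 100/0
spec <- membrane_spec(porosity = 0.8, r0_nm = 1000, area_nm2 = 1e6,
                      shrinkage_v = 0.9, harmonic_d_nm = 79.49)

predict_stress_strain(spec, params, seq(0, 0.5, by = 0.1))
#> <ss_curve> 6 points, strain [0, 0.5], stress [0, 3.05669] MPa
#>   strain stress_mpa
#> 1    0.0   0.000000
#> 2    0.1   1.673948
#> 3    0.2   2.238409
#> 4    0.3   2.589841
#> 5    0.4   2.849043
#> 6    0.5   3.056686
```

The curve starts at zero (at ε = 0 every fiber is unloaded or buckled),
rises steeply as fibers engage and reorient toward the load axis, and
hardens logarithmically — about 2.6 MPa at 30 % strain for the pure-silk
membrane at 80 % porosity. Against the Monte-Carlo oracle with 10⁵ discrete
fibers (seed 42) the analytic value at ε = 0.3 is 2.5898 MPa versus a
simulated 2.5966 ± 0.0060 MPa — agreement within 1.2 standard errors.

A command-line surface wraps the same functions:

```sh
exec/nanomech fit      --input curve.csv --out params.txt
exec/nanomech stats    --input diameters.csv
exec/nanomech predict  --config run.yaml --out pred.csv
exec/nanomech simulate --config run.yaml --n-fibers 100000 --seed 7 --out sim.csv
exec/nanomech compare  --config run.yaml --measured membrane.csv --out resid.csv
```

See `vignettes/membrane-micromechanics.Rmd` for the model's assumptions,
conventions (shrinkage, clamping, unit cell) and numerical choices.

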