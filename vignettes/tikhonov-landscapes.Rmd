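---
title: "Tikhonov-regularized landscapes: model, calibration and flux upscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tikhonov-regularized landscapes: model, calibration and flux upscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscape)
```

## The downscaling problem

A coarse remote-sensing pixel — say a 250 m vegetation-index pixel over
subarctic tundra — reports a single mean value for a surface that is in
reality patterned at the scale of individual vegetation patches (a few
meters).  Knowing only the mean, the least-committal reconstruction of the
subgrid is a constant field; knowing only physical bounds, it is an
independent uniform draw.  The truth lies between: neighboring patches are
similar, so the hidden fine-scale field is spatially autocorrelated.
Because leaf area index (LAI) is an exponential function of NDVI, and gross
primary productivity (GPP) a concave function of LAI, any nonlinearity makes
the spatial *distribution* of NDVI matter for landscape carbon flux, not just
its mean (Jensen's inequality).  `trscape` generates random subgrid NDVI
fields consistent with a coarse pixel's mean and variance, with a tunable and
calibratable degree of spatial smoothness, and carries them through to
landscape GPP.

## The generator

Let $\alpha$ be a vector of $N = n_r n_c$ independent draws from
$U(\text{min}, \text{max})$ (default $U(0,1)$, the plausible NDVI range of a
terrestrial surface), arranged on the pixel lattice.  Let $B$ be the sparse
first-difference operator whose rows encode every cardinal neighbor pair with
coefficients $+1,-1$ (free, non-periodic boundaries: only interior pairs, no
wraparound).  The smoothed draw is

$$ s = (I + \gamma\, B^{\mathsf T} B)^{-1} \alpha , $$

a Tikhonov-regularized compromise between the raw draw ($\gamma = 0$) and a
constant surface at the draw mean ($\gamma \to \infty$).  In this package the
multiplier $\gamma$ weights the squared-first-difference penalty
*linearly*; readers used to writing the penalty as $\gamma^2\|B x\|^2$ should
read our $\gamma$ as that squared weight.  We fixed this convention once,
because it is the parameterization under which the package's published-style
range statistics (semivariogram range as a function of $\gamma$, see below)
behave as a generalized logistic in $\log_{10}\gamma$ across the range
$\gamma \in [10^{-1}, 10^2]$, with the decade values producing distinctly
banded smoothness classes.

The output field is then renormalized exactly:

$$ \alpha' = \sqrt{\sigma^2_\star / \Psi}\,\bigl(s - \bar s\bigr) + \mu_\star ,$$

where $\bar s$ and $\Psi$ are the *empirical* mean and population variance
(divisor $N$) of the smoothed draw and $\mu_\star, \sigma^2_\star$ are the
coarse pixel's targets.  Every realization therefore has sample mean
$\mu_\star$ and population variance $\sigma^2_\star$ to machine precision —
a per-realization normalization, chosen over an ensemble-expectation scaling
so that single fields, not just ensembles, honor the coarse-pixel
constraint.  $\Psi$ can only vanish for a degenerate draw or smoothing to
exact constancy at machine precision; this is detected and reported rather
than producing a division by zero.  Values are *not* clipped to the draw
bounds by default, since clipping would destroy the exact normalization; at
the default tundra parameterization ($\mu_\star = 0.54$,
$\sigma^2_\star = 0.009$, i.e. $\sigma_\star \approx 0.095$) excursions
beyond $[0,1]$ are rare, and a `clip` flag exists for users who need hard
bounds.

The matrix $I + \gamma B^{\mathsf T}B$ is symmetric positive definite and
pentadiagonal-sparse; we store a sparse Cholesky factorization once per
$(\text{grid}, \gamma)$ and reuse it across draws, so ensembles of hundreds
of fields cost one factorization plus cheap solves.  The operator leaves
constants unchanged (its row sums are one, because $B$ annihilates
constants) and reduces to the identity at $\gamma = 0$; both properties are
verified against a literal dense inverse in the test suite.

Defaults: a $62 \times 62$ grid of 4 m pixels (the nearest integer grid to a
250 m coarse pixel at 4 m resolution; the slight shortfall to 248 m is
immaterial since domain size does not enter the model), $\mu_\star = 0.54$,
$\sigma^2_\star = 0.009$ — a measured tundra parameterization.  First
differences are taken between adjacent pixels in index units; the pixel size
(m) enters only when lags, ranges and frequencies are expressed in meters.

## Spatial statistics and the $\gamma \leftrightarrow$ range calibration

$\gamma$ is not itself observable; the semivariogram range is.  The package
therefore characterizes fields with the classical isotropic Matheron
estimator,

$$ \hat\gamma(h) = \frac{1}{2 N(h)} \sum_{\|x_i - x_j\| \in \text{bin}(h)}
   (z_i - z_j)^2 , $$

computed exactly over all pixel pairs (enumerating lattice offsets, which is
equivalent to the brute-force double loop the tests compare against), with
bins one pixel wide and a default maximum lag of half the longer grid side.
A spherical model
$\gamma(h) = c_0 + c\,(1.5 h/a - 0.5 (h/a)^3)$ for $h \le a$, $c_0 + c$
beyond, is fit by bounded nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`), parameters non-negative.

Three fitting choices deserve explanation, because the fit is where naive
protocols fail:

* **Weights $N(h)/h$.**  Pure pair-count weights overweight the long-lag
  bins (which hold most pairs); on weakly structured fields a tiny-sill,
  enormous-range component can then chase slow trends in the flat region of
  the variogram and the fitted range diverges.  The classical
  $N(h)/h^2$ weighting over-corrects the other way, shrinking genuinely
  long ranges.  Damping pair counts by one power of the lag resolves both
  regimes with a single protocol.
* **Range bounded at twice the maximum lag** (the domain side under the
  default max lag).  Beyond that, neither range nor sill is identifiable
  from data; without the bound both inflate together.
* **A fit whose range lands on that bound is flagged unidentifiable** and
  excluded from ensemble statistics, exactly as flat-variogram fits are.
  Ensemble summaries report how many fits were dropped; losing more than
  half an ensemble triggers a warning.

Several range starting values (including the first lag reaching 95% of the
apparent sill) are tried and the best weighted fit kept, with ties and
convergence assessed on the weighted residual sum of squares.

For calibration, `build_calibration_curve()` sweeps a grid of
$\log_{10}\gamma$ (default $-1$ to $2$ in half-decade steps), generates an
ensemble per point (default 100 fields), fits spherical models, and records
the mean and standard deviation of the fitted range.  A five-parameter
generalized logistic (Richards) curve
$R(x) = A + (K - A)\,(1 + e^{-g (x - m)})^{-1/\nu}$ is fit to the mean
ranges against $x=\log_{10}\gamma$ — mean ranges rather than pooled
per-field ranges, so each grid point contributes equally regardless of how
many individual fits survived — falling back to $\nu = 1$ if the full form
is ill-conditioned.  `calibrate_gamma()` inverts the curve in closed form,
refusing targets outside the asymptote interval $(A, K)$ and reporting the
achievable interval in the error.  The curve is monotone by construction
($g > 0$), so larger target ranges always return larger $\gamma$.

The radially averaged power spectrum complements the variogram: the field is
mean-centered, transformed with the 2D FFT, and squared magnitudes are
summed in annular bins one fundamental frequency wide, scaled so the total
over nonzero frequencies equals the field's population variance (a discrete
Parseval convention).  No taper window is applied by default; the generated
fields are not strongly anisotropic and the spectra are used comparatively.

## From NDVI to landscape carbon flux

LAI follows the exponential tundra transfer
$\mathrm{LAI} = 0.00067\, e^{9.237\,\mathrm{NDVI}}$ (m² leaf per m² ground).
The transfer is applied to NDVI values as generated, including rare
excursions outside $[0,1]$ — it is defined for all reals, and clamping would
bias the field statistics the generator guarantees.

The instantaneous canopy uptake rate is the aggregated light-response model
(PLIRTLE),

$$ \mathrm{GPP} = \frac{P_{\max}}{k}\,
   \ln\!\left( \frac{P_{\max} + E_0\,\mathrm{PPFD}}
   {P_{\max} + E_0\,\mathrm{PPFD}\, e^{-k\,\mathrm{LAI}}} \right) , $$

with the pan-arctic parameter set $P_{\max} = 15.831$ µmol m⁻² leaf s⁻¹,
$E_0 = 0.036$ µmol CO₂ per µmol photons, $k = 0.5$ (Beer's-law extinction).
Micrometeorological convention writes uptake as a negative flux; the package
returns the non-negative uptake magnitude and leaves sign conventions to the
caller.  The rate is zero at zero LAI or zero PPFD, monotone in both, and
concave and bounded in PPFD by the dense-canopy closed form — properties the
test suite asserts directly.

Seasonal totals hold each pixel's LAI fixed (one NDVI map, no phenology) and
accumulate a left-Riemann sum of the rate over a PPFD series at its native
timestep (default 1800 s, the usual flux-tower half-hour), times pixel area
and 12.011 × 10⁻⁶ g C per µmol CO₂.  Landscape totals are reported in kg C.
Because no spatial interaction enters the rate, totals are invariant under
pixel permutation; `jensen_comparison()` exposes the difference between
per-pixel aggregation and the flux of the mean-NDVI landscape, which is the
quantitative motivation for subgrid simulation.

The bundled forcing generator synthesizes a subarctic growing season as a
truncated half-sine of PPFD per day: defaults of 61 days, 20 h daylight and
an 800 µmol m⁻² s⁻¹ solar-noon peak sketch high-latitude June–July light.
It emulates the diurnal cycle and day count only — no weather, no cloud
variability (unless Gaussian noise is requested), no temperature.  It is a
synthetic stand-in: seasonal totals driven by it are internally comparable
across scenarios but are not comparable to totals driven by observed
meteorology, and the tests make claims only about arithmetic and invariances
of the integration, never about absolute flux realism.

## Vegetation patch edges

Field studies in tundra report GPP per unit LAI some 20–40% lower in the
transition zones (ecotones) between vegetation patches than at patch
centers, with edges covering roughly 30% of the landscape.  The package
implements four ways to designate edge pixels on an NDVI map:

1. **Near-mean quota** — rank by $|z - \bar z|$ ascending, take the first
   $\lfloor 0.3 N \rfloor$;
2. **Steep-slope quota** — rank by gradient magnitude descending (central
   differences, one-sided at borders, per meter);
3. **Curvature quota** — rank by the gradient magnitude *of* the slope
   field, descending.  "Rate of change of slope" admits several operators
   (second directional derivative, Laplacian); we chose the gradient of the
   gradient magnitude as the most direct reading and note that the choice
   moves which pixels rank highest;
4. **Class boundary** — clamp to $[0,1]$, round to the nearest integer (0.5
   rounds up) to form a binary patch map, and mark every pixel with at
   least one 4-connected neighbor of the opposite class, on both sides of
   the boundary.  The edge fraction here is emergent, not a quota.

Quota selections break ties by row-major pixel index, so all masks are
deterministic.  `apply_edge_reduction()` multiplies edge-pixel GPP by 0.7
(the mean of the reported 20–40% reduction; per-edge-type factors are out of
scope) and recomputes totals.  The identity
$1 - \text{total}_{\text{after}}/\text{total}_{\text{before}}
 = 0.3 \times (\text{edge share of GPP})$
makes the benchmark arithmetic transparent: a *random* 30% edge removes
exactly 9% of the landscape total, while gradient-based masks (methods 2–3)
concentrate on productive high-contrast pixels and remove more.

## Reproducibility and problem sizes

Everything stochastic flows from explicit seeds: `field_spec()` carries one,
the pipeline expands a single global seed into per-stage seeds and echoes
them in its JSON report, and identical configuration plus seed reproduces
every raster and report byte for byte.  The test suite exercises ensembles
of 100 fields at the default $62 \times 62$ study conditions for the
range-statistics checks (a few minutes of CPU), and 8–20 field ensembles on
the same or smaller grids for property checks; dense-oracle comparisons are
confined to grids of at most $8\times 8$ where a literal matrix inverse is
exact and cheap.

## Known limitations

* The generator reproduces a *single* dominant mode of spatial variability
  per $\gamma$; real landscapes mix structure at several scales, and a
  one-$\gamma$ field cannot capture a multi-modal power spectrum.
  Composite multi-$\gamma$ landscapes are deliberately out of scope.
* The smoothness prior is isotropic and first-order; anisotropy and
  higher-order penalties are not implemented.
* Only the uniform prior draw is exercised; the machinery admits other
  distributions, but the normalization guarantees are only tested for it.
* Absolute seasonal GPP totals depend on the forcing; with the synthetic
  half-sine forcing they characterize scenario *differences*, not site
  carbon budgets.
* Raster I/O is deliberately minimal (ESRI ASCII and headerless CSV, pixel
  size but no coordinate reference system); georeferenced workflows should
  wrap the package with a proper GIS raster library.
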