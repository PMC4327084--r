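---
title: "Designing a homogeneous heating zone for a transcutaneous oxygen-sensor matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a homogeneous heating zone for a transcutaneous oxygen-sensor matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofield)
```

## The problem

Transcutaneous oximetry measures the partial pressure of oxygen through
intact skin with an amperometric (Clark-type) cell. The method only works
if the skin under the sensor is heated to roughly 42-44 °C, which
vasodilates the capillary bed and opens a "diffusion corridor" for oxygen
toward the cathode. A *multichannel* sensor matrix — dozens of cells on a
square touchpad — adds a constraint a single sensor does not have: every
cell must sit at the same temperature, because a 1 °C difference changes
the measured signal by several percent and, at the high end, risks thermal
injury to thin (e.g. neonatal) skin.

A single square resistive heater cannot deliver that: driven between
electrodes on two opposite sides it produces a uniform volumetric heat
density, but the resulting *surface temperature* peaks at the center and
falls off toward the edges. The design studied here compensates with a
second, ring-shaped wire heater of the same diameter as the square side,
suspended just above the surface: the ring's field is *minimal* at its
center, so a suitably weighted superposition flattens the central zone.

## The model

Both media in contact with the heater plane are treated as homogeneous
half-spaces: air (thermal conductivity $\kappa_e$) above, biological
tissue ($\kappa_i$) below. For stationary conduction, a point source of
power $P$ at the interface produces the temperature increase

$$\delta T(R) = \frac{P}{2\pi(\kappa_e + \kappa_i)\,R},$$

i.e. the free-space Green's function with $\kappa$ replaced by the *sum*
of the two conductivities — only $\kappa_e + \kappa_i$ ever enters, so
swapping the media changes nothing. All fields below are superpositions of
this kernel; no PDE is solved numerically.

Working in units of the square side $a$ and splitting the temperature as
$T = T_0 + \delta T$, the two sources contribute

$$\delta T_1(x,y,z) = t_1 \int_{-1/2}^{1/2}\!\!\int_{-1/2}^{1/2}
  \frac{d\xi\, d\eta}{\sqrt{(x-\xi)^2 + (y-\eta)^2 + z^2}},
  \qquad t_1 = \frac{Q_1 d\, a}{2\pi(\kappa_e+\kappa_i)},$$

$$\delta T_2(x,y,z) = t_2 \int_0^{\pi}
  \frac{d\varphi}{\sqrt{1 + (2r)^2 - 4r\cos\varphi + 4(z-z_0)^2}},
  \qquad t_2 = \frac{Q_2 S}{\pi(\kappa_e+\kappa_i)},$$

where $Q_1 = U_1^2/(a^2\rho)$ is the Joule heat density of the square
layer (thickness $d$, resistivity $\rho$, drive voltage $U_1$),
$Q_2 = U_2^2/(\pi R_{tot} a S)$ that of the ring wire (cross-section $S$,
total resistance $R_{tot}$), $r = \sqrt{x^2+y^2}$ and $z_0$ is the ring
standoff. The scale temperatures $t_1, t_2$ (°C) are the *canonical
interface* of the package: electrical parameters only ever enter through
them (`thermal_scale_t1()`, `thermal_scale_t2()`), and every field
function takes `thermal_scales(t1, t2)` directly. This is deliberate — the
flatness of the heated zone depends only on the ratio $t_2/t_1$ and on
$z_0/a$, not on how those scales were realized electrically.

On the surface ($z = 0$) both integrals collapse to closed forms:

* the square integral is the classical uniform-sheet potential, a
  four-corner difference of $H(X,Y) = X\ln(Y+R) + Y\ln(X+R)$ with
  $R = \sqrt{X^2+Y^2}$ (`square_shape_surface()`); its center value is
  $4\ln(1+\sqrt 2) \approx 3.5255$;
* the ring integral reduces exactly to
  $\frac{2}{1+u}\,K\!\left(\frac{2\sqrt u}{1+u}\right)$ with $u = 2r$,
  $K$ the complete elliptic integral of the first kind
  (`ring_shape_surface()`); its center value is exactly $\pi$, and it
  diverges logarithmically at the wire $u \to 1$.

A variant of the ring surface form circulates with a bare $4\,K(2r)$
prefactor; under the standard modulus convention
$K(k) = \int_0^{\pi/2} d\theta/\sqrt{1-k^2\sin^2\theta}$ that expression
contradicts the defining angular integral already at the center ($2\pi$
instead of $\pi$). Printed closed forms drift in transcription; defining
integrals do not. The package therefore treats the *integrals* as
authoritative on both kernels, re-derives the closed forms, and accepts
them only because the test suite holds them to $10^{-8}$ relative
agreement against adaptive quadrature and against independent brute-force
summation oracles.

## Numerical choices

* **Square quadrature.** `square_shape_quadrature()` nests two adaptive
  Gauss–Kronrod integrations, splitting both ranges at the field point.
  For on-sheet surface points the integrand has an integrable $1/R$
  singularity; the splitting puts the singular line on panel endpoints,
  which the Kronrod rule never samples. Default relative tolerance
  `1e-9`, inner integral solved 100× tighter.
* **Corner degeneracy.** Exactly at the four sheet corners
  $(\pm\tfrac12, \pm\tfrac12)$ the closed form is a $0\cdot\infty$ limit;
  the field itself is finite there ($2\ln(1+\sqrt2)$). The kernel raises a
  degenerate-point error (offset by $10^{-12}$ if you need the limit);
  `total_surface_field()` patches such grid nodes via the quadrature
  route, so the default grid over $[-1,1]^2$ — which contains them — just
  works. Near-corner evaluations are kept stable by rewriting
  $\ln(Y+R)$ as $2\ln|X| - \ln(R-Y)$ when $Y < 0$.
* **Elliptic integral.** $K(k)$ is computed by the arithmetic–geometric
  mean, which converges quadratically to machine precision; no external
  special-function library is needed.
* **Wire singularity.** The ideal line source diverges like
  $-\ln\varepsilon$ on approach to the wire. A guard band
  ($|r - \tfrac12| < 10^{-6}$ *and* $|z - z_0| < 10^{-6}$, units of $a$)
  raises a singular-point error rather than returning a huge number, and
  grid construction reports the offending node.
* **Ring standoff default.** When only a surface map is requested the
  standoff defaults to $z_0/a = 0.02$ — small enough for the near-surface
  regime ($z_0 \ll a$) the model assumes, large enough that grid nodes at
  radius exactly $\tfrac12$ remain finite. It is a parameter everywhere;
  analytic anchor tests use $z_0 = 0$ at points safely inside the ring.
* **Isotherms.** `extract_isotherms()` delegates to base R's
  `contourLines()` (marching squares with linear edge interpolation and
  internal saddle disambiguation) behind a stable interface; fidelity is
  enforced by tests (pure-ring isotherms are circles to < 1% radius
  dispersion; vertices re-interpolate to their level within $10^{-6}$ of
  the field range).

## Quantifying "homogeneous"

"Almost homogeneous central zone" is made operational in two ways:

* `homogeneity_report()` measures, over a probe disc of radius
  $0.2a$ (default; the sensing zone), the maximum absolute deviation from
  the exact center value and the fraction of the zone within a tolerance
  `epsilon` (default 0.1 °C). Deviations are always measured against the
  exact center evaluation, not a nearest grid cell.
* `flatten_ratio()` optimizes the ring-to-square balance
  $\beta = t_2/t_1$ by minimizing the *worst-case* deviation over the
  probe disc (min–max, not variance: the engineering requirement is that
  no sensor cell exceeds a tolerance). The objective is unimodal here —
  the square field's negative central curvature is cancelled by the ring
  field's positive one — but a coarse scan still guards against multiple
  minima and flags them.

For the reference scenario bundled as `inst/extdata/reference_scales.json`
($t_1 = 0.65$ °C, $t_2 = 0.5$ °C), the package computes a center increase
of $0.65\cdot 4\ln(1+\sqrt2) + 0.5\pi \approx 3.862$ °C, an axis profile
flat to well under 5% of the center value over $|x| \le 0.2a$, and a
combined field whose worst deviation over the probe disc is an order of
magnitude smaller than either single source normalized to the same center
temperature. The min–max-optimal balance at probe radius $0.2a$ is
$\beta^\* \approx 0.85$; the reference choice $0.5/0.65 \approx 0.77$ is
not optimal under this objective (its worst-case deviation is about 5×
the optimum) but both stay below 0.01 °C — far inside any practical
thermostat tolerance, which is the design claim that matters. None of
these numbers is asserted here; all are computed by the test suite.

## The synthetic parameter generator

`fixture_cases()` draws random but physically valid parameter sets for
property tests: air-like $\kappa_e \in [0.02, 0.03]$, soft-tissue
$\kappa_i \in [0.2, 0.6]$ W m⁻¹ K⁻¹, centimetre-scale heaters
($a \in [1, 5]$ cm), layer thickness and ring standoff drawn as *ratios*
so the thin-layer ($d/a < 0.1$) and near-surface ($z_0/a < 0.1$) regimes
hold by construction, and bench-scale voltages and resistances. The
generator emulates parameter diversity, not data: the model is
deterministic, and the physics code contains no randomness at all. A
green property test therefore establishes algebraic invariants
(voltage-squared scaling, conductivity-sum dependence, power
conservation) across the realistic parameter range — it says nothing
about perfused, layered, anisotropic real skin, which the two-half-space
model idealizes away.

## Known limitations

* Stationary fields only; warm-up transients are out of scope.
* The ring is an ideal line source: fields within a few wire radii of the
  conductor are unphysical (logarithmic divergence), and finite wire
  thickness would cap them.
* Uniform current in the square layer (perfect electrodes, no contact
  resistance, temperature-independent resistivity).
* The touchpad and sensor hardware above the heater perturb the real
  field; the model addresses the bare heater design only.
* Physiology (perfusion, hyperemia, oxygen diffusion) is outside the
  model: $T_0$ and the 42–44 °C target enter only as reporting offsets.
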