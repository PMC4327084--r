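# thermofield

Stationary thermal-field modelling for the heater of a multichannel
transcutaneous oxygen-sensor matrix.

Transcutaneous oximetry needs the skin under the sensor heated to about
42–44 °C; a sensor *matrix* additionally needs that temperature to be the
same under every cell. `thermofield` models the design that achieves this:
a square resistive sheet heater (surface field maximal at the center,
falling toward the edges) combined with an O-ring wire heater of the same
diameter (surface field minimal at the center, rising toward the wire) at
the interface between two semi-infinite media, air above and tissue below.
A weighted superposition of the two flattens the central sensing zone.

## The model

For stationary conduction, a point source at the interface of half-spaces
with conductivities κ_e (air) and κ_i (tissue) heats the surface as
P / (2π(κ_e+κ_i)R). In units of the square side *a*, the two sources give

* square sheet: δT₁ = t₁ ∬ dξ dη / √((x−ξ)² + (y−η)² + z²) over [−½,½]²,
  with scale t₁ = Q₁ d a / (2π(κ_e+κ_i)), Q₁ = U²/(a²ρ);
  on the surface this is the classical sheet potential
  (center value 4 ln(1+√2) ≈ 3.5255);
* ring wire: δT₂ = t₂ ∫₀^π dφ / √(1 + (2r)² − 4r cosφ + 4(z−z₀)²),
  with scale t₂ = Q₂ S / (π(κ_e+κ_i)), Q₂ = U²/(πR a S);
  on the ring plane this reduces exactly to (2/(1+u)) K(2√u/(1+u)),
  u = 2r, K the complete elliptic integral of the first kind
  (center value π, logarithmic divergence at the wire r = a/2).

Everything downstream — grids, isotherms, homogeneity metrics, the min–max
heater-balance optimizer — consumes only the scale temperatures (t₁, t₂)
and the ring standoff z₀/a. See `vignettes/heater-field-design.Rmd` for
the assumptions, numerical choices and limitations.

## Worked example

The bundled reference scenario (`inst/extdata/reference_scales.json`) uses
t₁ = 0.65 °C, t₂ = 0.5 °C over a baseline T₀ = 39 °C:

```r
library(thermofield)
sc <- thermal_scales(t1 = 0.65, t2 = 0.5, T0 = 39)

axis_profile(sc, z0a = 0, s_values = c(0, 0.1, 0.2, 0.3, 0.4))
#>     s     dT1     dT2 dT_total
#> 1 0.0 2.29157 1.57080  3.86237
#> 2 0.1 2.27298 1.58687  3.85985
#> 3 0.2 2.21465 1.64000  3.85465
#> 4 0.3 2.10739 1.75075  3.85815
#> 5 0.4 1.92805 1.99530  3.92336
```

The square contribution falls with distance from the center while the ring
contribution rises, and their sum is flat: the total increase stays within
0.008 °C of its center value 3.86237 °C over the whole sensing disc
r ≤ 0.2a (absolute surface temperature T₀ + δT ≈ 42.9 °C):

```r
f <- function(x, y) 0.65 * square_shape_surface(x, y) +
  0.5 * ring_shape_surface(sqrt(x^2 + y^2))
homogeneity_report(f, probe_radius = 0.2, epsilon = 0.1)
#> Homogeneity over disc r <= 0.2 a:
#>   center dT        = 3.86237 degC
#>   max |deviation|  = 0.00772211 degC
#>   within +/- 0.1 degC: 100.0% of probed area

flatten_ratio(z0a = 0.02, probe_radius = 0.2)
#> Heater balance (probe disc r <= 0.2 a, z0a = 0.02):
#>   optimal t2/t1      = 0.848968
#>   max deviation / t1 = 0.00256033
```

The optimizer's min–max-optimal balance t₂/t₁ ≈ 0.85 flattens the zone a
further ~5× relative to the 0.5/0.65 reference choice.

## Command line

```sh
Rscript inst/scripts/thermofield-cli.R simulate \
    --config inst/extdata/reference_scales.json --out-dir out
# -> out/grid_long.csv, grid_matrix.csv, isotherms.csv,
#    homogeneity.json, run.log
Rscript inst/scripts/thermofield-cli.R profile  --config cfg.json --out p.csv
Rscript inst/scripts/thermofield-cli.R design   --z0a 0.02 --out design.json
Rscript inst/scripts/thermofield-cli.R fixtures --seed 7 --n 10 --out f.csv
```

Configs are flat JSON, either electrical (`kappa_e`, `kappa_i`,
`square.{a,d,rho,U}`, `ring.{z0,S,R,U}`) or direct scales
(`scales.{T0,t1,t2}` plus optional `z0a`); dotted CLI flags such as
`--scales.t2 0` override config values. Validation failures exit with
status 2 and name the offending key.

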