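# leadheat

Modelling of RF-induced heating at the tip of an insulated, implanted
lead during MRI, and prediction of the **resonant length** — the lead
length at which tip heating is maximal.

## Who this is for

MR-safety physicists and device engineers who need to estimate how lead
tip temperature rise depends on lead length, wire geometry and the
surrounding tissue, e.g. when assessing abandoned (capped) leads or
choosing insulation parameters. The package reproduces, in R, the kind
of calculation done with insulated antenna theory plus transfer-function
models of the lead, and adds fitting/model-comparison tools for bench
temperature measurements in an ASTM-style gel phantom.

## The model

The lead-tip voltage is the weighted line integral of the tangential
incident electric field along the lead,

    V = ∫₀ᵈ h(l) · E_t(l) dl ,        ΔT ∝ |V|² ,

with `l` the arc length from the lead tip and `h(l)` a complex transfer
function. Two families are implemented:

- **SEM** (simple exponential model): `h(l) = e^(−ikl)`
- **TLM** (transmission line model):
  `h(l) = e^(−ikl) (1 − Γe^(−2ik(d−l))) / (1 − Γe^(−2ikd))`,
  with reflection coefficient `Γ` at the capped (IPG) end; `Γ = 1` is an
  electrically open end and `Γ = 0` recovers the SEM.

The wavenumber `k = k_R + i·k_I` (convention `k_R ≥ 0`, `k_I ≤ 0`) can
be that of the embedding medium, `k_t = ω√(μ(ϵ + iσ/ω))`, or — much more
accurately for insulated wires — the **King wavenumber** from insulated
antenna theory,

    k = k_i √(1 + F(k_t b)/ln(b/a)) ,   F(z) = H₀⁽¹⁾(z) / (z·H₁⁽¹⁾(z)) ,

with `a`, `b` the conductor and insulation radii and `k_i` the insulator
wavenumber. For a constant field both models have closed-form `V(d)` and
`ΔT(d)`, and the resonant length reduces to `d_res = (λ/2)·g(u)` where
`u = −k_I/k_R` and `g(u) ∈ [½, 1]` solves a transcendental equation —
i.e. resonance always falls between a quarter and half wavelength in the
conductor. For general `Γ` the closed-form `ΔT(d)` is maximised
numerically. Model curves are fitted to measured `ΔT` data (after
transmit-gain correction, `ΔT_c = ΔT·10^((TG−TG_ref)/100)`) by a
closed-form least-squares scale, with `Γ` profiled over [0, 1] when
free, and compared by RMSE and OLS-form AIC.

## Worked example

Bench wire (a = 0.390 mm, b = 0.625 mm, insulation ϵᵣ = 2.3) in ASTM gel
(ϵᵣ = 80, σ = 0.47 S/m):

```r
library(leadheat)

f   <- larmor_frequency(1.5)                       # 63.87 MHz
gel <- material_properties(80, 0.47)
geo <- wire_geometry(0.390e-3, 0.625e-3, 2.3)
kt  <- medium_wavenumber(gel, f)
k   <- king_wavenumber(insulator_wavenumber(2.3, f), kt, geo)
k
#> <wavenumber> (6.7454 -0.6840i) rad/m  [u = 0.1014, lambda = 0.9315 m]

100 * resonant_length(transfer_model("sem", k))          # 43.96761 cm
100 * resonant_length(transfer_model("tlm", k, 1))       # 46.11498 cm
100 * resonant_length(transfer_model("tlm", k, 0.2759))  # 45.4004 cm
```

So at 1.5 T the insulated-conductor wavenumber puts resonance near
44–46 cm — far from the ~26 cm suggested by the bare gel wavenumber,
which is the practical point: the insulation moves the resonant length a
lot. The same pipeline at 3 T gives 22.7–24.0 cm.

Fitting synthetic measurements (15 wires, 5% noise, transmit-gain
spread) and ranking models by AIC:

```r
gen  <- transfer_model("tlm", k, gamma = 0.25)
data <- synthetic_measurements(gen, 50, seq(0.05, 0.5, length.out = 15),
                               noise_sd = 1, tg_spread = 2, seed = 1)
print(fit_models(data, k, tg_ref = 120), digits = 4)
#>      model  gamma  scale rmse_C    aic n_free_params d_res_m
#> 1      tlm 0.1629 57.803  1.137  9.851             2  0.4515
#> 2      sem     NA 72.182  1.344 12.864             1  0.4397
#> 3 tlm_open 1.0000  8.802  2.167 27.205             1  0.4611
```

The free-`Γ` transmission line model wins the AIC comparison and its
fitted reflection coefficient sits near the generating value (any single
noisy draw scatters around Γ = 0.25; across 100 seeded replicates the
median recovery error is about 0.02).

A command-line interface is installed at `exec/leadheat`
(`wavenumber | resonant-length | curve | fit | sweep`); see
`Rscript exec/leadheat help` and the vignette.

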