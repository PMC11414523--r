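---
title: "Modelling lead-tip RF heating and resonant length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lead-tip RF heating and resonant length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadheat)
```

## The physical problem

An implanted (or abandoned) device lead acts as a receiving antenna for
the electric field of the MRI body transmit coil. Current induced along
the wire exits into tissue at the exposed lead tip, and the local power
deposition — quadratic in the induced tip voltage — heats the tissue.
The heating depends strongly on lead length: at the *resonant length*
the standing current wave along the lead is maximally excited and tip
heating peaks. Predicting that length, and the shape of the
temperature-rise-versus-length curve, is the purpose of this package.

## Model and assumptions

The tip voltage is modelled as the transfer-function-weighted line
integral of the tangential incident field,
$V = \int_0^d h(l)\,E_t(l)\,dl$, with $l$ arc length from the tip and
$\Delta T \propto |V|^2$. The assumptions inherited from this framework:

- the incident field is evaluated along the *unperturbed* wire path
  (the wire's own scattered field is folded into $h$);
- heating is Ohmic at the tip; thermal diffusion and perfusion are not
  modelled, so $\Delta T$ is relative (one overall scale per data set);
- the wire is straight or gently curved, thin, and fully insulated
  except at the tip; helical leads and loops are out of scope.

Two transfer functions are provided. The simple exponential model (SEM)
$h(l) = e^{-ikl}$ captures resonance and loss with a single complex
wavenumber. The transmission line model (TLM) adds a reflection
coefficient $\Gamma$ at the capped proximal (IPG) end,
$h(l) = e^{-ikl}\,(1-\Gamma e^{-2ik(d-l)})/(1-\Gamma e^{-2ikd})$,
normalised so $h(0)=1$; $\Gamma=1$ is an electrically open cap and
$\Gamma=0$ recovers the SEM. For a constant field both models integrate
in closed form; `delta_T_tlm()` evaluates the TLM $\Delta T$ entirely in
real arithmetic via the factorisation
$|V|^2 \propto (1+A^2-2Ac)(1+\Gamma^2A^2-2\Gamma Ac)/(1+\Gamma^2A^4-2\Gamma A^2\cos 2k_Rd)$
with $A = e^{k_I d}$, $c = \cos k_R d$, which the test suite verifies
against $|$closed-form $V|^2$ as an independent route.

### Wavenumbers and sign conventions

Every wavenumber is stored with $k_R \ge 0$ and $k_I \le 0$, so
$e^{-ikl}$ decays: losses, not gains. The insulated-conductor
(King) wavenumber from insulated antenna theory,
$k = k_i\sqrt{1 + F(k_t b)/\ln(b/a)}$, is the recommended choice; the
original antenna-theory derivation uses the opposite sign for the
imaginary part, so the embedding-medium wavenumber is conjugated *only*
inside the Hankel-function argument and the principal square root (with
$\mathrm{Re} \ge 0$, imaginary part then forced negative) is taken at
the end. The theory assumes a conductive embedding medium; a lossless
medium is accepted with a warning since the expression stays evaluable.

Base R's Bessel functions are real-only, so `hankel_h1()` implements
$H_0^{(1)}, H_1^{(1)}$ for complex argument by the ascending series.
For insulated wires in tissue $|k_t b| \ll 1$ (about 0.017 for the
default geometry at 3 T), deep inside the series' comfortable range;
arguments with $|z| > 10$ are refused rather than returned inaccurately.
The implementation is pinned in the tests to 30-digit multiple-precision
reference values at machine precision.

The Larmor constant is fixed at 42.58 MHz/T; any frequency can be passed
explicitly instead. Fixed physical constants
($\epsilon_0 = 8.8541878128\times 10^{-12}$ F/m,
$\mu_0 = 4\pi\times 10^{-7}$ H/m) make the printed-value regression
tests bit-reproducible.

## Resonant length

With $u = -k_I/k_R$ and $g = k_R d/\pi$, stationarity of the closed-form
$\Delta T(d)$ gives
$-u e^{-\pi u g} + u\cos\pi g + \sin\pi g = 0$ for the SEM and
$\tan\pi g + u\tanh\pi u g = 0$ for the TLM with $\Gamma = 1$; the
smallest positive root lies in $[\tfrac12, 1]$, i.e. resonance between a
quarter and half wavelength. Roots are found by bracketed bisection
(`uniroot`) on $g \in (\tfrac12, 1]$ — the proven bounds, which excludes
the spurious root at $g = 0$ — with tolerance $10^{-13}$; returned roots
satisfy their equations to better than $10^{-10}$. `u = 0` returns 1
exactly; `u > 10^6` returns the asymptotic $\tfrac12$ rather than
chasing a root wedged against the bracket.

For general $\Gamma$ no comparably simple equation exists, and
`resonant_length()` maximises the closed-form $\Delta T$ on a 0.5 mm
grid over $(0, \lambda]$ (resonances of interest stay below
$\lambda/2$; the range is overridable) followed by golden-section
refinement. The test suite cross-checks the analytic branch against
brute-force maximisation on a 0.01 mm grid for randomly drawn
wavenumbers.

## Numerical line integral

For spatially varying fields, `numerical_voltage()` applies the midpoint
rule per path segment, subdividing segments longer than 1 mm (default).
The rule is first-order-or-better against the constant-field closed
forms as the step halves. Fields are complex 3-vectors on a regular
grid, interpolated trilinearly per component with no extrapolation —
affine fields are reproduced exactly, which the tests exploit as the
interpolation oracle. Arc length is measured from the lead tip (the
first path point); the transmission-line weight can also be evaluated in
its IPG-referenced form, which must and does give the same $|V|$ for
symmetric fields.

Degenerate inputs have analytic limits rather than 0/0 evaluations: the
$k = 0$ (unity transfer function) case returns $V = Ed$, and $d = 0$
returns $V = 0$ even at $\Gamma = 1$ where the TLM formula is formally
0/0. A genuinely singular TLM denominator (lossless wavenumber with
$|\Gamma| = 1$ at resonance) raises an error.

## Fitting and model comparison

Models predict $\Delta T(d)$ up to one scale (SEM, TLM with fixed
$\Gamma$) or scale plus $\Gamma$ (free-$\Gamma$ TLM). The scale has the
closed-form least-squares solution $c = \sum y_i p_i / \sum p_i^2$;
$\Gamma$ is profiled on a $10^{-3}$ grid over $[0, 1]$ with local
refinement, real-valued only — a complex $\Gamma$ would add a parameter
the length-only data cannot pin down. RMSE uses $1/n$ normalisation;
model comparison uses the OLS form of the AIC,
$n\ln(\mathrm{RSS}/n) + 2(K+1)$, where $K$ counts free parameters and
$+1$ is the residual variance. AIC is used for *ranking* only: its
absolute value depends on units and on the error model, so the package
validates ranking behaviour (the generating family wins on synthetic
data), not printed AIC values. Transmit-gain correction
$\Delta T_c = \Delta T \cdot 10^{(TG - TG_{ref})/100}$ rescales each
wire's measurement to a common RF power; the reference wire defaults to
the first record and is overridable, and the TG contribution to the
error budget is propagated to first order,
$\sigma_{\Delta T} = \Delta T_c \ln(10)/100\,\sigma_{TG}$, then combined
root-sum-square with the probe-difference and baseline terms.

## Synthetic data: what it emulates and what it does not

`synthetic_body_coil_field()` mimics the gross structure of a body-coil
field in a torso phantom — dominant $E_z$, smallest on the midline and
growing linearly towards the lateral walls, a smooth longitudinal taper,
a linear phase advance along $z$, and transverse components under 10% of
the peak. It is a parametric surrogate, not an electromagnetic
simulation: it has no eddy-current structure, no conductor-induced field
distortion, and its phase law is a convenience. Tests passing on it show
the *integration machinery* is correct, not that any particular scanner
field is represented.

`synthetic_measurements()` mirrors the bench protocol: per-wire
auto-prescan TG as the mean of four repeats around the reference (SD
`tg_spread`), the model curve scaled to degrees Celsius, RF-power
perturbation $10^{-(TG - TG_{ref})/100}$, and additive Gaussian
thermometry noise. Because the stored TG mean is the one used in the
generator, `tg_correct()` inverts the perturbation exactly and the
noiseless round trip recovers the generating scale (and $\Gamma$) to
machine precision — the key identity the fitting tests lean on. Real
measurements add effects the generator omits: probe placement error
correlated across wires, baseline drift, and field non-uniformity along
the wire.

Default study conditions used in the recovery tests: 15 wire lengths
from 2.38 to 50.78 cm (the bench set), generating
$\Gamma = 0.25$, scale 50 °C, TG spread 2 counts, noise 5% of the curve
maximum, 100 seeded replicates. At these settings the profiled $\Gamma$
is recovered with median error about 0.02 and the AIC selects the
generating family in every replicate.

## Design choices that were genuinely open

- **Quadrature rule**: midpoint per segment. Any low-order rule works at
  1 mm steps; midpoint keeps the tangential-field evaluation at one
  point per segment, which is also where the direction vector lives.
- **$\Gamma$ search**: real $[0, 1]$ only, grid-then-refine rather than
  a general optimiser, because the RMSE profile in $\Gamma$ can be
  multimodal near resonance and the grid is cheap (the closed form is
  vectorised over lengths).
- **Resonance comparisons**: published resonant lengths are printed on a
  0.05 cm grid, so tests compare at that tolerance rather than pretending
  to more precision than the source carries.
- **Field-strength coupling**: functions take a frequency, not a field
  strength; `larmor_frequency()` is the only place 42.58 MHz/T appears.

## Known limitations

- Straight or gently curved, fully insulated, capped leads only; no
  helices, loops, or IPG-terminated leads (finite load impedance).
- Relative $\Delta T$ only — converting to absolute degrees requires the
  fitted scale from measurements or a thermal model.
- The insulated-conductor wavenumber degrades in low-conductivity
  (fatty) embedding media; the package warns at $\sigma = 0$ but cannot
  judge intermediate cases.
- Dispersive (frequency-dependent) tissue properties and multi-layer
  insulation are not modelled.
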