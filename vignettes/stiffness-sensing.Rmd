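---
title: "Ultrasonic indentation stiffness sensing: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasonic indentation stiffness sensing: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sonodent)
```

## The measurement principle

A single-element pulse-echo transducer pressed against soft tissue plays
two roles at once. Mechanically it is a rigid flat-ended cylindrical punch:
under an applied force $P$ it indents the tissue to a depth $w$, and
classical flat-punch contact theory for an elastic layer gives

$$E = \frac{1-\nu^2}{2a}\,\frac{P}{w},$$

with $a$ the contact radius, $\nu$ the Poisson's ratio and $E$ the Young's
modulus. Acoustically it is a depth gauge: the echo returned by a deep
interface arrives after the round trip $2h/v$ through tissue of thickness
$h$ and sound speed $v$, so compressing the tissue by $w$ advances the
echo by the **ToF difference**

$$\tau = \frac{2w}{v}, \qquad w = \frac{v\,\tau}{2}.$$

Because $\tau \propto w$ at fixed $v$, the ToF difference measured under a
fixed pressure differential is itself a stiffness proxy — stiffer tissue
deforms less and yields a smaller $\tau$ — and no absolute knowledge of
$v$, $\nu$ or the contact conditions is needed for *relative* comparisons
(ranking tissues, comparing muscle states, screening a site against a
contralateral reference). Absolute modulus estimation additionally requires
$v$ and the contact geometry, and `sonodent` keeps that path explicit:
`estimate_modulus_from_sweep()` demands $v$ as an input rather than
assuming one.

The contact model's assumptions matter and are stated here once: the
tissue is treated as isotropic, homogeneous and elastic, large relative to
the contact, in frictionless conformal contact with a punch far stiffer
than itself. Real tissue violates all of these to some degree, which is
exactly why the τ-based relative readout, not the inverted modulus, is the
primary quantity.

## What the simulator models

`simulate_ascan()` is a deliberately minimal one-dimensional
two-interface model. The received signal is the excitation pulse — a
Gaussian-windowed 2 MHz sinusoid whose $-6$ dB spectral width is the
fractional bandwidth times the carrier — replicated at the probe-tissue
surface ($t = 0$, fixed amplitude) and at the compressed back interface
($t = 2(h-w)/v$). The back echo's amplitude is scaled by frequency-linear
attenuation $10^{-\alpha\, d_\mathrm{cm} f_\mathrm{MHz}/20}$ over the
round-trip path; attenuation never affects timing. There are no multiple
reflections, no diffraction, no beam profile, no speckle: the analysis
chain only ever tracks one echo's arrival, so this is the smallest model
that exercises it honestly.

The quasi-static mechanics come from `deform()`. With the strain-stiffening
coefficient $\beta = 0$ the deformation is the linear contact law; with
$\beta > 0$ it solves

$$P = \frac{2aE}{1-\nu^2}\, w\left(1 + \beta\frac{w}{h}\right)$$

by bisection on $[0,\,0.95h]$ to a relative tolerance of $10^{-10}$. The
quadratic stiffening term is the simplest law that reproduces the concave
$\tau(P)$ observed in real tissue (compressive resistance grows with
compression); $\beta = 0$ recovers the linear model exactly. Deformation is
capped at 95% of the resting thickness, and hitting the cap marks the state
as bottomed out and raises a warning — full compression is outside the
model's validity and should never pass silently.

An embedded stiff inclusion (the lesion analogue) is modelled mechanically,
not acoustically: the host layer and inclusion layer compress in series, so
compliances add by thickness fraction,

$$E_\mathrm{eff} = \left(\frac{1-f_\mathrm{inc}}{E} +
\frac{f_\mathrm{inc}}{E_\mathrm{inc}}\right)^{-1},$$

which strictly increases in $E_\mathrm{inc}$ and reduces $w$ — hence τ —
at every positive load.

Noise is additive white Gaussian, calibrated so that
$20\log_{10}(\mathrm{peak}/\mathrm{RMS}) = \texttt{snr\_db}$ with respect
to the clean signal's absolute peak, drawn from a locally seeded RNG that
never perturbs the caller's random state. Sweep signals derive their seeds
deterministically from the base seed plus the load index, so every
experiment is bit-reproducible from its configuration.

**What the simulator does not emulate.** Transducer ring-down, couplant
and standoff variability, beam diffraction, phase aberration, speckle from
distributed scatterers, viscoelastic creep and hysteresis, anisotropy, and
physiological motion. Passing tests therefore demonstrate that the
*estimators and decision rules* are correct under the stated physics; they
do not certify performance on in vivo recordings, where those effects set
the error floor.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `center_frequency` | 2e6 | Hz | low-frequency single-element probe, cm-deep penetration |
| `fractional_bandwidth` | 0.6 | — | typical single-element pulse-echo bandwidth |
| `sampling_rate` | 50e6 | Hz | 25× the carrier; sub-sample shifts stay resolvable |
| `contact_radius_a` | 10e-3 | m | cylindrical probe face |
| `poisson_ratio_nu` | 0.5 | — | incompressible soft tissue |
| `attenuation_alpha` | 0.5 | dB/(cm·MHz) | textbook soft-tissue value |
| `stiffening_beta` | 0 | — | linear elastic unless a tissue scenario asks otherwise |
| estimator `method` | `"xcorr"` | — | more noise-robust than envelope-peak tracking |
| `search_window` | rear 3/4 of signal | s | excludes the surface echo |
| alignment `threshold_frac` | 0.5 | — | first envelope peak above half the maximum |
| knee `plateau_fraction` | 0.25 | — | see operating pressure below |
| screen `min_relative_reduction` | 0.2 | — | below typical ~0.5 inclusion contrasts, above repeat scatter |

Applied cuff pressures are mapped to indentation force through the punch
contact area, $P = p \cdot \pi a^2$, isolated in `resolve_force()`. This is
the physically minimal mapping; if a specific device couples pressure
through a different effective area, the protocol can state forces directly.

## The ToF estimators

The estimator the analysis rests on is deliberately duplicated, and every
result records which method produced it.

**Envelope peak.** The analytic-signal envelope (one-sided spectrum
doubling via the FFT) demodulates the carrier; `peak_time()` takes the
discrete envelope argmax inside the search window and refines it by
3-point parabolic interpolation. Ties are broken toward the earliest
sample, and a window with a flat envelope is an error rather than an
arbitrary pick.

**Windowed cross-correlation** (default) is coarse-to-fine. The coarse
stage locates each signal's back echo as the argmax of its envelope
box-filtered over roughly a pulse width — integrating the echo's energy
this way means a lone noise excursion cannot outvote it, which plain peak
picking suffers from at 20 dB SNR once the back echo has been attenuated —
and pre-aligns the loaded signal by the integer-sample difference. The
fine stage maximizes the normalized cross-correlation of the windowed raw
signals over residual lags of at most 2 μs, refined parabolically. The
sign convention throughout: $\tau > 0$ when the loaded echo arrives
*earlier* (compression).

Numerical behaviour worth knowing: parabolic interpolation of a
correlation peak carries a small systematic bias that grows with
bandwidth; at the default 25× carrier oversampling the total error is a
few hundredths of a sample (tested against exact FFT-phase-ramp delays,
noise-free and at 20 dB peak SNR on band-limited random signals of 8192
samples — signals long enough that the information-theoretic delay bound
is comfortably below the tested 0.05-sample tolerance; a single short echo
at that SNR could not meet it no matter the estimator). Integer-sample
shifts are recovered exactly. On noise-free simulated compressions the two
methods agree within one sample period, and both match $2w/v$ to half a
sample.

`align_signals()` removes couplant/standoff offsets by shifting each
recording an integer number of samples so its surface echo — the first
envelope peak above half the global maximum — coincides with the
reference's. It is optional and never applied implicitly.

## Calibration, ranking and the operating pressure

`fit_tof_vs_load()` and `fit_tof_vs_hardness()` are ordinary least squares
with intercept, matching how calibration lines are usually drawn;
through-origin regression is used only inside
`estimate_modulus_from_sweep()`, where the contact law forces a zero
intercept. A zero-variance response returns slope 0 with $R^2 = 0$ rather
than `NaN`.

One limitation is worth stating plainly: with silicone phantom moduli
parameterized from Shore A hardness by the Gent relation,

$$E(\mathrm{MPa}) = \frac{0.0981\,(56 + 7.62336\,S)}
{0.137505\,(254 - 2.54\,S)},$$

τ at fixed load is proportional to $1/E(S)$, which is hyperbolically
convex in $S$. A straight line through a full 0–60 HA series is therefore
only a rough summary — the direction (negative slope) is robust, but
$R^2$ for the linear fit saturates around 0.7–0.8 regardless of noise
level or stiffening, because the curvature is intrinsic to the modulus
scale, not to measurement error. Users calibrating against durometer
readings should fit τ against $1/E$ (or restrict the hardness range)
when linearity matters.

`rank_stiffness()` orders samples by ascending τ at a fixed load
differential (smaller τ = stiffer) and reports exact ties as a group
instead of breaking them silently.

`select_operating_pressure()` formalizes choosing the measurement pressure
at the knee of a sensitivity curve. The curve's `rate_of_change` holds the
first differences of τ per pressure step (one fewer element than the
pressure grid, each aligned to the pressure its step ends at). The rule
returns the largest pressure whose incoming rate is still at least
`plateau_fraction` (default 0.25) of the maximum rate: below the knee the
system discriminates stiffness well; beyond it, added pressure costs
comfort without adding sensitivity. The default 0.25 maps a curve that is
steep through its fifth level and then drops at least four-fold — the
shape a strain-stiffening limb produces over a 1–7 kPa escalation — onto
that fifth level (5 kPa).

## The lesion screen

Single pre/post τ comparisons invite eyeballing; `lesion_screen()`
formalizes a reproducible rule. With repeated measurements on a reference
condition and a test condition, the site is flagged when

1. the relative reduction $1 - \bar\tau_\mathrm{test}/\bar\tau_\mathrm{ref}$
   reaches `min_relative_reduction` (default 0.2), **and**
2. the two $\bar\tau \pm 2\,\mathrm{SE}$ intervals do not overlap,

where SE is the sample standard deviation over $\sqrt{n}$. With a single
repeat on either side the separation check is undefined, so the reduction
criterion decides alone and the result carries a low-confidence marker.
The screen is one-sided (stiffening only) by default because lesion models
of interest are stiffer than host tissue; `two_sided = TRUE` also flags
softening. Under the bundled study conditions (25 dB SNR, 8 repeats per
condition, a series-composite inclusion cutting true deformation by ~34%)
the screen's measured error rates in the test suite are 0/100 false flags
on homogeneous pairs and 100/100 detections.

## Bundled scenarios and problem sizes

`scenario_configs()` defines five experiment families, chosen once as the
package's reference conditions and exercised end-to-end by the tests and
the acceptance script:

* **silicone_hardness_series** — 10 mm silicone pads, 0–60 HA in steps of
  10 (Gent moduli, $v = 1000$ m/s), 0 and 15 N, 30 dB SNR.
* **force_sweep** — a 10 HA pad under 0–35 N in 5 N steps.
* **exvivo_nonlinear** — 30 mm tissue blocks at 12/25/50 kPa (adipose,
  lean pork, lean beef analogues), $\beta = 3$, 0–10 N in 1 N steps:
  moduli separated ≥ 1.5× so ranking is well-posed, and soft enough to
  show clear concavity without approaching the bottom-out cap.
* **lesion_pair** — a 25 kPa host with and without a 30 HA silicone
  inclusion occupying 35% of the thickness, 0 vs 3 N, 8 repeated pairs at
  25 dB SNR.
* **muscle_states** — 40 mm phantoms at 15 kPa (relaxed) vs 45 kPa
  (contracted) under 1–5 kPa cuff pressure.

Modulus-recovery accuracy is characterized on 40 mm phantoms at 5–100 kPa
under a 0–2 N sweep in 0.25 N steps — a load range keeping all five moduli
in the moderate-strain regime — with 50 noise seeds per modulus at 20 dB
SNR; lesion error rates use 100 seeded pairs per condition. These sizes
make the full suite run in well under a minute while leaving the
Monte-Carlo margins wide.

## Known limitations

* The "back interface" is an abstraction; in vivo the tracked echo's
  anatomical origin (fascia, bone) is device- and site-dependent.
* The series-spring inclusion model ignores lateral load spreading around
  a finite inclusion; it bounds the stiffening effect from above.
* Cuff pressure → force via contact area is one defensible choice; a real
  pneumatic chamber may couple differently. The mapping is configurable
  and isolated.
* Absolute modulus estimates inherit every contact-model assumption;
  treat them as effective moduli. Relative τ comparisons are the robust
  output.
* No viscoelasticity: loading rate and hold time have no effect in the
  simulator, while real tissue creeps.
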