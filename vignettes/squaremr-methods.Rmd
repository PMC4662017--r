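---
title: "Simulation-based MOLLI relaxometry: models, parameters and numerical choices"
author: "squaremr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based MOLLI relaxometry: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squaremr)
```

## The problem

MOLLI (Modified Look-Locker Inversion recovery) is the workhorse of cardiac
T1 mapping: several inversion-recovery experiments, read out with
ECG-triggered single-shot bSSFP acquisitions, are merged into one
inversion-time series per pixel and fitted with the 3-parameter model

$$S(TI) = A - B\,e^{-TI/T_1^*},$$

followed by the Look-Locker correction $T_1 = T_1^*\,(B/A - 1)$. The bSSFP
readouts perturb the recovery, so the apparent constant $T_1^*$ is always
shorter than the true $T_1$, and the correction factor — derived for FLASH
readouts, not bSSFP — undercorrects. The error grows with $T_1$ and with
shortened schemes that leave no pause for full recovery, reaching well over
100 ms for blood-like $T_1$ on a 5(0p)3 scheme.

This package takes the simulation route instead of a closed form: the
*identical* pulse sequence — inversion pulse shape, ramp-up, every bSSFP TR,
the actual RR intervals, the actual effective TIs — is integrated through
the Bloch equations for a grid of physiological $(T_1, T_2)$ pairs. The
simulated signals form a dictionary, and each measured pixel is assigned the
$(T_1, T_2)$ of the dictionary entry with the least squared difference to
its signal, with a free non-negative amplitude per entry (the per-pixel
equilibrium magnetization is unknown). The conventional 3-parameter +
Look-Locker pipeline is included as the baseline the matching approach
improves upon.

## The Bloch engine

Each isochromat (a spin packet with one $T_1$, $T_2$, slice position $z$ and
off-resonance) is propagated through a discrete event timeline. Every event
carries a duration, RF amplitude and phase, slice-axis gradient, and
optional crusher or ADC markers. One step applies

1. a rotation about the effective field — transverse components
   $\gamma B_1(\cos\phi, \sin\phi)$, longitudinal component
   $\gamma G z + 2\pi\,\Delta f$ — through angle $\gamma|B_\mathrm{eff}|\,\Delta t$,
2. then relaxation: transverse scaled by $e^{-\Delta t/T_2}$, longitudinal
   relaxed toward equilibrium with $e^{-\Delta t/T_1}$.

This rotate-then-relax operator splitting is standard for discrete-event
Bloch solvers; its error vanishes with the step and is bounded in the tests
by two independent oracles: closed-form free relaxation, and a per-step
matrix exponential of the full 4x4 affine Bloch generator (rotation,
relaxation and recovery applied *simultaneously*), which the stepper matches
to 1e-6 per component on random 20-step timelines at a 1 microsecond step.
Long alternating-phase bSSFP trains reproduce the closed-form steady state
$M_0\sin\alpha\,(1-E_1)/(1-(E_1-E_2)\cos\alpha-E_1E_2)\cdot e^{-TE/T_2}$
within 1%.

Two representation choices matter:

* **Variable event durations.** RF waveforms are sampled at the simulation
  step `dt_us`; gaps without RF are emitted as single events of exact
  length. Rotation about z and relaxation commute, so this is exact for
  piecewise-constant fields and reduces a ~10 s MOLLI experiment from
  roughly a million uniform steps to ~30 000 events without touching the
  physics.
* **Single rotating frame.** The adiabatic inversion's frequency sweep is
  carried entirely by its time-varying phase, so the same stepper handles
  every pulse.

Crushers are ideal "software crushers": the transverse components are zeroed
in one event, with no gradient-area bookkeeping. They are placed before and
after each inversion pulse.

## Pulses

**Inversion** is a hyperbolic-secant adiabatic pulse,
$B_1(t) = B_{1,\max}\,\mathrm{sech}(\beta t)$,
$\phi(t) = \mu\,\ln\mathrm{sech}(\beta t)$, duration 4.74 ms. The classic
parameter set of this pulse family is not fully specified by its duration,
so the defaults are this package's own calibration, frozen before any
downstream analysis: $\mu = 5$; $\beta$ chosen so the envelope decays to 1%
of its peak at the pulse edges ($\beta \approx 2236\,\mathrm{s}^{-1}$ at
4.74 ms); and $B_{1,\max} = 40\,\mu\mathrm{T}$, about twice the numerically
measured adiabatic threshold, where the inversion efficiency has saturated
(final $M_z \le -0.98$, insensitive to a further 1.5x amplitude scaling).
The efficiency contract, not the parameter values, is the interface: any
override that still inverts to $-0.98$ behaves equivalently downstream.

**Excitation** is a Hann-apodized sinc of 490 us with 3 side lobes per side
(time-bandwidth product 8) — a typical product-pulse shape; the vendor's
exact lobe count is unknown and immaterial to the contracts. The amplitude
is calibrated analytically from the signed B1 area so the on-resonance flip
at slice center is exact; the slice gradient follows from the pulse
bandwidth and the 6 mm slice; a rephasing lobe of half the gradient area
follows the pulse, and a prewinder of the same area precedes it so that the
slice gradient is fully balanced over each TR and off-center spins refocus
at the echo. The small-tip profile matches the Fourier transform of the
envelope to better than 1% of the peak.

## Sequence expansion and timing

A scheme string such as `"5(3p)3"` (five readouts, three pause beats, three
readouts) plus an RR-interval series expands into the full timeline. Each
single-shot block is a 10-pulse linear ramp-up ($k\alpha/10$, no ADC)
followed by 65 full-angle bSSFP TRs with the 0/$\pi$ phase alternation
running continuously across ramp, acquisition, heartbeats and groups; the
echo of line 33 (the k-space center of the 65-line linear trajectory) is the
image sample. The effective TI of every image is the time from the *end* of
the inversion pulse to that echo; the inversion is placed so the first
readout's echo lands exactly the configured initial TI after it, which puts
the inversion in the preceding diastole. Pause beats contain free relaxation
only. Triggering is pure RR arithmetic with a zero trigger delay:
end-diastolic placement is absorbed into the RR bookkeeping, which is also
how the effective TIs are defined.

The receiver bandwidth only enters the protocol as metadata: the mapping
from rBW to a simulation step is vendor-specific, so `dt_us` is set
directly (default 10 us; the tests use 5-50 us depending on what the check
needs). Refining 10 us to 5 us changes MOLLI sample magnitudes by under
0.5% of the series maximum — per-sample *relative* change is not a useful
convergence measure because some samples sit near the signal null.

## The dictionary and the matcher

The default grid covers $T_1 \in [200, 1900]$ ms and $T_2 \in [20, 400]$ ms
(physiological pre-contrast range); combinations with $T_2 > T_1$ are
excluded. Grid values are integer-stepped in ms to avoid floating-point
accumulation. The stop endpoint is inclusive by default; the
performance-fixture grids use a half-open T1 axis ($600 \le T_1 < 2000$),
the convention under which the published entry counts (533 400 and 21 560)
are reproduced exactly.

Each entry is the magnitude of the complex sum over a slice-profile ensemble
— by default 21 isochromats spanning twice the slice thickness, one exactly
at slice center. Magnitudes are stored because matching is against scanner
magnitude images; the signed complex sums are available behind a flag. The
21-spin ensemble is the desk-scale default (the high-accuracy configuration
uses 101): its slice-profile quadrature sits about 4% away from the
converged integral (101 vs 201 spins agree to 0.5%), a systematic common
factor that cancels in matching because dictionary and simulated data share
the same ensemble — but it is one more reason a dictionary must never be
reused across acquisition configurations, which the stored config digest
enforces on load.

Matching is a full linear search. For entry $d_k$ the amplitude has the
closed form $a_k = \max(0, \langle s, d_k\rangle / \langle d_k, d_k\rangle)$
and the winning entry minimizes $\lVert s - a_k d_k\rVert^2$; ties break
toward smaller $(T_1, T_2)$. The clamp to non-negative amplitudes is this
package's contract (a magnitude signal cannot have a negative scale); with
it, ranking is equivalent to normalized correlation while keeping a physical
amplitude estimate. Whether the original processing normalized vectors
instead is unknown and makes no difference to the selected entry for
positive amplitudes.

**What matching can and cannot recover.** With noiseless data and truths on
the grid, recovery is exact — this is asserted in the tests. For truths off
the grid, the least-squares surface has a shallow valley along correlated
$(T_1, T_2)$ directions: when the $T_2$ nuisance coincides with a grid node,
the matched $T_1$ brackets the truth within one grid step (verified over 100
random pairs on a 20 ms grid), but for fully off-grid pairs a few percent of
matches land several steps away along the valley, even without noise. The
*mean* $T_1$ error stays well below one grid step, which is the regime the
phantom-bias results reflect; $T_2$ is well determined only for long-$T_1$ /
short-$T_2$ tissue and can err substantially elsewhere, exactly the
asymmetry the MOLLI sequence imposes (it encodes $T_1$, while $T_2$ enters
only through the readout perturbation).

## The conventional baseline

The 3-parameter magnitude fit restores polarity by exhaustive search: for
every candidate count $k$ of sign-flipped leading samples (sorted by TI),
the model is fitted and the global residual minimum over $k$ wins — at 8-9
samples this is cheap and deterministic. For fixed $T_1^*$ the model is
linear in $(A, B)$, so the nonlinear search is one-dimensional (variable
projection): a dense log-spaced profile over $T_1^* \in [30, 12000]$ ms
followed by local refinement to a 1e-10 tolerance. This subsumes the usual
handful of multi-start initializations and cannot be trapped by a local
minimum between grid nodes of the profile. On noiseless model data the fit
recovers $(A, B, T_1^*)$ to 1e-6 relative and selects the polarity index
equal to the number of TIs before the true zero crossing.

## The phantom generator

The synthetic-data generator emulates the phantom arm of a MOLLI validation
study:

* **Tissue values.** The default six-tissue table is the cardiac phantom:
  normal myocardium (1048/50 ms), blood (1570/196), edema (1249/62), infarct
  (1361/64), and post-contrast myocardium at 2-3 min (344/52) and 13-15 min
  (413/50). A second fixture is a Eurospin-like $T_1$ ladder from 212 to
  1522 ms at fixed $T_2 = 52$ ms; only its endpoints are reference values —
  the intermediate rungs are synthetic, evenly spaced choices, and are
  labeled as such.
* **ECG.** RR intervals are $60000/\mathrm{bpm}$ plus Gaussian jitter
  truncated at 3 SD, seeded. The phantom protocol uses a fixed 60 bpm
  (RR 1000 ms).
* **Noise.** Complex Gaussian noise of equal SD per channel is added to the
  noise-free complex signal before the magnitude is taken, giving Rician
  magnitude statistics (Rayleigh background, mean $\sigma\sqrt{\pi/2}$ —
  asserted in the tests). The dictionary itself stays noise-free, as in the
  measurement model. With the seed fixed the whole series is
  bit-reproducible.
* **Caching.** Each distinct $(T_1, T_2)$ pair is simulated once and
  broadcast to its pixels scaled by $M_0$, so a six-tissue image costs six
  Bloch runs regardless of matrix size.

What it does **not** emulate: motion and flow (stationary spins), B1+ and
B0 field maps, magnetization transfer, multi-compartment exchange, coil
sensitivities and SENSE reconstruction noise correlations, and partial
voluming at region edges. Passing tests therefore demonstrate correctness of
the *processing chain* under the stated signal model, not robustness to
everything an in-vivo scan adds.

## Numerical choices and degenerate inputs

* Relaxation can be disabled only through explicit `relax = FALSE` flags
  (validation runs); infinite $T_1/T_2$ are legal isochromat values and
  reduce to the same limit naturally.
* An all-zero pixel signal is a degenerate input (masked pixel) and is
  rejected by `match_signal` / skipped by the map functions; fit failures
  flag the pixel invalid rather than raising.
* A series whose TIs differ from the dictionary's by more than 1 ms per
  image demands a rebuild — TIs depend on the actual cardiac timing, so the
  dictionary is a per-session object, built *after* acquisition.
* `min_feasible_ti` reports the shortest initial TI the single-shot timing
  admits (ramp + lines-to-center + TE, plus the block-start-to-RF-center
  overhead when called with it); the protocol values leave 114 ms feasible
  with ~6 ms margin.
* Worker parallelism in dictionary construction is an ordered map over
  entry chunks; results are byte-identical for any worker count.

## Problem sizes in the test suite

The suite runs the full physics at reduced scale: the simulation step is
relaxed to 50 us for sequence-level checks (discretization convergence is
verified separately at 10 vs 5 us), the parameter-recovery harness uses a
20 ms / 20 ms dictionary (1665 entries) on the 5(3p)3 scheme, and phantom
images are 8-32 pixels on a side. These sizes were chosen so the whole suite
exercises every contract in about a minute on a single core; none of the
asserted properties is resolution-marginal at these settings.

## Known limitations

* $T_2$ estimates from MOLLI matching are trustworthy only in the
  long-$T_1$/short-$T_2$ regime; the package reports them but the
  documentation (and the identifiability discussion above) should temper
  their use.
* The Look-Locker baseline reproduces the *conventional* pipeline, not any
  vendor's exact fit; equivalence is asserted on noiseless model data and on
  qualitative bias behavior only.
* Off-resonance is supported per isochromat but the shipped protocol
  simulates on-resonance; banding behavior of bSSFP away from resonance is
  untested territory.
* The inversion- and excitation-pulse parameter defaults are calibrated
  contracts, not reproductions of a specific scanner's waveforms.
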