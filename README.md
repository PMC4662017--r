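# squaremr

Simulation-based cardiac T1 mapping for MOLLI image series, in R.

## The problem

MOLLI (Modified Look-Locker Inversion recovery) estimates myocardial and
blood T1 by merging images from several ECG-triggered inversion-recovery
experiments into one inversion-time series per pixel, fitting

S(TI) = A − B·exp(−TI/T1\*),

and correcting the apparent relaxation time with the Look-Locker factor
T1 = T1\*·(B/A − 1). Because the bSSFP readouts perturb the recovery and the
correction factor was derived for a different readout (FLASH), conventional
MOLLI post-processing systematically underestimates T1 — by more than
100 ms for blood-like T1 on schemes without recovery pauses.

`squaremr` removes the closed-form approximation entirely. It simulates the
*identical* pulse sequence — the adiabatic sech inversion, the 10-pulse
ramp-up, all 65 bSSFP TRs of every single-shot readout, the actual RR
intervals and effective TIs — with a discrete-event Bloch engine over a grid
of physiological (T1, T2) pairs and a realistic slice-profile ensemble. The
simulated signals form a dictionary; each pixel is assigned the (T1, T2) of
the entry with the least squared difference to its measured signal (with an
analytically optimal non-negative amplitude per entry). The conventional
3-parameter + Look-Locker pipeline is included as the baseline, together
with a digital-phantom generator (known T1/T2/M0 maps, simulated ECG, Rician
noise) so the entire chain is testable without scanner data.

Intended users: quantitative-MRI researchers validating T1-mapping
pipelines, and anyone who needs a transparent, scriptable MOLLI simulator
with a matched reconstruction.

## Worked example

Simulate a noisy six-tissue cardiac phantom on the clinical 5(3p)3 scheme,
build a 20 ms-resolution dictionary for the same session, and compare
dictionary matching against conventional post-processing:

```r
library(squaremr)
params <- acquisition_params(dt_us = 50)   # phantom protocol, desk-scale step
timing <- cardiac_timing(rep(1000, 11))    # simulated 60 bpm ECG

phantom <- make_phantom("disks", cardiac_tissues(), n = 48)
series <- simulate_acquisition(phantom, params, "5(3p)3", timing,
                               noise_sigma = 0.01, seed = 1)
dict <- build_dictionary(grid_spec(200, 1900, 20, 20, 400, 20),
                         params, "5(3p)3", timing)

maps_sq <- match_series(series, dict, mask = phantom$region_labels > 0)
maps_ll <- conventional_map(series, mask = phantom$region_labels > 0)

rois <- phantom_rois(phantom)
ref <- setNames(phantom$regions$t1_ms, phantom$regions$name)
ev_sq <- evaluate_bias(maps_sq, ref, rois)
ev_ll <- evaluate_bias(maps_ll, ref, rois)
print(ev_sq$stats[, c("roi", "reference", "mean", "bias")], digits = 4)
```

```
               roi reference   mean    bias
1       myocardium      1048 1040.8 -7.1837
2            blood      1570 1570.2  0.2041
3            edema      1249 1252.7  3.6531
4          infarct      1361 1361.6  0.6327
5   post_gd_2_3min       344  340.0 -4.0000
6 post_gd_13_15min       413  413.9  0.8776
```

Summaries over the six ROIs:

```
dictionary matching: bias -1.0 +/- 3.9 ms
conventional MOLLI:  bias -54.3 +/- 34.6 ms
```

The per-ROI `bias` is the ROI mean minus the reference T1 in ms. Dictionary
matching recovers every tissue to within a few ms even at a coarse 20 ms
grid, while the conventional pipeline underestimates T1 increasingly with
the tissue's T1 — the behavior the simulation-based approach exists to fix.
`bland_altman()` produces the corresponding modified Bland-Altman summary
(differences plotted against the reference value).

Command-line equivalents of each stage live in `inst/cli/`
(`simulate-phantom.R`, `build-dict.R`, `fit-squaremr.R`, `fit-molli.R`,
`evaluate.R`); they compose into the same pipeline from a YAML protocol
config (`inst/extdata/phantom_protocol.yaml`).

## Scope notes

T2 is estimated alongside T1 but is well determined only for long-T1 /
short-T2 tissue; see the methods vignette
(`vignettes/squaremr-methods.Rmd`) for the identifiability discussion, all
model assumptions, parameter defaults and numerical choices.
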