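# warpkit

Perceptual **warping** is the context-dependent displacement of a category
boundary: when listeners label sounds drawn from an acoustic continuum, the
stimulus at which their percept flips depends on the recent stimulus history.
Under serial presentation (stepping Tk1→Tk7 or Tk7→Tk1 along the continuum)
many listeners keep reporting the previous category beyond their usual
boundary (*hysteresis*), while random presentation yields the nominal
boundary. `warpkit` is an R toolkit for simulating and analyzing
two-alternative vowel-identification experiments that measure this effect
with mouse tracking, in clean and noise-masked (0 dB SNR) listening.

It is aimed at auditory psychophysicists who want (i) a fully parametric
synthetic testbed for categorization + mouse-tracking designs, and (ii) the
standard analysis chain for real trial logs in the same format.

## What it implements

**Stimuli.** A cascade formant synthesizer (impulse-train source at F0 = 100
Hz through three second-order resonators) builds a 7-token /u/–/a/ continuum
whose F1 moves in exactly equal steps from 430 to 730 Hz (F2 = 1090 Hz,
F3 = 2350 Hz; 100 ms tokens, 10 ms raised-cosine ramps, fs = 48 828 Hz, RMS
normalized). A speech-shaped masker is generated from the long-term power
spectrum (LTPS) of the vowel set and mixed at an exact SNR:
`20·log10(RMS_speech / RMS_noise) = SNR` to numerical precision.

**Identification model.** Per subject and condition, the proportion of /a/
responses is fit with the sigmoid

    P(x) = 1 / (1 + exp(-β1 · (x - β0)))

where `β0` is the category boundary (P = 0.5) and `β1` the slope. Warping is
quantified as the boundary shift `Δβ0` between serial and random orders. RTs
are medians per token after excluding outliers outside 250–2500 ms.

**Mouse tracking.** 100 Hz cursor trajectories are normalized to the unit
square and to 101 time points, left-target trials are mirrored onto the right
target, and two geometry measures are computed: the area between the path and
its straight start–end chord (a.u.c., shoelace formula) and the proportional
Euclidean proximity to the target, `1 − d/max(d)`, over normalized time.
Condition curves are compared with a running (sample-by-sample) paired
t-test at p < 0.01.

**Statistics.** Repeated-measures ANOVA on subject × condition cell means
(partial eta squared), Holm-adjusted pairwise contrasts, and Pearson
correlations linking each subject's boundary shift to the change in their
trajectory curvature, per SNR stratum.

**Synthetic observer.** `simulate_experiment()` generates complete trial
logs from a generative listener with a warped logistic response rule, an
inverted-V RT profile (slowest at the boundary, faster under serial order
and in noise), and two-phase trajectories whose curvature grows with
category ambiguity and shrinks under serial order in noise.

## Worked example

```r
library(warpkit)

spec <- continuum_spec()
w1 <- synthesize_vowel(spec, 1)
lpc_formants(w1)            # 430.000 1092.944 2350.375  <- F1 F2 F3 (Hz)
estimate_f0(w1)             # 99.99594

res <- run_all(run_config(seed = 42), "results_run")
res$split_half$r            # 0.98  (boundary is stable within subjects)
res$anova_auc
#           effect df1 df2 ss_effect  ss_error       F        p   pes
#              snr   1  28   0.01779 0.0003638 1368.91 2.55e-25 0.980
#        condition   1  28   0.00300 0.0001175  715.16 1.77e-21 0.962
#    snr:condition   1  28   0.00378 0.0004046  261.45 9.84e-16 0.903
res$runs$noise$runs         # serial-vs-random proximity diverges t* = 0.08-0.99
res$runs$clean$runs         # in clean speech only short, late runs
```

The order × SNR interaction on a.u.c. says trajectory curvature depends on
presentation order specifically in noise: serial ordering straightens the
paths toward the chosen category (mean a.u.c. lower by ~0.022 normalized
units², Holm-adjusted contrast p ≈ 3e-20), while clean-speech curvature is
order-invariant. The proximity running t-test shows the same effect in time:
in noise the serial-order advantage appears almost immediately and persists
through the trial.

`run_all()` writes the stimulus WAVs, the long-format trial log, fit/geometry
CSV tables, a JSON-lines event log and `report.md` with summary figures. The
same stages are scriptable via `inst/scripts/warpkit.R`
(`synth` / `simulate` / `psychometrics` / `mousetrack` / `run`).

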