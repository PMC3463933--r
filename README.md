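# wentaf — Wavelet Entropy analysis of atrial fibrillation organization

`wentaf` quantifies how *organized* the atrial fibrillatory (f) waves in
a single-lead surface ECG are, using the Wavelet Entropy (WE) of the
atrial activity that remains after ventricular (QRST) cancellation. The
degree of f-wave organization tracks the number of reentrant wavefronts
wandering the atria, which is what makes this scalar interesting for
anticipating whether a paroxysmal AF episode will self-terminate or
whether cardioversion of persistent AF will hold. The package is aimed
at biomedical-signal researchers who want the complete, reproducible
chain — filters, cancellation, transform, score, evaluation — plus a
ground-truth synthetic AF generator to exercise it without clinical
data.

## The score

Given the atrial activity signal, an $N$-level discrete wavelet
transform (default $N = 7$, biorthogonal (4,4) family, 1024 Hz analysis
rate, so the seventh detail band is 4–8 Hz — the f-wave band) yields
coefficient vectors $C_m$. The relative wavelet energies and their
Shannon entropy are

$$E_m = \frac{\sum_i |C_m(i)|^2}{\sum_{m=1}^{N} \sum_i |C_m(i)|^2},
\qquad
WE = -\sum_{m=1}^{N} E_m \log_{10} E_m .$$

Organized (spectrally concentrated) atrial activity scores near 0;
disorganized, broadband activity approaches $\log_{10} 7 \approx
0.845$. Higher WE marks the non-terminating / relapse-like class.

## Worked example

Synthesize one organized and one disorganized AF-like record and score
them through the full pipeline (conditioning filters → R-peak detection
→ SVD template cancellation → seven-level decomposition → entropy):

```r
library(wentaf)

org  <- synthesize_ecg(ecg_synth_spec(
  aa = aa_synth_spec(organization = 0.9, seed = 101), seed = 201))
dis  <- synthesize_ecg(ecg_synth_spec(
  aa = aa_synth_spec(organization = 0.3, seed = 102), seed = 202))

we_score(org)
#> [1] 0.3412818
we_score(dis)
#> [1] 0.3581213
```

The disorganized record scores higher. A full study-style evaluation —
a labeled cohort of 25 + 25 records, WE per record, ROC-optimal
thresholds learned inside a stratified 2-fold cross-validation repeated
five times — runs with:

```r
coh <- synthesize_cohort(25, 25, seed = 7)
ex  <- run_experiment(coh$records, coh$labels, seed = 7)
subset(ex$table, family == "bior4.4")
#>    family we_mean_pos  we_sd_pos we_mean_neg   we_sd_neg      p_value
#> 4 bior4.4   0.3959961 0.03271906   0.3496310 0.009589202 1.493571e-08
#>   sensitivity specificity  accuracy
#> 4   0.9185897   0.9057692 0.9121795
```

Here `we_mean_pos` is the disorganized-class mean WE, `p_value` the
pooled-variance t-test between classes, and the last three columns the
cross-validated classification metrics at ROC-optimal thresholds.

Records round-trip through CSV (`time_s,amplitude_mV` with metadata
header) and single-segment WFDB format-16 pairs; `resample_record()`
converts e.g. 128 Hz Holter excerpts to the 1024 Hz analysis rate. A
command-line entry point covering the same pipeline ships as
`inst/exec/wentaf` (subcommands `simulate`, `convert`, `preprocess`,
`extract-aa`, `score`, `evaluate`, `pipeline`).

## Scope

Single-lead, 30-second-scale records; no multi-lead fusion, no
time-resolved entropy, no clinical decision thresholds. See the
methods vignette (`vignettes/wavelet-entropy-af.Rmd`) for the model,
parameter meanings, design decisions, and limitations.
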