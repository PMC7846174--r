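# circatime

Infer the physiological circadian time of a single static transcriptome from
a reference time series, and decide whether a genotype's molecular clock
deviates from normal.

When each genotype in a panel is profiled only once — but the collection is
staggered around the clock — every sample carries an implicit timestamp in
its rhythmic gene expression. `circatime` reads that timestamp with a
modified **molecular-timetable method** and compares it with the wall-clock
harvest time: a consistent discrepancy reveals a shifted, fast, slow, or
disrupted clock. The package is aimed at chronobiologists analyzing bulk
expression time courses and high-frequency static cohorts (flies, rodents,
any system with a ~24-h transcriptional clock).

## The method

**Training.** Each gene of a reference time course is correlated with a
bundle of 144 cosine waves, `cos(2π(t − φ_k)/24)` with peak times `φ_k`
tiling the day at 10-min increments. Genes with maximum correlation > 0.5
and coefficient of variation > 0.20 become *time-indicating genes* (TIGs);
the peak time of the best wave is each TIG's *molecular peak time* (MPT).

**Prediction.** For a new sample, the TIG expression vector is correlated
across genes with candidate read-outs `cos(2π(MPT_g − φ)/24)` over the same
phase grid; the best `φ` is the sample's physiological time. Errors are
signed circular differences on `(−12, 12]` hours.

**Calibration and flagging.** A leave-one-out harness retrains the full
pipeline per fold and reports mean |error| and a precision defined as three
SDs of the signed errors; samples whose difference strictly exceeds the
3.4-h precision threshold are flagged as outliers. A detection-window
simulation quantifies during which part of the day a line with period `P`
and phase advance `δ` (internal time `τ = (24/P)(t + δ)`) is detectable at
all. Cosinor regression (mesor, amplitude, acrophase + delta-method SEs)
provides rhythm detection and the between-group phase-shift test (call iff
|Δphase| > 2 h **and** BH-FDR q < 0.05).

## Worked example

```r
library(circatime)

cfg <- simulation_config(n_genes = 40, cycler_fraction = 0.25,
                         amplitude_to_noise = 4, seed = 42)
ref <- generate_reference_timecourse(cfg)
ref$expression
#> expression_set: 40 genes x 72 samples
#> tissues: tissue1
#> harvest times: 0 - 22 h; regimes: LD/DD

model <- select_tigs(ref$expression)
model
#> timetable_model (LDDD_05): 10 time-indicating genes
#> cutoffs: r > 0.5, CV > 0.2; bundle: 144 waves, period 24 h
head(model$tigs[, 1:4], 3)
#>    gene_id mpt_hours     r_max        cv
#> 1 gene_001  0.000000 0.9392412 0.4750073
#> 2 gene_002  2.333333 0.9442713 0.5026120
#> 3 gene_003  4.666667 0.9476471 0.4803334

report <- loo_evaluate(ref$expression)
report
#> leave-one-out evaluation: 72 folds
#> mean |diff| = 0.338 h; SD(signed) = 0.434 h; precision (3 SD) = 1.302 h

sum(flag_outliers(report$per_sample)$outlier)
#> [1] 0

detection_window(30, 0)
#> detection window: 7.0 h (period 30.0 h, offset +0.0 h, threshold 3.4 h)
```

Reading the output: all 10 simulated cyclers were recovered as TIGs with
MPTs on the 10-min grid near their true phases; at an amplitude-to-noise
ratio of 4 the held-out predictions land within ~20 min of the harvest time
on average, so no sample crosses the 3.4-h outlier threshold. The last call
shows that a line whose clock runs at a 30-h period is distinguishable from
the reference during only 7 hours of the day — deviation size and
detectability are different things.

`run_pipeline(pipeline_config(...))` chains simulate → select → evaluate →
flag and writes TSV/JSON artifacts plus a run manifest;
`read_expression_tsv()` / `write_expression_set()` handle the TSV interchange
format (genes × samples, first column `gene_id`, separate metadata table).

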