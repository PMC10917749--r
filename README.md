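# temporsa

Time-resolved representational similarity analysis (RSA) with
variance partitioning, for ordering *when* different kinds of stimulus
information emerge in epoched multi-channel neural recordings.

The motivating question comes from scene perception: during a brief glance
at an indoor scene, do navigational affordances (where one could walk)
become available together with low-level 2D features, or only after 2D, 3D
and semantic information has been computed? The package implements the
full analysis chain needed to answer such questions with EEG-style data,
plus a synthetic-data generator that makes every stage testable by
parameter recovery — no recordings required.

## The method

For conditions $i, j$ and time $t$, a cross-validated Fisher discriminant
on the channel vectors at $t$ yields a pairwise decoding accuracy
$a_{ij}(t)$; collected over pairs these form a neural representational
dissimilarity matrix (RDM) per time point. Candidate feature spaces are
summarized the same way: feature matrices give model RDMs via
$d_{ij} = 1 - r_{ij}$ (Pearson), and navigational affordance maps give a
NAM RDM via Euclidean distances between 180-bin angular histograms of
drawn exit paths.

Variance partitioning then attributes the neural RDM's structure to model
families. With lower-triangle vectors $\mathbf{y}(t)$ (neural) and
predictor families $m = 1 \dots M$,

$$\mathrm{unique}_m(t) = R^2_{\mathrm{all}}(t) - R^2_{\mathrm{all} \setminus m}(t) \;\ge\; 0,$$

where each family contributes its member RDMs (e.g. mid and output network
layers) as separate OLS regressors. Group inference uses per-time-point
t-tests with Benjamini–Hochberg FDR (q = 0.05), participant-level bootstrap
(default 1000 iterations) for 95% peak-latency confidence intervals, and
paired bootstrap p-values (FDR-corrected across family pairs) for latency
differences.

## Worked example

Simulate an 8-participant cohort in which four model geometries (2D, 3D,
semantic, NAM) are injected at 0.13, 0.17, 0.16 and 0.30 s, run the whole
chain, and inspect the recovered peak latencies:

```r
library(temporsa)
cfg <- read_config(system.file("extdata", "demo_config.yaml",
                               package = "temporsa"))
res <- run_pipeline(cfg)
res$peaks[["2D"]]
res$peaks[["NAM"]]
subset(res$comparisons, a == "2D" & b == "NAM")
```

```
<peak_latency_result> 2D: peak 110.00 ms, 95% CI [90.00, 110.00] ms (peak_of_average, 500 boots)
<peak_latency_result> NAM: peak 310.00 ms, 95% CI [240.00, 590.00] ms (peak_of_average, 500 boots)
   a   b           p  p_adjusted
3 2D NAM 0.003992016 0.007984032
```

The 2D geometry is recovered early and the NAM geometry late, with the
paired bootstrap rejecting equality of the two peak latencies after FDR
correction — the qualitative signature the method is designed to detect.
Single stages are available as plain functions (`pairwise_decode()`,
`rdm_from_features()`, `angular_histogram()`, `nam_rdm()`,
`unique_variance_timecourse()`, `bootstrap_peaks()`, ...), and
preprocessing utilities (`baseline_correct()`, `downsample()`,
`select_channels()`, `crop()`) handle the epoch domain.

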