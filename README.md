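# avnode

Estimation of atrioventricular (AV) node refractory-period (RP) and
conduction-delay (CD) trends during atrial fibrillation (AF), from
non-invasive beat series.

During AF the AV node is the gatekeeper between the fibrillating atria and
the ventricles: its two pathways — fast (FP) and slow (SP) — block or
conduct atrial impulses according to their refractory periods and
conduction delays, and rate-control drugs act on exactly these properties.
`avnode` is for researchers who want patient-specific, uncertainty-aware
24-hour trends of $R^{FP}, R^{SP}, D^{FP}, D^{SP}$ using only an
RR-interval series and an atrial-fibrillatory-rate (AFR) trend.

## Method at its core

* **Model.** A 21-node network: two 10-node pathway chains joined at their
  distal ends, feeding a coupling node (His/Purkinje) with data-fixed RP
  and a 60 ms delay. Atrial input is a Poisson train with rate
  $\lambda = \mathrm{AFR}/60$. Per node,
  $R = R_{\min} + \Delta R\,(1-e^{-\tilde t/\tau_R})$ and
  $D = D_{\min} + \Delta D\,e^{-\tilde t/\tau_D}$, with $\tilde t$ the
  diastolic interval; refractory nodes block. Twelve parameters
  $\theta$ in total (six per pathway).
* **Error.** Observed and simulated RR series are compared by a 961-bin
  Poincaré histogram (successive RR pairs, 250–1800 ms in 50 ms steps) via
  a duration-normalized $\chi^2$-style distance $\epsilon$.
* **Fitting.** Per overlapping 10-minute segment: a dynamic genetic
  algorithm (population 300, 2–7 generations driven by the
  segment-to-segment histogram change, warm-started) followed by an ABC
  population Monte Carlo sampler (100 particles, 8 iterations, thresholds
  taken from the GA's own error ladder) that returns a posterior sample of
  $\theta$.
* **Reduction.** Each posterior particle is re-simulated and the realized
  $R$, $D$ values are pooled into four interpretable property
  distributions, summarized by density mode, 5–95 % band and the
  slow-pathway conduction share.
* **Variability.** Diurnal (day/night ratio of the mode), short-term (mean
  Kolmogorov–Smirnov distance between adjacent segments), Wilcoxon/Shapiro
  tests, Spearman correlation against drug response, and a frozen
  66-column per-patient feature table.

A synthetic-data generator produces 24-h recordings (beats + AFR +
demographics + per-segment ground-truth property samples) from the model
itself, so the entire chain is testable without patient data.

## Worked example

```r
library(avnode)
set.seed(1)

# a 30-minute synthetic patient with known ground truth
traj <- generate_theta_trajectory(6, "stationary")
rec  <- generate_recording(traj, seed = 1)
pre  <- preprocess_recording(rec$beat_times, rec$afr, rec$duration)
length(pre$segments)                     # 5 overlapping 10-min segments

# fit one segment: GA at desk scale, then ABC refinement
cfg <- ga_config(population_size = 60, first_segment_generations = 5)
ga  <- run_over_segments(pre$segments, rec$coupling, cfg, seed = 1)
abc <- run_abc(ga[[1]], pre$segments[[1]], rec$coupling,
               n_particles = 20, seed = 2)
c(ga_best = ga[[1]]$fitness[1], abc_best = min(abc$errors))
#>   ga_best  abc_best
#> 0.4826724 0.2595280

# reduce to interpretable properties
props <- properties_from_particles(abc, pre$segments[[1]]$lambda_hat,
                                   rec$coupling, seed = 3)
est <- summarize_properties(props)
round(est$phi_max, 1)
#>   r_fp   r_sp   d_fp   d_sp
#> 1287.5  359.4   56.8   55.2
round(est$sp_ratio, 2)
#> [1] 0.94

# the generator's own realized properties for the same segment
round(summarize_properties(rec$truth_samples[[1]])$phi_max, 1)
#>  r_fp  r_sp  d_fp  d_sp
#> 935.9 416.4   6.8  46.1
```

Reading the modes: the slow pathway — which carries 94 % of the conducted
beats here — recovers in about 0.36 s against a ground truth of 0.42 s, and
its total delay (55 ms per node × 10) is close to the truth. The
fast-pathway refractory period (1.29 s vs 0.94 s true) and the per-node
delays are recovered far more loosely: a pathway that conducts few beats
leaves little trace in the RR series, and delays largely cancel in
successive RR differences, so both carry wide credibility bands — which is
exactly the uncertainty information the posterior is there to expose. The
ABC stage ends below the best GA error by construction of its final
threshold (0.26 vs 0.48 above).

A staged, resumable pipeline (`avn_pipeline()` or
`inst/exec/avn-pipeline.R`) runs `synth → preprocess → fit-ga → fit-abc →
reduce → variability → report` against a run directory with manifests.

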