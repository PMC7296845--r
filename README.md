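# mabquant

Quantitative characterization of patient-derived monoclonal antibodies
(mAbs) against LGI1, the neuronal protein whose autoantibodies cause limbic
encephalitis. The package implements, at desk scale and driven entirely by
a synthetic-data generator with exact ground truth:

* **Internalization quantification** — per-frame robust normalization of
  pHrodo fluorescence stacks, `x' = (x − median) / MAD`, followed by the
  sum-above-threshold statistic `S_int = Σ x·[x > k]` with `k` the 99th
  percentile of the first four normalized frames (time-lapse) or of pooled
  control-antibody images (static); plus cluster counting and per-ROI
  positivity calls.
* **Equilibrium binding** — one-site hyperbola fits
  `y = Bmax·x / (x + Kd)` by damped least squares on log-parameters, with
  curvature-based standard errors.
* **End-point titres** — reproducible `mean(control) + 3·SD` positivity
  rule on dilution series, LRR:EPTP domain-titre ratios, Spearman
  correlation with exact/permutation p-values.
* **Epitope binning** — cross-competition normalization between the two
  assay anchors (`100·(control − raw)/(control − self)`; control
  preincubation = 0 % blocking, identical-mAb preincubation = 100 %) and
  inference of mutual-blocking groups, one-way blockers, and non-blockers.
* **Somatic hypermutation** — replacement vs silent V-region mutation
  counting under the standard genetic code, R:S ratios, and exact two-group
  comparisons.

Who it is for: anyone analysing live cell-based antibody assays
(internalization imaging, titrations, competition panels) who wants the
whole pipeline reproducible from seeds, with every stage testable against
planted ground truth — no microscopy or patient data required.

## Worked example

```r
library(mabquant)

# A 64x64, 12-frame stack: flat background + Gaussian noise, two clusters
# appearing at frames 6 and 8 with growing amplitude.
sim <- simulate_stack(stack_spec(64, 64, 12, background_noise_sd = 6, seed = 42,
  clusters = list(cluster_spec(c(20, 20), 4, 6, seq(40, 150, length.out = 7)),
                  cluster_spec(c(45, 40), 5, 8, seq(60, 160, length.out = 5)))))
quantify_timelapse(sim$stack)
#> <InternalizationResult> mode = time-lapse, k = 3.483, 12 frame(s)
#> S_int:  172.1  137.9  153.5  188.7  100.9  564.5  782.9 2101.0 2763.5 3449.1 4248.8 4991.3
```

`k = 3.483` is the 99th percentile of the four baseline frames on the
normalized scale. Frames 1–5 show only the noise tail's exceedance mass
(~1 % of pixels); from frame 6 the statistic climbs as the planted
clusters brighten — the signature of antibody internalization.

```r
curve <- simulate_titration(titration_spec(2, 500, c(0.25, 0.5, 1, 2, 4, 8, 16, 32),
                                           noise_sd = 10, seed = 42))
fit_one_site(curve)
#> <BindingFit> Kd = 1.959 (SE 0.0999) ug/ml, Bmax = 503.9 (SE 6.96) a.u.
#> rss = 393.3, converged = TRUE after 4 iteration(s)
```

The 2 %-noise curve generated with `Kd = 2`, `Bmax = 500` is recovered
within one standard error.

```r
infer_groups(build_matrix(simulate_blocking_matrix(competition_spec_default())))
#> <BlockingGroups> threshold = 50%
#>   group 1: mAb01, mAb02
#>   group 2: mAb03, mAb04, mAb05, mAb06, mAb07
#>   group 3: mAb11, mAb12, mAb13, mAb14
#>   non-blockers: mAb08, mAb09, mAb10
#>   one-way: mAb14 -> mAb12
```

The planted 14-mAb panel — two LRR epitope groups, one EPTP group with a
single one-way blocking pair, three non-blockers — is recovered exactly
from the raw fluorescence table.

```r
p <- simulate_ig_pair(igpair_spec(300, 6, 3, seed = 42))
count_mutations(p$germline, p$mature)
#> <MutationSummary> total 9 = 6 replacement + 3 silent + 0 unclassified
#> R:S = 2 (0 ambiguous codon(s))
```

## Command line

Every stage is scriptable via `exec/mabquant` (or
`mabquant_cli()` from R): `synth stack|titration|competition|igpair`,
`quant timelapse|static`, `fit kd`, `titre`, `compete normalize|groups`,
`shm count`. Runs with identical inputs and seeds are byte-identical; each
output directory contains a `log.json` with the full configuration.

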