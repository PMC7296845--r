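---
title: "Methods behind mabquant: models, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mabquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabquant)
```

## The problem

Patient-derived monoclonal antibodies (mAbs) against LGI1 — a secreted
neuronal protein bridging presynaptic ADAM23 and postsynaptic ADAM22 — are
characterized in live cell-based assays along several quantitative axes:
how strongly they bind (equilibrium binding), which of LGI1's two domains
(LRR, EPTP) they target and whether they share epitopes (cross-competition),
whether they drive internalization of the antigen into acidic endosomes
(pHrodo fluorescence over time), how serum reactivity titrates out
(end-point dilutions), and how somatically mutated their V regions are
(replacement vs silent mutations). `mabquant` implements each of these
analyses as a small, testable pipeline driven end-to-end by a synthetic-data
generator with exact ground truth.

## The internalization statistic

Each frame of a pHrodo time-lapse is first normalized robustly:

\[ x' = \frac{x - \mathrm{median}(x)}{\mathrm{MAD}(x)} \]

with the *raw* MAD (median absolute deviation, no 1.4826 consistency
factor; `mad_constant` makes this configurable). Centring before scaling is
the only order for which the normalized frame has median 0, so that is the
implemented order. The per-frame statistic is the sum of normalized
intensity strictly above a threshold \(k\):

\[ S_{\mathrm{int}} = \sum_x x \,[x > k] \]

with an Iverson bracket and *strict* inequality. In the time-lapse variant,
\(k\) is the 99th percentile of the pooled pixels of the first four
normalized frames (the first hour at 15-min intervals, before
internalization signal develops); in the static variant, \(k\) is the 99th
percentile of pooled images from a control-antibody condition. Percentiles
use linear interpolation between order statistics (type 7), configurable
among the standard quantile types since no convention is forced by the
assay.

Because each frame is normalized by its own location and scale, frame-global
affine changes — acquisition gain drift, uniform background shifts — cancel
exactly. This is the property the whole statistic is built around, and it is
asserted at `1e-9` relative tolerance on randomized stacks.

### Degenerate frames

A frame whose MAD is 0 (more than half its pixels share one value) cannot be
MAD-scaled. At the single-frame level `normalize_frame()` raises a classed
error and leaves policy to the caller. At the stack level the default
fallback is a *scale cascade*: MAD, then the mean absolute deviation from
the median, then (for truly constant frames) centring only. We deliberately
did not adopt the simpler centre-only fallback as the default: the mean
absolute deviation is still gain-equivariant, so the affine invariance that
motivates the normalization survives the degenerate case, whereas
centre-only scaling would make \(S_{\mathrm{int}}\) of a zero-noise planted
cluster scale with gain drift. This matters in practice because the
generator's exact zero-noise stacks — flat background plus hard disks — have
MAD 0 in *every* frame. Centre-only remains available
(`degenerate = "centre-only"`), and affected frame indices are always
reported in the result.

### Indexing

All indices exposed by the package are 1-based, the R convention: "the
first four frames" are frames 1–4, pixel coordinates are `(row, col)`
starting at 1, and a cluster with `onset_frame = 5` first appears in frame
5, so frames 1–4 are background-only.

### Cluster counting and ROI calls

Counting pHrodo-positive somatic clusters is, in the original assay, a
blinded human task. `count_clusters()` is an openly algorithmic surrogate:
threshold at \(k\), connected components (8-connectivity by default;
4-connectivity available), discard components under `min_area` (default
5 px), label deterministically in raster order. `classify_rois()` applies
the same \(S_{\mathrm{int}}\) within externally supplied per-cell masks and
calls an ROI positive when its statistic exceeds a threshold (default 0).

## One-site binding

Specific binding follows the one-site hyperbola
\(y = B_{\max} x / (x + K_d)\). `fit_one_site()` minimizes squared error by
damped (Levenberg–Marquardt) least squares on \((\log B_{\max}, \log K_d)\),
which enforces positivity without constraints; the analytic Jacobian is
used throughout. Starting values are \(B_{\max,0} = \max y\) and
\(K_{d,0}\) the smallest concentration reaching half of \(B_{\max,0}\).
Standard errors come from the Gauss–Newton curvature \(J^\top J\) at the
optimum with residual variance \(\mathrm{rss}/(n-2)\). The input `y` must
already be background-corrected; subtraction is the caller's duty. The test
suite checks noiseless recovery to `1e-6` relative error, scale
equivariance in `y`, unit equivariance in `x`, and — on 200 seeded 2%-noise
curves — that the median \(K_d\) error is no worse than a brute-force
profile-likelihood grid search on identical data.

## End-point titres and domain ratios

End-point titres were determined by eye in the original assay; the package
substitutes a reproducible rule: a dilution is positive when its signal
exceeds `mean(control) + 3 * sd(control)` (the rule object is pluggable,
including a fixed numeric threshold), and the titre is the largest
reciprocal dilution still positive. All-negative series give titre 0;
series positive at the final dilution are flagged `unsaturated`. Titres are
reciprocal dilutions (integers); ratios are floats. `domain_ratio()`
reports LRR:EPTP titre ratios, returning an explicit one-sided flag
(never infinity) when a domain titre is 0. `correlate_titres()` computes
Spearman correlation with mid-ranks and a permutation p-value — exhaustive
over all \(n!\) rank permutations for \(n \le 7\), seeded Monte-Carlo
otherwise — because the panels in this setting are small.

## Cross-competition and blocking groups

Raw fluorescence of a labelled second mAb after preincubation with a first
mAb is normalized linearly between two anchors: control-mAb preincubation
defines 0% blocking, full block defines 100%, so
`percent = 100 * (control - raw) / (control - self)`. Values are not
clipped to \([0,100]\); out-of-range values are informative noise
diagnostics. The ratio is computed before scaling so the two anchor
identities are floating-point exact.

One structural choice deserves explanation. The 100% anchor is *defined* by
preincubation with the identical mAb — but an antibody that fails to block
even itself would then have both anchors nearly equal and its column would
be unnormalizable. The package therefore treats the per-mAb `self_entries`
anchor as the full-block (assay background) reference of the labelled mAb,
which is measurable for every antibody, while the actual identical-mAb
preincubation appears as the diagonal of the measurement matrix. For
self-blocking antibodies the two coincide, so the printed anchor identities
hold exactly; for non-blockers the diagonal normalizes to about 0%, which
is precisely the signature `infer_groups()` uses to classify them.

Group inference: an edge joins two mAbs when both directions block at
`threshold` (default 50%, the midpoint of the anchors; membership is
monotone in this threshold — raising it never merges groups); groups are
connected components among self-blocking mAbs; pairs above threshold in
exactly one direction are recorded as one-way pairs and contribute no edge,
so a mAb stays grouped through its mutual relations while the asymmetric
direction is flagged.

## Replacement/silent mutation counting

`count_mutations()` compares aligned, gap-free germline/mature V-region
sequences codon by codon under the standard genetic code. Single-base
codon changes are replacement if the amino acid changes, silent otherwise.
Codons with several changed bases are counted as ambiguous codons; by
default (`"translate"`) their base changes are still classified by
translating the whole mutated codon against the germline codon (one event
per changed base, shared classification), while `"exclude"` leaves them
unclassified. `N`-containing codons are never classified; their differing
bases count only in the total. In every configuration
`replacement + silent + unclassified = total` holds exactly. The R:S ratio
is flagged undefined when silent = 0 rather than returned as infinity.
`summarize_cohort()` compares two groups by the absolute difference in
group medians (of total load or R:S), with an exact p-value by exhaustive
enumeration of group assignments when \(\binom{n}{n_1} \le 20000\) and a
seeded permutation otherwise; medians are compared because that is how
mutation loads in small mAb panels are reported.

## The synthetic-data generator

The generator states a world and sticks to it:

* **Stacks** — flat background (default 100 a.u.) plus additive Gaussian
  pixel noise (default SD 5 a.u., clipped at 0 since fluorescence is
  non-negative), hard-disk clusters with per-frame amplitude curves (held at
  the last value if the stack outlasts the curve), and an optional strictly
  positive frame-global gain drift. Hard disks make area/count ground truth
  exact; gain drift exists purely to exercise the normalization's scale
  invariance. Defaults: 15-min frame interval; stack length is a config
  choice (the assay fixes only the interval, not the duration).
* **Titrations** — exact one-site curves plus additive Gaussian noise,
  clipped at 0.
* **Competition** — raw signals at `signal_control` (1000 a.u.) or
  `signal_self` (50 a.u.) according to a planted group structure, plus
  noise. `competition_spec_default()` mirrors a published 14-mAb panel
  shape: two LRR groups (2 and 5 members), one EPTP group (4 members)
  containing one one-way pair, three non-blockers.
* **Ig pairs** — a stop-free random coding sequence with the requested
  numbers of silent and replacement point mutations planted in distinct
  codons (silent only where a synonymous single-base change exists;
  infeasible requests error).
* **Dilution series** — positive wells at the planted titre and above read
  a high signal, the rest background, both with noise.

Every generator is bit-identical under a fixed seed. What the generator
does **not** emulate: point-spread optics, photobleaching, cell morphology,
spatially structured background, focal drift, or repertoire-scale sequence
diversity. A green test therefore establishes algorithmic correctness
against the stated model — selection semantics, normalization algebra,
planted-truth recovery — not robustness to real microscopy artefacts.

## Numerical choices

* Percentile: type 7 (linear interpolation), configurable 1–9.
* Strict `x > k` everywhere, including ROI and cluster masks.
* Fit convergence: relative RSS decrease below `1e-12` or no downhill LM
  step; 200 iterations maximum.
* Threshold-monotonicity of \(S_{\mathrm{int}}\) is only claimed for
  \(k \ge 0\): below 0, negative normalized pixels enter the sum.
* Exact permutation enumerations switch to seeded Monte-Carlo above
  \(n = 7\) (Spearman) or \(\binom{n}{n_1} > 20000\) (cohort comparison).
* p-values from Monte-Carlo use the add-one estimator \((h+1)/(B+1)\);
  exhaustive enumerations report exact proportions.

## File formats

Stacks are 16-bit unsigned, little-endian, uncompressed multi-page TIFF
with a JSON sidecar for metadata; the codec is intentionally minimal and is
cross-validated in the test suite against an independent TIFF
implementation. Tables are strict comma-separated CSV with header rows and
`.` decimals (decimal commas are rejected loudly). Sequences are FASTA with
`_germline` / `_mature` record-name suffixes sharing an ID prefix.
Normalized (floating) frames are never written to TIFF; results are JSON.

## Known limitations

* The cluster counter is a surrogate for blinded human counting and is not
  validated against human raters.
* The end-point rule replaces visual calls; absolute titres depend on the
  chosen rule even though monotonicity does not.
* The TIFF reader handles only the narrow profile the writer emits (plus
  multi-strip uncompressed 16-bit pages).
* Noise is Gaussian-additive; Poisson photon statistics are not modelled.
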