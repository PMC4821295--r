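---
title: "Assessing transcription factor motif quality: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing transcription factor motif quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifbench)
```

## The assessment model

A PWM Θ for a motif of length $k$ assigns each window $S^t = S_{t..t+k-1}$ of
a sequence the occupancy probability

$$P(S^t \mid \Theta) = \prod_{j=1}^{k} \Theta_j[S^t_j],$$

and a sequence score aggregates windows. `motifbench` scans all $L-k+1$
windows of a length-$L$ sequence. (Some formulations write the product bound
as $L-k$, which silently drops the final window; this package always
includes it, matching the standard GOMER definition.) With
`strand = "both"` — the default for genomic sequences — the reverse
complement's windows enter the same aggregate, which makes every both-strand
score invariant under reverse-complementing the input.

Five scoring families are implemented:

* **GOMER** ($1-\prod_t(1-P(S^t\mid\Theta))$): the probability of binding at
  least one window under an independent-sites assumption. Because the
  product telescopes toward 1, the score is nondecreasing as a sequence is
  extended.
* **Occupancy aggregates**: sum, maximum and mean (average motif affinity,
  AMA) of the window occupancies. For a fully deterministic PWM the sum is
  exactly the count of consensus occurrences.
* **Binding energy**: per-position energies
  $\varepsilon(b,t) = -\ln(\Theta_t[b]/\max_{b'}\Theta_t[b'])$, so the
  consensus base costs nothing and every column's minimum is zero. The
  minimum window energy $E^*$ yields the Boltzmann binding probability
  $1/(1+e^{E^*-\mu})$. The chemical potential $\mu$ (default 0, so a perfect
  consensus match scores 0.5) shifts the sigmoid; it only rescales scores
  monotonically and therefore never changes AUC, MNCP or ranks.
* **Log-odds**: per-window $\sum_t \log_2(\Theta_t[b]/p_b)$ against a
  background $p$ (uniform 0.25 by default), aggregated by sum or by max.
  Log base 2 follows the MEME-suite convention; energies use the natural
  log of the Boltzmann form.

### Statistics

* **AUC** is computed in its Mann–Whitney form from midranks, which makes it
  exactly the fraction of (positive, negative) pairs won (ties count half)
  and guarantees $\mathrm{auc}(p,n)+\mathrm{auc}(n,p)=1$.
* **MNCP** ranks all $N$ scores in descending order; the $i$-th best
  positive at overall rank $r_i$ contributes $(i/n_{pos})/(r_i/N)$, and MNCP
  is the mean contribution. Random rankings give ≈1; a perfect ranking gives
  $N/n_{pos}$ (2.0 for balanced sets). Because early positives dominate the
  mean, MNCP is less sensitive than AUC to false positives deep in the
  ranking.
* **Pearson/Spearman** correlate motif scores of the positive set against an
  external signal (peak score, probe intensity); they need no negative set.
  Zero-variance input is an error, never a silent `NA`.
* **compare_configs** performs the two-sided Wilcoxon rank-sum test between
  two score vectors (e.g. AUCs under two window widths). It uses the exact
  distribution for small tie-free samples and the normal approximation with
  tie correction otherwise; fully tied inputs return $p=1$.

Both AUC and MNCP are rank-based, hence invariant under any strictly
monotone transform of the scores — this is why reporting $P(\text{bound})$
rather than raw minimum energy is purely cosmetic.

## Benchmark construction

Positive sets are fixed-width windows (50/100/250 bp are the conventional
choices; 100 bp default) centered on the midpoints of the top-$n$ peaks by
signal ($n = 500$ by default). ENCODE-style uniform peaks carry no summit
column, so the midpoint is the only computable center; a `summit_offset`
hook exists for callers with summit information. Peaks touching soft-masked
(lowercase) genome bases can be excluded before ranking, and score ties are
broken by (chrom, start) so selection is deterministic. Coordinates are
0-based half-open (BED convention) throughout.

Two negative-set constructions are provided:

* **Downstream**: for a positive window $[s,e)$ the negative is
  $[e+\delta,\, e+\delta+(e-s))$ with gap $\delta = 500$ bp by default,
  measured from the positive window end (the gap could equally be measured
  from the raw peak end; this choice is exposed via `offset`). Downstream is
  always "increasing coordinate" since uniform peaks are unstranded.
  Out-of-bounds negatives drop their paired positive too, keeping the sets
  matched in count and width.
* **Dinucleotide shuffle** of the positives (Altschul–Erickson Eulerian-path
  construction): preserves the exact multiset of overlapping dinucleotides,
  hence mononucleotide composition, plus the first and last characters. `N`
  is carried as a fifth symbol so dinucleotides involving `N` are preserved
  as well. The sampler draws a random "last exit" edge per vertex, accepts
  when those edges form a tree into the terminal vertex, and walks the
  Eulerian path — every valid shuffle is reachable. Per-record seeds are
  derived as `seed + record index`, so results are reproducible and
  insensitive to set order.

PBM probe tables (36 bp probes with intensities) are partitioned by an
intensity-quantile rule (top $q$ vs bottom $q$, default $q=0.05$) when no
explicit labels exist. No low-intensity probe filter is applied before
correlation statistics; the known fragility of Spearman on full arrays is
left visible rather than hidden by an arbitrary cutoff.

## Orchestration

`assess_tf()` computes every (motif, function, statistic, dataset) value,
averages over datasets *before* normalizing and ranking — the reverse order
changes results, and cross-dataset averaging of the raw statistic is the
convention for reducing cell-line-specific bias — and breaks rank ties
lexicographically by motif name for determinism. Motifs longer than the
sequence width are excluded with a warning and recorded in the result. A
motif's mean is taken over the datasets where it was scorable, with the
coverage count reported.

`crossranks()` gives the Spearman correlation of per-motif values between
scoring functions or between datasets; comparing negative-set constructions
is done by presenting the two constructions as two datasets.
`rank_databases()` represents each database within a TF by its best motif
*under the statistic being reported*, max-normalizes within the TF,
averages each database over the TFs where it appears, and ranks (ties share
the minimum rank). Max-normalization makes the ranking invariant under
rescaling any one TF's values by a positive constant.

`run_config()` drives all of this from a YAML file, validates every input
and option name before computing anything, and writes TSV reports plus a
JSON run log with no timestamps, so identical configs and seeds produce
byte-identical output. External enrichment values (e.g. from a motif
enrichment tool) can be merged downstream from the TSVs; no external tool
is ever invoked.

## Numerical choices

* **Zeros before logs.** Energy and log-odds lookups floor zero
  probabilities at a pseudo-probability of $10^{-3}$ and leave nonzero
  entries untouched, so a probability-1 base scores exactly
  $\log_2(1/0.25)=2$ bits. Probability-space scoring (GOMER, occupancy)
  uses the exact Θ; zeros are meaningful there.
* **`N` bases.** Probability-space scoring gives `N` the background
  probability 0.25; energy scoring skips windows containing `N` (a sequence
  with no scorable window returns `NA`); log-odds treats `N` positions as
  neutral (contribution 0).
* **GOMER in log space.** The complement product is accumulated as
  $\sum\log(1-P)$ via `log1p`, with an exact early return of 1 when any
  window has probability 1; window probabilities are clamped to $[0,1]$
  against floating-point overshoot.
* **Ties.** Midranks everywhere (AUC, MNCP, Spearman); ranking ties broken
  by motif name; peak-score ties by coordinate.
* **Degenerate inputs.** Sequences shorter than the motif, empty score
  classes, zero-variance correlations, non-column-stochastic matrices
  (beyond a $10^{-3}$ tolerance, below which columns are renormalized) are
  all errors that name the offending object.

## The synthetic fixture

The generator emulates the structure of a ChIP-seq benchmark so the whole
pipeline is testable without downloads. Its defaults define the package's
reference study: a 600 kb i.i.d. uniform-background genome, 500
non-overlapping peaks, a site sampled from the true motif implanted in 90%
of the central 100 bp windows (uniform offset, random strand), peak scores
proportional to site presence plus Gaussian noise, downstream negatives
500 bp away, and 9 decoy motifs (column permutations of the true motif with
Dirichlet perturbation, concentration $1/\text{magnitude}$).

The true motif is 10 bp, ~12.1 bits: a near-deterministic 7 bp core
(consensus probability 0.95) with degenerate 0.5-probability flanks,
mirroring how real TF motifs concentrate information in a core. Profile
matters: spreading the same total information content uniformly across
columns makes sampled sites so degenerate that recovery AUC drops to the
~0.90 boundary, while the core+flank profile keeps it at 0.90–0.94 across
seeds (MNCP ≈ 1.85–1.92, the true motif ranking first among the ten
candidates under GOMER, energy and all occupancy aggregates). The AUC
ceiling is ≈0.95, not 1, because 10% of positives carry no site. Sum
log-odds hovers near 0.5 on this benchmark — background windows swamp the
site contribution — reproducing qualitatively its known weakness.

The background is 0-order i.i.d. (not Markov) by design: downstream and
dinucleotide-shuffled negatives then have identical expected composition,
isolating the negative-set-choice effect from composition artifacts. PBM
emulation draws random 36 bp probes with intensity = single-strand sum
occupancy + Gaussian noise. Occupancy scores over random probes are
extremely heavy-tailed — a handful of probes contain a site — so at equal
signal/noise sd the Pearson correlation sits near $1/\sqrt2$ while the
full-array Spearman correlation is small; the tests assert this computed
behavior, including exact equality at zero noise.

What passing these tests does **not** show about real data: no nucleosome
or GC bias, no peak-shape or fragment-length structure, no repeat families
(masking is emulated by lowercase intervals), no indirect/cooperative
binding, and a single known true motif rather than a family of variants.
The fixture validates the machinery and the relative behavior of scoring
functions and statistics, not absolute performance levels on ENCODE-scale
data.

## Problem sizes

The test suite exercises the scoring engine against an independent
brute-force window enumerator on 1,000 random motif/sequence pairs (motif
lengths 4–20, sequence lengths 20–300, relative agreement $10^{-12}$),
verifies AUC by exhaustive pair counting up to $n=50$ and the Wilcoxon
p-value by exhaustive permutation enumeration up to 8 per group, checks
dinucleotide conservation on 1,000 length-100 shuffles, and runs the
full-size reference benchmark (500+500 windows, 10 motifs, 6 scoring
functions, both negative-set constructions). These sizes were chosen to pin
the mathematics tightly while keeping the default suite around a minute of
CPU.

## Known limitations

* Only the DNA alphabet A, C, G, T (with `N`) is supported; PWMs are
  0-order (no dinucleotide or higher-order extensions, no k-mer/SVR
  models).
* Only MEME minimal format and plain count matrices are parsed; convert
  other database formats upstream.
* No p-value calibration of scores and no ROC plotting beyond TSV points;
  no multiple-testing correction of Wilcoxon p-values (raw values are
  reported, matching common practice).
* Strand-aware extraction and liftover are out of scope; peaks are treated
  as unstranded.
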