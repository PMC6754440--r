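---
title: "Scoring candidate mRNA-associated proteins from oligonucleotide-capture MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring candidate mRNA-associated proteins from oligonucleotide-capture MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rnacap)
```

## The experimental design this package analyses

Antisense oligonucleotide capture isolates an endogenous mRNA together with
its bound proteins from a tissue lysate: a biotinylated DNA oligo
complementary to the target transcript is immobilised on avidin resin, the
lysate is passed over it, and the ribonucleoprotein complex is competitively
eluted with a non-biotinylated oligo. Mass spectrometry of the eluate yields,
for every identified protein, a *spectral count* — the number of MS/MS
spectra matched to its peptides — which serves as a semi-quantitative
abundance proxy.

Run alone, such a capture cannot distinguish a transcript-specific regulator
from a pan RNA-binding protein (one that coats most mRNAs) or from resin
background. The design therefore captures, in parallel, a housekeeping
control mRNA (*Actin* in the motivating experiments). Proteins abundant in
the control pulldown are pan binders or background; proteins abundant with
the bait mRNAs but absent from the control are candidate transcript-specific
regulators. `rnacap` implements the downstream arithmetic of this design:
the enrichment score, its exclusion/selection/highlight rules, the
RT-qPCR quality metrics of the capture itself, and the polysome-gradient
summaries used to interpret the candidate list.

## The enrichment statistic

Let $c_{i,r}$ be the raw spectral count of protein $i$ in control replicate
$r$, and $x_{i,b,r}$ its count in replicate $r$ of bait $b$. The procedure
is:

1. **Control-exclusion filter.** Protein $i$ is removed from consideration
   if *any single* control replicate count exceeds 11
   ($\exists r : c_{i,r} > 11$, strict). These are the pan RNA-binding and
   background proteins.
2. **Control denominator.** The control replicates are aggregated into one
   value $d_i$, by default their mean (configurable: sum or max). If the
   aggregate is exactly zero — the protein was never seen with the control
   mRNA — the denominator is replaced by **0.9**, a conservative value that
   prevents overestimating relative abundance, rather than by anything
   smaller. The substitution applies only to an exact zero, never to small
   nonzero aggregates.
3. **Weighted sums.** Each bait replicate count is divided by $d_i$ and
   summed per bait, $S_{i,b} = \sum_r x_{i,b,r} / d_i$, and the per-bait
   sums are added into a combined score $S_i = \sum_b S_{i,b}$.
4. **Selection and highlight.** Protein $i$ is a candidate when it survives
   the filter and $S_i > 9$ (strict). Among candidates, those with a *raw*
   bait replicate count above 10 in at least one replicate are highlighted
   as the strongest associations. Candidates are ranked by decreasing
   $S_i$, ties broken lexicographically by accession so output order is
   deterministic.

All three thresholds are strict inequalities; the boundary cases
($S = 9.0$, control count exactly 11) fall on the retained/rejected sides
exactly as stated, and the test suite pins them.

### Why the denominator is an aggregate

The experiments behind this procedure used two biological replicates per
bait but three for the control, so no one-to-one replicate pairing exists.
`rnacap` therefore aggregates the control replicates before dividing. The
mean is the default because it is invariant to the number of control
replicates; `sum` and `max` are one flag away
(`enrichment_config(denominator_policy = ...)`) for matching analyses that
pooled differently. The highlight rule operates on raw counts, not
normalized values, because it describes spectra actually observed rather
than the ratio statistic.

```{r}
counts <- matrix(
  c(20L, 15L, 0L, 1L, 0L, 0L, 0L),
  nrow = 1,
  dimnames = list(NULL, c("Tnp1_rep1", "Tnp1_rep2", "Tnp2_rep1",
                          "Tnp2_rep2", "Actin_rep1", "Actin_rep2",
                          "Actin_rep3"))
)
tab <- spectral_counts("Q91W50", "CSDE1", counts, control = "Actin")
score_table(tab)
```

An all-zero control gives denominator 0.9, so $S_{\mathrm{Tnp1}} =
(20 + 15)/0.9 = 38.9$ and the combined score $36/0.9 = 40$.

## Capture efficiency and specificity by $\Delta\Delta C_q$

The fraction of input mRNA recovered in the elution is measured by RT-qPCR
with the plain $\Delta\Delta C_q$ method at base 2: with
$\Delta C_q = C_q(\text{target}) - C_q(\text{reference})$ per sample and
$\Delta\Delta C_q = \Delta C_q(\text{elution}) - \Delta C_q(\text{input})$,

$$\text{percent of input} = 100 \times 2^{-\Delta\Delta C_q}.$$

Amplification efficiencies measured from standard curves
(`fit_standard_curve()`: OLS of mean $C_q$ against $\log_{10}$ input;
efficiency $= 10^{-1/\text{slope}} - 1$) are reported as diagnostics only —
efficiency-corrected quantification is deliberately out of scope, matching
the plain base-2 method the design uses. Technical replicates are averaged
on the $C_q$ scale, standard practice when replicate spread is a fraction
of a cycle. Capture *specificity* (`specificity_matrix()`) expresses each
transcript's reference-normalized elution abundance relative to the
captured transcript, so the captured transcript is exactly 1 and off-target
transcripts should be near 0.

## Polysome-gradient distributions

A sucrose-gradient fractionation separates mRNAs by ribosome load; with the
default 12-fraction collection, fractions 2–4 hold translationally inactive
mRNPs and monosomes while fractions 9–12 hold actively translated
polysomes. `fraction_percents()` expresses a transcript's signal as the
percentage per fraction relative to its sum across all fractions (so
percentages always total 100), `pool_share()` sums them over a named pool,
and `mean_profile()` averages per-replicate percent vectors with an SEM
using the sample (k−1) standard deviation — percentages are computed per
biological replicate and then averaged, which is what a per-fraction SEM
presupposes. Pool definitions are configuration, not constants, because
fraction numbering depends on the collection scheme.

## The synthetic-data generator

Nothing in the scoring arithmetic requires real data, so the package ships
a generator that plants ground truth for every stage:

* **Spectral counts** (`simulate_spectral_counts()`): five protein classes —
  `background`, `pan_rbp`, `bait1_specific`, `bait2_specific`,
  `shared_specific` — with per-class mean counts per sample. Counts are
  negative binomial with variance $\mu + \phi\mu^2$ ($\phi$ = `dispersion`,
  0 giving Poisson), then zeroed with a dropout probability to mimic the
  sparsity of spectral counting near the detection limit.
* **Cq tables** (`simulate_cq()`): the target's elution $C_q$ is offset by
  $\log_2(100/\text{recovery})$ cycles from its input $C_q$ with the
  reference held constant, plus per-replicate Gaussian cycle noise. On
  noiseless output `percent_of_input()` returns the planted recovery
  exactly.
* **Fraction tables** (`simulate_polysome()`): pool weights are spread
  uniformly (or by a supplied shape) over the pool's fractions, with
  optional multiplicative log-normal noise; `pool_share()` on noiseless
  output recovers the planted weights exactly.

### Default conditions and why

The default count model (2 baits × 2 replicates vs 3 control replicates,
50 proteins per class, dispersion 0.2, dropout 0.05) uses these per-replicate
means:

| class | bait 1 | bait 2 | control |
|---|---|---|---|
| background | 0.5 | 0.5 | 0.5 |
| pan_rbp | 20 | 20 | 30 |
| bait1_specific | 25 | 1 | 0 |
| bait2_specific | 1 | 25 | 0 |
| shared_specific | 25 | 25 | 0 |

The classes mirror the biology the filters assume: abundant pan RNA-binding
proteins (DDX4-like) dominate the housekeeping pulldown and must fall to
the control-exclusion filter; transcript-specific proteins — including
splicing-factor-like proteins shared by both baits — are absent from the
control, so their denominators take the 0.9 substitute; background
contaminants appear sporadically everywhere at sub-1 mean counts, the
typical 0–2 spectra of resin binders. The background mean sits well below
the bait-specific means because the ratio statistic is deliberately
sensitive when the control denominator is small: a background protein seen
a handful of times in the baits but once in three control runs already gets
a triple-digit-percent boost from a denominator of 1/3, and with background
means near 2 this pushes the false-positive rate beyond what any threshold
can contain. That sensitivity is a property of the published statistic, not
of the generator, and is the main caveat when reading low-scoring
candidates on real data.

With these defaults the planted-truth power check (20 seeds, metrics
aggregated as means over seeds, since per-seed values on 50-protein classes
carry binomial noise) gives sensitivity above 0.9, specificity above 0.95
and a pan-exclusion rate above 0.99 — this is the pipeline's operating
check on data it can control, not a claim about any real dataset.

### What the generator does not emulate

Peptide-level identification, database-search FDR, protein inference and
shared-peptide ambiguity, between-replicate batch effects, and correlation
between a protein's abundance in bait and control pulldowns. Passing the
planted-truth checks shows the arithmetic and thresholds behave as
specified under a realistic count model; it does not validate the
biological filter choices on real spectra.

## Numerical and design choices

* Exact strict inequalities, no tolerance, at all three thresholds — the
  rules are stated on integers and printed one-decimal scores, so fuzzing
  them would change the procedure.
* Ranking ties break by accession so repeated runs produce byte-identical
  output files; result TSVs print scores to one decimal (the convention of
  published candidate tables) while JSON summaries keep full precision.
* The 0.9 substitution is triggered only by an exact zero aggregate;
  degenerate inputs (empty control, non-positive denominator, all-zero
  polysome profile, fewer than 3 standard-curve points, zero dilution
  variance) are errors, not silent defaults.
* Missing count cells are errors unless `fill_missing = TRUE` explicitly
  declares that absent proteins mean zero spectra; silent zero-filling
  would hide malformed uploads.
* Reading deposited datasets with other column layouts is a matter of
  passing a modified `count_schema()`; the published supplementary
  dataset's exact layout is not fixed by the text, so the reader does not
  hard-code one.

## Problem sizes

The bundled checks run the full property suite (500-table brute-force
oracle equivalence, 20-seed power checks, 100–200-seed Monte-Carlo
recoveries) plus a 5,000-protein end-to-end enrichment run; together they
complete in well under a minute on a single CPU, so the suite is sized for
routine use, not overnight batches.

## Known limitations

* The weighted-sum score has no error model: it is a ratio of counts, and
  the package reports it as such rather than wrapping it in a significance
  statement the original procedure never made.
* Reproducing the published candidate table requires the deposited
  unfiltered dataset (ProteomeXchange PXD015384), which is not
  redistributable here; `reproduce_published_analysis()` runs the
  comparison — including the per-protein delta report and the search over
  denominator policies — once a local copy is supplied.
* $\Delta\Delta C_q$ assumes perfect doubling; measured efficiencies are
  surfaced so users can judge the assumption, but no correction is applied.
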