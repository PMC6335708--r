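---
title: "Methods and design of lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of lncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

`lncnet` packages the computational core of a de novo lncRNA study in a
non-model organism: a stepwise identification cascade over an assembled
transcriptome, co-expression inference between the retained lncRNAs and
the mRNAs with a permutation-validated correlation cutoff, transcript
structure comparisons, energy-weighted network assembly, and term
enrichment. This vignette explains the statistical model behind each
stage, the tunable parameters and their defaults, what the synthetic
study generator does and does not emulate, and the design choices made
where the method description left the design open.

## The identification cascade

The cascade removes each transcript at its **first** failing stage, so
the per-stage counts always partition the input — useful for the
"candidates before/after the classifier stages" bookkeeping that such
studies report.

| stage | rule | default |
|---|---|---|
| homology | ≥ 1 protein hit at E ≤ cutoff | 10⁻³ |
| length | length < minimum | 200 nt |
| ORF | longest stop-to-stop ORF ≥ cap | 100 aa |
| coding potential | id labeled "coding" by external classifier | pass-through if absent |
| domain | id present in domain hit table | pass-through if absent |

Design choices that were genuinely open:

* **The exclusion E-value.** Only one protein-search cutoff (10⁻³) is
  conventionally stated for annotation searches, so the exclusion stage
  reuses it; it is configurable (`filter_config()`).
* **Stop-to-stop ORFs.** ORFs are maximal stop-free codon runs bounded
  by stop codons *or sequence ends*, with no ATG requirement. This is
  deliberately conservative toward calling coding potential: a
  boundary-truncated reading frame still counts.
* **Both strands always.** Assembled transcript strand is unreliable, so
  all six frames are scanned regardless of the annotated strand.
* **N codons are never stops.** An ambiguous codon extends a segment.
  The alternative (treating N codons as breaks) would fragment real ORFs
  and manufacture spurious lncRNAs from low-quality sequence.
* **Boundary semantics.** "Longest ORF less than 100 aa" is kept;
  a transcript whose longest ORF is exactly 100 aa is removed. The
  suite pins this with sequences whose longest ORF is exactly 99 and
  exactly 100 aa.
* Ties across frames are broken deterministically (+ strand first, lower
  frame, leftmost segment), which makes reported coordinates
  reproducible; the tie-break never affects the length and therefore
  never affects filtering.

## Co-expression and the permutation null

Edges are Pearson correlations across the 16 libraries of
`log1p(normalized counts)`, retained when |r| ≥ 0.95 **and** the
two-sided p-value of the t approximation (df = n − 2) is below 0.05.
Three open points and how they were resolved:

* **Inclusive threshold.** Method descriptions alternate between
  "exceeded 0.95" and "≥ 0.95"; the inclusive reading is implemented
  (`pcc_threshold` is compared with `>=`).
* **Which expression scale.** The original description says only
  "expression value". Correlations are computed on `log1p` of
  median-of-ratios–normalized counts by default: the log stabilizes the
  negative-binomial variance and keeps a handful of very high counts
  from dominating the correlation. `log_transform = FALSE` gives the
  untransformed alternative.
* **The p-value method.** Unstated in the original; the t approximation
  is standard, cheap, and validated in the test suite against a 10⁶-draw
  permutation estimate (the two agree within Monte-Carlo error for
  r ∈ {0.3, 0.6, 0.9} at n = 16). Raw p-values gate edges; BH
  adjustment (`bh_adjust()`) is available but deliberately not applied
  to edge calling, matching the original convention.
* **Constant vectors.** A transcript with identical values in all
  libraries has no defined correlation. Such pairs are excluded and
  *counted* (`n_undefined` attribute) rather than silently propagated as
  `NaN` — silent propagation is the main corruption risk in an
  all-against-all scan.

`permutation_validate()` implements the individualized permutation test:
per repetition, `n_lncrnas` (default 100) lncRNAs are sampled without
replacement, each sampled lncRNA's library vector is permuted
independently (a shared-permutation variant is available by flag — the
independent reading is the natural one for "randomly permutated" per
transcript), correlations against every mRNA are pooled over
`n_repetitions` (default 1000) repetitions, and the proportion of
|r| ≥ threshold is reported. The whole procedure is driven by one seed
and is bit-reproducible. On independent Gaussian expression the pooled
proportion must follow the analytic t tail, and the suite checks this at
thresholds 0.5/0.6/0.7 with a pool of 500 lncRNAs × 200 mRNAs: pools of
that size keep the reuse of vectors across repetitions from inflating
the variance beyond the binomial band used in the check.

## Network assembly

The network is strictly bipartite (an id on both sides is an error, not
a warning, because it invariably indicates an id-mapping bug upstream).
Aggregate hybridization energy per pair — SUMENERGY — is interpreted as
the **sum of magnitudes** of per-site energies. The upstream convention
only fixes the log10 display bins, all of which are positive, which
motivates the magnitude default; `abs_sum` (magnitude of the signed sum)
and `min_site` (magnitude of the most favorable site) are available.
Bins are lower-inclusive: thin (log10 < 1), dotted (1 ≤ log10 < 2),
thick (log10 ≥ 2). A non-positive aggregate falls back to thin with a
warning rather than erroring, so one degenerate record cannot abort a
network build.

`naive_duplex_energy()` is test plumbing only: a sliding
reverse-complement match scored as match length × a constant. It exists
so the energy path can be exercised without an external RNA–RNA
interaction predictor and is labeled non-physical; do not use it for
inference.

## Transcript structure

Internally all coordinates are 0-based half-open; GTF I/O converts
from/to 1-based inclusive exactly. The five splicing modes are defined
on exon chains of two isoforms of one locus (loci = connected components
of same-strand exonic overlap):

* *intron retention*: an exon of one isoform covers an intron of the
  other plus at least one nucleotide of each flanking exon;
* *exon skipping*: an internal exon of one isoform, absent from the
  other, with both flanking exon boundaries shared;
* *alternative donor/acceptor*: two introns sharing exactly one
  boundary, with the flanking exons at the differing boundary
  overlapping — the overlap requirement prevents the flanking introns
  of a skipping event from also being miscalled as alternative splice
  sites. Labels are strand-aware: the genomic-left intron boundary is
  the donor on +, the acceptor on −.
* *mutually exclusive exons*: one internal exon per isoform, mutually
  non-overlapping, each absent from the other, between shared flanking
  boundaries.

Every qualifying pair emits an event; for mode *distributions* events
identical in (locus, mode, coordinates) are deduplicated by default,
since a distribution counts event types, not isoform pairs
(`dedupe = FALSE` reverts).

Cross-status transcript identity uses a canonical structure key: the
intron chain (with chromosome and strand) for multi-exon transcripts,
exact exon coordinates for mono-exon ones. Independent assemblies of the
same locus rarely agree on terminal exon ends, so the intron chain is
the stable part of the structure; mono-exon transcripts have nothing but
their coordinates.

## Enrichment

`ease_score()` computes the hypergeometric upper tail P(X ≥ k) and its
EASE variant — the same tail at k − 1, i.e. with one overlapping member
removed — so `ease_p ≥ fisher_p` always, and k ≤ 1 forces
`ease_p = 1`. Significance defaults to raw EASE ≤ 0.05 (the DAVID-style
convention); BH adjustment is available. The module takes any
annotation table plus an explicit background (for the motivating study,
the Swiss-Prot–annotated transcripts); term content is user data, not
code.

## The synthetic study generator

`simulate_study()` emulates the 16-library design: two conditions ×
three time points with 3/3/2/2/3/3 replicates.

* **Sequence classes.** Coding-designed transcripts embed a stop-free
  ORF (default 110–250 aa) between stop codons and carry strong
  homology hits (E ≤ 10⁻⁶); noncoding-designed transcripts interleave
  ≤ 150-nt random filler with the cassette `TTAATTAATTAA`, which is its
  own reverse complement and contains a stop codon in every frame, so
  every stop-free run is below ~58 aa *by construction* — the classes
  are separable and the cascade must recover the planted set exactly.
  A tenth of the noncoding set receives decoy hits above any sensible
  exclusion cutoff so the homology threshold is actually exercised.
* **Counts.** Negative binomial (default dispersion 0.05, a typical
  well-controlled biological replicate level) around log10-uniform base
  means (default 10^1.5–10^3.5), modulated per library by a latent
  log-normal factor. Background transcripts use a modest latent SD
  (0.1): real transcriptomes are mostly quiet, and planted expression
  shifts must be detectable above within-group variability.
* **Planted pairs.** Each planted lncRNA–mRNA pair shares a latent
  Gaussian factor with SD 3 (natural log) — strongly co-modulated,
  well-expressed transcripts (base means from the top 0.3 decade, with
  median-preserving modulation so typical counts stay high). The factor
  loading is inflated analytically so the *expected log-expression
  correlation* equals `planted_latent_correlation` after counting noise,
  clamped at 1 where the target is unreachable. Even with perfect
  planting, the sample correlation over 16 libraries has Fisher-scale
  SD ≈ 0.28, so a pair planted at 0.99 falls below 0.95 with
  probability ≈ 0.002 — recovering *every* one of 50 planted pairs
  therefore fails for an occasional seed; this is intrinsic to n = 16,
  not a defect.
* **Planted DE.** Default |log2 FC| = 2 in the infected 4-h libraries
  only, planted among well-expressed transcripts (upper half of the
  mean range, below the planted-pair abundance band so the two planted
  populations do not share a dispersion-trend neighborhood). The DE
  table is produced by a real two-sample exact negative-binomial test
  (TMM-normalized, robust dispersion estimation) with BH adjustment —
  not by setting p = 0 — so downstream multiple-testing behavior is
  exercised realistically. Strongly co-modulated pair members can
  legitimately be called DE by that test; they genuinely differ between
  groups in any finite sample.
* **What it does not emulate.** Read-level noise, alignment and
  assembly artifacts, batch effects, library-size trends,
  mean-dispersion trends, or the correlation structure of a real
  regulatory network. Passing tests therefore demonstrate correctness
  of the *computations* under a controlled model, not performance on
  real coral data.

All randomness flows from one config seed through per-purpose derived
seeds (sequences, counts, energies, annotation), so each layer can be
regenerated independently yet reproducibly; the same scheme gives each
pipeline stage its own derived seed.

## Pipeline, determinism and problem sizes

`run_pipeline()` runs filter → structure → coexpress → network → enrich,
writing each stage's artifacts before the next starts, and finishes
with a JSON manifest of MD5 checksums; the same configuration and seed
give byte-identical outputs (the coexpress stage re-reads its own edge
table from disk before handing it onward, so resumed and full runs see
bit-identical numbers). `resume = TRUE` skips stages whose outputs match
the previous manifest and invalidates everything downstream of the
first recomputed stage. Status presence for the overlap analysis is
defined as a positive count in at least one library of the status — a
proxy for per-status assembly, which the package does not perform.

The test suite sizes were chosen to give sharp statistical checks at
interactive runtimes: the cascade exactness check runs on 1,000 + 1,000
transcripts; the edge-recovery check on 50 planted pairs among 72,000
scanned pairs; permutation calibration pools 2 × 10⁷ null correlations;
the p-value oracle uses 10⁶ permutation draws over 50 Gaussian bases
(averaging over bases makes the estimator exactly unbiased for the
t tail, since a permuted Gaussian sample is again a Gaussian sample).

## Known limitations

* The ORF scanner is plain R; for millions of transcripts a compiled
  scanner would be preferable. At the tested scales (thousands) it runs
  in seconds.
* Alternative-splicing classification is pairwise and reports the five
  canonical modes only; complex events spanning more than two isoforms
  are reported as their pairwise projections.
* `aggregate_energy()` trusts the upstream predictor's site definitions;
  it does not model accessibility or seed–extension energetics.
* The permutation test reuses the observed library vectors; with very
  few libraries its null is discrete, and below n ≈ 5 the pooled
  proportions become visibly granular.
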