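---
title: "Methods: ceRNA network inference with cernaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference with cernaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The competing endogenous RNA (ceRNA) hypothesis holds that lncRNAs and
mRNAs sharing miRNA response elements compete for a common miRNA pool, so
that a sponging lncRNA and a protected mRNA co-vary positively while each
varies against the miRNA. In whole-transcriptome studies of plant stress
and senescence this is operationalised as a filter cascade over three
expression matrices measured on the same libraries:

1. every member of a candidate (lncRNA, miRNA, mRNA) triplet must be
   differentially expressed between the conditions of interest;
2. the miRNA must have a predicted binding site on both the mRNA and the
   lncRNA;
3. the miRNA must be rank-anticorrelated with both targets
   (Spearman SCC < −0.7, strict);
4. lncRNA and mRNA must be linearly co-expressed (Pearson PCC > 0.9,
   strict);
5. the mRNA must belong to the phenotype-associated co-expression module.

`cernaforge` implements this cascade end to end for the 2-genotype ×
3-leaf-position × 3-replicate design (18 libraries), plus the surrounding
machinery: normalisation, a documented differential-expression surrogate,
lncRNA positional classification, the small-RNA clean-tag filter, a
rule-based plant miRNA target engine, and WGCNA-style module detection.

## Differential expression surrogate

Dispersion-shrinkage count models are deliberately out of scope: lists of
differentially expressed genes from a particular data set are data-dependent
and not a contract this package can promise. What the pipeline needs from a
DE caller is its *threshold semantics* and known operating characteristics.
The surrogate is Welch's two-sample *t* on `log2(x + c)` with pseudocount
`c = 1` on the normalised (FPKM/TPM) scale, BH adjustment within each
contrast, and the class rules: mRNA/lncRNA significant at `q < 0.05` with
`|log2FC| ≥ 1`; miRNA at raw `p < 0.05` with `|log2FC| ≥ 1`. Published
descriptions of this workflow state the miRNA cutoff both as `p < 0.05` and
`p < 0.07`; the default follows the stricter value and the other is an
argument. "Fold change ≥ 2" and "|log2FC| > 1" are treated as the same rule,
applied boundary-inclusive as `|log2FC| ≥ 1`.

On the generator's count mode (Poisson sampling around abundance-scale
means, baselines 2^5–2^10 counts, log-normal noise σ = 0.15, n = 3 vs 3) the
suite measures an empirical type-I rate within [0.03, 0.07] at α = 0.05 and
sensitivity ≥ 0.9 for planted |log2FC| = 2, with no wrong-sign calls; these
are recomputed, not quoted, by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

## lncRNA classification

Candidates (≥ 200 nt spliced, boundary inclusive) receive exactly one of
five positional labels under a fixed precedence: `sense_overlapping`
(exon-level overlap with a coding exon, same strand) > `antisense`
(exon-level overlap, opposite strand) > `intronic` (fully contained in a
coding intron, no exon overlap) > `bidirectional` (no overlap; divergent
head-to-head promoter within 1,000 bp of an opposite-strand coding TSS) >
`intergenic`. The five names are standard; the exon-level-overlap reading
and the 1-kb bidirectional window are declared conventions of this package
(both configurable), since the taxonomy's boundary cases are rarely written
down. Labels are strand-flip covariant: inverting a lncRNA's strand swaps
sense_overlapping with antisense. The cis-neighbour search returns coding
genes whose span intersects the half-open window `[start − w, end + w)`
with `w = 10 kb` by default.

## Small-RNA filter cascade

Reads are removed by the first failing rule, which makes the report sum
exactly (`input = output + Σ removals`): (1) low quality — more than 50% of
bases at Phred Q ≤ 20, mirroring the fraction used by the companion
mRNA-seq quality rule; (2) 3′ adapter not found — the adapter is located by
its longest exactly-matching prefix (≥ 6 nt) and trimmed before any length
test; (3) 5′ adapter present in the insert; (4) trimmed insert outside the
18–30 nt tag window (the window is applied *after* trimming — the natural
reading, adopted as a stated decision); (5) polyA — a run of ≥ 8 consecutive
A. A `long` bin exists so the upper length bound and the conservation
identity can both hold; it is normally zero. Because clean tags are already
trimmed, the cascade is idempotent on its own output for every content rule;
re-filtering trimmed tags requires waiving the adapter-presence rule
(`require_adapter3 = FALSE`). Quantification is exact-match (T/U-insensitive)
against the catalog — the strictest reproducible assignment policy — with
non-matching tags tallied as `unassigned`.

## Target engine

The duplex model is gapless and antiparallel: miRNA position *i* (1-based
from the 5′ end) pairs with window position *L + 1 − i*. Wobbles (G:U)
score 0.5 and true mismatches 1.0. Ruleset A: score ≤ 4; no run of more
than two mismatch events; no adjacent mismatch pair within positions 2–12;
positions 10–11 paired; score over positions 1–12 ≤ 2.5; energy ratio
≥ 0.74. Ruleset B tightens the positional rules (no two consecutive
mismatch events anywhere; no mismatch event at positions 2–12) and relaxes
the energy threshold to 0.60. Whether a wobble counts as a "mismatch event"
for the positional rules is genuinely ambiguous in the field's informal
rule lists; the default counts it (a single consistent reading), and
`gu_positional = FALSE` gives the other reading.

No thermodynamic parameter set accompanies the published rule lists, and
the rule is a *ratio*, not an absolute energy. The engine therefore uses a
simple additive per-pair model (G:C −3, A:U −2, G:U −1, mismatch 0,
arbitrary units) applied identically to the duplex and to the perfect
complement; the constants are configuration and a nearest-neighbour model
can be plugged in behind the same contract without changing any rule.

Scanning evaluates every window. For speed, candidate windows are first
located with `Biostrings::vmatchPattern` against the miRNA's reverse
complement at `max.mismatch = 8`: any window with weighted score ≤ 4 has at
most 8 raw mismatches (worst case, eight wobbles), so the prefilter is
lossless for both rulesets; the test suite verifies exhaustive equivalence
against an independent window-by-window scorer.

## Co-expression modules

The module stage follows the weighted co-expression recipe with the study's
parameters: variance pre-filter dropping the 45% lowest-variance genes
(variance on the log2 scale, deterministic tie-break by id — the published
workflow states only "approximately 45%", and variance ranking is this
package's declared convention), unsigned soft-threshold adjacency with
power β = 8 (the companion text also mentions 7; both are one argument
away), the standard unsigned TOM, average-linkage clustering on `1 − TOM`,
minimum module size 50, and eigengene merging at dissimilarity 0.85 (taken
literally; the community default of 0.25 is reachable via `merge_cut`).

Two deliberate departures from common practice, both because determinism
and testability matter more here than squeezing out module resolution:

* **Static cut instead of dynamic tree cut.** The dynamic algorithm is
  unpublished in the workflow descriptions this package follows. The static
  cut height defaults to a fixed dissimilarity of 0.95: uncorrelated genes
  sit near `1 − TOM = 1`, so a cut just below that isolates genuine
  topological structure, behaves identically across instance sizes, and —
  unlike a quantile-of-merge-heights rule — does not move when the
  background grows. The height is configurable.
* **Deterministic eigengene orientation.** The first principal component's
  sign is arbitrary; eigengenes are oriented to correlate non-negatively
  with the mean member profile so tests and merges are reproducible.

Module labels follow the conventional colour order by size (largest =
`turquoise`), with `grey` reserved for unassigned genes. Module–trait
association correlates each eigengene with indicator traits (each
genotype × leaf group, each leaf, and the mutant genotype), with the usual
*t*-approximation p-value; the pipeline's "senescence module" is the one
whose eigengene best tracks the mutant second/third-leaf groups.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions every planted-structure check runs under.

* **Design**: 18 samples (2 genotypes × 3 leaf positions × 3 replicates).
* **Expression model**: log-normal around group means (σ = 0.15 on the log2
  scale). Log-normality keeps the planted correlations analytic; a count
  mode (Poisson around the abundance means) exists because the DE
  surrogate's operating characteristics must be measured on count-like
  noise.
* **Planted DE**: genotype-wide |log2FC| = 2 with alternating sign — a
  margin above the calling threshold of 1, as a recovery test requires
  (the generator refuses planted effects below 1.5).
* **Planted modules**: two 60-gene blocks driven by orthogonal sample
  patterns — a senescence pattern (high only in mutant second/third leaves,
  amplitude 3) and a genotype-crossed leaf contrast (amplitude 2) — with
  per-gene noise 0.5, giving within-module pairwise correlation ≈ 0.9.
  Orthogonality matters twice: unsigned adjacency would fuse
  *anti*-correlated patterns, and eigengene merging at dissimilarity 0.85
  would fuse *positively* correlated ones.
* **Planted triplets**: each triplet shares a latent profile (senescence
  pattern, amplitude 3, plus per-sample jitter of sd 0.35 shared within the
  triplet); mRNA and lncRNA add it, the miRNA subtracts it. The jitter is
  the graded component that keeps *rank* correlations high within groups;
  its size balances two pulls — larger jitter strengthens SCC, smaller
  jitter keeps the members' group contrasts strong enough that all three
  are called DE. At the defaults the planted pairs clear SCC < −0.7 and
  PCC > 0.9 in ≥ 95% of generator runs (measured, not assumed, by the
  suite). Triplet miRNAs are placed in the well-expressed range
  (2^7–2^8 expected read counts) so that Poisson read sampling in the
  library simulator does not erode their rank coherence — the realistic
  regime for miRNAs that make it into a ceRNA network.
* **Binding sites**: planted sites are perfect reverse complements
  (optionally with benign wobbles); six decoy pseudo-triplets carry the
  full expression structure *and* near-sites that each violate exactly one
  prediction rule (r1: nine spread wobbles, score 4.5; r2: a run of three;
  r3: an adjacent 5′ pair; r4: a mismatch at position 10; r5: 3.0 mismatch
  score in positions 1–12; r6: seven wobbles at G positions of an AU-rich
  carrier, ratio ≈ 0.71). Decoy carrier miRNAs have the base composition
  each template needs. The templates are defined for ruleset A: under
  ruleset B's stricter positional rules the energy budget reachable outside
  positions 2–12 cannot push the ratio below 0.60 while the other rules
  pass, so a "violates only rule 6" decoy does not exist there — a property
  of the rule system, not a generator limitation.
* **Small-RNA libraries**: clean reads are miRNA sequences flanked by the
  3′ adapter at Phred 40 (Phred+33 encoding), with contaminant classes
  generated in exactly the counts requested, each engineered to fail
  exactly its rule. miRNA catalog sequences are rejection-sampled to avoid
  the adapter's 6-nt seed and polyA runs, which would otherwise confound
  the filter.
* **Determinism**: a single integer seed drives every stage through
  `withr::with_seed`; equal seeds give identical output.

What the generator does **not** emulate — and what green tests therefore do
not show about real data: sequencing-depth-driven mean–variance
relationships beyond Poisson, batch and lane effects, isoform structure and
ambiguous multi-mapping, coding-potential ambiguity of lncRNA candidates,
miRNA families with shared seeds, imperfect or bulged binding sites, and
any biological correlation structure beyond the planted blocks. Recovery
results on synthetic data certify the *machinery* (thresholds applied as
stated, no leakage between stages, decoys rejected for the stated reason),
not the biological error rate on a real transcriptome.

A note on an inherent coupling: planted DE features share a common genotype
response, so they are themselves strongly co-expressed and legitimately
form network structure. Module-recovery checks therefore run on instances
without genotype-DE features; in full-study runs the DE-driven cluster is
simply additional true structure the module stage may report.

## Numerical and degenerate-input choices

* Correlations of constant profiles return `NA` (an undefined marker), and
  ceRNA filtering treats `NA` as failing the threshold — never as ±1.
* Spearman uses mid-ranks for ties (the standard definition).
* Hypergeometric tails come from `phyper` in log space, so deep enrichment
  does not underflow; BH is `p.adjust`'s step-up rule.
* Degenerate DE rows (zero variance in both groups) get p = 1 when the
  means agree and p = 0 when they differ.
* Welch's *t* is computed vectorised over features and verified against
  `stats::t.test` in the tests.
* Thresholds are strict inequalities where the workflow prints them as
  strict (SCC < −0.7, PCC > 0.9); length and fold-change screens are
  boundary-inclusive where the phrasing says "≥".
* The ceRNA step's published phrasing is ambiguous about which pair types
  the SCC filter governs; this package applies SCC to miRNA-vs-target pairs
  for both target classes and PCC to lncRNA–mRNA pairs — the only reading
  in which the two steps are non-redundant. Module intersection applies to
  the mRNA; requiring the lncRNA too is a flag (`require_lnc_in_module`,
  off by default), since published networks do not state it.
* Gene order never matters: module detection sorts genes internally, and
  enrichment results are independent of term-map row order.

## Problem sizes

The test suite and acceptance script run at sizes chosen to exercise every
code path at full fidelity: the end-to-end pipeline at 2,000 mRNAs / 300
lncRNAs / 100 miRNAs / 18 libraries; DE operating characteristics over 50
replicate simulations of 250 features; module recovery on two 60-gene
blocks over a 300-gene background; oracle equivalence for the target engine
on 50 random transcripts × 5 miRNAs under both rulesets. These sizes are the
package's own validation design; all scale linearly (quadratically for TOM)
if enlarged.

## Known limitations

* The DE surrogate is not a negative-binomial model; at very low counts its
  power drops and its size can drift from nominal. It is a stand-in with
  known, measured behaviour, not a DESeq2/edgeR replacement.
* The energy model is additive per pair; absolute energies are meaningless
  and only the ratio is interpreted.
* Static tree cut trades module resolution for determinism; deeply nested
  module structure will be under-split relative to dynamic cutting.
* Coding-potential assessment (CPC/CNCI-style) is out of scope; candidates
  must arrive with a `lncRNA_candidate` biotype from upstream.
* Enrichment operates on user-supplied term maps; no ontology topology is
  used.
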