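---
title: "lncSigMatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncSigMatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncSigMatch)
options(lncSigMatch.verbose = FALSE)
```

This vignette documents the statistical machinery of `lncSigMatch`, the
choices that were genuinely open when the package was designed, and what
its synthetic-data experiments do and do not demonstrate.

## The problem

Long non-coding RNAs (lncRNAs) change expression under small-molecule
perturbation, which makes them usable as signatures for connecting drugs
to diseases. Large perturbation compendia, however, were profiled on
coding-gene microarrays. The package therefore works in three stages:
reannotate the array's probes to lncRNA genes, build per-drug lncRNA
signatures from treatment/control instances, and match a disease query
against those signatures with two enrichment engines.

## Probe reannotation

A probe is a short fixed-length oligo (`probe_length`, default 25 nt, the
3'-array standard). The filter chain is:

1. **Exact matching.** Every full-length, mismatch-free occurrence of a
   probe in a transcript is a hit. Matching uses a precompiled
   Biostrings dictionary, which is exhaustive — identical to sliding the
   probe along every transcript position. Because only perfect
   full-length matches survive, a BLAST-style e-value cutoff can remove
   nothing further; `evalue_cutoff` is retained as an inert provenance
   parameter rather than an active filter.
2. **Cross-biotype exclusion.** A probe with *any* hit to a
   protein-coding transcript is removed entirely, including its lncRNA
   hits: such a probe measures a mixture and cannot be attributed to a
   lncRNA.
3. **Gene-level collapse.** Hits to several isoforms of one gene count
   once. A probe hitting two distinct lncRNA genes is ambiguous; the
   `drop_multi_gene` policy discards it (with a logged count). Keeping
   it under either gene would bias both gene estimates, and the loss is
   negligible at 25 nt specificity.
4. **Minimum support.** Genes with fewer than `min_probes_per_gene`
   (default 3) surviving probes are dropped: a one- or two-probe summary
   is too fragile for fold-change estimation.

Strand handling is genuinely underdetermined by probe files in the wild
(sense vs antisense storage differs by vendor pipeline), so `strand_mode`
defaults to `both` — a probe matches if it or its reverse complement
occurs — and can be restricted to either orientation. Gene assignment
comes from the annotation table (`transcript_id -> gene_id`), not from a
genomic alignment; that table carries exactly the information the
gene-level step consumes.

Every stage records provenance counters satisfying
input = retained + removed, so a map is auditable after the fact.

## Signatures and drug-induced lncRNA sets

Probe-to-gene summarization is the median (default; robust to a single
aberrant probe) or mean of the gene's probe values per sample, on log2
scale. Vendor preprocessing chains are deliberately out of scope: any
log2 intensity matrix is accepted, pre-summarized or probe-level.

For an instance, `log2fc = mean(treatment) - mean(control)`. The mean
(not median) of controls is used as the standard contrast for the small
control counts typical of perturbation instances. A gene is a DEL when
`|log2fc| >= log2(fc_threshold)`. The threshold is applied exactly:
log2(1.5) = 0.58496..., and 0.58 is treated as the rounded display value
only — using 0.58 itself would admit genes in the [0.58, 0.585) boundary
band. Per drug, the member set is the unsigned union of its instances'
DELs; direction-restricted sets remain available via `del_direction`,
but the unsigned union is what the enrichment engines consume.

## ORA

The upper-tail hypergeometric p-value is computed as the tail sum
`P(X >= r)` in log space (`lchoose` + log-sum-exp). Summing the upper
tail directly, rather than one minus the lower tail, keeps small
p-values at full relative precision; invalid index combinations fall out
naturally as `-Inf` log terms. q-values are Benjamini–Hochberg by
default (Benjamini–Yekutieli as an option); "FDR-corrected" does not by
itself pin a procedure, and BH is the field's default step-up.

The universe `m` defaults to the genes of the reannotation map — the
measurable lncRNA universe — and is overridable. Query and sets are
intersected with the universe before counting; out-of-universe
identifiers are logged, and an empty post-intersection query is an
error rather than a silent p = 1 table.

## LSEA

Genes are ranked between the two phenotype classes. The default metric
is signal-to-noise, `(mu1 - mu0) / (s1 + s0)`, with each class standard
deviation floored at `max(0.2 |mu|, 0.2)`; the floor prevents
near-constant genes from dominating the ranking by vanishing
denominators. Welch t and difference-of-means are alternatives, and
metrics needing within-class variance fall back to difference-of-means
(logged) when a class has a single sample. Ties in scores are broken
lexicographically by gene identifier so rankings are deterministic.

The running sum walks the ranked list: with `weight_exponent = 0`, hits
add `1/Nh` and misses subtract `1/(N - Nh)`, so the walk ends exactly at
zero; with `weight_exponent = 1` (default) each hit adds its absolute
ranking score over the summed absolute hit scores. ES is the signed
value of maximal absolute deviation; when the hit scores are all equal,
the weighted walk collapses onto the unweighted one. If every hit score
is exactly zero, weights degenerate and the implementation falls back to
equal hit increments. The unweighted statistic is the plain
textbook running sum; the weighted one is the modern GSEA default, and
both are first-class here.

**Null model.** Phenotype permutation (relabel samples uniformly at
random, re-rank, recompute every ES) is the default: it preserves
gene-gene correlation and is the recommended null when both classes have
at least 7 samples. Below that, the permutation space is too small and
`gene_set` mode — random member sets of equal size drawn on the observed
ranking — is the appropriate fallback; requesting phenotype permutation
with fewer than 2 samples in a class is an error that names the
alternative. All permutation randomness derives from `params$seed`, so
results are exactly reproducible.

**Normalization and testing.** Per set, NES divides ES by the mean
absolute null ES of matching sign; the nominal p is the add-one tail
fraction among matching-sign nulls, `(1 + #{null >= es}) / (1 + #null)`,
which can never be zero. A set whose sign has no null samples gets an
undefined NES, is flagged, and ranks last. FDR q is the GSEA-style
sign-stratified ratio of pooled-null to observed tail fractions, clipped
to [0, 1] and made monotone (a more extreme NES never receives a larger
q); BH on nominal p is available instead. FWER p is the add-one fraction
of permutations whose maximum absolute null NES reaches |NES|, floored
at the set's own nominal p: the two add-one estimators have different
denominators, and without the floor their discreteness could make the
family-wise estimate look more significant than the per-set one, which a
family-wise bound must not do.

One symmetry caveat: swapping the 0/1 labels negates every observed ES
exactly, but a permuted walk can attain its maximal deviation at both
+x and -x simultaneously (the unweighted walk is lattice-valued); the
first extremum is kept, so a handful of null values may flip sign
rather than negate under the swap. Significance orderings are
unaffected beyond that discreteness.

## The synthetic generator

`fixtureSpec()` fixes the study conditions; every artifact draws from a
stream seed derived from the one master seed, so each stage is
independently reproducible and byte-identical under a repeated seed.

* Transcriptome: i.i.d. uniform nucleotides, 60 lncRNA + 20 coding genes,
  1–3 isoforms of 200–400 nt. Sixty lncRNA genes is a deliberate
  scale-down of the few-hundred-lncRNA universes measurable on repurposed
  coding arrays.
* Probes: 5 exact substrings per lncRNA gene, 10% additionally copied
  into a coding transcript (cross-biotype by construction), plus 5
  random decoys verified absent on both strands. Each probe's expected
  filter fate is certified at generation by an independent fixed-string
  scan, so the truth table does not depend on the matching code it is
  later used to test.
* Instances: per-gene Normal(7, 1) baselines shared across samples,
  probe-level Normal(0, `noise_sd` = 0.3) noise, 10 drugs x 3 instances
  (1 treatment, 2 controls), each drug shifting 10 measurable genes by
  ±1.5 log2 units.
* Disease profile: two classes of 6 samples; class 1 shifts 8 members of
  one target drug's set upward by 1.5 over the same noise model, emitting
  both the profile (LSEA input) and the shifted-gene list (ORA input).

The Gaussian log-intensity model is chosen for transparency. It does
**not** emulate real microarray error structure: no intensity-dependent
variance, probe affinity effects, background, saturation, batch
structure, or correlated biological variation. Passing the package's
recovery experiments therefore demonstrates correctness of the
algorithms under known ground truth, not performance on real arrays.

## Experiment sizes and numerical tolerances

The test-suite experiments use sizes chosen to make their Monte-Carlo
bands tight enough to be meaningful while keeping the suite quick to run:
exact-match oracle comparisons on 50 random fixtures (≤100 probes × ≤50
transcripts); hypergeometric agreement against exhaustive enumeration on
all universes up to m = 10 and against the exact survival function up to
m = 60 at 1e-12 relative error; running-sum agreement with a brute-force
walk on 200 random lists (N ≤ 200) at 1e-9; type-I calibration over 100
label-exchangeable datasets (20 genes × 12 samples, 10 sets, 200
phenotype permutations), with the rejection fraction assessed against a
3-standard-error band around the nominal 0.05; and planted-drug recovery
over 100 generator seeds at the default conditions, with 1000 gene-set
permutations (six samples per class is below the 7-per-class rule of
thumb for phenotype permutation, so the recovery experiment uses the
gene-set null). `scripts/acceptance.R` recomputes the same quantities
from scratch under a user-supplied seed.

## Known limitations

* Exact matching admits no mismatches or indels; probes designed against
  a variant transcriptome build may be lost rather than rescued.
* The reannotation treats the annotation table as ground truth; no
  genomic re-alignment is attempted.
* Instance log2 fold changes carry no variance estimate, so DEL calls are
  threshold-only, as is standard for two-sample perturbation instances.
* GSEA-style FDR q-values can be 0 when no pooled null value reaches the
  observed NES; they are estimates, not exact probabilities.
* The CLI covers the pipeline stages one at a time; orchestration across
  many datasets is left to the caller.
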