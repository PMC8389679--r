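---
title: "Methods: allele-specific TFBS scanning for regulatory SNP detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific TFBS scanning for regulatory SNP detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rsnpscan` predicts which promoter SNPs change transcription factor (TF)
binding. Its unit of evidence is a position weight matrix (PWM): a
per-position base-frequency model of a TF's binding motif. A SNP is
*regulatory* (an rSNP) when, for at least one PWM, the predicted binding
site differs between the two alleles — the site is lost, gained, or its
binding score changes.

The pipeline makes three assumptions worth stating explicitly:

* **Promoter proxy.** Because experimentally mapped promoters are scarce in
  most genomes, the promoter is approximated by a fixed window around the
  annotated transcription start site (TSS): 7.5 kb upstream and 2.5 kb
  downstream by default. The window is deliberately generous to absorb TSS
  annotation error; the biological promoter is usually smaller, which is why
  all query operations accept post-hoc narrowing bounds.
* **Binding = motif match.** A site is "bound" when its similarity scores
  pass cutoffs. Chromatin accessibility, TF concentration and cooperative or
  competitive binding are outside the model.
* **Biallelic substitutions only.** Insertions, deletions and symbolic
  alleles are discarded on input; multiallelic records are split into one
  record per alternate allele, each treated independently.

## Similarity scores

For a PWM of width $L$ with frequencies $f(i,b)$, each position carries an
information weight

$$I(i) = \sum_b f(i,b)\,\ln\!\big(4 f(i,b)\big), \qquad 0\ln 0 := 0,$$

which is 0 for a fully degenerate column and $\ln 4$ for an invariant one.
A candidate site $s_1 \ldots s_L$ scores

$$\mathrm{MSS} = \frac{\mathrm{Current} - \mathrm{Min}}
                      {\mathrm{Max} - \mathrm{Min}}, \qquad
  \mathrm{Current} = \sum_{i=1}^{L} I(i)\, f(i, s_i),$$

with Min and Max substituting the per-position minimum and maximum
frequency. The core similarity score (CSS) is the same quantity restricted
to the *core*: the five consecutive positions with maximal total
information (ties resolve to the leftmost window; a matrix narrower than
five positions uses all of it, making CSS = MSS). Both scores live in
$[0,1]$: the consensus sequence scores exactly 1, the anti-consensus
exactly 0. Information weighting means mismatches at conserved positions
cost more than mismatches at degenerate ones.

## Consequence classification

Each SNP yields two 51-bp sequences (reference and alternate allele, SNP at
position 26). Both are scanned with every PWM at every offset on both
strands; minus-strand hits are reported in forward coordinates so the two
alleles' hits are directly comparable. Hits are kept when MSS and CSS both
reach the matrix's cutoffs **and** the site's span covers the SNP — a site
not overlapping the SNP sees identical sequence on both alleles, so it
cannot differ between them; dropping such sites changes no call, and the
test suite asserts exactly that property rather than assuming it.

Two predictions are *the same site* when PWM, start position and strand all
agree. Then:

| reference | alternate | scores (rounded)        | consequence    |
|-----------|-----------|-------------------------|----------------|
| hit       | hit       | MSS and CSS both equal  | `no_effect`    |
| hit       | hit       | anything differs        | `score_change` |
| hit       | absent    | —                       | `loss`         |
| absent    | hit       | —                       | `gain`         |

A SNP is flagged as an rSNP when at least one of its records is a loss,
gain or score-change.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `upstream_bp` / `downstream_bp` | 7500 / 2500 | bp | generous promoter proxy around the TSS; narrowable at query time |
| `half_width` | 25 | bp | 51-bp flanks put every SNP-overlapping site of a PWM up to width 26 fully inside the flank |
| `mss_cutoff` / `css_cutoff` | 0.95 / 0.90 | score | strict defaults chosen to keep false positive site calls low; production PWM libraries ship curated per-matrix cutoffs, so both are overridable globally and per matrix via a cutoff-profile file |
| `digits` (score comparison) | 3 | decimals | site scores are conventionally reported to three decimals; equality for `no_effect` is judged after rounding, and the precision is configurable because the classification depends on it |
| `pseudocount` | 0 | count | zero frequencies are legal (they contribute 0 to both `Current` and `I`); a pseudocount is available for user matrices estimated from few sites |
| `bin_width` / `range` (histogram) | 500 / [−7500, 2500) | bp | whole-promoter view; 50 / [−750, 250) gives the proximal view |

# Conventions and numerical choices

* **Coordinates** are 1-based and fully closed internally (VCF/GFF
  convention); BED export is 0-based half-open.
* **TSS distance** is signed along the direction of transcription: negative
  upstream, and 0 at the TSS base itself. "Downstream" in the per-gene
  statistics means `dist_tss >= 0`.
* **Isoform collapsing.** Transcripts of one gene sharing chromosome,
  strand and TSS define identical promoters and are collapsed to one entry;
  isoforms with distinct TSSs are kept separate. A SNP is therefore
  reported once per distinct TSS, not once per isoform.
* **Histogram bins** are half-open `[lo, lo + w)` ascending from the range
  start, so each distance falls in exactly one bin.
* **Degenerate matrices.** A matrix (or core) whose Max equals Min is fully
  uninformative; its score is defined as 1.0 and a warning is raised rather
  than dividing by zero.
* **Exactness at the anchors.** Min and Max are accumulated
  position-by-position in the same order as Current, so the consensus
  sequence reproduces Max bit-for-bit and MSS is *exactly* 1 (and the
  anti-consensus exactly 0), not merely within tolerance. Scores are
  clamped to $[0,1]$ against last-bit rounding drift.
* **CSS-only differences.** When a matched site's MSS is equal at the
  comparison precision but its CSS differs, the record is classified
  `score_change` — `no_effect` requires *both* scores equal — and the
  `score_component` column records which score moved, keeping the
  borderline cases auditable. This rule is a package decision: the
  definitions cover MSS-differs and both-equal, and leave this edge open.
* **Ref-mismatch handling.** A SNP whose stated reference allele disagrees
  with the genome base is discarded with a distinct `ref_mismatch` status
  (it signals catalog/assembly version drift) rather than silently scanned.

# The synthetic-data generator

`simulate_fixture()` writes a complete input set — genome, annotation, SNP
catalog, PWM library — plus a manifest of planted ground truth, all
deterministic under a seed.

What it emulates: non-overlapping genes on both strands across several
chromosomes; promoter SNPs at varying TSS distances; motif instances
spanning SNPs, half of them on the reverse strand; PWMs sharp enough
(consensus frequency 0.91, others 0.03) that one mismatch reliably crosses
the default cutoffs, so a planted loss/gain is a definite loss/gain; for
score-changes, one tolerant matrix column (0.55/0.36) keeps both alleles
above cutoff with distinct scores; neutral promoter SNPs away from any
motif; and SNPs outside every promoter.

What it does **not** emulate: realistic GC structure beyond a single
genome-wide parameter, repeat content and assembly gaps, population allele
frequencies and linkage, overlapping promoters, TSS annotation error, and
redundant PWM libraries where many matrices hit the same site. Passing the
planted-recovery tests therefore demonstrates the pipeline's bookkeeping
and classification are exact, not that real-genome hit rates or score
distributions are realistic.

One generator detail matters for test integrity: after planting, every SNP
flank is re-scanned and background (non-motif, non-SNP) bases are
deterministically resampled in the rare event a chance background match
would have created a real site missing from the manifest. This keeps the
manifest the *complete* truth — the alternative would be silently
under-documented fixtures — and it never alters a planted motif.

# Problem sizes in the test suite

The suite is sized for a single CPU: bound/anchor properties over 100,000
randomized scoring cases; exhaustive oracle comparison over all $4^5$
sequences of a width-5 matrix; SNP-to-promoter assignment checked against an
all-pairs containment oracle at 10,000 SNPs x 1,000 promoters; scanning
checked against an exhaustive (PWM, offset, strand) oracle with a 10-matrix
library; classification semantics on constructed pairs and five fixture
seeds; and a full end-to-end fixture with 5 planted losses, 5 gains and 5
score-changes round-tripped through the store, the CSV export and all four
query modes.

# Known limitations

* Binding-affinity prediction from PWMs alone over-calls sites relative to
  in-vivo binding; cutoffs trade sensitivity against false positives and are
  not calibrated as p-values.
* Distal regulatory elements (enhancers) are out of scope; only
  promoter-proximal windows are scanned.
* The wide default promoter inflates per-gene rSNP counts by design; narrow
  at query time for proximal-promoter analyses.
* Only single-base substitutions are modeled; indels, MNPs and structural
  variants are discarded on input.
* Score equality (hence `no_effect` vs `score_change`) depends on the
  comparison precision; changing `digits` can reclassify borderline sites.
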