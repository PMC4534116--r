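---
title: "Separating mixed-species RNA-seq by genome of origin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating mixed-species RNA-seq by genome of origin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenosplit)
```

## The problem

When human tumor cells grow in a mouse host (a xenograft) or two species'
cells are co-cultured, RNA-seq of the excised specimen yields a single
library of intermixed human and mouse reads. Physically sorting the cells
before sequencing perturbs the very transcriptomes one wants to measure.
`xenosplit` instead separates the mixed transcriptome bioinformatically:
every read is aligned to both candidate genomes and classified by where,
how uniquely, and how cleanly it aligns. The package covers the complete
path from alignments to per-species expression tables and downstream
differential-expression statistics, plus a self-contained simulator so the
whole method can be exercised and benchmarked without any external data.

## The classification rule

For each read and each genome $g$ we record whether the read aligned,
whether its best alignment is unique within $g$, and the edit distance
$m_g$ of that best alignment (the SAM `NM` tag). Uniqueness follows the
common aligner convention of mapping quality 255 (`mapq255`, default) or
`NH == 1` (`nh_tag`). Multimapping within one genome collapses to a single
observation carrying the minimum $m_g$; the lost uniqueness is what later
disqualifies the read.

Three integer thresholds govern the decision for a read observed across
genomes $A$ and $B$:

* `Mu` (default 1) — maximum mismatches for a read seen in **only one**
  genome;
* `Ms` (default 1) — maximum mismatches, in the winning genome, for a read
  seen in **both**;
* `D` (default 2) — minimum mismatch advantage ($m_{loser} - m_{winner}
  \ge D$) required to rescue a read seen in both genomes.

The procedure: a read aligned nowhere is *unassigned*; a read aligned
uniquely in exactly one genome is assigned there if $m \le Mu$ (otherwise
unassigned for quality); a read aligned in both genomes is assigned to the
genome with fewer mismatches only when that alignment is unique, has
$m \le Ms$, and beats every other aligned genome by at least `D` —
otherwise the read is *species-ambiguous* and discarded. Ties
($m_A = m_B$) are always ambiguous since no `D ≥ 1` can be met. A
non-unique alignment can never win, but a non-unique alignment in the
*losing* genome still counts as cross-species evidence: it forces the read
through the shared-read rule rather than the unique-to-one-genome rule.
`strict_mode` disables the rescue entirely, reproducing the conservative
"discard everything that aligns to both" policy; its label partition is
identical to letting `D` exceed any observed mismatch difference. In
three-genome mode the winner must beat **each** other aligned genome by
`D`, and "unique to one genome" requires no alignment in any other.

Reads failing `Mu`/`Ms` are reported as *unassigned*
(`too_many_mismatches`), not ambiguous: they are lost to sequencing
quality, not to species conflict. Both tallies appear in the outputs so
either accounting convention can be compared.

## Quantification

Gene models are exon unions per gene symbol, merged across isoforms
(refFlat or GTF input). Before counting:

* **multi-gene masking** removes every base pair claimed by two or more
  distinct gene symbols from all of them, so shared sequence can never
  attribute a read; genes left with zero exonic length are dropped and
  reported rather than silently discarded. Masking is idempotent and
  order-independent.
* **small-RNA removal** excludes miRNA and snoRNA genes (by biotype, or by
  symbol prefix `MIR`/`MIRLET`/`SNOR` followed by a digit or `LET` —
  the word-boundary requirement keeps names like "MIRROR1" untouched).
  These genes are highly variable between preparations and mostly
  non-polyadenylated, so they distort normalization.

A species-assigned read is counted to a gene when its alignment interval
overlaps the masked exon union by at least 1 bp; each read counts at most
once (largest overlap wins; ties break by gene id order). Expression is
RPKM — reads per kilobase of masked exon model per million
species-assigned, gene-counted reads — so a gene's value is invariant to
overall sequencing depth. The detection cutoff is 1 read.

Between-sample normalization is TMM (trimmed mean of M-values) applied to
the RPKM matrix: per-gene log2 ratios against a reference sample are
double-trimmed (30 % on M, 5 % on A), and the factor is 2 to the
precision-weighted mean of the surviving ratios, with factors rescaled to
geometric mean one. Because the inputs are already depth- and
length-normalized RPKM values rather than raw counts, the textbook
library-size machinery of count-based implementations does not apply; the
package computes TMM directly with delta-method precision weights
$1/(1/x_s + 1/x_r)$, the small-count limit of the usual binomial weights.
The reference is chosen automatically as the sample whose upper quartile
of positive values is closest to the mean upper quartile (overridable).
Degenerate pairs (no commonly expressed genes, or an empty post-trim set)
fall back to a factor of 1; an all-zero sample is an error naming the
sample.

## Technical performance metrics

With per-read truth (from the simulator or from single-species control
samples) the package reports:

* **ambiguous fraction** — species-ambiguous reads over aligned reads
  (the default denominator) and over all reads; both are emitted because
  the choice is a convention.
* **misassignment rate** — reads assigned to a genome other than their
  origin, over all species-assigned reads; defined as 0 when nothing is
  assigned so the identical-genomes limit is well behaved.
* **read loss ratio** — cross-genome ambiguous reads over reads aligned to
  the genome of origin, for single-species samples.
* **full / partial gene loss** — among genes expressed when shared reads
  are retained (uniqueness-only filtering), the fraction dropping to zero
  counts, and the fraction keeping some but fewer counts, after full
  separation. The two categories are disjoint by construction.
* **mixing fidelity** — Spearman correlation between a pure sample's RPKM
  and the same species' RPKM recovered from an in-silico mixture,
  over genes detected in at least one of the two vectors (excluding the
  doubly-undetected block prevents a tie mass from dominating the rank
  correlation).

## Downstream statistics

Fold changes add a pseudo-value of 0.3 RPKM to both sides before forming
the ratio, a background level below which expression estimates are noise;
this keeps fold changes defined at zero and conservative at low
expression. Differential expression uses the SAM-style moderated
statistic $d = (\bar{x}_1 - \bar{x}_2)/(s + s_0)$ with $s$ the pooled
standard error of the mean difference. The regularizer $s_0$ defaults to
the median of the per-gene $s$ (a 5th-percentile rule is available);
the original SAM literature tunes $s_0$ per dataset, so it is exposed as
a parameter. Significance comes from label permutations with the null
pooled across genes per permutation and additive (+1) smoothing, so
$p \ge 1/(1 + n_{null})$ and the test is valid at any permutation count.
When the number of distinct two-group splits is small (e.g. triplicate
designs: $\binom{6}{3}/2 = 10$ splits), all splits are enumerated instead
of sampled, removing Monte-Carlo noise. FDRs are Benjamini-Hochberg.
Gene-list overlaps use the one-sided hypergeometric tail $P(X \ge k)$
given list sizes and an annotated-genome universe (on the order of
24,000 genes for mammalian annotations) — one-sided because the question
is whether overlap exceeds chance. For designs with very unequal group
sizes a plain fold-change cutoff (default > 2, either direction) over
detected genes is offered alongside the FDR cutoff, since the
permutation test's power is then lopsided.

## The simulator and what it does (not) emulate

`simulate_genomes()` builds genome A as uniform random sequence and each
further genome by independent per-bp substitutions at the configured
divergence, so gene coordinates are shared exactly (perfect orthologs
with no gaps). Defaults: 50 kb genome, 100 genes in non-overlapping
windows with 1–3 exons each, exons at least one read length long,
lognormal(0, 1) per-gene expression weights drawn once per genome (a
fixed "biological state" reused by every sample simulated from the
object), 50 bp single-end reads, per-bp error rate 0.005, and 50,000
reads per sample. The default divergence of 0.10/bp emulates human/mouse
exonic sequence divergence (roughly 85–90 % identity); at this setting
the benchmark reproduces the behavior expected of human/mouse
separation — about 95 % of reads species-assigned, ~4–6 % ambiguous, and
misassignment in the $10^{-5}$ range.

The oracle aligner enumerates, on both strands, every ungapped placement
of a read within `max_mismatch` (default 10) substitutions. Exactness
comes from pigeonhole seeding — a placement with $\le k$ mismatches must
contain one of $k+1$ disjoint exact seeds — followed by full Hamming
verification, so its results provably match a naive full scan (and are
tested against an independent one). Best placements are reported with
`NM`; unique bests get MAPQ 255, multimapped reads MAPQ 3 with `NH` set,
matching the uniqueness conventions the parser consumes.

Deliberate non-realism, and hence what passing benchmarks do *not*
demonstrate about real data:

* divergence is uniform along the genome, whereas real conservation is
  strongly gene-dependent — real ambiguity concentrates in conserved
  genes while simulated ambiguity spreads evenly. One visible
  consequence: at deep per-gene coverage almost every simulated gene
  loses *some* reads (high partial-loss fraction, near-zero full loss),
  whereas real pipelines concentrate losses in a few conserved genes.
* no indels, no splicing across read boundaries (reads never span exon
  junctions by construction), no quality-score structure, no
  amplification or GC bias, and toy genome sizes. The aligner is ungapped
  by design, matching the substitution-only divergence model.

## Behavior at low divergence

The mismatch-difference rescue needs a read to cover at least `D`
divergent sites. At 0.01 substitutions/bp, a 50 bp read covers $\ge 2$
divergent sites with probability $\approx 9\,\%$ (Binomial(50, 0.01)), so
only about a tenth of reads can ever be species-assigned with the default
`D = 2`, even with error-free sequencing — the remainder are correctly
(not erroneously) ambiguous, and misassignment stays near zero. Very
closely related genomes therefore trade read yield for specificity;
recovering yield requires longer reads, a smaller `D` (at a misassignment
cost), or accepting that only reads over divergent positions are
informative. The package reports this regime honestly rather than
inflating the assigned fraction.

## Numerical and design choices

* Internal coordinates are the Bioconductor convention (1-based, closed,
  `GRanges`/`IRanges`); refFlat (0-based half-open), GTF (1-based closed)
  and SAM (1-based) are converted exactly once at the parse/write
  boundary.
* The 1 bp overlap rule for counting treats a read touching a gene at
  either end as fully counted (a deliberate, stated approximation of
  end-inclusive exon-union counting); reads overlapping only masked
  multi-gene sequence are uncounted.
* RPKM with a zero total (no assigned reads in a sample) is defined as 0
  for all genes rather than NaN.
* Permutation p-values are deterministic given the seed; exhaustive mode
  is chosen automatically whenever the distinct-split count does not
  exceed `n_perm`.
* Tests and benchmarks run at 50 kb genomes, 100 genes and 50,000 reads
  per sample — sizes chosen so the exhaustive aligner remains exact while
  the full pipeline runs in seconds to a couple of minutes on a single
  core.

## Known limitations

Single-end reads only (no mate reconciliation); no CRAM; no BAM writing;
no k-mer (alignment-free) classification; no isoform-level
quantification or multi-mapper rescue by EM; the third-genome mode
assumes all genomes are of comparable assembly quality — in real data a
poor assembly inflates cross-assignment toward the better assemblies, a
caveat to keep in mind when adding species.
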