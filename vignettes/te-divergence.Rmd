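---
title: "Repeat clustering, age classification and methylation divergence: methods"
author: "repeatdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat clustering, age classification and methylation divergence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`repeatdiv` analyses the repetitive fraction of a genome from low-coverage
short-read sampling, in the setting of a clonal (apomictic) plant lineage
where several accessions of the same lineage are compared. The workflow has
five analytical stages, each usable on its own:

1. **Read clustering.** Reads are vertices of a similarity graph; an edge
   joins two reads when their best overlap alignment spans at least 55 % of
   the shorter read and reaches at least 90 % identity over the overlap.
   Connected components with two or more reads are repeat clusters. In
   low-coverage sampling (well below 1x per haplotype) two random reads
   almost never overlap the same genomic copy, so clusters collect reads
   from *different copies* of a repeat family, and cluster read fractions
   estimate genomic abundance.
2. **Abundance accounting.** A cluster's read-base fraction is scaled by the
   monoploid genome size (865 Mb by default) to give occupancy in Mb and in
   percent. Occupancy is *never* computed from raw read-base sums: only a
   fraction of the genome is sampled, so only fractions carry meaning.
   Between-accession differences in per-annotation read counts are tested
   with the likelihood-ratio chi-square (G) statistic, without continuity or
   Williams corrections.
3. **Cluster age classification.** For each cluster, the identities of all
   accepted read pairs are binned on [0.90, 1.00] at 0.001 width. A linear
   and a quadratic model are fitted to the relative frequencies by ordinary
   least squares and compared with the Gaussian-residual BIC,
   `n ln(rss/n) + k ln n` (`k` = 2 or 3). Six categories follow from the
   winning model's coefficients (see `?classify_age`); categories 1, 4 and 6
   — rising lines, upward parabolas and downward parabolas peaking above
   99 % identity — indicate young, recently proliferating families, because
   recent copies have had little time to diverge. The method is a
   deliberately simple heuristic for ranking histogram shapes, not an
   inferential test between clusters.
4. **Expression.** Per-cluster DNA and RNA read counts are normalised to
   reads-per-million and FPKM; transcription is summarised as
   `log2((rna_fpkm + 0.1) / (dna_fpkm + 0.1))` and, per accession, RNA
   content is regressed on DNA content across clusters (RPM scale by
   default). Clusters whose log ratio exceeds the accession median by more
   than three scaled median absolute deviations are flagged as
   low-abundance/high-expression outliers.
5. **Methylation divergence.** Reduced-representation bisulfite count tables
   (per locus, position, context, and accession) are filtered to CG
   positions with at least 50x coverage in *every* accession. Because plant
   CG methylation is strongly bimodal, proportions are collapsed to three
   qualitative levels: low (< 25 %), intermediate (25–75 %, both bounds
   inclusive), high (> 75 %). A position or locus is a *true* DMP/DMR when
   both low and high occur among accessions, *partial* when exactly two
   adjacent levels occur, *invariant* otherwise. Locus-level calls use the
   unweighted mean of per-position proportions (a coverage-weighted variant
   is available via `weighted = TRUE`).

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_overlap` | 0.55 | minimum overlap, fraction of the shorter read |
| `min_identity` | 0.90 | minimum identity over the overlapping region |
| `min_fraction` | 0.002 | cluster abundance floor (fraction of nuclear reads), inclusive |
| `bin_width` | 0.001 | identity histogram resolution (0.1 % identity) |
| `b_tol` | 0.001 | slope band around zero for the flat category |
| `optimum_cut` | 0.99 | parabola optimum above which a cluster is young |
| `min_pairs` | 20 | pair identities required to classify a cluster |
| `min_coverage` | 50 | bisulfite coverage floor per accession, inclusive |
| `g_monoploid` | 865 Mb | monoploid genome size for occupancy |
| `ploidy` | 3 | ploidy of the sequenced genome (triploid) |
| `pseudocount` | 0.1 FPKM | stabiliser for log expression ratios |

Scale conventions for the age classifier were a genuinely open choice: the
histogram could be fitted on raw pair counts or relative frequencies, with
identity as a fraction or a percentage, and the `b_tol` band only has
meaning relative to those scales. This package fixes X = identity fraction
in [0.90, 1.00] and Y = relative frequency summing to one, and applies
`b_tol` on that scale; both the histogram and the tolerance are exposed so
alternative scalings can be reproduced. Normalised Y also makes the category
invariant to rescaling raw pair counts, which the test suite checks.

# The overlap aligner

Edges of the similarity graph come from an exact free end-gap (overlap)
dynamic programming alignment, computed in both orientations (reverse
complements are emitted by sequencing at random strand). Scoring is
match +1, mismatch −1, gap −2 per column, with leading and trailing gaps
free; a zero mismatch penalty would be degenerate here, since with free
internal gaps the optimum would collapse onto a longest-common-subsequence
alignment that destroys true overlaps. Identity is *counted* on the optimal
alignment as matches divided by alignment columns, with gap columns counting
as mismatches. Among co-optimal alignments the one with more matches and
then fewer columns is reported, which makes results deterministic. `N` never
matches anything.

A pair is accepted when at least one orientation's optimal alignment passes
both thresholds; the better-scoring passing orientation is reported. The
aligner is cross-checked in the test suite against an independent
implementation of overlap alignment with identical scoring
(`Biostrings::pairwiseAlignment(type = "overlap")`).

**k-mer prefilter.** All-versus-all alignment is quadratic, so pairs that
cannot qualify are skipped when they share no exact k-mer (on either
strand). The k is computed from the thresholds by a pigeonhole argument: an
accepted pair must have an alignment with `M >= ceil(0.9 C)` match columns
among `C >= ceil(0.55 L)` columns, and its longest run of consecutive
matches — an exact shared k-mer — is at least `ceil(M / (C - M + 1))`,
minimised over admissible `C`. At the default thresholds and 125 bp reads
this guarantees k = 8, so the prefilter is provably lossless there (a naive
16-mer filter would not be: 69 aligned columns may carry 6 mismatches,
leaving runs as short as 9). When the thresholds admit no useful lossless k,
the prefilter disables itself; it can also be forced off
(`kmer_prefilter = FALSE`), and the oracle-equivalence tests run both ways.

# Numerical choices and degenerate inputs

* BIC ties (within 1e-12) select the linear model (parsimony), and a
  selected quadratic with `c = 0` falls back to the linear rules.
* A zero residual sum of squares is floored at 1e-12 inside the BIC so
  analytically exact fits stay finite.
* Histogram bins are left-closed and right-open with the last bin closed;
  a 1e-9 epsilon in the bin index keeps boundary values such as 0.95 in
  their nominal bin despite floating point.
* Clusters with fewer than 20 accepted pair identities are reported
  `unclassified-age` rather than forced into a category.
* The "curve opens upward/downward" rule is read as the sign of the
  quadratic coefficient `c` (a literal squared coefficient could never be
  negative).
* The abundance filter is applied after chloroplast-cluster removal, with
  read fractions recomputed against the remaining (nuclear) input reads;
  0.2 % exactly is kept.
* Level thresholds place 0.25 and 0.75 in the intermediate class, matching
  the strict inequalities that define low and high.
* Methylation loci whose positions are all filtered out leave the
  denominator of every reported fraction.
* Zero-coverage positions cannot occur in generator output: coverage is
  truncated at 1 so proportions stay defined.
* G-test inputs with an empty row or column raise an error naming the
  offending margin; `0 ln 0` terms are treated as 0.

# The synthetic-data generator

No public raw data accompanies this analysis design, so the package ships a
seeded generator that reproduces the *statistical structure* the pipeline
assumes, and every claim in the test suite is made against it.

* **Families and copies.** Each repeat family has a random consensus and a
  per-accession copy number; copies are the consensus with i.i.d.
  substitutions at the family's divergence rate (uniform among the three
  alternative bases). Substitution-only mutation keeps pairwise identity
  analytically checkable: two copies at rate *d* agree per site with
  probability `(1-d)^2 + d^2/3`, which the tests verify by brute force.
* **Ages.** Divergence is the proxy for age. A family with
  `age_mixture = TRUE` draws per-copy divergence uniformly between
  `min(0.01, d/3)` and `d`, emulating an old main burst with continued
  low-level proliferation; this is what places decreasing identity mass
  inside the [0.90, 1.00] window that the classifier actually sees. Copy
  numbers default to the hundreds-to-thousands realistic for abundant
  families (a 0.2 % family at ~1 kb per copy in an 865 Mb genome exceeds
  1000 copies), which keeps identical-copy read pairs — identity-1.0 spikes
  — at their realistic rarity of about 1/copy-number.
* **Reads.** 125 bp reads are sampled at uniform positions and strands,
  allocated to families proportionally to total copy length, plus a unique
  background sequence whose reads stay unclustered. Read counts are
  scaled-down stand-ins for the millions of reads of a real design; the
  identity structure of read pairs does not depend on that scale.
* **Expression.** RNA counts are Poisson with mean
  `expression_rate x dna_count`; outlier families get high rates at low
  copy number.
* **Methylation.** Loci draw bimodal levels (near 0 or near 1, TE loci
  leaning methylated); planted fractions of loci receive low/high or
  extreme/intermediate shifts in one or two accessions. Coverage is Poisson
  around a per-locus depth drawn from a gamma law, so the coverage filter
  has realistic work to do.

What the generator deliberately does **not** emulate: indels and structural
features of LTR elements (target-site duplications, PBS/PPT), insertion-site
preferences, bisulfite conversion error, mapping ambiguity, or sequencing
error profiles. Tests passing on this generator therefore demonstrate the
pipeline's logic and numerics, not robustness to those real-data artefacts.

# Validation design and problem sizes

The suite validates each stage against an independent oracle: clustering
against brute-force all-pairs alignment plus union-find; least squares
against closed-form normal equations (1e-8); the G statistic against a hand
computation (1e-9); level calls against a literal threshold oracle on
10 000 random proportions, exactly. Recovery experiments use 100 simulated
clusters per age condition (young: divergence <= 0.01; old: >= 0.06 with the
age-mixture tail; about 120 reads, 1000 copies, 800 bp consensus per
cluster) and 1000 bisulfite loci at mean coverage 100 with 10 % planted
true shifts. The demonstration pipeline runs five stages over three to five
accessions at 300–1000 reads each; these sizes were chosen so a full check
runs on a laptop in minutes while keeping every estimate comfortably inside
its statistical tolerance.

# Known limitations

* Connected components replace the community detection of full repeat-
  discovery pipelines; at these scales components are the simplest rule
  consistent with the stated edge criteria, but they can chain distinct
  subfamilies through intermediate reads.
* Cluster annotation is supplied externally (or from simulation truth);
  no homology search is performed.
* The identity window [0.90, 1.00] blinds the classifier to families whose
  pair identities lie mostly below 90 %: such clusters are seen only through
  their upper tail, and steeply decaying tails can be fitted as upward
  parabolas (category 4). This is inherent to the category definitions, not
  to this implementation.
* The classifier's six categories are a heuristic ranking, with no
  uncertainty attached; `young_fraction()` should be read descriptively.
* DMR calls are qualitative by design; no smoothing, no statistical test,
  and CHG/CHH contexts are filterable but not further analysed.
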