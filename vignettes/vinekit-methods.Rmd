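---
title: "vinekit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vinekit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinekit)
```

vinekit is a desk-scale toolkit for the computational core of a
haplotype-resolved grapevine genome/transcriptome platform: reconciling a
transcript-sequencing-derived gene annotation against a reference model,
mining a large normalized expression compendium with correlation-based
tools, calling genes impacted by structural variants between haplotypes,
and genotyping assemblies in silico against a SNP panel with
neighbor-joining trees. This vignette explains the models behind each
component, the tunable parameters with their defaults and units, the
synthetic-data generators the test suite scores itself against, and the
design decisions taken where the methodology was genuinely open.

## Coordinate conventions

All intervals inside the package are 0-based half-open `[start, end)`;
GFF3 on disk is 1-based inclusive. The conversion happens in exactly one
place (`read_gff3()` / `write_gff3()`), which removes a whole class of
off-by-one drift between modules. Gene features require a `+`/`-`
strand; only structural-variant records may be unstranded, and only SV
intervals may be zero-width (the haplotype-2 anchor of a deletion is a
point).

## Annotation reconciliation

The reconciliation pipeline mirrors a multistep annotation build:
genes transferred from a reference model by liftover are accepted when
both alignment **coverage and identity reach 0.80** (closed boundaries:
a "threshold of acceptance" reads as inclusive, and an inclusive
boundary is what the tests pin down). Transcript-level quality filters
then remove likely artifacts:

* **Nonsense-mediated decay (NMD).** A transcript is flagged when its
  stop codon lies more than `nmd_rule_nt = 50` spliced nucleotides
  upstream of the final exon-exon junction - the canonical 50-nt rule.
  Single-exon transcripts are never flagged. A CDS whose length is not a
  multiple of 3 is an error; a CDS without a terminal stop codon is an
  invalid model, reported separately from NMD (attribute
  `invalid = TRUE`) and likewise discarded by the pipeline.
* **RT template switching.** Reverse transcriptase jumping between
  direct repeats creates artifactual introns whose boundaries carry the
  repeat. We flag a transcript when, for any intron, the
  `rtswitch_repeat_len = 8` bases ending at the 5' exon/intron boundary
  (exonic side) equal the 8 bases ending at the intron/3'-exon boundary
  (intronic side), both read in transcription orientation. Eight bases
  is long enough that random boundaries collide with probability
  $4^{-8} \approx 1.5\times10^{-5}$ per intron, yet short enough to
  catch genuine template-switch repeats.

Genes with no protein-database hit are discarded as pseudogene
candidates, and genes must be **supported by expression**: a raw count
of at least `min_support_count = 5` in at least
`min_support_samples = 2` samples. The support rule is a package
default - any platform-scale cutoff is a judgment call, so both numbers
are configurable.

Surviving query genes are classified against the reference by
**same-strand exonic overlap** (the union of transcript exons, not gene
spans - the models are transcript-derived, so exonic bases are the
denominators that mean something):

* **novel** - no exonic overlap with any reference gene;
* **fused** - at least two reference genes each have at least
  `fusion_member_fraction = 0.50` of their exonic bases covered by the
  query gene; half-coverage per member keeps incidental UTR overlap from
  fabricating fusions;
* **covered** - a unique reciprocal best partner with both overlap
  fractions at least `covered_reciprocal_fraction = 0.80`, mirroring the
  80% acceptance rule;
* **split** - reported per reference gene when two or more query genes
  each cover at least half of it; the query-side members are labelled
  `split_member`;
* **ambiguous** - everything else.

Fused is attributed to query genes and split to reference genes, which
is the direction each is defined in. Best partners rank by overlap
bases with ties broken by gene id, so classification is deterministic,
and the five classes are a true partition of the retained query genes.

## Expression tools

**Normalization** corrects for gene feature length and library size:
counts are divided by gene length and each sample is rescaled to sum to
one million (TPM). TPM is the canonical scheme of that form; the column
sums give an exact internal check (relative tolerance $10^{-6}$ in the
tests, satisfied to machine precision). Raw counts and normalized values
are distinct types, so normalization cannot be applied twice; the same
guard applies to the `log2(x + 1)` transform.

**Correlation tools** operate on `log2(TPM + 1)` by default (raw TPM is
an option): expression spans four orders of magnitude, and the log
stabilizes variance so a handful of extreme samples cannot dominate a
Pearson coefficient. The correlation gene finder returns genes above a
threshold (default 0.75) or the top-k by `|r|` (default 10), always
excluding the target and silently skipping zero-variance genes, whose
correlation is undefined - the finder is exploratory. Clustered heatmaps
support Euclidean distance on the expression levels or Pearson distance
`1 - r`, with average linkage by default; there a zero-variance row is
an error naming the gene, because a distance matrix with undefined
entries should never be clustered silently. The weighted correlation
network follows the soft-threshold convention `w = |r|^beta` with
`beta = 6`, the customary default where a weighting scheme is not
otherwise specified; nodes are the seeds plus neighbors with
`w >= min_weight`, and both seed-neighbor and neighbor-neighbor edges
are kept. The correlation-circle layout places genes at radius `1 - r`
(clipped to `[0, 2]`): the higher the correlation, the shorter the
distance to the target.

Condition handling is ambiguous at platform scale (a "condition" may be
one sample or a replicate group). The tools treat columns as samples
after metadata filtering; `aggregate_conditions()` optionally collapses
replicate samples to condition means first.

Group profiles report per-condition mean and sample standard deviation
(denominator $n-1$); a single-sample group reports 0 rather than `NA`
so line charts with error bars degrade gracefully.

**qPCR validation math** implements the comparative Ct method: dCt is
the mean target Ct minus the mean of per-reference-gene mean Cts
(several reference genes, e.g. ACT/EF1/UBQ, are first averaged within
and then across genes), ddCt subtracts the calibrator's dCt, and the
fold change is $2^{-\Delta\Delta Ct}$.

## Structural-variant impact

Genes impacted by SVs between haplotypes are called by interval
overlap against typed SyRI-style records. Insertions and deletions
count only when their size **strictly exceeds 1 kb** ("exceeding"
means `>`, so a 1,000-bp deletion does not qualify); inversions and
translocations count at any size; duplications are listed but excluded
from both summary counts. Overlap is on the gene span by default with
an exon-only option - "impacted" has no canonical definition, and a
span-level hit is the more conservative screen for follow-up. Impact is
computed per haplotype side; `combine_impact_reports()` unions sides
and deduplicates genes.

## In-silico genotyping and trees

Marker alleles are retrieved from an assembly by **exact matching** of
`flank + allele + flank` with a `k = 50` bp window on each flank,
searching both strands of every contig. Exact matching is deterministic
and fast, and on assemblies of the same species the 101-bp context is
effectively unique; a mismatch-tolerant mode is deliberately out of
scope. A call is made only when exactly one allele matches at exactly
one locus - anything ambiguous is missing.

Genotype distance is allele sharing (identity by state) on dosages:
`mean(|dose_x - dose_y|/2)` over jointly non-missing markers, `NA` below
`min_shared = 100` markers. IBS requires no pedigree or frequency model,
which suits a ranking task ("the closest cultivars", default top 40).
The "robust subset" selection keeps markers with unambiguous calls in
every query assembly and a panel call rate of at least 95%.

Neighbor joining is the standard Saitou-Nei agglomeration on the Q
criterion. Two conventions make it reproducible: ties in Q are broken
by the lexicographically lowest label pair, and negative limb estimates
are clamped to zero with the deficit reported. On additive matrices the
output path lengths reproduce the input exactly (the tests demand
$10^{-9}$); the three-point closed form for the last three nodes yields
an unrooted tree whose internal nodes have degree 3.

## Promoter motif scanning

Promoters are the `window = 2000` bp immediately 5' of the TSS
(reverse-complemented for minus-strand genes), truncated with a warning
at contig edges; 2 kb is the common plant-promoter default where no
window is otherwise fixed. Scanning is exact degenerate-consensus
matching of IUPAC strings on both strands - the sites of interest are
published as consensus presence/absence, so position weight scoring
would suggest precision the inputs do not have. Matching uses
`Biostrings::matchPattern(fixed = FALSE)`; note that under this
semantics an `N` in the *subject* matches any pattern letter (generated
fixtures are ACGT-only, so the property tests are unaffected). A small
curated set of Myb-family consensus strings ships as replaceable
defaults (`myb_motifs()`).

## Synthetic data: what it emulates, and what it does not

Each generator is seeded and fully deterministic (identical
configuration and seed give byte-identical files), and each emits the
planted ground truth needed to score the downstream module.

* **Annotation pairs** plant covered/novel/fused/split relationships
  among non-overlapping two-exon genes (split genes get equal exon
  halves so each member covers exactly half of the reference exonic
  bases); an optional jitter shifts copied genes to create the partial
  overlaps that exercise the covered/ambiguous boundary.
* **Expression matrices** emulate a black/white berry design: a latent
  pathway-activity factor per black sample drives a
  `module_size = 7` gene module at target pairwise correlation
  `module_r = 0.9` on the log2 scale; the slope on the latent factor is
  the smallest achieving that correlation once negative-binomial
  counting noise is accounted for (delta-method variance
  `dispersion / ln(2)^2` on the log2 scale). White samples express the
  module at a flat, near-zero level - flat matters: a proportional
  knockdown would leave white samples echoing the black per-gene
  profile and blur Pearson-distance clustering. Background genes vary
  independently of berry color. Counts are negative binomial
  (`dispersion = 0.05`) with uniform per-gene lengths (0.5-5 kb) and
  library sizes (200k-500k) - scaled-down libraries, chosen so the
  fixtures stay fast while keeping counting noise realistic. Defaults
  mirror the 150 black / 63 white berry design; the test suite uses
  40 + 20 samples with 500 background genes.
* **Haplotype pairs** apply typed SVs (DEL/INS/INV/DUP/TRA) to a copy
  of haplotype 1, with in-gene variants placed wholly inside distinct
  gene bodies and gene spans sized to fit the largest variant.
  Coordinates of untouched genes are lifted exactly; genes overlapping
  an SV - precisely the impacted set - are omitted from the haplotype-2
  annotation rather than approximately lifted.
* **Marker panels** evolve biallelic markers along a random binary tree
  by independent per-branch flips (probability `0.1` per unit branch
  length, capped at 0.4); one leaf's alleles are embedded in a
  two-contig assembly as flank-allele-flank sites. No back-mutation
  bookkeeping or substitution model is attempted - per-branch flips are
  sufficient for topology-recovery and end-to-end genotyping tests.

What passing these tests does **not** show: real annotations have
overlapping isoforms, UTR-only exons and trans-splicing that the
two-exon fixtures lack; real expression compendia carry batch and
project effects the generator does not model (batch correction is out
of scope); real SV calls are noisy at breakpoints; and real marker
panels violate the infinite-sites idealization. The fixtures establish
algorithmic correctness, not field performance.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise
every code path while completing in minutes on one core: 50-locus
annotation pairs (plus 20 randomized pairs up to ~100 genes against a
per-base brute-force oracle), 100 replicates of the 60-sample /
507-gene expression design, 100 random additive 8-leaf matrices for
neighbor joining, a 60-leaf / 300-marker genotyping chain, and 100
random 10-kb promoters against a sliding-window motif oracle.

Other conventions: acceptance boundaries are closed (`>=`) and the SV
size rule is strictly open (`>`); degenerate equidistant distance
matrices resolve by the deterministic label-pair tie-break; an
all-zero sample column is a normalization error (naming the sample)
rather than a silent `NaN` column; and reading any generated file back
through the package's own readers reproduces the in-memory objects
exactly.

## Known limitations

Liftover, protein searches, read mapping and SV calling all happen
upstream - the package consumes their outputs. Marker calling has no
mismatch tolerance, so diverged flanks yield missing calls rather than
approximate ones. The NJ implementation is quadratic per join
(adequate to hundreds of leaves, not tens of thousands). IBS distances
are not additive evolutionary distances; trees built from them are
rank summaries of similarity, as in the intended cultivar-neighborhood
use, not phylogenies in the strict sense.
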