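---
title: "Methods: 18S amplicon analysis for brine-pool habitats"
author: "brine18s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 18S amplicon analysis for brine-pool habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brine18s)
```

## The analysis problem

Deep-sea brine pools and cold seeps host eukaryotic microbial communities
that are poorly represented in reference databases: a large fraction of 18S
rRNA amplicon reads from such habitats cannot be classified by
similarity-based assignment. This package implements the two-track analysis
such surveys use:

1. a **similarity track** — quality-controlled reads are clustered into
   operational taxonomic units (OTUs) at 3% dissimilarity and summarised by
   rarefied diversity indices (observed OTUs, Shannon, Chao1, Good's
   coverage); and
2. a **phylogeny track** — representatives of much coarser OTUs (20%
   dissimilarity, roughly kingdom-level for the 18S V1–V3 fragment) are
   placed on a de-novo tree together with a panel of reference sequences
   spanning the eukaryotic kingdoms, each OTU is labelled by the kingdoms in
   the smallest well-supported clade containing it, and the per-sample clade
   profiles are compared by Bray–Curtis dissimilarity and ordination.

The study design the defaults encode is a multiplexed 454 pyrosequencing
library: seven habitat samples (microbial mat, bottom water, brine–seawater
interface, two bottom sediments, two brine sediments), each tagged with an
8-nt barcode ahead of the universal eukaryotic forward primer 1A
(`AACCTGGTTGATCCTGCCAG`), amplifying the V1–V3 region down to reverse primer
564R.

Because the original raw reads require retired denoising and chimera tools
to reprocess, correctness here is established against *synthetic* data with
known ground truth rather than against published per-sample numbers; the
generator is a first-class, tested module.

## The synthetic generator

`generate_reference_panel()` builds a multi-kingdom panel by mutating one
root per kingdom away from a shared ancestor. Mutation at rate
$r/2$ per lineage yields pairwise divergence of approximately $r$, so
`inter_divergence` and `intra_divergence` are stated directly as the target
pairwise divergences (defaults 0.30 between and 0.03 within kingdoms — the
scale at which 18S fragments separate kingdoms while leaving within-kingdom
structure). The primer and the two internal probes (Euk381
`TCCGGAGAGGGAGCC`, Euk422 `GGCAGCAGGCACGAA`) are planted verbatim and
protected from mutation, so every genuine template is a positive control for
the probe screen. Default dimensions are 23 kingdoms × 5 representatives,
the size of a curated kingdom-level panel.

`simulate_reads()` emits `barcode + primer + insert` reads with:

* substitutions at `sub_rate` (default 0.005/base) and ±1 indels at
  homopolymer runs ≥ 3 nt (`homopolymer_rate`, default 0.02/run) — the
  dominant 454 error mode;
* per-base Phred qualities decaying linearly from Q38 to Q28 with ±1 noise.
  The end-of-read floor sits above the windowed-quality threshold on
  purpose: with a floor much below Q28 *every* full-length read would fail
  a 50-bp window at mean < 25, and the windowed rule could not act as a
  detector of genuinely bad stretches. Planted low-quality reads instead
  receive an explicit 50-nt window at Q10;
* exactly `floor(fraction × n_reads)` reads per sample planted with each
  violation class (probe-free false amplicon, short, ambiguous,
  long homopolymer, low-quality window, corrupted barcode), mutually
  exclusive, with the remainder clean. False amplicons are rejection-sampled
  until every window sits ≥ 3 mismatches from both probes, and clean reads
  are rejection-sampled so sequencing error never fabricates a violation —
  the classes are separable by construction, which is what makes exact
  precision/recall assertions meaningful;
* a per-sample log-normal taxon abundance profile (σ = 1.5) unless an
  explicit composition matrix is given. `community_archetypes()` builds
  compositions in which samples sharing a habitat archetype draw from the
  same dominant kingdom subset — it emulates strong habitat partitioning,
  not the actual taxon membership of any real site.

What the generator does *not* emulate: flowgram-level noise, chimeras
(chimera removal is out of scope), PCR abundance bias, and the real
length-vs-quality structure of 454 reads. Passing tests therefore
demonstrate algorithmic correctness under a controlled error model, not
field performance on raw survey data.

All randomness flows from the single `seed`; the caller's RNG state is
saved and restored, and two runs with the same configuration are
byte-identical down to the FASTQ.

## Quality control

Filters run in a fixed order so each read has exactly one rejection reason:
complete-barcode demultiplexing (exact by default), mean quality < 25,
any sliding 50-bp window with mean quality < 25, ≥ 1 ambiguous base,
length < 150 nt, homopolymer > 6 nt, then the false-amplicon screen:
the read must start with the complete forward primer (exact) and contain at
least one internal probe within 2 mismatches (Hamming windows, no indels; an
`N` counts as a mismatch). Reads shorter than the quality window skip the
window rule — they are almost always caught by the length rule, and a
partial-window mean would make the rule's meaning depend on read length.
The "average flowgram score" of the original instrument pipeline is mapped
onto mean Phred quality, the scale a FASTQ rendering of those reads
carries; the windowed rule rejects rather than truncates by default so that
the qualified set is an exact function of the thresholds — truncation at the
first failing window is available behind `qc_params(window_truncate =
TRUE)`, as is trimming at a read-through reverse-primer site
(`trim_reverse`), both off by default.

Coordinates are 1-based throughout, following R and Bioconductor
convention.

## OTU clustering

Greedy abundance-ordered centroid clustering: unique sequences are processed
in decreasing total-count order (ties: longer first, then lexicographic);
each sequence joins the first centroid whose pairwise identity is at least
`1 − level`, else founds a new centroid. Identity is computed from an
optimal Needleman–Wunsch global alignment (match +1, mismatch −1, gap −2,
deterministic traceback) as matches over alignment columns *excluding
terminal-gap columns* — so a shorter amplicon that matches a centroid prefix
is not penalised for length, which matters at the 20% level where inserts of
different lengths must co-cluster. A shared 8-mer prefilter (occurrence
counts, not unique k-mers) skips alignments that provably cannot reach the
threshold; the bound is conservative, and the test suite asserts the table
is identical with the filter on and off.

Representatives are the most-abundant member sequence per OTU (ties:
centroid, then lexicographic). Singleton OTUs (total count 1 across all
samples) are removed before phylogenetic classification, mirroring standard
practice for placement of amplicon OTUs.

## Diversity

Every sample is rarefied to the smallest library by drawing reads without
replacement (each OTU's subsampled count is multivariate hypergeometric,
which the tests verify distributionally), then summarised by observed OTUs,
Shannon index in **bits** (base-2 logarithm; natural log available via
argument), bias-corrected Chao1
$S_{obs} + n_1(n_1-1)/(2(n_2+1))$, and Good's coverage $1 - n_1/N$.
The summary reports a single seeded rarefaction draw by default
(`replicates = 1`) so the emitted table is an exact function of the seed;
averaging over draws is available but changes reproducibility from
"byte-identical" to "statistically identical", so it is opt-in.

## Phylogeny-based classification

Queries (20%-level OTU representatives) and the reference panel are aligned
by progressive profile–profile Needleman–Wunsch along a UPGMA guide tree
built from shared 6-mer distances. Terminal alignment blocks whose gap
fraction exceeds 0.9 are trimmed — the region beyond the amplicon's extent
is alignment noise, not signal; interior columns are never touched.

Distances are Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1-\tfrac{4p}{3})$, over
shared (both-ungapped) columns; saturated pairs ($p \ge 0.75$) and values
above 5 are capped at $d_{max}=5$, and pairs sharing fewer than 20 columns
are flagged unreliable. JC is deliberately simple: the quantity consumed
downstream is clade *membership*, not branch-length inference, so a
Bayesian machinery with a richer substitution model would add cost and
stochasticity without changing the labels; neighbor joining with bootstrap
is also exactly the procedure such studies use for their intra-clade trees.

Neighbor joining follows the canonical Saitou–Nei algorithm. Exact ties in
the Q criterion — common, because JC distances are ratios of small integer
counts — are broken by the lexicographically smallest pair of cluster
labels, which makes the topology deterministic *and* independent of input
row order (an index-based tie-break would silently depend on the order rows
arrived). Negative branch lengths are clamped to zero with the deficit
moved to the sibling edge. On additive matrices the output path metric
reproduces the input to numerical precision, which the tests assert against
randomly generated trees.

Bootstrap supports resample alignment columns with replacement, rebuild the
JC+NJ tree per replicate, and attach to each internal node of the
midpoint-rooted full-data tree the fraction of replicates containing its
bipartition. Midpoint rooting is used because no outgroup is defined for a
tree that spans all eukaryotic kingdoms. The package default is 100
replicates (sufficient to resolve supports at the 0.5 acceptance threshold);
the command-line `run` default is 1000, the conventional publication
setting.

A query is labelled by the set of reference kingdoms in the smallest clade
containing it and ≥ 1 reference with support ≥ 0.5 (the acceptance threshold
used for posterior support in comparable Bayesian analyses). Queries whose
smallest such clade is the entire tree are `NOVEL`. A long-branch guard also
flags queries whose terminal branch exceeds **twice** the 95th percentile of
the reference terminal branches, where those reference branches are measured
on the reference-only subtree obtained by pruning all queries. Both details
matter. Measuring the yardstick on the joint tree would let the queries
deflate it: a query attaching right next to a reference absorbs part of that
reference's terminal branch, so with many queries the reference terminals
collapse toward zero and the bare percentile would flag most correctly
placeable sequences. The factor of 2 adds headroom for queries that are
legitimately somewhat more divergent than the curated references; genuinely
unplaceable sequences sit at branch lengths an order of magnitude larger
(near the saturation cap), so any factor in the range 1.5–10 separates the
two regimes and 2 keeps the guard conservative.

## Ordination

The per-sample clade read-percentage matrix (rows sum to 100) is compared by
Bray–Curtis dissimilarity $\sum|x_i-y_i| / \sum(x_i+y_i)$ and ordinated by
principal coordinates analysis (classical metric scaling). "PCA with
Bray–Curtis as input" — as survey methods sections usually phrase it — is
literally PCoA, so PCoA on Bray–Curtis is the default; negative eigenvalues
(possible because Bray–Curtis is non-Euclidean) are reported untouched and
excluded from the variance-explained denominator. `group_separation()`
scores habitat groupings by the mean silhouette width over the first two
axes.

## Problem sizes and numerical choices

The test and acceptance workloads are sized so the whole suite exercises
every stage at the study's design shape (7 samples × 8-nt barcodes, ~5,000
reads for the QC oracle, 100 query OTUs against a 32-sequence panel for
classification, 100 bootstrap replicates) while remaining quick to run on a
laptop; these sizes are stated in the scripts themselves. Other fixed
choices: alignment scoring +1/−1/−2; k-mer sizes 8 (cluster prefilter) and 6
(guide tree); JC cap 5.0; minimum 20 shared columns for a reliable distance;
trim threshold 0.9; all tables TSV with `#`-prefixed headers, trees Newick,
sequences FASTA/FASTQ.

## Known limitations

* The generator's error model is substitution + homopolymer-indel only; no
  chimeras, no flowgram noise, no PCR bias — conclusions about real 454
  libraries require the original denoising steps that are out of scope here.
* JC+NJ underestimates divergence for saturated pairs; the cap bounds but
  does not remove this, which is acceptable only because labels, not branch
  lengths, are the product.
* The clade vocabulary is the reference panel's kingdom labels; a query from
  a lineage absent from the panel can only be `NOVEL` or mislabelled into a
  neighbouring kingdom.
* Rarefying to the smallest library discards data in deep samples; that is
  the standard, comparability-first choice and the only one offered.
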