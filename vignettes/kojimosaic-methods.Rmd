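---
title: "Methods: clade structure, mosaicism and mutation spectra in clonal fungal genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade structure, mosaicism and mutation spectra in clonal fungal genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kojimosaic)
```

## The problem

Industrial koji moulds (*Aspergillus oryzae* and relatives) are propagated
clonally. Whole-genome comparisons of such strains show three characteristic
signals that this package quantifies:

1. **Tight clades.** Strains fall into groups whose concatenated coding
   sequences are almost identical (dissimilarity on the order of 0.01%),
   while different clades are separated by roughly percent-level divergence.
2. **Chromosomal mosaicism.** Along a chromosome, the clade whose sequence a
   strain most resembles changes from segment to segment, the footprint of
   ancestral recombination between clade ancestors rather than of ongoing
   sexual reproduction. Mating-type (MAT1-1/MAT1-2) idiomorphs segregating
   perfectly with clades corroborate the clonality of the clades themselves.
3. **A skewed mutation spectrum.** The few mutations that separate members
   of one clade are strongly enriched for non-synonymous and gap
   (insertion/deletion) changes relative to the between-clade or
   between-species background, the signature of domestication pressure on
   gene function.

All analyses run on four plain-text inputs: per-orthogroup aligned coding
sequences (one FASTA per single-copy orthogroup, SCG), a gene-order map
anchoring orthogroups to chromosomes, samtools-depth read-depth tables, and
MAT marker sequences.

## Clade definition

`concat_degapped()` removes every alignment column containing a gap in *any*
strain and concatenates the remainder in lexicographic orthogroup order.
Removing columns gapped in any strain (rather than per-pair) guarantees one
rectangular, gap-free matrix, which is what a "degapped gene sequence"
concatenation denotes; the retained-column count is reported per orthogroup
and all-gap orthogroups are skipped with a warning.

`pdistance()` is the proportion of differing columns, with `N` treated as a
wildcard that matches anything. The wildcard choice prevents low-coverage
ambiguity codes from inflating distances between otherwise identical
strains; its cost is that `pdistance` is only a pseudo-metric in the
presence of `N` (the triangle inequality is asserted in the test suite on
gap-free, N-free instances).

`cluster_clades()` applies single linkage at a threshold of `1e-4` (0.01%)
by default. Single linkage is the weakest clustering assumption consistent
with a statement of the form "members are within 0.01% of each other", and
the threshold is exposed because the 0.01% figure is descriptive, not an
algorithmic constant. Clusters are labelled `C1`, `C2`, ... by order of
first-appearing strain so labels are stable under row order.

`nj_tree()` implements Saitou–Nei neighbor joining with two documented
conventions: Q-matrix ties break to the smallest `(i, j)` index pair, and a
negative branch length is clamped to zero with the deficit moved to its
sister so path lengths are conserved. Neighbor joining is a deliberate
desk-scale replacement for maximum-likelihood inference: at intra-clade
distances of 1e-4 and inter-clade distances of 1e-2, distance methods
recover the same grouping structure at a tiny fraction of the cost, and the
test suite cross-checks topologies against `ape::nj` and against the
3-taxon closed form. Bootstrap support and model-based inference are out of
scope.

`mat_type()` does exact substring search for each MAT idiomorph marker and
its reverse complement; exactly one hit gives the type, neither gives
`unknown`, both give `ambiguous`. `mat_clade_ld()` then reports, per clade,
the set of observed MAT types with `unknown` ignored; a clade showing both
idiomorphs is flagged, since under clonal clade structure MAT must be in
complete linkage with clade membership.

## Mosaicism

The unit of comparison is the gene. `clade_reference()` builds a per-clade
consensus (column majority, ties broken by the fixed order
`A < C < G < T < N < -`), and `identity_profile()` scores a query gene 1
against a clade iff it equals that clade's consensus exactly, after
dropping columns gapped in both. Exact identity — rather than a similarity
threshold — is the right statistic here because intra-clade divergence is
so low that a single substitution is already informative, and it
degenerates correctly: for a tight clade the consensus equals the shared
sequence. Comparing to the consensus rather than to "any member" is
reproducible and clade-size invariant; a member-wise mode can be emulated
by passing single-member assignments.

`mosaic_track()` smooths the indicators with a centred window of `window`
genes (default 21, clipped at chromosome ends), reports per-clade scores as
percentages, and assigns each gene the argmax clade. Score ties produce
`"unassigned"` rather than an arbitrary clade, so mosaic structure is never
fabricated by tie-breaking. `genome_share()` is the unsmoothed mean
indicator per clade; shares intentionally do not sum to one because one
gene can be identical to several clade references.

`mixture_test()` asks whether a genome is explained by two donor clades:
the best pair coverage (fraction of genes identical to at least one of the
pair) must reach `coverage_threshold` (default 0.95) *and* each member must
individually cover at least `min_each` (default 10%). The second clause is
this package's own addition: without it any single-donor strain would
trivially pass, because the pair {true donor, anything} already covers
everything.

## Mutation spectra

`classify_codon_change()` orders its rules: any `-` makes a change a gap;
otherwise any `N` makes it ambiguous; otherwise the standard genetic code
decides synonymous versus non-synonymous, with stop-to-stop synonymous and
sense-to-stop non-synonymous (function-changing by definition). Multi-hit
codons are classified by the net amino-acid effect, since path counting
would require an evolutionary model the data do not constrain.

`count_intra()` compares each clade member to the clade consensus and
counts **distinct variants**: the same alternate codon at the same site in
several members is one mutation event. This makes counts invariant to
clade size and matches the event interpretation of "mutations were
counted"; per-occurrence counting is available behind `distinct = FALSE`.
A maximal run of consecutive gap codons in one member is one gap event (a
single indel should not be counted once per codon it spans).
`count_inter()` compares consensus pairs and sums over unordered clade
pairs; `count_baseline()` treats a whole species as one group.

`odds_vs_baseline()` forms `(nonsyn/syn) / (nonsyn_b/syn_b)` (and the gap
analogue) and tests each 2x2 table with `fisher_exact()`, an exact
log-space hypergeometric summation using the two-sided "sum of tables no
more probable than the observed" convention (with the customary `1 + 1e-7`
relative fudge). The exact path covers the count magnitudes that arise at
genome scale (totals around 1e5–1e6); a normal approximation, flagged in
the output, only engages beyond 2e7 support states. A `continuity` flag
adds 0.5 to the odds cells when a zero synonymous count would otherwise
make the ratio undefined; p-values always use the raw counts.

```{r odds-example}
intra <- mutation_table("intra_clade", syn = 265, nonsyn = 528, gap = 93)
flavus <- mutation_table("baseline_species", syn = 79068, nonsyn = 53922,
                         gap = 1336)
odds_vs_baseline(intra, flavus)
```

## Copy number from depth

`gene_mean_depth()` averages per-base depth over half-open gene spans,
counting absent positions as zero so deletions read as depth loss rather
than missing data. `normalize_depths()` divides by the strain's **median**
per-gene mean depth — robust against the CNV genes themselves, unlike the
mean; a mode-based constant is available. The normalized depth is the copy
number estimate; integer calls round half-up, and zero-depth genes are
called copy number 0. `cnv_by_clade()` lists distinct calls per
(orthogroup, clade) and flags intra-cladal variability. Repeat families
(transposons, rRNA, tRNA) violate the unit-mappability assumption behind
depth-as-copy-number; the intended workflow excludes them via the caller's
gene selection rather than modelling mappability.

## The simulator

`simulate_dataset()` generates the statistical structure the analyses
assume, with complete ground truth:

* **Ancestors** (`simulate_ancestors()`): one random root CDS per
  orthogroup (ATG start, no internal stop, terminal stop), then one branch
  per clade on a star phylogeny substituting internal-codon sites at rate
  `divergence/2` with transition:transversion 2:1 (a generic fungal
  default; the exact ratio is immaterial to the analyses, which never
  model the substitution process). A star is used because the clades of
  interest diverged near-simultaneously; a tree-shaped option is out of
  scope.
* **Clade strains**: each descends directly from its clade ancestor plus
  private domestication mutations — Poisson(`intra_mut_rate`) substituted
  codons whose non-synonymous probability realizes the `target_ns_odds`
  multiplier on the neutral odds, and Poisson(`gap_rate`) single-codon
  deletions (the simplest frame-preserving gap), re-padded as `---` so
  alignment columns survive.
* **Recombinants** (`simulate_recombinant_strain()`): crossovers uniform
  without replacement over intra-chromosome gene junctions, donors
  changing at every crossover; genes are copied verbatim, i.e. crossovers
  never fall within genes, because the gene is the analysis unit.
* **Depth and MAT**: per-base depth is Poisson(`mean_depth` x copy
  number) over a fixed reference layout; each strain carries one of two
  fixed synthetic 30 bp MAT markers (random strand), alternating by clade
  to reproduce MAT-clade linkage.

Defaults (5 clades x 3 strains, 200 genes of 200 codons on two
chromosomes, divergence 0.01, 3 substituted codons and 1 gap event per
strain, odds multiplier 2.9, depth 100) are the package's standard
validation conditions; the mutation load is set so the expected
intra-clade p-distance (about 1e-5 per event pair over the 1.2e5-column
concatenation) stays at the 0.01% scale that defines a clade. The entire
dataset, including file checksums from `emit_dataset()`, is a pure
function of the configuration.

What the simulator does **not** emulate: sequencing error and read-level
artefacts (depth is Poisson, not mapped reads), within-gene recombination,
alignment error (emitted alignments are exact by construction), repeat
families and mappability structure, and selection acting on specific gene
functions. Passing recovery tests therefore demonstrates correctness of
the statistical machinery on data satisfying its assumptions, not
robustness to assembly or alignment noise in real draft genomes.

## Validation sizes and numerical choices

The test suite and the acceptance script (`scripts/acceptance.R`) run the
recovery analyses at the default conditions: 20 simulated datasets for
closest-clade recovery (donor-label accuracy and breakpoint recall within
±10 genes), 10 for copy-number calls at depth 50 with truth copies up to
3, exact truth replay of intra-clade mutation counts, exact MAT recovery,
and mixture verdicts on one-, two- and three-donor simulants. Fisher
p-values are validated against full binomial-coefficient enumeration on
every 2x2 table with total at most 30, and neighbor joining against the
3-taxon closed form, all three 4-taxon additive topologies, and the
independent `ape::nj` implementation.

Score ties in `mosaic_track()` use a 1e-9 absolute tolerance (scores are
means of 0/100 indicators, so genuine ties are exact and the tolerance
only guards floating summation). Degenerate inputs fail loudly: ragged
alignments, non-consecutive gene maps, unsorted or negative depth,
out-of-frame orthogroups, clades without members, and windows that are
even or non-positive all raise errors naming the offending object.

## Known limitations

* **Short donor segments are invisible to the label track.** A windowed
  argmax cannot represent a donor segment much shorter than half the
  window: the window majority stays with the flanking donor, so a 4-gene
  segment sandwiched between two segments of the same clade, or a few-gene
  segment at a chromosome end (where the clipped window is dominated by
  the neighbour), produces no label change. With crossovers uniform over
  junctions, occasional short segments are expected, and 20-seed
  breakpoint-recall batches typically land in the high-80s to low-90s
  percent range while donor-label accuracy stays near 98%. The per-clade score columns retain
  the signal a user needs to inspect such regions; shrinking the window
  trades this blindness for noisier labels.
* Mixture verdicts compare against clade consensus references; they
  cannot separate a true two-clade mixture from a mixture involving an
  unsampled donor whose descendants are absent from the reference panel.
* Copy-number calls assume unit mappability and integer copies; tandem
  families and partial duplications produce fractional normalized depths
  that round to the nearest integer.
* p-distances, and every identity comparison, treat `N` permissively;
  heavily N-padded assemblies bias distances downward rather than upward.
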