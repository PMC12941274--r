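---
title: "Methods: gene-family characterization on ledger-backed synthetic genomes"
author: "zfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization on ledger-backed synthetic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfam)
```

## Scope and design

`zfam` re-implements, as a tested and reusable pipeline, the bespoke
computational stages of a gene-family characterization study built around
C4-type zinc finger proteins (the DNA-binding module of nuclear hormone
receptors) in tardigrades: a domain-distribution census, multi-evidence
family identification, promoter cis-element scanning, duplicate-gene
classification with enrichment, Nei–Gojobori Ka/Ks, phylostratigraphic
gene ages, physicochemical properties, clade grouping, and
differential-expression integration.

The real study's headline counts depend on downloaded genomes, database
versions, and external tool runs (hmmscan, BLAST, MAFFT, FastTree, MEME,
DeepLoc, DESeq2, ...). Those tools are consumed as *files* here, never
executed: the package's claim is that, given equivalent inputs, each
computational stage does what it says. That claim is made checkable by a
synthetic-data generator that plants known structure — families with known
duplication layout, promoters with known element counts, codon pairs with
known dN/dS, genes with known phylostrata and expression status — and
serializes everything planted into a **truth ledger** (JSON). Every
analysis stage is then required to recover the ledger exactly (or within a
stated stochastic tolerance).

## Coordinate conventions

All coordinates are 1-based inclusive throughout, the GFF3 convention. R's
string and range infrastructure (`substr`, Biostrings, IRanges) is
1-based inclusive as well, so keeping a single convention removes the
conversion layer entirely rather than centralizing it; the round-trip
property (write → read reproduces coordinates and strands exactly) is
tested instead. Strands are exactly `+`/`-`; the nucleotide alphabet is
restricted to A/C/G/T/N on input so pattern-scanning semantics stay
unambiguous.

## The synthetic genome and what it does not emulate

`simulate_genome()` emits chromosomes of uniform-length, single-exon,
non-overlapping genes on alternating strands; each CDS begins ATG, ends
with a stop and is free of internal stops. Defaults: 4 chromosomes × 30
genes, 300 bp CDS, 4.2 kb intergenic spacing, GC 0.45. The spacing is
chosen so every gene has a full 2 kb promoter window that overlaps no
other gene's window on either strand — a deliberate idealization that
makes exact planted-count recovery well-defined. Background sequence is
i.i.d. at the configured GC.

Not emulated: introns and isoform structure beyond one transcript per
gene, repeats and higher-order sequence composition, codon-usage bias,
transition/transversion bias or rate heterogeneity in divergence,
assembly artifacts, and realistic proteome-wide amino-acid composition
(so, e.g., the fraction of hydrophilic family proteins on synthetic data
is a property of uniform random codons, not of real zinc fingers).
Passing tests therefore demonstrate the *correctness of the
computations*, not distributional realism of tardigrade genomes.

RNG discipline: every generator operation derives its own stream from
(master seed, operation label), so adding a stage never perturbs earlier
outputs, and a full pipeline rerun with one seed is byte-identical
(hash-verified manifest).

## Family planting and duplicate classification

`plant_family()` copies a founder CDS into existing equal-length gene
slots: tandem copies occupy consecutive gene ranks next to the founder,
proximal copies sit at rank distance 2–10 (never adjacent to another
member), dispersed copies go to other chromosomes (rank distance > 10
from any same-chromosome member). Planting by slot replacement keeps all
coordinates fixed. Copies are per-site mutated (start/stop fixed, internal
stops rejected); homology is emitted directly as a 12-column hit table so
tests never shell out to an aligner, while the sequences remain mutated
copies a real aligner could rediscover.

`classify_duplicates()` mirrors the MCScanX-style classifier over the
rank index: tandem if some homolog sits at rank distance 1 on the same
chromosome, else proximal at distance 2–`proximal_max_rank` (default 10,
the classifier's conventional default), else dispersed, else singleton —
priority tandem > proximal > dispersed. The WGD/segmental class is
omitted: it requires collinearity-block detection, which is out of scope,
and the family analyses report exactly the three duplicate classes plus
singletons. Rank distance is computed on *all* annotated genes, not just
family members, because the classification context is the whole
self-aligned proteome. Only intra-genome hits are used.

## Promoter extraction and cis-element scanning

The promoter is the 2000 bp immediately upstream of the representative
(longest-protein; ties to the lexicographically smallest protein id)
transcript's start codon: `[max(1, s-2000), s-1]` on the plus strand,
`[e+1, min(len, e+2000)]` reverse-complemented on the minus strand.
Truncation at a chromosome end is flagged; a start codon at the edge
yields an empty promoter with zero counts, not an error.

PFMs in JASPAR text form are reduced to IUPAC degenerate consensus
strings with the familiar Cavener-style rule (per column with sorted
counts c1 ≥ c2 ≥ c3 ≥ c4, total T: single base if c1 > T/2 and c1 > 2c2;
two-base code if c1 + c2 > 0.75T; three-base code if c4 = 0; else N), and
IUPAC words compile to character classes (R → `[AG]`, ..., N →
`[ACGT]`). Counting is greedy non-overlapping left-to-right on the
extracted strand only; both an `overlapping` option and the opposite
strand (by scanning the reverse complement yourself) remain available.
These two policies are the package's defaults because a plain
`gregexpr`-style scan of extracted upstream sequence behaves exactly this
way; neither choice is forced by the biology. An N in the scanned
sequence matches no pattern position.

The twenty packaged nematode elements ship as IUPAC words
(`nematode_elements()`). Three structural facts about this set shape the
generator: two elements (elt-3, elt-2) share one word; one word's every
realization contains another element's match (daf-16 ⊃ fkh-2, jun-1 ⊃
fos-1); and some degenerate words contain another element's match only
for particular realizations. The generator therefore plants each distinct
word once, places words adaptively (longest motifs first, topping each up
to its target against the live window), prefers realizations that create
no other listed motif's match, and `harmonize_motif_targets()` raises a
contained motif's target to what its containers guarantee. Final windows
are validated with a naive membership-scan counter that shares no code
with the regex scanner, so ledger recovery by `scan_all()` is a genuine
two-route check.

## Hypergeometric enrichment

Over/under-representation uses exact hypergeometric tails
(`stats::phyper` behind the module surface; tests compare against
exhaustive subset enumeration for all N ≤ 12). Tests are one-sided in the
observed direction — the upper tail when fold enrichment `(k/n)/(K/N)`
exceeds 1, the lower tail otherwise, with fold exactly 1 scored on the
depleted side — because the signed ±log10(P) reporting convention
(positive = enriched, negative = depleted) implies directional testing;
both tails are always present in the unfiltered table. Multiplicity is
controlled by Benjamini–Hochberg across all tested terms globally (not
per namespace); terms with zero study-set genes are not tested, to avoid
inflating the correction, and this is switchable. Reported rows satisfy
q < 0.05 and fold enrichment > 2. "lg" is read as log10.

A note on invariants: the BH *adjusted p-value map* is not idempotent
(re-application can raise values); the properties asserted in the tests
are the ones that do hold — flat vectors are fixed points, adjusted
values never decrease under re-application, and monotonicity along
ascending p is preserved.

## Nei–Gojobori Ka/Ks

Site counting: per codon position, the synonymous fraction is the number
of single-base changes preserving the amino acid divided by the number of
changes not creating a stop, summed over positions, so s + n = 3 for
every sense codon (no codon position has all three changes leading to
stops). Difference counting averages synonymous/nonsynonymous steps over
all d! substitution orderings between two codons, excluding pathways that
pass through a stop (unless all do, in which case all are kept; a step
touching a stop is never synonymous). This stop handling follows the
convention of the distance software named for the original method; the
original variant — stop-creating changes counted as nonsynonymous with
denominator 3 — is available via `stops_as_nonsyn = TRUE`, and the
enumeration oracles in the test suite cover both. Columns with gaps,
ambiguity codes or stops in either sequence are dropped pairwise
(complete deletion).

Distances use the Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p);
p ≥ 3/4 leaves the distance (and ω = dN/dS, or any ratio with dS = 0)
flagged undefined rather than raising an error. The bootstrap resamples
codon columns with replacement (default 1000 replicates, seeded,
deterministic); per-column site and difference counts are memoized table
lookups so long alignments and bootstraps cost array indexing.
Codon alignments come from protein-guided back-translation of a supplied
peptide alignment — the reproducible equivalent of a codon-aware aligner
given any protein aligner's output — with exact translation validation.

The divergence simulator applies a fixed number of *accepted*
substitution events: proposals creating stops are redrawn; for ω ≤ 1
nonsynonymous proposals are accepted with probability ω (synonymous
always), for ω > 1 synonymous proposals with probability 1/ω. Calibration
at the study scale (500 codons, 200 events, 20 replicates per ω) recovers
ω = 0.2 vs ω = 1.0 with non-overlapping group means; the tables are
produced by `analysis/06_molevol_age.R`.

## Gene age, clade groups, integration

Phylostratigraphy: a species carries a homolog iff both reciprocal
E-values are strictly below 1e-5 ("less than", so the boundary is
excluded); a gene's age is the oldest ladder stratum containing a species
with a called homolog, defaulting to the youngest stratum. Any-hit (not
best-hit-only) evidence per species is accepted. The packaged ladder has
the four grades used for tardigrade genes (Cellular organisms, Eukaryota,
Metazoa, Tardigrada-specific) and is fully configurable.

Clade grouping consumes a newick tree (inference is external), reroots at
a named outgroup leaf, and makes the manual clade delineation reproducible
through anchors: each group is the MRCA clade of its anchor leaves, and
overlapping group clades are an error rather than silently resolved.

Integration applies the expression filter |fold change| > 2 (i.e.
|log2FC| > 1) and p < 0.05, both strict, on the raw p-value column by
default (configurable to an adjusted column); flags groups whose
significant members all share one direction (NA when a group has none);
reports the fraction of upregulated genes carrying ≥ 1 cis element; and
reconciles subcellular localisation by letting the primary predictor's
compartment stand while flagging auxiliary disagreement as a conflict.

Family identification follows the three-channel protocol: BLASTp evidence
at E ≤ 1e-5 (inclusive, as that channel's protocol states) and three
profile-HMM channels at their stated strict thresholds (seed model
< 1e-2, full model < 1e-5, published-domain model < 1e-2), merged as a
union with exact-id deduplication; validation keeps candidates confirmed
by ≥ 1 of the four domain sources (a require-all rule would contradict
merging four partial sources), minus an explicit exclusion list, with
full provenance columns. The census counts *distinct proteins carrying a
domain* (not domain instances) over the denominator of proteins with ≥ 1
annotated domain, which keeps m and M in [0, 1]; a domain absent from the
reference panel reports p as flagged-undefined, never infinity.

## Problem sizes and determinism

The default study runs 120 genes (14 planted family members across three
families), 19 distinct planted motif words, Ka/Ks with 200-replicate
bootstraps over the family pairs, and ω calibration at 500 codons × 20
replicates — sizes chosen so the full pipeline, run twice for the
byte-identity check, completes in a few minutes on one core while leaving
every recovery property exact. `scripts/acceptance.R` re-runs the whole
study from a single `--seed` and writes the resulting quantities as JSON.

## Known limitations

Tree inference, aligners, HMM scanners, DE model fitting and GO
annotation are consumed as files, never run. The duplicate classifier has
no WGD/segmental class. PWM scanning is pattern-count based (no log-odds
threshold scanning). The DE p-value column is taken as printed (raw by
default). Synthetic realism is deliberately minimal, as described above.
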