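---
title: "Methods: comparative genomics of conjugative elements with mobilomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of conjugative elements with mobilomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilomics)
```

# Scope

`mobilomics` implements an end-to-end comparative analysis of conjugative
elements (CEs) — plasmids, chromids and integrative and conjugative elements
(ICEs) — in bacterial genomes: species delineation by average nucleotide
identity (ANI), protein-sharing networks among elements, rule-based mobility
classification, defense-system inventories (CRISPR, toxin–antitoxin,
restriction–modification), core-genome phylogeny, ICE backbone/hotspot
decomposition with windowed SNP profiles, composition-based chromid
diagnosis, and metagenomic fragment recruitment with RPKG normalisation.
A synthetic mobilome generator with complete ground-truth records makes the
whole pipeline testable without any external data download.

This vignette documents the models, the defaults and why they were chosen,
the numerical conventions, and the limits of what the synthetic tests can
show about real data.

# The alignment kernel

Every stage shares two alignment primitives, implemented in C++.

**Local alignment** (`align_local`) is a k-mer-seeded, banded Smith–Waterman
with affine gaps. A gap of length $L$ costs `gap_open` $+ L\,$`gap_ext`
(defaults 5 + L for nucleotides; BLOSUM62 with 10 + L for proteins). When
the full dynamic-programming matrix fits a cell budget (2M cells) the exact
unbanded optimum is computed; otherwise seed k-mers (k = 13 nt / 5 aa) are
clustered by diagonal and the top clusters are evaluated in a padded band.
Identity is **always** matches / alignment columns with gap columns counted
in the denominator (the BLAST convention), and ambiguity codes (N, X) never
match — the conservative choice for SNP calling. Coverage is aligned query
bases / full query length.

**Whole-genome alignment** (`align_genomes`) finds maximal exact matches
that are unique in both sequences (MUM-like anchors, minimum 20 bp), chains
them collinearly (small anchor overlaps from chance extensions are allowed
and trimmed), and closes inter-anchor gaps by full affine-gap global
alignment. Two rules matter:

* Gap pairs at least 200 bp on both sides whose global alignment score is
  not positive are **left unaligned**. With match +1 / mismatch −2, a
  positive global score separates homologous segments (up to roughly 20%
  divergent) from unrelated cargo cleanly; force-aligning unrelated
  cassettes would fabricate SNPs inside what are really presence/absence
  differences.
* Aligned runs separated by fewer than 90 gap columns are merged into one
  block; per-block identity keeps gap columns in the denominator.

Tie-breaking in the traceback is fixed (diagonal, then gap-in-query, then
gap-in-target; opening preferred over extension at equal score) so output
is deterministic, and on small problems the SNP calls are identical to a
full Needleman–Wunsch/Gotoh reference — the test suite asserts exact
agreement against an independent plain-R implementation on hundreds of
random mutated pairs, and score agreement with `Biostrings::pairwiseAlignment`.

Small inputs (≲ 2 kb × 2 kb) skip anchoring entirely and run the single
full-matrix pass.

# ANI and genospecies

`compute_ani` follows the classic fragment convention: the query genome is
cut into consecutive 1020-bp fragments, each is aligned to the other genome
on both strands, and fragments aligning at ≥ 30% identity over ≥ 70% of
their length contribute their identity to the directed mean. The reported
ANI is the arithmetic mean of the two directed values. The 1020/30/70
constants are the established defaults of fragment-based ANI tools; the
analysis itself only fixes the species threshold (95%).

`cluster_genospecies` is single-linkage: genomes are vertices, pairs with
symmetrised ANI at or above the threshold are edges, genospecies are
connected components, labelled `GS1, GS2, ...` by their smallest member id
for determinism. Raising the threshold can only split components, never
merge them (tested as a property).

# Protein-sharing networks and homolog scans

`build_sharing_network` performs an all-versus-all protein comparison
between elements. A shared protein pair is a best hit at ≥ 90% amino-acid
identity covering ≥ 70% of the query; the edge weight is the number of
*distinct unordered* protein pairs, so reciprocal hits are not counted
twice and two elements sharing ten identical proteins get one edge of
weight 10. Nodes without edges stay in the graph as singletons. The same
90/70 rule is applied in both directions — the coverage filter is applied
throughout, not only when counting.

`homolog_scan` counts each query protein at most once per target proteome
(best hit only), which prevents paralog inflation; thresholds of 70% (CE
proteins vs chromosomes) and 50% (chromid vs chromosome) are the intended
operating points.

# Mobility classification

`classify_mobility` is driven entirely by a user-editable marker rule table
(`default_marker_rules()`): relaxase (MOB) rows and a 12-gene
mating-pair-formation (MPF/T4SS) set whose `required` rows define
completeness. The logic is:

* **C** (conjugative): any relaxase present and all required MPF genes
  present;
* **MB** (mobilizable): relaxase present, MPF incomplete — the "incomplete
  T4SS" case; relaxase presence alone suffices, since oriT detection is
  out of scope;
* **NMB** (non-mobilizable): no relaxase.

Completeness is binary (all required rows present), with the observed
fraction reported as evidence; the call depends only on marker presence,
never on feature order. Markers match either by gene-name regex or by
alignment to a protein exemplar at a per-row identity threshold.

# CRISPR arrays and spacers

`detect_crispr` seeds candidate arrays with 8-mers recurring at CRISPR-like
periods (repeat 23–55 bp, spacer 0.6–2.5 × repeat length), then grows
repeat boundaries by column consensus across the repeat units: a column is
accepted when at least $n - 1$ of $n$ units (and at least 75%) agree and
no unit exceeds its per-repeat mismatch budget (default 1). Imperfect
terminal columns are trimmed so clean arrays are recovered with
byte-identical spacers. Spacer lengths must stay within ±25% of their
median. Overlapping candidates are resolved by most repeats, then
leftmost. With very few repeats (n = 3) boundary determination is
intrinsically noisier; the detector is calibrated for the 6–10-repeat
arrays typical of the systems this package targets.

`match_spacers` reports best hits per spacer over both strands, requiring
93% identity over the full spacer length by default — the operating point
at which a spacer–protospacer link is still credible.

# TA, RM and integration hallmarks

A toxin–antitoxin locus is a toxin and antitoxin of the same family
(relBE, HipAB, MazFE, vapBC, parED) on the same strand within 500 bp — the
bicistron rule. An RM system is a REase + MTase pair of the same type
(I–IV) within 3 kb, or a lone member reported as incomplete with its
surviving component (loss of the REase is the common degradation mode).
Counts are additive over concatenated replicons.

`detect_trna_duplication` looks for the hallmark of a single integration
event at a tRNA locus: a duplicated copy of the tRNA's 3'-end downstream.
Each downstream exact copy of the 3'-terminal 10-mer is extended leftwards
while it still matches the tRNA end (capped at 30 bp); copies within 2 bp
of the best extension are candidates and the farthest wins, which makes
nested islands report the outermost boundary while random short matches
lose to the true duplication. The island generator keeps the boundary
unambiguous by never ending an island with the base that precedes the
duplicated fragment.

`diagnose_chromid` calls a megaplasmid a chromid when it carries at least
3 essential single-copy markers (DNA ligase, DNA polymerase III β,
topoisomerase IV subunits, RecA, tRNA(Ile)-lysidine synthetase — matched
by product regex) *and* at least one tRNA isoacceptor already encoded on
the chromosome (functional redundancy).

# Core genomes and phylogeny

`find_orthologs` replaces profile-HMM orthology with reciprocal best hits
at 70% identity / 70% coverage — database-free and adequate for the
single-copy core role. Mutual-best in-genome hits (paralog edges) join
duplicated genes into the same component, which then fails the
one-per-genome core rule, so duplications disqualify their group from the
core rather than silently passing.

`align_core_and_concatenate` uses center-star multiple alignment per group
(center = member minimising summed pairwise distance; merging by "once a
gap, always a gap"), concatenated in sorted group order. Center-star is
deterministic and accurate for the high-identity core genes it is applied
to; it is not intended for deeply divergent families. A variable site is a
column with at least two distinct non-gap characters.

`distance_matrix` implements the Kimura two-parameter closed form
$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ over columns ungapped
in both rows (P transitions, Q transversions), the Poisson amino-acid
distance $-\ln(1-p)$, and the raw p-distance. Saturated pairs (log
argument ≤ 0) are reported as `Inf` with a warning rather than clamped.
The implementation is cross-checked against `ape::dist.dna` in the tests.

`neighbor_joining` delegates to `ape::nj` (canonical Saitou–Nei) and then
clamps negative branch lengths to zero, moving the deficit to the sister
branch so path lengths are preserved. Maximum-likelihood and
recombination-aware methods are deliberately out of scope; on the
high-identity concatenates this package produces, NJ recovers additive
topologies exactly (a property the suite sweeps over random trees).

# ICE backbone and hotspots

`extract_ice_core` aligns every element to the longest one (the
reference), intersects the aligned reference intervals across all
elements, and keeps intersections ≥ 500 bp. Variable sites and identity
are computed on a reference-anchored character matrix (element bases at
reference positions; insertions relative to the reference do not add
columns). The summary identity is defined as the **length-weighted mean
pairwise identity over all element pairs** within core blocks; an
alternative would be column-consensus identity, which is systematically
higher — the pairwise definition is the one that corresponds to "average
identity at the nucleotide level" between family members and is what the
package reports.

`snp_windows` bins SNPs into non-overlapping 1000-bp windows on the
reference; windows without aligned coverage are `NA`, never zero — absence
of homology is not absence of variation. `detect_variable_regions` calls
maximal unaligned intervals ≥ 2 kb (merging intervals separated by < 200
aligned bp) on either sequence: these are the hotspots and cargo
cassettes. Because unalignable gap pairs are never force-aligned, core
blocks and VRs partition the reference without overlap.

`classify_snps` makes codon-aware synonymous/nonsynonymous calls with the
standard genetic code (single codons are translated by table lookup, not
as initiators), taking the most severe call when CDS overlap.

# Composition and the module contrast

`composition` reports global and windowed GC and GC skew (windows wrap on
circular replicons), tetranucleotide z-scores, CAI and coding density.
Tetranucleotide expectations use the maximal-order (order-2) Markov model,
$E[n_{abcd}] = n_{abc}\,n_{bcd}/n_{bc}$, with the standard variance
approximation $\mathrm{Var} \approx E\,(n_{bc}-n_{abc})(n_{bc}-n_{bcd})/n_{bc}^2$,
both strands pooled; on random sequences the z-scores are calibrated to
mean 0, sd 1 (tested over seeds). CAI is Sharp & Li relative adaptiveness
(geometric mean of codon weights, single-codon families excluded; codons
absent from the reference floored at w = 0.01 and flagged). The default
CAI reference is the replicon's CDS annotated as ribosomal proteins — the
conventional highly expressed set — and is overridable.

`compare_modules` splits a circular replicon at two breakpoints and
contrasts the arcs on |ΔGC|, |ΔCAI|, |Δ coding density| and the cosine
distance between tetranucleotide z-vectors. Significance comes from a
permutation test that shuffles 5-kb window (and gene) arc labels, with
empirical p-value $(1 + \#\{perm \ge obs\})/(B+1)$ and a fixed seed. The
underlying analyses in this field typically assert "no significant
difference" without naming a test; the permutation test *is* this
package's operational definition of that statement, and its null
calibration is itself part of the test suite.

# Recruitment

`recruit` aligns each read on both strands and recruits it when the best
hit reaches the identity cutoff over at least 70% of the **full read
length**. The stringent default (99%) targets near-identical populations;
95% is the relaxed cutoff for more divergent replicons such as chromids.
One best hit per read per replicon; in a panel, a read may be recruited by
several replicons (profiles are independent, as in per-genome
recruitment), with RPKG = reads recruited / (replicon kb × metagenome Gb)
and metagenome size defaulting to the total bases of the read set. Note
that local alignment may clip a read's mutated ends, so the recruited
fraction at a strict cutoff sits slightly above the naive binomial
prediction from per-base divergence; the 70% length filter bounds how much
clipping can help.

# The synthetic mobilome

The generator is first-class, tested code, and defines the conditions the
test suite and the acceptance script run under:

* ancestors hit a GC target within ±0.01 (intergenic GC is tuned to
  balance the codon-tilted genes) and a coding density near the requested
  fraction, with valid ORFs only, one tRNA, a `prfC` gene (the SXT/R391
  integration target) and ribosomal-protein annotations so the default
  CAI reference exists;
* `derive_strain` implants substitutions (site-wise Binomial, or an exact
  count for near-clonal pairs) and geometric-length indels, with every
  event recorded in derived coordinates;
* conjugative elements carry marker complements that encode their mobility
  class; cargo cassettes default to 3% lower GC than the host, the typical
  plasmid–chromosome offset;
* `simulate_ice_family` derives each element from a shared backbone at
  **half** the target pairwise divergence (so two elements differ at the
  stated rate) and inserts private cassettes at fixed hotspot positions;
* metagenomes are single-end fixed-length reads, strand-symmetric, with
  uniform substitution errors and full per-read truth.

What the generator does **not** emulate: rearrangements and inversions,
codon-usage evolution, transposable-element proliferation, quality-score
structure, paired ends, or compositional heterogeneity beyond the knobs
above. Green tests therefore demonstrate correctness of the algorithms
under point-mutation + insertion/deletion divergence with cassette
turnover — the regime the analysis targets — not robustness to assembly
artefacts or inversion-rich histories.

Problem sizes used by the shipped tests and the acceptance script (chosen
as the smallest sizes at which the statistics are stable): a 4-Mb
chromosome for the near-clonal strain pair, 40–60-kb genomes for ANI and
genospecies recovery, a 46-kb ICE backbone with five elements at 3.5%
pairwise divergence, 20 seeded CRISPR arrays plus ten 100-kb negative
controls, 500–1000-read metagenomes, 50 random 6–10-taxon trees, and 20
homogeneous 40-kb sequences for the permutation-test null.

# Determinism and seeds

All generators take explicit integer seeds; identical seed and
configuration give byte-identical sequences, features and files.
`run_pipeline` fans one global seed out to stages by a stable hash of the
stage name, so skipping a stage never changes another stage's output, and
rerunning a pipeline reproduces every TSV byte-for-byte.

# Known limitations

* The seeded local aligner guarantees the exact optimum only when the full
  matrix fits the cell budget; for very large targets it is a best-hit
  heuristic (top diagonal clusters), like every seeded mapper.
* `align_genomes` does not chain across inversions; an inverted segment
  appears as a variable region.
* The CRISPR detector's boundary consensus is designed for ≥ 4 repeats;
  3-repeat arrays at the detection floor may have imprecise edges.
* RBH orthology under-groups very fast-evolving or horizontally chimeric
  families; the core set is intentionally conservative.
* Recruitment identity is computed on aligned columns, so strict cutoffs
  interact with end-clipping as described above.
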