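# mobilomics

Comparative genomics of the marine mobilome: plasmids, chromids and
integrative and conjugative elements (ICEs), analysed as one reproducible
pipeline in R.

Marine bacteria of the same species can differ enormously in their
conjugative elements (CEs): megaplasmids that have picked up
chromosome-like cargo ("chromids"), SXT/R391-family ICEs integrated 5' of
*prfC* that swap cassettes at a handful of hotspots, and small plasmids
that move by transformation rather than conjugation. `mobilomics` is for
microbial genomicists who want to run that comparative analysis —
species delineation, element networks, mobility typing, defense-system
inventories, backbone/hotspot decomposition, composition contrasts and
metagenomic abundance — from plain FASTA/GFF3 inputs, with every stage
testable against a built-in synthetic mobilome whose ground truth is
recorded down to each SNP, cassette and CRISPR spacer.

## What it computes

* **ANI and genospecies** — fragment-based average nucleotide identity
  (1020-bp fragments, ≥ 30% identity over ≥ 70% of the fragment kept;
  ANI = mean identity of kept fragments, symmetrised), single-linkage
  clustering at the 95% species threshold.
* **Protein-sharing networks** — all-vs-all protein comparison among
  elements; an edge weight is the number of distinct protein pairs shared
  at ≥ 90% amino-acid identity over ≥ 70% coverage.
* **Mobility classes** — rule-table-driven MOB/MPF logic:
  conjugative (**C**, relaxase + complete T4SS), mobilizable (**MB**,
  relaxase + incomplete T4SS), non-mobilizable (**NMB**, no relaxase).
* **Defense and integration hallmarks** — CRISPR arrays (repeat–spacer
  detection, spacer matching at 93% full-length identity), toxin–antitoxin
  bicistrons (relBE, HipAB, MazFE, vapBC, parED), complete/incomplete
  restriction–modification systems, duplicated tRNA 3'-ends, chromid
  diagnosis (essential single-copy markers + redundant tRNAs).
* **Core genomes and phylogeny** — reciprocal-best-hit orthologs,
  center-star concatenated alignments, K2P distances
  d = −½ ln(1−2P−Q) − ¼ ln(1−2Q), neighbour-joining trees.
* **ICE backbone decomposition** — shared core blocks ≥ 500 bp across a
  family, variable regions/hotspots, SNPs averaged in 1000-bp windows,
  synonymous/nonsynonymous calls.
* **Fragment recruitment** — reads recruited at 99% identity over 70% of
  the read (95% for divergent targets), RPKG = reads per Kb of replicon
  per Gb of metagenome.
* **Synthetic mobilome** — generators for chromosomes, strains, CEs,
  CRISPR arrays, tRNA islands, ICE families and metagenomes, each
  returning a TruthRecord used by the test suite.

The alignment engine (seeded banded Smith–Waterman and MUM-anchored
whole-genome alignment with affine-gap closure) is implemented in C++ and
is exact against full dynamic programming on small inputs — the test
suite asserts SNP-level agreement with an independent oracle.

## Worked example

Simulate a family of five ICEs that share a 46-kb backbone at 3.5%
pairwise divergence with private hotspot cassettes, then recover the
backbone:

```r
library(mobilomics)

fam  <- simulate_ice_family(n_elements = 5, backbone_len = 46000,
                            divergence = 0.035, seed = 11)
core <- extract_ice_core(fam$elements, min_block = 500)
core
#> <ice_core> 4 blocks, 45,864 bp core, 3876 variable sites, 96.5% identity, 45 genes

glance(core)
#> # A tibble: 1 x 6
#>   reference n_blocks core_length variable_sites average_identity n_genes_in_core
#>   <chr>        <int>       <int>          <int>            <dbl>           <int>
#> 1 ICE01            4       45864           3876            0.965              45
```

The reported core (45,864 bp over 4 blocks, the backbone minus the three
5-kb hotspots) recovers the implanted 46-kb backbone within 0.3%, and the
96.5% mean pairwise identity is exactly the divergence the family was
built with. A pairwise SNP profile along the reference:

```r
g  <- align_genomes(fam$elements[[1]], fam$elements[[2]])
sw <- snp_windows(g, window = 1000)
plot_snp_profile(sw)
detect_variable_regions(g)   # the three swapped hotspot cassettes
```

Mobility typing on a simulated conjugative plasmid:

```r
el <- build_conjugative_element("pDEMO", "MB", seed = 5)
classify_mobility(el$replicon)
#> # A tibble: 1 x 6
#>   element class mob_present mpf_completeness n_mpf_present n_mpf_required
#>   <chr>   <chr> <lgl>                  <dbl>         <int>          <int>
#> 1 pDEMO   MB    TRUE                   0.583             7             12
```

The relaxase is present but only 7 of the 12 required mating-pair
formation genes are — an incomplete T4SS, so the element is mobilizable
but not self-transmissible.

`run_pipeline(pipeline_config(...))` chains every stage over a set of
replicons (plus optional reads) and writes deterministic TSV/GraphML/
newick outputs with a JSON manifest.

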