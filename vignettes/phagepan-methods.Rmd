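---
title: "Methods: gene-content phage grouping, RBP phylogeny, and host-genotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-content phage grouping, RBP phylogeny, and host-genotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phagepan implements a desk-scale comparative-genomics pipeline for dairy
*Streptococcus thermophilus* phages and their host strains. The scientific
question it serves is host-range prediction: phages of this species attach to
cell-wall polysaccharides — exocellular polysaccharides encoded by the *eps*
operon and rhamnose-containing polysaccharides encoded by the *rgp* operon —
through their receptor-binding protein (RBP), so phage lineages defined by
RBP sequence should track the polysaccharide genotype of the strains they
infect. The pipeline quantifies that association from annotated genomes
alone.

This vignette documents the models and procedures, the tunable parameters
and their defaults, the simulator that generates test populations, the
numerical choices, and the known limitations.

## Pipeline overview

1. **Orthology** (`all_vs_all()`, `bbh_edges()`, `ortholog_groups()`).
   Translated proteins are compared all-versus-all across genomes with exact
   global alignment; hits passing identity/coverage thresholds feed a
   bidirectional-best-hit (BBH) graph whose connected components are the
   ortholog groups.
2. **Pangenome** (`build_matrix()`, `jaccard_distances()`, `upgma()`,
   `cut_dendrogram()`, `pangenome_stats()`). Genomes-by-groups
   presence/absence, Jaccard distances, average-linkage clustering, a k = 4
   cut into phage groups, and core/unique/near-core statistics.
3. **Phylogeny** (`select_rbps()`, `progressive_msa()`, `msa_nj_tree()`,
   `bootstrap_support()`, `tree_clusters()`, `concatenate_core()`). RBP and
   concatenated-core trees by neighbor joining on Poisson-corrected protein
   distances; lineages by single-linkage patristic clustering.
4. **Operon typing** (`locate_cluster()`, `operon_matrix()`,
   `assign_genotypes()`, `type_strains()`). *eps*/*rgp* clusters are
   extracted between flanking markers (epsA / predicted membrane protein
   TMS6; radC / bactoprenol glucosyl transferase), re-clustered by gene
   content under a relaxed identity preset, and labelled A, B, C, ...
5. **Association** (`build_association()`, `hypergeom_pmf()` and
   relatives, `shared_host_concordance()`). Exact
   sampling-without-replacement probabilities for "phages of these RBP
   clusters infect hosts of these genotypes".

## Alignment substrate

All sequence comparison rests on exact Needleman–Wunsch global alignment
with affine gaps (Gotoh's algorithm, implemented in C++). Defaults are
BLOSUM62 with gap open 11 and extension 1; a gap of length $L$ costs
$11 + L$. Three conventions needed fixing, since the upstream literature
leaves them ambiguous:

* **Identity** is identical columns divided by columns where *both* rows
  carry a residue (one of several BLAST-compatible conventions).
* **Coverage** of a sequence is the fraction of its residues aligned
  opposite a residue of the partner. The coverage threshold applies to
  *both* sequences by default (`coverage_mode = "both"`); a one-sided mode
  exists. The symmetric rule avoids asymmetric ortholog graphs.
* **Traceback ties** prefer match/mismatch, then gap-in-second, then
  gap-in-first — fixed so results are reproducible to the byte.

A shared 4-mer prefilter skips hopeless pairs: a pair is aligned only when
it shares at least `kmer_min` distinct 4-mers (default 3), scaled up with
length as a quarter of the conservation expected at the identity floor
(a pair at identity $p$ conserves $\approx p^4$ of its 4-mers, so a
100-residue pair at the 50% floor still shares about six). Unrelated random
proteins share three or more 4-mers so rarely that the filter removes
essentially all of the quadratic background; `kmer_min = 0` disables it,
and every filtered pair is treated as identity 0. Length-ratio pairs that
cannot reach the coverage floor are skipped on the same grounds.

The progressive aligner builds a UPGMA guide tree from pairwise alignment
identities and merges profiles leaf-to-root with average-of-pairs column
scores; with two sequences it reduces exactly to the pairwise aligner.
Input order does not matter (sequences are processed in label order).
Phylogeny-aware gap placement of the kind prank performs is *not*
attempted: the alignment only has to support distance computation.

## Distance-based phylogeny in place of maximum likelihood

Tree inference is neighbor joining (via ape) on Poisson-corrected protein
distances $d = -\ln(1 - p)$ with the p-distance capped at 0.95 before the
logarithm so saturated pairs stay finite. This is a deliberate design
choice: the downstream claims rest entirely on clade membership of
well-separated lineages, which NJ recovers exactly on additive data (a
property the test suite checks on 100 random additive matrices), and a
dependency-free distance method keeps the pipeline deterministic and fast.
Maximum-likelihood inference under GTR/GAMMA or WAG, as practiced on the
real data, is out of scope and would be the natural upgrade for users with
marginal clades. Negative NJ branch estimates are clamped to zero with the
deficit moved to the sister edge, preserving path lengths through the
parent. Bootstrap support resamples alignment columns with replacement and
reports the percentage of replicates containing each original bipartition.

RBP lineages are read off the tree by single-linkage clustering on
patristic distances at a stated threshold (default 0.3 substitutions/site).
The published analysis delineated clusters by comparing phylogram and
radial layouts by eye; a threshold rule is the reproducible substitute, and
the threshold is an exposed parameter, not an inferred intent. RBPs whose
best identity against every other RBP falls below 30% are excluded before
tree building (no credible homology, hence no phylogeny); the boundary is
closed — exactly 30% stays in.

## Operon typing

Markers are found by exact product-string match on annotated genomes, or by
global-alignment identity ≥ 0.5 against user-supplied marker proteins when
annotations use a different vocabulary. With both markers on one contig the
cluster is the genes strictly between them, in either marker order. With
markers on two contigs the cluster is read from each marker towards its
contig end on the marker's downstream side (strand-aware), flagged
`complete = FALSE` and still typed on partial content — mirroring how the
split-contig strains in the study were handled — so users can filter on the
flag. Operon ortholog groups use the relaxed preset of 40% identity and 80%
coverage: polysaccharide operon genes travel by horizontal transfer and
diverge faster than the genome average, but homologs remain near-full
length.

Genotype letters come from Jaccard + UPGMA on the operon presence/absence
matrix. No cut rule is printed in the source material; the default is a
height cut at Jaccard distance 0.5, with `k` as an override. On simulated
populations the planted genotype count is known and `k` recovers the
genotypes exactly; the height default is an exploratory tool, and with
heavily overlapping gene pools two genotypes can merge below 0.5 — which is
a fact about the data, not an error. Letters are assigned A, B, ... by
decreasing cluster size, ties broken by smallest strain id.

## Exact association probabilities

The association statistic is the hypergeometric probability of the observed
draw: from $N$ phages of which $K$ infect hosts of the designated genotype
letters, the $n$ phages of the designated RBP clusters contain $k$ such
"successes". When the draw is pure ($k = n$) the reported probability is
$\binom{K}{n}/\binom{N}{n}$; otherwise the upper tail from the observed
count (the "all but one" phrasing maps to at-least-$(n-1)$; a point-mass
option exists behind `tail = "point"`). A phage with several listed hosts
counts as a success only when *every* host matches — no such phage occurs
in the bundled analysis table, so the convention is untested by real data
and is stated rather than inferred. Probabilities are computed exactly:
binomial coefficients are expanded into prime-power exponents (Legendre's
formula), all cancellation happens on integer exponents, and only the final
product is evaluated in floating point. The test suite pins the two
bundled-table probabilities to their exact rational values
($33/117{,}285{,}338 \approx 2.81\times10^{-7}$ and
$1698/8{,}675{,}723 \approx 1.96\times10^{-4}$) and checks the pmf against
exhaustive subset enumeration for all populations up to $N = 12$. No
multiple-testing correction is applied, matching the raw probabilities the
analysis reports.

## The simulator and what it does (and does not) show

`simulate_population()` generates the study conditions: four phage groups
of 20/10/4/4 genomes; 40–63 genes per genome drawn uniformly; per group a
pool of 120 ancestral protein families (100–400 aa, uniform over the
20-letter alphabet) plus 20 families shared across groups; 13 core families
per group carried by every member, the rest sampled without replacement per
genome (mosaic accessory content); per-copy point substitution at rate
0.05. Each genome carries exactly one RBP: a 100-aa N-terminal region
conserved within its group plus a 200-aa variable region drawn per lineage
at divergence 0.4 from the group ancestor and mutated at 0.05 per copy. Six
RBP lineages are spread round-robin over the four groups, echoing the
several-lineages-per-group structure of the real data. Host strains (23,
matching the analysis set) carry an *eps* cluster of 13–22 genes and an
*rgp* cluster of 14–20 genes — brackets chosen to emulate the reported
averages of 17.7 and 16.8 with minima 13 and 14 — between fixed literal
marker proteins, with genotype-specific gene subsets drawn from pools of
30 families; 6 EPS and 5 RGP genotypes are assigned round-robin, which
guarantees strain pairs that share an EPS genotype but differ in RGP
genotype. Host range links each phage to one or two strains of the EPS
genotype matched to its RBP lineage, flipped to a non-matched genotype with
probability `host_range_noise` (default 0: the noise-free limit is the
ground truth for recovery tests).

All randomness flows from one master seed through named per-object
substreams, so populations are bit-reproducible and adding a genome never
perturbs existing ones.

What passing recovery tests shows: the pipeline's operators correctly
invert the generative structure they assume — group-private gene pools,
lineage-structured RBPs, genotype-structured operons. What they do not
show: robustness to real-data phenomena the simulator deliberately omits —
recombination breakpoints within genes, shared ancestry between group
pools, annotation errors, genes split across contigs, temperate/lytic
biology, and compositional (non-uniform) protein alphabets. The random
alphabet is a conscious choice: every downstream operator consumes only
identity and coverage, for which compositional realism is irrelevant, while
random sequences make the "unrelated pairs stay far below threshold"
property provable and testable.

## Numerical and determinism choices

* Internal coordinates are 0-based half-open; GFF3 I/O converts from/to
  1-based inclusive. Reverse-strand CDS are translated from the reverse
  complement with the bacterial genetic code (table 11), applied literally
  (no initiator-codon remapping) so protein round trips are exact.
* UPGMA is `stats::hclust(method = "average")` — the same tool the original
  analysis used; merge heights are average distances, and the exported
  ultrametric tree halves them so leaf-to-leaf path lengths reproduce the
  input (cophenetic identity, property-tested on random ultrametrics).
* Cluster labels are deterministic everywhere: by smallest leaf
  (dendrogram cuts, roman-numeral tree lineages) or by decreasing size then
  smallest strain (genotype letters). Best-hit ties break lexicographically.
* The hypergeometric routines reject out-of-range counts rather than
  clamping them.

## Problem sizes

The shipped tests run the full pipeline on 20 independent default
populations (38 genomes, ~2,000 proteins, 23 strains each) for the recovery
suite, plus property suites at small n (alignments up to length 8 against
exhaustive enumeration, trees up to 10 leaves, populations up to N = 12 for
the exact probabilities); `scripts/acceptance.R` re-runs the recovery on 5
populations by default (`--n-populations` raises it). These sizes were
chosen so the whole battery completes comfortably on one CPU while keeping
every check at full strength.

## Known limitations

* Distance-based trees, not ML: fine for well-separated lineages, not for
  marginal clades; no model selection.
* The `similarity = 1` Proteinortho-style setting is interpreted as strict
  reciprocal best hits with component grouping; near-best expansion and
  spectral partitioning are not implemented.
* "Unique genes" means singleton columns of the presence/absence matrix;
  a genome-private family with cross-genome paralog structure would be
  counted differently under other definitions.
* Sub-cluster structure inside phage groups is exposed only through
  user-chosen dendrogram cuts; there is no automatic sub-cluster detection.
* Multi-contig assemblies are taken in the contig order given; no
  reordering or scaffolding is attempted.
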