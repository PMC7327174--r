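---
title: "Methods: multiheme cytochrome repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiheme cytochrome repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: what each stage
computes, the assumptions behind it, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## MHC calling from CXXCH motifs

A c-type cytochrome binds each heme covalently at a CXXCH attachment site:
cysteine, two arbitrary residues, cysteine, histidine. `find_heme_motifs()`
enumerates **every** occurrence, including overlapping ones — two sites can
share the second cysteine, so consecutive starts may be only 3 residues
apart. The field's operational threshold for calling a protein a putative
multiheme cytochrome is **at least 3 motifs** (`min_motifs = 3` in
`call_mhc()`/`scan_proteome()`).

Decisions around the edges of the definition:

- **Overlap**: all occurrences count by default. Whether overlapping sites
  should count separately is not settled usage, so a `disjoint = TRUE`
  option provides greedy non-overlapping counting instead.
- **Stops and ambiguity codes**: one terminal `*` is stripped (gene-caller
  artifact); internal stops are rejected. `X` matches the two wildcard
  positions but never the anchored C/C/H — a conservative choice that
  avoids calling motifs into ambiguous sequence.
- **Domain verification**: comparative workflows commonly verify MHC calls
  with cytochrome-domain HMM searches. That step is pluggable here: pass a
  domain hit table (`domains=`) to fill `has_cyt_domain`/`has_slayer_domain`;
  core calling never requires it and defaults to `"untested"`.
- **NiFe L1/L2 motifs**: `check_nife_motifs()` ships canonical default
  expressions (`RxCGxCxxxH`, `DPCxxCxxH`) chosen by this package; they are
  flagged in a message as implementation defaults and should be overridden
  to match whatever reference scheme a study uses.

## Local alignment, bit scores, E-values

`align_pair()`/`search_all()` delegate optimal local (Smith–Waterman
style) alignment to Biostrings with BLOSUM62 and affine gap penalties
(open 11, extend 1) — the common blastp parameterisation. Raw scores are
converted with Karlin–Altschul constants `lambda = 0.267`, `K = 0.041`
(the blastp gapped defaults) via `S' = (lambda*S - ln K)/ln 2`, and
E-values use the closed form `E = m*n*2^(-S')` with `m` the query length
and `n` the database residue count. Exact blastp score parity is **not** a
goal: all thresholds in this package are applied to this aligner's own
outputs, which an independent Gotoh dynamic-programming implementation in
the test suite verifies exactly.

Percent identity is identical columns over **alignment length including
gap columns** (`pid_denom = "alignment"`, mirroring blastp tabular
reporting; `"shorter"` is available). Because local alignment trims weakly
matching stretches, hit identity generally sits a few points above the
global identity of the two sequences — relevant when interpreting
thresholds near a planted divergence level.

Symmetric all-vs-all searches align each unordered pair once and mirror
the hit (scores and identities are symmetric; E-values are recomputed per
direction). Best-hit ties break deterministically: bit score, then
alignment length, then lexicographic subject id.

## Reciprocal best hits and AAI

`compute_aai()` implements the standard RBH-based average amino acid
identity: mean hit identity over reciprocal best hit pairs passing
`min_identity = 30` (percent) and `min_coverage = 70` (percent of the
shorter sequence spanned by the alignment). These filter defaults follow
common AAI practice; published AAI tools rarely print their internal
filters, so they are explicit, logged parameters here.
Genome pairs are ordered canonically before searching, making
`AAI(a, b) == AAI(b, a)` exact. Zero qualifying pairs yield an explicit
`NA` ("undefined AAI"), never a number.

A caveat the package's own validation surfaced: in small proteomes, a
protein whose ortholog is absent from the other genome can form a weak
(~30% identity) reciprocal pair that passes the default filters and visibly
drags the mean — at realistic proteome sizes this noise is diluted.
The planted-identity validation study therefore plants every family in
both genomes (each protein has a true ortholog) via an explicit presence
matrix.

## Orthologous families

`build_homology_graph()` draws an undirected edge between two proteins iff
**both** directed best hits pass `max_evalue = 1e-3`,
`min_identity = 50`, and `min_coverage = 50` (percent of the shorter
sequence). The coverage criterion is the standard companion to identity in
homology-graph clustering; without it, ~30-bit local matches of 20–40
residues between unrelated proteins pass the E/identity pair at small
database sizes and merge families.

`cluster_families()` partitions the graph by connected components
(default) or a deterministic MCL-style flow clustering (expansion 2,
inflation 2, column-stochastic with self-loops, converged when the walk
matrix stabilises) for finer granularity — useful when weak bridges join
otherwise dense clusters. This is deliberately **not** an OrthoFinder
reimplementation: orthogroup counts are tool-dependent, and the package
prefers a deterministic, dependency-free clustering whose behaviour is
fully specified. Family ids are assigned by descending size then smallest
member id, so output is stable across runs.

The `abundance_matrix()` rows/columns are never reordered by the
computational core; `heatmap_ordering()` offers a cosmetic average-linkage
ordering for display only.

## Gene-neighborhood signatures

`match_pattern()` scans per-scaffold gene orders (from `order_genes()`,
which sorts by start coordinate; strand is retained but ignored for
ordering). Genes matching any pattern component are chained while at most
`max_gap = 2` non-component genes separate consecutive matched genes; a
maximal chain satisfying the component multiset is reported **once**
(overlap resolution by maximal-window merging, so no gene is
double-counted within a pattern). Matching is strand- and order-agnostic
by default — gene-cluster descriptions in the field say "adjacent"
without fixing orientation or order — with `require_strand`/
`require_order` available per pattern. The 2-intervening-gene default is
this package's choice of what still counts as one neighborhood.

Merging has one consequence worth stating: raising `max_gap` can merge two
neighbouring clusters of the same composition into one match, so the
*count* of matches is not monotone in the gap allowance — the *set of
genes covered* by matches is, and that is the property the tests enforce.

The five built-in oxidoreductase signatures encode the following
compositions: group 1 = bc-complex + 2 hypothetical + 2 MHC(= 6 hemes);
groups 2 and 3 = b-type cytochrome + MHC(= 6 hemes); groups 4 and 5 =
NrfD-like + 4Fe-4S ferredoxin + ≥ 2 MHC(≥ 3 hemes). The "6 hemes"
constraint is exact (tolerance 0): the signature specifies the heme count
as a defining feature, not an approximation.
Groups 2/3 — and likewise 4/5 — share a composition; the biological
distinction between them is phylogenetic, which is outside this package's
scope, so a planted instance of one twin is reported by both pattern
names. Evaluation of sensitivity and false positives is therefore done at
the level of composition classes ({1}, {2,3}, {4,5}).

Functional labels are an **input contract** (a per-gene label table), not
a computation: annotation pipelines vary, and the package deliberately
does not infer labels. `marker_matrix()` reduces labels to a binary
genomes-by-markers matrix with idempotent presence semantics.

## Cross-taxon MHC networks

`build_network()` searches the union of query MHCs and a user-supplied
reference panel all-vs-all and keeps edges whose reciprocal best hits pass
`max_evalue = 1e-20` and `min_identity = 50`, the conventional cutoffs for
cross-taxon MHC homology networks. A "≥50% AAI" cutoff in this protein-
level context is interpreted as per-hit percent identity (not genome-level
AAI); the interpretation is recorded here because the term is overloaded. One hit per unordered pair (the best) defines the edge
weight. `prune_components()` removes every connected component composed
solely of query or solely of reference nodes — mirroring the removal of
clusters containing only, or no, query-taxon homologs — and is idempotent.
A `by_family` mode collapses queries to one representative (longest
member) per orthologous family before searching.

The reference panel is user-supplied: curated MHC databases are large and
version-dependent, so none is redistributed; `make_reference_panel()`
derives a synthetic panel from a generated genome set for testing.

## The synthetic data generator

`generate_genome_set()` emulates the statistical shape of a 16-member
archaeal family comparison:

| Parameter | Default | Rationale |
|---|---|---|
| `n_genomes` | 16 | size of the emulated genome set |
| `proteins_per_genome` | 1,700–4,700 | observed proteome-size range |
| `mhc_per_genome` | 3–49 (uniform) | observed repertoire range; the true per-genome distribution is unpublished, so uniform is a declared stand-in |
| `heme_count_range` | 3–113 | observed motif-count range; right-skewed draw (mean ≈ 12) with the maximum planted exactly once, emulating a single largest MHC |
| `n_families` | 82 | observed family count; includes one conserved family per planted cluster pattern |
| `family_identity` | 85% | within-family amino-acid identity |
| `decoy_motif_max` | 2 | decoys stay strictly below the calling threshold |

Design choices that make the truth *exact* rather than probabilistic:

- Backgrounds are drawn over the 20 canonical amino acids with **C and H
  excluded** outside planted motifs, so a CXXCH site can only exist where
  planted; a global verification scan re-checks every emitted protein and
  regenerates any mismatch.
- Motifs are planted at **irregular spacings** (minimum 5 residues apart,
  arbitrary offsets). A fixed grid would give unrelated heme-dense
  proteins a shared C..CH lattice that aligns at spuriously high identity;
  real MHCs do not share a fixed heme period.
- Family members use a **variable-sites construction**: a fixed fraction
  `v = (1 - t/100) * 18/17` of non-motif columns is redrawn independently
  per member, so *pairwise* identity between any two members concentrates
  at the target `t` (the 18/17 factor corrects for chance agreement on the
  18-letter background alphabet). Motif columns are conserved, which also
  means very heme-dense families have a floor on reachable divergence —
  `make_reference_panel()` prefers motif-sparse families when asked for
  low-identity derivatives.
- Family sizes follow Zipf-like weights (exponent 0.7) after seeding each
  family with one guaranteed member: ortholog family-size distributions
  are heavy-tailed, giving a minority of widespread families and many
  sporadic ones.
- Cluster instances are planted contiguously with at least 4 background
  genes between blocks; each pattern draws its MHC components from one
  conserved per-pattern family, so cluster MHC families are shared across
  genomes exactly as conserved oxidoreductase clusters are. With
  `planted_clusters = "auto"`, each genome plants every signature its
  drawn MHC budget allows, so small repertoires (3 MHCs) carry few
  clusters — total per-genome MHC counts remain exactly the drawn values.
- Gene layout is deterministic given the seed: two scaffolds per genome,
  genes left-to-right, 1-based inclusive coordinates, 50 bp intergenic
  gaps, alternating strand. Outputs (FASTA, GFF3, truth TSV, JSON
  manifest) are byte-identical for a fixed seed.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: amino-acid composition bias (real MHCs are
C/H-rich everywhere, not only at motifs), indel evolution within families
(members share their prototype's length), domain architecture, paralog
divergence within genomes, annotation noise in labels, and fragmented or
contaminated MAG assemblies. Recovery results on synthetic data bound the
pipeline's correctness, not the biological difficulty of real repertoires.

## Problem sizes and runtime

Validation uses two scales, chosen as the package's own balance between
coverage and turnaround on a single core: the scanner and truth-recovery
checks run at full emulated scale (16 genomes, ~50,000 proteins — scanning
is linear and fast), while alignment-bound stages (family clustering, AAI,
networks) run on reduced studies (4 genomes × 120–160 proteins, ~50–80
MHCs; AAI on 2 genomes × 26 proteins with all 18 families shared), since
exhaustive all-vs-all Smith–Waterman is quadratic and the package
deliberately ships no heuristic seeding (a non-goal). The acceptance
script's family-clustering stage is the one full-scale alignment run
(~500 MHCs all-vs-all, about a minute).

## Known limitations

- No heuristic search acceleration: desk-scale only. Delegation to an
  external search tool is an adapter users can apply upstream (any tool
  emitting blastp tabular columns feeds `build_homology_graph()` directly).
- Family clustering is graph-based, not tree-aware: no duplication/loss
  modelling, and orthogroup counts will differ from tools like OrthoFinder
  by design.
- Component counting in patterns is per-predicate, without bipartite
  assignment; a pattern whose components have overlapping predicates could
  double-count a gene (the built-in signatures have disjoint predicates).
- Marker and cluster matching trust the supplied labels; no homology-based
  label inference.
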