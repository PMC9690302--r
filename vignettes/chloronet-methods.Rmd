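---
title: "Methods: comparative chloroplast genomics and consensus network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative chloroplast genomics and consensus network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloronet)
```

chloronet implements a two-part analysis for population samples of a
conifer with an unusually reduced plastome: (1) comparative genomics of
annotated chloroplast genomes — quadripartite structure, gene composition,
and the classification of polymorphic genes into location groups — and
(2) inference of a regulator-to-target expression network with a modular
prior and subsample-consensus edge selection, followed by Fisher/FDR term
enrichment of target sets.  This vignette records the models, the
parameters that matter, and the design choices that were genuinely open.

## Quadripartite genome structure

Chloroplast genomes are circular and canonically partition into a large
single-copy region (LSC), a small single-copy region (SSC) and two
inverted repeats (IRa/IRb) whose sequences are exact reverse complements.
In Pinaceae-adjacent conifers the repeats are drastically reduced — on the
order of 850 bp rather than the usual ~25 kb — so detection must work at
exact-match scale rather than rely on annotation.

`detect_inverted_repeats()` finds the maximal pair of non-overlapping
intervals whose sequences are reverse complements by exact k-mer seeding
(k = 21) between the sequence and its reverse complement.  Seeds sharing a
diagonal merge into maximal runs, which for exact k-mer cover are already
maximal exact matches, so no separate extension pass is needed.  Circular
topology is handled by searching the doubled sequence and mapping
candidates back to the circle; a match that pairs with itself is a
reverse-complement palindrome and is split into its two halves.  Ties in
length break toward the leftmost first-copy start.  The default
`min_len = 100` sits well below the ~780–880 bp repeats of interest and
well above the longest chance match in random sequence (k = 21 makes a
random seed collision essentially impossible at genome scale).

`partition_regions()` assigns the longer inter-repeat arc to the LSC and
the shorter to the SSC; the four intervals provably tile the circle, and a
zero-length SSC (adjacent repeats) is legal.  GC content excludes
ambiguous bases from the denominator and is reported as integer percent in
summaries, mirroring the conventional feature-table format, while full
precision is kept internally.

Gene counts are reported two ways: per annotated occurrence (`n_genes`,
so an IR-duplicated gene counts twice) and per distinct name
(`n_genes_unique`).  Published feature tables are ambiguous about which
convention they use; exposing both avoids committing to either.

## Gene-name harmonisation

Annotations produced a decade apart disagree on case, synonyms and tRNA
naming.  All cross-sample comparisons run on `normalize_gene_name()`
output: a shipped synonym table maps alternate symbols (e.g. *ycf3* to
*pafI*) case-insensitively, tRNA names are rewritten to the `trnX-NNN`
form with an RNA anticodon, and any other symbol gets its three-letter
stem lowercased so `PsbA`/`PSBA`/`psbA` agree.  The synonym table is the
controlling artifact for harmonisation and can be extended without code
changes.

## Composition comparison

`build_presence_matrix()` collapses annotation to presence/absence (an
IR-duplicated gene is still one gene present).  `unique_genes()` returns
genes present in *every* focal sample and absent from *every* other —
deliberately strict set semantics, so focal and complement unique sets are
provably disjoint.  `jaccard_cluster()` uses average-linkage hierarchical
clustering on binary Jaccard distance.  No clustering method is canonical
for binary gene-composition profiles; average linkage over Jaccard is the
standard choice for presence/absence data and is recorded in the result's
`method` field.  The two-cluster cut is reported together with the genes
whose presence discriminates the two clusters (the role the single gene
*psbM* plays among the hinterland samples in the motivating data).

## Polymorphism groups

For each per-gene alignment, a *polymorphic site* is a column with at
least two distinct symbols among `A, C, G, T, -` after uppercasing.  Gap
columns count as alleles — the observed between-population differences
include indel-scale events — while columns containing `N` (or any other
ambiguity code) in any sample are skipped as unreliable.  The *sample
partition* of a gene groups samples that agree at every polymorphic site;
it is invariant to row order and to monomorphic columns.

`classify_partition()` labels a partition relative to a focal single
sample (default `TW`) and a focal pair (default `JPL`, `SMP`):

1. one class → `MONOMORPHIC`;
2. focal single is a singleton class and the rest form one class → `TW`;
3. the focal pair is exactly one class and the focal single is *not* a
   singleton → `CZ`;
4. focal single is a singleton but the rest split further → `TW2`;
5. otherwise `ELSE`.

When the focal single sample is absent from a gene's sample set (a gene
missing from that genome), rules 2 and 4 are skipped.  The one genuinely
open question is precedence when a focal singleton *and* an isolated focal
pair co-occur (a pattern absent from the observed tables): the
focal-singleton rules win, classifying `TW2`.  This choice reproduces
every observed row and treats the outlier sample as the primary signal;
it is asserted by a dedicated test so any future change is deliberate.
The classifier is configuration-driven, so other sample layouts reuse it
unchanged.

`concatenate_supergene()` links per-gene alignments end-to-end and records
each gene's column range; `write_nexus_supergene()` emits a NEXUS matrix
with a `charset` block per gene as input for external tree software.
Tree inference itself is out of scope.

## Network model

Expression is a genes × samples matrix with a designated regulator
subset.  Rows are zero-mean transformed, then targets are kept only if
they deviate by at least ±1 from their mean in at least five samples
(`filter_expression()`, thresholds configurable).  Regulators are exempt
from this filter by default so a fixed regulator panel remains
representable even when individual regulators vary weakly; `strict = TRUE`
filters them too.

Per target \(y\), inference greedily builds a regulator set by forward
selection.  Adding candidate \(r\) to the current predictor set \(S\)
scores

\[ \mathrm{gain}(r) = \frac{n}{2}\,
   \ln\frac{\mathrm{RSS}(S)}{\mathrm{RSS}(S \cup \{r\})}
   \;-\; \lambda \;+\; \beta \cdot \mathrm{support}(r), \]

the Gaussian log-likelihood improvement of the ordinary-least-squares fit
(no intercept; rows are centered), minus a sparsity penalty, plus a
module-consistency bonus.  Selection adds the maximal positive gain until
no candidate helps or `max_regulators` (default 5) is reached; self-edges
are forbidden; a candidate collinear with the current set is skipped.

*Modules.*  Targets are clustered once by average-linkage hierarchical
clustering on correlation distance (1 − Pearson), cut at height
`h = 0.6` — tight enough that a module shares most of its regulatory
input, loose enough to survive noise.  `support(r)` is the fraction of the
target's module co-members whose current regulator set already contains
\(r\) (zero for singleton modules).  Selection and support recomputation
alternate for `n_iterations = 3` sweeps (or until the edge set is stable);
with `beta = 0` the support term vanishes and the algorithm reduces
exactly to independent per-target forward selection, a property the test
suite checks against an independent normal-equations implementation.

*Sparsity penalty.*  The default \(\lambda\) is the BIC per-parameter cost
\(\log(n)/2\).  A fixed AIC-scale cost (\(\lambda = 2\)) was considered
and rejected: the likelihood gain of an irrelevant candidate is
asymptotically \(\chi^2_1/2\) regardless of sample size, so a fixed
threshold admits false regulators at a constant per-candidate rate
(about 4.6% at \(\lambda = 2\)) and the false-discovery load grows with
the candidate pool.  The BIC cost shrinks that rate as samples accumulate
and is the standard consistent model-selection choice; with it, planted
structure at the default simulation design is recovered with recall 1.0
and precision above 0.9.  Any fixed `lambda` can still be passed.

*Determinism.*  The seed is used only to shuffle the candidate order that
breaks exact score ties (lexicographic regulator ID underneath); the edge
set is invariant to sample-column permutation, and increasing \(\lambda\)
never grows the edge set on a fixed input.

## Consensus (stability selection)

`consensus_network()` re-infers the network on `k = 6` random subsets of
`floor(0.5 · n)` sample columns (134 of 268 in the motivating design) and
retains edges appearing in at least `m = 5` runs, i.e. confidence
100·5/6 ≈ 83.3%.  Retained edges carry their occurrence, confidence and
mean weight.  Per-subset seeds derive as `seed + index`, so subsets are
independent but the whole procedure is reproducible; retained sets are
nested in `m` by construction.  Whether the original analysis fixed its
subsampling seed is unknowable; the derivation rule here is the package's
own convention.

## Enrichment

`fisher_enrichment()` tests a target set against a background for each
term set: the two-tailed Fisher exact p-value sums hypergeometric
point probabilities of all tables (at the observed margins) no more
probable than the observed one — the convention of mainstream statistics
tools, and verified in the tests against `fisher.test()` by full
enumeration over all small tables.  Benjamini–Hochberg adjustment runs
across all terms tested in one call (the FDR family is one ontology run);
significance is `q < 0.05`.  Terms with no background overlap are skipped
and reported, not silently tested.

## Synthetic data: what it emulates, and what it does not

The generators plant ground truth for every pipeline stage:

- `simulate_genomes()` builds six circular genomes as
  LSC + IRa + SSC + revcomp(IRa) over a shared random backbone at 39% GC,
  with ~130 genes tiled in the single-copy regions.  Defaults mirror the
  motivating comparison: a focal outlier (`TW`) carrying 22 private genes
  (21 tRNAs and one protein-coding gene), 32 genes private to the five
  hinterland samples, one gene (*psbM*) splitting the hinterland subgroups,
  and 850 bp repeats.  Single-copy lengths default to 12 kb/8 kb — desk
  scale rather than the real ~65 kb/52 kb — because structure, not size,
  is what the analyses consume; the generator accepts real-scale lengths
  when wanted.  The bases flanking the repeats are pinned so the planted
  pair is exactly maximal and region lengths are recovered exactly.
- `simulate_alignments()` plants partition strings (by default the
  packaged 19-gene table) as one mutated column per non-reference class,
  including a gap allele, plus monomorphic filler genes.
- `simulate_expression()` draws regulator rows iid standard normal and
  makes each target the sum of its module's regulators (default 2 per
  module, coefficient 1) plus Gaussian noise (sd 0.1), with 10 regulators,
  5 modules × 40 targets and 200 samples by default — a scaled-down
  stand-in for a 121-regulator × 21,638-target atlas.
- `simulate_annotation()` plants one enriched term (80% sampling inside
  the target set vs 10% outside) among uniform decoys.

Every generator is a pure function of its config including the seed.
The synthetic data deliberately omits much of what makes real data hard:
no annotation errors or coordinate drift, no alignment uncertainty, no
codon or repeat structure beyond the planted IRs, expression that is
exactly linear-Gaussian with homoscedastic noise and orthogonal
regulators, and term sets without the size skew and overlap of real
ontologies.  Passing recovery tests therefore demonstrates correctness of
the machinery under the stated model, not performance on real atlases —
on real data, collinear regulators and heavy-tailed noise will reduce
precision before they reduce recall.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; GenBank I/O converts at the
boundary, flattening compound `join()` locations to their spanning
interval.  Perfect regression fits are detected at relative residual
1e-10 and capped at a large finite gain.  Constant expression rows get
singleton modules with a warning.  Zero-length SSC partitions are legal;
empty gene annotations summarise to zero counts.  Monotone BH q-values
come from `p.adjust`.  Problem sizes in the tests (hundreds of genes,
tens-to-hundreds of samples, six consensus runs) were chosen so the whole
suite exercises every stage end-to-end in well under a minute each while
keeping recovery margins wide.

## Known limitations

The IR detector targets exact repeats; biologically degraded, mismatched
repeats would need a gapped or affine extension it does not attempt.  The
network model is linear and directed by construction (regulator panel →
everything else); it cannot represent combinatorial logic, feedback, or
post-transcriptional control.  Module assignment is fixed after
initialisation rather than re-estimated, a simplification relative to
full modular-network learners.  Enrichment treats terms independently;
correlated terms share signal and the BH family is per call.
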