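---
title: "Detecting tandem gene duplication and analyzing duplicate classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem gene duplication and analyzing duplicate classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdup)
```

## The model

`tandemdup` treats a genome annotation as an ordered list of gene intervals
per scaffold, together with a partition of (a subset of) the genes into
paralogous or orthologous groups. Tandem duplication is then a purely
positional notion: two genes are *linked* when they

1. belong to the same group,
2. have at most `max_intervening` annotated genes between them on one
   scaffold (an inclusive bound; default 10), and
3. lie at a pairwise distance strictly below `max_distance` (default
   100,000 bp).

A *tandem cluster* is a connected component of these links with at least
`min_members` (default 2) genes. The transitive chaining matters: a run of
k co-group genes, each near its neighbor, is one cluster of k even when its
ends are farther apart than `max_distance`. We adopt chained-neighbor
semantics deliberately — requiring *every* pair in a cluster to satisfy the
bounds would make cluster membership depend on cluster size in a way that is
hard to justify biologically, and reported mean cluster sizes in genome
papers (well above 2) are consistent with chaining. This is a design choice,
not a claim about what any particular study implemented.

Because a gene belongs to at most one group and components within a group
are disjoint, no gene can appear in two clusters. The detector is a sorted
window sweep over each (group, scaffold) restriction with its own union-find;
the test suite checks it against an independent all-pairs enumeration with
igraph transitive closure on hundreds of random instances.

### Distance definition

The pairwise distance between genes is not standardized across studies. The
default here is the *intergenic gap*: `start(downstream) − end(upstream) − 1`,
clamped at 0 for overlapping genes. It is invariant to gene length, which
matters when arrays mix short and long paralogs. `start_to_start` is
available for compatibility with order-based definitions. Both interpret the
bound strictly (`< max_distance`), and the intervening-gene bound
inclusively (`≤ max_intervening`), reading "less than" and "no more than"
literally.

Intervening genes are counted over **all** annotated genes, including other
members of the same group. Excluding co-group members would only matter for
pairs that skip over array members, and those pairs are joined through the
chain anyway.

## Chi-squared enrichment of duplicate classes

For a focal gene class (tandem genes, singletons, …) and a category map,
each category's 2×2 table is focal/background × with/without, where the
background is the complement of the focal set within the annotated gene
universe. The two classes must be disjoint for the independence test to be
valid; a study's exact background is often unstated, and the complement is
the one choice that guarantees disjointness. The statistic is the literal
Pearson formula with 1 df; the upper tail comes from `pchisq`. Numerical
choices:

* **Yates correction off by default** — a bare "χ² test" is the uncorrected
  Pearson statistic; the flag exists for small tables.
* **No multiple-testing correction by default**, matching raw per-category
  reporting at a stringent α (1e-4); a Bonferroni flag is provided.
* **Zero marginals** (a category carried by nobody, or by everybody) make
  the statistic undefined; such tables are flagged `untestable` with `NA`
  values rather than given a fabricated 0 or ∞.
* Genes with no annotation at all count as "without category" — dropping
  them would silently shrink the universe.

Categories are opaque labels: no GO-graph propagation or slim mapping is
performed, so a category and its ancestors are unrelated tests here.

## Assembly metrics

N50 uses the standard assembler convention: sort lengths descending and
return the first length where the cumulative sum reaches half the total (a
tie-free rule that always returns an observed length). Contigs are maximal
scaffold substrings containing no N run of length ≥ `min_gap_len`; the
default of 10 is a common scaffolding convention, surfaced as a parameter
because gap definitions vary. Runs shorter than the threshold stay inside
contigs and still count toward the N total. The N percentage is rounded
half-away-from-zero to one decimal, the convention that reproduces
published-style "(0.9%)" figures exactly. Scaffold filtering drops
below-threshold and explicitly excluded scaffolds, reporting each removal
with its reason; an exclusion id absent from the assembly is a warning, not
an error, so contaminant lists can be reused across assembly versions.

## Paralog clustering and family partitions

The similarity graph takes the 12-column tabular alignment dialect, drops
self-hits, and adds an edge when a hit passes the E-value threshold
(default 1e-5, the screening cutoff conventional in annotation pipelines) —
in both directions when `reciprocal = TRUE`. Connected components with ≥ 2
members become paralogous groups. Components deliberately replace MCL-style
inflation: at the scale this package targets, and with the generator's
within-family identities (~90%) far above between-family noise (~5%),
components recover planted families exactly, and real OrthoFinder-style
group files can be supplied instead wherever a `group_set` is accepted.

`family_partition` answers "of these N labeled genes (say, cytochrome
P450s), how many fall in clusters vs. singletons?" using a
restricted-subgroup rule: a group counts as a cluster only if ≥ 2 *labeled*
members are in it, and only labeled members count toward cluster genes.
This keeps a group that mixes P450 and non-P450 members from inflating the
cluster count, and guarantees cluster genes + singletons = N.

## Pathway candidates and neighborhoods

`best_hits` keeps one hit per reference enzyme — maximum bit score, ties
broken by identity then gene id so results are order-invariant — and
computes coverage relative to the *reference* protein length, capped at
100%. Reference-relative coverage is the only computable choice when the
reference set is a list of characterized proteins with known lengths;
whether a published table meant query- or subject-relative coverage is
usually unstated, and this assumption is flagged here. References with no
hit are reported with `NA` candidates rather than dropped, so a pathway
table always has one row per enzyme.

The neighborhood scan generalizes the qualitative observation of pathway
homologs co-located on one scaffold: per scaffold, candidates are chained
while successive intergenic gaps stay ≤ `max_gap` (default 100 kbp), and
maximal chains with ≥ `min_members` members spanning ≥ `min_stages` distinct
pathway stages are reported. The stage requirement (default 2) filters out
single-family tandem arrays, which are already reported by the tandem
detector.

## What the generator emulates — and what it does not

`simulate_annotation` places non-overlapping genes left-to-right per
scaffold with intergenic gaps drawn from 1–8 kbp, gene lengths 0.5–2 kbp,
and defaults of 10 scaffolds × 150–250 genes (≈ 2000 genes — large enough
for stable enrichment counts, small enough that a full pipeline run takes
seconds). Sixty families of 2–6 members are planted, half as tandem arrays
(consecutive slots, 0.2–2 kbp internal spacing, comfortably inside the
100 kbp bound) and half as dispersed duplicates placed on *distinct
scaffolds*, which satisfies any separation floor trivially; a family larger
than the scaffold count is a hard sizing error rather than a silent
constraint violation. N runs (50–500 bp, 1–4 per scaffold) are planted only
inside intergenic gaps with ≥ 1 bp of margin, so gene bodies are N-free and
contig-splitting truth stays exact.

Proteins derive from one random ancestor per family with per-site
substitution rate `1 − sqrt(identity/100)`, so two members — each mutated
independently — match at the target *pairwise* identity in expectation
(calibrating to the ancestor instead would undershoot pairwise identity by
roughly the square). The similarity table contains reciprocal within-family
hits at the realized identities; optional noise rows connect cross-family
pairs at a sub-threshold E-value. The GO map plants one category among
tandem-array genes at a controlled odds ratio (default 4 against a 10%
baseline) and spreads background categories uniformly at 15%.

Determinism: one integer seed drives everything; the four generator
functions use fixed small offsets of it (+1 proteins, +2 similarity, +3 GO,
+4 orthogroup augmentation) so each artifact is reproducible independently.
Identical parameters produce byte-identical files.

What passing tests on this generator **does not** show: real annotations
have overlapping and nested genes, fragmented gene models, families whose
identity distributions straddle clustering thresholds, tandem arrays
interrupted by unrelated insertions at ranges near the criterion bounds,
and GO annotations that are sparse and biased by study effort. The
planted-truth guarantees (precision = recall = 1) certify the algorithmic
machinery, not performance on such borderline biology.

For the multi-species partition, `simulate_orthogroups` augments each
planted family with companion-species members under a Bernoulli presence
draw (default 0.8) — enough structure to exercise Venn sectors, marginals
and singleton accounting, with no pretense of modeling real gene-family
evolution.

## Interfaces

The package's functions are the interface: `run_all()` wires all stages over
one validated configuration (an R list or a YAML file) and writes one TSV
per stage plus a summary and a JSON manifest, with fail-fast validation
before any stage executes. Per-stage functions are exported individually so
real data — a genome FASTA, a GFF3, an OrthoFinder-style group file, a
tabular similarity file, a two-column GO map — can be substituted at any
point via the `read_*` functions, which enforce the dialects strictly and
report malformed lines by number.

## Known limitations

* Whether the distance criterion should bind every pair in a cluster or
  only chained neighbors is genuinely ambiguous in the literature; only
  chained-neighbor semantics are implemented.
* Enlarging `max_distance` or `max_intervening` can *merge* clusters, so
  the cluster count is not monotone in the bounds (the tandem gene count
  is); parameter sweeps should track genes, not clusters.
* Connected-components clustering is deliberately simple; proteomes with
  promiscuous domains would chain families together and need MCL-style
  methods upstream, whose output files this package accepts.
* The Fisher exact test is noted as the small-count alternative to χ² but
  intentionally not offered, to keep the statistic interpretable as the
  classical uncorrected Pearson test.
* Ka/Ks dating, synteny-based duplicate classification, and whole-genome
  duplication detection are out of scope.
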