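# tandemdup

Tandem gene duplication detection and duplicate-class analysis for genome
annotations.

## The problem

Plant genomes — especially those of species rich in specialized metabolites —
carry extensive gene duplication, and tandem duplication in particular is a
major template for the diversification of enzyme families. Given an annotated
assembly (scaffold FASTA + gene GFF3) and a clustering of its proteome into
paralogous/orthologous groups, `tandemdup` answers the questions a genome
paper's duplication section asks:

* Which genes form **tandem duplicated clusters**? Two genes are linked when
  (i) they belong to the same paralogous/orthologous group, (ii) no more than
  *k* annotated genes lie between them on one scaffold (default *k* = 10,
  inclusive), and (iii) their pairwise distance is strictly less than *d*
  (default *d* = 100 kbp). Clusters are the connected components of these
  links with ≥ 2 members.
* Which **GO categories** are over- or under-represented among a duplicate
  class? For each category a 2×2 table (focal vs. background × with vs.
  without the category) is tested with the Pearson χ² statistic,
  χ² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), 1 df.
* What are the **assembly summary metrics** (scaffold/contig N50, N-base
  count and percentage, gap count) and which scaffolds survive a length /
  exclusion-list filter?
* Which genes are **candidate pathway orthologs** of characterized reference
  enzymes (top bit-score hit per reference, with identity and
  reference-relative coverage), and where do candidates from different
  pathway stages cluster physically on a scaffold?
* How do orthogroups **partition across species** (Venn sectors by exact
  species presence) and how many genes per species are singletons?

A synthetic-annotation generator plants tandem arrays, dispersed duplicates,
family-consistent similarity tables, an enriched GO category at a controlled
odds ratio, and N-gap runs — so every stage is testable against known truth
without downloading any data.

## Worked example

```r
library(tandemdup)

params <- sim_params(seed = 42, n_scaffolds = 8, genes_per_scaffold = c(60, 90),
                     n_families = 25, family_size = c(2, 5))
sim <- simulate_annotation(params)

clusters <- detect_tandem_clusters(sim$genes, sim$groups)
head(clusters[, c("cluster_id", "group_id", "scaffold_id", "n_members", "span_bp")], 3)
#>   cluster_id group_id scaffold_id n_members span_bp
#> 1    TC00001  FAM0015      scf001         2    5073
#> 2    TC00002  FAM0008      scf002         2    2554
#> 3    TC00003  FAM0004      scf002         5   13360

tandem_summary(clusters)
#> $n_clusters  12
#> $n_genes     47
#> $size_histogram   2:3  3:1  4:2  5:6

tandem_recovery(clusters, sim)
#> $precision 1   $recall 1   $n_detected 12   $n_planted 12
```

Every detected cluster names its group, scaffold, member genes (sorted by
start) and genomic span; here the 12 detected clusters are exactly the 12
planted arrays. The planted GO enrichment is recovered by the χ² scan:

```r
go <- simulate_go(sim)
res <- enrichment_scan(sim$truth$tandem_gene_ids, sim$genes$gene_id, go,
                       alpha = 1e-4)
head(res[, c("term", "a", "c", "statistic", "p_value", "direction")], 1)
#>                 term  a  c statistic      p_value direction
#> 1 response to stress 16 67  16.11657 5.956073e-05  enriched
```

16 of 47 tandem genes carry the planted category versus 67 of 531 background
genes; the raw p-value clears the 1e-4 significance level in the enriched
direction. Assembly metrics for the same simulated genome:

```r
str(assembly_metrics(sim$genome))
#> total_length 3231296 · n_scaffolds 8 · n50_scaffold 406088
#> n50_contig 189811 · n_count 5574 · n_percent 0.2 · n_gaps 20
```

The whole pipeline — simulation, metrics, paralog clustering from the
similarity table, tandem detection, enrichment, pathway candidates and
neighborhoods, multi-species Venn partition — runs end to end with
`run_all(run_config(outdir = "out", seed = 42))`, writing one TSV per stage
plus `summary.tsv` and `manifest.json`; a rerun with the same configuration
is byte-identical.

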