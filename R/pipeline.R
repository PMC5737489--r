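#' Assemble and validate a pipeline run configuration
#'
#' Plain named-list configuration for [run_all()]. Every field has a default;
#' `...` overrides individual fields, and a YAML file with the same keys can
#' be loaded with [load_run_config()]. Validation is fail-fast: parameter
#' bounds are checked here, before any stage runs.
#'
#' @param outdir Output directory for all stage results.
#' @param seed Integer seed driving the simulation and every random draw.
#' @param sim Named list of [sim_params()] overrides (the seed is taken from
#'   `seed`).
#' @param min_gap_len Minimum N-run length counted as an assembly gap.
#' @param min_scaffold_length Scaffold length filter applied in the metrics
#'   stage.
#' @param max_evalue,reciprocal Similarity-graph edge thresholds.
#' @param groups_source `"inferred"` (cluster the simulated similarity table)
#'   or `"planted"` (use the generator's family file) for the tandem stage.
#' @param tandem Named list of [tandem_params()] overrides.
#' @param alpha,min_term_count Enrichment-scan settings.
#' @param neighborhood Named list with `max_gap`, `min_members`,
#'   `min_stages`.
#' @param n_pathway_families Number of planted tandem families recast as
#'   pathway reference enzymes for the candidate/neighborhood stages.
#' @return Validated configuration list of class `"run_config"`.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       sim = list(),
                       min_gap_len = 10L,
                       min_scaffold_length = 0L,
                       max_evalue = 1e-5,
                       reciprocal = TRUE,
                       groups_source = c("inferred", "planted"),
                       tandem = list(),
                       alpha = 1e-4,
                       min_term_count = 5L,
                       neighborhood = list(max_gap = 100000L,
                                           min_members = 2L,
                                           min_stages = 2L),
                       n_pathway_families = 3L) {
  groups_source <- match.arg(groups_source)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              min_gap_len = min_gap_len,
              min_scaffold_length = min_scaffold_length,
              max_evalue = max_evalue, reciprocal = reciprocal,
              groups_source = groups_source, tandem = tandem,
              alpha = alpha, min_term_count = min_term_count,
              neighborhood = neighborhood,
              n_pathway_families = n_pathway_families)
  # fail fast: exercise the parameter constructors before any stage runs
  do.call(sim_params, c(list(seed = cfg$seed), cfg$sim))
  do.call(tandem_params, cfg$tandem)
  stopifnot(cfg$max_evalue > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$neighborhood$max_gap > 0, cfg$min_gap_len >= 1,
            cfg$n_pathway_families >= 0)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [run_config()] arguments.
#' @param outdir Optional override of the configured output directory.
#' @return Validated `"run_config"`.
#' @export
load_run_config <- function(path, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  do.call(run_config, raw)
}

write_tsv_report <- function(df, path, comment_cols = TRUE) {
  header <- paste0(if (comment_cols) "# " else "",
                   paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  writeLines(c(header, if (nrow(df)) body), path)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes, in order: annotation simulation, assembly metrics, paralog
#' clustering (or ingestion of the planted groups), tandem-cluster
#' detection, GO enrichment of tandem genes, pathway candidate/neighborhood
#' identification, and the multi-species orthogroup partition. Each stage
#' writes its result table under `outdir`; a `summary.tsv` of headline
#' counts and a `manifest.json` listing every output are written at the end.
#' All randomness derives from `config$seed`, and no output embeds
#' timestamps or absolute paths, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [run_config()], or arguments understood by it (a plain
#'   list), or a YAML path.
#' @return Invisibly, a list with `summary` (data frame), `manifest`
#'   (character vector of relative output paths) and `outdir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary_rows <- list()
  manifest <- character(0)
  note <- function(stage, key, value) {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      stage = stage, key = key, value = as.character(value),
      stringsAsFactors = FALSE)
  }
  emit <- function(rel) manifest <<- c(manifest, rel)

  # -- simulate ---------------------------------------------------------
  params <- do.call(sim_params, c(list(seed = config$seed), config$sim))
  sim <- simulate_annotation(params, outdir = file.path(outdir, "sim"))
  emit("sim/genome.fa"); emit("sim/genes.gff3"); emit("sim/orthogroups.txt")
  emit("sim/truth/families.tsv"); emit("sim/truth/arrays.tsv")
  emit("sim/truth/gaps.tsv")
  note("simulate", "n_genes", nrow(sim$genes))
  note("simulate", "n_families", length(sim$groups$groups))
  note("simulate", "n_planted_arrays", nrow(sim$truth$arrays))

  # -- metrics ----------------------------------------------------------
  genome <- read_fasta(file.path(outdir, "sim", "genome.fa"))
  filt <- filter_scaffolds(genome, min_length = config$min_scaffold_length)
  met <- assembly_metrics(filt$kept, min_gap_len = config$min_gap_len)
  metrics_df <- data.frame(metric = names(met),
                           value = vapply(met, function(x)
                             format(x, scientific = FALSE), character(1)),
                           stringsAsFactors = FALSE)
  write_tsv_report(metrics_df, file.path(outdir, "metrics.tsv"))
  emit("metrics.tsv")
  note("metrics", "n_scaffolds", met$n_scaffolds)
  note("metrics", "total_length", format(met$total_length, scientific = FALSE))
  note("metrics", "n50_scaffold", met$n50_scaffold)
  note("metrics", "n_percent", met$n_percent)
  note("metrics", "n_gaps", met$n_gaps)
  note("metrics", "n_removed", nrow(filt$report))

  # -- paralogs ---------------------------------------------------------
  proteins <- simulate_proteins(sim)
  hits <- simulate_similarity(sim, proteins)
  write_similarity_table(hits, file.path(outdir, "hits.tsv"))
  emit("hits.tsv")
  graph <- build_similarity_graph(hits, max_evalue = config$max_evalue,
                                  reciprocal = config$reciprocal)
  inferred <- cluster_paralogs(graph, species = params$species_tag)
  write_orthogroups(inferred, file.path(outdir, "paralog_groups.txt"))
  emit("paralog_groups.txt")
  note("paralogs", "n_groups", length(inferred$groups))
  note("paralogs", "n_grouped_genes", length(grouped_genes(inferred)))
  note("paralogs", "n_graph_singletons", length(attr(inferred, "singletons")))

  # -- tandem -----------------------------------------------------------
  genes <- assign_gene_order(read_gff3(file.path(outdir, "sim", "genes.gff3")))
  groups_used <- if (config$groups_source == "planted") {
    read_orthogroups(file.path(outdir, "sim", "orthogroups.txt"))
  } else inferred
  tpar <- do.call(tandem_params, config$tandem)
  clusters <- detect_tandem_clusters(genes, groups_used, tpar)
  write_tandem_clusters(clusters, file.path(outdir, "tandem_clusters.tsv"))
  emit("tandem_clusters.tsv")
  tsum <- tandem_summary(clusters)
  note("tandem", "n_clusters", tsum$n_clusters)
  note("tandem", "n_tandem_genes", tsum$n_genes)

  # -- enrich -----------------------------------------------------------
  go <- simulate_go(sim)
  write_go_map(go, file.path(outdir, "go.tsv"))
  emit("go.tsv")
  focal <- unique(unlist(clusters$member_ids, use.names = FALSE))
  enr <- enrichment_scan(focal, genes$gene_id, go, alpha = config$alpha,
                         min_term_count = config$min_term_count)
  write_enrichment(enr, file.path(outdir, "enrichment.tsv"))
  emit("enrichment.tsv")
  note("enrich", "n_terms_tested", nrow(enr))
  note("enrich", "n_enriched",
       sum(enr$significant & enr$direction == "enriched"))
  note("enrich", "n_depleted",
       sum(enr$significant & enr$direction == "depleted"))

  # -- candidates / neighborhoods --------------------------------------
  pw <- pathway_stage_inputs(sim, proteins, config$n_pathway_families)
  best <- best_hits(pw$hits, pw$refs)
  write_tsv_report(best, file.path(outdir, "candidates.tsv"))
  emit("candidates.tsv")
  nbh <- find_neighborhoods(genes, pw$candidates,
                            max_gap = config$neighborhood$max_gap,
                            min_members = config$neighborhood$min_members,
                            min_stages = config$neighborhood$min_stages)
  write_tsv_report(nbh[, setdiff(names(nbh), "member_table")],
                   file.path(outdir, "neighborhoods.tsv"))
  emit("neighborhoods.tsv")
  note("candidates", "n_references", nrow(pw$refs))
  note("candidates", "n_with_hit", sum(!is.na(best$gene_id)))
  note("neighborhoods", "n_neighborhoods", nrow(nbh))

  # -- venn -------------------------------------------------------------
  og <- simulate_orthogroups(sim)
  vp <- species_signature(og$groups)
  write_venn(vp, file.path(outdir, "venn.tsv"))
  emit("venn.tsv")
  singles <- count_singletons(og$inventories, og$groups)
  note("venn", "n_groups", vp$n_groups)
  note("venn", "n_sectors", length(vp$counts))
  note("venn", "all_species_sector",
       if (length(vp$counts)) {
         full <- paste(sort(og$groups$species_universe), collapse = "+")
         if (full %in% names(vp$counts)) vp$counts[[full]] else 0L
       } else 0L)
  for (sp in names(singles)) {
    note("venn", paste0("singletons_", sp), singles[[sp]])
  }

  summary_df <- do.call(rbind, summary_rows)
  write_tsv_report(summary_df, file.path(outdir, "summary.tsv"))
  emit("summary.tsv")
  jsonlite::write_json(list(outputs = manifest),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary_df, manifest = manifest, outdir = outdir))
}

# recast a few planted tandem families as pathway references: one reference
# enzyme per family, hits from the reference to each member, members labeled
# with cycling pathway stages so neighborhoods can span stages
pathway_stage_inputs <- function(sim, proteins, n_families = 3L) {
  arrays <- sim$truth$arrays
  # prefer arrays sharing a scaffold so the neighborhood scan has something
  # to chain across stages
  sc_count <- table(arrays$scaffold_id)
  use <- utils::head(order(-as.integer(sc_count[arrays$scaffold_id]),
                           arrays$scaffold_id, arrays$group_id), n_families)
  stages <- c("MEP", "iridoid", "alkaloid")
  refs <- list(); hit_rows <- list(); cand <- list()
  for (i in seq_along(use)) {
    arr <- arrays[use[i], ]
    members <- strsplit(arr$members, ",", fixed = TRUE)[[1]]
    len <- nchar(proteins[[members[1]]])
    ref_id <- paste0("REF_", arr$group_id)
    abbr <- paste0("ENZ", i)
    stage <- stages[((i - 1L) %% length(stages)) + 1L]
    refs[[i]] <- data.frame(ref_id = ref_id, enzyme_abbr = abbr,
                            pathway_stage = stage, protein_length = len,
                            stringsAsFactors = FALSE)
    id <- sim$params$within_family_identity
    hit_rows[[i]] <- data.frame(
      query_id = ref_id, subject_id = members,
      pct_identity = round(id - seq_along(members) + 1, 2),
      aln_length = len,
      mismatches = as.integer(round(len * (1 - id / 100))),
      gap_opens = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = 1e-50,
      bitscore = round(2 * len * id / 100, 1) - seq_along(members) + 1,
      stringsAsFactors = FALSE)
    cand[[i]] <- data.frame(gene_id = members, enzyme_abbr = abbr,
                            pathway_stage = stage, stringsAsFactors = FALSE)
  }
  list(refs = do.call(rbind, refs), hits = do.call(rbind, hit_rows),
       candidates = do.call(rbind, cand))
}
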