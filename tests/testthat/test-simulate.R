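small_params <- function(seed = 5, ...) {
  sim_params(seed = seed, n_scaffolds = 6, genes_per_scaffold = c(30, 50),
             n_families = 12, family_size = c(2, 4), ...)
}

test_that("a minimal instance plants exactly one array", {
  p <- sim_params(seed = 1, n_scaffolds = 1, genes_per_scaffold = c(10, 10),
                  n_families = 1, family_size = c(3, 3), tandem_fraction = 1)
  sim <- simulate_annotation(p)
  expect_identical(nrow(sim$genes), 10L)
  expect_identical(nrow(sim$truth$arrays), 1L)
  members <- strsplit(sim$truth$arrays$members, ",")[[1]]
  expect_length(members, 3L)
  # planted array members are consecutive in gene order
  ranks <- sort(sim$genes$rank[sim$genes$gene_id %in% members])
  expect_identical(ranks, seq(min(ranks), length.out = 3L))
})

test_that("identical parameters give byte-identical files", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_annotation(small_params(), outdir = d1)
  simulate_annotation(small_params(), outdir = d2)
  for (f in c("genome.fa", "genes.gff3", "orthogroups.txt",
              "truth/families.tsv", "truth/arrays.tsv", "truth/gaps.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("emitted files re-read through the readers reproduce the truth", {
  d <- file.path(tempdir(), "simC")
  sim <- simulate_annotation(small_params(seed = 8), outdir = d)

  genes <- assign_gene_order(read_gff3(file.path(d, "genes.gff3")))
  truth <- sim$genes[order(sim$genes$gene_id), ]
  back <- genes[order(genes$gene_id), ]
  rownames(truth) <- rownames(back) <- NULL
  expect_identical(back, truth)

  gs <- read_orthogroups(file.path(d, "orthogroups.txt"))
  expect_identical(lapply(gs$groups, `[[`, "gene_id"),
                   lapply(sim$groups$groups, `[[`, "gene_id"))

  genome <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(genome, sim$genome)
  # every planted N run is present at its recorded coordinates, and no N
  # falls inside a gene body
  for (k in seq_len(nrow(sim$truth$gaps))) {
    row <- sim$truth$gaps[k, ]
    run <- substr(genome[[row$scaffold_id]], row$start, row$end)
    expect_identical(run, strrep("N", row$end - row$start + 1))
  }
  for (k in seq_len(nrow(sim$genes))) {
    body <- substr(genome[[sim$genes$scaffold_id[k]]],
                   sim$genes$start[k], sim$genes$end[k])
    expect_false(grepl("N", body, fixed = TRUE))
  }
  unlink(d, recursive = TRUE)
})

test_that("gap truth matches the package's own N-run finder", {
  sim <- simulate_annotation(small_params(seed = 13))
  found <- do.call(rbind, lapply(names(sim$genome), function(sc) {
    runs <- tandemdup:::find_n_runs(sim$genome[[sc]], 1L)
    if (nrow(runs)) cbind(scaffold_id = sc, runs) else NULL
  }))
  truth <- sim$truth$gaps[order(sim$truth$gaps$scaffold_id,
                                sim$truth$gaps$start), ]
  rownames(found) <- rownames(truth) <- NULL
  expect_identical(found$start, truth$start)
  expect_identical(found$end, truth$end)
})

test_that("protein identity is calibrated: identical at 100, near target at 90", {
  sim <- simulate_annotation(small_params(seed = 3,
                                          within_family_identity = 100))
  pr <- simulate_proteins(sim)
  fam <- split(sim$truth$families$gene_id, sim$truth$families$group_id)
  for (m in fam) {
    expect_identical(unname(pr[m[1]]), unname(pr[m[2]]))
  }

  p90 <- sim_params(seed = 4, n_scaffolds = 8, genes_per_scaffold = c(40, 60),
                    n_families = 50, family_size = c(2, 3),
                    within_family_identity = 90,
                    protein_length = c(300, 300))
  sim90 <- simulate_annotation(p90)
  pr90 <- simulate_proteins(sim90)
  fam90 <- split(sim90$truth$families$gene_id, sim90$truth$families$group_id)
  ids <- vapply(fam90, function(m) {
    mean(utf8ToInt(pr90[[m[1]]]) == utf8ToInt(pr90[[m[2]]])) * 100
  }, numeric(1))
  expect_lt(abs(mean(ids) - 90), 5)

  # unrelated proteins match at the 1/20 background coincidence rate
  solo <- setdiff(sim90$genes$gene_id, sim90$truth$families$gene_id)[1:40]
  bg <- vapply(seq(1, 39, by = 2), function(i) {
    a <- utf8ToInt(pr90[[solo[i]]]); b <- utf8ToInt(pr90[[solo[i + 1]]])
    n <- min(length(a), length(b))
    mean(a[1:n] == b[1:n])
  }, numeric(1))
  expect_lt(abs(mean(bg) - 0.05), 0.03)
})

test_that("similarity tables carry reciprocal within-family hits", {
  p <- sim_params(seed = 2, n_scaffolds = 2, genes_per_scaffold = c(6, 6),
                  n_families = 1, family_size = c(2, 2), tandem_fraction = 1)
  sim <- simulate_annotation(p)
  hits <- simulate_similarity(sim)
  expect_identical(nrow(hits), 2L)
  expect_identical(sort(hits$query_id), sort(hits$subject_id))
  expect_true(all(hits$evalue <= 1e-5))
})

test_that("noise hits above the E-value threshold leave components unchanged", {
  clean <- simulate_annotation(small_params(seed = 6))
  quiet <- simulate_similarity(clean)
  noisy_sim <- simulate_annotation(small_params(seed = 6, noise_hits = 40,
                                                noise_evalue = 1e-3))
  noisy <- simulate_similarity(noisy_sim)
  expect_identical(nrow(noisy), nrow(quiet) + 40L)
  comp_of <- function(h) {
    cluster_keys(lapply(
      cluster_paralogs(build_similarity_graph(h, 1e-5))$groups,
      `[[`, "gene_id"))
  }
  expect_identical(comp_of(noisy), comp_of(quiet))
})

test_that("the planted GO odds ratio is realized in expectation", {
  p <- small_params(seed = 30, enriched_term_odds_ratio = 4,
                    baseline_term_prob = 0.1)
  # odds ratio 4 against baseline 0.1 implies P(term | tandem) = 4/13.5
  odds1 <- 4 * 0.1 / 0.9
  expect_equal(odds1 / (1 + odds1), 0.3076923, tolerance = 1e-6)
  sim <- simulate_annotation(p)
  go <- simulate_go(sim)
  focal <- sim$truth$tandem_gene_ids
  has <- vapply(sim$genes$gene_id, function(g) {
    "response to stress" %in% go[[g]]
  }, logical(1))
  p1_hat <- mean(has[sim$genes$gene_id %in% focal])
  p0_hat <- mean(has[!sim$genes$gene_id %in% focal])
  expect_lt(abs(p0_hat - 0.1), 0.08)
  expect_gt(p1_hat, p0_hat)
})

test_that("a zero baseline probability is handled without errors", {
  p <- small_params(seed = 31, baseline_term_prob = 0)
  sim <- simulate_annotation(p)
  go <- simulate_go(sim)
  carriers <- names(go)[vapply(go, function(t) "response to stress" %in% t,
                               logical(1))]
  expect_true(all(carriers %in% sim$truth$tandem_gene_ids))
  res <- enrichment_scan(sim$truth$tandem_gene_ids, sim$genes$gene_id, go,
                         alpha = 1e-4, min_term_count = 1)
  expect_s3_class(res, "data.frame")
})

test_that("oversized dispersed families fail fast with a sizing hint", {
  p <- sim_params(seed = 1, n_scaffolds = 2, genes_per_scaffold = c(10, 10),
                  n_families = 1, family_size = c(5, 5), tandem_fraction = 0)
  expect_error(simulate_annotation(p), "increase n_scaffolds")
  p2 <- sim_params(seed = 1, n_scaffolds = 2, genes_per_scaffold = c(3, 3),
                   n_families = 4, family_size = c(3, 3), tandem_fraction = 1)
  expect_error(simulate_annotation(p2), "slots")
})
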