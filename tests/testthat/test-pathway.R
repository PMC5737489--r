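ref_row <- function(id = "AAF65154.1", abbr = "DXR", stage = "MEP",
                    len = 400L) {
  data.frame(ref_id = id, enzyme_abbr = abbr, pathway_stage = stage,
             protein_length = len, stringsAsFactors = FALSE)
}

test_that("best_hits keeps the top bitscore hit with reference-relative coverage", {
  # a full-length hit on a 400-residue reference: coverage 100, identity as
  # reported by the alignment
  hits <- make_hit("AAF65154.1", "geneX", identity = 88.82, aln = 400,
                   bitscore = 780)
  out <- best_hits(hits, ref_row())
  expect_identical(out$gene_id, "geneX")
  expect_equal(out$pct_coverage, 100)
  expect_equal(out$pct_identity, 88.82)

  two <- make_hits(
    make_hit("AAF65154.1", "low", identity = 99, aln = 100, bitscore = 300),
    make_hit("AAF65154.1", "high", identity = 60, aln = 380, bitscore = 500))
  expect_identical(best_hits(two, ref_row())$gene_id, "high")
})

test_that("best_hits breaks ties by identity then gene id, and caps coverage", {
  tied <- make_hits(
    make_hit("R1", "zed", identity = 80, aln = 100, bitscore = 250),
    make_hit("R1", "abc", identity = 90, aln = 100, bitscore = 250))
  expect_identical(best_hits(tied, ref_row("R1", len = 100L))$gene_id, "abc")

  tied2 <- make_hits(
    make_hit("R1", "zed", identity = 80, aln = 100, bitscore = 250),
    make_hit("R1", "abc", identity = 80, aln = 100, bitscore = 250))
  expect_identical(best_hits(tied2, ref_row("R1", len = 100L))$gene_id, "abc")

  long <- make_hit("R1", "g", identity = 70, aln = 150, bitscore = 250)
  expect_equal(best_hits(long, ref_row("R1", len = 100L))$pct_coverage, 100)
})

test_that("references without hits are reported, not dropped", {
  refs <- rbind(ref_row("R1"), ref_row("R2", abbr = "GOR", stage = "iridoid"))
  out <- best_hits(make_hit("R1", "g1"), refs)
  expect_identical(nrow(out), 2L)
  expect_true(is.na(out$gene_id[out$ref_id == "R2"]))
})

test_that("best_hits is deterministic under hit permutation and equals brute force", {
  set.seed(99)
  refs <- do.call(rbind, lapply(1:20, function(i) {
    ref_row(sprintf("R%02d", i), len = sample(100:500, 1))
  }))
  hits <- do.call(rbind, lapply(1:200, function(k) {
    make_hit(sprintf("R%02d", sample(20, 1)), sprintf("g%03d", sample(80, 1)),
             identity = round(runif(1, 40, 99), 2),
             aln = sample(50:500, 1), bitscore = round(runif(1, 50, 900), 1))
  }))
  out1 <- best_hits(hits, refs)
  out2 <- best_hits(hits[sample(nrow(hits)), ], refs)
  expect_identical(out1, out2)
  for (i in seq_len(nrow(refs))) {
    h <- hits[hits$query_id == refs$ref_id[i], ]
    if (!nrow(h)) next
    expect_identical(out1$bitscore[i], max(h$bitscore))
  }
})

test_that("co-located candidates across stages form one neighborhood", {
  g <- assign_gene_order(make_genes_at(c(10000, 40000, 75000),
                                       ids = c("c1", "c2", "c3")))
  cand <- data.frame(gene_id = c("c1", "c2", "c3"),
                     enzyme_abbr = c("IPP2", "GOR", "NMT"),
                     pathway_stage = c("MEP", "iridoid", "alkaloid"),
                     stringsAsFactors = FALSE)
  nb <- find_neighborhoods(g, cand, max_gap = 50000)
  expect_identical(nrow(nb), 1L)
  expect_identical(nb$n_members, 3L)
  expect_identical(nb$n_stages, 3L)
})

test_that("distant candidates do not chain", {
  g <- assign_gene_order(make_genes_at(c(10000, 5010000),
                                       ids = c("c1", "c2")))
  cand <- data.frame(gene_id = c("c1", "c2"), enzyme_abbr = c("A", "B"),
                     pathway_stage = c("MEP", "iridoid"),
                     stringsAsFactors = FALSE)
  expect_identical(nrow(find_neighborhoods(g, cand, max_gap = 100000)), 0L)
})

test_that("single-stage chains are dropped unless min_stages allows them", {
  g <- assign_gene_order(make_genes_at(c(1000, 5000, 9000),
                                       ids = c("c1", "c2", "c3")))
  cand <- data.frame(gene_id = c("c1", "c2", "c3"), enzyme_abbr = "GOR",
                     pathway_stage = "iridoid", stringsAsFactors = FALSE)
  expect_identical(nrow(find_neighborhoods(g, cand, max_gap = 50000)), 0L)
  nb <- find_neighborhoods(g, cand, max_gap = 50000, min_stages = 1)
  expect_identical(nrow(nb), 1L)
  expect_identical(nb$n_members, 3L)
})

test_that("unknown candidate genes are skipped with a warning", {
  g <- assign_gene_order(make_genes_at(c(1000, 5000), ids = c("c1", "c2")))
  cand <- data.frame(gene_id = c("c1", "c2", "ghost"),
                     enzyme_abbr = c("A", "B", "C"),
                     pathway_stage = c("MEP", "iridoid", "alkaloid"),
                     stringsAsFactors = FALSE)
  expect_warning(nb <- find_neighborhoods(g, cand, max_gap = 50000), "ghost")
  expect_identical(nb$n_members, 2L)
})

test_that("chains are maximal and equal a brute-force sweep", {
  set.seed(313)
  for (i in 1:15) {
    inst <- random_instance(120)
    g <- assign_gene_order(inst$genes)
    picks <- sort(sample(nrow(g), 30))
    cand <- data.frame(gene_id = g$gene_id[picks],
                       enzyme_abbr = sample(c("E1", "E2", "E3", "E4"), 30,
                                            replace = TRUE),
                       pathway_stage = sample(c("MEP", "iridoid", "alkaloid"),
                                              30, replace = TRUE),
                       stringsAsFactors = FALSE)
    max_gap <- sample(c(20000, 60000, 120000), 1)
    nb <- find_neighborhoods(g, cand, max_gap = max_gap, min_members = 2,
                             min_stages = 1)
    # brute-force: per scaffold, walk sorted candidates and cut at big gaps
    want <- list()
    for (sc in unique(g$scaffold_id)) {
      cc <- merge(cand, g, by = "gene_id")
      cc <- cc[cc$scaffold_id == sc, ]
      cc <- cc[order(cc$start), ]
      if (!nrow(cc)) next
      run <- cc$gene_id[1]
      if (nrow(cc) > 1) for (k in 2:nrow(cc)) {
        gap <- max(0, cc$start[k] - cc$end[k - 1] - 1)
        if (gap <= max_gap) run <- c(run, cc$gene_id[k])
        else {
          if (length(run) >= 2) want[[length(want) + 1]] <- run
          run <- cc$gene_id[k]
        }
      }
      if (length(run) >= 2) want[[length(want) + 1]] <- run
    }
    got <- lapply(nb$member_table, `[[`, "gene_id")
    expect_identical(cluster_keys(got), cluster_keys(want))
  }
})

test_that("reference lists round-trip through the TSV reader", {
  f <- tempfile()
  writeLines(c("# ref_id\tabbr\tstage\tlength",
               "AAF65154.1\tDXR\tMEP\t400",
               "AHK60836.1\tGOR\tiridoid\t360"), f)
  refs <- read_reference_enzymes(f)
  expect_identical(refs$enzyme_abbr, c("DXR", "GOR"))
  expect_identical(refs$protein_length, c(400L, 360L))
  writeLines("only\tthree\tcols", f)
  expect_error(read_reference_enzymes(f), "4 columns at line 1")
  unlink(f)
})
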