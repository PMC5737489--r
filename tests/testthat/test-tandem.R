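test_that("assign_gene_order ranks genes by start within each scaffold", {
  g <- make_genes(c(100, 500, 300), c(150, 550, 350))
  r <- assign_gene_order(g)
  expect_identical(r$rank, c(0L, 2L, 1L))

  g2 <- rbind(make_genes(c(100, 500), c(150, 550), "sc1", c("a", "b")),
              make_genes(c(900, 10), c(950, 60), "sc2", c("c", "d")))
  r2 <- assign_gene_order(g2)
  expect_identical(r2$rank, c(0L, 1L, 1L, 0L))

  dup <- make_genes(c(100, 100), c(150, 150), ids = c("x", "x"))
  expect_error(assign_gene_order(dup), "duplicate gene record")
})

test_that("intervening_count is the rank gap and requires one scaffold", {
  g <- assign_gene_order(make_genes_at(seq(100, 1600, by = 100)))
  expect_identical(intervening_count(g[5, ], g[6, ]), 0L)
  expect_identical(intervening_count(g[3, ], g[15, ]), 11L)
  other <- assign_gene_order(make_genes_at(100, scaffold = "sc2"))
  expect_error(intervening_count(g[1, ], other[1, ]), "different scaffolds")
})

test_that("intervening_count equals explicit enumeration of intermediate genes", {
  set.seed(31)
  g <- assign_gene_order(random_instance(200)$genes)
  for (k in 1:50) {
    sc <- sample(unique(g$scaffold_id), 1)
    m <- g[g$scaffold_id == sc, ]
    ij <- sample(nrow(m), 2)
    a <- m[ij[1], ]; b <- m[ij[2], ]
    lo <- min(a$start, b$start); hi <- max(a$start, b$start)
    n_between <- sum(m$start > lo & m$start < hi)
    expect_identical(intervening_count(a, b), n_between)
  }
})

test_that("gene_distance implements both modes with overlap clamped to zero", {
  a <- make_genes(100, 900); b <- make_genes(1000, 1500)
  expect_identical(gene_distance(a, b, "intergenic"), 99)
  expect_identical(gene_distance(b, a, "intergenic"), 99)
  expect_identical(gene_distance(a, b, "start_to_start"), 900L)
  ov <- make_genes(800, 1200)
  expect_identical(gene_distance(a, ov, "intergenic"), 0)
  expect_error(gene_distance(a, make_genes(1, 5, "sc9")), "different scaffolds")
})

test_that("a near pair of co-group genes forms one cluster of two", {
  g <- make_genes_at(c(1000, 6500), ids = c("a", "b"))
  cl <- detect_tandem_clusters(g, make_groups(c("a", "b")))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$member_ids[[1]], c("a", "b"))
  expect_identical(cl$n_members, 2L)
})

test_that("the intervening-gene bound is inclusive at 10 and fails at 11", {
  # co-group genes at the ends, unrelated genes between, tight spacing
  layout <- function(n_between) {
    starts <- seq(1000, by = 2000, length.out = n_between + 2L)
    ids <- c("dupA", sprintf("x%02d", seq_len(n_between)), "dupB")
    assign_gene_order(make_genes_at(starts, ids = ids, len = 500L))
  }
  groups <- make_groups(c("dupA", "dupB"))
  at10 <- detect_tandem_clusters(layout(10L), groups)
  expect_identical(nrow(at10), 1L)
  at11 <- detect_tandem_clusters(layout(11L), groups)
  expect_identical(nrow(at11), 0L)
})

test_that("the distance bound is strict: 99 999 bp links, 100 000 bp does not", {
  pair_at_gap <- function(gap) {
    g <- make_genes(c(1000, 1000 + 499 + gap + 1),
                    c(1499, 1000 + 499 + gap + 500),
                    ids = c("dupA", "dupB"))
    detect_tandem_clusters(g, make_groups(c("dupA", "dupB")))
  }
  expect_identical(nrow(pair_at_gap(99999L)), 1L)
  expect_identical(nrow(pair_at_gap(100000L)), 0L)
})

test_that("a run of k adjacent co-group genes yields exactly one cluster of k", {
  for (k in c(2L, 3L, 5L, 8L)) {
    ids <- sprintf("m%02d", seq_len(k))
    g <- make_genes_at(seq(1000, by = 3000, length.out = k), ids = ids)
    cl <- detect_tandem_clusters(g, make_groups(ids))
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$member_ids[[1]], ids)
  }
})

test_that("clusters are disjoint and members are start-sorted", {
  set.seed(77)
  inst <- random_instance(300)
  cl <- detect_tandem_clusters(inst$genes, inst$groups)
  all_members <- unlist(cl$member_ids)
  expect_identical(anyDuplicated(all_members), 0L)
  for (m in cl$member_ids) {
    starts <- inst$genes$start[match(m, inst$genes$gene_id)]
    expect_identical(starts, sort(starts))
  }
})

test_that("missing catalog genes are skipped with a warning", {
  g <- make_genes_at(c(1000, 4000), ids = c("a", "b"))
  expect_warning(
    cl <- detect_tandem_clusters(g, make_groups(c("a", "b", "ghost"))),
    "absent from gene catalog")
  expect_identical(nrow(cl), 1L)
})

test_that("enlarging either bound never loses tandem genes", {
  set.seed(55)
  for (i in 1:10) {
    inst <- random_instance(250)
    base <- tandem_summary(detect_tandem_clusters(
      inst$genes, inst$groups, tandem_params(max_intervening = 5,
                                             max_distance = 50000)))
    wider <- tandem_summary(detect_tandem_clusters(
      inst$genes, inst$groups, tandem_params(max_intervening = 10,
                                             max_distance = 50000)))
    farther <- tandem_summary(detect_tandem_clusters(
      inst$genes, inst$groups, tandem_params(max_intervening = 5,
                                             max_distance = 200000)))
    expect_gte(wider$n_genes, base$n_genes)
    expect_gte(farther$n_genes, base$n_genes)
  }
})

test_that("detection equals the all-pairs closure oracle on random instances", {
  set.seed(404)
  for (i in 1:20) {
    inst <- random_instance(sample(50:300, 1))
    params <- tandem_params(
      max_intervening = sample(0:12, 1),
      max_distance = sample(c(5000, 50000, 100000, 300000), 1),
      distance_mode = sample(c("intergenic", "start_to_start"), 1))
    got <- detect_tandem_clusters(inst$genes, inst$groups, params)
    want <- oracle_tandem_clusters(inst$genes, inst$groups, params)
    expect_identical(cluster_keys(got$member_ids), cluster_keys(want))
  }
})

test_that("tandem_summary aggregates counts and the size histogram", {
  empty <- detect_tandem_clusters(make_genes_at(1), make_groups(c("g001")))
  expect_identical(tandem_summary(empty),
                   list(n_clusters = 0L, n_genes = 0L,
                        size_histogram = integer(0)))
  g <- rbind(make_genes_at(c(1000, 4000), "s1", ids = c("a", "b")),
             make_genes_at(c(1000, 4000), "s2", ids = c("c", "d")),
             make_genes_at(c(1000, 4000, 7000), "s3", ids = c("e", "f", "h")))
  cl <- detect_tandem_clusters(
    g, make_groups(c("a", "b"), c("c", "d"), c("e", "f", "h")))
  s <- tandem_summary(cl)
  expect_identical(s$n_clusters, 3L)
  expect_identical(s$n_genes, 7L)
  expect_identical(s$size_histogram, c(`2` = 2L, `3` = 1L))
})
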