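# small in-code fixture builders shared across test files

make_genes <- function(starts, ends, scaffold = "sc1", ids = NULL,
                       strand = "+") {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  data.frame(gene_id = ids,
             scaffold_id = rep_len(scaffold, n),
             start = as.integer(starts), end = as.integer(ends),
             strand = rep_len(strand, n), rank = -1L,
             stringsAsFactors = FALSE)
}

# equally sized genes of length `len` at the given starts
make_genes_at <- function(starts, scaffold = "sc1", len = 500L, ids = NULL) {
  make_genes(starts, starts + len - 1L, scaffold = scaffold, ids = ids)
}

make_groups <- function(..., species = "focal") {
  members <- list(...)
  if (is.null(names(members))) {
    names(members) <- sprintf("OG%03d", seq_along(members))
  }
  group_set(lapply(members, function(m) {
    data.frame(species = rep_len(species, length(m)), gene_id = m,
               stringsAsFactors = FALSE)
  }))
}

make_hit <- function(q, s, evalue = 1e-10, bitscore = 100, identity = 90,
                     aln = 200L) {
  data.frame(query_id = q, subject_id = s, pct_identity = identity,
             aln_length = as.integer(aln),
             mismatches = as.integer(round(aln * (1 - identity / 100))),
             gap_opens = 0L, qstart = 1L, qend = as.integer(aln),
             sstart = 1L, send = as.integer(aln),
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

# a random gene catalog plus random group assignments, for oracle-equivalence
# sweeps; genes are placed with random lengths/gaps on a few scaffolds
random_instance <- function(n_genes, n_scaffolds = 3L, n_groups = 12L,
                            group_prob = 0.6) {
  sc <- sort(sample.int(n_scaffolds, n_genes, replace = TRUE))
  rows <- lapply(seq_len(n_scaffolds), function(s) {
    n <- sum(sc == s)
    if (!n) return(NULL)
    lens <- sample(200:3000, n, replace = TRUE)
    gaps <- sample(c(50:5000, 20000:150000), n, replace = TRUE)
    starts <- cumsum(gaps) + cumsum(c(0L, lens[-n]))
    make_genes(starts, starts + lens - 1L, scaffold = sprintf("s%02d", s),
               ids = sprintf("s%02d_g%03d", s, seq_len(n)))
  })
  genes <- do.call(rbind, rows)
  grouped <- genes$gene_id[stats::runif(nrow(genes)) < group_prob]
  assignment <- sample.int(n_groups, length(grouped), replace = TRUE)
  members <- split(grouped, assignment)
  members <- members[lengths(members) >= 2L]
  groups <- if (length(members)) {
    names(members) <- sprintf("OG%03d", seq_along(members))
    group_set(lapply(members, function(m) {
      data.frame(species = "focal", gene_id = m, stringsAsFactors = FALSE)
    }))
  } else {
    group_set(stats::setNames(list(), character(0)), "focal")
  }
  list(genes = genes, groups = groups)
}

# canonical form for cluster comparison: one string per cluster
cluster_keys <- function(member_lists) {
  sort(unname(vapply(member_lists, function(m) paste(sort(m), collapse = ","),
                     character(1))))
}
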