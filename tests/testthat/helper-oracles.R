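# independent oracles: different algorithms from the implementation,
# used to freeze expected values and for equivalence sweeps

# all-pairs link enumeration + igraph transitive closure (the implementation
# uses its own union-find and a sorted-window sweep)
oracle_tandem_clusters <- function(genes, groups, params = tandem_params()) {
  g <- genes[order(genes$scaffold_id, genes$start, genes$end, genes$gene_id), ]
  g$rank <- stats::ave(seq_len(nrow(g)), g$scaffold_id, FUN = seq_along) - 1L
  gene_group <- rep(NA_character_, nrow(g))
  for (gid in names(groups$groups)) {
    gene_group[g$gene_id %in% groups$groups[[gid]]$gene_id] <- gid
  }
  links <- list()
  for (sc in unique(g$scaffold_id)) {
    m <- g[g$scaffold_id == sc, ]
    grp <- gene_group[g$scaffold_id == sc]
    n <- nrow(m)
    if (n < 2L) next
    pr <- t(utils::combn(n, 2L))
    i <- pr[, 1]; j <- pr[, 2]
    same_group <- !is.na(grp[i]) & !is.na(grp[j]) & grp[i] == grp[j]
    interv <- abs(m$rank[i] - m$rank[j]) - 1L
    d <- if (params$distance_mode == "start_to_start") {
      abs(m$start[i] - m$start[j])
    } else {
      up_end <- ifelse(m$start[i] <= m$start[j], m$end[i], m$end[j])
      pmax(0, pmax(m$start[i], m$start[j]) - up_end - 1)
    }
    ok <- same_group & interv <= params$max_intervening & d < params$max_distance
    if (any(ok)) {
      links[[length(links) + 1L]] <- data.frame(
        from = m$gene_id[i[ok]], to = m$gene_id[j[ok]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(links)) return(list())
  edges <- do.call(rbind, links)
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  members <- split(names(comp$membership), comp$membership)
  Filter(function(m) length(m) >= params$min_members, members)
}

# direct definition: smallest prefix of the descending sort whose sum
# reaches half the total, by explicit loop
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(as.numeric(x))
  }
}

# single-pass character-level metrics via rle over the letter vector
oracle_metrics <- function(records, min_gap_len = 10L) {
  lens <- nchar(records)
  n_count <- 0L
  n_gaps <- 0L
  contigs <- integer(0)
  for (s in records) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(ch == "N")
    n_count <- n_count + sum(r$lengths[r$values])
    gap <- r$values & r$lengths >= min_gap_len
    n_gaps <- n_gaps + sum(gap)
    # contigs: merge runs, splitting only at qualifying gaps
    piece <- cumsum(gap)
    keep <- !gap
    if (any(keep)) {
      contigs <- c(contigs,
                   as.integer(tapply(r$lengths[keep], piece[keep], sum)))
    }
  }
  total <- sum(as.numeric(lens))
  list(total_length = total, n_scaffolds = length(records),
       max_len = max(lens), min_len = min(lens),
       n50_scaffold = oracle_n50(lens),
       n50_contig = if (length(contigs)) oracle_n50(contigs) else NA_real_,
       n_count = n_count,
       n_percent = sign(n_count) * floor(abs(100 * n_count / total) * 10 + 0.5) / 10,
       n_gaps = n_gaps)
}

# Pearson statistic via observed/expected cells, sum (O-E)^2/E
oracle_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

random_assembly <- function(n_scaffolds = 20L, max_len = 4000L) {
  seqs <- vapply(seq_len(n_scaffolds), function(i) {
    len <- sample(50:max_len, 1L)
    ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # plant a few N runs of mixed lengths (some below the gap threshold)
    for (k in seq_len(sample(0:4, 1L))) {
      run <- sample(2:60, 1L)
      if (run + 2L >= len) next
      at <- sample.int(len - run, 1L)
      ch[at:(at + run - 1L)] <- "N"
    }
    paste(ch, collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("rs%03d", seq_len(n_scaffolds)))
}
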