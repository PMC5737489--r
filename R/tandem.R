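#' Parameters for tandem-cluster detection
#'
#' The three detection criteria are: (i) two or more genes share a
#' paralogous/orthologous group; (ii) at most `max_intervening` annotated
#' genes lie between a pair on one scaffold (inclusive bound); and (iii) the
#' pairwise gene distance is strictly less than `max_distance`. Pairs passing
#' (ii) and (iii) within a group are chained transitively into clusters.
#'
#' @param max_intervening Maximum number of intervening genes allowed between
#'   a linked pair (inclusive; counts all annotated genes, not just group
#'   members).
#' @param max_distance Distance bound in bp; pairs at `>= max_distance` are
#'   not linked (strict bound).
#' @param min_members Minimum cluster size to report.
#' @param distance_mode `"intergenic"` (gap between gene bodies;
#'   length-invariant, the default) or `"start_to_start"`.
#' @return An object of class `"tandem_params"`.
#' @export
tandem_params <- function(max_intervening = 10L, max_distance = 100000L,
                          min_members = 2L,
                          distance_mode = c("intergenic", "start_to_start")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(max_intervening >= 0L, max_distance > 0L, min_members >= 2L)
  structure(list(max_intervening = as.integer(max_intervening),
                 max_distance = as.numeric(max_distance),
                 min_members = as.integer(min_members),
                 distance_mode = distance_mode),
            class = "tandem_params")
}

#' Assign per-scaffold gene order ranks
#'
#' Ranks are 0-based indices after sorting each scaffold's genes by
#' `(start, end, gene_id)`; strand is ignored. Ranks make the
#' intervening-gene criterion computable in O(1) per pair.
#'
#' @param genes Gene-catalog data frame (see [read_gff3()]).
#' @return The same data frame, row order preserved, with `rank` filled in.
#' @export
assign_gene_order <- function(genes) {
  key <- paste(genes$scaffold_id, genes$start, genes$end, genes$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate gene record: ", key[duplicated(key)][1])
  }
  ord <- order(genes$scaffold_id, genes$start, genes$end, genes$gene_id)
  rank <- integer(nrow(genes))
  rank[ord] <- stats::ave(seq_along(ord), genes$scaffold_id[ord],
                          FUN = seq_along) - 1L
  genes$rank <- rank
  genes
}

#' Number of annotated genes between two genes on one scaffold
#'
#' Counts ALL annotated genes with ranks strictly between the pair,
#' regardless of group membership.
#'
#' @param a,b Single-row gene records with assigned ranks.
#' @return Integer count.
#' @export
intervening_count <- function(a, b) {
  if (!identical(a$scaffold_id, b$scaffold_id)) {
    stop("intervening_count: genes on different scaffolds")
  }
  if (a$rank < 0L || b$rank < 0L) stop("ranks not assigned")
  abs(a$rank - b$rank) - 1L
}

#' Pairwise gene distance on a scaffold
#'
#' In `"intergenic"` mode the distance is the gap between gene bodies,
#' `max(0, start(downstream) - end(upstream) - 1)`; overlapping genes are at
#' distance 0. In `"start_to_start"` mode it is `|start_a - start_b|`.
#'
#' @param a,b Single-row gene records on the same scaffold.
#' @param mode `"intergenic"` or `"start_to_start"`.
#' @return Distance in bp.
#' @export
gene_distance <- function(a, b, mode = c("intergenic", "start_to_start")) {
  mode <- match.arg(mode)
  if (!identical(a$scaffold_id, b$scaffold_id)) {
    stop("gene_distance: genes on different scaffolds")
  }
  if (mode == "start_to_start") {
    return(abs(a$start - b$start))
  }
  if (a$start > b$start) {
    tmp <- a; a <- b; b <- tmp
  }
  max(0, b$start - a$end - 1)
}

# vectorized intergenic distance for sorted-by-start member tables
.pair_distance <- function(start_a, end_a, start_b, end_b, mode) {
  if (mode == "start_to_start") return(abs(start_a - start_b))
  up_end <- ifelse(start_a <= start_b, end_a, end_b)
  down_start <- pmax(start_a, start_b)
  pmax(0, down_start - up_end - 1)
}

# minimal union-find over 1..n
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect tandem duplicated gene clusters
#'
#' Within each (group, scaffold) restriction, gene pairs satisfying both the
#' intervening-gene bound and the strict distance bound are linked; clusters
#' are the connected components of these links with at least
#' `params$min_members` members. Grouped genes missing from the catalog are
#' skipped with a warning. If the catalog still carries the unassigned-rank
#' sentinel, [assign_gene_order()] is applied first.
#'
#' @param genes Gene-catalog data frame.
#' @param groups A [group_set()] of paralogous/orthologous groups.
#' @param params A [tandem_params()] object.
#' @return Data frame of clusters sorted by (scaffold, start of first
#'   member): columns `cluster_id`, `group_id`, `scaffold_id`, `n_members`,
#'   `first_start`, `last_end`, `span_bp`, `members` (comma-joined, ordered
#'   by start) and a list column `member_ids`.
#' @export
detect_tandem_clusters <- function(genes, groups, params = tandem_params()) {
  stopifnot(inherits(groups, "group_set"), inherits(params, "tandem_params"))
  if (any(genes$rank < 0L)) genes <- assign_gene_order(genes)
  idx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)

  out <- list()
  for (gid in names(groups$groups)) {
    member_ids <- groups$groups[[gid]]$gene_id
    present <- member_ids %in% names(idx)
    if (!all(present)) {
      warning("group ", gid, ": ", sum(!present),
              " member(s) absent from gene catalog, skipped")
      member_ids <- member_ids[present]
    }
    if (length(member_ids) < 2L) next
    g <- genes[idx[member_ids], , drop = FALSE]
    for (sc in unique(g$scaffold_id)) {
      m <- g[g$scaffold_id == sc, , drop = FALSE]
      if (nrow(m) < 2L) next
      m <- m[order(m$rank), , drop = FALSE]
      n <- nrow(m)
      parent <- .uf_new(n)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (m$rank[j] - m$rank[i] - 1L > params$max_intervening) break
          d <- .pair_distance(m$start[i], m$end[i], m$start[j], m$end[j],
                              params$distance_mode)
          if (d < params$max_distance) {
            ri <- .uf_find(parent, i)
            rj <- .uf_find(parent, j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
      root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
      for (comp in split(seq_len(n), root)) {
        if (length(comp) < params$min_members) next
        cm <- m[comp, , drop = FALSE]
        cm <- cm[order(cm$start, cm$end, cm$gene_id), , drop = FALSE]
        out[[length(out) + 1L]] <- list(
          group_id = gid, scaffold_id = sc,
          n_members = nrow(cm),
          first_start = min(cm$start), last_end = max(cm$end),
          member_ids = cm$gene_id
        )
      }
    }
  }

  if (!length(out)) {
    return(data.frame(cluster_id = character(0), group_id = character(0),
                      scaffold_id = character(0), n_members = integer(0),
                      first_start = integer(0), last_end = integer(0),
                      span_bp = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- data.frame(
    group_id = vapply(out, `[[`, character(1), "group_id"),
    scaffold_id = vapply(out, `[[`, character(1), "scaffold_id"),
    n_members = vapply(out, `[[`, integer(1), "n_members"),
    first_start = vapply(out, function(x) as.integer(x$first_start), integer(1)),
    last_end = vapply(out, function(x) as.integer(x$last_end), integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(res$scaffold_id, res$first_start, res$group_id)
  res <- res[ord, , drop = FALSE]
  member_ids <- lapply(out, `[[`, "member_ids")[ord]
  res$span_bp <- res$last_end - res$first_start + 1L
  res$members <- vapply(member_ids, paste, character(1), collapse = ",")
  res$member_ids <- member_ids
  res$cluster_id <- sprintf("TC%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("cluster_id", "group_id", "scaffold_id", "n_members", "first_start",
          "last_end", "span_bp", "members", "member_ids")]
}

#' Summarize tandem clusters
#'
#' @param clusters Output of [detect_tandem_clusters()].
#' @return List with `n_clusters`, `n_genes` (sum of member counts) and
#'   `size_histogram` (named integer vector keyed by cluster size).
#' @export
tandem_summary <- function(clusters) {
  if (!nrow(clusters)) {
    return(list(n_clusters = 0L, n_genes = 0L,
                size_histogram = integer(0)))
  }
  tab <- table(clusters$n_members)
  list(n_clusters = nrow(clusters),
       n_genes = sum(clusters$n_members),
       size_histogram = stats::setNames(as.integer(tab), names(tab)))
}

#' Write tandem clusters as TSV
#'
#' @param clusters Output of [detect_tandem_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tandem_clusters <- function(clusters, path) {
  cols <- c("cluster_id", "group_id", "scaffold_id", "n_members", "span_bp",
            "members")
  lines <- c(paste0("# ", paste(cols, collapse = "\t")),
             do.call(sprintf,
                     c(list("%s\t%s\t%s\t%d\t%d\t%s"),
                       unname(as.list(clusters[, cols])))))
  writeLines(if (nrow(clusters)) lines else lines[1], path)
  invisible(path)
}
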