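#' Build a protein similarity graph from pairwise hits
#'
#' Self-hits are dropped. An undirected edge (a, b) is added when the a→b hit
#' has `evalue <= max_evalue`; with `reciprocal = TRUE` a qualifying b→a hit
#' is also required. Edge weight is the maximum bit score among supporting
#' hits. All gene ids seen in the table become vertices, so genes whose hits
#' all fail the threshold remain as isolated nodes (future singletons).
#'
#' @param hits Similarity table (see [read_similarity_table()]).
#' @param max_evalue E-value threshold for a supporting hit.
#' @param reciprocal Require support in both directions?
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
build_similarity_graph <- function(hits, max_evalue = 1e-5, reciprocal = TRUE) {
  stopifnot(max_evalue > 0)
  nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  h <- hits[hits$query_id != hits$subject_id & hits$evalue <= max_evalue, ,
            drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste0(a, "\r", b)
    dir_fwd <- h$query_id < h$subject_id
    if (reciprocal) {
      both <- intersect(unique(key[dir_fwd]), unique(key[!dir_fwd]))
      keep <- key %in% both
    } else {
      keep <- rep(TRUE, nrow(h))
    }
    edges <- if (any(keep)) {
      weight <- tapply(h$bitscore[keep], key[keep], max)
      pairs <- strsplit(names(weight), "\r", fixed = TRUE)
      data.frame(from = vapply(pairs, `[`, character(1), 1L),
                 to = vapply(pairs, `[`, character(1), 2L),
                 weight = as.numeric(weight),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0), stringsAsFactors = FALSE)
    }
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Cluster paralogs as connected components of the similarity graph
#'
#' Components with at least two nodes become paralogous groups; isolated
#' nodes are singletons, not groups. Group ids are assigned `PG%06d` in
#' descending component size, ties broken by the lexicographically smallest
#' member id, so output is invariant to node/edge input order.
#'
#' @param graph Graph from [build_similarity_graph()].
#' @param species Species tag applied to all members.
#' @return A [group_set()]; the singleton gene ids are attached as the
#'   `"singletons"` attribute.
#' @export
cluster_paralogs <- function(graph, species = "focal") {
  comp <- igraph::components(graph)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  sizes <- lengths(members)
  keep <- sizes >= 2L
  singletons <- sort(unlist(members[!keep], use.names = FALSE))
  members <- members[keep]
  if (length(members)) {
    first <- vapply(members, `[`, character(1), 1L)
    ord <- order(-lengths(members), first)
    members <- members[ord]
  }
  groups <- stats::setNames(
    lapply(members, function(m) {
      data.frame(species = species, gene_id = m, stringsAsFactors = FALSE)
    }),
    sprintf("PG%06d", seq_along(members))
  )
  gs <- group_set(groups, species_universe = species)
  attr(gs, "singletons") <- singletons
  gs
}

#' Partition a labeled gene family into clusters and singletons
#'
#' Applies the restricted-subgroup rule: a paralogous group counts as a
#' cluster of the family only if at least two of its members carry the label
#' (e.g. are annotated as cytochrome P450s); only those labeled members count
#' as cluster genes. Labeled genes in no counted cluster are singletons, so
#' `n_cluster_genes + n_singletons` equals the family size.
#'
#' @param member_genes Character vector of gene ids carrying the label.
#' @param groups A [group_set()].
#' @return List with `n_clusters`, `n_cluster_genes`, `n_singletons`.
#' @export
family_partition <- function(member_genes, groups) {
  stopifnot(inherits(groups, "group_set"))
  member_genes <- unique(member_genes)
  counts <- vapply(groups$groups, function(m) {
    sum(m$gene_id %in% member_genes)
  }, integer(1))
  clustered <- counts >= 2L
  n_cluster_genes <- sum(counts[clustered])
  list(n_clusters = sum(clustered),
       n_cluster_genes = n_cluster_genes,
       n_singletons = length(member_genes) - n_cluster_genes)
}
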