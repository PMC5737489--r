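#' Read a reference-enzyme list
#'
#' Tab-separated columns: `ref_id` (accession), `enzyme_abbr`,
#' `pathway_stage` (e.g. MEP, iridoid, alkaloid), `protein_length`
#' (residues). Comment lines starting `#` are skipped.
#'
#' @param path Path to the TSV.
#' @return Data frame with those four columns.
#' @export
read_reference_enzymes <- function(path) {
  if (!file.exists(path)) stop("reference list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) stop("expected 4 columns at line ", keep[bad[1]], " of ", path)
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  refs <- data.frame(ref_id = m[, 1], enzyme_abbr = m[, 2],
                     pathway_stage = m[, 3],
                     protein_length = as.integer(m[, 4]),
                     stringsAsFactors = FALSE)
  if (any(is.na(refs$protein_length)) || any(refs$protein_length < 1L)) {
    stop("reference protein_length must be a positive integer")
  }
  refs
}

#' Top hit per reference enzyme, with identity and reference coverage
#'
#' For each reference, keeps the single hit with maximum bit score (ties
#' broken by higher percent identity, then lexicographically smallest gene
#' id), so results are invariant to hit order. Coverage is computed relative
#' to the reference protein length, `100 * aln_length / protein_length`,
#' capped at 100. References with no hits are reported with `NA` candidate
#' fields rather than dropped.
#'
#' @param hits Similarity table with reference ids as `query_id` and gene ids
#'   as `subject_id`.
#' @param refs Reference data frame (see [read_reference_enzymes()]).
#' @return Data frame with one row per reference: `ref_id`, `enzyme_abbr`,
#'   `pathway_stage`, `gene_id`, `pct_coverage`, `pct_identity`, `bitscore`.
#' @export
best_hits <- function(hits, refs) {
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    h <- hits[hits$query_id == r$ref_id, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(ref_id = r$ref_id, enzyme_abbr = r$enzyme_abbr,
                        pathway_stage = r$pathway_stage,
                        gene_id = NA_character_, pct_coverage = NA_real_,
                        pct_identity = NA_real_, bitscore = NA_real_,
                        stringsAsFactors = FALSE))
    }
    h <- h[order(-h$bitscore, -h$pct_identity, h$subject_id), , drop = FALSE]
    top <- h[1, ]
    data.frame(ref_id = r$ref_id, enzyme_abbr = r$enzyme_abbr,
               pathway_stage = r$pathway_stage, gene_id = top$subject_id,
               pct_coverage = min(100, 100 * top$aln_length / r$protein_length),
               pct_identity = top$pct_identity, bitscore = top$bitscore,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan scaffolds for physical neighborhoods of pathway candidates
#'
#' Per scaffold, candidate genes are sorted by start and chained while the
#' intergenic distance between successive candidates is at most `max_gap`.
#' Maximal chains with at least `min_members` members and at least
#' `min_stages` distinct pathway stages are reported; this turns the
#' qualitative observation of pathway homologs co-located on one scaffold
#' into a parameterized scan.
#'
#' @param genes Gene-catalog data frame.
#' @param candidates Data frame with columns `gene_id`, `enzyme_abbr`,
#'   `pathway_stage`. Candidates absent from the catalog are skipped with a
#'   warning.
#' @param max_gap Maximum intergenic distance (bp) between successive
#'   candidates in a chain (inclusive).
#' @param min_members Minimum candidates per neighborhood.
#' @param min_stages Minimum distinct pathway stages per neighborhood.
#' @return Data frame with one row per neighborhood: `scaffold_id`,
#'   `first_start`, `last_end`, `n_members`, `n_stages`, `members`
#'   (comma-joined `gene_id(abbr)` labels) plus a list column `member_table`.
#' @export
find_neighborhoods <- function(genes, candidates, max_gap = 100000L,
                               min_members = 2L, min_stages = 2L) {
  stopifnot(max_gap > 0)
  missing <- setdiff(candidates$gene_id, genes$gene_id)
  if (length(missing)) {
    warning("candidate gene(s) absent from catalog, skipped: ",
            paste(missing, collapse = ", "))
    candidates <- candidates[!candidates$gene_id %in% missing, , drop = FALSE]
  }
  cand <- merge(candidates, genes, by = "gene_id", sort = FALSE)
  out <- list()
  for (sc in unique(cand$scaffold_id)) {
    m <- cand[cand$scaffold_id == sc, , drop = FALSE]
    m <- m[order(m$start, m$end, m$gene_id), , drop = FALSE]
    if (!nrow(m)) next
    gap <- if (nrow(m) > 1L) {
      pmax(0, m$start[-1] - m$end[-nrow(m)] - 1)
    } else numeric(0)
    chain <- cumsum(c(0L, as.integer(gap > max_gap)))
    for (piece in split(seq_len(nrow(m)), chain)) {
      cm <- m[piece, , drop = FALSE]
      n_stages <- length(unique(cm$pathway_stage))
      if (nrow(cm) < min_members || n_stages < min_stages) next
      out[[length(out) + 1L]] <- list(
        scaffold_id = sc, first_start = min(cm$start),
        last_end = max(cm$end), n_members = nrow(cm), n_stages = n_stages,
        members = paste0(cm$gene_id, "(", cm$enzyme_abbr, ")",
                         collapse = ","),
        member_table = cm[, c("gene_id", "enzyme_abbr", "pathway_stage",
                              "start", "end")]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(0), first_start = integer(0),
                      last_end = integer(0), n_members = integer(0),
                      n_stages = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- data.frame(
    scaffold_id = vapply(out, `[[`, character(1), "scaffold_id"),
    first_start = vapply(out, function(x) as.integer(x$first_start), integer(1)),
    last_end = vapply(out, function(x) as.integer(x$last_end), integer(1)),
    n_members = vapply(out, `[[`, integer(1), "n_members"),
    n_stages = vapply(out, `[[`, integer(1), "n_stages"),
    members = vapply(out, `[[`, character(1), "members"),
    stringsAsFactors = FALSE
  )
  ord <- order(res$scaffold_id, res$first_start)
  res <- res[ord, , drop = FALSE]
  res$member_table <- lapply(out, `[[`, "member_table")[ord]
  rownames(res) <- NULL
  res
}
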