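#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and record ids are truncated at the first
#' whitespace, so `">s1 some description"` yields the id `"s1"`. This is the
#' carrier used for genome scaffolds and for protein sets throughout the
#' package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record ids, in file
#'   order. An empty file returns an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0L || !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id: ", dup[1])
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Extracts one record per row of `feature_type` (default `"gene"`), keeping
#' GFF3's 1-based inclusive coordinates. mRNA/exon/CDS rows are ignored. When
#' no rows of type `"gene"` exist but mRNA rows do, the mRNA rows are promoted
#' to genes using their ID attribute, so annotations that only ship transcript
#' rows still yield one analysis unit per locus.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to extract.
#' @return A gene-catalog `data.frame` with columns `gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand` and `rank`. `rank` is the per-scaffold order
#'   index, left at the `-1` sentinel until [assign_gene_order()] is called.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)

  parse_rows <- function(type) {
    sel <- vapply(rows, function(f) length(f) >= 9L && f[3] == type, logical(1))
    if (!any(sel)) return(NULL)
    idx <- which(sel)
    out <- lapply(idx, function(i) {
      f <- rows[[i]]
      start <- suppressWarnings(as.integer(f[4]))
      end <- suppressWarnings(as.integer(f[5]))
      if (is.na(start) || is.na(end)) {
        stop("non-numeric coordinates at line ", lineno[i], " of ", path)
      }
      if (start > end) {
        stop("start > end at line ", lineno[i], " of ", path)
      }
      m <- regmatches(f[9], regexec("(^|;)\\s*ID=([^;]+)", f[9]))[[1]]
      if (length(m) < 3L || !nzchar(m[3])) {
        stop("missing ID attribute at line ", lineno[i], " of ", path)
      }
      list(gene_id = m[3], scaffold_id = f[1], start = start, end = end,
           strand = if (f[7] %in% c("+", "-")) f[7] else ".")
    })
    data.frame(
      gene_id = vapply(out, `[[`, character(1), "gene_id"),
      scaffold_id = vapply(out, `[[`, character(1), "scaffold_id"),
      start = vapply(out, `[[`, integer(1), "start"),
      end = vapply(out, `[[`, integer(1), "end"),
      strand = vapply(out, `[[`, character(1), "strand"),
      rank = -1L,
      stringsAsFactors = FALSE
    )
  }

  genes <- parse_rows(feature_type)
  if (is.null(genes) && identical(feature_type, "gene")) {
    genes <- parse_rows("mRNA")
  }
  if (is.null(genes)) {
    return(data.frame(gene_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene id in GFF3: ", dup[1])
  genes
}

#' Write a gene catalog as GFF3
#'
#' @param genes Gene-catalog data frame (see [read_gff3()]).
#' @param path Output path.
#' @param feature_type Feature type to emit.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature_type = "gene", source = "tandemdup") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$scaffold_id, source, feature_type,
                     genes$start, genes$end, genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a group set
#'
#' A group set is the package's container for paralogous or orthologous
#' groups: a named list mapping group id to a data frame of members with
#' `species` and `gene_id` columns. A gene id may appear in at most one group.
#'
#' @param groups Named list of member data frames (columns `species`,
#'   `gene_id`).
#' @param species_universe Character vector of species tags; defaults to the
#'   tags observed in `groups`.
#' @return An object of class `"group_set"`.
#' @export
group_set <- function(groups, species_universe = NULL) {
  stopifnot(is.list(groups))
  if (length(groups) && is.null(names(groups))) stop("groups must be named")
  all_genes <- unlist(lapply(groups, `[[`, "gene_id"), use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup)) stop("gene assigned to more than one group: ", dup[1])
  if (any(vapply(groups, nrow, integer(1)) < 1L)) {
    stop("every group must have at least one member")
  }
  if (is.null(species_universe)) {
    species_universe <- sort(unique(unlist(lapply(groups, `[[`, "species"),
                                           use.names = FALSE)))
  }
  structure(list(groups = groups, species_universe = species_universe),
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  sizes <- vapply(x$groups, nrow, integer(1))
  cat("group_set:", length(x$groups), "groups,",
      sum(sizes), "genes,", length(x$species_universe), "species\n")
  invisible(x)
}

#' Gene ids of all grouped genes
#'
#' @param gs A [group_set()].
#' @param species Optional species tag to restrict to.
#' @return Character vector of gene ids.
#' @export
grouped_genes <- function(gs, species = NULL) {
  stopifnot(inherits(gs, "group_set"))
  if (is.null(species)) {
    unlist(lapply(gs$groups, `[[`, "gene_id"), use.names = FALSE)
  } else {
    unlist(lapply(gs$groups, function(m) m$gene_id[m$species %in% species]),
           use.names = FALSE)
  }
}

#' Read an Orthogroups.txt-style group file
#'
#' Parses the one-line-per-group dialect `"OG0000001: geneA geneB ..."` (colon
#' after the group id, whitespace-separated members). With
#' `species_from_prefix = TRUE`, members are expected as `"species|gene"` and
#' the species tag is split off; otherwise every member receives
#' `default_species`.
#'
#' @param path Path to the group file.
#' @param species_from_prefix Parse species tags from `"species|gene"`
#'   prefixes?
#' @param default_species Species tag used when no prefixes are parsed.
#' @return A [group_set()], groups in file order.
#' @export
read_orthogroups <- function(path, species_from_prefix = FALSE,
                             default_species = "focal") {
  if (!file.exists(path)) stop("group file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  groups <- list()
  for (i in lines_keep) {
    m <- regmatches(lines[i], regexec("^(\\S+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) < 3L || !nzchar(m[2])) {
      stop("malformed group line ", i, " of ", path)
    }
    gid <- sub(":$", "", m[2])
    members <- strsplit(trimws(m[3]), "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (!length(members)) stop("group with no members at line ", i, " of ", path)
    if (species_from_prefix) {
      has_pipe <- grepl("|", members, fixed = TRUE)
      if (!all(has_pipe)) {
        stop("member without species prefix at line ", i, " of ", path)
      }
      species <- sub("\\|.*$", "", members)
      gene <- sub("^[^|]*\\|", "", members)
    } else {
      species <- rep(default_species, length(members))
      gene <- members
    }
    if (gid %in% names(groups)) stop("duplicate group id at line ", i, ": ", gid)
    groups[[gid]] <- data.frame(species = species, gene_id = gene,
                                stringsAsFactors = FALSE)
  }
  group_set(groups)
}

#' Write a group set in the Orthogroups.txt dialect
#'
#' @param gs A [group_set()].
#' @param path Output path.
#' @param with_prefix Emit members as `"species|gene"`?
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(gs, path, with_prefix = FALSE) {
  stopifnot(inherits(gs, "group_set"))
  lines <- vapply(names(gs$groups), function(gid) {
    m <- gs$groups[[gid]]
    members <- if (with_prefix) paste0(m$species, "|", m$gene_id) else m$gene_id
    paste0(gid, ": ", paste(members, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

similarity_columns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                        "mismatches", "gap_opens", "qstart", "qend", "sstart",
                        "send", "evalue", "bitscore")

empty_similarity_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular similarity table
#'
#' The standard tab-separated pairwise-alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, E-value, bit score). Row order is preserved and self-hits are
#' retained; downstream consumers filter them.
#'
#' @param path Path to the table.
#' @return Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("similarity table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(empty_similarity_table())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("expected 12 tab-separated columns at line ", keep[bad[1]], " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             pct_identity = as.numeric(m[, 3]),
             aln_length = as.integer(m[, 4]),
             mismatches = as.integer(m[, 5]),
             gap_opens = as.integer(m[, 6]),
             qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
             sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             stringsAsFactors = FALSE)
}

#' Write a similarity table in the 12-column tabular dialect
#'
#' @param hits Data frame as returned by [read_similarity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  stopifnot(all(similarity_columns %in% names(hits)))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$subject_id,
                   format(hits$pct_identity, trim = TRUE, scientific = FALSE),
                   hits$aln_length, hits$mismatches, hits$gap_opens,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   format(hits$evalue, trim = TRUE),
                   format(hits$bitscore, trim = TRUE, scientific = FALSE))
  writeLines(if (nrow(hits)) lines else character(0), path)
  invisible(path)
}

#' Read a two-column gene-to-GO-category map
#'
#' Lines are `gene_id<TAB>category`; repeated gene ids accumulate categories
#' and duplicate pairs collapse (set semantics).
#'
#' @param path Path to the TSV.
#' @return Named list mapping gene id to a character vector of categories.
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) stop("GO map not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("expected 2 columns at line ", keep[bad[1]], " of ", path)
  gene <- vapply(fields, `[`, character(1), 1L)
  term <- vapply(fields, `[`, character(1), 2L)
  if (any(!nzchar(trimws(gene)))) {
    stop("blank gene id at line ", keep[which(!nzchar(trimws(gene)))[1]], " of ", path)
  }
  if (any(!nzchar(trimws(term)))) {
    stop("blank category at line ", keep[which(!nzchar(trimws(term)))[1]], " of ", path)
  }
  lapply(split(term, gene), function(x) sort(unique(x)))
}

#' Write a gene-to-GO-category map as two-column TSV
#'
#' @param go Named list as returned by [read_go_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_map <- function(go, path) {
  gene <- rep(names(go), lengths(go))
  term <- unlist(go, use.names = FALSE)
  writeLines(if (length(gene)) paste(gene, term, sep = "\t") else character(0),
             path)
  invisible(path)
}
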