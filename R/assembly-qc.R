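# round half away from zero, to d decimals (base round() is round-half-even)
round_half_away <- function(x, d = 1L) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}

#' N50 of a set of sequence lengths
#'
#' Sorts the lengths in descending order and returns the first length at which
#' the running cumulative sum reaches at least half the total — the standard
#' assembler-reporting convention.
#'
#' @param lengths Positive integer vector of scaffold or contig lengths.
#' @return The N50 length (a member of `lengths`).
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50: empty length list")
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("n50: lengths must be positive")
  }
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Split a scaffold sequence into contig lengths
#'
#' Contigs are maximal substrings containing no N run of length at least
#' `min_gap_len`; shorter N runs stay inside contigs. Leading or trailing gap
#' runs produce no empty contigs, and an all-N sequence yields no contigs.
#'
#' @param seq Nucleotide string (uppercase; Ns mark gaps).
#' @param min_gap_len Minimum N-run length that counts as a gap.
#' @return Integer vector of contig lengths, left to right.
#' @export
split_contigs <- function(seq, min_gap_len = 10L) {
  stopifnot(length(seq) == 1L, min_gap_len >= 1L)
  n <- nchar(seq)
  if (n == 0L) return(integer(0))
  gaps <- find_n_runs(seq, min_gap_len)
  if (!nrow(gaps)) return(n)
  bounds <- c(0L, as.vector(t(as.matrix(gaps))), n + 1L)
  starts <- bounds[seq(1, length(bounds), by = 2)] + 1L
  ends <- bounds[seq(2, length(bounds), by = 2)] - 1L
  len <- ends - starts + 1L
  len[len > 0L]
}

# maximal N runs of length >= min_len; data.frame(start, end), 1-based
find_n_runs <- function(seq, min_len = 1L) {
  m <- gregexpr(sprintf("N{%d,}", min_len), seq)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Assembly summary metrics
#'
#' Computes whole-assembly totals, length extremes, scaffold and contig N50s,
#' the N-base count and percentage (rounded half away from zero to one
#' decimal), and the number of gaps (maximal N runs of length at least
#' `min_gap_len`). Contig lengths come from [split_contigs()] applied to every
#' scaffold with the same gap threshold.
#'
#' @param records Named character vector of scaffold sequences.
#' @param min_gap_len Minimum N-run length that counts as a gap.
#' @return List with fields `total_length`, `n_scaffolds`, `max_len`,
#'   `min_len`, `n50_scaffold`, `n50_contig`, `n_count`, `n_percent`,
#'   `n_gaps`.
#' @export
assembly_metrics <- function(records, min_gap_len = 10L) {
  stopifnot(length(records) >= 1L)
  lens <- nchar(records)
  n_count <- sum(lens - nchar(gsub("N", "", records, fixed = TRUE)))
  contigs <- unlist(lapply(records, split_contigs, min_gap_len = min_gap_len),
                    use.names = FALSE)
  n_gaps <- sum(vapply(records, function(s) nrow(find_n_runs(s, min_gap_len)),
                       integer(1)))
  total <- sum(as.numeric(lens))
  list(
    total_length = total,
    n_scaffolds = length(records),
    max_len = max(lens),
    min_len = min(lens),
    n50_scaffold = n50(lens),
    n50_contig = if (length(contigs)) n50(contigs) else NA_real_,
    n_count = n_count,
    n_percent = n_percent(n_count, total),
    n_gaps = n_gaps
  )
}

#' Percentage of N bases, reported to one decimal
#'
#' @param n_count Number of N bases.
#' @param total_length Total assembly length in bp.
#' @return Percentage rounded half away from zero to one decimal.
#' @export
n_percent <- function(n_count, total_length) {
  stopifnot(total_length > 0, n_count >= 0, n_count <= total_length)
  round_half_away(100 * n_count / total_length, 1L)
}

#' Filter scaffolds by minimum length and an exclusion list
#'
#' Mirrors the pre-release cleanup applied to draft assemblies: drop scaffolds
#' shorter than `min_length` and scaffolds on an explicit exclusion list
#' (e.g. contaminant matches). Survivor order is preserved.
#'
#' @param records Named character vector of scaffold sequences.
#' @param min_length Minimum scaffold length to keep, in bp.
#' @param exclude_ids Character vector of scaffold ids to drop regardless of
#'   length. Ids absent from `records` raise a warning, not an error.
#' @return List with `kept` (surviving records) and `report` (data frame of
#'   removals with columns `scaffold_id`, `length`, `reason`; reasons are
#'   `"excluded_id"` and `"below_min_length"`).
#' @export
filter_scaffolds <- function(records, min_length = 0L, exclude_ids = character(0)) {
  stopifnot(min_length >= 0L)
  ids <- names(records)
  missing <- setdiff(exclude_ids, ids)
  if (length(missing)) {
    warning("exclude ids not present in assembly: ",
            paste(missing, collapse = ", "))
  }
  lens <- nchar(records)
  excluded <- ids %in% exclude_ids
  short <- !excluded & lens < min_length
  drop <- excluded | short
  report <- data.frame(
    scaffold_id = ids[drop],
    length = as.integer(lens[drop]),
    reason = ifelse(excluded[drop], "excluded_id", "below_min_length"),
    stringsAsFactors = FALSE
  )
  list(kept = records[!drop], report = report)
}
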