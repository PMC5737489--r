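#' Build a 2x2 contingency table for one GO category
#'
#' The background is the complement of the focal set within `all_genes`, so
#' the two classes are disjoint (a requirement of the independence test).
#' Genes with no GO annotation at all count as "without term".
#'
#' @param term Category label.
#' @param focal Character vector of focal gene ids (subset of `all_genes`).
#' @param all_genes Character vector of all genes in the universe.
#' @param go GO map (named list, see [read_go_map()]).
#' @return List with counts `a` (focal with term), `b` (focal without),
#'   `c` (background with), `d` (background without).
#' @export
make_contingency <- function(term, focal, all_genes, go) {
  focal <- unique(focal)
  all_genes <- unique(all_genes)
  if (!all(focal %in% all_genes)) {
    stop("focal set is not a subset of the gene universe")
  }
  background <- setdiff(all_genes, focal)
  if (!length(focal) || !length(background)) {
    stop("focal and background sets must both be non-empty")
  }
  with_term <- names(go)[vapply(go, function(t) term %in% t, logical(1))]
  a <- sum(focal %in% with_term)
  c_ <- sum(background %in% with_term)
  list(a = a, b = length(focal) - a,
       c = c_, d = length(background) - c_)
}

#' Pearson chi-squared statistic for a 2x2 table (1 df)
#'
#' The literal Pearson formula
#' `N * (ad - bc)^2 / ((a+b) (c+d) (a+c) (b+d))` with `N = a+b+c+d`; the
#' p-value is the upper tail of the chi-squared distribution with 1 degree of
#' freedom. The Yates continuity correction subtracts `N/2` from `|ad - bc|`
#' (floored at 0) before squaring. A table with any zero marginal is not
#' testable: the result carries `untestable = TRUE` and `NA` values rather
#' than a fabricated number.
#'
#' @param table Contingency list from [make_contingency()] (fields a,b,c,d).
#' @param yates Apply the continuity correction?
#' @return List with `statistic`, `p_value`, `untestable`.
#' @export
chi_square_1df <- function(table, yates = FALSE) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c_ <- as.numeric(table$c); d <- as.numeric(table$d)
  if (any(c(a, b, c_, d) < 0)) stop("negative cell count")
  n <- a + b + c_ + d
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, untestable = TRUE))
  }
  num <- abs(a * d - b * c_)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(marg)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       untestable = FALSE)
}

#' Scan GO categories for enrichment or depletion in a focal gene set
#'
#' One chi-squared test per category whose total gene count in the universe
#' reaches `min_term_count`. Both directions are reported: a category is
#' `"enriched"` when its focal frequency exceeds the background frequency and
#' `"depleted"` when it falls below. No multiple-testing correction is
#' applied by default, matching raw per-category significance reporting;
#' `bonferroni = TRUE` multiplies p-values by the number of tested terms.
#'
#' @param focal Focal gene ids (e.g. tandem duplicated genes).
#' @param all_genes Gene universe.
#' @param go GO map (named list).
#' @param alpha Significance level (e.g. `1e-4`).
#' @param min_term_count Minimum genes carrying a category for it to be
#'   tested.
#' @param yates Apply the continuity correction?
#' @param bonferroni Apply a Bonferroni correction before calling
#'   significance?
#' @return Data frame sorted by ascending p-value with columns `term`, `a`,
#'   `b`, `c`, `d`, `statistic`, `p_value`, `direction`, `significant`,
#'   `untestable`.
#' @export
enrichment_scan <- function(focal, all_genes, go, alpha = 1e-4,
                            min_term_count = 5L, yates = FALSE,
                            bonferroni = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  focal <- unique(focal)
  all_genes <- unique(all_genes)
  if (!all(focal %in% all_genes)) {
    stop("focal set is not a subset of the gene universe")
  }
  background <- setdiff(all_genes, focal)
  if (!length(focal) || !length(background)) {
    stop("focal and background sets must both be non-empty")
  }
  go <- go[names(go) %in% all_genes]
  term_genes <- split(rep(names(go), lengths(go)), unlist(go, use.names = FALSE))
  term_genes <- term_genes[lengths(term_genes) >= min_term_count]
  if (!length(term_genes)) {
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), statistic = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      significant = logical(0), untestable = logical(0),
                      stringsAsFactors = FALSE))
  }
  nf <- length(focal); nb <- length(background)
  rows <- lapply(names(term_genes), function(term) {
    tg <- term_genes[[term]]
    a <- sum(tg %in% focal)
    c_ <- length(tg) - a
    tab <- list(a = a, b = nf - a, c = c_, d = nb - c_)
    res <- chi_square_1df(tab, yates = yates)
    direction <- if (res$untestable || a / nf == c_ / nb) "none"
      else if (a / nf > c_ / nb) "enriched" else "depleted"
    data.frame(term = term, a = a, b = nf - a, c = c_, d = nb - c_,
               statistic = res$statistic, p_value = res$p_value,
               direction = direction, untestable = res$untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_adj <- if (bonferroni) pmin(1, out$p_value * nrow(out)) else out$p_value
  out$significant <- !out$untestable & !is.na(p_adj) & p_adj < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "a", "b", "c", "d", "statistic", "p_value", "direction",
          "significant", "untestable")]
}

#' Write enrichment results as TSV
#'
#' @param results Data frame from [enrichment_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  cols <- c("term", "a", "b", "c", "d", "statistic", "p_value", "direction",
            "significant")
  header <- paste0("# ", paste(cols, collapse = "\t"))
  body <- sprintf("%s\t%d\t%d\t%d\t%d\t%.6g\t%.6g\t%s\t%s",
                  results$term, results$a, results$b, results$c, results$d,
                  results$statistic, results$p_value, results$direction,
                  results$significant)
  writeLines(c(header, body), path)
  invisible(path)
}
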