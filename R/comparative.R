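#' Partition orthogroups by their exact species-presence signature
#'
#' Each group contributes one count to the sector of the Venn partition
#' matching exactly the set of species with at least one member in the group.
#' Signatures are the sorted species tags joined by `"+"`.
#'
#' @param groups A [group_set()] whose members carry species tags.
#' @return List of class `"venn_partition"` with `counts` (named integer
#'   vector keyed by signature), `species_universe` and `n_groups`.
#' @export
species_signature <- function(groups) {
  stopifnot(inherits(groups, "group_set"))
  sigs <- vapply(groups$groups, function(m) {
    sp <- m$species
    if (any(is.na(sp) | !nzchar(sp))) {
      stop("group member without species tag")
    }
    paste(sort(unique(sp)), collapse = "+")
  }, character(1))
  tab <- table(sigs)
  structure(list(counts = stats::setNames(as.integer(tab), names(tab)),
                 species_universe = groups$species_universe,
                 n_groups = length(groups$groups)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over {", paste(x$species_universe, collapse = ", "),
      "}:", x$n_groups, "groups\n")
  for (s in names(sort(x$counts, decreasing = TRUE))) {
    cat(sprintf("  %-40s %d\n", s, x$counts[[s]]))
  }
  invisible(x)
}

#' Marginal group count for one species
#'
#' Number of groups containing at least one member of `species`, i.e. the sum
#' of Venn sectors whose signature includes it.
#'
#' @param partition A `"venn_partition"` from [species_signature()].
#' @param species Species tag.
#' @return Integer count.
#' @export
venn_marginal <- function(partition, species) {
  stopifnot(inherits(partition, "venn_partition"))
  sets <- strsplit(names(partition$counts), "+", fixed = TRUE)
  sum(partition$counts[vapply(sets, function(s) species %in% s, logical(1))])
}

#' Count singleton genes per species
#'
#' A singleton is a gene in the species' inventory assigned to no group of
#' the group set (the "unassigned" semantics of multi-species orthology
#' clustering), not a single-member group. With
#' `single_member_groups = TRUE`, sole members of size-1 groups are counted
#' as singletons too (the alternative reading).
#'
#' @param inventories Named list: species tag → character vector of all gene
#'   ids of that species.
#' @param groups A [group_set()].
#' @param single_member_groups Also count sole members of size-1 groups?
#' @return Named integer vector of singleton counts per species.
#' @export
count_singletons <- function(inventories, groups, single_member_groups = FALSE) {
  stopifnot(inherits(groups, "group_set"), is.list(inventories))
  assigned <- lapply(groups$groups, function(m) {
    if (single_member_groups && nrow(m) == 1L) NULL else m
  })
  assigned <- do.call(rbind, assigned)
  out <- vapply(names(inventories), function(sp) {
    inv <- inventories[[sp]]
    sp_assigned <- if (is.null(assigned)) character(0)
      else assigned$gene_id[assigned$species == sp]
    stray <- setdiff(sp_assigned, inv)
    if (length(stray)) {
      warning("species ", sp, ": ", length(stray),
              " grouped gene(s) missing from inventory")
    }
    length(setdiff(inv, sp_assigned))
  }, integer(1))
  out
}

#' Write a Venn partition as TSV
#'
#' @param partition A `"venn_partition"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn <- function(partition, path) {
  lines <- c("# signature\tn_groups",
             paste(names(partition$counts), partition$counts, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
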