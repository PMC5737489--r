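# sample() misbehaves on length-1 x; this doesn't
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

sample_range <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Parameters for the synthetic-annotation generator
#'
#' The generator emulates the structure a tandem-duplication analysis sees in
#' a real plant genome annotation: per-scaffold gene order with realistic
#' intergenic distances, paralog families laid out either as tandem arrays
#' (consecutive genes, sub-100-kbp spacing) or as dispersed duplicates on
#' distinct scaffolds, similarity hits consistent with family membership, a
#' GO category enriched among tandem genes at a controlled odds ratio, and
#' N-gap runs placed between genes (never inside them). One integer seed
#' drives every draw, so identical parameters yield byte-identical outputs.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_scaffolds Number of scaffolds.
#' @param genes_per_scaffold Range (length-2) of genes per scaffold.
#' @param gene_length Range of gene lengths, bp.
#' @param intergenic_gap Range of gaps between unrelated neighbors, bp.
#' @param n_families Number of paralog families.
#' @param family_size Range of family sizes (min 2).
#' @param tandem_fraction Fraction of families laid out as tandem arrays.
#' @param array_spacing Range of gaps inside a tandem array, bp; must stay
#'   below the detection distance bound.
#' @param dispersed_min_separation Minimum separation of dispersed
#'   duplicates, bp; the generator places them on distinct scaffolds, which
#'   satisfies any separation floor.
#' @param within_family_identity Target pairwise percent identity between
#'   family member proteins.
#' @param protein_length Range of protein lengths, residues.
#' @param go_terms Background GO category labels.
#' @param enriched_term Label of the category planted as enriched among
#'   tandem genes.
#' @param enriched_term_odds_ratio Odds ratio of the planted enrichment.
#' @param baseline_term_prob Probability a non-tandem gene carries the
#'   planted category.
#' @param background_term_prob Per-gene probability of each background
#'   category.
#' @param gap_runs_per_scaffold Range of N runs planted per scaffold.
#' @param gap_run_length Range of N-run lengths, bp.
#' @param noise_hits Number of spurious cross-family similarity rows.
#' @param noise_evalue E-value given to noise rows (above any sensible
#'   threshold).
#' @param species_tag Species tag used in emitted group files.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(seed = 1L,
                       n_scaffolds = 10L,
                       genes_per_scaffold = c(150L, 250L),
                       gene_length = c(500L, 2000L),
                       intergenic_gap = c(1000L, 8000L),
                       n_families = 60L,
                       family_size = c(2L, 6L),
                       tandem_fraction = 0.5,
                       array_spacing = c(200L, 2000L),
                       dispersed_min_separation = 200000L,
                       within_family_identity = 90,
                       protein_length = c(150L, 400L),
                       go_terms = c("transport", "signal transduction",
                                    "cell organization and biogenesis",
                                    "other cellular processes",
                                    "other metabolic processes",
                                    "DNA metabolism", "protein metabolism",
                                    "developmental processes"),
                       enriched_term = "response to stress",
                       enriched_term_odds_ratio = 4,
                       baseline_term_prob = 0.1,
                       background_term_prob = 0.15,
                       gap_runs_per_scaffold = c(1L, 4L),
                       gap_run_length = c(50L, 500L),
                       noise_hits = 0L,
                       noise_evalue = 1e-3,
                       species_tag = "caca") {
  p <- as.list(environment())
  for (f in c("genes_per_scaffold", "gene_length", "intergenic_gap",
              "family_size", "array_spacing", "protein_length",
              "gap_runs_per_scaffold", "gap_run_length")) {
    r <- p[[f]]
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
      stop("sim_params: ", f, " must be a non-empty range c(lo, hi)")
    }
  }
  stopifnot(p$seed == round(p$seed), p$n_scaffolds >= 1L,
            p$family_size[1] >= 2L,
            p$tandem_fraction >= 0, p$tandem_fraction <= 1,
            p$within_family_identity > 0, p$within_family_identity <= 100,
            p$baseline_term_prob >= 0, p$baseline_term_prob < 1,
            p$enriched_term_odds_ratio >= 0,
            p$dispersed_min_separation > 0)
  structure(p, class = "sim_params")
}

#' Simulate a genome annotation with planted tandem arrays
#'
#' Places non-overlapping genes left to right on each scaffold with sampled
#' intergenic gaps. Families marked tandem occupy consecutive slots with
#' array-internal spacing drawn from `array_spacing`; dispersed families put
#' each member on a different scaffold, so no dispersed pair can satisfy the
#' same-scaffold criteria. N runs are inserted into intergenic gaps only
#' (one run per gap, with at least 1 bp of non-N margin), so gene bodies
#' never contain Ns.
#'
#' @param params A [sim_params()] object.
#' @param outdir Optional directory; when given, `genome.fa`, `genes.gff3`,
#'   `orthogroups.txt` and `truth/*.tsv` are written there.
#' @return List of class `"sim_annotation"`: `genome` (named character
#'   vector), `genes` (gene catalog with ranks assigned), `groups`
#'   ([group_set()] of planted families), `truth` (list with `families`,
#'   `arrays`, `gaps`, `tandem_gene_ids`, `gene_ids`) and `params`.
#' @export
simulate_annotation <- function(params = sim_params(), outdir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  ns <- params$n_scaffolds
  scaffold_ids <- sprintf("scf%03d", seq_len(ns))
  n_slots <- sample_range(params$genes_per_scaffold, ns)

  sizes <- sample_range(params$family_size, params$n_families)
  n_tandem <- round(params$tandem_fraction * params$n_families)
  tandem_idx <- if (n_tandem > 0) sort(resample(seq_len(params$n_families),
                                                n_tandem)) else integer(0)
  is_tandem <- seq_len(params$n_families) %in% tandem_idx

  if (sum(sizes) > sum(n_slots)) {
    stop("families need ", sum(sizes), " gene slots but scaffolds provide ",
         sum(n_slots), "; increase genes_per_scaffold or n_scaffolds")
  }
  if (any(sizes[!is_tandem] > ns)) {
    stop("a dispersed family of size ", max(sizes[!is_tandem]),
         " cannot be spread over ", ns,
         " scaffolds; increase n_scaffolds or reduce family_size")
  }

  # reserve blocks: tandem families take runs of consecutive slots on one
  # scaffold; dispersed members take single slots on distinct scaffolds
  rem <- n_slots
  blocks <- lapply(seq_len(ns), function(i) list())
  add_block <- function(sc, fam, k) {
    blocks[[sc]][[length(blocks[[sc]]) + 1L]] <<- list(family = fam, k = k)
    rem[sc] <<- rem[sc] - k
  }
  for (f in tandem_idx) {
    eligible <- which(rem >= sizes[f])
    if (!length(eligible)) {
      stop("no scaffold has ", sizes[f], " free gene slots for a tandem ",
           "array; increase genes_per_scaffold or n_scaffolds")
    }
    add_block(resample(eligible), f, sizes[f])
  }
  for (f in setdiff(seq_len(params$n_families), tandem_idx)) {
    eligible <- which(rem >= 1L)
    if (length(eligible) < sizes[f]) {
      stop("not enough scaffolds with free slots for a dispersed family of ",
           "size ", sizes[f])
    }
    for (sc in resample(eligible, sizes[f])) add_block(sc, f, 1L)
  }
  for (sc in seq_len(ns)) {
    while (rem[sc] > 0L) add_block(sc, NA_integer_, 1L)
  }

  # lay out each scaffold: shuffle blocks, flatten to slots, sample
  # coordinates, then plant N runs in intergenic gaps
  gene_rows <- list()
  gap_rows <- list()
  genome <- stats::setNames(character(ns), scaffold_ids)
  fam_of_gene <- character(0)
  gene_counter <- 0L
  code <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

  for (sc in seq_len(ns)) {
    bl <- blocks[[sc]][sample.int(length(blocks[[sc]]))]
    slot_family <- unlist(lapply(bl, function(b) rep(b$family, b$k)))
    slot_in_array <- unlist(lapply(bl, function(b) rep(b$k > 1L, b$k)))
    n <- length(slot_family)
    lens <- sample_range(params$gene_length, n)
    same_array <- slot_in_array[-n] & slot_in_array[-1] &
      !is.na(slot_family[-n]) & slot_family[-n] == slot_family[-1]
    same_array[is.na(same_array)] <- FALSE
    inner <- ifelse(same_array,
                    sample_range(params$array_spacing, n - 1L),
                    sample_range(params$intergenic_gap, n - 1L))
    lead <- sample_range(params$intergenic_gap)
    trail <- sample_range(params$intergenic_gap)
    starts <- lead + 1L + c(0L, cumsum(lens[-n] + inner))
    ends <- starts + lens - 1L
    scaffold_len <- ends[n] + trail

    ids <- sprintf("g%05d", gene_counter + seq_len(n))
    gene_counter <- gene_counter + n
    gene_rows[[sc]] <- data.frame(
      gene_id = ids, scaffold_id = scaffold_ids[sc],
      start = starts, end = ends,
      strand = sample(c("+", "-"), n, replace = TRUE),
      rank = seq_len(n) - 1L, stringsAsFactors = FALSE)
    fam_of_gene <- c(fam_of_gene,
                     stats::setNames(as.character(slot_family), ids))

    # intergenic gap intervals: before, between and after genes
    gap_start <- c(1L, ends + 1L)
    gap_end <- c(starts - 1L, scaffold_len)
    gap_len <- gap_end - gap_start + 1L
    n_runs <- sample_range(params$gap_runs_per_scaffold)
    run_lens <- sample_range(params$gap_run_length, n_runs)
    used <- logical(length(gap_len))
    seq_codes <- sample(code[1:4], scaffold_len, replace = TRUE)
    placed <- list()
    for (r in seq_len(n_runs)) {
      host <- which(!used & gap_len >= run_lens[r] + 2L)
      if (!length(host)) next
      g <- resample(host)
      used[g] <- TRUE
      off <- resample(seq_len(gap_len[g] - run_lens[r] - 1L))
      run_start <- gap_start[g] + off
      run_end <- run_start + run_lens[r] - 1L
      seq_codes[run_start:run_end] <- code[["N"]]
      placed[[length(placed) + 1L]] <- c(run_start, run_end)
    }
    genome[sc] <- intToUtf8(seq_codes)
    gap_rows[[sc]] <- if (length(placed)) {
      data.frame(scaffold_id = scaffold_ids[sc],
                 start = vapply(placed, function(p) as.integer(p[1]), integer(1)),
                 end = vapply(placed, function(p) as.integer(p[2]), integer(1)),
                 stringsAsFactors = FALSE)
    } else NULL
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  fam_assign <- fam_of_gene[!is.na(fam_of_gene) & fam_of_gene != "NA"]
  fam_ids <- sprintf("FAM%04d", as.integer(fam_assign))
  families <- data.frame(gene_id = names(fam_assign), group_id = fam_ids,
                         type = ifelse(is_tandem[as.integer(fam_assign)],
                                       "tandem", "dispersed"),
                         stringsAsFactors = FALSE)
  families <- families[order(families$group_id, families$gene_id), ]
  rownames(families) <- NULL

  grp <- lapply(split(families$gene_id, families$group_id), function(m) {
    data.frame(species = params$species_tag, gene_id = sort(m),
               stringsAsFactors = FALSE)
  })
  groups <- group_set(grp, species_universe = params$species_tag)

  tandem_members <- families[families$type == "tandem", , drop = FALSE]
  arrays <- if (nrow(tandem_members)) {
    sp <- split(tandem_members$gene_id, tandem_members$group_id)
    scf <- vapply(sp, function(m) {
      genes$scaffold_id[match(m[1], genes$gene_id)]
    }, character(1))
    data.frame(group_id = names(sp), scaffold_id = scf,
               n_members = lengths(sp),
               members = vapply(sp, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group_id = character(0), scaffold_id = character(0),
               n_members = integer(0), members = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(arrays) <- NULL

  gaps <- do.call(rbind, gap_rows)
  if (is.null(gaps)) {
    gaps <- data.frame(scaffold_id = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(gaps) <- NULL

  sim <- structure(list(
    genome = genome, genes = genes, groups = groups,
    truth = list(families = families, arrays = arrays, gaps = gaps,
                 gene_ids = genes$gene_id,
                 tandem_gene_ids = sort(tandem_members$gene_id)),
    params = params), class = "sim_annotation")

  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulated annotation to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `orthogroups.txt` and the truth tables
#' under `truth/`.
#'
#' @param sim A `"sim_annotation"` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  write_orthogroups(sim$groups, file.path(outdir, "orthogroups.txt"))
  utils::write.table(sim$truth$families,
                     file.path(outdir, "truth", "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$arrays,
                     file.path(outdir, "truth", "arrays.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gaps,
                     file.path(outdir, "truth", "gaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate family-consistent protein sequences
#'
#' One random ancestral protein per family; members are derived by point
#' substitutions at per-site rate `1 - sqrt(identity/100)`, so two members
#' (each mutated independently from the ancestor) match at the target
#' pairwise identity in expectation. Substitutions go to a uniform choice of
#' the other 19 residues. Non-family genes get independent random proteins,
#' whose expected pairwise identity is the 1/20 background coincidence rate.
#'
#' @param sim A `"sim_annotation"` object.
#' @param params Generator parameters; defaults to `sim$params`.
#' @return Named character vector of protein sequences, one per gene.
#' @export
simulate_proteins <- function(sim, params = sim$params) {
  set.seed(params$seed + 1L)
  p_site <- 1 - sqrt(params$within_family_identity / 100)
  proteins <- stats::setNames(character(nrow(sim$genes)), sim$genes$gene_id)
  fam <- split(sim$truth$families$gene_id, sim$truth$families$group_id)
  for (members in fam) {
    len <- sample_range(params$protein_length)
    anc <- sample.int(20L, len, replace = TRUE)
    for (g in members) {
      mut <- which(stats::runif(len) < p_site)
      derived <- anc
      if (length(mut)) {
        derived[mut] <- ((anc[mut] - 1L +
                            sample.int(19L, length(mut), replace = TRUE)) %% 20L) + 1L
      }
      proteins[g] <- paste(AA_ALPHABET[derived], collapse = "")
    }
  }
  solo <- setdiff(sim$genes$gene_id, sim$truth$families$gene_id)
  for (g in solo) {
    len <- sample_range(params$protein_length)
    proteins[g] <- paste(sample(AA_ALPHABET, len, replace = TRUE),
                         collapse = "")
  }
  proteins
}

pct_identity_of <- function(s1, s2) {
  a <- utf8ToInt(s1); b <- utf8ToInt(s2)
  stopifnot(length(a) == length(b))
  100 * mean(a == b)
}

#' Simulate a pairwise similarity table consistent with planted families
#'
#' Emits reciprocal hits for every within-family protein pair, with the
#' realized percent identity, full-length alignments, a bit score
#' proportional to identity times length, and an E-value decreasing in the
#' bit score. Optional noise rows connect random cross-family pairs at a
#' deliberately sub-threshold E-value.
#'
#' @param sim A `"sim_annotation"` object.
#' @param proteins Proteins from [simulate_proteins()]; generated if `NULL`.
#' @param params Generator parameters; defaults to `sim$params`.
#' @return Similarity table data frame (see [read_similarity_table()]).
#' @export
simulate_similarity <- function(sim, proteins = NULL, params = sim$params) {
  if (is.null(proteins)) proteins <- simulate_proteins(sim, params)
  set.seed(params$seed + 2L)
  fam <- split(sim$truth$families$gene_id, sim$truth$families$group_id)
  rows <- list()
  for (members in fam) {
    if (length(members) < 2L) next
    pairs <- utils::combn(sort(members), 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      id <- pct_identity_of(proteins[[a]], proteins[[b]])
      aln <- nchar(proteins[[a]])
      bits <- round(2 * aln * id / 100, 1)
      ev <- 10^(-pmin(bits / 4, 180))
      mm <- as.integer(round(aln * (1 - id / 100)))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = c(a, b), subject_id = c(b, a),
        pct_identity = round(id, 2), aln_length = aln, mismatches = mm,
        gap_opens = 0L, qstart = 1L, qend = aln, sstart = 1L, send = aln,
        evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_similarity_table()
  if (params$noise_hits > 0L && length(fam) >= 2L) {
    gene_fam <- stats::setNames(sim$truth$families$group_id,
                                sim$truth$families$gene_id)
    all_ids <- sim$genes$gene_id
    noise <- list()
    while (length(noise) < params$noise_hits) {
      pair <- resample(all_ids, 2L)
      f1 <- gene_fam[pair[1]]; f2 <- gene_fam[pair[2]]
      if (!is.na(f1) && !is.na(f2) && f1 == f2) next
      aln <- 100L
      id <- round(stats::runif(1, 20, 30), 2)
      noise[[length(noise) + 1L]] <- data.frame(
        query_id = pair[1], subject_id = pair[2], pct_identity = id,
        aln_length = aln, mismatches = as.integer(round(aln * (1 - id / 100))),
        gap_opens = 2L, qstart = 1L, qend = aln, sstart = 1L, send = aln,
        evalue = params$noise_evalue,
        bitscore = round(stats::runif(1, 25, 35), 1),
        stringsAsFactors = FALSE)
    }
    hits <- rbind(hits, do.call(rbind, noise))
  }
  rownames(hits) <- NULL
  hits
}

#' Simulate a gene-to-GO-category map with a planted enrichment
#'
#' One designated category is assigned to tandem-array genes with probability
#' `p1` and to all other genes with probability `p0 = baseline_term_prob`,
#' where the odds ratio `(p1/(1-p1)) / (p0/(1-p0))` equals
#' `enriched_term_odds_ratio`. Background categories are assigned uniformly
#' at `background_term_prob` regardless of class. `p0 = 0` is a valid
#' degenerate input: the planted category is then simply absent outside the
#' focal set.
#'
#' @param sim A `"sim_annotation"` object, or any list with `truth$gene_ids`
#'   and `truth$tandem_gene_ids`.
#' @param params Generator parameters; defaults to `sim$params`.
#' @return Named list mapping gene id to categories (a GO map).
#' @export
simulate_go <- function(sim, params = sim$params) {
  set.seed(params$seed + 3L)
  gene_ids <- sim$truth$gene_ids
  focal <- sim$truth$tandem_gene_ids
  p0 <- params$baseline_term_prob
  or_ <- params$enriched_term_odds_ratio
  odds1 <- or_ * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  is_focal <- gene_ids %in% focal
  gene_vec <- character(0)
  term_vec <- character(0)
  has_term <- stats::runif(length(gene_ids)) <
    ifelse(is_focal, p1, p0)
  gene_vec <- gene_ids[has_term]
  term_vec <- rep(params$enriched_term, sum(has_term))
  for (term in params$go_terms) {
    hit <- stats::runif(length(gene_ids)) < params$background_term_prob
    gene_vec <- c(gene_vec, gene_ids[hit])
    term_vec <- c(term_vec, rep(term, sum(hit)))
  }
  lapply(split(term_vec, gene_vec), function(x) sort(unique(x)))
}

#' Augment planted families into a multi-species orthogroup set
#'
#' For every planted family, each companion species is present with
#' probability `presence_prob` and contributes one to three pseudo-ortholog
#' gene ids. Per-species gene inventories (group members plus a proportion
#' of extra ungrouped genes) are returned alongside, for singleton
#' accounting.
#'
#' @param sim A `"sim_annotation"` object.
#' @param other_species Companion species tags.
#' @param presence_prob Per-species presence probability in each group.
#' @param extra_singleton_frac Extra ungrouped genes per species, as a
#'   fraction of that species' grouped genes.
#' @param params Generator parameters; defaults to `sim$params`.
#' @return List with `groups` (multi-species [group_set()]) and
#'   `inventories` (named list species → gene ids).
#' @export
simulate_orthogroups <- function(sim,
                                 other_species = c("arath", "ambtr", "catro"),
                                 presence_prob = 0.8,
                                 extra_singleton_frac = 0.25,
                                 params = sim$params) {
  set.seed(params$seed + 4L)
  counters <- stats::setNames(integer(length(other_species)), other_species)
  grp <- lapply(sim$groups$groups, function(m) {
    for (sp in other_species) {
      if (stats::runif(1) < presence_prob) {
        k <- sample.int(3L, 1L)
        ids <- sprintf("%s_g%05d", sp, counters[[sp]] + seq_len(k))
        counters[[sp]] <<- counters[[sp]] + k
        m <- rbind(m, data.frame(species = sp, gene_id = ids,
                                 stringsAsFactors = FALSE))
      }
    }
    m
  })
  groups <- group_set(grp, species_universe = c(params$species_tag,
                                                other_species))
  inventories <- lapply(stats::setNames(nm = groups$species_universe),
                        function(sp) {
    if (sp == params$species_tag) return(sim$genes$gene_id)
    ingrp <- grouped_genes(groups, sp)
    n_extra <- ceiling(extra_singleton_frac * max(1L, length(ingrp)))
    c(ingrp, sprintf("%s_solo%05d", sp, seq_len(n_extra)))
  })
  list(groups = groups, inventories = inventories)
}

#' Precision and recall of detected tandem clusters against planted arrays
#'
#' A detected cluster is a true positive only when its member set equals a
#' planted array exactly; partial overlaps count against both precision and
#' recall.
#'
#' @param clusters Output of [detect_tandem_clusters()].
#' @param sim A `"sim_annotation"` object carrying `truth$arrays`.
#' @return List with `precision`, `recall`, `n_detected`, `n_planted`.
#' @export
tandem_recovery <- function(clusters, sim) {
  planted <- strsplit(sim$truth$arrays$members, ",", fixed = TRUE)
  key <- function(l) {
    vapply(l, function(m) paste(sort(m), collapse = ","), character(1))
  }
  pk <- key(planted)
  dk <- if (nrow(clusters)) key(clusters$member_ids) else character(0)
  tp <- length(intersect(pk, dk))
  list(precision = if (length(dk)) tp / length(dk) else NA_real_,
       recall = if (length(pk)) tp / length(pk) else NA_real_,
       n_detected = length(dk), n_planted = length(pk))
}
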