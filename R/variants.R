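#' Call variant events against a root reference
#'
#' Walks a multiple alignment and records, in the coordinate frame of the
#' designated root taxon, every substitution, insertion and deletion carried
#' by any non-root taxon. One substitution event is emitted per distinct
#' alternate allele per column (carriers = taxa showing that allele);
#' maximal runs of contiguous gap columns in a taxon become single
#' insertion/deletion events, left-normalised within homopolymer context so
#' coordinates are deterministic across aligners. A taxon showing an IUPAC
#' ambiguity code compatible with the root base is not counted as a
#' carrier; an incompatible code is, with the code recorded verbatim.
#'
#' @param aln A [multi_alignment()].
#' @param root_id Taxon used as the (artificial) root: all events are
#'   polarised relative to this sequence.
#' @return Tibble of events: `ref_start`, `ref_end` (1-based, root frame),
#'   `kind`, `ref_allele`, `alt_allele`, `carriers` (list column),
#'   `component_count`, `effect`, `aa_change`, `region`.
#' @export
call_events <- function(aln, root_id) {
  stopifnot(root_id %in% aln$taxa)
  M <- aln_matrix(aln)
  root <- M[root_id, ]
  if (all(root == "-")) stop("root row is all gaps")
  root_pos <- cumsum(root != "-")
  root_seq <- paste(root[root != "-"], collapse = "")
  others <- setdiff(aln$taxa, root_id)

  ev <- list()
  add <- function(start, end, kind, ref_al, alt_al, carrier) {
    ev[[length(ev) + 1L]] <<- list(ref_start = start, ref_end = end,
                                   kind = kind, ref_allele = ref_al,
                                   alt_allele = alt_al, carrier = carrier)
  }

  base_cols <- which(root != "-")
  for (tx in others) {
    row <- M[tx, ]
    # substitutions: root base vs taxon base
    cand <- base_cols[row[base_cols] != root[base_cols] &
                        row[base_cols] != "-"]
    for (cc in cand) {
      b <- row[cc]; rb <- root[cc]
      if (b %in% names(IUPAC_SETS) && !b %in% c("A", "C", "G", "T") &&
            iupac_compatible(b, rb)) next
      add(root_pos[cc], root_pos[cc], "substitution", rb, b, tx)
    }
    # deletions: runs of taxon-gap over root-base columns
    gap_at <- row[base_cols] == "-"
    if (any(gap_at)) {
      r <- rle(gap_at)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        p1 <- root_pos[base_cols[starts[i]]]
        p2 <- root_pos[base_cols[ends[i]]]
        al <- substring(root_seq, p1, p2)
        norm <- left_align_indel(root_seq, p1, p2, al, deletion = TRUE)
        add(norm$start, norm$end, "deletion", norm$allele, "", tx)
      }
    }
    # insertions: runs of root-gap columns where the taxon has bases
    ins_at <- root == "-" & row != "-"
    if (any(ins_at)) {
      r <- rle(ins_at)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        p <- root_pos[starts[i]]       # preceding root position (0 allowed)
        al <- paste(row[starts[i]:ends[i]], collapse = "")
        norm <- left_align_indel(root_seq, p, p, al, deletion = FALSE)
        add(norm$start, norm$end, "insertion", "", norm$allele, tx)
      }
    }
  }
  if (length(ev) == 0L) return(empty_events())
  df <- dplyr::bind_rows(lapply(ev, tibble::as_tibble))
  out <- df |>
    dplyr::group_by(.data$ref_start, .data$ref_end, .data$kind,
                    .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(carriers = list(sort(unique(.data$carrier))),
                     .groups = "drop") |>
    dplyr::arrange(.data$ref_start, .data$ref_end, .data$kind,
                   .data$alt_allele) |>
    dplyr::mutate(component_count = 1L, effect = NA_character_,
                  aa_change = NA_character_, region = NA_character_)
  out
}

empty_events <- function() {
  tibble::tibble(ref_start = integer(), ref_end = integer(),
                 kind = character(), ref_allele = character(),
                 alt_allele = character(), carriers = list(),
                 component_count = integer(), effect = character(),
                 aa_change = character(), region = character())
}

# VCF-style left normalisation of an indel within homopolymer/tandem context
left_align_indel <- function(root_seq, start, end, allele, deletion) {
  if (nchar(allele) == 0L) return(list(start = start, end = end, allele = allele))
  if (deletion) {
    while (start > 1L &&
             substring(root_seq, start - 1L, start - 1L) ==
             substring(root_seq, end, end)) {
      allele <- paste0(substring(root_seq, start - 1L, start - 1L),
                       substring(allele, 1L, nchar(allele) - 1L))
      start <- start - 1L; end <- end - 1L
    }
  } else {
    while (start > 0L &&
             substring(allele, nchar(allele), nchar(allele)) ==
             substring(root_seq, start, start)) {
      allele <- paste0(substring(root_seq, start, start),
                       substring(allele, 1L, nchar(allele) - 1L))
      start <- start - 1L; end <- start
    }
  }
  list(start = start, end = end, allele = allele)
}

#' Merge clustered differences into micro-reorganization events
#'
#' Runs of nearby differences with an identical carrier set usually
#' represent a single mutational event that an aligner has split into a
#' string of substitutions. Maximal groups of at least `min_components`
#' events sharing one carrier set, with inter-event reference gaps of at
#' most `max_gap` bp, are replaced by a single `micro_reorganization` event
#' spanning the group; everything else passes through unchanged. Already
#' merged events are never re-merged, so the operation is idempotent.
#'
#' @param events Event tibble from [call_events()].
#' @param max_gap Maximum gap (bp) between consecutive grouped events
#'   (default 2).
#' @param min_components Minimum events per merged group (default 3).
#' @return Event tibble with merged rows.
#' @export
merge_micro_events <- function(events, max_gap = 2L, min_components = 3L) {
  if (nrow(events) == 0L) return(events)
  events <- dplyr::arrange(events, .data$ref_start, .data$ref_end)
  sig <- vapply(events$carriers, function(cs) paste(sort(cs), collapse = "|"),
                character(1))
  mergeable <- events$kind != "micro_reorganization"
  group_id <- integer(nrow(events))
  next_group <- 0L
  last_end <- list(); last_grp <- list()
  for (i in seq_len(nrow(events))) {
    if (!mergeable[i]) { group_id[i] <- 0L; next }
    s <- sig[i]
    le <- last_end[[s]]
    if (!is.null(le) && events$ref_start[i] - le - 1L <= max_gap) {
      group_id[i] <- last_grp[[s]]
    } else {
      next_group <- next_group + 1L
      group_id[i] <- next_group
      last_grp[[s]] <- next_group
    }
    last_end[[s]] <- max(events$ref_end[i],
                         if (is.null(le)) -Inf else le)
  }
  keep <- events[group_id == 0L, , drop = FALSE]
  grouped <- split(seq_len(nrow(events))[group_id > 0L],
                   group_id[group_id > 0L])
  merged <- lapply(grouped, function(idx) {
    sub <- events[idx, , drop = FALSE]
    if (nrow(sub) < min_components) return(sub)
    tibble::tibble(
      ref_start = min(sub$ref_start), ref_end = max(sub$ref_end),
      kind = "micro_reorganization",
      ref_allele = paste(sub$ref_allele, collapse = ""),
      alt_allele = paste(sub$alt_allele, collapse = ""),
      carriers = list(sub$carriers[[1]]),
      component_count = sum(sub$component_count),
      effect = NA_character_, aa_change = NA_character_,
      region = NA_character_)
  })
  dplyr::arrange(dplyr::bind_rows(c(list(keep), merged)),
                 .data$ref_start, .data$ref_end)
}

#' Classify events by sharing pattern over a focal taxon set
#'
#' Each event is labelled with the subset of the focal taxa among its
#' carriers (e.g. `wisent`, `bison+yak`, `wisent+bison+yak`); events carried
#' by no focal taxon are binned as `"non-focal"`.
#'
#' @param events Event tibble.
#' @param focal_taxa Character vector of focal taxa (root excluded).
#' @return The event tibble with a `pattern` column.
#' @export
classify_sharing <- function(events, focal_taxa) {
  if (length(focal_taxa) == 0L) stop("focal taxon set is empty")
  pat <- vapply(events$carriers, function(cs) {
    s <- intersect(focal_taxa, cs)
    if (length(s) == 0L) "non-focal" else paste(sort(s), collapse = "+")
  }, character(1))
  dplyr::mutate(events, pattern = pat)
}

#' Tally events per sharing pattern
#' @param classified Output of [classify_sharing()].
#' @return Tibble with `pattern` and `n`, sorted by decreasing count.
#' @export
pattern_counts <- function(classified) {
  dplyr::count(classified, .data$pattern, sort = TRUE)
}

#' Map sharing patterns onto branches of a fixed rooted topology
#'
#' A pattern whose taxon set forms a clade is assigned to the branch above
#' the most recent common ancestor of exactly that set (a singleton pattern
#' goes to the taxon's terminal branch): the derived state is assumed to
#' have arisen once, on the subtending branch. Patterns whose taxon set is
#' not a clade on the topology (homoplasy or conflicting signal) are
#' reported separately as unresolved.
#'
#' @param classified Output of [classify_sharing()] (must have `pattern`).
#' @param tree Rooted `phylo` containing every focal taxon as a leaf.
#' @return List with `branches` (tibble: `branch`, `label`, `node`, `n`)
#'   and `unresolved` (tibble: `pattern`, `n`). Branch labels are
#'   `"unique"` for terminal branches and `"shared"` for internal ones.
#' @export
map_to_branches <- function(classified, tree) {
  pats <- pattern_counts(classified)
  pats <- pats[pats$pattern != "non-focal", , drop = FALSE]
  branches <- list(); unresolved <- list()
  for (i in seq_len(nrow(pats))) {
    set <- strsplit(pats$pattern[i], "+", fixed = TRUE)[[1]]
    missing <- setdiff(set, tree$tip.label)
    if (length(missing) > 0) {
      stop("pattern taxa not in tree: ", paste(missing, collapse = ", "))
    }
    if (length(set) == 1L) {
      node <- match(set, tree$tip.label)
      branches[[length(branches) + 1L]] <- tibble::tibble(
        branch = pats$pattern[i], label = "unique", node = node,
        n = pats$n[i])
      next
    }
    node <- ape::getMRCA(tree, set)
    clade_tips <- tree$tip.label[tips_under(tree, node)]
    root_node <- length(tree$tip.label) + 1L
    if (setequal(clade_tips, set) && node != root_node) {
      branches[[length(branches) + 1L]] <- tibble::tibble(
        branch = pats$pattern[i], label = "shared", node = node,
        n = pats$n[i])
    } else {
      unresolved[[length(unresolved) + 1L]] <- tibble::tibble(
        pattern = pats$pattern[i], n = pats$n[i])
    }
  }
  list(branches = dplyr::bind_rows(branches),
       unresolved = if (length(unresolved) > 0) dplyr::bind_rows(unresolved)
                    else tibble::tibble(pattern = character(), n = integer()))
}

# tip indices under a node of a phylo tree
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Detect difference islands in a two-genome comparison
#'
#' Maximal runs of at least `min_events` events whose consecutive
#' inter-event gaps are at most `max_island_gap` bp. Differences between
#' close mitogenomes tend to gather in such islands rather than spread
#' uniformly.
#'
#' @param events Event tibble (typically a two-taxon comparison), sorted or
#'   not.
#' @param max_island_gap Maximum gap between consecutive island members
#'   (default 60 bp).
#' @param min_events Minimum events per island (default 4).
#' @param genome Optional [annotated_genome()] used to report overlapping
#'   region names.
#' @return Tibble: `start`, `end`, `n_events`, `n_substitutions`,
#'   `n_indels`, `regions`.
#' @export
find_islands <- function(events, max_island_gap = 60L, min_events = 4L,
                         genome = NULL) {
  out <- tibble::tibble(start = integer(), end = integer(),
                        n_events = integer(), n_substitutions = integer(),
                        n_indels = integer(), regions = character())
  if (nrow(events) == 0L) return(out)
  events <- dplyr::arrange(events, .data$ref_start, .data$ref_end)
  gap_prev <- c(Inf, events$ref_start[-1] -
                  cummax(events$ref_end)[-nrow(events)] - 1L)
  cluster <- cumsum(gap_prev > max_island_gap)
  for (cl in split(seq_len(nrow(events)), cluster)) {
    if (length(cl) < min_events) next
    sub <- events[cl, ]
    regions <- ""
    if (!is.null(genome) && nrow(genome$regions) > 0) {
      ov <- genome$regions$start <= max(sub$ref_end) &
            genome$regions$end >= min(sub$ref_start)
      regions <- paste(genome$regions$name[ov], collapse = ",")
    }
    is_sub <- sub$kind %in% c("substitution", "micro_reorganization")
    out <- dplyr::bind_rows(out, tibble::tibble(
      start = min(sub$ref_start), end = max(sub$ref_end),
      n_events = nrow(sub),
      n_substitutions = sum(is_sub),
      n_indels = sum(!is_sub),
      regions = regions))
  }
  out
}

#' Annotate coding effects of events
#'
#' Substitutions inside protein-coding regions are translated under the
#' vertebrate mitochondrial genetic code (translation table 2) and labelled
#' synonymous or nonsynonymous with the residue change; indels whose length
#' is not a multiple of 3 inside coding regions are frameshifts, with the
#' novel residue stretch up to the next stop reported; in-frame coding
#' indels are nonsynonymous; events in rRNA/tRNA regions are `rna_gene`;
#' events outside all regions are `intergenic`; with an empty region map
#' everything is `not_annotated`. Minus-strand genes are
#' reverse-complemented before translation.
#'
#' @param events Event tibble (coordinates in the frame of `genome`).
#' @param genome [annotated_genome()] supplying the region map.
#' @return Event tibble with `effect`, `aa_change`, `region` filled.
#' @export
annotate_effect <- function(events, genome) {
  if (nrow(events) == 0L) return(events)
  if (any(events$ref_end > nchar(genome$sequence) | events$ref_start < 0L)) {
    stop("event outside genome bounds")
  }
  regs <- genome$regions
  if (nrow(regs) == 0L) {
    return(dplyr::mutate(events, effect = "not_annotated", region = NA_character_))
  }
  code <- Biostrings::getGeneticCode("2")
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    ov <- regs[regs$start <= e$ref_end & regs$end >= max(e$ref_start, 1L), ,
               drop = FALSE]
    if (nrow(ov) == 0L) {
      events$effect[i] <- "intergenic"; next
    }
    pref <- order(match(ov$kind, c("protein_coding", "rRNA", "tRNA",
                                   "d_loop", "other")))
    r <- ov[pref[1], ]
    events$region[i] <- r$name
    if (r$kind %in% c("rRNA", "tRNA")) { events$effect[i] <- "rna_gene"; next }
    if (r$kind %in% c("d_loop", "other")) { events$effect[i] <- "intergenic"; next }
    # protein-coding
    if (e$kind == "substitution" &&
          e$alt_allele %in% c("A", "C", "G", "T")) {
      ann <- substitution_effect(genome, r, e$ref_start, e$alt_allele, code)
      events$effect[i] <- ann$effect
      events$aa_change[i] <- ann$aa_change
    } else if (e$kind %in% c("insertion", "deletion")) {
      len <- if (e$kind == "insertion") nchar(e$alt_allele)
             else nchar(e$ref_allele)
      if (len %% 3L != 0L) {
        events$effect[i] <- "frameshift"
        events$aa_change[i] <- frameshift_stretch(genome, r, e, code)
      } else {
        events$effect[i] <- "nonsynonymous"
      }
    } else {
      events$effect[i] <- "not_annotated"
    }
  }
  events
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

substitution_effect <- function(genome, region, pos, alt, code) {
  gene <- substring(genome$sequence, region$start, region$end)
  gpos <- pos - region$start + 1L
  if (region$strand == "-") {
    gene <- revcomp(gene)
    gpos <- (region$end - region$start + 1L) - gpos + 1L
    alt <- revcomp(alt)
  }
  cds_pos <- gpos - region$frame
  if (cds_pos < 1L) return(list(effect = "not_annotated", aa_change = NA))
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  cstart <- region$frame + (codon_i - 1L) * 3L + 1L
  codon <- substring(gene, cstart, cstart + 2L)
  if (nchar(codon) < 3L) return(list(effect = "not_annotated", aa_change = NA))
  alt_codon <- codon
  substring(alt_codon, within, within) <- alt
  aa_ref <- unname(code[codon]); aa_alt <- unname(code[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) {
    return(list(effect = "not_annotated", aa_change = NA))
  }
  eff <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  list(effect = eff, aa_change = paste0(aa_ref, codon_i, aa_alt))
}

# novel residue stretch introduced by a frameshifting indel, translated up
# to the next stop (or gene end)
frameshift_stretch <- function(genome, region, e, code) {
  gene <- substring(genome$sequence, region$start, region$end)
  if (region$strand == "-") return(NA_character_)  # reported on + genes only
  gpos <- e$ref_start - region$start + 1L
  mutated <- if (e$kind == "insertion") {
    paste0(substring(gene, 1L, gpos), e$alt_allele,
           substring(gene, gpos + 1L, nchar(gene)))
  } else {
    paste0(substring(gene, 1L, gpos - 1L),
           substring(gene, gpos + nchar(e$ref_allele), nchar(gene)))
  }
  cds_pos <- max(gpos - region$frame, 1L)
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  cstart <- region$frame + (codon_i - 1L) * 3L + 1L
  tail_seq <- substring(mutated, cstart, nchar(mutated))
  n_codons <- nchar(tail_seq) %/% 3L
  if (n_codons == 0L) return(NA_character_)
  codons <- substring(tail_seq, 3L * seq_len(n_codons) - 2L,
                      3L * seq_len(n_codons))
  aas <- unname(code[codons])
  aas[is.na(aas)] <- "X"
  stop_i <- which(aas == "*")
  if (length(stop_i) > 0) aas <- aas[seq_len(stop_i[1] - 1L)]
  paste(aas, collapse = "")
}

#' Write / read the event table as TSV
#'
#' Carriers are serialised comma-separated. The table mirrors a
#' supplementary-style mutation catalogue.
#' @param events Event tibble.
#' @param path TSV path.
#' @export
write_event_tsv <- function(events, path) {
  df <- events
  df$carriers <- vapply(df$carriers, paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df$carriers <- strsplit(df$carriers, ",", fixed = TRUE)
  for (col in c("ref_allele", "alt_allele")) df[[col]][is.na(df[[col]])] <- ""
  tibble::as_tibble(df)
}
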