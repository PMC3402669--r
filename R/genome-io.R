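#' Annotated mitochondrial genome
#'
#' Bundles one mitogenome sequence with its region map (protein-coding genes,
#' rRNAs, tRNAs, the non-coding control region / D-loop) in 1-based inclusive
#' coordinates. Genomes are stored as linear strings in record orientation; a
#' control region spanning the origin of the circular molecule must be
#' annotated as two regions.
#'
#' @param id Accession or label.
#' @param sequence DNA string (uppercased; U is normalised to T). IUPAC
#'   ambiguity codes are retained.
#' @param regions Data frame with columns `name`, `start`, `end`, `kind`
#'   (one of `"protein_coding"`, `"rRNA"`, `"tRNA"`, `"d_loop"`, `"other"`),
#'   `strand` (`"+"`/`"-"`) and `frame` (reading-frame offset, 0-2).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, regions = empty_regions()) {
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (nchar(sequence) == 0L) stop("empty sequence for genome '", id, "'")
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence)) {
    stop("sequence for '", id, "' contains non-IUPAC characters")
  }
  regions <- tibble::as_tibble(regions)
  if (nrow(regions) > 0) {
    stopifnot(all(c("name", "start", "end", "kind", "strand", "frame") %in%
                    names(regions)))
    if (any(regions$start < 1 | regions$end > nchar(sequence) |
              regions$start > regions$end)) {
      stop("region coordinates out of bounds for genome '", id, "'")
    }
    bad <- !regions$kind %in% c("protein_coding", "rRNA", "tRNA", "d_loop", "other")
    if (any(bad)) stop("unknown region kind: ", regions$kind[bad][1])
    dl <- regions[regions$kind == "d_loop", ]
    pc <- regions[regions$kind == "protein_coding", ]
    if (nrow(dl) > 0 && nrow(pc) > 0) {
      for (i in seq_len(nrow(dl))) {
        if (any(pc$start <= dl$end[i] & pc$end >= dl$start[i])) {
          stop("d_loop region overlaps a protein_coding region in '", id, "'")
        }
      }
    }
  }
  structure(list(id = id, sequence = sequence, regions = regions),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$regions), " regions\n", sep = "")
  invisible(x)
}

empty_regions <- function() {
  tibble::tibble(name = character(), start = integer(), end = integer(),
                 kind = character(), strand = character(), frame = integer())
}

#' Read a mitogenome from GenBank flat file or FASTA
#'
#' GenBank records contribute both sequence and feature annotations (CDS,
#' rRNA, tRNA, D-loop); FASTA contributes sequence only, with an optional
#' sidecar region table (TSV: name/start/end/kind/strand) supplying the map.
#' Coordinates are taken verbatim from the record, 1-based inclusive.
#'
#' @param path File path.
#' @param fmt `"genbank"` or `"fasta"` (default guessed from the extension).
#' @param regions_path Optional region TSV for FASTA inputs.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, fmt = NULL, regions_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  fmt <- match.arg(fmt, c("genbank", "fasta"))
  if (fmt == "genbank") return(read_genbank(path))
  seqs <- Biostrings::readBStringSet(path)   # tolerate u/U before we normalise
  if (length(seqs) == 0L) stop("no sequence in FASTA file: ", path)
  id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  regions <- if (!is.null(regions_path)) read_region_tsv(regions_path)
             else empty_regions()
  annotated_genome(id, as.character(seqs[[1]]), regions)
}

# Minimal GenBank flat-file parser: LOCUS/FEATURES/ORIGIN. Handles simple
# 'start..end' and 'complement(start..end)' locations; joins and remote
# references are rejected (mitogenome records in this pipeline do not use
# them; origin-spanning control regions appear as two separate features).
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed GenBank record (no LOCUS): ", path)
  locus <- strsplit(sub("^LOCUS\\s+", "", lines[locus_i[1]]), "\\s+")[[1]][1]
  acc_i <- grep("^VERSION", lines)
  id <- if (length(acc_i) > 0)
    strsplit(sub("^VERSION\\s+", "", lines[acc_i[1]]), "\\s+")[[1]][1] else locus

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("malformed GenBank record (no ORIGIN): ", path)

  regions <- empty_regions()
  if (length(feat_i) > 0) {
    fl <- lines[(feat_i[1] + 1):(orig_i[1] - 1)]
    key_rows <- grep("^ {5}\\S", fl)
    for (j in seq_along(key_rows)) {
      row <- fl[key_rows[j]]
      key <- sub("^ {5}(\\S+).*", "\\1", row)
      loc <- sub("^ {5}\\S+\\s+", "", row)
      block_end <- if (j < length(key_rows)) key_rows[j + 1] - 1 else length(fl)
      block <- fl[key_rows[j]:block_end]
      kind <- switch(key,
                     CDS = "protein_coding", rRNA = "rRNA", tRNA = "tRNA",
                     D_loop = "d_loop", `D-loop` = "d_loop", NULL)
      if (key == "misc_feature" &&
          any(grepl("D-loop|control region", block, ignore.case = TRUE))) {
        kind <- "d_loop"
      }
      if (is.null(kind) && key != "gene") kind <- NULL
      if (is.null(kind)) next
      strand <- if (grepl("^complement", loc)) "-" else "+"
      loc2 <- gsub("complement\\(|\\)", "", loc)
      if (grepl("join|order|:", loc2)) {
        stop("unsupported compound location at feature '", key, "' (line: ",
             row, ")")
      }
      m <- regmatches(loc2, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc2))[[1]]
      if (length(m) == 0L) {
        m1 <- regmatches(loc2, regexec("^(\\d+)$", loc2))[[1]]
        if (length(m1) == 0L) stop("unparseable location '", loc, "'")
        m <- c(m1[1], m1[2], m1[2])
      }
      start <- as.integer(m[2]); end <- as.integer(m[3])
      name <- key
      gq <- grep("/(gene|product)=", block, value = TRUE)
      if (length(gq) > 0) name <- gsub('.*="?([^"]*)"?.*', "\\1", gq[1])
      cs <- grep("/codon_start=", block, value = TRUE)
      frame <- if (length(cs) > 0)
        as.integer(gsub("\\D", "", cs[1])) - 1L else 0L
      regions <- dplyr::bind_rows(regions, tibble::tibble(
        name = name, start = start, end = end, kind = kind,
        strand = strand, frame = frame))
    }
  }
  seq_lines <- lines[(orig_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("empty sequence in GenBank record: ", path)
  annotated_genome(id, sequence, regions)
}

#' Write a genome as a GenBank flat file
#'
#' Emits a minimal LOCUS/FEATURES/ORIGIN record that [read_genome()] parses
#' back; used for fixtures and simulator output.
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   01-JAN-2000",
                   genome$id, n),
           sprintf("DEFINITION  %s mitochondrion.", genome$id),
           sprintf("VERSION     %s", genome$id),
           "FEATURES             Location/Qualifiers")
  key_of <- c(protein_coding = "CDS", rRNA = "rRNA", tRNA = "tRNA",
              d_loop = "D_loop", other = "misc_feature")
  for (i in seq_len(nrow(genome$regions))) {
    r <- genome$regions[i, ]
    loc <- sprintf("%d..%d", r$start, r$end)
    if (r$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-16s%s", key_of[[r$kind]], loc),
             sprintf("                     /product=\"%s\"", r$name))
    if (r$kind == "protein_coding") {
      out <- c(out, sprintf("                     /codon_start=%d", r$frame + 1L))
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1, n, by = 60)
  for (p in pos) {
    starts <- seq(p, min(p + 59, n), by = 10)
    chunk <- substring(genome$sequence, starts, pmin(starts + 9L, n))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

#' Read / write a region sidecar table
#'
#' TSV with columns name, start, end, kind, strand and optionally frame;
#' lets pure-FASTA inputs participate in D-loop exclusion and effect
#' annotation.
#' @param path TSV path.
#' @return Region tibble.
#' @export
read_region_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"frame" %in% names(df)) df$frame <- 0L
  tibble::as_tibble(df[, c("name", "start", "end", "kind", "strand", "frame")])
}

#' @rdname read_region_tsv
#' @param regions Region tibble.
#' @export
write_region_tsv <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA (70-character lines)
#' @param seqs Named character vector of sequences (gapped allowed).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Multiple alignment keyed to a reference coordinate frame
#'
#' Equal-length gapped rows plus a column map giving, for every column, the
#' 1-based reference position it aligns to (NA for columns where the
#' reference has a gap, i.e. insertions relative to the reference).
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @param ref_id Taxon whose coordinates define the frame.
#' @param colmap Optional integer vector (recomputed from the reference row
#'   when omitted).
#' @return Object of class `multi_alignment`.
#' @export
multi_alignment <- function(rows, ref_id, colmap = NULL) {
  stopifnot(length(rows) >= 1, !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in length")
  if (!ref_id %in% names(rows)) stop("ref_id '", ref_id, "' not in alignment")
  if (anyDuplicated(names(rows))) stop("duplicate taxon ids in alignment")
  if (is.null(colmap)) {
    refc <- strsplit(rows[[ref_id]], "")[[1]]
    colmap <- rep(NA_integer_, length(refc))
    colmap[refc != "-"] <- seq_len(sum(refc != "-"))
  }
  structure(list(taxa = names(rows), rows = rows, ref_id = ref_id,
                 colmap = as.integer(colmap)),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat("<multi_alignment> ", length(x$taxa), " taxa x ", nchar(x$rows[[1]]),
      " columns (reference: ", x$ref_id, ")\n", sep = "")
  invisible(x)
}

#' Alignment as a character matrix (taxa x columns)
#' @param aln A [multi_alignment()].
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unlist(aln$rows), ""))
  rownames(m) <- aln$taxa
  m
}

#' Number of columns in an alignment
#' @param aln A [multi_alignment()].
#' @export
aln_ncol <- function(aln) nchar(aln$rows[[1]])

#' Drop gaps from one alignment row
#' @param aln A [multi_alignment()].
#' @param taxon Row to degap.
#' @export
degap <- function(aln, taxon) gsub("-", "", aln$rows[[taxon]], fixed = TRUE)

#' Read / write aligned FASTA
#' @param path Aligned FASTA path.
#' @param ref_id Reference taxon (default: first record).
#' @return A [multi_alignment()].
#' @export
read_alignment <- function(path, ref_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  rows <- setNames(toupper(as.character(seqs)),
                   vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1))
  if (is.null(ref_id)) ref_id <- names(rows)[1]
  multi_alignment(rows, ref_id)
}

#' @rdname read_alignment
#' @param aln A [multi_alignment()].
#' @export
write_alignment <- function(aln, path) write_fasta(aln$rows, path)

#' Restrict an alignment to coding columns (exclude the D-loop)
#'
#' Drops every column whose reference coordinate falls inside any `d_loop`
#' region of the reference genome's region map, together with insertion
#' columns (reference-gap columns) keyed to excluded positions. The
#' hypervariable control region otherwise distorts distance and likelihood
#' estimates. The reference taxon's coordinate frame decides inclusion for
#' all taxa; this convention is recorded in the returned object's
#' `exclusion` attribute.
#'
#' @param aln A [multi_alignment()].
#' @param genomes Named list of [annotated_genome()] covering all taxa.
#' @return A [multi_alignment()] with the D-loop columns removed.
#' @export
extract_coding_alignment <- function(aln, genomes) {
  missing <- setdiff(aln$taxa, names(genomes))
  if (length(missing) > 0) {
    stop("no genome annotation for taxa: ", paste(missing, collapse = ", "))
  }
  ref <- genomes[[aln$ref_id]]
  dl <- ref$regions[ref$regions$kind == "d_loop", , drop = FALSE]
  if (nrow(dl) == 0L) return(aln)
  excluded_pos <- unique(unlist(Map(seq.int, dl$start, dl$end)))
  cm <- aln$colmap
  # insertion columns inherit the status of the last preceding reference base
  anchor <- cumfill(cm)
  keep <- is.na(anchor) | !(anchor %in% excluded_pos)
  rows <- vapply(aln$rows, function(s) {
    paste(strsplit(s, "")[[1]][keep], collapse = "")
  }, character(1))
  out <- multi_alignment(rows, aln$ref_id, colmap = cm[keep])
  attr(out, "exclusion") <- list(frame_taxon = aln$ref_id,
                                 excluded_columns = sum(!keep))
  out
}

# carry last non-NA value forward (insertion columns anchor to the
# preceding reference position)
cumfill <- function(x) {
  notna <- !is.na(x)
  idx <- cumsum(notna)
  out <- c(NA_integer_, x[notna])[idx + 1L]
  out
}
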