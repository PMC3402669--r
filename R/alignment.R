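#' Chain unique k-mer anchors between two near-identical sequences
#'
#' Finds k-mers occurring exactly once in each sequence, matches them, and
#' extracts the maximal collinear chain (longest-increasing-subsequence
#' dynamic programming on query positions of matches sorted by reference
#' position). Adjacent same-diagonal matches are merged into maximal exact
#' blocks; matches that would overlap a previous block in either sequence
#' are dropped so blocks stay strictly increasing and non-overlapping.
#'
#' @param ref,query DNA strings.
#' @param k Seed length (>= 8; default 12).
#' @return Tibble with columns `ref_start`, `query_start`, `length`
#'   (1-based); zero rows when the sequences share no unique k-mer.
#' @export
chain_anchors <- function(ref, query, k = 12L) {
  stopifnot(nchar(ref) > 0, nchar(query) > 0, k >= 8L)
  empty <- tibble::tibble(ref_start = integer(), query_start = integer(),
                          length = integer())
  if (nchar(ref) < k || nchar(query) < k) return(empty)
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  rk <- kmers(ref); qk <- kmers(query)
  r_uni <- which(!(duplicated(rk) | duplicated(rk, fromLast = TRUE)))
  q_uni <- which(!(duplicated(qk) | duplicated(qk, fromLast = TRUE)))
  qpos <- setNames(q_uni, qk[q_uni])
  hit <- r_uni[rk[r_uni] %in% names(qpos)]
  if (length(hit) == 0L) return(empty)
  rp <- hit
  qp <- unname(qpos[rk[hit]])
  # longest increasing subsequence of qp (rp already increasing)
  o <- order(rp)
  rp <- rp[o]; qp <- qp[o]
  n <- length(qp)
  tails <- integer(0)        # index into qp of smallest tail of LIS length l
  parent <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {          # first l with qp[tails[l]] >= qp[i]
      mid <- (lo + hi) %/% 2L
      if (qp[tails[mid]] < qp[i]) lo <- mid + 1L else hi <- mid
    }
    parent[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  chain <- integer(0)
  at <- tails[length(tails)]
  while (at != 0L) { chain <- c(at, chain); at <- parent[at] }
  rp <- rp[chain]; qp <- qp[chain]
  # merge into blocks; drop matches overlapping the previous block
  blocks <- list()
  cur <- c(rp[1], qp[1], k)
  for (i in seq_along(rp)[-1]) {
    if (qp[i] - rp[i] == cur[2] - cur[1] && rp[i] <= cur[1] + cur[3]) {
      cur[3] <- rp[i] + k - cur[1]
    } else if (rp[i] >= cur[1] + cur[3] && qp[i] >= cur[2] + cur[3]) {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- c(rp[i], qp[i], k)
    } # else: overlapping off-diagonal match, dropped
  }
  blocks[[length(blocks) + 1L]] <- cur
  b <- do.call(rbind, blocks)
  tibble::tibble(ref_start = as.integer(b[, 1]),
                 query_start = as.integer(b[, 2]),
                 length = as.integer(b[, 3]))
}

#' Banded global alignment guided by an anchor chain
#'
#' Global affine-gap alignment computed inside a diagonal band that follows
#' the anchor chain (piecewise-linear interpolation between anchors). The
#' result equals unconstrained affine-gap global alignment whenever the
#' optimal path stays within the band. When the offset between consecutive
#' anchors exceeds the band the band is widened automatically (with a
#' warning), up to the full matrix. A gap of length L scores
#' `gap_open + L * gap_extend`.
#'
#' @param ref,query DNA strings.
#' @param chain Anchor chain from [chain_anchors()]; an empty chain falls
#'   back to the full matrix.
#' @param band Band half-width in columns (default 50).
#' @param match,mismatch,gap_open,gap_extend Alignment scores
#'   (defaults +1/-2/-5/-1).
#' @param ref_id,query_id Row labels of the returned alignment.
#' @return A two-row [multi_alignment()] with a `score` attribute.
#' @export
banded_pairwise_align <- function(ref, query, chain = chain_anchors(ref, query),
                                  band = 50L, match = 1, mismatch = -2,
                                  gap_open = -5, gap_extend = -1,
                                  ref_id = "ref", query_id = "query") {
  n <- nchar(ref); m <- nchar(query)
  full <- function() list(lo = rep(0L, n + 1L), hi = rep(m, n + 1L))
  if (nrow(chain) == 0L) {
    bd <- full()
  } else {
    # piecewise-linear band center through (0,0), anchor ends, (n,m)
    xs <- c(0L, chain$ref_start - 1L, chain$ref_start + chain$length - 1L, n)
    ys <- c(0L, chain$query_start - 1L, chain$query_start + chain$length - 1L, m)
    o <- order(xs); xs <- xs[o]; ys <- ys[o]
    keep <- !duplicated(xs)
    xs <- xs[keep]; ys <- ys[keep]
    jump <- max(abs(diff(ys - xs)), abs(ys[1] - xs[1]), 0)
    eff_band <- band
    if (jump > band) {
      eff_band <- min(max(jump + 10L, band), m)
      warning("inter-anchor offset ", jump, " exceeds band ", band,
              "; widening band to ", eff_band)
    }
    center <- round(approx(xs, ys, xout = 0:n, rule = 2)$y)
    lo <- pmax(0L, as.integer(center - eff_band))
    hi <- pmin(m, as.integer(center + eff_band))
    lo[1] <- 0L; hi[n + 1L] <- m
    # monotone envelopes so consecutive rows always connect
    lo <- cummax(lo)
    hi <- rev(cummin(rev(hi)))
    if (any(lo > hi)) bd <- full() else bd <- list(lo = lo, hi = hi)
  }
  res <- .banded_align_cpp(ref, query, bd$lo, bd$hi,
                           match, mismatch, gap_open, gap_extend)
  rows <- setNames(c(res$ref_aln, res$query_aln), c(ref_id, query_id))
  out <- multi_alignment(rows, ref_id)
  attr(out, "score") <- res$score
  out
}

#' Project pairwise alignments into a reference-framed MSA
#'
#' Builds a multiple alignment with one column per reference base plus the
#' union of insertion columns keyed by (reference position, insertion
#' offset). Insertions at the same reference position in different taxa are
#' left-aligned and stacked, not re-aligned to each other. Column keys are
#' canonical, so the result is independent of the order in which the
#' pairwise alignments are supplied.
#'
#' @param ref_id Reference taxon id (must be the reference row of every
#'   pairwise alignment).
#' @param pairwise List of two-row [multi_alignment()] objects sharing
#'   `ref_id`.
#' @return A [multi_alignment()] over the reference and all query taxa.
#' @export
project_msa <- function(ref_id, pairwise) {
  stopifnot(length(pairwise) >= 1)
  per_taxon <- list()
  ref_seq <- NULL
  for (pw in pairwise) {
    if (pw$ref_id != ref_id) stop("pairwise alignment not framed on ", ref_id)
    qid <- setdiff(pw$taxa, ref_id)
    if (length(qid) != 1L) stop("pairwise alignment must have exactly 2 rows")
    if (qid %in% names(per_taxon)) stop("duplicate taxon id: ", qid)
    rs <- degap(pw, ref_id)
    if (is.null(ref_seq)) ref_seq <- rs
    else if (!identical(ref_seq, rs)) stop("reference rows disagree")
    rc <- strsplit(pw$rows[[ref_id]], "")[[1]]
    qc <- strsplit(pw$rows[[qid]], "")[[1]]
    pos <- cumsum(rc != "-")            # ref position per column (0 before 1st)
    at_base <- rc != "-"
    base_char <- rep("-", nchar(ref_seq))
    base_char[pos[at_base]] <- qc[at_base]
    ins <- split(qc[!at_base], pos[!at_base])  # keyed by preceding ref pos
    per_taxon[[qid]] <- list(base = base_char, ins = ins)
  }
  L <- nchar(ref_seq)
  ins_len <- integer(L + 1L)                   # index p+1 = after ref pos p
  for (pt in per_taxon) {
    for (key in names(pt$ins)) {
      p <- as.integer(key)
      ins_len[p + 1L] <- max(ins_len[p + 1L], length(pt$ins[[key]]))
    }
  }
  ref_chars <- strsplit(ref_seq, "")[[1]]
  build_row <- function(base, ins) {
    out <- vector("list", 2L * (L + 1L))
    for (p in 0:L) {
      if (p > 0) out[[2L * p]] <- base[p]
      if (ins_len[p + 1L] > 0L) {
        seg <- rep("-", ins_len[p + 1L])
        v <- ins[[as.character(p)]]
        if (!is.null(v)) seg[seq_along(v)] <- v
        out[[2L * p + 1L]] <- seg
      }
    }
    paste(unlist(out), collapse = "")
  }
  rows <- c(setNames(build_row(ref_chars, list()), ref_id),
            vapply(per_taxon, function(pt) build_row(pt$base, pt$ins),
                   character(1)))
  multi_alignment(rows, ref_id)
}

#' Align several genomes against a reference
#'
#' Convenience wrapper: anchors, banded-aligns each query against the
#' reference, and projects the pairwise alignments into one MSA.
#' @param genomes Named list of [annotated_genome()] (or named character
#'   vector of sequences).
#' @param ref_id Reference taxon.
#' @inheritParams banded_pairwise_align
#' @return A [multi_alignment()].
#' @export
align_genomes <- function(genomes, ref_id, k = 12L, band = 50L) {
  seqs <- if (is.character(genomes)) as.list(genomes)
          else lapply(genomes, function(g) g$sequence)
  stopifnot(ref_id %in% names(seqs))
  qids <- setdiff(names(seqs), ref_id)
  pw <- lapply(qids, function(q) {
    banded_pairwise_align(seqs[[ref_id]], seqs[[q]],
                          chain = chain_anchors(seqs[[ref_id]], seqs[[q]], k),
                          band = band, ref_id = ref_id, query_id = q)
  })
  project_msa(ref_id, pw)
}
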