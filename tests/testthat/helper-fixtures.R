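# shared fixture builders; everything is generated in code

random_dna <- function(n, seed = NULL,
                       pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(pi), n, replace = TRUE, prob = pi), collapse = "")
}

# plant point substitutions; returns the mutated string
mutate_at <- function(seq, pos, bases) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- bases[i]
  seq
}

toy_alignment <- function(rows, ref_id = names(rows)[1]) {
  multi_alignment(rows, ref_id)
}

# rooted ultrametric quartet used across likelihood tests
quartet_tree <- function() {
  ape::read.tree(text = "((A:0.04,B:0.04):0.03,(C:0.04,D:0.04):0.03);")
}

# alignment score oracle: full-matrix affine-gap global alignment
biostrings_score <- function(ref, query, match = 1, mismatch = -2,
                             gap_open = -5, gap_extend = -1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = query, subject = ref, type = "global",
    substitutionMatrix = sm, gapOpening = -gap_open,
    gapExtension = -gap_extend))
}

# a mutated copy of `ref` with planted substitutions and one indel pair
mutated_copy <- function(ref, sub_rate = 0.02, indel = TRUE) {
  q <- strsplit(ref, "")[[1]]
  L <- length(q)
  nsub <- rpois(1, L * sub_rate)
  pos <- sample(L, min(nsub, L))
  for (p in pos) q[p] <- sample(setdiff(c("A", "C", "G", "T"), q[p]), 1)
  if (indel) {
    ins_at <- sample(L - 10, 1)
    q <- append(q, sample(c("A", "C", "G", "T"), 4, TRUE), after = ins_at)
    del_at <- sample(length(q) - 10, 1)
    q <- q[-(del_at:(del_at + 2))]
  }
  paste(q, collapse = "")
}
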