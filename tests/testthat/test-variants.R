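test_that("event calling on toy alignments matches hand-derived results", {
  # identical sequences: no events
  aln <- toy_alignment(c(root = "ACGT", a = "ACGT", b = "ACGT"))
  expect_equal(nrow(call_events(aln, "root")), 0L)
  # one substitution
  aln <- toy_alignment(c(root = "ACGT", a = "ACAT", b = "ACGT"))
  ev <- call_events(aln, "root")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_start, 3L)
  expect_equal(ev$ref_allele, "G")
  expect_equal(ev$alt_allele, "A")
  expect_equal(ev$carriers[[1]], "a")
  # multi-allelic column: one event per alternate allele
  aln <- toy_alignment(c(root = "ACGT", a = "ACAT", b = "ACTT", c = "ACAT"))
  ev <- call_events(aln, "root")
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$alt_allele, c("A", "T"))
  expect_equal(ev$carriers[[match("A", ev$alt_allele)]], c("a", "c"))
  # root all gaps errors
  expect_error(call_events(toy_alignment(c(root = "--", a = "AC"), "a"),
                           "root"), "all gaps")
})

test_that("indel runs become single left-normalised events", {
  # deletion of TT within a TTT homopolymer left-aligns to the first T
  aln <- toy_alignment(c(root = "GATTTACA", a = "GAT--ACA"))
  ev <- call_events(aln, "root")
  expect_equal(ev$kind, "deletion")
  expect_equal(c(ev$ref_start, ev$ref_end), c(3L, 4L))
  expect_equal(ev$ref_allele, "TT")
  # insertion keyed to the preceding root position
  aln <- toy_alignment(c(root = "GACA--TT", a = "GACAGGTT"))
  ev <- call_events(aln, "root")
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$ref_start, 4L)
  expect_equal(ev$alt_allele, "GG")
})

test_that("ambiguity codes compatible with the root are not carriers", {
  aln <- toy_alignment(c(root = "ACGT", a = "ACRT", b = "ACYT"))
  ev <- call_events(aln, "root")
  # R = A/G is compatible with root G; Y = C/T is not
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$alt_allele, "Y")
  expect_equal(ev$carriers[[1]], "b")
})

test_that("micro-event merging reproduces the contiguous worked example", {
  root <- random_dna(2000, seed = 31)
  alt <- root
  for (p in 1472:1479) {
    substr(alt, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substring(root, p, p))[1]
  }
  aln <- toy_alignment(c(BRS = root, wisent = alt))
  ev <- call_events(aln, "BRS")
  expect_equal(nrow(ev), 8L)
  merged <- merge_micro_events(ev, max_gap = 2, min_components = 3)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kind, "micro_reorganization")
  expect_equal(merged$ref_start, 1472L)
  expect_equal(merged$ref_end, 1479L)
  expect_equal(merged$component_count, 8L)
  expect_equal(merged$carriers[[1]], "wisent")
})

empty_events_for_test <- function() {
  call_events(toy_alignment(c(r = "ACGT", q = "ACGT")), "r")
}

test_that("merging respects carrier-set identity and distance", {
  mk <- function(pos, carriers) tibble::tibble(
    ref_start = pos, ref_end = pos, kind = "substitution",
    ref_allele = "A", alt_allele = "G", carriers = list(carriers),
    component_count = 1L, effect = NA_character_,
    aa_change = NA_character_, region = NA_character_)
  ev <- dplyr::bind_rows(mk(10L, "A"), mk(12L, "A"), mk(14L, "A"),
                         mk(15L, c("A", "B")))
  out <- merge_micro_events(ev, max_gap = 2, min_components = 3)
  expect_equal(nrow(out), 2L)
  m <- out[out$kind == "micro_reorganization", ]
  expect_equal(m$component_count, 3L)
  expect_equal(m$carriers[[1]], "A")
  # events farther apart than max_gap pass through unchanged
  far <- dplyr::bind_rows(mk(10L, "A"), mk(50L, "A"), mk(90L, "A"))
  expect_equal(merge_micro_events(far, 2, 3), dplyr::arrange(far, ref_start))
  expect_equal(merge_micro_events(empty_events_for_test()),
               empty_events_for_test())
})

test_that("merging preserves the outer reference span and is idempotent", {
  set.seed(32)
  for (i in 1:20) {
    root <- random_dna(500)
    alt <- root
    starts <- sort(sample(seq(10, 450, by = 40), 4))
    for (s in starts) {
      for (p in s:(s + sample(2:6, 1))) {
        substr(alt, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substring(root, p, p))[1]
      }
    }
    ev <- call_events(toy_alignment(c(r = root, q = alt)), "r")
    m1 <- merge_micro_events(ev)
    expect_equal(range(c(m1$ref_start, m1$ref_end)),
                 range(c(ev$ref_start, ev$ref_end)))
    expect_equal(sum(m1$component_count), sum(ev$component_count))
    expect_equal(merge_micro_events(m1), m1)
  }
})

test_that("sharing patterns partition events and map onto tree branches", {
  tree <- ape::read.tree(text = "(BRS,(wisent,(bison,yak)));")
  mk <- function(pos, carriers) tibble::tibble(
    ref_start = pos, ref_end = pos, kind = "substitution",
    ref_allele = "A", alt_allele = "G", carriers = list(carriers),
    component_count = 1L, effect = NA_character_,
    aa_change = NA_character_, region = NA_character_)
  ev <- dplyr::bind_rows(
    mk(1L, "wisent"), mk(2L, "wisent"), mk(3L, c("bison", "yak")),
    mk(4L, c("wisent", "bison", "yak")), mk(5L, c("wisent", "yak")),
    mk(6L, "outgroupX"))
  cls <- classify_sharing(ev, c("wisent", "bison", "yak"))
  expect_equal(sum(pattern_counts(cls)$n), nrow(ev))
  expect_equal(cls$pattern[6], "non-focal")
  bm <- map_to_branches(cls, tree)
  expect_equal(sum(bm$branches$n) + sum(bm$unresolved$n), nrow(ev) - 1L)
  expect_equal(bm$branches$n[bm$branches$branch == "wisent"], 2L)
  expect_equal(bm$branches$label[bm$branches$branch == "bison+yak"], "shared")
  expect_equal(bm$unresolved$pattern, "wisent+yak")
  expect_error(classify_sharing(ev, character(0)), "empty")
  # a focal taxon that carries events but is absent from the tree
  expect_error(map_to_branches(classify_sharing(ev, "outgroupX"), tree),
               "not in tree")
})

test_that("difference islands are detected with their composition", {
  mk <- function(pos, kind = "substitution") tibble::tibble(
    ref_start = pos, ref_end = pos, kind = kind, ref_allele = "A",
    alt_allele = if (kind == "substitution") "G" else "",
    carriers = list("q"), component_count = 1L, effect = NA_character_,
    aa_change = NA_character_, region = NA_character_)
  # 20 events packed in a 223-bp window -> one island
  ev <- dplyr::bind_rows(lapply(seq(1471, 1693, length.out = 20),
                                function(p) mk(as.integer(p))))
  ev$kind[1:4] <- "deletion"
  isl <- find_islands(ev, max_island_gap = 60, min_events = 4)
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(1471L, 1693L))
  expect_equal(isl$n_events, 20L)
  expect_equal(isl$n_indels, 4L)
  expect_equal(isl$n_substitutions, 16L)
  # sparse events: no islands
  sparse <- dplyr::bind_rows(lapply(seq(100L, 2000L, by = 150L), mk))
  expect_equal(nrow(find_islands(sparse, 60, 4)), 0L)
  # two planted clusters -> two islands
  two <- dplyr::bind_rows(lapply(c(100:105, 900:905), mk))
  isl2 <- find_islands(two, 60, 4)
  expect_equal(nrow(isl2), 2L)
  expect_equal(isl2$start, c(100L, 900L))
})

test_that("coding effects follow the vertebrate mitochondrial code", {
  # gene 4..15: codons CTA CGA GGA TAA under code 2: L R G *
  seq <- paste0("AAA", "CTACGAGGATAA", "TTTTT")
  regions <- tibble::tibble(name = "cds", start = 4L, end = 15L,
                            kind = "protein_coding", strand = "+",
                            frame = 0L)
  g <- annotated_genome("g", seq, regions)
  mk <- function(start, end, kind, ref_al, alt_al) tibble::tibble(
    ref_start = start, ref_end = end, kind = kind, ref_allele = ref_al,
    alt_allele = alt_al, carriers = list("q"), component_count = 1L,
    effect = NA_character_, aa_change = NA_character_,
    region = NA_character_)
  # third position of CGA (R, 4-fold degenerate): synonymous
  ev <- annotate_effect(mk(9L, 9L, "substitution", "A", "G"), g)
  expect_equal(ev$effect, "synonymous")
  expect_equal(ev$aa_change, "R2R")
  # first position of GGA -> AGA: G3X nonsynonymous (AGA is a stop in code 2)
  ev <- annotate_effect(mk(10L, 10L, "substitution", "G", "A"), g)
  expect_equal(ev$effect, "nonsynonymous")
  expect_equal(ev$aa_change, "G3*")
  # 1-bp insertion inside the gene: frameshift with a residue stretch
  ev <- annotate_effect(mk(7L, 7L, "insertion", "", "T"), g)
  expect_equal(ev$effect, "frameshift")
  expect_true(nchar(ev$aa_change) >= 1)
  # 3-bp in-frame deletion: nonsynonymous
  ev <- annotate_effect(mk(4L, 6L, "deletion", "CTA", ""), g)
  expect_equal(ev$effect, "nonsynonymous")
  # outside every region: intergenic
  ev <- annotate_effect(mk(1L, 1L, "substitution", "A", "G"), g)
  expect_equal(ev$effect, "intergenic")
  # no region map at all: not_annotated
  g0 <- annotated_genome("g0", seq)
  ev <- annotate_effect(mk(9L, 9L, "substitution", "A", "G"), g0)
  expect_equal(ev$effect, "not_annotated")
  # out of bounds errors
  expect_error(annotate_effect(mk(100L, 100L, "substitution", "A", "G"), g),
               "bounds")
})

test_that("rRNA hits and minus-strand genes annotate correctly", {
  seq <- paste0("AAAA", "TTAGCGTTAG", "CCCC", "ACGTACGTACGT")
  regions <- tibble::tibble(
    name = c("rrn", "mcds"), start = c(5L, 19L), end = c(14L, 30L),
    kind = c("rRNA", "protein_coding"), strand = c("+", "-"),
    frame = c(0L, 0L))
  g <- annotated_genome("g", seq, regions)
  mk <- function(start, alt) tibble::tibble(
    ref_start = start, ref_end = start, kind = "substitution",
    ref_allele = substring(seq, start, start), alt_allele = alt,
    carriers = list("q"), component_count = 1L, effect = NA_character_,
    aa_change = NA_character_, region = NA_character_)
  expect_equal(annotate_effect(mk(6L, "C"), g)$effect, "rna_gene")
  # minus strand gene 19..30 = ACGTACGTACGT; revcomp = ACGTACGTACGT
  # last base (pos 30, T) is position 1 of the revcomp gene (A-complement)
  ev <- annotate_effect(mk(30L, "A"), g)
  expect_true(ev$effect %in% c("synonymous", "nonsynonymous"))
  expect_equal(ev$region, "mcds")
})

test_that("ten third-position substitutions in one window are all synonymous", {
  # build a 108-bp gene of 4-fold degenerate codons (GGx: Gly) and mutate
  # third positions only
  gene <- paste(rep("GGA", 36), collapse = "")
  seq <- paste0("AA", gene, "TT")
  regions <- tibble::tibble(name = "nad3", start = 3L,
                            end = 3L + 108L - 1L,
                            kind = "protein_coding", strand = "+",
                            frame = 0L)
  g <- annotated_genome("g", seq, regions)
  third_pos <- 3L + seq(2L, 107L, by = 3L)[1:10] * 1L
  ev <- dplyr::bind_rows(lapply(third_pos, function(p) tibble::tibble(
    ref_start = p, ref_end = p, kind = "substitution",
    ref_allele = substring(seq, p, p), alt_allele = "C",
    carriers = list("q"), component_count = 1L, effect = NA_character_,
    aa_change = NA_character_, region = NA_character_)))
  out <- annotate_effect(ev, g)
  expect_true(all(out$effect == "synonymous"))
})

test_that("event tables round-trip through TSV", {
  aln <- toy_alignment(c(root = "ACGTACGTA", a = "ACATACG-A",
                         b = "ACATACGTA"))
  ev <- call_events(aln, "root")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_tsv(ev, f)
  back <- read_event_tsv(f)
  expect_equal(back$ref_start, ev$ref_start)
  expect_equal(back$carriers, ev$carriers)
  expect_equal(back$alt_allele, ev$alt_allele)
})

test_that("simulated catalogues are recovered exactly from the true alignment", {
  for (seed in c(101, 202)) {
    cfg <- study_emulator(seed = seed)
    sim <- simulate_evolution(cfg)
    called <- call_events(sim$alignment, "BRS")
    expect_equal(
      called[, c("ref_start", "ref_end", "kind", "ref_allele", "alt_allele",
                 "carriers")],
      sim$truth$realized[, c("ref_start", "ref_end", "kind", "ref_allele",
                             "alt_allele", "carriers")])
  }
})
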