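#' Pairwise p-distance
#'
#' Proportion of differing sites over compared sites. Compared columns
#' exclude any column where either taxon (pairwise deletion, default) or
#' any taxon (complete deletion) shows a gap or IUPAC ambiguity code.
#' Indels are therefore never counted here; they are catalogued separately
#' by [call_events()].
#'
#' @param aln A [multi_alignment()].
#' @param taxon_a,taxon_b Taxa to compare.
#' @param complete_deletion If `TRUE`, columns with a gap/ambiguity in any
#'   row are excluded for every pair (keeps the distance matrix computed on
#'   one common site set).
#' @return Tibble: `taxon_a`, `taxon_b`, `p_distance`, `sites_compared`.
#' @export
p_distance <- function(aln, taxon_a, taxon_b, complete_deletion = FALSE) {
  cmp <- compared_columns(aln, taxon_a, taxon_b, complete_deletion)
  if (length(cmp$a) == 0L) stop("no comparable columns between ",
                                taxon_a, " and ", taxon_b)
  tibble::tibble(taxon_a = taxon_a, taxon_b = taxon_b,
                 p_distance = mean(cmp$a != cmp$b),
                 sites_compared = length(cmp$a))
}

compared_columns <- function(aln, taxon_a, taxon_b, complete_deletion,
                             M = aln_matrix(aln)) {
  ok_base <- function(x) x %in% c("A", "C", "G", "T")
  keep <- if (complete_deletion) {
    apply(M, 2, function(col) all(ok_base(col)))
  } else {
    ok_base(M[taxon_a, ]) & ok_base(M[taxon_b, ])
  }
  list(a = M[taxon_a, keep], b = M[taxon_b, keep])
}

#' Tamura-Nei (1993) distance with gamma rate correction
#'
#' Closed-form TN93 distance distinguishing the two transition classes
#' (A<->G, C<->T) from transversions, with pooled empirical base
#' frequencies (symmetric in the two taxa) and gamma-distributed
#' among-site rate variation of shape `shape`. `shape = Inf` gives the
#' uncorrected TN93 distance. When a power/logarithm argument is
#' non-positive the distance is saturated and reported as inestimable
#' (`NA` with `status = "inestimable"`), never silently NaN.
#'
#' @inheritParams p_distance
#' @param shape Gamma shape parameter alpha (default 0.1).
#' @return Tibble: `taxon_a`, `taxon_b`, `tn93_gamma`, `sites_compared`,
#'   `shape`, `status`.
#' @export
tn93_gamma_distance <- function(aln, taxon_a, taxon_b, shape = 0.1,
                                complete_deletion = FALSE) {
  cmp <- compared_columns(aln, taxon_a, taxon_b, complete_deletion)
  if (length(cmp$a) == 0L) stop("no comparable columns between ",
                                taxon_a, " and ", taxon_b)
  d <- tn93_from_columns(cmp$a, cmp$b, shape)
  tibble::tibble(taxon_a = taxon_a, taxon_b = taxon_b,
                 tn93_gamma = d$distance, sites_compared = length(cmp$a),
                 shape = shape,
                 status = if (is.na(d$distance)) "inestimable" else "ok")
}

tn93_from_columns <- function(a, b, shape) {
  n <- length(a)
  freq <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
             table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * n)
  pA <- freq[["A"]]; pC <- freq[["C"]]; pG <- freq[["G"]]; pT <- freq[["T"]]
  gR <- pA + pG; gY <- pC + pT
  diff <- a != b
  P1 <- mean(diff & ((a == "A" & b == "G") | (a == "G" & b == "A")))
  P2 <- mean(diff & ((a == "C" & b == "T") | (a == "T" & b == "C")))
  Q <- mean(diff) - P1 - P2
  if (pA * pG == 0 || pC * pT == 0 || gR * gY == 0) {
    return(list(distance = NA_real_))
  }
  c1 <- 2 * pA * pG / gR
  c2 <- 2 * pC * pT / gY
  c3 <- 2 * (gR * gY - pA * pG * gY / gR - pC * pT * gR / gY)
  x1 <- 1 - P1 / c1 - Q / (2 * gR)
  x2 <- 1 - P2 / c2 - Q / (2 * gY)
  x3 <- 1 - Q / (2 * gR * gY)
  if (x1 <= 0 || x2 <= 0 || x3 <= 0) return(list(distance = NA_real_))
  d <- if (is.infinite(shape)) {
    -c1 * log(x1) - c2 * log(x2) - c3 * log(x3)
  } else {
    shape * (c1 * (x1^(-1 / shape) - 1) + c2 * (x2^(-1 / shape) - 1) +
               c3 * (x3^(-1 / shape) - 1))
  }
  list(distance = d)
}

#' Bootstrap standard error of a pairwise distance
#'
#' Resamples alignment columns with replacement to the original length,
#' recomputes the estimator per replicate, and reports the sample standard
#' deviation across replicates. Seeded and reproducible.
#'
#' @inheritParams p_distance
#' @param estimator `"p"` or `"tn93"`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param shape Gamma shape for the TN93 estimator.
#' @param seed Integer seed.
#' @return Standard error (numeric scalar). Errors if more than 10% of
#'   replicates are inestimable.
#' @export
bootstrap_se <- function(aln, taxon_a, taxon_b, estimator = c("p", "tn93"),
                         replicates = 1000L, shape = 0.1, seed = 1L,
                         complete_deletion = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(replicates >= 2L)
  cmp <- compared_columns(aln, taxon_a, taxon_b, complete_deletion)
  L <- length(cmp$a)
  if (L == 0L) stop("no comparable columns")
  set.seed(seed)
  vals <- vapply(seq_len(replicates), function(r) {
    idx <- sample.int(L, L, replace = TRUE)
    if (estimator == "p") mean(cmp$a[idx] != cmp$b[idx])
    else tn93_from_columns(cmp$a[idx], cmp$b[idx], shape)$distance
  }, numeric(1))
  fail <- mean(is.na(vals))
  if (fail > 0.1) stop("bootstrap failed: ", round(100 * fail, 1),
                       "% of replicates inestimable")
  sd(vals, na.rm = TRUE)
}

#' Full pairwise distance table for an alignment
#'
#' @inheritParams p_distance
#' @param shape Gamma shape for TN93 (default 0.1).
#' @param bootstrap Number of bootstrap replicates for standard errors
#'   (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return Tibble with one row per unordered taxon pair: `p_distance`,
#'   `tn93_gamma`, `se` (of the TN93 distance when bootstrapped),
#'   `sites_compared`, `shape`.
#' @export
distance_table <- function(aln, shape = 0.1, complete_deletion = FALSE,
                           bootstrap = 0L, seed = 1L) {
  pairs <- utils::combn(aln$taxa, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    pd <- p_distance(aln, a, b, complete_deletion)
    tn <- tn93_gamma_distance(aln, a, b, shape, complete_deletion)
    se <- if (bootstrap > 0L) {
      bootstrap_se(aln, a, b, "tn93", bootstrap, shape, seed + i,
                   complete_deletion)
    } else NA_real_
    tibble::tibble(taxon_a = a, taxon_b = b,
                   p_distance = pd$p_distance, tn93_gamma = tn$tn93_gamma,
                   se = se, sites_compared = pd$sites_compared, shape = shape)
  })
}

#' Write a square distance matrix (TSV or PHYLIP)
#' @param dists Output of [distance_table()].
#' @param path Output path.
#' @param value Column to write (`"tn93_gamma"` or `"p_distance"`).
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_distance_matrix <- function(dists, path, value = "tn93_gamma",
                                  format = c("tsv", "phylip")) {
  format <- match.arg(format)
  taxa <- unique(c(dists$taxon_a, dists$taxon_b))
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(dists))) {
    m[dists$taxon_a[i], dists$taxon_b[i]] <- dists[[value]][i]
    m[dists$taxon_b[i], dists$taxon_a[i]] <- dists[[value]][i]
  }
  if (format == "tsv") {
    write.table(format(m, digits = 6), path, sep = "\t", quote = FALSE,
                col.names = NA)
  } else {
    lines <- c(sprintf("%5d", length(taxa)),
               vapply(taxa, function(t) {
                 paste0(formatC(t, width = -10),
                        paste(formatC(m[t, ], format = "f", digits = 6),
                              collapse = "  "))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
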