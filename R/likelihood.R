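#' Log-likelihood of an alignment on a fixed tree under GTR+Gamma
#'
#' Felsenstein pruning over unique site patterns with per-pattern weights;
#' the discrete-gamma mixture is averaged with equal category weights.
#' Gaps and IUPAC ambiguity codes are treated as (partially) missing data:
#' the tip partial likelihood is 1 for every base compatible with the code.
#'
#' @param aln A [multi_alignment()] whose taxa match the tree's tips.
#' @param tree Rooted `phylo` with branch lengths (substitutions/site).
#' @param model A [substitution_model()].
#' @return Log-likelihood (natural log), a finite scalar.
#' @export
log_likelihood <- function(aln, tree, model) {
  prep <- ll_prep(aln, tree)
  ll_eval(prep, tree$edge.length, model)
}

# pattern-compress the alignment and precompute tip partials
ll_prep <- function(aln, tree) {
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree tips and alignment taxa differ")
  }
  M <- aln_matrix(aln)[tree$tip.label, , drop = FALSE]
  key <- do.call(paste0, lapply(seq_len(nrow(M)), function(i) M[i, ]))
  first <- !duplicated(key)
  pat_cols <- which(first)
  weights <- as.vector(table(factor(key, levels = key[first])))
  ntip <- length(tree$tip.label)
  states <- c("A", "C", "G", "T")
  codes <- names(IUPAC_SETS)
  ind <- vapply(codes, function(cd) as.numeric(states %in% IUPAC_SETS[[cd]]),
                numeric(4))
  tipL <- lapply(seq_len(ntip), function(i) {
    idx <- match(M[i, pat_cols], codes)
    L <- matrix(1, 4, length(pat_cols))     # gap/unknown: missing data
    L[, !is.na(idx)] <- ind[, idx[!is.na(idx)]]
    L
  })
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_order = match(paste(po$edge[, 1], po$edge[, 2]),
                                          paste(tree$edge[, 1], tree$edge[, 2])),
       ntip = ntip, nnode = tree$Nnode, root = ntip + 1L,
       tipL = tipL, weights = weights, pat_cols = pat_cols)
}

# evaluate lnL for given edge lengths (ordered as tree$edge rows)
ll_eval <- function(prep, edge_lengths, model) {
  K <- length(model$gamma_rates)
  npat <- length(prep$weights)
  total <- prep$ntip + prep$nnode
  lik <- numeric(npat)
  el <- edge_lengths[prep$edge_order]
  for (k in seq_len(K)) {
    r <- model$gamma_rates[k]
    partial <- vector("list", total)
    for (i in seq_len(nrow(prep$edge))) {
      p <- prep$edge[i, 1]; ch <- prep$edge[i, 2]
      Lc <- if (ch <= prep$ntip) prep$tipL[[ch]] else partial[[ch]]
      term <- prob_matrix(model, el[i], r) %*% Lc
      partial[[p]] <- if (is.null(partial[[p]])) term else partial[[p]] * term
    }
    lik <- lik + colSums(model$pi * partial[[prep$root]]) / K
  }
  if (any(lik <= 0)) {
    stop("zero site likelihood at alignment column ",
         prep$pat_cols[which(lik <= 0)[1]])
  }
  sum(prep$weights * log(lik))
}

#' Optimize branch lengths (and optionally model parameters) on a fixed
#' topology
#'
#' Cyclic univariate optimization of each branch by bracketed scalar
#' search, iterated to convergence of the log-likelihood; when
#' `optimize_model = TRUE`, the gamma shape and GTR exchangeabilities are
#' optimized between branch sweeps. The log-likelihood is non-decreasing
#' across sweeps.
#'
#' @inheritParams log_likelihood
#' @param optimize_model Also optimize alpha and the exchangeabilities.
#' @param max_sweeps Maximum optimization sweeps (default 100).
#' @param tol Convergence tolerance on the log-likelihood change per sweep
#'   (default 1e-6).
#' @param max_branch Upper bracket for a single branch length.
#' @return Object of class `mito_ml_fit`: list with `tree`, `model`,
#'   `lnL`, `converged`, `sweeps`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, optimize_model = FALSE,
                                    max_sweeps = 100L, tol = 1e-6,
                                    max_branch = 3) {
  prep <- ll_prep(aln, tree)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0.05, nrow(tree$edge))
  cur <- ll_eval(prep, el, model)
  sweeps <- 0L; converged <- FALSE
  repeat {
    sweeps <- sweeps + 1L
    before <- cur
    for (b in seq_along(el)) {
      f <- function(t) { el2 <- el; el2[b] <- t; ll_eval(prep, el2, model) }
      op <- optimize(f, c(0, max_branch), maximum = TRUE, tol = 1e-8)
      # golden-section search cannot land on the boundary exactly
      at0 <- f(0)
      if (at0 >= op$objective) { op$maximum <- 0; op$objective <- at0 }
      if (op$objective > cur) { el[b] <- op$maximum; cur <- op$objective }
    }
    if (optimize_model) {
      fa <- function(la) {
        m2 <- substitution_model(model$rates, model$pi, exp(la),
                                 model$n_categories)
        ll_eval(prep, el, m2)
      }
      opa <- optimize(fa, log(c(0.02, 100)), maximum = TRUE, tol = 1e-4)
      if (opa$objective > cur) {
        model <- substitution_model(model$rates, model$pi,
                                    exp(opa$maximum), model$n_categories)
        cur <- opa$objective
      }
      fr <- function(lr) {
        m2 <- substitution_model(c(exp(lr), 1), model$pi, model$alpha,
                                 model$n_categories)
        ll_eval(prep, el, m2)
      }
      opr <- optim(log(pmax(model$rates[1:5], 1e-6)), fr,
                   control = list(fnscale = -1, maxit = 200))
      if (opr$value > cur) {
        model <- substitution_model(c(exp(opr$par), 1), model$pi,
                                    model$alpha, model$n_categories)
        cur <- opr$value
      }
    }
    if (cur - before < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  if (!converged) {
    warning("branch-length optimization did not converge after ",
            max_sweeps, " sweeps; returning best so far")
  }
  tree$edge.length <- el
  structure(list(tree = tree, model = model, lnL = cur,
                 converged = converged, sweeps = sweeps),
            class = "mito_ml_fit")
}

#' @export
print.mito_ml_fit <- function(x, ...) {
  cat("<mito_ml_fit> lnL = ", sprintf("%.4f", x$lnL), ", ",
      length(x$tree$tip.label), " taxa, alpha = ",
      signif(x$model$alpha, 4), ", Ts/Tv = ", signif(x$model$ts_tv, 4),
      "\n", sep = "")
  invisible(x)
}

# mean root-to-tip depth below every node (substitutions/site)
node_mean_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  depth <- numeric(total); count <- integer(total)
  count[seq_len(ntip)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]; len <- po$edge.length[i]
    depth[p] <- depth[p] + depth[ch] + len * count[ch]
    count[p] <- count[p] + count[ch]
  }
  depth / count
}

# fit clock-constrained (ultrametric) branch lengths by optimizing node
# heights: root height on log scale, every other internal height as a
# fraction of its parent's height on logit scale
clock_fit <- function(aln, tree, model, init_tree = tree) {
  prep <- ll_prep(aln, tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  pre_nodes <- rev(unique(po$edge[, 1]))            # root first
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  depths <- node_mean_depths(init_tree)
  h0 <- pmax(depths[pre_nodes], 1e-8)
  par0 <- numeric(length(pre_nodes))
  par0[1] <- log(h0[1])
  for (j in seq_along(pre_nodes)[-1]) {
    hp <- h0[match(parent_of[pre_nodes[j]], pre_nodes)]
    frac <- min(max(h0[j] / hp, 0.02), 0.98)
    par0[j] <- stats::qlogis(frac)
  }
  heights_from <- function(par) {
    h <- numeric(ntip + tree$Nnode)
    h[pre_nodes[1]] <- exp(par[1])
    for (j in seq_along(pre_nodes)[-1]) {
      h[pre_nodes[j]] <- h[parent_of[pre_nodes[j]]] * stats::plogis(par[j])
    }
    h
  }
  obj <- function(par) {
    h <- heights_from(par)
    el <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
    ll_eval(prep, el, model)
  }
  op <- optim(par0, obj, control = list(fnscale = -1, maxit = 2000,
                                        reltol = 1e-12))
  op <- optim(op$par, obj, control = list(fnscale = -1, maxit = 2000,
                                          reltol = 1e-12))
  h <- heights_from(op$par)
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  list(tree = tree, lnL = op$value, heights = h)
}

#' Likelihood-ratio test of the molecular clock on a fixed topology
#'
#' Compares unconstrained branch lengths (2n-3 effective parameters) with
#' an ultrametric, node-height parameterisation (n-1 parameters) under the
#' same substitution model. The statistic 2(lnL_free - lnL_clock) is
#' referred to a chi-square with n-2 degrees of freedom.
#'
#' @inheritParams log_likelihood
#' @param max_sweeps Sweeps for the free optimization.
#' @return Object of class `mito_clock_lrt`: list with `lnL_free`,
#'   `lnL_clock`, `statistic`, `df`, `p_value`, `tree_free`, `tree_clock`.
#' @export
clock_lrt <- function(aln, tree, model, max_sweeps = 100L) {
  ntip <- length(tree$tip.label)
  stopifnot(ntip >= 3L)
  free <- optimize_branch_lengths(aln, tree, model, max_sweeps = max_sweeps)
  clock <- clock_fit(aln, tree, model, init_tree = free$tree)
  if (clock$lnL > free$lnL + 1e-6) {
    stop("clock likelihood exceeds free likelihood; optimizer failure")
  }
  stat <- max(2 * (free$lnL - clock$lnL), 0)
  df <- ntip - 2L
  structure(list(lnL_free = free$lnL, lnL_clock = clock$lnL,
                 statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 tree_free = free$tree, tree_clock = clock$tree),
            class = "mito_clock_lrt")
}

#' @export
print.mito_clock_lrt <- function(x, ...) {
  cat("<mito_clock_lrt> 2(lnL_free - lnL_clock) = ",
      sprintf("%.4f", x$statistic), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

# the two nearest-neighbour-interchange alternatives around an internal
# edge (p -> c). For a non-root parent, the sibling subtree at p is
# swapped with either child of c. When p is the root of a binary rooted
# tree the edge p->c and its sibling edge represent the same edge of the
# underlying unrooted tree, and swapping the whole sibling subtree would
# merely re-root it; the true alternatives cross a child of c with a
# child of the sibling. A sibling tip in that situation means the
# unrooted edge is pendant: no NNI exists (NULL).
nni_trees <- function(tree, edge_i) {
  p <- tree$edge[edge_i, 1]; cc <- tree$edge[edge_i, 2]
  root <- length(tree$tip.label) + 1L
  sibs <- tree$edge[tree$edge[, 1] == p, 2]
  s <- setdiff(sibs, cc)[1]
  kids <- tree$edge[tree$edge[, 1] == cc, 2]
  if (is.na(s) || length(kids) < 2) return(NULL)
  swap <- function(parent_a, a, parent_b, b) {
    tr <- tree
    i_a <- which(tr$edge[, 1] == parent_a & tr$edge[, 2] == a)
    i_b <- which(tr$edge[, 1] == parent_b & tr$edge[, 2] == b)
    tr$edge[i_a, 2] <- b
    tr$edge[i_b, 2] <- a
    attr(tr, "order") <- NULL
    tr
  }
  if (p == root && length(sibs) == 2L) {
    s_kids <- tree$edge[tree$edge[, 1] == s, 2]
    if (length(s_kids) < 2) return(NULL)     # sibling is a tip: pendant edge
    return(list(swap(cc, kids[1], s, s_kids[1]),
                swap(cc, kids[2], s, s_kids[1])))
  }
  list(swap(p, s, cc, kids[1]), swap(p, s, cc, kids[2]))
}

#' Approximate likelihood-ratio branch support (aLRT)
#'
#' For every internal branch, the test statistic is twice the
#' log-likelihood difference between the fitted tree and the better of the
#' two nearest-neighbour-interchange rearrangements of that branch
#' (branch lengths re-optimized); support is 1 - p under the
#' half-chi0/half-chi1 mixture. Degenerate branches (no NNI alternative)
#' get `NA`.
#'
#' @param fit A `mito_ml_fit` from [optimize_branch_lengths()].
#' @param aln The alignment used for the fit.
#' @param max_sweeps Sweeps for re-optimizing each rearranged tree.
#' @return Tibble: `node` (child end of the branch), `statistic`,
#'   `support`.
#' @export
alrt_support <- function(fit, aln, max_sweeps = 25L) {
  tree <- fit$tree; model <- fit$model
  ntip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > ntip)
  out <- purrr::map_dfr(internal_edges, function(ei) {
    alts <- nni_trees(tree, ei)
    if (is.null(alts)) {
      return(tibble::tibble(node = tree$edge[ei, 2],
                            statistic = NA_real_, support = NA_real_))
    }
    alt_lnL <- vapply(alts, function(tr) {
      optimize_branch_lengths(aln, tr, model, max_sweeps = max_sweeps)$lnL
    }, numeric(1))
    stat <- max(2 * (fit$lnL - max(alt_lnL)), 0)
    p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
    tibble::tibble(node = tree$edge[ei, 2], statistic = stat,
                   support = 1 - p)
  })
  out
}

#' Harmonic-mean model log-likelihood from a posterior trace
#'
#' Stable log-space computation: log HM = log(n) - logsumexp(-logL_i).
#' Used to compare models via Bayes factors on externally produced
#' log-likelihood samples.
#'
#' @param samples Numeric vector of per-draw log-likelihoods.
#' @return Log of the harmonic mean of the likelihoods.
#' @export
harmonic_mean_loglik <- function(samples) {
  if (length(samples) == 0L) stop("empty sample vector")
  if (any(!is.finite(samples))) stop("non-finite log-likelihood samples")
  neg <- -samples
  m <- max(neg)
  log(length(samples)) - (m + log(sum(exp(neg - m))))
}

#' Log Bayes factor from two harmonic-mean model likelihoods
#' @param samples_a,samples_b Log-likelihood traces of models A and B.
#' @return log BF = log HM(A) - log HM(B) (positive favours A).
#' @export
bayes_factor <- function(samples_a, samples_b) {
  harmonic_mean_loglik(samples_a) - harmonic_mean_loglik(samples_b)
}

#' Read a log-likelihood trace file (one value per line, '#' comments)
#' @param path Trace file path.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  as.numeric(lines[nzchar(lines)])
}
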