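test_that("transition probabilities satisfy the basic identities", {
  m <- substitution_model(c(1.2, 4, 0.8, 1.1, 6, 1),
                          c(0.31, 0.24, 0.18, 0.27), alpha = 0.5)
  expect_equal(prob_matrix(m, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
  for (t in c(0.001, 0.05, 0.5, 3)) {
    P <- prob_matrix(m, t)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0))
    # detailed balance of the reversible chain: diag(pi) P is symmetric
    M <- m$pi * P
    expect_equal(M, t(M), tolerance = 1e-10, ignore_attr = TRUE)
  }
  # discrete gamma rates average to 1
  expect_equal(mean(m$gamma_rates), 1, tolerance = 1e-12)
  expect_equal(mean(discrete_gamma_rates(0.1, 4)), 1, tolerance = 1e-12)
})

test_that("JC pattern probabilities match the closed form to 1e-10", {
  m <- jc_model()
  for (t in c(0.01, 0.1, 0.5)) {
    P <- prob_matrix(m, t)
    same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    diffp <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    expect_lt(max(abs(diag(P) - same)), 1e-10)
    expect_lt(max(abs(P[upper.tri(P)] - diffp)), 1e-10)
    # two-sequence likelihood assembled from those pattern probabilities
    aln <- toy_alignment(c(A = "AC", B = "AG"))
    tr <- ape::read.tree(text = sprintf("(A:%f,B:0);", t))
    expect_equal(log_likelihood(aln, tr, m),
                 log(0.25 * same) + log(0.25 * diffp), tolerance = 1e-10)
  }
  # single identical site on a zero-length tree: lnL = ln(1/4)
  aln1 <- toy_alignment(c(A = "G", B = "G"))
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(log_likelihood(aln1, tr0, m), log(0.25), tolerance = 1e-12)
})

test_that("likelihood is invariant to pattern order and additive over copies", {
  cfg <- simulation_config(quartet_tree(), jc_model(alpha = 0.5),
                           genome_length = 800, seed = 51)
  sim <- simulate_evolution(cfg)
  m <- substitution_model(c(1, 3, 1, 1, 3, 1), rep(0.25, 4), alpha = 0.5)
  lnl <- log_likelihood(sim$alignment, sim$truth$tree, m)
  # column shuffle: same pattern multiset, different compression order
  set.seed(52)
  perm <- sample(aln_ncol(sim$alignment))
  rows <- vapply(sim$alignment$rows, function(s) {
    paste(strsplit(s, "")[[1]][perm], collapse = "")
  }, character(1))
  shuf <- multi_alignment(rows, sim$alignment$ref_id)
  expect_equal(log_likelihood(shuf, sim$truth$tree, m), lnl,
               tolerance = 1e-9)
  # doubling the alignment doubles the log-likelihood exactly
  dbl <- multi_alignment(vapply(sim$alignment$rows,
                                function(s) paste0(s, s), character(1)),
                         sim$alignment$ref_id)
  expect_equal(log_likelihood(dbl, sim$truth$tree, m), 2 * lnl,
               tolerance = 1e-8)
})

test_that("likelihood agrees with phangorn on a GTR+Gamma quartet", {
  skip_if_not_installed("phangorn")
  cfg <- simulation_config(quartet_tree(), jc_model(),
                           genome_length = 1500, seed = 53)
  sim <- simulate_evolution(cfg)
  m <- substitution_model(c(1.5, 4, 0.7, 1.2, 6, 1),
                          c(0.3, 0.22, 0.21, 0.27), alpha = 0.7)
  tr <- sim$truth$tree
  mine <- log_likelihood(sim$alignment, tr, m)
  dat <- phangorn::phyDat(aln_matrix(sim$alignment))
  # phangorn Q order is ACGT pairwise lower-triangle: AC AG AT CG CT GT
  fitp <- phangorn::pml(ape::unroot(tr), dat, bf = m$pi,
                        Q = m$rates, shape = 0.7, k = 4)
  expect_equal(mine, fitp$logLik, tolerance = 1e-4)
})

test_that("likelihood is invariant under re-rooting", {
  cfg <- simulation_config(quartet_tree(), jc_model(),
                           genome_length = 1000, seed = 54)
  sim <- simulate_evolution(cfg)
  m <- substitution_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3),
                          alpha = 0.9)
  tr <- sim$truth$tree
  lnl <- log_likelihood(sim$alignment, tr, m)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "C",
                        resolve.root = TRUE)
  expect_equal(log_likelihood(sim$alignment, rerooted, m), lnl,
               tolerance = 1e-8)
})

test_that("two-taxon optimization reproduces the analytic JC distance", {
  cfg <- simulation_config("(A:0.08,B:0.0);", jc_model(),
                           genome_length = 4000, seed = 55)
  sim <- simulate_evolution(cfg)
  p <- p_distance(sim$alignment, "A", "B")$p_distance
  analytic <- -3 / 4 * log(1 - 4 / 3 * p)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  fit <- optimize_branch_lengths(sim$alignment, tr, jc_model())
  expect_equal(sum(fit$tree$edge.length), analytic, tolerance = 1e-6)
})

test_that("optimization is a fixed point at its own optimum", {
  cfg <- simulation_config(quartet_tree(), jc_model(),
                           genome_length = 2000, seed = 56)
  sim <- simulate_evolution(cfg)
  fit1 <- optimize_branch_lengths(sim$alignment, sim$truth$tree, jc_model())
  fit2 <- optimize_branch_lengths(sim$alignment, fit1$tree, jc_model())
  expect_lt(abs(fit2$lnL - fit1$lnL), 1e-6)
  expect_true(fit1$converged)
})

test_that("clock LRT degenerates correctly on identical sequences", {
  s <- random_dna(300, seed = 57)
  aln <- toy_alignment(c(A = s, B = s, C = s, D = s))
  lrt <- clock_lrt(aln, quartet_tree(), jc_model())
  expect_lt(lrt$statistic, 1e-6)
  expect_equal(lrt$p_value, 1, tolerance = 1e-6)
  expect_equal(lrt$df, 2L)
})

test_that("clock LRT detects a strongly violated clock", {
  tr <- ape::read.tree(
    text = "((A:0.12,B:0.04):0.03,(C:0.04,D:0.04):0.03);")
  cfg <- simulation_config(tr, jc_model(), genome_length = 10000, seed = 58)
  sim <- simulate_evolution(cfg)
  lrt <- clock_lrt(sim$alignment, tr, jc_model())
  expect_lt(lrt$p_value, 1e-4)
  expect_gte(lrt$statistic, 0)
  g <- generics::glance(lrt)
  expect_equal(g$statistic, lrt$statistic)
})

test_that("aLRT support is high for a well-resolved quartet and invariant
           to leaf order", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  cfg <- simulation_config(tr, jc_model(), genome_length = 10000, seed = 59)
  sim <- simulate_evolution(cfg)
  fit <- optimize_branch_lengths(sim$alignment, tr, jc_model())
  sup <- alrt_support(fit, sim$alignment)
  ntip <- 4L
  inner <- sup[sup$node > ntip + 1L, ]      # skip the root-incident branch
  expect_true(all(inner$support > 0.99))
  # permuting alignment rows leaves supports unchanged
  perm_aln <- multi_alignment(sim$alignment$rows[c(3, 1, 4, 2)],
                              sim$alignment$taxa[3])
  fit2 <- optimize_branch_lengths(perm_aln, tr, jc_model())
  sup2 <- alrt_support(fit2, perm_aln)
  expect_equal(sup$support, sup2$support, tolerance = 1e-4)
})

test_that("aLRT support is near zero without internal signal", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.0001,(C:0.05,D:0.05):0.0001);")
  cfg <- simulation_config(tr, jc_model(), genome_length = 2000, seed = 60)
  sim <- simulate_evolution(cfg)
  fit <- optimize_branch_lengths(sim$alignment, tr, jc_model())
  sup <- alrt_support(fit, sim$alignment)
  inner <- sup[sup$node > 5L, ]
  expect_true(all(inner$support < 0.95))
})

test_that("harmonic-mean likelihoods and Bayes factors follow the definition", {
  expect_equal(harmonic_mean_loglik(rep(-12.5, 20)), -12.5)
  # harmonic mean of {1, 1/3} is 1/2
  expect_equal(harmonic_mean_loglik(c(log(1), log(1 / 3))), log(0.5),
               tolerance = 1e-12)
  tr <- c(log(1), log(1 / 3))
  expect_equal(bayes_factor(tr, tr), 0)
  # stable far from zero: no overflow for very negative log-likelihoods
  expect_true(is.finite(harmonic_mean_loglik(rnorm(100, -30000, 5))))
  expect_error(harmonic_mean_loglik(numeric(0)), "empty")
  expect_error(harmonic_mean_loglik(c(1, NA)), "finite")
  f <- withr::local_tempfile()
  writeLines(c("# trace", "-10.5", "", "-11.25  # comment"), f)
  expect_equal(read_trace(f), c(-10.5, -11.25))
})

test_that("tidiers expose fit summaries", {
  cfg <- simulation_config(quartet_tree(), jc_model(),
                           genome_length = 800, seed = 61)
  sim <- simulate_evolution(cfg)
  fit <- optimize_branch_lengths(sim$alignment, sim$truth$tree, jc_model())
  td <- generics::tidy(fit)
  expect_equal(nrow(td), nrow(fit$tree$edge))
  expect_true(all(td$branch_length >= 0))
  gl <- generics::glance(fit)
  expect_equal(gl$lnL, fit$lnL)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
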