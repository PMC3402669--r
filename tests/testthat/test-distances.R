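test_that("p-distance matches hand counts and handles deletion modes", {
  aln <- toy_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(p_distance(aln, "a", "b")$p_distance, 0.25)
  expect_equal(p_distance(aln, "a", "a")$p_distance, 0)
  # gap and ambiguity columns are excluded pairwise
  aln <- toy_alignment(c(a = "ACGTN", b = "AC-TA", c = "ACGTA"))
  d <- p_distance(aln, "a", "b")
  expect_equal(d$sites_compared, 3L)
  # complete deletion restricts all pairs to clean columns
  d2 <- p_distance(aln, "a", "c", complete_deletion = TRUE)
  expect_equal(d2$sites_compared, 3L)
  expect_error(p_distance(toy_alignment(c(a = "N-", b = "AC")), "a", "b"),
               "comparable")
})

test_that("distances are symmetric", {
  cfg <- simulation_config("(A:0.05,B:0.0);", jc_model(),
                           genome_length = 2000, seed = 41)
  sim <- simulate_evolution(cfg)
  expect_identical(p_distance(sim$alignment, "A", "B")$p_distance,
                   p_distance(sim$alignment, "B", "A")$p_distance)
  expect_identical(tn93_gamma_distance(sim$alignment, "A", "B")$tn93_gamma,
                   tn93_gamma_distance(sim$alignment, "B", "A")$tn93_gamma)
})

test_that("TN93 limits: zero on identity, uncorrected at huge alpha", {
  aln <- toy_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(tn93_gamma_distance(aln, "a", "b", shape = 0.1)$tn93_gamma, 0)
  cfg <- simulation_config("(A:0.08,B:0.0);",
                           substitution_model(c(1, 6, 1, 1, 10, 1),
                                              c(0.3, 0.2, 0.2, 0.3)),
                           genome_length = 5000, seed = 42)
  sim <- simulate_evolution(cfg)
  big <- tn93_gamma_distance(sim$alignment, "A", "B", shape = 1e6)$tn93_gamma
  inf <- tn93_gamma_distance(sim$alignment, "A", "B", shape = Inf)$tn93_gamma
  expect_lt(abs(big - inf), 1e-6)
  # gamma correction always enlarges the finite-alpha distance
  small <- tn93_gamma_distance(sim$alignment, "A", "B", shape = 0.1)$tn93_gamma
  expect_gt(small, inf)
  expect_gte(inf, p_distance(sim$alignment, "A", "B")$p_distance)
})

test_that("TN93 agrees with an independent implementation", {
  cfg <- simulation_config("(A:0.07,B:0.0);",
                           substitution_model(c(1, 8, 1, 1, 16, 1),
                                              c(0.33, 0.26, 0.13, 0.28)),
                           genome_length = 8000, seed = 43)
  sim <- simulate_evolution(cfg)
  M <- aln_matrix(sim$alignment)
  bin <- ape::as.DNAbin(M)
  expect_equal(tn93_gamma_distance(sim$alignment, "A", "B",
                                   shape = Inf)$tn93_gamma,
               as.numeric(ape::dist.dna(bin, model = "TN93")),
               tolerance = 1e-10)
  expect_equal(tn93_gamma_distance(sim$alignment, "A", "B",
                                   shape = 0.5)$tn93_gamma,
               as.numeric(ape::dist.dna(bin, model = "TN93", gamma = 0.5)),
               tolerance = 1e-10)
})

test_that("TN93 estimates recover a known simulated branch length", {
  model <- substitution_model(c(1, 8, 1, 1, 16, 1),
                              c(0.3, 0.25, 0.15, 0.3),
                              alpha = 0.5, n_categories = 8L)
  cfg <- simulation_config("(A:0.05,B:0.0);", model,
                           genome_length = 100000, seed = 44)
  sim <- simulate_evolution(cfg)
  est <- tn93_gamma_distance(sim$alignment, "A", "B", shape = 0.5)$tn93_gamma
  se <- bootstrap_se(sim$alignment, "A", "B", "tn93", replicates = 200,
                     shape = 0.5, seed = 44)
  expect_lt(abs(est - 0.05), 3 * se)
})

test_that("TN93 reduces to Jukes-Cantor on JC-like data", {
  cfg <- simulation_config("(A:0.06,B:0.0);", jc_model(),
                           genome_length = 50000, seed = 45)
  sim <- simulate_evolution(cfg)
  tn <- tn93_gamma_distance(sim$alignment, "A", "B", shape = Inf)$tn93_gamma
  p <- p_distance(sim$alignment, "A", "B")$p_distance
  jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_lt(abs(tn - jc) / jc, 0.02)
})

test_that("saturated distances are flagged inestimable, not NaN", {
  aln <- toy_alignment(c(a = paste(rep("A", 40), collapse = ""),
                         b = paste(rep(c("G", "C"), 20), collapse = "")))
  r <- tn93_gamma_distance(aln, "a", "b", shape = 0.1)
  expect_equal(r$status, "inestimable")
  expect_true(is.na(r$tn93_gamma))
})

test_that("bootstrap SE is zero on identity, deterministic, and near the
           binomial closed form", {
  aln <- toy_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(bootstrap_se(aln, "a", "b", "p", 50, seed = 1), 0)
  L <- 10000
  a <- random_dna(L, seed = 46)
  b <- a
  flip <- sample(L, L * 0.05)
  for (p in flip) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substring(a, p, p))[1]
  }
  aln <- toy_alignment(c(a = a, b = b))
  se1 <- bootstrap_se(aln, "a", "b", "p", replicates = 1000, seed = 7)
  se2 <- bootstrap_se(aln, "a", "b", "p", replicates = 1000, seed = 7)
  expect_identical(se1, se2)
  closed <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(se1 - closed) / closed, 0.15)
})

test_that("distance tables and matrix writers are consistent", {
  cfg <- simulation_config("(A:0.02,(B:0.02,C:0.02):0.01);", jc_model(),
                           genome_length = 2000, seed = 47)
  sim <- simulate_evolution(cfg)
  dt <- distance_table(sim$alignment, shape = 0.2, bootstrap = 50, seed = 1)
  expect_equal(nrow(dt), 3L)
  expect_true(all(dt$tn93_gamma >= dt$p_distance))
  expect_true(all(dt$se >= 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dt, f)
  m <- as.matrix(read.delim(f, row.names = 1))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m[1, 2], m[2, 1])
  fp <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dt, fp, format = "phylip")
  expect_equal(trimws(readLines(fp)[1]), "3")
})
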