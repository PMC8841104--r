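test_that("prevalence and heritability match direct 9-term summation", {
  const <- matrix(0.3, 3, 3)
  expect_equal(prevalence(const, 0.2, 0.2), 0.3)
  expect_equal(heritability(const, 0.2, 0.2), 0)
  expect_equal(prevalence(matrix(0, 3, 3), 0.3, 0.3), 0)

  # hand table at maf 0.5 against the explicit double sum
  tab <- matrix(c(0.5, 0.3, 0.5,
                  0.3, 0.7, 0.3,
                  0.5, 0.3, 0.5), 3, 3, byrow = TRUE)
  p <- c(0.25, 0.5, 0.25)
  K <- 0
  for (i in 1:3) for (j in 1:3) K <- K + p[i] * p[j] * tab[i, j]
  v <- 0
  for (i in 1:3) for (j in 1:3) v <- v + p[i] * p[j] * (tab[i, j] - K)^2
  expect_equal(prevalence(tab, 0.5, 0.5), K)
  expect_equal(heritability(tab, 0.5, 0.5), v / (K * (1 - K)))

  # invariant under swapping the loci together with transposing the table
  tab2 <- matrix(stats::runif(9), 3, 3)
  expect_equal(heritability(tab2, 0.2, 0.4), heritability(t(tab2), 0.4, 0.2))

  expect_error(heritability(matrix(0, 3, 3), 0.2, 0.2), "undefined")
  expect_error(prevalence(matrix(1.2, 3, 3), 0.2, 0.2), "\\[0, 1\\]")
})

test_that("generated penetrance models hit the target heritability with pure marginals", {
  for (s in 1:5) {
    m <- gen_penetrance_model(0.2, 0.4, K = 0.35, seed = s)
    expect_equal(m$h2, 0.4, tolerance = 1e-9)
    expect_equal(m$K, 0.35, tolerance = 1e-9)
    p <- hwe_freqs(0.2)
    expect_lt(max(abs(as.vector(m$table %*% p) - m$K)), 1e-9)
    expect_lt(max(abs(as.vector(p %*% m$table) - m$K)), 1e-9)
    # purity => single-locus genotype distribution identical in cases:
    # P(gA = i | case) = p_i * (row marginal) / K = p_i
    p_case <- as.vector(m$table %*% hwe_freqs(0.2)) * p / m$K
    expect_equal(p_case, p, tolerance = 1e-9)
  }
  # near-zero heritability limit: table approaches the constant K
  m0 <- gen_penetrance_model(0.2, 1e-8, K = 0.35, seed = 1)
  expect_lt(max(abs(m0$table - 0.35)), 1e-3)
  # infeasible combination errors out with guidance
  expect_error(gen_penetrance_model(0.2, 0.4, K = 0.05, max_tries = 200),
               "smaller h2")
})

test_that("heritability scales quadratically in the deviation amplitude", {
  m <- gen_penetrance_model(0.25, 0.2, K = 0.35, seed = 7)
  for (c in c(0.3, 0.5)) {
    scaled <- 0.35 + c * (m$table - 0.35)
    expect_equal(heritability(scaled, 0.25, 0.25), c^2 * m$h2,
                 tolerance = 1e-9)
  }
})

test_that("architecture validation enforces shared K, label counts and pools", {
  m1 <- gen_penetrance_model(0.2, 0.4, K = 0.35, seed = 1)
  m2 <- gen_penetrance_model(0.2, 0.4, K = 0.3, seed = 2)
  expect_error(sim_architecture(list(m1, m2), c("A", "B", "C", "D")),
               "same prevalence")
  expect_error(sim_architecture(list(m1), c("A", "B", "C")), "2 labels")
  expect_error(sim_architecture(list(m1), c("A", "A")), "duplicate")
  arch <- sim_architecture(list(m1), c("A", "B"), n_noise = 5,
                           noise_labels = sprintf("n%d", 1:5))
  expect_length(arch$noise_labels, 5L)
  expect_error(sim_architecture(list(m1), c("A", "B"), n_noise = 6,
                                noise_labels = sprintf("n%d", 1:5)),
               "exhausted")
  relab <- assign_labels(arch, c("X", "Y"), sprintf("p%02d", 1:9))
  expect_identical(relab$functional_labels, c("X", "Y"))
  expect_identical(relab$noise_labels, sprintf("p%02d", 1:5))
  expect_identical(epistasis_architecture(seed = 1)$functional_labels,
                   c("PTBP1", "U2AF2", "SRSF9", "SFSWAP", "PCBP4", "NPM1",
                     "C1QBP", "SAP18"))
})

test_that("simulated datasets have the requested shape and are seed-reproducible", {
  arch <- epistasis_architecture(n_noise = 40, seed = 2)
  ds <- simulate_dataset(arch, 50, 60, seed = 5)
  expect_equal(dim(ds), c(110L, 48L))
  expect_equal(sum(ds$phenotype), 50L)
  expect_identical(snp_ids(ds)[1:8], arch$functional_labels)
  ds2 <- simulate_dataset(arch, 50, 60, seed = 5)
  expect_identical(ds$genotypes, ds2$genotypes)
  expect_false(identical(simulate_dataset(arch, 50, 60, seed = 6)$genotypes,
                         ds$genotypes))
})

test_that("a constant-penetrance model yields phenotype independent of genotype", {
  tab <- matrix(0.35, 3, 3)
  m <- penetrance_model(tab, 0.2, 0.2)
  arch <- sim_architecture(list(m), c("A", "B"), n_noise = 3)
  ds <- simulate_dataset(arch, 150, 150, seed = 8)
  sc <- chi2_scores(ds)
  # no association: chi2 values should look null (df = 2 -> mean ~ 2)
  expect_lt(max(sc$score), stats::qchisq(1 - 1e-4, df = 2))
})

test_that("case status follows the additive combination of pair penetrances", {
  arch <- epistasis_architecture(n_pairs = 2, maf = 0.25, h2 = 0.3,
                                 K = 0.35, n_noise = 0, seed = 3)
  arch$functional_labels <- c("A1", "A2", "B1", "B2")
  # Monte-Carlo: empirical P(case | joint genotype) vs the combination rule
  for (comb in c("scaled_sum", "mean")) {
    set.seed(40)
    n <- 150000
    g <- vapply(rep(0.25, 4), function(m) stats::rbinom(n, 2, m),
                numeric(n))
    f1 <- arch$pairs[[1]]$table[cbind(g[, 1] + 1, g[, 2] + 1)]
    f2 <- arch$pairs[[2]]$table[cbind(g[, 3] + 1, g[, 4] + 1)]
    pen <- if (comb == "mean") (f1 + f2) / 2
           else pmin(1, pmax(0, 0.35 + ((f1 - 0.35) + (f2 - 0.35)) / sqrt(2)))
    status <- stats::rbinom(n, 1, pen)
    # group by the first pair's joint genotype; compare to the marginalized rule
    cell <- g[, 1] * 3 + g[, 2]
    emp <- tapply(status, cell, mean)
    expect_gt(length(emp), 7)
    thr <- tapply(pen, cell, mean)
    se <- sqrt(thr * (1 - thr) / table(cell))
    expect_true(all(abs(emp - thr[names(emp)]) < 4 * se[names(emp)] + 1e-3))
  }
})
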