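test_that("chi-square scores match the hand-computed 2x2 allele table", {
  # cases: 30 minor / 10 major alleles; controls: 10 minor / 30 major
  # Pearson chi2 on [[30,10],[10,30]] = 80 * (30*30-10*10)^2 / 40^4 = 20
  g <- c(rep(2L, 10), rep(1L, 10),   # 20 cases
         rep(1L, 10), rep(0L, 10))   # 20 controls
  gm <- matrix(g, ncol = 1, dimnames = list(sprintf("s%02d", 1:40), "rs1"))
  ds <- genotype_dataset(gm, rep(1:0, each = 20))
  expect_equal(chi2_scores(ds, mode = "allelic")$score, 20)
})

test_that("chi-square is zero for identical class distributions and monomorphic SNPs", {
  block <- c(0L, 0L, 1L, 1L, 2L, 2L)
  g <- cbind(rs1 = c(block, block), rs2 = rep(1L, 12))
  rownames(g) <- sprintf("s%02d", 1:12)
  ds <- genotype_dataset(g, rep(1:0, each = 6))
  for (mode in c("genotypic", "allelic")) {
    sc <- chi2_scores(ds, mode)
    expect_equal(sc$score, c(0, 0))
    expect_false(anyNA(sc$score))
  }
  ds$phenotype <- rep(1L, 12)
  expect_error(chi2_scores(ds), "both phenotype classes")
})

test_that("pairwise distances count mismatching genotypes over shared SNPs", {
  g <- rbind(s1 = c(0L, 1L, 2L),
             s2 = c(0L, 1L, 2L),
             s3 = c(1L, 2L, 0L),
             s4 = c(0L, 1L, 0L),
             s5 = c(NA, NA, 2L))
  colnames(g) <- paste0("rs", 1:3)
  d <- pairwise_distances(genotype_dataset(g, c(0L, 1L, 0L, 1L, 0L)))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  expect_equal(d["s1", "s4"], 1 / 3)
  expect_equal(d["s1", "s5"], 0)        # only rs3 jointly observed, equal
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_identical(d, t(d))
})

test_that("MultiSURF and MultiSURF* agree with the exhaustive oracle, with and without missingness", {
  for (s in 1:25) {
    ds <- rand_dataset(n = sample(6:30, 1), p = sample(2:6, 1), seed = 400 + s,
                       miss_frac = if (s %% 3 == 0) 0.08 else 0)
    g <- ds$genotypes; y <- ds$phenotype
    expect_equal(multisurf_scores(ds)$score, oracle_relief(g, y, FALSE),
                 tolerance = 1e-12)
    expect_equal(multisurf_star_scores(ds)$score, oracle_relief(g, y, TRUE),
                 tolerance = 1e-12)
  }
})

test_that("constant features score exactly zero", {
  ds <- rand_dataset(30, 4, seed = 77)
  ds$genotypes[, 2] <- 1L
  expect_equal(multisurf_scores(ds)$score[2], 0)
  expect_equal(multisurf_star_scores(ds)$score[2], 0)
})

test_that("a feature equal to the phenotype dominates the MultiSURF ranking", {
  set.seed(55)
  n <- 100
  y <- rep(0:1, 50)[sample(n)]
  g <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10)
  g[, 1] <- 2L * y
  dimnames(g) <- list(sprintf("s%03d", 1:n), sprintf("rs%02d", 1:10))
  sc <- multisurf_scores(genotype_dataset(g, y))$score
  expect_gt(sc[1], 0)
  expect_equal(which.max(sc), 1L)
})

test_that("Relief scores are invariant to sample order, feature order and label swap", {
  ds <- rand_dataset(24, 5, seed = 88)
  base <- multisurf_star_scores(ds)$score
  set.seed(1); perm <- sample(24)
  ds_s <- subset_dataset(ds, samples = perm)
  expect_equal(multisurf_star_scores(ds_s)$score, base, tolerance = 1e-12)
  fperm <- c(3, 1, 5, 2, 4)
  ds_f <- subset_dataset(ds, snps = fperm)
  expect_equal(multisurf_star_scores(ds_f)$score, base[fperm],
               tolerance = 1e-12)
  ds_y <- ds; ds_y$phenotype <- 1L - ds$phenotype
  expect_equal(multisurf_star_scores(ds_y)$score, base, tolerance = 1e-12)
  expect_equal(multisurf_scores(ds_y)$score, multisurf_scores(ds)$score,
               tolerance = 1e-12)
})

test_that("an epistatic pair outranks noise under MultiSURF* but not chi-square", {
  arch <- sim_architecture(list(gen_penetrance_model(0.2, 0.4, 0.35, seed = 5)),
                           functional_labels = c("F1", "F2"), n_noise = 18)
  ds <- simulate_dataset(arch, 400, 400, seed = 12)
  star_rank <- rank(-multisurf_star_scores(ds)$score)[1:2]
  expect_true(all(star_rank <= 2))
  chi_rank <- rank(-chi2_scores(ds)$score)[1:2]
  expect_false(all(chi_rank <= 2))
})

test_that("a purely univariate feature loses rank to an epistatic pair under MultiSURF*", {
  arch <- sim_architecture(list(gen_penetrance_model(0.2, 0.4, 0.35, seed = 5)),
                           functional_labels = c("F1", "F2"), n_noise = 15)
  ds <- simulate_dataset(arch, 300, 300, seed = 13)
  # append a noisy copy of the phenotype: a purely univariate feature
  set.seed(66)
  uni <- ifelse(stats::runif(600) < 0.7, ds$phenotype * 2L,
                sample(0:2, 600, TRUE))
  g <- cbind(ds$genotypes, UNI = as.integer(uni))
  ds2 <- genotype_dataset(g, ds$phenotype)
  r_ms <- stats::setNames(rank(-multisurf_scores(ds2)$score), snp_ids(ds2))
  r_star <- stats::setNames(rank(-multisurf_star_scores(ds2)$score),
                            snp_ids(ds2))
  expect_equal(unname(r_ms["UNI"]), 1)            # MultiSURF loves main effects
  expect_gt(unname(r_star["UNI"]), unname(r_ms["UNI"]))
  expect_true(all(r_star[c("F1", "F2")] <= 3))    # the pair stays on top
})

test_that("cross-validation averaging is deterministic and tracks full-data scores", {
  ds <- rand_dataset(80, 12, seed = 101)
  cv1 <- cv_average_scores(ds, "multisurf", k = 5, seed = 3)
  cv2 <- cv_average_scores(ds, "multisurf", k = 5, seed = 3)
  expect_identical(cv1$score, cv2$score)
  expect_identical(attr(cv1, "method"), "multisurf")

  # when fold scores are identical, the average equals the single-run score
  fixed <- function(d) feature_scores(snp_ids(d), seq_len(ncol(d$genotypes)),
                                      "chi2_genotypic")
  cv_fix <- cv_average_scores(ds, fixed, k = 4, seed = 1)
  expect_equal(cv_fix$score, as.numeric(seq_len(12)))

  arch <- epistasis_architecture(n_noise = 30, seed = 4)
  sim <- simulate_dataset(arch, 150, 150, seed = 9)
  cv <- cv_average_scores(sim, "multisurf", k = 10, seed = 5)
  full <- multisurf_scores(sim)
  expect_gt(stats::cor(cv$score, full$score, method = "spearman"), 0.9)

  expect_error(cv_average_scores(rand_dataset(10, 3, 1), "chi2", k = 8),
               "at least k")
})
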