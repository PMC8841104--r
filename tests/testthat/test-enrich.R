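mk_ranked <- function(n, seed = 1) {
  set.seed(seed)
  ranked_gene_list(sprintf("g%04d", 1:n), sort(stats::rnorm(n), decreasing = TRUE))
}

test_that("gene-set size filtering intersects with the universe first, bounds inclusive", {
  rl <- mk_ranked(300)
  coll <- gene_set_collection(list(
    tiny = rl$gene[1:19],
    edge = rl$gene[1:20],
    big_out = c(rl$gene[1:150], sprintf("x%03d", 1:100)),  # 250 total, 150 in
    huge = c(rl$gene[1:201])))
  f <- filter_gene_sets(coll, rl, 20, 200)
  expect_setequal(names(f), c("edge", "big_out"))
  expect_length(f$big_out, 150L)
  expect_error(filter_gene_sets(coll, rl, 50, 20), "min_size")

  set.seed(7)
  sizes <- sample(5:300, 60, replace = TRUE)
  coll2 <- gene_set_collection(stats::setNames(
    lapply(sizes, function(s) sample(rl$gene, min(s, 299))),
    sprintf("S%02d", 1:60)))
  f2 <- filter_gene_sets(coll2, rl, 20, 200)
  expect_equal(length(f2), sum(lengths(coll2) >= 20 & lengths(coll2) <= 200))
})

test_that("running-sum enrichment score matches a hand-stepped walk", {
  rl <- ranked_gene_list(paste0("g", 1:10), 10:1)
  r <- enrichment_score(rl, c("g1", "g2", "g3"))
  # N_R = 10+9+8 = 27; all three hits lead, so the sum peaks at 1 at rank 3
  expect_equal(r$es, 1)
  expect_equal(r$peak, 3L)
  expect_equal(r$running[1], 10 / 27)
  expect_equal(r$running[2], 19 / 27)
  expect_equal(r$running[10], 0, tolerance = 1e-12)

  walk <- oracle_es_walk(rl$score, rl$gene %in% c("g2", "g5", "g9"))
  r2 <- enrichment_score(rl, c("g2", "g5", "g9"))
  expect_equal(r2$es, walk$es)
  expect_equal(r2$peak, walk$peak)
  expect_equal(r2$running, walk$running)

  expect_error(enrichment_score(rl, rl$gene), "equals the ranked universe")
  expect_error(enrichment_score(rl, "nope"), "no member")
  # single top-ranked gene: ES = 1 at rank 1
  expect_equal(enrichment_score(rl, "g1")$es, 1)
  # all-zero hit scores fall back to unweighted increments
  rl0 <- ranked_gene_list(paste0("g", 1:6), c(3, 2, 1, 0, 0, 0))
  expect_warning(r0 <- enrichment_score(rl0, c("g5", "g6")), "unweighted")
  expect_equal(r0$es, -1)      # four misses at -1/4 each before the hits
  expect_equal(r0$peak, 4L)
})

test_that("the hit-position shortcut reproduces the full walk on random sets", {
  rl <- mk_ranked(200, seed = 5)
  es_fast <- getFromNamespace("es_from_hits", "episgsea")
  set.seed(6)
  for (rep in 1:50) {
    m <- sample(1:40, 1)
    idx <- sort(sample(200, m))
    full <- oracle_es_walk(rl$score, seq_len(200) %in% idx)
    expect_equal(es_fast(idx, abs(rl$score[idx]), 200), full$es,
                 tolerance = 1e-12)
  }
})

test_that("enrichment scores never exceed 1 in magnitude and conserve at p = 0", {
  set.seed(8)
  for (rep in 1:20) {
    rl <- mk_ranked(80, seed = rep)
    gs <- sample(rl$gene, sample(3:40, 1))
    r <- enrichment_score(rl, gs)
    expect_lte(abs(r$es), 1)
    r0 <- enrichment_score(rl, gs, p = 0)
    expect_equal(r0$running[80], 0, tolerance = 1e-12)
    # p = 0 walk is invariant to positive affine rescaling of scores
    rl2 <- rl; rl2$score <- rl$score * 3 + 100
    expect_equal(enrichment_score(rl2, gs, p = 0)$es, r0$es)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  rl <- mk_ranked(150, seed = 11)
  set.seed(12)
  stats_vec <- stats::setNames(rl$score, rl$gene)
  for (rep in 1:20) {
    idx <- sort(sample(150, sample(5:50, 1)))
    ours <- enrichment_score(rl, rl$gene[idx])$es
    ref <- fgsea::calcGseaStat(stats_vec, idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("a planted top-ranked set is strongly enriched; permutations are seed-stable", {
  rl <- mk_ranked(1000, seed = 21)
  set.seed(22)
  coll <- gene_set_collection(c(
    list(planted = rl$gene[1:10]),
    stats::setNames(lapply(1:40, function(i) sample(rl$gene, 30)),
                    sprintf("rand%02d", 1:40))))
  res <- preranked_gsea(rl, coll, n_perm = 500, seed = 3)
  planted <- res[res$set == "planted", ]
  expect_lt(planted$fdr_q, 0.05)
  expect_equal(planted$p_value, 1 / 501)
  expect_gt(planted$nes, max(res$nes[res$set != "planted"], na.rm = TRUE))
  expect_identical(attr(res, "leading_edge")[[1]], rl$gene[1:10])

  res2 <- preranked_gsea(rl, coll, n_perm = 500, seed = 3)
  expect_identical(res$fdr_q, res2$fdr_q)
  expect_error(preranked_gsea(rl, coll, n_perm = 5), "at least 10")

  # q-values are monotone non-increasing in |NES| within each sign
  for (sgn in c(1, -1)) {
    sub <- res[!is.na(res$nes) & sign(res$nes) == sgn, ]
    o <- order(-abs(sub$nes))
    expect_true(all(diff(sub$fdr_q[o]) >= -1e-12))
  }
})

test_that("leading edge collects members at or before a positive peak, after a negative one", {
  rl <- ranked_gene_list(paste0("g", 1:10), 10:1)
  r <- enrichment_score(rl, c("g1", "g2", "g3"))
  expect_identical(leading_edge(rl, c("g1", "g2", "g3"), r),
                   c("g1", "g2", "g3"))
  walk <- enrichment_score(rl, c("g2", "g9", "g10"))
  le <- leading_edge(rl, c("g2", "g9", "g10"), walk)
  if (walk$es > 0) {
    expect_true(all(match(le, rl$gene) <= walk$peak))
  } else {
    expect_true(all(match(le, rl$gene) >= walk$peak))
  }
  # negative enrichment: members piled at the bottom
  rneg <- enrichment_score(rl, c("g8", "g9", "g10"))
  expect_lt(rneg$es, 0)
  expect_identical(leading_edge(rl, c("g8", "g9", "g10"), rneg),
                   c("g8", "g9", "g10"))
})

test_that("cross-analysis leading-edge summary builds the occurrence matrix and replication list", {
  rl <- mk_ranked(400, seed = 31)
  set.seed(32)
  shared <- rl$gene[1:15]
  mk_res <- function(seed) {
    coll <- gene_set_collection(c(
      list(planted = shared),
      stats::setNames(lapply(1:15, function(i) sample(rl$gene, 25)),
                      sprintf("r%02d_%d", 1:15, seed))))
    preranked_gsea(rl, coll, n_perm = 100, seed = seed)
  }
  results <- list(a1 = mk_res(1), a2 = mk_res(2))
  le <- leading_edge_analysis(results, top_n = 5)
  expect_equal(ncol(le$occurrence), 10L)
  expect_true(all(le$occurrence %in% 0:1))
  expect_true(all(le$le_fraction > 0 & le$le_fraction <= 1))
  # the planted set tops both analyses, so its leading edge replicates
  expect_true(all(attr(results$a1, "leading_edge")[[1]] %in% le$replicated))

  # disjoint leading edges across analyses -> empty replication list
  fake <- function(name, genes) {
    structure(data.frame(set = name, size = length(genes), es = 0.5,
                         nes = 2, p_value = 0.01, fdr_q = 0.01, peak = 5L),
              leading_edge = list(genes),
              class = c("enrichment_result", "data.frame"))
  }
  le2 <- leading_edge_analysis(list(x = fake("sx", c("A", "B")),
                                    y = fake("sy", c("C", "D"))), top_n = 1)
  expect_length(le2$replicated, 0L)

  expect_warning(leading_edge_analysis(list(only = mk_res(7)), top_n = 50),
                 "using all")
})

test_that("enrichment tables round-trip through TSV including leading edges", {
  rl <- mk_ranked(100, seed = 41)
  set.seed(42)
  coll <- gene_set_collection(stats::setNames(
    lapply(1:5, function(i) sample(rl$gene, 12)), paste0("S", 1:5)))
  res <- preranked_gsea(rl, coll, n_perm = 100, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_enrichment(path)
  expect_equal(back$es, res$es, tolerance = 1e-12)
  expect_identical(attr(back, "leading_edge"), attr(res, "leading_edge"))
})
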