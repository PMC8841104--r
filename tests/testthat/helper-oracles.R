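# Independent brute-force reference implementations used to cross-check the
# package's fast paths, plus small fixture generators. These deliberately
# re-derive everything from the definitions with plain loops.

# Random 0/1/2 dataset with balanced labels.
rand_dataset <- function(n, p, seed, miss_frac = 0) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("rs%03d", 1:p)))
  if (miss_frac > 0) g[sample(n * p, round(miss_frac * n * p))] <- NA
  y <- rep(0:1, length.out = n)[sample(n)]
  genotype_dataset(g, y)
}

# Exhaustive Relief scorer: enumerates every instance pair, recomputes the
# distance and the per-instance thresholds from scratch.
oracle_relief <- function(g, y, star = FALSE) {
  n <- nrow(g); p <- ncol(g)
  d <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    d[i, j] <- if (sum(ok) == 0) NA else sum(g[i, ok] != g[j, ok]) / sum(ok)
  }
  total <- numeric(p)
  for (i in 1:n) {
    dj <- d[i, ]; valid <- which(!is.na(dj))
    if (!length(valid)) next
    mu <- mean(dj[valid]); sdv <- sqrt(mean((dj[valid] - mu)^2))
    near <- valid[dj[valid] < mu - sdv / 2]
    far  <- valid[dj[valid] > mu + sdv / 2]
    diffv <- function(j) {
      as.numeric(ifelse(is.na(g[i, ]) | is.na(g[j, ]), 0, g[i, ] != g[j, ]))
    }
    grp <- function(js) {
      if (!length(js)) return(NULL)
      rowMeans(vapply(js, diffv, numeric(p)))
    }
    delta <- numeric(p)
    nh <- grp(near[y[near] == y[i]]); nm <- grp(near[y[near] != y[i]])
    if (!is.null(nm)) delta <- delta + nm
    if (!is.null(nh)) delta <- delta - nh
    if (star) {
      fh <- grp(far[y[far] == y[i]]); fm <- grp(far[y[far] != y[i]])
      if (!is.null(fh)) delta <- delta + fh
      if (!is.null(fm)) delta <- delta - fm
    }
    total <- total + delta
  }
  total / (if (star) 2 * n else n)
}

# Step-by-step running-sum walk, straight from the definition.
oracle_es_walk <- function(scores_desc, hit, p = 1) {
  N <- length(scores_desc)
  nr <- sum(abs(scores_desc[hit])^p)
  run <- numeric(N); cur <- 0
  for (i in 1:N) {
    cur <- cur + if (hit[i]) abs(scores_desc[i])^p / nr
                 else -1 / (N - sum(hit))
    run[i] <- cur
  }
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak, running = run)
}

# Pairwise squared Pearson correlation by explicit sums.
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]; n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  (num / den)^2
}

# Random Mendelian-consistent trios: child alleles drawn from the parents.
rand_trios <- function(n_trios, n_snps, seed, maf = 0.3) {
  set.seed(seed)
  transmit <- function(g) ifelse(g == 0L, 0L, ifelse(g == 2L, 1L,
                                                     rbinom(length(g), 1L, 0.5)))
  f <- matrix(rbinom(n_trios * n_snps, 2L, maf), n_trios, n_snps)
  m <- matrix(rbinom(n_trios * n_snps, 2L, maf), n_trios, n_snps)
  cld <- matrix(transmit(f) + transmit(m), n_trios, n_snps)
  dn <- list(sprintf("trio%04d", 1:n_trios), sprintf("rs%04d", 1:n_snps))
  dimnames(f) <- dimnames(m) <- dimnames(cld) <- dn
  trio_dataset(f, m, cld)
}
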