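#' Hardy-Weinberg genotype frequencies
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Numeric vector of length 3: frequencies of genotypes 0, 1, 2.
#' @export
hwe_freqs <- function(maf) {
  if (maf <= 0 || maf > 0.5) stop("`maf` must be in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Population prevalence of a two-locus penetrance table
#'
#' K = sum over the nine joint genotypes of the HWE genotype frequencies
#' times the penetrance: `K = sum_ij p_i q_j f_ij`.
#'
#' @param table 3x3 numeric matrix of penetrances `f_ij` in \[0, 1\], rows
#'   indexed by genotype count 0/1/2 at locus A, columns at locus B.
#' @param maf_a,maf_b Minor allele frequencies of the two loci.
#' @return Prevalence in \[0, 1\].
#' @export
prevalence <- function(table, maf_a, maf_b) {
  check_pen_table(table)
  sum(outer(hwe_freqs(maf_a), hwe_freqs(maf_b)) * table)
}

#' Broad-sense heritability of a two-locus penetrance table
#'
#' The variance in disease liability explained by the joint genotype, on
#' the scale of the binary trait:
#' `h2 = sum_ij p_i q_j (f_ij - K)^2 / (K (1 - K))`
#' with `K` the model prevalence under HWE.
#'
#' @inheritParams prevalence
#' @return Heritability in \[0, 1).
#' @export
heritability <- function(table, maf_a, maf_b) {
  check_pen_table(table)
  w <- outer(hwe_freqs(maf_a), hwe_freqs(maf_b))
  K <- sum(w * table)
  if (K <= 0 || K >= 1)
    stop("heritability undefined: prevalence is 0 or 1")
  sum(w * (table - K)^2) / (K * (1 - K))
}

check_pen_table <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(3L, 3L)))
    stop("penetrance table must be a 3x3 matrix")
  if (anyNA(table) || any(table < 0 | table > 1))
    stop("penetrances must lie in [0, 1]")
  invisible(table)
}

#' Construct a validated two-locus penetrance model
#'
#' Checks the purity conditions (both single-locus marginal penetrances
#' constant and equal to the prevalence) that make the model a *pure*
#' epistatic model with no main effects, and records prevalence and
#' heritability.
#'
#' @inheritParams prevalence
#' @param tol Residual tolerance for the purity check.
#' @return An object of class `penetrance_model` with elements `table`,
#'   `maf_a`, `maf_b`, `K`, `h2`.
#' @export
penetrance_model <- function(table, maf_a, maf_b, tol = 1e-9) {
  check_pen_table(table)
  p <- hwe_freqs(maf_a); q <- hwe_freqs(maf_b)
  K <- prevalence(table, maf_a, maf_b)
  row_marg <- as.vector(table %*% q)   # penetrance of each locus-A genotype
  col_marg <- as.vector(p %*% table)   # penetrance of each locus-B genotype
  if (max(abs(c(row_marg, col_marg) - K)) > tol)
    stop("table is not pure: single-locus marginal penetrances differ from K")
  structure(list(table = table, maf_a = maf_a, maf_b = maf_b,
                 K = K, h2 = heritability(table, maf_a, maf_b)),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("pure two-locus penetrance model: MAF (%.3g, %.3g), K = %.4g, h2 = %.4g\n",
              x$maf_a, x$maf_b, x$K, x$h2))
  tbl <- round(x$table, 4)
  dimnames(tbl) <- list(paste0("A=", 0:2), paste0("B=", 0:2))
  print(tbl)
  invisible(x)
}

# Orthonormal basis of penetrance deviations d_ij = f_ij - K satisfying the
# purity constraints sum_j q_j d_ij = 0 (each i) and sum_i p_i d_ij = 0
# (each j). The constraint matrix has rank 5, so the null space is 4-dim.
purity_null_space <- function(maf_a, maf_b) {
  p <- hwe_freqs(maf_a); q <- hwe_freqs(maf_b)
  C <- matrix(0, 6L, 9L)
  idx <- function(i, j) (j - 1L) * 3L + i        # column-major d vector
  for (i in 1:3) for (j in 1:3) {
    C[i, idx(i, j)] <- q[j]
    C[3L + j, idx(i, j)] <- p[i]
  }
  sv <- svd(C, nv = 9L)
  rank <- sum(sv$d > 1e-12)
  sv$v[, (rank + 1L):9L, drop = FALSE]
}

#' Generate a pure two-locus epistatic penetrance model
#'
#' Random generation of a 3x3 penetrance table with *exact* target
#' heritability and no single-locus main effects, in the spirit of the
#' GAMETES model family. The purity conditions define a linear system on
#' the deviations `d_ij = f_ij - K`; a random direction is drawn in its
#' null space and rescaled by the unique positive factor that sets the
#' heritability to `h2_target`. Draws whose penetrances leave \[0, 1\] are
#' rejected and resampled.
#'
#' Not every (MAF, K, h2) combination is attainable: purity plus the
#' \[0, 1\] box bound the achievable heritability (at MAF 0.2 the maximum
#' is about 0.34 at K = 0.25 and 0.47 at K = 0.4). The generator fails
#' with a hint when the retry cap is hit.
#'
#' @param maf Minor allele frequency shared by both loci, in (0, 0.5].
#' @param h2_target Target heritability in (0, 1).
#' @param K Population prevalence in (0, 1); default 0.35.
#' @param seed Optional integer seed.
#' @param max_tries Retry cap for the accept/reject loop.
#' @return A [penetrance_model()] with `h2` equal to `h2_target` to within
#'   1e-9 and purity residuals below 1e-9.
#' @export
gen_penetrance_model <- function(maf, h2_target, K = 0.35, seed = NULL,
                                 max_tries = 10000L) {
  if (h2_target <= 0 || h2_target >= 1) stop("`h2_target` must be in (0, 1)")
  if (K <= 0 || K >= 1) stop("`K` must be in (0, 1)")
  N <- purity_null_space(maf, maf)
  w <- as.vector(outer(hwe_freqs(maf), hwe_freqs(maf)))
  denom <- K * (1 - K)
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(max_tries)) {
    d <- as.vector(N %*% stats::rnorm(ncol(N)))
    h2_raw <- sum(w * d^2) / denom
    if (h2_raw <= 0) next
    f <- K + d * sqrt(h2_target / h2_raw)
    if (all(f >= 0 & f <= 1)) {
      return(penetrance_model(matrix(f, 3L, 3L), maf, maf))
    }
  }
  stop(sprintf(paste0("no pure model with h2 = %g found at MAF %g, K = %g ",
                      "after %d tries; try a smaller h2 or K nearer 0.4"),
               h2_target, maf, K, max_tries))
}
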