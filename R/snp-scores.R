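#' @useDynLib episgsea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a per-SNP feature-score table
#'
#' @param snp_id Character vector of rsIDs.
#' @param score One numeric importance score per SNP.
#' @param method Scoring method tag: one of `"chi2_allelic"`,
#'   `"chi2_genotypic"`, `"multisurf"`, `"multisurf_star"`.
#' @param n_samples Number of samples the scores were computed from.
#' @return A data frame of class `feature_scores` with columns `snp_id`,
#'   `score`.
#' @export
feature_scores <- function(snp_id, score, method, n_samples = NA_integer_) {
  stopifnot(length(snp_id) == length(score))
  if (startsWith(method, "multisurf") &&
      any(abs(score) > 1 + 1e-12, na.rm = TRUE))
    stop("Relief scores must lie in [-1, 1]")
  structure(data.frame(snp_id = as.character(snp_id), score = score,
                       stringsAsFactors = FALSE),
            method = method, n_samples = as.integer(n_samples),
            class = c("feature_scores", "data.frame"))
}

#' Write per-SNP scores as TSV
#' @param x A `feature_scores` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  out <- data.frame(snp_id = x$snp_id, score = x$score,
                    method = attr(x, "method"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP scores from TSV
#' @param path Path to a table written by [write_scores()].
#' @return A `feature_scores` table.
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  feature_scores(df$snp_id, df$score, df$method[1L])
}

#' Univariate chi-square association scores
#'
#' Pearson chi-square statistic per SNP comparing cases with controls,
#' used purely as a ranking statistic (no multiple-testing correction).
#' `mode = "genotypic"` contrasts the 0/1/2 genotype distributions (2 x up
#' to 3 table, df = observed genotype classes - 1); `mode = "allelic"`
#' contrasts allele counts (2 x 2 table, 1 df). Missing genotypes are
#' dropped per SNP; monomorphic SNPs score 0.
#'
#' @param x A [genotype_dataset()] with both phenotype classes present.
#' @param mode `"genotypic"` (default) or `"allelic"`.
#' @return A [feature_scores()] table.
#' @export
chi2_scores <- function(x, mode = c("genotypic", "allelic")) {
  stopifnot(inherits(x, "genotype_dataset"))
  mode <- match.arg(mode)
  y <- x$phenotype
  if (length(unique(y)) < 2L) stop("both phenotype classes must be present")
  g <- x$genotypes
  score <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]; ok <- !is.na(gj)
    gj <- gj[ok]; yj <- y[ok]
    if (length(unique(gj)) < 2L || length(unique(yj)) < 2L) return(0)
    if (mode == "genotypic") {
      tab <- table(factor(yj, levels = 0:1), gj)
    } else {
      minor <- tapply(gj, yj, sum)                 # minor-allele counts
      major <- tapply(2L - gj, yj, sum)
      tab <- cbind(minor, major)
      if (any(colSums(tab) == 0L)) return(0)
    }
    unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
  }, numeric(1L))
  feature_scores(colnames(g), score,
                 paste0("chi2_", mode), nrow(g))
}

#' Pairwise genotype mismatch distances
#'
#' Distance between two samples = number of SNPs with differing
#' non-missing genotypes divided by the number of jointly non-missing
#' SNPs. The Relief algorithms derive their adaptive neighbourhood
#' thresholds from this matrix.
#'
#' @param x A [genotype_dataset()].
#' @return Symmetric numeric matrix with zero diagonal; `NA` where a
#'   sample pair shares no non-missing SNP.
#' @export
pairwise_distances <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  d <- cpp_pairwise_dist(x$genotypes)
  dimnames(d) <- list(sample_ids(x), sample_ids(x))
  d
}

relief_check <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (nrow(x$genotypes) < 3L) stop("Relief scoring needs at least 3 samples")
  if (length(unique(x$phenotype)) < 2L)
    stop("both phenotype classes must be present")
}

#' MultiSURF feature importance scores
#'
#' For each target instance, instances closer than the adaptive threshold
#' (mean pairwise distance minus half its standard deviation) form the
#' near neighbourhood. Features whose values differ between the target and
#' a near *miss* (different class) gain score; differences against near
#' *hits* (same class) lose score. Group averages are summed over targets
#' and divided by the sample count, so scores fall in \[-1, 1\]; higher
#' means more phenotype-relevant, with sensitivity to both univariate and
#' interaction effects.
#'
#' @param x A [genotype_dataset()].
#' @param diff `"discrete"` (0/1 genotype mismatch, default) or
#'   `"continuous"` (`|a - b| / 2`).
#' @return A [feature_scores()] table, method `"multisurf"`.
#' @export
multisurf_scores <- function(x, diff = c("discrete", "continuous")) {
  relief_check(x)
  diff <- match.arg(diff)
  s <- cpp_relief_scores(x$genotypes, x$phenotype, FALSE,
                         diff == "continuous")
  feature_scores(snp_ids(x), s, "multisurf", nrow(x$genotypes))
}

#' MultiSURF* feature importance scores
#'
#' Extends [multisurf_scores()] with the far neighbourhood (distance above
#' mean plus half standard deviation) scored with inverted sign: far hits
#' with differing values gain score, far misses lose it. The summed near
#' and far contributions are divided by twice the sample count, keeping
#' scores in \[-1, 1\]. This variant is more sensitive to pure interaction
#' effects at the cost of univariate sensitivity.
#'
#' @inheritParams multisurf_scores
#' @return A [feature_scores()] table, method `"multisurf_star"`.
#' @export
multisurf_star_scores <- function(x, diff = c("discrete", "continuous")) {
  relief_check(x)
  diff <- match.arg(diff)
  s <- cpp_relief_scores(x$genotypes, x$phenotype, TRUE,
                         diff == "continuous")
  feature_scores(snp_ids(x), s, "multisurf_star", nrow(x$genotypes))
}

#' Cross-validated average of per-SNP scores
#'
#' Splits the samples into `k` stratified folds, scores the training
#' portion (k - 1 folds) of each, and averages the k score vectors per
#' SNP. Averaging over folds damps the variance of the Relief scores.
#'
#' @param x A [genotype_dataset()].
#' @param method A scoring function `(dataset) -> feature_scores`, e.g.
#'   [multisurf_scores()], or one of the strings `"chi2"`, `"multisurf"`,
#'   `"multisurf_star"`.
#' @param k Number of folds (>= 2); default 10.
#' @param seed Integer seed for the fold assignment.
#' @param on_held_out Score the held-out fold instead of the training
#'   portion (default `FALSE`).
#' @return A [feature_scores()] table of fold-averaged scores.
#' @export
cv_average_scores <- function(x, method, k = 10L, seed = 1L,
                              on_held_out = FALSE) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (k < 2L) stop("`k` must be at least 2")
  if (is.character(method)) {
    method <- switch(method,
                     chi2 = chi2_scores,
                     multisurf = multisurf_scores,
                     multisurf_star = multisurf_star_scores,
                     stop("unknown method '", method, "'"))
  }
  y <- x$phenotype
  if (min(table(y)) < k) stop("each phenotype class needs at least k samples")
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  per_fold <- lapply(seq_len(k), function(f) {
    sel <- if (on_held_out) fold == f else fold != f
    method(subset_dataset(x, samples = which(sel)))
  })
  mats <- vapply(per_fold, `[[`, numeric(ncol(x$genotypes)), "score")
  feature_scores(snp_ids(x), rowMeans(mats),
                 attr(per_fold[[1L]], "method"), nrow(x$genotypes))
}
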