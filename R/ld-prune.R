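#' Prune SNPs in linkage disequilibrium
#'
#' Greedy sliding-window LD pruning of a genotype dataset, in the style of
#' PLINK's `--indep-pairwise`. Within each window of `window` SNPs, every
#' pair with squared Pearson genotype correlation above `r2_max` loses its
#' later member (the earlier SNP is kept); the window then slides forward by
#' `step` SNPs. SNPs are considered in (chromosome, position) order when
#' coordinates are attached, otherwise in input order; windows never span
#' chromosomes.
#'
#' Missing genotypes are excluded pairwise from the correlation; pairs with
#' fewer than 3 complete observations, or involving a monomorphic SNP, are
#' treated as uncorrelated.
#'
#' @param x A [genotype_dataset()].
#' @param r2_max Squared-correlation threshold in (0, 1]; default 0.2.
#' @param window Window size in SNPs (>= 2); default 50.
#' @param step Slide in SNPs; default 5.
#' @return A `genotype_dataset` containing the surviving SNPs in their
#'   original column order.
#' @export
ld_prune <- function(x, r2_max = 0.2, window = 50L, step = 5L) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (!(r2_max > 0 && r2_max <= 1)) stop("`r2_max` must be in (0, 1]")
  if (window < 2) stop("`window` must be at least 2")
  if (step < 1) stop("`step` must be at least 1")
  p <- ncol(x$genotypes)
  if (p < 2) return(x)

  if (!is.null(x$positions)) {
    ord <- order(x$positions$chrom, x$positions$bp)
    chrom <- x$positions$chrom[ord]
  } else {
    ord <- seq_len(p)
    chrom <- rep("", p)
  }
  g <- x$genotypes[, ord, drop = FALSE]
  storage.mode(g) <- "double"
  alive <- rep(TRUE, p)

  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[alive[win]]
      if (length(win) >= 2L) {
        r2 <- suppressWarnings(
          stats::cor(g[, win, drop = FALSE], use = "pairwise.complete.obs"))^2
        nobs <- crossprod(!is.na(g[, win, drop = FALSE]))
        r2[is.na(r2) | nobs < 3L] <- 0
        for (i in seq_len(length(win) - 1L)) {
          if (!alive[win[i]]) next
          for (j in seq(i + 1L, length(win))) {
            if (alive[win[j]] && r2[i, j] > r2_max) alive[win[j]] <- FALSE
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  subset_dataset(x, snps = sort(ord[alive]))
}
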