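#' Assign SNPs to genes by positional windows
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' `window_bp` of the gene body: with the SNP's 0-based position
#' `bp0 = bp - 1` and the gene's 0-based half-open interval
#' `[start, end)`, the SNP maps iff
#' `start - window_bp <= bp0 < end + window_bp`. One SNP may map to
#' several overlapping genes; SNPs mapping nowhere are reported in the
#' `unmapped` attribute.
#'
#' @param positions Data frame with columns `snp_id`, `chrom`, `bp`
#'   (1-based), e.g. the `positions` slot of a [genotype_dataset()].
#' @param genes A [gene_table()].
#' @param window_bp Window in base pairs on each side of the gene
#'   (default 10000).
#' @return Named list mapping gene symbol to a character vector of rsIDs
#'   (genes with no SNPs are omitted), with attribute `unmapped`.
#' @export
map_snps_to_genes <- function(positions, genes, window_bp = 10000L) {
  if (window_bp < 0) stop("`window_bp` must be non-negative")
  positions <- as.data.frame(positions)
  stopifnot(all(c("snp_id", "chrom", "bp") %in% names(positions)))
  mapping <- stats::setNames(vector("list", nrow(genes)), genes$symbol)
  hit_any <- rep(FALSE, nrow(positions))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    si <- which(positions$chrom == chr)
    if (length(si) == 0L) next
    # 0-based half-open windows -> 1-based closed IRanges
    win <- IRanges::IRanges(start = genes$start[gi] - window_bp + 1L,
                            end = genes$end[gi] + window_bp)
    snp <- IRanges::IRanges(start = positions$bp[si], width = 1L)
    ov <- IRanges::findOverlaps(snp, win)
    if (length(ov) > 0L) {
      hit_any[si[S4Vectors::queryHits(ov)]] <- TRUE
      sp <- split(positions$snp_id[si[S4Vectors::queryHits(ov)]],
                  S4Vectors::subjectHits(ov))
      for (k in names(sp)) {
        gidx <- gi[as.integer(k)]
        mapping[[gidx]] <- c(mapping[[gidx]], sp[[k]])
      }
    }
  }
  mapping <- mapping[!vapply(mapping, is.null, TRUE)]
  structure(mapping, unmapped = positions$snp_id[!hit_any])
}

#' Aggregate SNP scores into a ranked gene list
#'
#' Summarizes each gene's assigned SNP scores into a single gene score
#' (default: the maximum), the statistic fed to pre-ranked GSEA. Genes
#' with no assigned SNPs are dropped; a gene whose SNPs are all absent
#' from the score table is an error.
#'
#' @param mapping Gene-to-SNPs list from [map_snps_to_genes()].
#' @param scores A [feature_scores()] table covering the mapped SNPs.
#' @param agg Aggregation function (default `max`).
#' @return A [ranked_gene_list()] tagged with the scoring method.
#' @export
gene_scores <- function(mapping, scores, agg = max) {
  if (length(mapping) == 0L) stop("empty gene-to-SNP mapping")
  lookup <- stats::setNames(scores$score, scores$snp_id)
  s <- vapply(names(mapping), function(g) {
    v <- lookup[mapping[[g]]]
    if (all(is.na(v)))
      stop("no scores available for any SNP of gene '", g, "'")
    agg(v[!is.na(v)])
  }, numeric(1L))
  ranked_gene_list(names(mapping), unname(s), method = attr(scores, "method"))
}

#' Spearman rank correlation between two ranked gene lists
#'
#' Computed on the intersection of gene symbols with average-rank tie
#' handling and a two-sided p-value.
#'
#' @param a,b [ranked_gene_list()] objects.
#' @return List with `rho`, `p_value` and `n_genes` (intersection size).
#' @export
rank_correlation <- function(a, b) {
  common <- intersect(a$gene, b$gene)
  if (length(common) < 3L)
    stop("need at least 3 shared genes to correlate ranks")
  sa <- a$score[match(common, a$gene)]
  sb <- b$score[match(common, b$gene)]
  ct <- suppressWarnings(
    stats::cor.test(sa, sb, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(common))
}
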