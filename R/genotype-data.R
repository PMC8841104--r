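#' Construct a genotype dataset
#'
#' Container for a samples-by-SNPs matrix of additively coded genotypes
#' (0/1/2 copies of the variant allele, `NA` for missing) together with a
#' binary phenotype and optional SNP coordinates.
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns.
#'   Row names are sample identifiers, column names are rsIDs; both must be
#'   unique. Entries must be 0, 1, 2 or `NA`.
#' @param phenotype Integer vector, one value per sample; 0 = control,
#'   1 = case. No missing values are allowed.
#' @param positions Optional data frame with columns `snp_id`, `chrom` and
#'   `bp` (1-based physical position) covering every SNP in `genotypes`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype` and `positions`.
#' @export
genotype_dataset <- function(genotypes, phenotype, positions = NULL) {
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  if (is.null(colnames(genotypes)) ||
      (nrow(genotypes) > 0L && is.null(rownames(genotypes))))
    stop("`genotypes` must carry sample ids (rownames) and rsIDs (colnames)")
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(genotypes)))
    stop("duplicate rsIDs: ", paste(unique(colnames(genotypes)[duplicated(colnames(genotypes))]), collapse = ", "))
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype out of {0,1,2} at sample '%s', SNP '%s'",
                 rownames(genotypes)[w[1L]], colnames(genotypes)[w[2L]]))
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("`phenotype` length must equal the number of samples")
  if (anyNA(phenotype) || !all(phenotype %in% 0:1))
    stop("`phenotype` must be 0/1 with no missing values")
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    need <- c("snp_id", "chrom", "bp")
    if (!all(need %in% names(positions)))
      stop("`positions` needs columns snp_id, chrom, bp")
    if (!all(colnames(genotypes) %in% positions$snp_id))
      stop("`positions` must cover every SNP")
    positions <- positions[match(colnames(genotypes), positions$snp_id),
                           need, drop = FALSE]
    rownames(positions) <- NULL
    if (any(positions$bp < 1)) stop("`bp` must be a positive 1-based position")
  }
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 positions = positions),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs (%d cases, %d controls)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0) cat(sprintf("  missing genotypes: %d\n", nmiss))
  if (!is.null(x$positions)) cat("  SNP coordinates attached\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Sample identifiers of a genotype dataset
#' @param x A `genotype_dataset`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$genotypes)

#' SNP identifiers of a genotype dataset
#' @param x A `genotype_dataset`.
#' @return Character vector of rsIDs.
#' @export
snp_ids <- function(x) colnames(x$genotypes)

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param samples,snps Index vectors (integer, logical or character) into the
#'   samples / SNPs; `NULL` keeps all.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  g <- x$genotypes
  if (is.null(samples)) samples <- seq_len(nrow(g))
  if (is.null(snps)) snps <- seq_len(ncol(g))
  if (is.character(samples)) samples <- match(samples, rownames(g))
  g2 <- g[samples, snps, drop = FALSE]
  pos <- x$positions
  if (!is.null(pos)) pos <- pos[match(colnames(g2), pos$snp_id), , drop = FALSE]
  if (is.logical(samples)) samples <- which(samples)
  genotype_dataset(g2, x$phenotype[samples], pos)
}

#' Read a genotype table
#'
#' Reads a delimited text table of additively coded genotypes: a header row
#' with a sample-id column, one column per rsID and a final phenotype
#' column, then one row per sample.
#'
#' @param path Path to the text file.
#' @param sep Field separator (default tab).
#' @param missing Token encoding a missing genotype (default `"NA"`).
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, sep = "\t", missing = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0))
  if (!"sample_id" %in% names(df) || !"phenotype" %in% names(df))
    stop("genotype table needs 'sample_id' and 'phenotype' columns")
  rsids <- names(df)[!names(df) %in% c("sample_id", "phenotype")]
  if (anyDuplicated(rsids))
    stop("duplicate rsID in header: ",
         paste(unique(rsids[duplicated(rsids)]), collapse = ", "))
  raw <- as.matrix(df[, rsids, drop = FALSE])
  raw[raw == missing] <- NA_character_
  bad <- !is.na(raw) & !(raw %in% c("0", "1", "2"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype token '%s' at row %d, column '%s'",
                 raw[w[1L], w[2L]], w[1L], rsids[w[2L]]))
  }
  g <- matrix(as.integer(raw), nrow = nrow(raw), ncol = length(rsids),
              dimnames = list(if (nrow(raw) > 0L) df$sample_id, rsids))
  genotype_dataset(g, as.integer(df$phenotype))
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: emits the tab-delimited 0/1/2 table
#' with `sample_id` first and `phenotype` last.
#'
#' @param x A `genotype_dataset`.
#' @param path Output path.
#' @param sep Field separator.
#' @param missing Token to emit for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, sep = "\t", missing = "NA") {
  stopifnot(inherits(x, "genotype_dataset"))
  g <- x$genotypes
  chr <- matrix(as.character(g), nrow = nrow(g), ncol = ncol(g),
                dimnames = dimnames(g))
  chr[is.na(chr)] <- missing
  sid <- if (is.null(rownames(g))) character(0) else rownames(g)
  out <- data.frame(sample_id = sid, chr,
                    phenotype = x$phenotype,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
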