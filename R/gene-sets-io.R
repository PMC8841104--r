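#' Read a GMT gene-set collection
#'
#' GMT is tab-delimited with one gene set per line: name, description, then
#' member gene symbols. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of
#'   gene symbols, with per-set descriptions in `attr(,"description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, vapply(parts, `[[`, "", 2L))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene symbols per set).
#' @param description Optional character vector of per-set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) > 0L) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("sets must be uniquely named")
    if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  }
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, description = stats::setNames(description, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets", length(x)))
  if (length(x) > 0L)
    cat(sprintf(" (sizes %d-%d)", min(lengths(x)), max(lengths(x))))
  cat("\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param x A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- rep("", length(x))
  lines <- vapply(seq_along(x), function(i)
    paste(c(names(x)[i], desc[[i]], x[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked gene list (RNK)
#'
#' Two tab-delimited columns, gene symbol and score, no header. Rows may be
#' in any order; the result is sorted by decreasing score with ties broken
#' by gene symbol.
#'
#' @param path Path to an RNK file.
#' @param method Optional tag recording how the scores were produced.
#' @return A [ranked_gene_list()].
#' @export
read_rnk <- function(path, method = NA_character_) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "character"),
                          stringsAsFactors = FALSE, quote = "")
  score <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(score))
    stop(sprintf("non-numeric score '%s' for gene '%s'",
                 df[[2L]][which(is.na(score))[1L]],
                 df[[1L]][which(is.na(score))[1L]]))
  ranked_gene_list(df[[1L]], score, method = method)
}

#' Construct a ranked gene list
#'
#' The pre-ranked GSEA input: unique gene symbols with one summary score
#' each, ordered by decreasing score (ties broken lexicographically by
#' symbol for determinism).
#'
#' @param gene Character vector of gene symbols (unique).
#' @param score Numeric score per gene.
#' @param method Optional tag recording the scoring method.
#' @return A data frame of class `ranked_gene_list` with columns `gene` and
#'   `score`, sorted.
#' @export
ranked_gene_list <- function(gene, score, method = NA_character_) {
  if (anyDuplicated(gene))
    stop("duplicate gene symbol: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  if (length(gene) != length(score)) stop("gene/score length mismatch")
  o <- order(-score, gene)
  structure(data.frame(gene = gene[o], score = score[o],
                       stringsAsFactors = FALSE),
            method = method, class = c("ranked_gene_list", "data.frame"))
}

#' Write a ranked gene list as RNK
#' @param x A `ranked_gene_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(x, path) {
  stopifnot(inherits(x, "ranked_gene_list"))
  utils::write.table(data.frame(x$gene, format(x$score, trim = TRUE,
                                               scientific = FALSE, digits = 15)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene coordinate table
#'
#' Tab-delimited, no header: chromosome, start, end, gene symbol, with
#' 0-based half-open intervals (BED convention).
#'
#' @param path Path to the table.
#' @return A `gene_table` data frame with columns `chrom`, `start`, `end`,
#'   `symbol`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "symbol"),
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          stringsAsFactors = FALSE, quote = "")
  gene_table(df$chrom, df$start, df$end, df$symbol)
}

#' Construct a gene coordinate table
#'
#' @param chrom Chromosome name per gene.
#' @param start,end Integer 0-based half-open interval bounds, `start < end`.
#' @param symbol Unique gene symbols.
#' @return A data frame of class `gene_table`.
#' @export
gene_table <- function(chrom, start, end, symbol) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("gene intervals require start < end")
  if (anyDuplicated(symbol))
    stop("duplicate gene symbol: ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       symbol = as.character(symbol),
                       stringsAsFactors = FALSE),
            class = c("gene_table", "data.frame"))
}

#' Write a gene coordinate table
#' @param x A `gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "symbol")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
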