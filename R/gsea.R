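#' Filter gene sets by in-universe size
#'
#' Each set is first restricted to the genes present in the ranked list,
#' then kept iff its remaining size lies in `[min_size, max_size]`
#' (inclusive).
#'
#' @param collection A [gene_set_collection()].
#' @param ranked A [ranked_gene_list()] defining the gene universe.
#' @param min_size,max_size Inclusive size bounds (defaults 20 and 200).
#' @return A filtered `gene_set_collection` whose members all lie in the
#'   universe.
#' @export
filter_gene_sets <- function(collection, ranked, min_size = 20L,
                             max_size = 200L) {
  if (min_size > max_size) stop("`min_size` must not exceed `max_size`")
  universe <- ranked$gene
  trimmed <- lapply(collection, intersect, universe)
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  gene_set_collection(trimmed[keep],
                      attr(collection, "description")[names(collection)[keep]])
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom. Genes in the set ("hits")
#' advance the sum by `|score|^p / N_R` (with `N_R` the sum of `|score|^p`
#' over hits); genes outside it retreat by `1 / (N - N_H)`. The
#' enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed, first occurrence on ties). When every hit
#' has score 0 the walk falls back to unweighted increments (`p = 0`)
#' with a warning.
#'
#' @param ranked A [ranked_gene_list()].
#' @param gene_set Character vector of gene symbols, a non-empty proper
#'   subset of the universe.
#' @param p Weighting exponent (default 1).
#' @return List with `es`, `peak` (1-based rank index of the extremum)
#'   and `running` (the full running-sum profile).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  n_h <- sum(hit)
  if (n_h == 0L) stop("gene set has no member in the ranked universe")
  if (n_h == N) stop("gene set equals the ranked universe")
  w <- abs(ranked$score[hit])^p
  if (sum(w) == 0) {
    warning("all hit scores are zero; falling back to unweighted (p = 0) increments")
    w <- rep(1, n_h)
  }
  steps <- rep(-1 / (N - n_h), N)
  steps[hit] <- w / sum(w)
  running <- cumsum(steps)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

# Enrichment score from sorted hit positions only (no profile); exact same
# extremum rule as the full walk. `w` are the |score|^p weights at `pos`.
es_from_hits <- function(pos, w, N) {
  m <- length(pos)
  if (sum(w) == 0) w <- rep(1, m)
  miss <- 1 / (N - m)
  cw <- cumsum(w) / sum(w)
  gaps <- (pos - seq_len(m)) * miss
  A <- cw - gaps                 # running sum at each hit position
  B <- c(0, cw[-m]) - gaps       # running sum just before each hit
  ka <- which.max(A); kb <- which.min(B)
  maxA <- A[ka]; minB <- min(B[kb], 0)
  if (abs(maxA) > abs(minB)) return(maxA)
  if (abs(minB) > abs(maxA)) return(minB)
  # tie on |value|: the walk reports the first occurrence
  if (pos[kb] - 1L < pos[ka]) minB else maxA
}

#' Pre-ranked gene set enrichment analysis
#'
#' Competitive GSEA on a user-supplied ranked gene list with a gene-set
#' permutation null: for every gene set the observed running-sum
#' enrichment score (ES) is compared with `n_perm` same-size random gene
#' draws from the universe. The normalized score is
#' `NES = ES / mean(|null ES| of the same sign)`; the nominal p-value is
#' the fraction of same-sign null ES at least as extreme (floored at
#' `1 / (n_perm + 1)`). The FDR q-value pools the sign-matched normalized
#' null scores across all sets:
#' `q = P(|null NES| >= |NES|) / P(|observed NES| >= |NES|)`, clipped to
#' \[0, 1\] and made monotone non-increasing in `|NES|` within each sign.
#'
#' @param ranked A [ranked_gene_list()].
#' @param collection A [gene_set_collection()], typically already passed
#'   through [filter_gene_sets()].
#' @param n_perm Number of gene-set permutations (>= 10; default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param p Running-sum weighting exponent (default 1).
#' @return A data frame of class `enrichment_result` with one row per
#'   set: `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`, `peak`, and a
#'   list-column `leading_edge`.
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                           p = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (n_perm < 10L) stop("`n_perm` must be at least 10")
  if (length(collection) == 0L) stop("empty gene-set collection")
  N <- nrow(ranked)
  wall <- abs(ranked$score)^p
  set.seed(as.integer(seed))

  obs <- lapply(collection, function(gs) {
    r <- enrichment_score(ranked, gs, p = p)
    le <- leading_edge_genes(ranked, gs, r$es, r$peak)
    m <- sum(ranked$gene %in% gs)
    null_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(N, m))
      es_from_hits(pos, wall[pos], N)
    }, numeric(1L))
    list(es = r$es, peak = r$peak, size = m, le = le, null = null_es)
  })

  es <- vapply(obs, `[[`, 0, "es")
  nes <- numeric(length(obs)); null_nes <- vector("list", length(obs))
  p_nom <- numeric(length(obs))
  for (i in seq_along(obs)) {
    nul <- obs[[i]]$null
    pos_mean <- mean(nul[nul > 0]); neg_mean <- mean(abs(nul[nul < 0]))
    norm <- ifelse(nul > 0, nul / pos_mean, ifelse(nul < 0, nul / neg_mean, 0))
    null_nes[[i]] <- norm[is.finite(norm)]
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul <= 0]
    if (length(same) == 0L) {
      nes[i] <- NA_real_; p_nom[i] <- NA_real_
    } else {
      denom <- mean(abs(same))
      nes[i] <- if (denom > 0) es[i] / denom else NA_real_
      p_nom[i] <- max(mean(abs(same) >= abs(es[i])), 1 / (n_perm + 1))
    }
  }

  pooled <- unlist(null_nes)
  q <- rep(NA_real_, length(obs))
  for (i in seq_along(obs)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- mean(pooled[pooled >= 0] >= abs(nes[i]))
      den <- mean(nes[!is.na(nes) & nes >= 0] >= abs(nes[i]))
    } else {
      num <- mean(abs(pooled[pooled <= 0]) >= abs(nes[i]))
      den <- mean(abs(nes[!is.na(nes) & nes <= 0]) >= abs(nes[i]))
    }
    q[i] <- if (den > 0) min(1, num / den) else NA_real_
  }
  # monotone non-increasing in |NES| within each sign
  for (sgn in c(1, -1)) {
    ok <- !is.na(nes) & !is.na(q)
    idx <- which(ok & if (sgn == 1) nes >= 0 else nes < 0)
    if (length(idx) > 1L) {
      o <- idx[order(-abs(nes[idx]))]
      q[o] <- rev(cummin(rev(q[o])))
    }
  }

  structure(data.frame(set = names(collection),
                       size = vapply(obs, `[[`, 0L, "size"),
                       es = es, nes = nes, p_value = p_nom, fdr_q = q,
                       peak = vapply(obs, `[[`, 0L, "peak"),
                       stringsAsFactors = FALSE, row.names = NULL),
            leading_edge = lapply(obs, `[[`, "le"),
            n_perm = n_perm,
            class = c("enrichment_result", "data.frame"))
}

leading_edge_genes <- function(ranked, gene_set, es, peak) {
  hit <- ranked$gene %in% gene_set
  if (es > 0) ranked$gene[hit & seq_len(nrow(ranked)) <= peak]
  else if (es < 0) ranked$gene[hit & seq_len(nrow(ranked)) >= peak]
  else character(0)
}

#' Leading-edge genes of a gene set
#'
#' The set members driving the enrichment signal: members ranked at or
#' before the running-sum peak for a positive ES, at or after it for a
#' negative ES.
#'
#' @param ranked A [ranked_gene_list()].
#' @param gene_set Character vector of gene symbols.
#' @param es_result Optional output of [enrichment_score()]; computed if
#'   missing.
#' @param p Weighting exponent used when `es_result` is computed here.
#' @return Character vector of leading-edge gene symbols (in rank order);
#'   empty with a warning when ES is exactly 0.
#' @export
leading_edge <- function(ranked, gene_set, es_result = NULL, p = 1) {
  if (is.null(es_result)) es_result <- enrichment_score(ranked, gene_set, p)
  if (es_result$es == 0) {
    warning("enrichment score is exactly 0; empty leading edge")
    return(character(0))
  }
  leading_edge_genes(ranked, gene_set, es_result$es, es_result$peak)
}

#' Cross-analysis leading-edge summary
#'
#' Restricts each analysis to its `top_n` gene sets (largest `|NES|`,
#' ties by smaller q then set name), and summarizes their leading edges:
#' a binary gene-by-set occurrence matrix, the fraction of each set on
#' its leading edge, per-gene occurrence counts, and the genes appearing
#' on a leading edge in *every* analysis (the replication construction).
#'
#' @param results Named list of [preranked_gsea()] results, one per
#'   analysis.
#' @param top_n Number of top sets per analysis (default 10).
#' @return A list of class `leading_edge_summary` with elements
#'   `occurrence` (genes x sets 0/1 matrix, columns `analysis|set`),
#'   `le_fraction`, `gene_counts` and `replicated`.
#' @export
leading_edge_analysis <- function(results, top_n = 10L) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("analysis", seq_along(results))
  picked <- lapply(names(results), function(an) {
    res <- results[[an]]
    le <- attr(res, "leading_edge")
    ok <- which(!is.na(res$nes))
    if (length(ok) < top_n)
      warning(sprintf("analysis '%s' has only %d usable sets; using all",
                      an, length(ok)))
    o <- ok[order(-abs(res$nes[ok]), res$fdr_q[ok], res$set[ok])]
    o <- o[seq_len(min(top_n, length(o)))]
    data.frame(analysis = an, set = res$set[o], size = res$size[o],
               le = I(le[o]), stringsAsFactors = FALSE)
  })
  picked <- do.call(rbind, picked)
  cols <- paste(picked$analysis, picked$set, sep = "|")
  genes <- sort(unique(unlist(picked$le)))
  occ <- matrix(0L, length(genes), length(cols),
                dimnames = list(genes, cols))
  for (k in seq_along(cols)) occ[match(picked$le[[k]], genes), k] <- 1L
  per_analysis_genes <- lapply(split(seq_along(cols), picked$analysis),
                               function(ix) unique(unlist(picked$le[ix])))
  structure(list(occurrence = occ,
                 le_fraction = stats::setNames(lengths(picked$le) / picked$size,
                                               cols),
                 gene_counts = rowSums(occ),
                 replicated = sort(Reduce(intersect, per_analysis_genes))),
            class = "leading_edge_summary")
}

#' @export
print.leading_edge_summary <- function(x, ...) {
  cat(sprintf("leading_edge_summary: %d genes x %d sets; %d gene(s) replicated across all analyses\n",
              nrow(x$occurrence), ncol(x$occurrence), length(x$replicated)))
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' @param x An `enrichment_result`.
#' @param path Output path. Leading-edge genes are comma-joined.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  out <- as.data.frame(x)
  out$leading_edge <- vapply(attr(x, "leading_edge"), paste, "",
                             collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment result table written by [write_enrichment()]
#' @param path Path to the TSV.
#' @return An `enrichment_result` data frame.
#' @export
read_enrichment <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  le <- strsplit(ifelse(is.na(df$leading_edge), "", df$leading_edge), ",",
                 fixed = TRUE)
  names(le) <- df$set
  df$leading_edge <- NULL
  structure(df, leading_edge = le,
            class = c("enrichment_result", "data.frame"))
}
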