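#' Construct a case-parent trio dataset
#'
#' Genotypes for father, mother and affected child over a shared SNP panel,
#' one row per trio.
#'
#' @param father,mother,child Integer matrices (trios x SNPs) with entries
#'   0/1/2 or `NA`, identical dimnames: trio ids in rows, rsIDs in columns.
#' @return An object of class `trio_dataset`.
#' @export
trio_dataset <- function(father, mother, child) {
  mats <- list(father = father, mother = mother, child = child)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m)) stop("`", nm, "` must be a matrix")
    storage.mode(m) <- "integer"
    if (any(!is.na(m) & !(m %in% 0:2)))
      stop("`", nm, "` has genotypes outside {0,1,2}")
    mats[[nm]] <- m
  }
  d <- dim(mats$father)
  if (!identical(d, dim(mats$mother)) || !identical(d, dim(mats$child)))
    stop("father/mother/child matrices must share dimensions")
  if (is.null(rownames(mats$father)) || is.null(colnames(mats$father)))
    stop("matrices must carry trio ids (rownames) and rsIDs (colnames)")
  if (anyDuplicated(rownames(mats$father))) stop("duplicate trio ids")
  if (anyDuplicated(colnames(mats$father))) stop("duplicate rsIDs")
  structure(mats, class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat(sprintf("trio_dataset: %d trios x %d SNPs\n",
              nrow(x$father), ncol(x$father)))
  invisible(x)
}

#' Read a trio genotype table
#'
#' Tab-delimited long format with header
#' `trio_id, snp_id, father, mother, child`, genotypes 0/1/2 or a missing
#' token.
#'
#' @param path Path to the table.
#' @param missing Missing-genotype token (default `"NA"`).
#' @return A [trio_dataset()].
#' @export
read_trio_table <- function(path, missing = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE,
                          na.strings = character(0))
  need <- c("trio_id", "snp_id", "father", "mother", "child")
  if (!all(need %in% names(df))) stop("trio table needs columns: ",
                                      paste(need, collapse = ", "))
  trios <- unique(df$trio_id); snps <- unique(df$snp_id)
  mk <- function(col) {
    v <- df[[col]]; v[v == missing] <- NA_character_
    m <- matrix(NA_integer_, length(trios), length(snps),
                dimnames = list(trios, snps))
    m[cbind(match(df$trio_id, trios), match(df$snp_id, snps))] <- as.integer(v)
    m
  }
  trio_dataset(mk("father"), mk("mother"), mk("child"))
}

#' Build pseudo-controls from case-parent trios
#'
#' For each trio the affected child becomes a case, and an artificial
#' control is formed from the parental alleles *not* transmitted to the
#' child: pseudo-control genotype = father + mother - child. Together the
#' case and its pseudo-control always carry all four parental alleles, so
#' their genotype sum equals father + mother at every SNP.
#'
#' A (trio, SNP) cell is set missing when any member is missing or when the
#' child genotype is Mendelian-inconsistent with the parents (e.g. two
#' homozygous-reference parents with a homozygous-variant child); a warning
#' reports the count. Trios with entirely missing child genotypes are
#' dropped.
#'
#' @param trios A [trio_dataset()].
#' @return A [genotype_dataset()] with `2 * n_trios` samples: one case
#'   (`<trio>_case`, phenotype 1) and one pseudo-control
#'   (`<trio>_pseudo`, phenotype 0) per trio.
#' @export
make_pseudo_controls <- function(trios) {
  stopifnot(inherits(trios, "trio_dataset"))
  f <- trios$father; m <- trios$mother; cld <- trios$child

  all_missing <- rowSums(!is.na(cld)) == 0L
  if (any(all_missing)) {
    warning(sprintf("dropping %d trio(s) with entirely missing child genotypes",
                    sum(all_missing)))
    f <- f[!all_missing, , drop = FALSE]
    m <- m[!all_missing, , drop = FALSE]
    cld <- cld[!all_missing, , drop = FALSE]
  }
  if (nrow(cld) == 0L) stop("no usable trios")

  # feasible child range given parental transmissions: a homozygous parent
  # always transmits its allele
  cmin <- (f == 2L) + (m == 2L)
  cmax <- 2L - ((f == 0L) + (m == 0L))
  inconsistent <- !is.na(f) & !is.na(m) & !is.na(cld) &
    (cld < cmin | cld > cmax)
  if (any(inconsistent))
    warning(sprintf("%d Mendelian-inconsistent (trio, SNP) genotype(s) set missing",
                    sum(inconsistent)))

  pseudo <- f + m - cld
  pseudo[inconsistent] <- NA_integer_
  case <- cld
  case[inconsistent] <- NA_integer_

  rownames(case) <- paste0(rownames(cld), "_case")
  rownames(pseudo) <- paste0(rownames(cld), "_pseudo")
  g <- rbind(case, pseudo)
  genotype_dataset(g, c(rep(1L, nrow(case)), rep(0L, nrow(pseudo))))
}

#' Downsample controls to match the number of cases
#'
#' Keeps every case and a uniform random subset of controls of equal size,
#' preserving the original sample order of the retained rows.
#'
#' @param x A [genotype_dataset()] with at least as many controls as cases.
#' @param seed Integer seed making the control draw reproducible.
#' @return A balanced `genotype_dataset`.
#' @export
balance_controls <- function(x, seed) {
  stopifnot(inherits(x, "genotype_dataset"))
  cases <- which(x$phenotype == 1L)
  controls <- which(x$phenotype == 0L)
  if (length(controls) < length(cases))
    stop("fewer controls than cases; nothing to downsample")
  keep_ctl <- local({
    set.seed(as.integer(seed))
    sample(controls, length(cases))
  })
  subset_dataset(x, samples = sort(c(cases, keep_ctl)))
}
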