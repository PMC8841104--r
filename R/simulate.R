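#' Default functional gene labels for the epistasis simulation
#'
#' Eight genes from the GO category *negative regulation of mRNA splicing*,
#' used to label the functional SNPs of the four simulated epistatic pairs
#' so that a gene-set analysis has a ground-truth pathway to recover.
#'
#' @return Character vector of 8 gene symbols.
#' @export
splicing_gene_labels <- function() {
  c("PTBP1", "U2AF2", "SRSF9", "SFSWAP", "PCBP4", "NPM1", "C1QBP", "SAP18")
}

#' Describe a simulated epistatic architecture
#'
#' Bundles several pure two-locus penetrance models (one per interacting
#' SNP pair), the rsID labels of the functional loci, and the layout of the
#' no-effect background SNPs. All pair models must share the same
#' prevalence `K` so that the additive combination across pairs is exact.
#'
#' @param pairs List of [penetrance_model()] objects, one per epistatic
#'   pair.
#' @param functional_labels Character vector of `2 * length(pairs)` unique
#'   rsID/gene labels, consumed two per pair in order.
#' @param n_noise Number of no-effect SNPs.
#' @param noise_maf_range Interval from which each noise SNP's MAF is drawn
#'   (uniformly, once per SNP).
#' @param noise_labels Optional pool of ids for the noise SNPs; defaults to
#'   `noise0001...`; must provide at least `n_noise` distinct ids.
#' @return An object of class `sim_architecture`.
#' @export
sim_architecture <- function(pairs, functional_labels = splicing_gene_labels(),
                             n_noise = 1000L,
                             noise_maf_range = c(0.05, 0.5),
                             noise_labels = NULL) {
  if (!all(vapply(pairs, inherits, TRUE, "penetrance_model")))
    stop("`pairs` must be a list of penetrance_model objects")
  Ks <- vapply(pairs, `[[`, 0, "K")
  if (diff(range(Ks)) > 1e-9)
    stop("all pair models must share the same prevalence K")
  if (anyDuplicated(functional_labels)) stop("duplicate functional label")
  if (length(functional_labels) != 2L * length(pairs))
    stop("need exactly 2 labels per epistatic pair")
  n_noise <- as.integer(n_noise)
  if (is.null(noise_labels))
    noise_labels <- sprintf("noise%04d", seq_len(n_noise))
  noise_labels <- unique(noise_labels)
  if (length(noise_labels) < n_noise)
    stop("noise label pool exhausted: need ", n_noise, " distinct ids")
  noise_labels <- noise_labels[seq_len(n_noise)]
  if (any(noise_labels %in% functional_labels))
    stop("noise labels must not collide with functional labels")
  if (noise_maf_range[1] <= 0 || noise_maf_range[2] > 0.5 ||
      noise_maf_range[1] > noise_maf_range[2])
    stop("`noise_maf_range` must lie within (0, 0.5]")
  structure(list(pairs = pairs, functional_labels = functional_labels,
                 n_noise = n_noise, noise_maf_range = noise_maf_range,
                 noise_labels = noise_labels),
            class = "sim_architecture")
}

#' Relabel the loci of a simulated architecture
#'
#' Assigns gene labels to the functional loci (two per pair, in pair order)
#' and ids from a pool to the no-effect SNPs.
#'
#' @param arch A [sim_architecture()].
#' @param functional_genes Character vector of `2 * n_pairs` unique labels.
#' @param noise_id_pool Character pool with at least `n_noise` distinct ids.
#' @return The relabelled `sim_architecture`.
#' @export
assign_labels <- function(arch, functional_genes, noise_id_pool) {
  stopifnot(inherits(arch, "sim_architecture"))
  sim_architecture(arch$pairs, functional_genes, arch$n_noise,
                   arch$noise_maf_range, noise_id_pool)
}

#' Standard epistasis-only study architecture
#'
#' Convenience constructor for the simulation design used throughout the
#' package's examples and tests: four pure two-locus epistatic pairs (MAF
#' 0.2, heritability 0.4 each) combined additively, 1000 no-effect SNPs,
#' and the eight mRNA-splicing gene labels on the functional loci.
#'
#' @param n_pairs Number of epistatic pairs.
#' @param maf Functional-locus MAF.
#' @param h2 Per-pair heritability.
#' @param K Shared model prevalence.
#' @param n_noise Number of no-effect SNPs.
#' @param seed Integer seed for the penetrance-table draws.
#' @return A [sim_architecture()].
#' @export
epistasis_architecture <- function(n_pairs = 4L, maf = 0.2, h2 = 0.4,
                                   K = 0.35, n_noise = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  pair_seeds <- sample.int(.Machine$integer.max, n_pairs)
  pairs <- lapply(pair_seeds, function(s)
    gen_penetrance_model(maf, h2, K, seed = s))
  labels <- if (n_pairs == 4L) splicing_gene_labels()
            else sprintf("FUNC%02d", seq_len(2L * n_pairs))
  sim_architecture(pairs, labels, n_noise = n_noise)
}

#' Simulate a balanced case/control genotype dataset
#'
#' Draws genotypes independently under HWE (functional loci at their model
#' MAFs; each noise SNP at a MAF drawn once from the architecture's range)
#' and assigns case status from the additive combination of the M pair
#' models, each contributing one M-th of the genetic effect:
#'
#' * `combine = "scaled_sum"` (default):
#'   `P(case | g) = K + sum_k (f_k(g) - K) / sqrt(M)`, clipped to
#'   \[0, 1\]. Summing the penetrance deviations scaled by `1/sqrt(M)`
#'   keeps the heritability of the simulated outcome equal to the (shared)
#'   per-pair model heritability, with each pair contributing exactly
#'   one M-th of it.
#' * `combine = "mean"`: `P(case | g) = mean_k f_k(g)`. Deviations scale
#'   by `1/M`, so the outcome heritability shrinks to `h2 / M` while each
#'   pair still contributes one M-th of it.
#'
#' Individuals are rejection-sampled in batches until both quotas are
#' filled.
#'
#' @param arch A [sim_architecture()].
#' @param n_cases,n_controls Sample sizes per class.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param combine Additive combination rule, `"scaled_sum"` or `"mean"`.
#' @param max_batches Cap on the rejection-sampling batches.
#' @return A [genotype_dataset()] with functional SNP columns first (in
#'   pair order) followed by the noise SNPs, and an attribute
#'   `functional_snps` naming the functional columns.
#' @export
simulate_dataset <- function(arch, n_cases = 405L, n_controls = 405L,
                             seed = 1L, combine = c("scaled_sum", "mean"),
                             max_batches = 1000L) {
  stopifnot(inherits(arch, "sim_architecture"))
  combine <- match.arg(combine)
  set.seed(as.integer(seed))
  M <- length(arch$pairs)
  K <- arch$pairs[[1L]]$K
  n_func <- 2L * M
  noise_maf <- stats::runif(arch$n_noise, arch$noise_maf_range[1],
                            arch$noise_maf_range[2])
  mafs <- c(vapply(arch$pairs, function(m) c(m$maf_a, m$maf_b),
                   numeric(2L)),
            noise_maf)
  p_snps <- length(mafs)

  draw_genotypes <- function(n) {
    # HWE: genotype = sum of two Bernoulli(maf) alleles
    g <- matrix(0L, n, p_snps)
    for (j in seq_len(p_snps)) {
      g[, j] <- as.integer(stats::rbinom(n, 2L, mafs[j]))
    }
    g
  }

  batch <- max(1000L, n_cases + n_controls)
  cases <- list(); controls <- list()
  n_ca <- 0L; n_co <- 0L
  for (b in seq_len(max_batches)) {
    g <- draw_genotypes(batch)
    fk <- vapply(seq_len(M), function(k) {
      tab <- arch$pairs[[k]]$table
      tab[cbind(g[, 2L * k - 1L] + 1L, g[, 2L * k] + 1L)]
    }, numeric(batch))
    pen <- if (combine == "mean") rowMeans(fk)
           else pmin(1, pmax(0, K + rowSums(fk - K) / sqrt(M)))
    status <- stats::rbinom(batch, 1L, pen)
    if (n_ca < n_cases) {
      take <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                              n_cases - n_ca))]
      if (length(take)) {
        cases[[length(cases) + 1L]] <- g[take, , drop = FALSE]
        n_ca <- n_ca + length(take)
      }
    }
    if (n_co < n_controls) {
      take <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                              n_controls - n_co))]
      if (length(take)) {
        controls[[length(controls) + 1L]] <- g[take, , drop = FALSE]
        n_co <- n_co + length(take)
      }
    }
    if (n_ca >= n_cases && n_co >= n_controls) break
  }
  if (n_ca < n_cases || n_co < n_controls)
    stop("rejection sampling exceeded the batch cap; K too extreme?")

  g <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  colnames(g) <- c(arch$functional_labels, arch$noise_labels)
  rownames(g) <- c(sprintf("case%05d", seq_len(n_cases)),
                   sprintf("ctrl%05d", seq_len(n_controls)))
  out <- genotype_dataset(g, c(rep(1L, n_cases), rep(0L, n_controls)))
  attr(out, "functional_snps") <- arch$functional_labels
  attr(out, "noise_maf") <- noise_maf
  out
}

#' Synthetic gene coordinates for a simulated SNP panel
#'
#' Places each simulated SNP at its own well-separated locus (1 Mb apart on
#' one synthetic chromosome) and defines one gene per SNP carrying the
#' SNP's label, so that window-based SNP-to-gene mapping reproduces the
#' label assignment exactly. This mirrors labelling simulated SNPs with
#' rsIDs drawn from real genes.
#'
#' @param dataset A simulated [genotype_dataset()].
#' @return A list with `positions` (data frame `snp_id`, `chrom`, `bp`) and
#'   `genes` (a [gene_table()]).
#' @export
synthetic_gene_layout <- function(dataset) {
  ids <- snp_ids(dataset)
  bp <- seq_along(ids) * 1e6           # 1-based SNP positions, 1 Mb apart
  positions <- data.frame(snp_id = ids, chrom = "chrS", bp = as.integer(bp),
                          stringsAsFactors = FALSE)
  genes <- gene_table("chrS", as.integer(bp - 501L), as.integer(bp + 500L),
                      ids)
  list(positions = positions, genes = genes)
}

#' Synthetic gene-set collection with one planted functional set
#'
#' Builds a GMT-style collection for simulation studies: one set holding
#' the functional gene labels plus `n_random` sets drawn uniformly from the
#' gene universe with sizes uniform in `size_range`.
#'
#' @param universe Character vector of gene symbols to draw from.
#' @param functional_genes Members of the planted set.
#' @param n_random Number of random background sets.
#' @param size_range Inclusive size interval for the random sets.
#' @param seed Integer seed.
#' @return A [gene_set_collection()]; the planted set is named
#'   `"functional_set"`.
#' @export
synthetic_gene_sets <- function(universe, functional_genes,
                                n_random = 150L, size_range = c(20L, 200L),
                                seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- sample(size_range[1]:size_range[2], n_random, replace = TRUE)
  sizes <- pmin(sizes, length(universe) - 1L)
  sets <- c(list(functional_set = functional_genes),
            stats::setNames(lapply(sizes, function(s) sample(universe, s)),
                            sprintf("random_set_%03d", seq_len(n_random))))
  gene_set_collection(sets)
}
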