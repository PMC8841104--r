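#' Default pipeline configuration
#'
#' Returns the full configuration list with the standard analysis
#' settings: LD pruning at r2 = 0.2 (window 50, step 5), the three
#' scoring methods with 10-fold cross-validation averaging, 10 kb
#' gene windows, max-score gene aggregation, and gene-set filtering to
#' sizes 20-200 with 1000 gene-set permutations. Any field can be
#' overridden in the list passed to [run_pipeline()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    mode = "simulate",            # simulate | case_control | trio
    seed = 1L,
    input = list(genotype_table = NULL, trio_table = NULL,
                 snp_positions = NULL, missing = "NA"),
    simulator = list(n_pairs = 4L, maf = 0.2, h2 = 0.4, K = 0.35,
                     n_noise = 1000L, n_cases = 405L, n_controls = 405L,
                     combine = "scaled_sum"),
    balance = list(enabled = FALSE),
    ld_prune = list(enabled = TRUE, r2 = 0.2, window = 50L, step = 5L),
    scoring = list(methods = c("chi2", "multisurf", "multisurf_star"),
                   cv_k = 10L, chi2_mode = "genotypic"),
    mapping = list(gene_table = NULL, window_bp = 10000L),
    gsea = list(gmt = NULL, min_size = 20L, max_size = 200L,
                n_perm = 1000L, apply_size_filter = TRUE,
                n_random_sets = 150L),
    leading_edge = list(top_n = 10L),
    out_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#' @param path Path to a YAML file with (a subset of) the fields of
#'   [default_config()].
#' @return Full configuration list with defaults filled in.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

log_stage <- function(log, ...) {
  msg <- sprintf(...)
  message("[episgsea] ", msg)
  c(log, msg)
}

#' Run the full univariate-versus-Relief enrichment pipeline
#'
#' Executes the complete analysis on simulated, case-control or trio
#' input: (trio mode) pseudo-control construction, optional control
#' balancing, LD pruning, per-method SNP scoring with cross-validation
#' averaging, SNP-to-gene mapping with max-score aggregation, pre-ranked
#' GSEA per method, the between-method Spearman rank-correlation table,
#' and a cross-method leading-edge summary. All stage outputs are
#' written as text tables under `out_dir` together with a JSON manifest
#' recording configuration, seeds and per-stage record counts.
#'
#' Per-stage seeds are derived from the master seed by fixed offsets so
#' stages can be re-run in isolation.
#'
#' @param config Configuration list (see [default_config()]) or path to
#'   a YAML file.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a `pipeline_bundle` list with the in-memory stage
#'   results: `dataset`, `scores`, `ranked`, `gsea`, `correlations`,
#'   `leading_edge`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  seeds <- list(simulate = seed, balance = seed + 101L, cv = seed + 202L,
                sets = seed + 303L, gsea = seed + 404L)
  log <- character(0)
  counts <- list()

  # --- input stage ---------------------------------------------------
  layout <- NULL
  if (cfg$mode == "simulate") {
    sim <- cfg$simulator
    arch <- epistasis_architecture(sim$n_pairs, sim$maf, sim$h2, sim$K,
                                   sim$n_noise, seed = seeds$simulate)
    dataset <- simulate_dataset(arch, sim$n_cases, sim$n_controls,
                                seed = seeds$simulate, combine = sim$combine)
    layout <- synthetic_gene_layout(dataset)
    dataset$positions <- layout$positions
    log <- log_stage(log, "simulated %d samples x %d SNPs (%d functional)",
                     nrow(dataset$genotypes), ncol(dataset$genotypes),
                     length(arch$functional_labels))
  } else if (cfg$mode == "trio") {
    if (is.null(cfg$input$trio_table)) stop("trio mode needs input$trio_table")
    trios <- read_trio_table(cfg$input$trio_table,
                             missing = cfg$input$missing)
    dataset <- make_pseudo_controls(trios)
    log <- log_stage(log, "built %d cases + pseudo-controls from %d trios",
                     sum(dataset$phenotype == 1L), nrow(trios$father))
  } else if (cfg$mode == "case_control") {
    if (is.null(cfg$input$genotype_table))
      stop("case_control mode needs input$genotype_table")
    dataset <- read_genotype_table(cfg$input$genotype_table,
                                   missing = cfg$input$missing)
    log <- log_stage(log, "read %d samples x %d SNPs",
                     nrow(dataset$genotypes), ncol(dataset$genotypes))
  } else stop("unknown mode '", cfg$mode, "'")
  counts$samples_in <- nrow(dataset$genotypes)
  counts$snps_in <- ncol(dataset$genotypes)

  if (isTRUE(cfg$balance$enabled)) {
    dataset <- balance_controls(dataset, seed = seeds$balance)
    log <- log_stage(log, "balanced to %d samples", nrow(dataset$genotypes))
  }

  if (isTRUE(cfg$ld_prune$enabled)) {
    dataset <- ld_prune(dataset, cfg$ld_prune$r2, cfg$ld_prune$window,
                        cfg$ld_prune$step)
    log <- log_stage(log, "LD pruning kept %d SNPs", ncol(dataset$genotypes))
  }
  counts$snps_after_prune <- ncol(dataset$genotypes)
  write_genotype_table(dataset, file.path(cfg$out_dir, "genotypes.tsv"))

  # --- scoring -------------------------------------------------------
  scores <- list()
  for (m in cfg$scoring$methods) {
    fun <- switch(m,
                  chi2 = function(d) chi2_scores(d, cfg$scoring$chi2_mode),
                  multisurf = multisurf_scores,
                  multisurf_star = multisurf_star_scores,
                  stop("unknown scoring method '", m, "'"))
    sc <- if (cfg$scoring$cv_k >= 2L)
      cv_average_scores(dataset, fun, k = cfg$scoring$cv_k, seed = seeds$cv)
    else fun(dataset)
    scores[[m]] <- sc
    write_scores(sc, file.path(cfg$out_dir, paste0("scores_", m, ".tsv")))
    log <- log_stage(log, "scored %d SNPs with %s", nrow(sc), m)
  }

  # --- gene mapping --------------------------------------------------
  if (!is.null(cfg$mapping$gene_table)) {
    genes <- read_gene_table(cfg$mapping$gene_table)
  } else if (!is.null(layout)) {
    genes <- layout$genes
  } else stop("a gene table is required outside simulate mode")
  if (!is.null(cfg$input$snp_positions)) {
    pos <- utils::read.table(cfg$input$snp_positions, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    dataset$positions <- pos[match(snp_ids(dataset), pos$snp_id), ,
                             drop = FALSE]
  }
  if (is.null(dataset$positions))
    stop("SNP positions are required for gene mapping; supply input$snp_positions")
  mapping <- map_snps_to_genes(dataset$positions, genes,
                               cfg$mapping$window_bp)
  log <- log_stage(log, "mapped SNPs to %d genes (%d SNPs unmapped)",
                   length(mapping), length(attr(mapping, "unmapped")))
  counts$genes_mapped <- length(mapping)

  ranked <- lapply(scores, function(sc) gene_scores(mapping, sc))
  for (m in names(ranked))
    write_rnk(ranked[[m]], file.path(cfg$out_dir, paste0("genes_", m, ".rnk")))

  # --- GSEA ----------------------------------------------------------
  universe <- ranked[[1L]]$gene
  if (!is.null(cfg$gsea$gmt)) {
    collection <- read_gmt(cfg$gsea$gmt)
  } else if (cfg$mode == "simulate") {
    collection <- synthetic_gene_sets(universe, arch$functional_labels,
                                      n_random = cfg$gsea$n_random_sets,
                                      seed = seeds$sets)
  } else stop("a GMT file is required outside simulate mode")

  gsea <- list()
  for (m in names(ranked)) {
    coll <- if (isTRUE(cfg$gsea$apply_size_filter))
      filter_gene_sets(collection, ranked[[m]], cfg$gsea$min_size,
                       cfg$gsea$max_size)
    else collection
    res <- preranked_gsea(ranked[[m]], coll, n_perm = cfg$gsea$n_perm,
                          seed = seeds$gsea)
    gsea[[m]] <- res
    write_enrichment(res, file.path(cfg$out_dir, paste0("gsea_", m, ".tsv")))
    log <- log_stage(log, "%s GSEA: %d sets, %d at q < 0.05", m, nrow(res),
                     sum(res$fdr_q < 0.05, na.rm = TRUE))
  }

  # --- rank correlations --------------------------------------------
  correlations <- NULL
  if (length(ranked) >= 2L) {
    prs <- utils::combn(names(ranked), 2L)
    correlations <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      rc <- rank_correlation(ranked[[prs[1L, k]]], ranked[[prs[2L, k]]])
      data.frame(method_a = prs[1L, k], method_b = prs[2L, k],
                 rho = rc$rho, p_value = rc$p_value, n_genes = rc$n_genes)
    }))
  } else {
    correlations <- data.frame(method_a = character(0),
                               method_b = character(0), rho = numeric(0),
                               p_value = numeric(0), n_genes = integer(0))
  }
  utils::write.table(correlations,
                     file.path(cfg$out_dir, "rank_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  le <- leading_edge_analysis(gsea, top_n = cfg$leading_edge$top_n)
  utils::write.table(le$occurrence,
                     file.path(cfg$out_dir, "leading_edge_matrix.tsv"),
                     sep = "\t", quote = FALSE)

  manifest <- list(config = cfg, seeds = seeds, counts = counts,
                   package_version = as.character(utils::packageVersion("episgsea")),
                   log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  bundle <- structure(list(dataset = dataset, scores = scores,
                           ranked = ranked, gsea = gsea,
                           correlations = correlations, leading_edge = le,
                           manifest = manifest),
                      class = "pipeline_bundle")
  invisible(bundle)
}

#' Summarize a pipeline run
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param top_n Number of top gene sets per method to tabulate
#'   (default 15).
#' @return List with `significant_sets` (per-method count of sets at
#'   q < 0.05), `top_sets` (per-method top-`top_n` table by `|NES|`),
#'   `le_fraction` and `correlations`.
#' @export
pipeline_report <- function(bundle, top_n = 15L) {
  if (!inherits(bundle, "pipeline_bundle") || is.null(bundle$gsea))
    stop("not a completed pipeline bundle")
  sig <- vapply(bundle$gsea, function(r)
    sum(r$fdr_q < 0.05, na.rm = TRUE), integer(1L))
  tops <- lapply(bundle$gsea, function(r) {
    ok <- which(!is.na(r$nes))
    o <- ok[order(-abs(r$nes[ok]), r$fdr_q[ok], r$set[ok])]
    as.data.frame(r)[o[seq_len(min(top_n, length(o)))], ]
  })
  list(significant_sets = sig, top_sets = tops,
       le_fraction = bundle$leading_edge$le_fraction,
       correlations = bundle$correlations)
}
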