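# End-to-end orchestration of the synthetic "induction" study:
# simulate -> cluster -> tu -> enrich -> promoter, with a deterministic
# artifact directory and a run log.

#' Build a run configuration
#'
#' Collects scenario and stage parameters for [run_all()]. Every
#' stochastic stage takes its seed from `seed` plus a fixed stage offset,
#' so one integer reproduces the full run.
#'
#' @param seed master integer seed; mandatory.
#' @param n_genes_per_cohort cohort sizes of the time-series scenario
#'   (default the standard six-cohort design).
#' @param noise_sd time-series noise sd (natural-log scale).
#' @param k_range candidate cluster numbers.
#' @param n_restarts EM restarts per K.
#' @param m number of DFT components.
#' @param theta_gene,theta_tu immediate-response thresholds.
#' @param p_sort,p_min,p_txt enrichment table sorting/rendering cutoffs.
#' @param n_tu,plant_prob,n_repeats promoter scenario parameters.
#' @param window_w motif profile window width (bp).
#' @param min_genes_gradient minimum TU size for the gradient table.
#' @param gradient_delta planted 5'->3' gradient (log2).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed,
                       n_genes_per_cohort = NULL,
                       noise_sd = 0.15,
                       k_range = 2:10, n_restarts = 20L, m = 6L,
                       theta_gene = 0.01, theta_tu = 0.15,
                       p_sort = 0.01, p_min = 1e-10, p_txt = 1e-5,
                       n_tu = 300L, plant_prob = 0.8, n_repeats = 3L,
                       window_w = 5L, min_genes_gradient = 4L,
                       gradient_delta = 1.5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed),
              n_genes_per_cohort = n_genes_per_cohort,
              noise_sd = noise_sd, k_range = k_range,
              n_restarts = n_restarts, m = m,
              theta_gene = theta_gene, theta_tu = theta_tu,
              p_sort = p_sort, p_min = p_min, p_txt = p_txt,
              n_tu = n_tu, plant_prob = plant_prob,
              n_repeats = n_repeats, window_w = window_w,
              min_genes_gradient = min_genes_gradient,
              gradient_delta = gradient_delta)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Simulates the default induction study, clusters the gene time series,
#' maps the clustering onto transcription units, computes immediate
#' response labels, enrichment profiles against the planted truth, the
#' fold-change gradient table, and the promoter structure profiles.
#' All outputs are plain TSV under a deterministic directory layout
#' (`inputs/`, `clustering/`, `tu/`, `enrichment/`, `promoter/`,
#' `logs/run.log`); rerunning with the same config reproduces them
#' byte for byte.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly; stage results are also returned in the
#'   attribute `results`.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  for (d in c("", "inputs", "clustering", "tu", "enrichment", "promoter",
              "logs"))
    dir.create(file.path(outdir, d), showWarnings = FALSE,
               recursive = TRUE)
  logf <- file.path(outdir, "logs", "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(paste0(...), logcon)
  say("supercoilr ", as.character(packageVersion("supercoilr")))
  say("seed: ", config$seed)

  cfg_path <- file.path(outdir, "logs", "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  say("config md5: ", unname(tools::md5sum(cfg_path)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ------------------------------------------------------
  res <- list()
  stage("simulate", {
    tsc <- timeseries_scenario(noise_sd = config$noise_sd,
                               seed = config$seed)
    if (!is.null(config$n_genes_per_cohort))
      tsc$cohorts$n_genes <- config$n_genes_per_cohort
    sim <- simulate_timeseries(tsc)
    psc <- promoter_scenario(n_tu = config$n_tu,
                             plant_prob = config$plant_prob,
                             n_repeats = config$n_repeats,
                             seed = config$seed + 100L)
    gen <- simulate_genome(psc)
    gen$genome <- plant_promoter_motifs(gen$genome, gen$tus, psc)
    gsc <- gradient_scenario(delta = config$gradient_delta,
                             seed = config$seed + 200L)
    # group simulated genes into multi-gene TUs for the TU stages
    tus_expr <- genes_to_tus(names(sim$truth), sim$truth)
    fc <- simulate_foldchanges(tus_expr, gsc)
    res$sim <- sim; res$gen <- gen; res$psc <- psc
    res$tus_expr <- tus_expr; res$fc <- fc
    write_expression_tsv(sim$matrix,
                         file.path(outdir, "inputs", "expression.tsv"),
                         file.path(outdir, "inputs", "samples.tsv"))
    write_classification(sim$truth,
                         file.path(outdir, "inputs", "truth.tsv"))
    write_genome_fasta(gen$genome,
                       file.path(outdir, "inputs", "genome.fasta"))
    write_tu_table(gen$tus, file.path(outdir, "inputs", "tus.tsv"))
    write_tu_table(tus_expr,
                   file.path(outdir, "inputs", "tus_expression.tsv"))
    write_foldchanges(fc, file.path(outdir, "inputs", "foldchanges.tsv"))
    say("simulated ", nrow(sim$matrix$values), " genes, ",
        config$n_tu, " promoter TUs")
  })

  # --- cluster -------------------------------------------------------
  stage("cluster", {
    feats <- build_features(res$sim$matrix, sample_subset = 2:16,
                            m = config$m)
    cr <- select_k(feats, K_range = config$k_range,
                   n_restarts = config$n_restarts,
                   seed = config$seed + 300L)
    res$feats <- feats; res$clustering <- cr
    write.table(data.frame(gene_id = names(cr$labels),
                           cluster = unname(cr$labels)),
                file.path(outdir, "clustering", "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cr$bic_by_k,
                file.path(outdir, "clustering", "bic_by_k.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("chosen K = ", cr$K, "; excluded genes: ", nrow(cr$excluded))
  })

  # --- tu ------------------------------------------------------------
  stage("tu", {
    tumat <- aggregate_to_tu(res$sim$matrix, res$tus_expr)
    tufeats <- build_features(tumat, sample_subset = 2:16, m = config$m)
    km <- kmeans_seeded(tufeats, res$clustering$model$means)
    resp_gene <- immediate_response(res$sim$matrix,
                                    theta = config$theta_gene)
    resp_tu <- immediate_response(tumat, theta = config$theta_tu)
    grad <- tu_gradient(res$fc, res$tus_expr,
                        min_genes = config$min_genes_gradient)
    res$tumat <- tumat; res$km <- km
    res$resp_gene <- resp_gene; res$resp_tu <- resp_tu
    res$grad <- grad
    write.table(data.frame(tu_id = names(km$labels),
                           cluster = unname(km$labels)),
                file.path(outdir, "tu", "tu_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(resp_gene, file.path(outdir, "tu", "response_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(resp_tu, file.path(outdir, "tu", "response_tus.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(grad, file.path(outdir, "tu", "gradients.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("TU stage: ", length(km$labels), " TUs labeled; gradient rows: ",
        nrow(grad))
  })

  # --- enrich --------------------------------------------------------
  stage("enrich", {
    labels <- setNames(as.character(res$clustering$labels),
                       names(res$clustering$labels))
    ot <- cross_tabulate(labels, res$sim$truth)
    ot <- sort_overlaps(ot, p_sort = config$p_sort)
    style <- render_profile(ot, p_min = config$p_min,
                            p_txt = config$p_txt)
    res$overlaps <- ot
    write.table(as.data.frame.table(ot$counts,
                                    responseName = "count"),
                file.path(outdir, "enrichment", "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame.table(ot$p_enrich,
                                    responseName = "p_enrich"),
                file.path(outdir, "enrichment", "p_enrich.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(style, file.path(outdir, "enrichment", "style.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("enrichment: ", nrow(ot$counts), " clusters x ",
        ncol(ot$counts), " truth cohorts; cut_row = ", ot$cut_row)
  })

  # --- promoter ------------------------------------------------------
  stage("promoter", {
    motif <- motif_def("ATRACT4")
    aligned <- align_at_tss(res$gen$genome, res$gen$tus, motif,
                            upstream = res$psc$upstream,
                            downstream = res$psc$downstream)
    planted <- unique(attr(res$gen$genome, "plants")$tu_id)
    prof <- positional_tests(aligned, planted, w = config$window_w)
    acfp <- acf_periodicity(res$gen$genome, res$gen$tus,
                            motif = motif_def("AT2"),
                            region = c(-res$psc$upstream, -1))
    res$profile <- prof; res$acf <- acfp
    write.table(prof, file.path(outdir, "promoter", "profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(acfp$acf, file.path(outdir, "promoter", "acf.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("promoter: profile argmax at ",
        prof$position[which.max(prof$freq)], " bp; ACF period ",
        format(acfp$period))
  })

  out <- invisible(outdir)
  attr(out, "results") <- res
  out
}

#' Group genes into synthetic transcription units
#'
#' Helper for the pipeline: partitions genes (within each cohort, to keep
#' TU composition homogeneous) into consecutive TUs of 1-5 genes, on a
#' dummy replicon. Deterministic: sizes cycle through 4, 1, 2, 5, 3.
#'
#' @param gene_ids character vector of gene ids.
#' @param truth named cohort vector used to group genes.
#' @return A [tu_table].
#' @export
genes_to_tus <- function(gene_ids, truth = NULL) {
  if (!is.null(truth)) gene_ids <- gene_ids[order(truth[gene_ids])]
  sizes_cycle <- c(4L, 1L, 2L, 5L, 3L)
  genes <- list(); i <- 1L; s <- 0L
  while (i <= length(gene_ids)) {
    sz <- min(sizes_cycle[s %% length(sizes_cycle) + 1L],
              length(gene_ids) - i + 1L)
    genes[[length(genes) + 1L]] <- gene_ids[i:(i + sz - 1L)]
    i <- i + sz; s <- s + 1L
  }
  n <- length(genes)
  tu_table(tu_id = sprintf("TUE%04d", seq_len(n)),
           replicon = rep("expr_dummy", n),
           replicon_class = rep("chromosome", n),
           strand = rep("+", n),
           tss = seq_len(n) * 10L,
           genes = genes)
}
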