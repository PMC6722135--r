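#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage, each stochastic stage with an
#' explicit seed derived from the top-level seed. The configuration
#' round-trips losslessly through its YAML file form
#' (\code{\link{write_run_config}} / \code{\link{read_run_config}}).
#'
#' @param seed top-level integer seed.
#' @param input optional dataset directory (read with
#'   \code{\link{read_dataset}}); NULL simulates a cohort instead.
#' @return nested list of class \code{run_config}.
#' @export
default_config <- function(seed = 1, input = NULL) {
  structure(list(
    seed = seed,
    input = input,
    simulate = list(seed = seed),
    qc = list(min_genes = 200, max_genes = 2500, max_mito = 0.05,
              min_cells = 3),
    normalize = list(scale_factor = 1e4),
    variable_genes = list(x_low = 0.0125, x_high = 3, y_cutoff = 0.5,
                          n_bins = 20),
    pca = list(n_components = 20, n_pcs = 8),
    cluster = list(k = 20, resolution = 0.2, seed = seed + 1),
    embedding = list(method = "tsne", perplexity = 30, seed = seed + 2),
    velocity = list(spliced_min = 0.5, unspliced_min = 0.05,
                    filter_rule = "both", fit_quantile = 0.02,
                    dt = 1, sigma_corr = 0.05),
    fate = list(level = 0.95),
    trajectory = list(resolution = 2.5, seed = seed + 3, df = 4,
                      top_n = 100, n_iter = 10)
  ), class = "run_config")
}

#' @rdname default_config
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(config) {
  if (is.null(config$seed)) stop("config validation: top-level seed missing")
  for (st in c("simulate", "cluster", "embedding", "trajectory"))
    if (!is.null(config[[st]]) && is.null(config[[st]]$seed))
      stop("config validation: stage '", st, "' lacks a seed")
  if (!is.null(config$input) && !dir.exists(config$input))
    stop("config validation: input path does not exist: ", config$input)
  invisible(config)
}

write_stage <- function(outdir, stage, tables) {
  if (is.null(outdir)) return(invisible(NULL))
  d <- file.path(outdir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x)) x <- data.frame(id = rownames(x), x,
                                      stringsAsFactors = FALSE)
    utils::write.table(x, file.path(d, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(d)
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> QC -> normalization/variable genes ->
#' PCA/clustering/embedding -> velocity -> fate (TPn per subset) ->
#' trajectory/temporal genes, writing per-stage TSV outputs and a
#' line-oriented key:value manifest when \code{outdir} is given. A stage
#' failure aborts with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config a \code{\link{default_config}}-style list.
#' @param outdir optional run directory for stage outputs and the manifest.
#' @return list with all stage results (see Details in the vignette).
#' @export
run_pipeline <- function(config = default_config(1), outdir = NULL) {
  validate_run_config(config)
  manifest <- c(package = as.character(utils::packageVersion("velofate")),
                seed = config$seed)
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## --- simulate / ingest -------------------------------------------------
  res$sim <- stage("simulate", {
    if (is.null(config$input)) simulate_cohort(sim_config(),
                                               seed = config$simulate$seed)
    else {
      ds <- read_dataset(config$input)
      list(counts = ds$counts, truth = ds$truth)
    }
  })
  manifest["simulate.cells"] <- ncol(res$sim$counts$spliced)

  ## --- qc ----------------------------------------------------------------
  res$qc <- stage("qc", {
    f <- filter_cells(res$sim$counts, config$qc$min_genes, config$qc$max_genes,
                      config$qc$max_mito)
    f$data <- filter_genes(f$data, config$qc$min_cells)
    f
  })
  keep_cells <- res$qc$cells$cell_id
  truth <- res$sim$truth
  if (!is.null(truth)) truth <- truth[match(keep_cells, truth$cell_id), ]
  res$truth <- truth
  manifest["qc.cells"] <- length(keep_cells)
  manifest["qc.genes"] <- nrow(res$qc$data$spliced)
  write_stage(outdir, "qc", list(cell_qc = res$qc$cells))

  ## --- normalize + variable genes + scale --------------------------------
  res$norm <- stage("normalize",
                    log_normalize(res$qc$data, config$normalize$scale_factor))
  res$hvg <- stage("variable_genes",
                   find_variable_genes(res$norm,
                                       config$variable_genes$x_low,
                                       config$variable_genes$x_high,
                                       config$variable_genes$y_cutoff,
                                       config$variable_genes$n_bins))
  vg <- res$hvg$gene[res$hvg$variable]
  if (length(vg) < 20) vg <- utils::head(
    res$hvg$gene[order(-res$hvg$dispersion_scaled)], 50)
  res$scaled <- stage("scale", scale_and_regress(
    res$norm[vg, , drop = FALSE], res$qc$cells$total_counts))
  manifest["variable_genes.n"] <- length(vg)

  ## --- pca / graph / clusters / embedding --------------------------------
  res$pcs <- stage("pca", run_pca(res$scaled, config$pca$n_components))
  n_pcs <- min(config$pca$n_pcs, ncol(res$pcs$scores))
  scores <- res$pcs$scores[, seq_len(n_pcs), drop = FALSE]
  res$graph <- stage("knn_graph", build_knn_graph(scores, config$cluster$k))
  res$clusters <- stage("cluster", cluster_graph(res$graph,
                                                 config$cluster$resolution,
                                                 config$cluster$seed))
  res$embedding <- stage("embedding", run_embedding(
    scores, config$embedding$method, config$embedding$seed,
    config$embedding$perplexity))
  manifest["cluster.n"] <- length(unique(res$clusters))
  write_stage(outdir, "cluster", list(
    labels = data.frame(cell_id = keep_cells, cluster = res$clusters),
    embedding = data.frame(cell_id = keep_cells, res$embedding)))

  ## --- velocity ----------------------------------------------------------
  res$velocity <- stage("velocity", fit_velocity(
    res$qc$data, res$clusters, res$graph, res$embedding,
    spliced_min = config$velocity$spliced_min,
    unspliced_min = config$velocity$unspliced_min,
    filter_rule = config$velocity$filter_rule,
    fit_quantile = config$velocity$fit_quantile,
    dt = config$velocity$dt, sigma_corr = config$velocity$sigma_corr))
  res$rel_velocity <- relative_2d_velocity(res$velocity$arrows)
  manifest["velocity.genes"] <- length(res$velocity$genes)
  write_stage(outdir, "velocity", list(
    gamma = data.frame(gene = names(res$velocity$gamma),
                       gamma = res$velocity$gamma),
    arrows = data.frame(cell_id = keep_cells, res$velocity$arrows,
                        rel_velocity = res$rel_velocity)))

  ## --- fate --------------------------------------------------------------
  subset_labels <- if (!is.null(truth)) truth$population else res$clusters
  res$fate <- stage("fate", {
    lapply(stats::setNames(nm = unique(as.character(subset_labels))),
           function(pop) {
      ts <- subset_transition_probability(res$velocity$transition,
                                          subset_labels == pop,
                                          clusters = subset_labels,
                                          subset_label = pop)
      ell <- tryCatch(confidence_ellipse(
        res$embedding[subset_labels == pop, , drop = FALSE],
        level = config$fate$level), warning = function(w) NULL,
        error = function(e) NULL)
      list(summary = ts, call = fate_call(ts), ellipse = ell)
    })
  })
  write_stage(outdir, "fate", list(
    tpn = data.frame(cell_id = keep_cells,
                     vapply(res$fate, function(f) f$summary$tpn,
                            numeric(length(keep_cells))))))

  ## --- trajectory ---------------------------------------------------------
  res$trajectory <- stage("trajectory", {
    traj_pops <- intersect(TRAJ_POPS, unique(as.character(subset_labels)))
    sc <- subcluster_for_trajectory(res$graph, subset_labels, traj_pops,
                                    resolution = config$trajectory$resolution,
                                    seed = config$trajectory$seed)
    keep <- sc$keep
    cent <- cluster_centroids(scores[keep, , drop = FALSE], sc$labels[keep])
    start_candidates <- names(sc$mapping)[sc$mapping == traj_pops[1]]
    start_sizes <- table(factor(as.character(sc$labels[keep]),
                                levels = rownames(cent)))
    start <- start_candidates[which.max(start_sizes[start_candidates])]
    model <- infer_lineages(cent, start)
    ## follow the lineage that ends in the terminal trajectory population
    terminal <- names(sc$mapping)[sc$mapping == traj_pops[length(traj_pops)]]
    ends <- vapply(model$lineages, function(l) l[length(l)], character(1))
    lin <- which(ends %in% terminal)
    if (length(lin) == 0) lin <- 1L
    pt <- pseudotime(scores[keep, , drop = FALSE], model, lineage = lin[1],
                     n_iter = config$trajectory$n_iter)
    tg <- temporal_genes(res$norm[, keep, drop = FALSE], pt$pseudotime,
                         df = config$trajectory$df,
                         top_n = config$trajectory$top_n)
    list(subclusters = sc, model = model, pt = pt, temporal = tg,
         cells = keep_cells[keep])
  })
  write_stage(outdir, "trajectory", list(
    pseudotime = data.frame(cell_id = res$trajectory$cells,
                            pseudotime = res$trajectory$pt$pseudotime),
    temporal_genes = res$trajectory$temporal$results))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0(names(manifest), ": ", manifest),
               file.path(outdir, "manifest.txt"))
  }
  res$manifest <- manifest
  res
}
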