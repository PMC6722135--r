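# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full default cohort taken through QC -> normalization -> PCA -> graph;
# the conditions every planted-recovery property is stated under
default_fixture <- function(seed = 42) {
  cached(paste0("fix", seed), {
    sim <- simulate_cohort(sim_config(), seed = seed)
    f <- suppressMessages(filter_cells(sim$counts))
    d <- filter_genes(f$data)
    truth <- sim$truth[match(f$cells$cell_id, sim$truth$cell_id), ]
    norm <- log_normalize(d)
    hvg <- suppressMessages(find_variable_genes(norm))
    vg <- hvg$gene[hvg$variable]
    scaled <- scale_and_regress(norm[vg, , drop = FALSE],
                                f$cells$total_counts)
    pcs <- run_pca(scaled, 20)
    scores <- pcs$scores[, 1:8]
    graph <- build_knn_graph(scores, 20)
    list(sim = sim, data = d, cells = f$cells, truth = truth, norm = norm,
         scaled = scaled, pcs = pcs, scores = scores, graph = graph)
  })
}

# velocity field (with t-SNE embedding) on the default fixture
velocity_fixture <- function(seed = 42) {
  cached(paste0("vel", seed), {
    fx <- default_fixture(seed)
    emb <- run_embedding(fx$scores, "tsne", seed = seed + 5)
    vf <- suppressMessages(fit_velocity(fx$data, fx$truth$population,
                                        fx$graph, emb))
    c(fx, list(embedding = emb, vf = vf))
  })
}

# trajectory stage (subclustering, lineage, pseudotime) on the default fixture
trajectory_fixture <- function(seed = 42) {
  cached(paste0("traj", seed), {
    fx <- default_fixture(seed)
    pops <- c("MonoLy6Clo", "CD16_2_intermediate", "CD206neg_IM")
    sc <- subcluster_for_trajectory(fx$graph, fx$truth$population, pops,
                                    resolution = 2.5, seed = seed + 2)
    cent <- cluster_centroids(fx$scores[sc$keep, , drop = FALSE],
                              sc$labels[sc$keep])
    starts <- names(sc$mapping)[sc$mapping == pops[1]]
    sz <- table(factor(as.character(sc$labels[sc$keep]),
                       levels = rownames(cent)))
    start <- starts[which.max(sz[starts])]
    model <- infer_lineages(cent, start)
    term <- names(sc$mapping)[sc$mapping == pops[3]]
    ends <- vapply(model$lineages, function(l) l[length(l)], character(1))
    lin <- which(ends %in% term)[1]
    if (is.na(lin)) lin <- 1L
    pt <- suppressWarnings(pseudotime(fx$scores[sc$keep, , drop = FALSE],
                                      model, lineage = lin))
    c(fx, list(sub = sc, model = model, pt = pt, lineage = lin))
  })
}

# small deterministic layered_counts object for unit tests
toy_layers <- function(n_genes = 8, n_cells = 5, seed = 1, mito = 0) {
  set.seed(seed)
  g <- c(if (mito > 0) sprintf("mt-g%d", seq_len(mito)),
         sprintf("g%d", seq_len(n_genes - mito)))
  s <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(g, sprintf("c%d", seq_len(n_cells))))
  u <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells,
              dimnames = dimnames(s))
  layered_counts(s, u)
}

expect_rows_stochastic <- function(tm) {
  rs <- Matrix::rowSums(tm)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-8))
}
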