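test_that("velocity gene filter applies the layer thresholds per cluster", {
  clusters <- rep(c("a", "b"), each = 5)
  s <- rbind(g1 = c(rep(0.6, 5), rep(0, 5)),   # spliced 0.6 / unspliced 0.06
             g2 = c(rep(0.6, 5), rep(0, 5)),   # spliced ok, unspliced 0
             g3 = rep(0.1, 10))                # fails both
  u <- rbind(g1 = c(rep(0.06, 5), rep(0, 5)),
             g2 = rep(0, 10),
             g3 = rep(0.01, 10))
  colnames(s) <- colnames(u) <- sprintf("c%d", 1:10)
  expect_identical(filter_velocity_genes(s, u, clusters), "g1")
  expect_setequal(filter_velocity_genes(s, u, clusters, rule = "either"),
                  c("g1", "g2"))
  expect_error(filter_velocity_genes(s * 0, u * 0, clusters), "relax")
  # cluster means against a group-by oracle on a random fixture
  set.seed(50)
  sr <- matrix(runif(20 * 10), 20, 10,
               dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  m <- velofate:::cluster_row_means(sr, clusters)
  for (g in c(1, 20))
    expect_equal(unname(m[g, ]),
                 unname(c(mean(sr[g, 1:5]), mean(sr[g, 6:10]))))
})

test_that("kNN pooling equals the explicit neighborhood average", {
  set.seed(51)
  x <- matrix(rnorm(12 * 30), 12, 30,
              dimnames = list(sprintf("g%d", 1:12), sprintf("c%d", 1:30)))
  pts <- matrix(rnorm(30 * 3), 30, 3)
  g <- build_knn_graph(pts, k = 4)
  pooled <- knn_pool(x, g)
  for (i in c(1, 15, 30))
    expect_equal(pooled[, i], rowMeans(x[, c(i, g$idx[i, ])]),
                 tolerance = 1e-12)
  # constant gene is a smoothing fixed point
  x2 <- x; x2[1, ] <- 3
  expect_equal(unname(knn_pool(x2, g)[1, ]), rep(3, 30))
  # k = 0 is the identity with a warning
  g0 <- g; g0$k <- 0
  expect_warning(p0 <- knn_pool(x, g0), "identity")
  expect_identical(p0, x)
})

test_that("gamma fit is exact on steady-state data and matches the closed form", {
  set.seed(52)
  s <- matrix(runif(5 * 400, 0, 10), 5, 400,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  u <- 0.7 * s
  gam <- fit_gamma(s, u)
  expect_equal(unname(gam), rep(0.7, 5), tolerance = 1e-12)
  # closed-form oracle gamma = sum(su)/sum(s^2) on the extreme set
  un <- u + matrix(rnorm(length(u), 0, 0.3), nrow(u))
  gn <- fit_gamma(s, un, fit_quantile = 0.02)
  for (g in 1:5) {
    qs <- quantile(s[g, ], c(0.02, 0.98), names = FALSE)
    ext <- s[g, ] <= qs[1] | s[g, ] >= qs[2]
    expect_equal(unname(gn[g]),
                 max(sum(s[g, ext] * un[g, ext]) / sum(s[g, ext]^2), 1e-4),
                 tolerance = 1e-12)
  }
  # all-zero gene is dropped with a message
  s0 <- s; s0[2, ] <- 0
  expect_message(gz <- fit_gamma(s0, u), "dropped")
  expect_true(is.na(gz[2]))
})

test_that("planted degradation rates are recovered on the default cohort", {
  fx <- velocity_fixture()
  nrm <- size_normalize(fx$data)
  cm <- velofate:::cluster_row_means(nrm$s, fx$truth$population)
  mx <- apply(cm, 1, max)
  hi <- intersect(rownames(nrm$s)[mx >= 1],
                  names(fx$vf$gamma)[is.finite(fx$vf$gamma)])
  gt <- fx$sim$params$gamma_true[match(hi, fx$sim$params$gene_id)]
  rel <- abs(fx$vf$gamma[hi] - gt) / gt
  expect_gte(mean(rel <= 0.10), 0.9)
})

test_that("velocity arithmetic and extrapolation flooring", {
  u <- matrix(c(2, 0.5), 1); s <- matrix(c(2, 0.1), 1)
  rownames(u) <- rownames(s) <- "g"
  v <- compute_velocity(u, s, c(g = 0.5), dt = 1)
  expect_equal(unname(v$velocity[1, 1]), 1)   # u=2, gamma=0.5, s=2 -> v=1
  expect_equal(unname(v$extrapolated[1, 1]), 3)
  # u = gamma*s -> v = 0, s' = s
  v0 <- compute_velocity(matrix(1), matrix(2), 0.5)
  expect_equal(v0$velocity[1, 1], 0)
  expect_equal(v0$extrapolated[1, 1], 2)
  # flooring at zero
  vf <- compute_velocity(matrix(0), matrix(1), 1.1, dt = 1)
  expect_equal(vf$extrapolated[1, 1], 0)
})

test_that("transition probabilities are row-stochastic and match hand computation", {
  set.seed(53)
  s <- matrix(runif(40 * 30, 0, 5), 40, 30,
              dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:30)))
  ext <- s + matrix(rnorm(length(s), 0, 0.5), nrow(s))
  g <- build_knn_graph(matrix(rnorm(30 * 3), 30, 3), k = 6)
  tm <- transition_probabilities(s, ext, g)
  expect_rows_stochastic(tm)
  # support within the neighbor sets
  for (i in c(2, 17)) {
    nz <- which(tm[i, ] > 0)
    expect_true(all(nz %in% g$idx[i, ]))
  }
  # 3-cell, 2-gene toy against the direct formula
  s3 <- matrix(c(1, 1, 2, 1, 1, 2), 2, 3,
               dimnames = list(c("gA", "gB"), c("x", "y", "z")))
  ext3 <- s3 + c(0.5, -0.2)
  g3 <- build_knn_graph(cbind(c(0, 1, 2), c(0, 0, 0)), k = 2)
  t3 <- transition_probabilities(s3, ext3, g3, sigma_corr = 0.05)
  di <- ext3[, 1] - s3[, 1]
  r12 <- cor(di, s3[, 2] - s3[, 1]); r13 <- cor(di, s3[, 3] - s3[, 1])
  r12 <- ifelse(is.na(r12), 0, r12)
  w <- exp(c(r12, r13) / 0.05)
  expect_equal(as.numeric(t3[1, 2:3]), w / sum(w), tolerance = 1e-10)
})

test_that("zero-velocity cells get uniform rows by the r = 0 convention", {
  s <- matrix(runif(20 * 10, 1, 3), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  g <- build_knn_graph(matrix(rnorm(10 * 2), 10, 2), k = 3)
  tm <- transition_probabilities(s, s, g)    # extrapolated == s -> v = 0
  expect_equal(as.numeric(tm[1, g$idx[1, ]]), rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("embedding projection obeys baseline cancellation and closed forms", {
  emb <- cbind(c(0, 1, 0, -1), c(0, 0, 1.5, 0))
  rownames(emb) <- sprintf("c%d", 1:4)
  g <- build_knn_graph(emb, k = 2)
  # uniform transition rows -> near-zero arrows
  tm_u <- Matrix::sparseMatrix(i = rep(1:4, each = 2),
                               j = as.vector(t(g$idx)), x = 0.5,
                               dims = c(4, 4))
  a_u <- project_to_embedding(tm_u, emb, g)
  expect_equal(max(abs(a_u)), 0, tolerance = 1e-12)
  # all mass on one neighbor (k = 2): arrow = e_hat - mean(e_hats)
  tm_1 <- Matrix::sparseMatrix(i = c(1, 2, 3, 4),
                               j = c(g$idx[1, 1], g$idx[2, 1],
                                     g$idx[3, 1], g$idx[4, 1]),
                               x = 1, dims = c(4, 4))
  a_1 <- project_to_embedding(tm_1, emb, g)
  nb <- g$idx[1, ]
  disp <- emb[nb, ] - rep(1, 2) %o% emb[1, ]
  e_hat <- disp / sqrt(rowSums(disp^2))
  expect_equal(unname(a_1[1, ]), unname(e_hat[1, ] - colMeans(e_hat)),
               tolerance = 1e-12)
  # all-zero row -> zero arrow
  tm_0 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(4, 4))
  a_0 <- project_to_embedding(tm_0, emb, g)
  expect_equal(unname(a_0[3, ]), c(0, 0))
})

test_that("relative 2D velocity is the arrow length", {
  arrows <- rbind(c(0, 0), c(3, 4))
  rownames(arrows) <- c("a", "b")
  expect_equal(unname(relative_2d_velocity(arrows)), c(0, 5))
})

test_that("transit cells out-pace every stable population in relative 2D velocity", {
  fx <- velocity_fixture()
  rv <- relative_2d_velocity(fx$vf$arrows)
  med <- tapply(rv, fx$truth$population, median)
  stable <- setdiff(names(med), "CD16_2_intermediate")
  expect_true(all(med["CD16_2_intermediate"] > med[stable]))
  cmp <- compare_subsets(rv, fx$truth$population)
  tr <- cmp$a == "CD16_2_intermediate" | cmp$b == "CD16_2_intermediate"
  expect_true(all(cmp$p_value[tr] < 0.01))
})

test_that("transit arrows point along the planted differentiation direction", {
  # evaluated in the linear (PCA) embedding, where the latent-time gradient
  # is a well-defined global direction; a t-SNE layout bends the path and
  # has no single gradient to compare against
  fx <- default_fixture()
  emb <- run_embedding(fx$scores, "pca")
  vf <- suppressMessages(fit_velocity(fx$data, fx$truth$population,
                                      fx$graph, emb))
  tr <- which(fx$truth$population == "CD16_2_intermediate")
  lt <- fx$truth$latent_time
  gx <- coef(lm(emb[tr, 1] ~ lt[tr]))[2]
  gy <- coef(lm(emb[tr, 2] ~ lt[tr]))[2]
  grad <- c(gx, gy) / sqrt(gx^2 + gy^2)
  rv <- relative_2d_velocity(vf$arrows)[tr]
  cosine <- as.numeric(vf$arrows[tr, ] %*% grad) / pmax(rv, 1e-12)
  expect_gte(mean(cosine > 0), 0.8)
})

test_that("grid summaries average arrows with kernel weights", {
  # the opposite-arrow pair sits symmetric about its lattice-cell center
  emb <- rbind(c(1, 1), c(7, 8), c(8, 7))
  arrows <- rbind(c(1, 0), c(0.5, 0.5), c(-0.5, -0.5))
  g <- grid_summarize(arrows, emb, n_grid = 2, bandwidth = 1)
  # single cell in its lattice cell keeps its own arrow
  row1 <- g[g$n == 1, ]
  expect_equal(c(row1$dx, row1$dy), c(1, 0))
  # opposite equal arrows at symmetric positions cancel
  row2 <- g[g$n == 2, ]
  expect_equal(c(row2$dx, row2$dy), c(0, 0), tolerance = 1e-10)
  # kernel-weighted mean against direct summation
  set.seed(55)
  emb2 <- matrix(runif(40 * 2, 0, 10), 40, 2)
  ar2 <- matrix(rnorm(80), 40, 2)
  g2 <- grid_summarize(ar2, emb2, n_grid = 4, bandwidth = 0.8)
  expect_equal(sum(g2$n), 40)
  expect_error(grid_summarize(ar2, emb2, n_grid = 1), "n_grid")
})

test_that("velocity_fit methods expose the model components", {
  fx <- velocity_fixture()
  vf <- fx$vf
  expect_s3_class(vf, "velocity_fit")
  expect_identical(coef(vf), vf$gamma)
  expect_identical(residuals(vf), vf$velocity)
  expect_identical(predict(vf), vf$extrapolated)
  p2 <- predict(vf, dt = 2)
  ok <- is.finite(vf$gamma)
  expect_equal(p2, pmax(vf$pooled_s[ok, ] + 2 * vf$velocity, 0))
  expect_output(print(vf), "velocity_fit")
  sm <- summary(vf)
  expect_equal(sm$zero_rows, 0)
  expect_rows_stochastic(vf$transition)
})

test_that("an equilibrium cohort yields a vanishing velocity field", {
  # exact null: all populations (and the transit bridge) at steady state,
  # zero-noise diagnostic mode, so u = gamma * s holds identically
  cfg <- sim_config(pop_sizes = c(MonoLy6Chi = 40, MonoLy6Clo = 40,
                                  CD16_2_intermediate = 40,
                                  CD206neg_IM = 40, CD206pos_IM = 40),
                    n_genes = 300, n_traj_genes = 30, n_mito = 10,
                    n_markers_per_pop = 10, n_qc_low = 0, n_qc_mito = 0,
                    steady_state = TRUE, noise = "none")
  sim <- simulate_cohort(cfg, seed = 56)
  d <- sim$counts
  norm <- log_normalize(d)
  hvg <- suppressMessages(find_variable_genes(norm))
  vg <- hvg$gene[hvg$variable]
  if (length(vg) < 20) vg <- hvg$gene[order(-hvg$dispersion_scaled)][1:50]
  scaled <- scale_and_regress(norm[vg, , drop = FALSE],
                              Matrix::colSums(d$spliced))
  scores <- suppressWarnings(run_pca(scaled, 10))$scores[, 1:8]
  graph <- build_knn_graph(scores, 20)
  emb <- run_embedding(scores, "pca")
  vf <- suppressMessages(fit_velocity(d, sim$truth$population, graph, emb))
  expect_lt(max(abs(vf$velocity)), 1e-8)
  null_mean <- mean(relative_2d_velocity(vf$arrows))
  # reference scale: the trajectory fixture's transit-population mean arrow
  fx <- velocity_fixture()
  transit_mean <- mean(relative_2d_velocity(
    fx$vf$arrows)[fx$truth$population == "CD16_2_intermediate"])
  expect_lt(null_mean, 0.10 * transit_mean)
  # and on a noisy equilibrium cohort every population is self-dominant
  sim2 <- simulate_cohort(sim_config(steady_state = TRUE), seed = 57)
  f2 <- suppressMessages(filter_cells(sim2$counts))
  d2 <- filter_genes(f2$data)
  truth2 <- sim2$truth[match(f2$cells$cell_id, sim2$truth$cell_id), ]
  norm2 <- log_normalize(d2)
  hvg2 <- suppressMessages(find_variable_genes(norm2))
  sc2 <- scale_and_regress(norm2[hvg2$gene[hvg2$variable], , drop = FALSE],
                           f2$cells$total_counts)
  g2 <- build_knn_graph(run_pca(sc2, 20)$scores[, 1:8], 20)
  vf2 <- suppressMessages(fit_velocity(d2, truth2$population, g2))
  for (p in unique(truth2$population)) {
    tp <- subset_transition_probability(vf2$transition,
                                        truth2$population == p,
                                        clusters = truth2$population,
                                        subset_label = p)
    expect_identical(names(sort(tp$mass_by_cluster, decreasing = TRUE))[1],
                     p)
  }
})
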