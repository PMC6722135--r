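test_that("signatures apply strict thresholds on logFC and expressed fraction", {
  mk <- data.frame(gene = c("a", "b", "c", "d"),
                   log_fc = c(0.09, 0.11, 0.5, 0.3),
                   pct_in = c(0.5, 0.5, 0.10, 0.8),
                   pct_out = 0.1)
  sig <- build_signature(mk)
  expect_false("a" %in% sig)   # logFC 0.09 below threshold
  expect_true("b" %in% sig)    # logFC 0.11 in
  expect_false("c" %in% sig)   # pct exactly 0.10 is not "more than 10%"
  expect_true("d" %in% sig)
  expect_warning(empty <- build_signature(mk[1, , drop = FALSE]), "empty")
  expect_length(empty, 0)
  # predicate oracle on a random table
  set.seed(80)
  rt <- data.frame(gene = sprintf("g%d", 1:300),
                   log_fc = rnorm(300, 0.1, 0.2),
                   pct_in = runif(300), pct_out = runif(300))
  sig2 <- suppressWarnings(build_signature(rt))
  expect_setequal(sig2, rt$gene[rt$log_fc > 0.1 & rt$pct_in > 0.1])
})

test_that("set overlap counts every Venn region (inclusion-exclusion oracle)", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"))
  ov <- set_overlap(sets)
  expect_equal(ov$count[ov$region == "A"], 1)       # x
  expect_equal(ov$count[ov$region == "B"], 1)       # w
  expect_equal(ov$count[ov$region == "A&B"], 2)     # y, z
  # disjoint and identical edge cases
  d <- set_overlap(list(A = "p", B = "q"))
  expect_equal(d$count[d$region == "A&B"], 0)
  idn <- set_overlap(list(A = c("p", "q"), B = c("p", "q")))
  expect_equal(idn$count[idn$region == "A&B"], 2)
  expect_equal(sum(idn$count[idn$region != "A&B"]), 0)
  # 3-set random fixture vs inclusion-exclusion
  set.seed(81)
  pool <- sprintf("g%d", 1:60)
  s3 <- list(A = sample(pool, 25), B = sample(pool, 25),
             C = sample(pool, 25))
  ov3 <- set_overlap(s3)
  nAB <- length(intersect(s3$A, s3$B))
  nABC <- length(Reduce(intersect, s3))
  expect_equal(ov3$count[ov3$region == "A&B&C"], nABC)
  expect_equal(ov3$count[ov3$region == "A&B"], nAB - nABC)
  expect_equal(sum(ov3$count), length(Reduce(union, s3)))
  expect_error(set_overlap(list(A = "x")), "2 sets")
})

test_that("Signal2Noise scores follow the floored closed form", {
  expr <- rbind(g_equal = rep(5, 8),
                g_clean = c(rep(2, 4), rep(1, 4)),
                g_tiny_sd = c(rep(10, 4), rep(5, 4)))
  colnames(expr) <- sprintf("s%d", 1:8)
  # add spread so sds are nonzero where intended
  expr["g_clean", ] <- expr["g_clean", ] + rep(c(-0.5, 0.5), 4) *
    c(rep(1, 4), rep(1, 4)) * 0.5773503 * sqrt(4 / 3)
  labels <- rep(c("A", "B"), each = 4)
  rk <- signal2noise_rank(expr, labels)
  expect_equal(rk$score[rk$gene == "g_equal"], 0)
  # flooring: sd 0 -> floored at max(0.2*|mu|, 0.2)
  mA <- 10; mB <- 5
  expect_equal(rk$score[rk$gene == "g_tiny_sd"],
               (mA - mB) / (0.2 * mA + 0.2 * mB), tolerance = 1e-10)
  expect_error(signal2noise_rank(expr[, 1:5], labels[1:5]), "3 samples")
  # hand-checked arithmetic: mu 2 vs 1, sd 0.5 each -> score 1
  set.seed(82)
  e2 <- rbind(g = c(2, 2.5, 1.5, 2, 1, 1.5, 0.5, 1))
  colnames(e2) <- sprintf("s%d", 1:8)
  sA <- sd(e2[1, 1:4]); sB <- sd(e2[1, 5:8])
  rk2 <- signal2noise_rank(e2, labels)
  expect_equal(rk2$score, (2 - 1) / (max(sA, 0.4) + max(sB, 0.2)),
               tolerance = 1e-10)
})

test_that("enrichment score matches the running-sum oracle and extremes", {
  ranked <- data.frame(gene = sprintf("g%d", 1:50),
                       score = seq(5, -5, length.out = 50))
  # single member at rank 1 -> ES = 1
  expect_equal(gsea_es(ranked, "g1")$es, 1, tolerance = 1e-12)
  # single member at the last rank -> maximal negative deviation
  es_last <- gsea_es(ranked, "g50")
  expect_equal(es_last$es, -(49) / 49, tolerance = 1e-12)
  # brute-force running sum for a random set
  set.seed(83)
  memb <- sample(ranked$gene, 8)
  es <- gsea_es(ranked, memb, weight_p = 1)
  hit <- ranked$gene %in% memb
  w <- abs(ranked$score)
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (50 - 8))
  run <- cumsum(inc)
  expect_equal(es$running, run, tolerance = 1e-12)
  expect_equal(es$es, run[which.max(abs(run))], tolerance = 1e-12)
  expect_error(gsea_es(ranked, "nope"), "no member")
  expect_error(gsea_es(ranked, ranked$gene), "whole")
})

test_that("weight 0 makes ES rank-only and label swap flips the sign", {
  ranked <- data.frame(gene = sprintf("g%d", 1:40),
                       score = sort(rexp(40), decreasing = TRUE))
  set.seed(84)
  memb <- sample(ranked$gene, 6)
  es_a <- gsea_es(ranked, memb, weight_p = 0)$es
  # monotone transform of the scores leaves rank-only ES unchanged
  ranked2 <- ranked; ranked2$score <- log1p(ranked2$score)
  expect_equal(gsea_es(ranked2, memb, weight_p = 0)$es, es_a,
               tolerance = 1e-12)
  # phenotype swap flips the ranking and the ES sign
  set.seed(85)
  expr <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(sprintf("g%d", 1:60), sprintf("s%d", 1:8)))
  labels <- rep(c("A", "B"), each = 4)
  r1 <- signal2noise_rank(expr, labels)
  # exchanging the phenotype groups negates every score
  r2 <- signal2noise_rank(expr[, c(5:8, 1:4)], labels)
  set_g <- sprintf("g%d", 1:6)
  expect_equal(gsea_es(r1, set_g, weight_p = 0)$es,
               -gsea_es(r2, set_g, weight_p = 0)$es, tolerance = 1e-10)
})

test_that("phenotype permutation GSEA detects planted sets and stays calibrated", {
  set.seed(86)
  n_genes <- 400
  expr <- matrix(rnorm(n_genes * 12), n_genes, 12,
                 dimnames = list(sprintf("g%d", 1:n_genes),
                                 sprintf("s%d", 1:12)))
  labels <- rep(c("A", "B"), each = 6)
  planted <- sprintf("g%d", 1:25)
  expr[planted, labels == "A"] <- expr[planted, labels == "A"] + 1.5
  res <- gsea_significance(expr, labels, list(planted = planted),
                           n_perm = 100, seed = 87)
  expect_gt(res$nes, 0)
  expect_lte(res$nominal_p, 0.05)
  expect_equal(res$n_permutations, 100)
  # null sets yield uniform nominal p-values
  null_sets <- lapply(1:50, function(i)
    sample(sprintf("g%d", 101:n_genes), 15))
  names(null_sets) <- sprintf("null%d", 1:50)
  null_expr <- matrix(rnorm(n_genes * 12), n_genes, 12,
                      dimnames = dimnames(expr))
  res0 <- gsea_significance(null_expr, labels, null_sets, n_perm = 100,
                            seed = 88)
  expect_gt(suppressWarnings(
    stats::ks.test(res0$nominal_p, "punif"))$p.value, 0.01)
  expect_true(all(res0$fdr >= 0 & res0$fdr <= 1))
  expect_error(gsea_significance(expr, labels, list(planted), n_perm = 0),
               "n_perm")
  expect_warning(gsea_significance(expr[, 1:6], labels[c(1:3, 7:9)],
                                   list(planted = planted), n_perm = 50,
                                   seed = 89), "distinct")
})

test_that("GO statistics reproduce the fold-enrichment arithmetic", {
  # fixtures built so 'expected' comes out exactly at the printed values
  uni1 <- sprintf("u%d", 1:129600)
  term1 <- uni1[1:1296]
  query1 <- c(uni1[1:33], uni1[2000:2675])     # 709 genes, 33 in the term
  go1 <- go_enrichment(query1, uni1, list(defense_response = term1))
  expect_equal(go1$reference, 1296)
  expect_equal(go1$expected, 7.09, tolerance = 1e-12)
  expect_equal(go1$specific, 33)
  expect_equal(round(go1$fold_enrichment, 2), 4.65)

  uni2 <- sprintf("v%d", 1:9500)
  term2 <- uni2[1:95]
  query2 <- c(uni2[1:9], uni2[200:242])        # 52 genes, 9 in the term
  go2 <- go_enrichment(query2, uni2, list(antigen_presentation = term2))
  expect_equal(go2$expected, 0.52, tolerance = 1e-12)
  expect_equal(round(go2$fold_enrichment, 2), 17.31)

  # query = universe -> fold enrichment 1 for every term
  uni <- sprintf("g%d", 1:40)
  ann <- list(t1 = uni[1:10], t2 = uni[5:20])
  go_all <- go_enrichment(uni, uni, ann)
  expect_equal(go_all$fold_enrichment, c(1, 1))
  expect_error(go_enrichment(c(uni, "zz"), uni, ann), "outside")
  expect_message(go_enrichment(uni[1:5], uni,
                               c(ann, list(t0 = "absent"))), "skipped")
})

test_that("specific counts accumulate once per annotated term (incidence oracle)", {
  set.seed(90)
  uni <- sprintf("g%d", 1:200)
  query <- sample(uni, 40)
  ann <- lapply(1:8, function(i) sample(uni, sample(10:60, 1)))
  names(ann) <- sprintf("t%d", 1:8)
  go <- go_enrichment(query, uni, ann)
  inc <- vapply(ann, function(tg) sum(query %in% tg), numeric(1))
  expect_equal(go$specific[match(names(ann), go$term)], unname(inc))
  expect_true(all(go$adjusted_p >= go$p_value - 1e-12))
})

test_that("ES agrees with an independent implementation on a shared fixture", {
  set.seed(91)
  stats_v <- sort(rnorm(100), decreasing = TRUE)
  names(stats_v) <- sprintf("g%d", 1:100)
  ranked <- data.frame(gene = names(stats_v), score = unname(stats_v))
  memb <- sample(names(stats_v), 12)
  ours <- gsea_es(ranked, memb, weight_p = 1)$es
  fg <- fgsea::calcGseaStat(stats_v, selectedStats = which(names(stats_v)
                                                           %in% memb),
                            gseaParam = 1)
  expect_equal(ours, fg, tolerance = 1e-6)
})

test_that("the bundled synthetic signature file loads as gene sets", {
  gmt <- system.file("extdata", "synthetic_im_signatures.gmt",
                     package = "velofate")
  sets <- read_gmt(gmt)
  expect_length(sets, 4)
  expect_equal(length(sets$IM1_IM2_shared_signature_synthetic), 634)
  expect_equal(length(sets$IM3_signature_synthetic), 97)
  expect_false(anyDuplicated(sets[[1]]) > 0)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("a", "b", "c"), beta = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, sets)
})
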