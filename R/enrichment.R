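#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: name, description, members...).
#' @return named list of unique-member character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- mapply(function(nm, genes, d)
    paste(c(nm, d, unique(genes)), collapse = "\t"),
    names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

#' Build an expression signature from a marker table
#'
#' Genes upregulated in the group (positive log fold change above
#' \code{logfc_min}) and expressed in more than \code{min_pct} of the
#' group's cells (strict inequalities, matching "more than 10% of cells").
#'
#' @param markers a \code{\link{find_markers}} table.
#' @param logfc_min log-fold-change threshold (default 0.1).
#' @param min_pct expressed-fraction threshold (default 0.10).
#' @return character vector of signature genes (possibly empty, with a
#'   warning).
#' @export
build_signature <- function(markers, logfc_min = 0.1, min_pct = 0.10) {
  keep <- markers$log_fc > logfc_min & markers$pct_in > min_pct
  genes <- unique(markers$gene[keep])
  if (length(genes) == 0)
    warning("no gene passes the signature thresholds; returning an empty set")
  genes
}

#' Exclusive region counts of a collection of gene sets
#'
#' Counts every Venn region: for each non-empty combination of sets, the
#' number of genes belonging to exactly those sets.
#'
#' @param sets named list of at least two character vectors.
#' @return data.frame with \code{region} (set names joined by "&") and
#'   \code{count}, covering all 2^k - 1 regions.
#' @export
set_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(key, levels = combos))
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Signal2Noise gene ranking between two phenotypes
#'
#' Per gene, (muA - muB) / (sA + sB) where each group standard deviation is
#' floored at max(0.2 * |mu|, 0.2), as in the canonical GSEA
#' implementation. Requires at least 3 samples per phenotype.
#'
#' @param expr genes x samples expression matrix.
#' @param labels per-sample phenotype labels (exactly two levels); the
#'   first level encountered is phenotype A.
#' @return data.frame with \code{gene} and \code{score}, sorted by
#'   descending score (ties broken by gene name).
#' @export
signal2noise_rank <- function(expr, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two levels")
  a <- labels == lev[1]
  b <- labels == lev[2]
  if (sum(a) < 3 || sum(b) < 3)
    stop("fewer than 3 samples in a phenotype; use a different ranking metric")
  x <- as.matrix(expr)
  muA <- rowMeans(x[, a, drop = FALSE]); muB <- rowMeans(x[, b, drop = FALSE])
  sdA <- apply(x[, a, drop = FALSE], 1, stats::sd)
  sdB <- apply(x[, b, drop = FALSE], 1, stats::sd)
  sdA <- pmax(sdA, 0.2 * abs(muA), 0.2)
  sdB <- pmax(sdB, 0.2 * abs(muB), 0.2)
  score <- (muA - muB) / (sdA + sdB)
  ord <- order(-score, rownames(x))
  data.frame(gene = rownames(x)[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' GSEA enrichment score by the weighted running sum
#'
#' Walking down the ranked list, hits increment the running sum by
#' |score|^weight_p normalized over the set's hits and misses decrement it
#' by 1/(N - N_hit); the enrichment score is the signed maximum deviation
#' from zero.
#'
#' @param ranked a \code{\link{signal2noise_rank}}-style data.frame
#'   (columns \code{gene}, \code{score}), ordered.
#' @param set character vector of member genes.
#' @param weight_p hit weighting exponent (default 1).
#' @return list: \code{es}, \code{running} (profile over the list),
#'   \code{hit_positions}.
#' @export
gsea_es <- function(ranked, set, weight_p = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% set
  Nh <- sum(hit)
  if (Nh == 0) stop("gene set has no member in the ranked list")
  if (Nh == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight_p
  inc <- numeric(N)
  tot_hit <- sum(w[hit])
  inc[hit] <- if (tot_hit > 0) w[hit] / tot_hit else 1 / Nh
  inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hit_positions = which(hit))
}

#' GSEA significance by phenotype permutation
#'
#' Recomputes the Signal2Noise ranking and enrichment score under
#' \code{n_perm} random permutations of the phenotype labels. NES is
#' ES divided by the mean |permuted ES| of matching sign; the nominal
#' p-value is the fraction of same-sign permuted ES at least as extreme.
#' With several sets, FDR is the standard same-sign NES ratio (fraction of
#' permuted NES beyond each observed NES over the fraction of observed NES
#' beyond it, capped at 1); with a single set FDR equals the nominal p.
#'
#' @param expr genes x samples expression matrix.
#' @param labels per-sample phenotype labels (two levels).
#' @param sets named list of gene sets (a single character vector is
#'   wrapped).
#' @param n_perm number of phenotype permutations (default 100, > 0).
#' @param seed RNG seed.
#' @param weight_p hit weighting exponent.
#' @return data.frame per set: \code{set}, \code{es}, \code{nes},
#'   \code{nominal_p}, \code{fdr}, \code{n_permutations}.
#' @export
gsea_significance <- function(expr, labels, sets, n_perm = 100, seed = 1,
                              weight_p = 1) {
  if (n_perm <= 0) stop("n_perm must be > 0")
  if (!is.list(sets)) sets <- list(set = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  labels <- as.character(labels)
  n_distinct <- choose(length(labels), sum(labels == labels[1]))
  if (n_distinct < n_perm)
    warning("only ", n_distinct, " distinct label permutations exist; ",
            "permutations will repeat")
  set.seed(seed)
  obs_rank <- signal2noise_rank(expr, labels)
  es_obs <- vapply(sets, function(s) gsea_es(obs_rank, s, weight_p)$es,
                   numeric(1))
  es_perm <- matrix(NA_real_, n_perm, length(sets))
  for (p in seq_len(n_perm)) {
    pl <- sample(labels)
    pr <- signal2noise_rank(expr, pl)
    es_perm[p, ] <- vapply(sets, function(s) gsea_es(pr, s, weight_p)$es,
                           numeric(1))
  }
  nes <- nom_p <- numeric(length(sets))
  nes_perm <- matrix(NA_real_, n_perm, length(sets))
  for (k in seq_along(sets)) {
    ep <- es_perm[, k]
    same <- if (es_obs[k] >= 0) ep[ep >= 0] else ep[ep < 0]
    denom <- mean(abs(same))
    nes[k] <- if (length(same) && denom > 0) es_obs[k] / denom else NA_real_
    nom_p[k] <- if (length(same))
      mean(abs(same) >= abs(es_obs[k])) else 1 / n_perm
    pos <- ep >= 0
    mp <- mean(abs(ep[pos]))
    mn <- mean(abs(ep[!pos]))
    nes_perm[pos, k] <- if (is.finite(mp) && mp > 0) ep[pos] / mp else NA
    nes_perm[!pos, k] <- if (is.finite(mn) && mn > 0) -ep[!pos] / mn else NA
    nes_perm[!pos, k] <- -abs(nes_perm[!pos, k])
  }
  fdr <- vapply(seq_along(sets), function(k) {
    if (length(sets) == 1) return(nom_p[k])
    nv <- nes[k]
    if (!is.finite(nv)) return(NA_real_)
    allp <- as.numeric(nes_perm)
    if (nv >= 0) {
      num <- mean(allp >= nv, na.rm = TRUE) /
        max(mean(allp >= 0, na.rm = TRUE), 1e-12)
      den <- mean(nes >= nv) / max(mean(nes >= 0), 1e-12)
    } else {
      num <- mean(allp <= nv, na.rm = TRUE) /
        max(mean(allp < 0, na.rm = TRUE), 1e-12)
      den <- mean(nes <= nv) / max(mean(nes < 0), 1e-12)
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))
  data.frame(set = names(sets), es = es_obs, nes = nes, nominal_p = nom_p,
             fdr = pmin(pmax(fdr, 0), 1), n_permutations = n_perm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' GO-style over-representation statistics
#'
#' Per term: reference = |term within the universe|, expected =
#' reference x |query| / |universe|, specific = |term within the query|,
#' fold enrichment = specific / expected; the p-value comes from Fisher's
#' exact test (one-sided, over-representation) or the binomial test, with
#' Benjamini-Hochberg adjustment across terms. Terms with expected = 0 are
#' skipped (with a message).
#'
#' @param query character vector of genes of interest (must be contained in
#'   the universe).
#' @param universe character vector of all considered genes.
#' @param annotations named list: term -> member genes.
#' @param method \code{"fisher"} (default) or \code{"binomial"}.
#' @return data.frame per term: term, reference, expected, specific,
#'   fold_enrichment, p_value, adjusted_p.
#' @export
go_enrichment <- function(query, universe, annotations,
                          method = c("fisher", "binomial")) {
  method <- match.arg(method)
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  nq <- length(query)
  nu <- length(universe)
  rows <- lapply(names(annotations), function(term) {
    tg <- intersect(annotations[[term]], universe)
    ref <- length(tg)
    expected <- ref * nq / nu
    if (expected == 0) return(NULL)
    spec <- length(intersect(tg, query))
    p <- if (method == "fisher") {
      stats::fisher.test(matrix(c(spec, nq - spec, ref - spec,
                                  nu - nq - ref + spec), 2, 2),
                         alternative = "greater")$p.value
    } else {
      stats::binom.test(spec, nq, ref / nu, alternative = "greater")$p.value
    }
    data.frame(term = term, reference = ref, expected = expected,
               specific = spec, fold_enrichment = spec / expected,
               p_value = p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) message(skipped, " term(s) with expected = 0 skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no term overlaps the universe")
  out$adjusted_p <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), , drop = FALSE]
}
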