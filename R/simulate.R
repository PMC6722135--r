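#' Default configuration of the synthetic cohort
#'
#' The generator emulates a merged lung mononuclear-phagocyte dataset with
#' five populations: two stable monocyte pools (Ly-6Chi classical and Ly-6Clo
#' patrolling), one population in active transit (CD64+CD16.2+ monocytes),
#' and two stable interstitial-macrophage pools (CD206- and CD206+ IM). A
#' block of 100 trajectory genes is switched from a silent to an active
#' transcriptional state along the planted lineage Ly-6Clo monocyte ->
#' CD16.2+ intermediate -> CD206- IM; transit cells are sampled at
#' mid-trajectory latent times so their spliced/unspliced phase-plane
#' position lies above the steady-state line u = gamma * s.
#'
#' @param pop_sizes named integer vector of cells per population.
#' @param n_genes total number of genes (includes mito/trajectory/markers).
#' @param n_traj_genes number of planted trajectory genes.
#' @param n_mito number of mitochondrial (tagged, stable) genes.
#' @param n_markers_per_pop population-specific marker genes per population.
#' @param marker_fold fold elevation of a marker gene in its own population.
#' @param base_rate median baseline transcription rate (sets sequencing
#'   depth; trajectory genes are drawn around 4/3 of it).
#' @param transit_marker_fold marker fold of the transit population (milder:
#'   extravasating CD16.2+ monocytes differ from patrolling monocytes by a
#'   handful of moderately induced genes).
#' @param traj_fold fold change of trajectory genes between lineage endpoints.
#' @param hk_sigma sdlog of the per-gene, per-population log-normal
#'   modulation of constitutive genes (cell types share housekeeping
#'   programs at quantitatively different levels; this also anchors the
#'   extreme-quantile phase-plane fit with real between-population signal).
#' @param libsize_sigma sdlog of the mean-one log-normal per-cell size factor.
#' @param alpha_cell_sigma sdlog of the mean-one log-normal per-cell,
#'   per-gene transcription-rate heterogeneity. It emulates slowly varying
#'   transcriptional heterogeneity: both layers scale together, so cells
#'   spread along (not off) the steady-state line u = gamma * s, as
#'   expression heterogeneity does in real data. Skipped when
#'   \code{noise = "none"}.
#' @param traj_cell_sigma rate-heterogeneity sdlog of trajectory genes,
#'   smaller than \code{alpha_cell_sigma}: the planted differentiation
#'   program drives these genes, so their expression tracks latent time
#'   tightly.
#' @param n_modules,module_sigma co-regulated gene programs: every
#'   non-mitochondrial gene belongs to one of \code{n_modules} modules and
#'   every cell draws a mean-one log-normal activity (sdlog
#'   \code{module_sigma}) per module, multiplying both layers. Unlike the
#'   i.i.d. per-gene heterogeneity, program activity is shared by
#'   transcriptionally similar cells' neighborhoods, so it survives k-NN
#'   pooling — the within-population expression structure that anchors the
#'   extreme-quantile phase-plane fit in real data. Skipped when
#'   \code{noise = "none"}.
#' @param mito_frac_mean target mean mitochondrial count fraction per cell.
#' @param mito_cell_sigma sdlog of the per-cell jitter on the mito fraction
#'   (capped at 0.04 so non-violating cells stay below the 5% QC filter).
#' @param mito_violator_range uniform range of the mito fraction planted in
#'   high-mito QC-violating cells.
#' @param qc_low_factor depth multiplier of the planted low-depth
#'   QC-violating cells.
#' @param n_qc_low,n_qc_mito planted QC-violating cells (low depth / high
#'   mito), appended on top of \code{pop_sizes}.
#' @param transit_time_range latent-time window (fraction of the full
#'   transit) over which intermediate cells are spread.
#' @param total_transit_time full transit duration in splicing-time units.
#' @param unspliced_capture relative capture efficiency of the unspliced
#'   layer (1 keeps both layers on the same scale).
#' @param steady_state when TRUE, transit cells are placed at the
#'   quasi-static equilibrium of rates interpolated along the same path
#'   (u = gamma * s everywhere): a null cohort with the same geometry but
#'   no kinetic disequilibrium, for testing that velocity vanishes at
#'   steady state.
#' @param noise noise model: \code{"poisson"} (default), \code{"nb"}
#'   (negative binomial, see \code{nb_size}) or \code{"none"} (returns the
#'   real-valued kinetic means; diagnostic mode).
#' @param nb_size negative-binomial size (inverse overdispersion) when
#'   \code{noise = "nb"}.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(pop_sizes = c(MonoLy6Chi = 200, MonoLy6Clo = 200,
                                     CD16_2_intermediate = 200,
                                     CD206neg_IM = 200, CD206pos_IM = 200),
                       n_genes = 1000, n_traj_genes = 100, n_mito = 20,
                       n_markers_per_pop = 30, marker_fold = 4,
                       transit_marker_fold = 4,
                       traj_fold = 8, hk_sigma = 0.35, libsize_sigma = 0.3,
                       alpha_cell_sigma = 0.35, traj_cell_sigma = 0.15,
                       base_rate = 6, n_modules = 4, module_sigma = 0.5,
                       mito_frac_mean = 0.02, mito_cell_sigma = 0.2,
                       mito_violator_range = c(0.08, 0.15),
                       qc_low_factor = 0.005,
                       n_qc_low = 10, n_qc_mito = 10,
                       transit_time_range = c(0.2, 0.8),
                       total_transit_time = 4,
                       unspliced_capture = 1, steady_state = FALSE,
                       noise = c("poisson", "nb", "none"), nb_size = 10) {
  noise <- match.arg(noise)
  cfg <- list(pop_sizes = pop_sizes, n_genes = n_genes,
              n_traj_genes = n_traj_genes, n_mito = n_mito,
              n_markers_per_pop = n_markers_per_pop,
              marker_fold = marker_fold,
              transit_marker_fold = transit_marker_fold,
              traj_fold = traj_fold, hk_sigma = hk_sigma,
              libsize_sigma = libsize_sigma,
              alpha_cell_sigma = alpha_cell_sigma,
              traj_cell_sigma = traj_cell_sigma,
              base_rate = base_rate,
              n_modules = n_modules, module_sigma = module_sigma,
              mito_frac_mean = mito_frac_mean,
              mito_cell_sigma = mito_cell_sigma,
              mito_violator_range = mito_violator_range,
              qc_low_factor = qc_low_factor,
              n_qc_low = n_qc_low, n_qc_mito = n_qc_mito,
              transit_time_range = transit_time_range,
              total_transit_time = total_transit_time,
              unspliced_capture = unspliced_capture,
              steady_state = steady_state,
              noise = noise, nb_size = nb_size)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$pop_sizes)) || any(!nzchar(names(cfg$pop_sizes))))
    stop("pop_sizes must be a named vector")
  if (any(cfg$pop_sizes <= 0)) stop("all population sizes must be > 0")
  if (cfg$traj_fold <= 1)
    stop("trajectory endpoints coincide (traj_fold <= 1): no lineage to plant")
  needed <- cfg$n_mito + cfg$n_traj_genes +
    cfg$n_markers_per_pop * length(cfg$pop_sizes)
  if (cfg$n_genes < needed)
    stop("n_genes too small for the requested mito/trajectory/marker blocks")
  invisible(cfg)
}

# The planted lineage: patrolling monocytes extravasate through a CD16.2+
# intermediate toward the CD206- interstitial macrophage state.
TRAJ_POPS <- c("MonoLy6Clo", "CD16_2_intermediate", "CD206neg_IM")

#' Simulate a spliced/unspliced cohort with known ground truth
#'
#' Draws per-gene kinetic parameters, builds per-population kinetic means
#' (stable populations at their transcriptional steady state, transit cells
#' along the analytic induction curve of the trajectory genes), and samples
#' counts under the configured noise model with a mean-one log-normal
#' per-cell size factor. A tagged block of mitochondrial genes and a small
#' set of planted QC-violating cells (too few detected genes, or
#' mitochondrial fraction above threshold) are included so quality filters
#' have work to do.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; the output is bit-reproducible for a fixed seed.
#' @return list with elements \code{counts} (\code{\link{layered_counts}}),
#'   \code{truth} (per-cell data.frame: cell_id, population, latent_time,
#'   expected_fate, qc_violation, size_factor), \code{params}
#'   (\code{\link{kinetic_params}}), \code{gene_roles} (per-gene role
#'   label), and \code{state_on} (genes x populations logical activity
#'   matrix).
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("an explicit seed is required")
  validate_sim_config(config)
  set.seed(as.integer(seed))
  pops <- names(config$pop_sizes)
  n_pop <- length(pops)

  ## ---- gene roles -------------------------------------------------------
  n_marker <- config$n_markers_per_pop * n_pop
  roles <- c(rep("mito", config$n_mito),
             rep("trajectory", config$n_traj_genes),
             rep(pops, each = config$n_markers_per_pop),
             rep("housekeeping",
                 config$n_genes - config$n_mito - config$n_traj_genes - n_marker))
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  genes[roles == "mito"] <- sprintf("mt-sim%02d", seq_len(config$n_mito))

  ## ---- kinetic parameters ----------------------------------------------
  gamma <- pmin(pmax(stats::rlnorm(config$n_genes, log(0.7), 0.4), 0.2), 2.5)
  base <- stats::rlnorm(config$n_genes, log(config$base_rate), 0.5)
  # trajectory genes are drawn from the well-expressed range so the planted
  # kinetic signal is measurable after count noise
  base[roles == "trajectory"] <-
    pmax(stats::rlnorm(config$n_traj_genes, log(config$base_rate * 4 / 3), 0.3),
         config$base_rate * 2 / 3)
  fold <- ifelse(roles == "trajectory", config$traj_fold,
          ifelse(roles == "CD16_2_intermediate", config$transit_marker_fold,
          ifelse(roles %in% pops, config$marker_fold, 2)))
  alpha_off <- base
  alpha_on <- base * fold
  # housekeeping and mito genes are constitutively active at their base rate
  const <- roles %in% c("housekeeping", "mito")
  alpha_on[const] <- base[const]
  alpha_off[const] <- 0
  params <- kinetic_params(genes, alpha_on = alpha_on, alpha_off = alpha_off,
                           beta = 1, gamma_true = gamma, switch_time = 0)

  ## ---- per-population activity states -----------------------------------
  state_on <- matrix(FALSE, config$n_genes, n_pop, dimnames = list(genes, pops))
  state_on[const, ] <- TRUE
  for (p in pops) state_on[roles == p, p] <- TRUE
  state_on[roles == "trajectory", "CD206neg_IM"] <- TRUE

  ## constitutive genes are expressed at population-modulated levels
  ## (log-normal factor on alpha); mito genes stay population-invariant
  hk <- roles == "housekeeping"
  modulation <- matrix(1, config$n_genes, n_pop, dimnames = list(genes, pops))
  modulation[hk, ] <- stats::rlnorm(sum(hk) * n_pop, 0, config$hk_sigma)

  ## ---- per-population kinetic means --------------------------------------
  u_mean <- s_mean <- matrix(0, config$n_genes, n_pop,
                             dimnames = list(genes, pops))
  for (p in pops) {
    a <- ifelse(state_on[, p], params$alpha_on, params$alpha_off) *
      modulation[, p]
    u_mean[, p] <- a / params$beta
    s_mean[, p] <- a / params$gamma_true
  }

  mito <- roles == "mito"

  ## ---- assemble cells ----------------------------------------------------
  cell_pop <- rep(pops, config$pop_sizes)
  n_core <- length(cell_pop)
  # planted QC violators are extra cells drawn from the first population
  viol <- c(rep("low_genes", config$n_qc_low), rep("high_mito", config$n_qc_mito))
  cell_pop <- c(cell_pop, rep(pops[1], length(viol)))
  qc_violation <- c(rep("none", n_core), viol)
  n_cells <- length(cell_pop)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  latent <- rep(NA_real_, n_cells)
  latent[cell_pop == "MonoLy6Clo"] <- 0
  latent[cell_pop == "CD206neg_IM"] <- 1
  is_transit <- cell_pop == "CD16_2_intermediate"
  latent[is_transit] <- stats::runif(sum(is_transit),
                                     config$transit_time_range[1],
                                     config$transit_time_range[2])

  ## expected per-cell mean matrices
  Um <- u_mean[, cell_pop, drop = FALSE]
  Sm <- s_mean[, cell_pop, drop = FALSE]
  traj <- roles == "trajectory"
  if (any(is_transit)) {
    ## transit cells carry the differentiation program: trajectory genes and
    ## the terminal population's markers are being induced, the starting
    ## population's markers repressed, and constitutive levels drift
    ## log-linearly between the endpoint populations' modulation factors
    ind <- traj | roles == "CD206neg_IM"       # switching on
    rep_ <- roles == "MonoLy6Clo"              # switching off
    p_ind <- params[ind, , drop = FALSE]
    p_rep <- params[rep_, , drop = FALSE]
    ss_ind0 <- steady_state_means(p_ind, "silent")
    ss_rep0 <- steady_state_means(p_rep, "active")
    tau <- latent[is_transit] * config$total_transit_time
    tnorm <- latent[is_transit]
    log_m0 <- log(modulation[hk, "MonoLy6Clo"])
    log_m1 <- log(modulation[hk, "CD206neg_IM"])
    for (k in seq_along(tau)) {
      idx <- which(is_transit)[k]
      if (config$steady_state) {
        ## null mode: rates interpolated along the path, cells at their
        ## quasi-static equilibrium (u = gamma * s holds exactly)
        a_ind <- exp(log(p_ind$alpha_off) +
                       tnorm[k] * (log(p_ind$alpha_on) - log(p_ind$alpha_off)))
        Um[ind, idx] <- a_ind / p_ind$beta
        Sm[ind, idx] <- a_ind / p_ind$gamma_true
        a_rep <- exp(log(p_rep$alpha_on) +
                       tnorm[k] * (log(pmax(p_rep$alpha_off, 1e-3)) -
                                     log(p_rep$alpha_on)))
        Um[rep_, idx] <- a_rep / p_rep$beta
        Sm[rep_, idx] <- a_rep / p_rep$gamma_true
      } else {
        mi <- trajectory_moments(p_ind, tau[k], ss_ind0$u_mean,
                                 ss_ind0$s_mean, "active")
        Um[ind, idx] <- mi$u_t
        Sm[ind, idx] <- mi$s_t
        mr <- trajectory_moments(p_rep, tau[k], ss_rep0$u_mean,
                                 ss_rep0$s_mean, "silent")
        Um[rep_, idx] <- mr$u_t
        Sm[rep_, idx] <- mr$s_t
      }
      m_t <- exp(log_m0 + tnorm[k] * (log_m1 - log_m0))
      a_hk <- params$alpha_on[hk] * m_t
      Um[hk, idx] <- a_hk / params$beta[hk]
      Sm[hk, idx] <- a_hk / params$gamma_true[hk]
    }
  }

  ## per-cell, per-gene transcription-rate heterogeneity (both layers scale
  ## together: heterogeneous cells slide along the u = gamma * s line)
  if (config$noise != "none" && config$alpha_cell_sigma > 0) {
    sa <- rep(config$alpha_cell_sigma, config$n_genes)
    ## the planted program drives trajectory genes tightly: their
    ## gene-autonomous rate noise is smaller than that of bystander genes
    sa[traj] <- config$traj_cell_sigma
    eta <- matrix(stats::rlnorm(length(Um), rep(-sa^2 / 2, n_cells),
                                rep(sa, n_cells)), nrow(Um), ncol(Um))
    Um <- Um * eta
    Sm <- Sm * eta
  }

  ## co-regulated program (module) activity: per-cell factors shared by all
  ## genes of a module. Mito genes are module-free; trajectory genes are
  ## driven by the differentiation program itself, not by orthogonal
  ## stochastic programs, so they are module-free too.
  gene_module <- rep(NA_integer_, config$n_genes)
  in_mod <- !mito & !traj
  if (config$noise != "none" && config$n_modules > 0 &&
      config$module_sigma > 0) {
    sm_ <- config$module_sigma
    gene_module[in_mod] <- sample.int(config$n_modules, sum(in_mod),
                                      replace = TRUE)
    act <- matrix(stats::rlnorm(config$n_modules * n_cells, -sm_^2 / 2, sm_),
                  config$n_modules, n_cells)
    fac <- act[gene_module[in_mod], , drop = FALSE]
    Um[in_mod, ] <- Um[in_mod, ] * fac
    Sm[in_mod, ] <- Sm[in_mod, ] * fac
  }

  ## mitochondrial block: each cell's expected mito mass is a target
  ## fraction of its realized non-mito total (mean mito_frac_mean with
  ## log-normal per-cell jitter, capped below the QC threshold; violators
  ## drawn from mito_violator_range, above it); at steady state u = gamma*s
  sj <- config$mito_cell_sigma
  r <- config$mito_frac_mean * stats::rlnorm(n_cells, -sj^2 / 2, sj)
  r <- pmin(r, 0.04)
  nv <- sum(qc_violation == "high_mito")
  r[qc_violation == "high_mito"] <- stats::runif(nv,
                                                 config$mito_violator_range[1],
                                                 config$mito_violator_range[2])
  w_mito <- base[mito] / sum(base[mito])
  tot_nonmito <- colSums(Sm[!mito, , drop = FALSE])
  Sm[mito, ] <- w_mito %o% (tot_nonmito * r / (1 - r))
  Um[mito, ] <- Sm[mito, , drop = FALSE] * params$gamma_true[mito]

  ## mean-one log-normal size factors; low-depth violators are scaled down
  sl <- config$libsize_sigma
  sf <- stats::rlnorm(n_cells, -sl^2 / 2, sl)
  low <- qc_violation == "low_genes"
  sf[low] <- pmin(sf[low], 1) * config$qc_low_factor
  Um <- sweep(Um, 2, sf * config$unspliced_capture, `*`)
  Sm <- sweep(Sm, 2, sf, `*`)

  ## ---- sample counts -----------------------------------------------------
  draw <- switch(config$noise,
    poisson = function(m) stats::rpois(length(m), m),
    nb = function(m) stats::rnbinom(length(m), mu = m, size = config$nb_size),
    none = function(m) as.numeric(m))
  S <- matrix(draw(Sm), nrow(Sm), ncol(Sm), dimnames = list(genes, cells))
  U <- matrix(draw(Um), nrow(Um), ncol(Um), dimnames = list(genes, cells))

  counts <- if (config$noise == "none") {
    ## diagnostic mode: keep real-valued means, bypass integer validation
    x <- structure(list(spliced = as_sparse(S), unspliced = as_sparse(U),
                        genes = genes, cells = cells,
                        mito = grepl("^mt-", genes), mito_pattern = "^mt-"),
                   class = "layered_counts")
    x
  } else layered_counts(S, U, mito_pattern = "^mt-")

  truth <- data.frame(
    cell_id = cells,
    population = cell_pop,
    latent_time = latent,
    expected_fate = ifelse(cell_pop == "CD16_2_intermediate", "CD206neg_IM",
                           ifelse(cell_pop %in% names(config$pop_sizes),
                                  cell_pop, NA_character_)),
    qc_violation = qc_violation,
    size_factor = sf,
    stringsAsFactors = FALSE
  )
  list(counts = counts, truth = truth, params = params,
       gene_roles = roles, state_on = state_on, modulation = modulation,
       gene_module = gene_module, config = config)
}
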