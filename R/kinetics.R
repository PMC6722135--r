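#' Per-gene transcription/splicing/degradation kinetics
#'
#' The simulator models each gene with the standard two-ODE system
#' \deqn{du/dt = \alpha - \beta u, \qquad ds/dt = \beta u - \gamma s,}
#' where u is unspliced and s is spliced abundance, \eqn{\alpha} the
#' transcription rate (molecules per unit time; \code{alpha_on} when the gene
#' is active, \code{alpha_off} when silent), \eqn{\beta} the splicing rate
#' (fixed to 1 so that time is measured in splicing units) and
#' \eqn{\gamma > 0} the degradation rate. \code{switch_time} is the latent
#' time at which a trajectory gene switches transcriptional state.
#'
#' @param gene_id character vector of gene identifiers.
#' @param alpha_on,alpha_off transcription rates in the active/silent state;
#'   recycled; must satisfy \code{alpha_on > alpha_off >= 0}.
#' @param beta splicing rate, > 0 (default 1).
#' @param gamma_true degradation rate, > 0.
#' @param switch_time latent time of the on/off switch (default 0).
#' @return data.frame of class \code{kinetic_params}, one row per gene.
#' @export
kinetic_params <- function(gene_id, alpha_on, alpha_off = 0, beta = 1,
                           gamma_true, switch_time = 0) {
  df <- data.frame(gene_id = as.character(gene_id),
                   alpha_on = alpha_on, alpha_off = alpha_off,
                   beta = beta, gamma_true = gamma_true,
                   switch_time = switch_time,
                   stringsAsFactors = FALSE)
  if (any(df$alpha_off < 0)) stop("alpha_off must be >= 0")
  if (any(df$alpha_on <= df$alpha_off))
    stop("alpha_on must exceed alpha_off for every gene")
  if (any(df$beta <= 0)) stop("beta must be > 0")
  if (any(df$gamma_true <= 0)) stop("gamma_true must be > 0")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in kinetic_params")
  class(df) <- c("kinetic_params", "data.frame")
  df
}

#' Equilibrium unspliced/spliced means of the kinetic model
#'
#' At equilibrium the two-ODE system gives \eqn{u^* = \alpha/\beta} and
#' \eqn{s^* = \alpha/\gamma}.
#'
#' @param params a \code{kinetic_params} data.frame.
#' @param state \code{"active"} (uses \code{alpha_on}) or \code{"silent"}
#'   (uses \code{alpha_off}).
#' @return list with numeric vectors \code{u_mean} and \code{s_mean}.
#' @export
steady_state_means <- function(params, state = c("active", "silent")) {
  state <- match.arg(state)
  alpha <- if (state == "active") params$alpha_on else params$alpha_off
  list(u_mean = alpha / params$beta, s_mean = alpha / params$gamma_true)
}

#' Time-resolved means of the kinetic model
#'
#' Analytic solution of the induction/repression system started from
#' \code{(u0, s0)} under transcription rate alpha:
#' \deqn{u(t) = u_0 e^{-\beta t} + (\alpha/\beta)(1 - e^{-\beta t})}
#' and the matching closed form for s(t); the equal-rate case
#' \eqn{\beta = \gamma} is handled by its analytic limit
#' \eqn{(e^{-\beta t} - e^{-\gamma t})/(\gamma-\beta) \to t e^{-\beta t}}.
#'
#' @param params a \code{kinetic_params} data.frame.
#' @param t time(s) since the switch, >= 0 (recycled against genes).
#' @param u0,s0 initial abundances.
#' @param state transcriptional state after the switch.
#' @return list with numeric vectors \code{u_t}, \code{s_t}.
#' @export
trajectory_moments <- function(params, t, u0, s0,
                               state = c("active", "silent")) {
  state <- match.arg(state)
  if (any(t < 0)) stop("t must be >= 0")
  alpha <- if (state == "active") params$alpha_on else params$alpha_off
  beta <- params$beta
  gamma <- params$gamma_true
  eb <- exp(-beta * t)
  eg <- exp(-gamma * t)
  u_t <- u0 * eb + (alpha / beta) * (1 - eb)
  # transient kernel (e^{-bt} - e^{-gt})/(g - b), with the b == g limit t e^{-bt}
  near <- abs(gamma - beta) < 1e-10
  kern <- ifelse(near, t * eb, (eb - eg) / (gamma - beta))
  s_t <- s0 * eg + (alpha / gamma) * (1 - eg) + beta * (u0 - alpha / beta) * kern
  list(u_t = u_t, s_t = s_t)
}
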