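#' Per-analyte Z-scores of a proteome-profiler matrix
#'
#' Each analyte (row) is transformed to (value - analyte mean) / analyte
#' standard deviation (sample, n-1 denominator). Zero-variance rows return
#' zeros with a warning.
#'
#' @param m analytes x conditions numeric matrix (no missing values).
#' @return matrix of the same shape.
#' @export
analyte_zscores <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("analyte matrix contains missing values")
  if (ncol(m) < 2) stop("need at least 2 conditions per analyte")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant analyte row(s) set to zero")
    s[s == 0] <- Inf
  }
  (m - mu) / s
}

#' Control-subtracted mean fluorescence intensity
#'
#' @param sample_mfi sample MFI value(s).
#' @param control_mfis MFI values of the control cells (>= 1).
#' @return sample minus the mean of the controls.
#' @export
normalized_mfi <- function(sample_mfi, control_mfis) {
  if (length(control_mfis) < 1) stop("need at least one control MFI")
  sample_mfi - mean(control_mfis)
}

#' Spatial distribution percentages across tissue compartments
#'
#' Computes the mean cell count per field within each compartment (e.g.
#' peribronchial/perivascular vs alveolar), then the percentage of each
#' compartment's mean over the sum of means.
#'
#' @param field_counts data.frame with columns \code{compartment} and
#'   \code{count} (one row per imaged field).
#' @return data.frame: compartment, mean_per_field, percentage.
#' @export
spatial_distribution <- function(field_counts) {
  stopifnot(all(c("compartment", "count") %in% names(field_counts)))
  means <- tapply(field_counts$count, field_counts$compartment, mean)
  tot <- sum(means)
  if (tot == 0) stop("all-zero sample: spatial distribution undefined")
  data.frame(compartment = names(means),
             mean_per_field = as.numeric(means),
             percentage = 100 * as.numeric(means) / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Label-decay half-life from a fate-mapping time series
#'
#' Labeled fractions are normalized to the reference timepoint and a
#' log-linear decay ln(f) = -lambda * (t - t_ref) is fitted through the
#' origin by least squares; the half-life is ln(2)/lambda. A
#' non-decreasing series yields an explicit infinite half-life. When
#' replicate series are provided, a bootstrap over replicates gives a
#' percentile confidence interval.
#'
#' @param series data.frame with columns \code{time} (strictly increasing
#'   per replicate), \code{fraction} (> 0), optional \code{replicate}.
#' @param reference_timepoint normalization timepoint (default: the
#'   earliest).
#' @param n_boot bootstrap draws when replicates are present (default 500).
#' @param level CI coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list: \code{half_life}, \code{lambda}, \code{ci} (or NULL).
#' @export
label_decay_halflife <- function(series, reference_timepoint = NULL,
                                 n_boot = 500, level = 0.95, seed = 1) {
  stopifnot(all(c("time", "fraction") %in% names(series)))
  if (any(series$fraction <= 0)) stop("fractions must be > 0")
  if (is.null(reference_timepoint)) reference_timepoint <- min(series$time)
  fit_lambda <- function(df) {
    ref <- df$fraction[df$time == reference_timepoint]
    if (length(ref) == 0) stop("reference timepoint absent from series")
    f0 <- mean(ref)
    use <- df$time > reference_timepoint
    if (sum(use) < 1) stop("need at least one timepoint after the reference")
    tt <- df$time[use] - reference_timepoint
    y <- log(df$fraction[use] / f0)
    -sum(tt * y) / sum(tt^2)        # least squares through the origin
  }
  lambda <- fit_lambda(series)
  hl <- if (lambda <= 0) Inf else log(2) / lambda
  ci <- NULL
  if ("replicate" %in% names(series) &&
      length(unique(series$replicate)) >= 2) {
    reps <- unique(series$replicate)
    set.seed(seed)
    hb <- replicate(n_boot, {
      rs <- sample(reps, length(reps), replace = TRUE)
      df <- do.call(rbind, lapply(rs, function(r)
        series[series$replicate == r, , drop = FALSE]))
      l <- fit_lambda(df)
      if (l <= 0) Inf else log(2) / l
    })
    alpha <- (1 - level) / 2
    ci <- stats::quantile(hb, c(alpha, 1 - alpha), names = FALSE)
  }
  list(half_life = hl, lambda = lambda, ci = ci)
}
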