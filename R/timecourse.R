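# Per-step ensemble summaries, hourly interpolation, correlation with the
# behavioural signal and the two-null-model permutation significance test.

measure_registry <- function() {
  list(
    AND = function(c, cfg, seed) average_node_degree(c),
    CPL = function(c, cfg, seed) characteristic_path_length(c),
    AE = function(c, cfg, seed) average_efficiency(c),
    ACC = function(c, cfg, seed) average_clustering_coefficient(c),
    ACCE = function(c, cfg, seed) average_closeness_centrality(c),
    ANBC = function(c, cfg, seed) average_node_betweenness(c),
    AEBC = function(c, cfg, seed) average_edge_betweenness(c),
    AR = function(c, cfg, seed) average_radiality(c),
    LCPcorr = function(c, cfg, seed) lcp_correlation(c),
    SWsigma = function(c, cfg, seed)
      suppressWarnings(smallworldness_sigma(
        c, null_config(cfg$n_realizations, cfg$swap_multiplier, seed))),
    SWomega = function(c, cfg, seed)
      suppressWarnings(smallworldness_omega(
        c, null_config(cfg$n_realizations, cfg$swap_multiplier, seed))),
    PLpvalue = function(c, cfg, seed) power_lawness(c, cfg$n_bootstrap, seed),
    Q = function(c, cfg, seed) modularity_q(c, seed),
    SC = function(c, cfg, seed)
      suppressWarnings(structural_consistency(
        c, cfg$perturb_fraction, cfg$sc_repeats, seed)))
}

#' Summarize one measure over a time-step ensemble
#'
#' The collection of connectomes recorded inside one step's narrow window is
#' treated as a statistical sampling of the system's steady state: the mean
#' of the measure over the ensemble is the step's value and the standard
#' error quantifies its (typically small) uncertainty. Members on which the
#' measure is undefined are dropped from the mean and counted.
#'
#' @param ensemble Non-empty list of binarized `connectome`s.
#' @param measure_name One of [measure_names()].
#' @param cfg A [measure_config()] (stochastic measures draw per-member
#'   sub-seeds from `cfg$seed`).
#' @return A list with `mean`, `se`, `n_defined`, `n_undefined`.
#' @export
summarize_step <- function(ensemble, measure_name, cfg = measure_config()) {
  if (length(ensemble) == 0) stop("empty ensemble")
  fn <- measure_registry()[[measure_name]]
  if (is.null(fn)) stop("unknown measure: ", measure_name)
  seeds <- derive_seeds(cfg$seed, length(ensemble))
  vals <- vapply(seq_along(ensemble), function(i)
    tryCatch(fn(ensemble[[i]], cfg, seeds[i]), error = function(e) NA_real_),
    1)
  ok <- !is.na(vals)
  if (!any(ok)) stop("measure ", measure_name,
                     " undefined on every ensemble member")
  list(mean = mean(vals[ok]),
       se = if (sum(ok) > 1) stats::sd(vals[ok]) / sqrt(sum(ok)) else 0,
       n_defined = sum(ok), n_undefined = sum(!ok))
}

#' Time course of one measure over a series
#'
#' Applies [summarize_step()] at every step of a series.
#'
#' @param series A `connectome_series` (binarized members).
#' @param measure_name One of [measure_names()].
#' @param cfg A [measure_config()].
#' @return A list of class `measure_timecourse` with `measure_name`,
#'   `step_hours`, `means`, `ses`.
#' @export
measure_timecourse <- function(series, measure_name, cfg = measure_config()) {
  seeds <- derive_seeds(cfg$seed, length(series$ensembles))
  means <- ses <- numeric(length(series$ensembles))
  for (s in seq_along(series$ensembles)) {
    scfg <- cfg; scfg$seed <- seeds[s]
    sm <- summarize_step(series$ensembles[[s]], measure_name, scfg)
    means[s] <- sm$mean; ses[s] <- sm$se
  }
  structure(list(measure_name = measure_name,
                 step_hours = series$step_hours,
                 means = means, ses = ses),
            class = "measure_timecourse")
}

#' Convert recording-day labels to hours post surgery
#'
#' `"3 h"` maps to hour 3; `"d days"` maps to hour `24 * d` (the affine
#' mapping consistent with a grid running from hour 3 of day 1 to hour 24 of
#' day 16). The default study schedule maps to
#' `c(3, 96, 144, 216, 264, 288, 360, 384)`.
#'
#' @param labels Character vector like `c("3 h", "4 days", ...)`.
#' @return Integer hours, strictly increasing.
#' @export
step_hours_from_labels <- function(labels) {
  hours <- vapply(labels, function(lb) {
    m <- regmatches(lb, regexec("^\\s*(\\d+)\\s*(h|hour|hours|d|day|days)\\s*$",
                                lb, ignore.case = TRUE))[[1]]
    if (length(m) == 0) stop("unparseable time label: ", lb)
    v <- as.integer(m[2])
    if (tolower(substr(m[3], 1, 1)) == "h") v else 24L * v
  }, 1L, USE.NAMES = FALSE)
  if (is.unsorted(hours, strictly = TRUE))
    stop("labels must map to strictly increasing hours")
  hours
}

#' Default study labels
#' @return The eight recording labels of the default study design.
#' @export
default_step_labels <- function() {
  c("3 h", "4 days", "6 days", "9 days", "11 days", "12 days",
    "15 days", "16 days")
}

# Knot derivatives of the monotone piecewise cubic Hermite interpolant:
# zero wherever the secant slope changes sign (local extrema are knots, so
# no interval ever overshoots its local sample range), otherwise the
# weighted harmonic mean of the neighbouring secant slopes; endpoints use
# the shape-preserving one-sided three-point rule.
pchip_derivatives <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  if (n == 2) {
    d[] <- delta
    return(d)
  }
  for (k in 2:(n - 1)) {
    if (delta[k - 1] * delta[k] > 0) {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1] + w2 / delta[k])
    }                                   # else 0: knot is a local extremum
  }
  edge <- function(h0, h1, del0, del1) {
    dd <- ((2 * h0 + h1) * del0 - h0 * del1) / (h0 + h1)
    if (sign(dd) != sign(del0)) 0
    else if (sign(del0) != sign(del1) && abs(dd) > 3 * abs(del0))
      3 * del0
    else dd
  }
  d[1] <- edge(h[1], h[2], delta[1], delta[2])
  d[n] <- edge(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  d
}

#' Monotone shape-preserving interpolation on an hourly grid
#'
#' Interpolates the sparsely sampled per-step values on a one-hour grid with
#' monotone piecewise cubic Hermite interpolation (PCHIP): knot derivatives
#' are the weighted harmonic mean of neighbouring secant slopes, set to zero
#' where the slope changes sign. The interpolant passes through the samples
#' exactly, reproduces linear data, preserves monotone sections and never
#' leaves the local sample range of an interval (no overshoot). No
#' extrapolation is performed.
#'
#' @param sample_hours Strictly increasing numeric vector (>= 2 samples).
#' @param sample_values Numeric values at `sample_hours`; must all be defined.
#' @param grid_hours Consecutive integer grid, within the sample range;
#'   defaults to one value per hour from the first to the last sample (382
#'   points for the default study schedule).
#' @return A list of class `interpolated_signal` with `grid_hours`, `values`.
#' @export
pchip_interpolate <- function(sample_hours, sample_values,
                              grid_hours = NULL) {
  if (length(sample_hours) < 2) stop("need at least 2 samples")
  if (is.unsorted(sample_hours, strictly = TRUE))
    stop("sample_hours must be strictly increasing")
  if (length(sample_values) != length(sample_hours))
    stop("sample_values length mismatch")
  if (anyNA(sample_values) || any(!is.finite(sample_values)))
    stop("undefined sample values")
  if (is.null(grid_hours))
    grid_hours <- seq(sample_hours[1], sample_hours[length(sample_hours)])
  if (min(grid_hours) < sample_hours[1] ||
      max(grid_hours) > sample_hours[length(sample_hours)])
    stop("grid outside sample range (no extrapolation)")
  x <- as.numeric(sample_hours)
  y <- as.numeric(sample_values)
  d <- pchip_derivatives(x, y)
  k <- pmin(pmax(findInterval(grid_hours, x), 1L), length(x) - 1L)
  h <- x[k + 1] - x[k]
  t <- (grid_hours - x[k]) / h
  h00 <- 2 * t^3 - 3 * t^2 + 1
  h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2
  h11 <- t^3 - t^2
  vals <- y[k] * h00 + h * d[k] * h10 + y[k + 1] * h01 + h * d[k + 1] * h11
  structure(list(grid_hours = grid_hours, values = vals),
            class = "interpolated_signal")
}

#' Linear interpolation on an hourly grid
#'
#' Same contract as [pchip_interpolate()] with a piecewise linear
#' interpolant; used to check that conclusions are robust to the
#' interpolation scheme.
#'
#' @inheritParams pchip_interpolate
#' @return An `interpolated_signal`.
#' @export
linear_interpolate <- function(sample_hours, sample_values,
                               grid_hours = NULL) {
  if (length(sample_hours) < 2) stop("need at least 2 samples")
  if (is.null(grid_hours))
    grid_hours <- seq(sample_hours[1], sample_hours[length(sample_hours)])
  if (min(grid_hours) < sample_hours[1] ||
      max(grid_hours) > sample_hours[length(sample_hours)])
    stop("grid outside sample range (no extrapolation)")
  structure(list(grid_hours = grid_hours,
                 values = stats::approx(sample_hours, sample_values,
                                        xout = grid_hours)$y),
            class = "interpolated_signal")
}

#' Correlate two interpolated signals
#'
#' Pearson (linear) and Spearman (rank, nonlinear) correlation between two
#' signals on identical grids.
#'
#' @param a,b `interpolated_signal`s on the same grid.
#' @return Named numeric vector `c(pearson = ..., spearman = ...)`.
#' @export
correlate <- function(a, b) {
  if (!identical(a$grid_hours, b$grid_hours))
    stop("signals must share the same grid")
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0)
    stop("zero-variance signal")
  c(pearson = stats::cor(a$values, b$values),
    spearman = stats::cor(a$values, b$values, method = "spearman"))
}

#' Gaussian null behavioural sample
#'
#' Draws `n_steps` i.i.d. standard-normal values: the Gaussian white-noise
#' (G) null model for the behavioural signal.
#'
#' @param n_steps Number of time steps (>= 2).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Numeric vector of length `n_steps`.
#' @export
null_behavioral_G <- function(n_steps, seed = NULL) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  with_seed(seed, stats::rnorm(n_steps))
}

#' Distribution-preserving null behavioural sample
#'
#' Randomly permutes the observed behavioural values along the time
#' direction: the distribution-preserving (DP) null model, which keeps the
#' value multiset intact.
#'
#' @param behavioral Numeric vector (>= 2 values).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A permutation of `behavioral`.
#' @export
null_behavioral_DP <- function(behavioral, seed = NULL) {
  if (length(behavioral) < 2) stop("need at least 2 values")
  with_seed(seed, behavioral[sample.int(length(behavioral))])
}

# Interpolate M null behavioural draws on the grid; rows = iterations.
# Zero-variance interpolants are redrawn (counted, capped at 10 * M).
null_signal_matrix <- function(model, behav_samples, sample_hours,
                               grid_hours, M, interp_fn = pchip_interpolate) {
  n <- length(sample_hours)
  out <- matrix(NA_real_, M, length(grid_hours))
  redraws <- 0L
  for (i in seq_len(M)) {
    repeat {
      draw <- if (model == "G") stats::rnorm(n)
              else behav_samples[sample.int(n)]
      vals <- interp_fn(sample_hours, draw, grid_hours)$values
      if (stats::sd(vals) > 0) break
      redraws <- redraws + 1L
      if (redraws > 10L * M)
        stop("too many degenerate null draws")
    }
    out[i, ] <- vals
  }
  attr(out, "redraws") <- redraws
  out
}

#' Significance test for the correlation of interpolated signals
#'
#' Tests the null hypothesis that a high correlation between two interpolated
#' signals can arise by chance from the interpolation procedure alone. Both
#' real signals are interpolated on the hourly grid and their correlation `c`
#' observed; then `M` random behavioural 8-tuples are drawn from the chosen
#' null model (`"G"`: standard-normal white noise; `"DP"`: permutations of
#' the observed behavioural values), each interpolated the same way and
#' correlated with the interpolated topological signal. The two-tailed
#' p-value is `2 * min(#[C_rand <= c]/M, #[C_rand >= c]/M)` (capped at 1; a
#' continuity-corrected `(k+1)/(M+1)` variant is reported alongside but never
#' substituted). Significance is conventionally declared at `p < 0.05`.
#'
#' @param topo_samples,behav_samples Per-step values of the topological
#'   measure and of the behavioural test (all defined).
#' @param sample_hours Strictly increasing hour stamps of the steps.
#' @param model `"G"` or `"DP"`.
#' @param M Number of null iterations (>= 100).
#' @param corr_type `"pearson"` or `"spearman"`.
#' @param seed Integer seed.
#' @param interp_fn Interpolator, [pchip_interpolate()] by default.
#' @return A list with the observed correlation `c`, the p-value `p`, the
#'   continuity-corrected `p_cc`, and the null distribution record `null`
#'   (`model`, `M`, `correlations`, `redraws`).
#' @export
interpolation_significance_test <- function(topo_samples, behav_samples,
                                            sample_hours, model = c("G", "DP"),
                                            M = 10000,
                                            corr_type = c("pearson",
                                                          "spearman"),
                                            seed = 1,
                                            interp_fn = pchip_interpolate) {
  model <- match.arg(model)
  corr_type <- match.arg(corr_type)
  if (M < 100) stop("M below minimum 100")
  if (anyNA(topo_samples) || anyNA(behav_samples))
    stop("undefined sample values")
  grid <- seq(sample_hours[1], sample_hours[length(sample_hours)])
  topo_i <- interp_fn(sample_hours, topo_samples, grid)
  behav_i <- interp_fn(sample_hours, behav_samples, grid)
  obs <- unname(correlate(topo_i, behav_i)[corr_type])
  with_seed(seed, {
    nulls <- null_signal_matrix(model, behav_samples, sample_hours, grid, M,
                                interp_fn)
    cr <- drop(stats::cor(topo_i$values, t(nulls), method = corr_type))
    lo <- sum(cr <= obs); hi <- sum(cr >= obs)
    p <- min(1, 2 * min(lo / M, hi / M))
    p_cc <- min(1, 2 * min((lo + 1) / (M + 1), (hi + 1) / (M + 1)))
    list(c = obs, p = p, p_cc = p_cc,
         null = list(model = model, M = M, correlations = cr,
                     redraws = attr(nulls, "redraws")))
  })
}

#' Per-measure correlation summary of a study
#'
#' For each topological measure time course of a series: interpolates the
#' per-step ensemble means and the behavioural signal on the hourly grid,
#' computes Pearson and Spearman correlations, and assesses each correlation
#' against both null models. The `max_correlation` column reports the
#' correlation of larger absolute value (sign retained) and `max_p` the more
#' conservative (larger) of the two null-model p-values for that correlation;
#' `significant` flags `max_p < alpha`. Measures constant over time are
#' excluded with a note.
#'
#' @param series A `connectome_series` (binarized members).
#' @param cfg A [measure_config()] for the per-matrix measures.
#' @param measures Measure names to include (default all 14).
#' @param M Null iterations per model.
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the null draws.
#' @param timecourses Optional precomputed list of `measure_timecourse`
#'   objects (one per requested measure), to avoid recomputation.
#' @param interp_fn Interpolator, [pchip_interpolate()] by default.
#' @return A `data.frame` with one row per measure and columns `measure`,
#'   `pearson`, `spearman`, `p_G_pearson`, `p_G_spearman`, `p_DP_pearson`,
#'   `p_DP_spearman`, `max_correlation`, `max_p`, `significant`; excluded
#'   measures are reported in the `"excluded"` attribute.
#' @export
summary_table <- function(series, cfg = measure_config(),
                          measures = measure_names(), M = 10000,
                          alpha = 0.05, seed = 1, timecourses = NULL,
                          interp_fn = pchip_interpolate) {
  hours <- series$step_hours
  grid <- seq(hours[1], hours[length(hours)])
  behav_i <- interp_fn(hours, series$behavioral, grid)
  if (is.null(timecourses)) {
    timecourses <- lapply(measures, function(mn)
      measure_timecourse(series, mn, cfg))
  }
  names(timecourses) <- vapply(timecourses, `[[`, "", "measure_name")
  seeds <- derive_seeds(seed, 2L)
  # one shared null ensemble per model serves every measure and both
  # correlation types
  nulls <- list(
    G = with_seed(seeds[1], null_signal_matrix("G", series$behavioral,
                                               hours, grid, M, interp_fn)),
    DP = with_seed(seeds[2], null_signal_matrix("DP", series$behavioral,
                                                hours, grid, M, interp_fn)))
  rows <- list()
  excluded <- character(0)
  for (mn in measures) {
    tc <- timecourses[[mn]]
    if (is.null(tc) || anyNA(tc$means)) {
      excluded <- c(excluded, paste0(mn, ": undefined time course"))
      next
    }
    if (stats::sd(tc$means) == 0) {
      excluded <- c(excluded, paste0(mn, ": zero variance over time"))
      next
    }
    topo_i <- interp_fn(hours, tc$means, grid)
    cors <- correlate(topo_i, behav_i)
    ps <- list()
    for (model in c("G", "DP")) {
      for (ct in c("pearson", "spearman")) {
        cr <- drop(stats::cor(topo_i$values, t(nulls[[model]]),
                              method = ct))
        obs <- unname(cors[ct])
        ps[[paste0("p_", model, "_", ct)]] <-
          min(1, 2 * min(sum(cr <= obs) / M, sum(cr >= obs) / M))
      }
    }
    best_ct <- if (abs(cors["spearman"]) > abs(cors["pearson"]))
      "spearman" else "pearson"
    max_p <- max(ps[[paste0("p_G_", best_ct)]],
                 ps[[paste0("p_DP_", best_ct)]])
    rows[[mn]] <- data.frame(
      measure = mn,
      pearson = unname(cors["pearson"]),
      spearman = unname(cors["spearman"]),
      p_G_pearson = ps$p_G_pearson, p_G_spearman = ps$p_G_spearman,
      p_DP_pearson = ps$p_DP_pearson, p_DP_spearman = ps$p_DP_spearman,
      max_correlation = unname(cors[best_ct]),
      max_p = max_p,
      significant = max_p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) data.frame()
         else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "excluded") <- excluded
  out
}
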