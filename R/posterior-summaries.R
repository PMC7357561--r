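## evaluate theta(tau_g) for every retained demography: samples x grid
theta_at <- function(ens, tau_grid) {
  S <- nrow(ens$theta)
  out <- matrix(NA_real_, S, length(tau_grid))
  J <- ncol(ens$tau)
  for (s in seq_len(S)) {
    tau_s <- if (J > 0) ens$tau[s, ] else numeric(0)
    j <- findInterval(tau_grid, c(0, tau_s))
    out[s, ] <- ens$theta[s, j]
  }
  out
}

kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(log(x), bw = "nrd0")  # Silverman bandwidth on ln Ne
  exp(d$x[which.max(d$y)])
}

#' Posterior effective-size trajectory summaries
#'
#' Evaluates every retained step demography on a time grid and converts
#' `theta` to `Ne = theta / (4 mu)`. Reports the arithmetic mean, harmonic
#' mean, median, mode (Gaussian kernel density on `ln Ne`), and 2.5/97.5\%
#' quantiles per grid time, plus the global scaled-size estimates:
#' `theta_o` (posterior median of the first epoch), `theta_a` (last
#' epoch), and `theta_i` (median of the time-average over the horizon),
#' with their natural-scale counterparts. Times are reported in generations
#' and years (generation time default 8.75 y).
#'
#' @param ens a `posterior_ensemble` from [sample_posterior()].
#' @param grid time grid in generations; default 101 log-spaced points on
#'   `(0, gbar]`.
#' @param gen_years generation time in years.
#' @param horizons named generation horizons for point summaries (e.g.
#'   `c(N0 = 0, N5000 = 5000)`).
#' @return a `trajectory_summary`: list with data frame `trajectory`
#'   (generations, years, arithmetic, harmonic, median, mode, q025, q975),
#'   `global` (theta_o/i/a, N_o/i/a), and `horizons` (four summaries per
#'   named horizon).
#' @export
trajectory_summaries <- function(ens, grid = NULL, gen_years = 8.75,
                                 horizons = c(N0 = 0, N5000 = 5000)) {
  if (nrow(ens$theta) == 0L) stop("empty ensemble")
  mu <- ens$mu
  if (is.null(grid))
    grid <- exp(seq(log(1), log(ens$prior$gbar), length.out = 101))
  if (length(grid) == 0L) stop("empty grid")
  TH <- theta_at(ens, grid * mu)
  NE <- TH / (4 * mu)
  traj <- data.frame(
    generations = grid,
    years = grid * gen_years,
    arithmetic = colMeans(NE),
    harmonic = 1 / colMeans(1 / NE),
    median = apply(NE, 2, stats::median),
    mode = apply(NE, 2, kde_mode),
    q025 = apply(NE, 2, stats::quantile, 0.025),
    q975 = apply(NE, 2, stats::quantile, 0.975)
  )
  ## time-averaged theta over (0, gbar * mu] per sample
  Tg <- ens$prior$gbar * mu
  J <- ncol(ens$tau)
  tavg <- vapply(seq_len(nrow(ens$theta)), function(s) {
    tau_s <- if (J > 0) pmin(ens$tau[s, ], Tg) else numeric(0)
    widths <- diff(c(0, tau_s, Tg))
    widths <- pmax(widths, 0)
    sum(widths * ens$theta[s, seq_along(widths)]) / Tg
  }, numeric(1))
  th_o <- stats::median(ens$theta[, 1])
  th_a <- stats::median(ens$theta[, ncol(ens$theta)])
  th_i <- stats::median(tavg)
  glob <- list(theta_o = th_o, theta_i = th_i, theta_a = th_a,
               N_o = th_o / (4 * mu), N_i = th_i / (4 * mu),
               N_a = th_a / (4 * mu))
  hz <- lapply(horizons, function(g) {
    ne <- if (g <= 0) ens$theta[, 1] / (4 * mu) else
      as.numeric(theta_at(ens, g * mu)) / (4 * mu)
    c(arithmetic = mean(ne), harmonic = 1 / mean(1 / ne),
      median = stats::median(ne), mode = kde_mode(ne),
      q025 = unname(stats::quantile(ne, 0.025)),
      q975 = unname(stats::quantile(ne, 0.975)))
  })
  structure(list(trajectory = traj, global = glob, horizons = hz,
                 gen_years = gen_years, mu = mu),
            class = "trajectory_summary")
}

#' Posterior TMRCA density of two random alleles
#'
#' Averages the pair-coalescence density over the retained demographies on
#' a time grid. Peaks mark times when coalescence events concentrated -
#' the signature of past bottlenecks; the density is reported per
#' generation with a year conversion.
#'
#' @param ens a `posterior_ensemble`.
#' @param grid time grid in generations; default 200 log-spaced points on
#'   `(0, gbar]`.
#' @param gen_years generation time in years.
#' @param prominence fraction of the maximum below which local maxima are
#'   not reported as peaks.
#' @return a `tmrca_density`: data frame `density` (generations, years,
#'   density per generation) plus `peaks` (generations of detected local
#'   maxima).
#' @export
tmrca_density <- function(ens, grid = NULL, gen_years = 8.75,
                          prominence = 0.05) {
  if (nrow(ens$theta) == 0L) stop("empty ensemble")
  mu <- ens$mu
  if (is.null(grid))
    grid <- exp(seq(log(1), log(ens$prior$gbar), length.out = 200))
  tau <- grid * mu
  S <- nrow(ens$theta)
  J <- ncol(ens$tau)
  dens <- rep(0, length(tau))
  for (s in seq_len(S)) {
    demog <- step_demography(ens$theta[s, ],
                             if (J > 0) ens$tau[s, ] else numeric(0))
    dens <- dens + coalescence_density(demog, tau)
  }
  dens <- dens / S * mu  # per-generation scale
  y <- dens
  is_peak <- c(y[1] >= y[2],
               y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)],
               y[length(y)] > y[length(y) - 1])
  is_peak <- is_peak & y > prominence * max(y)
  structure(list(
    density = data.frame(generations = grid, years = grid * gen_years,
                         density = dens),
    peaks = grid[is_peak],
    gen_years = gen_years
  ), class = "tmrca_density")
}

#' Convert between generations and years
#'
#' @param generations generations (scalar or vector).
#' @param gen_years generation time in years per generation (study default
#'   8.75).
#' @return years.
#' @export
generations_to_years <- function(generations, gen_years = 8.75) {
  generations * gen_years
}
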