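#' Prior specification for the effective-size trajectory sampler
#'
#' Encodes the Bayesian priors of the step-function demography model.
#' Epoch log-sizes `ln theta_j` get a Gaussian prior centred on
#' `ln(4 Nbar mu)` with variance `varp1` (natural-log scale) and
#' first-order autoregressive correlation `rhocorn` between adjacent
#' epochs; transition log-times get independent Gaussians (variance
#' `varp2`) centred so the epochs spread over `(0, gbar * mu]`.
#'
#' @param nbar prior mean effective size, individuals (study default
#'   5,000).
#' @param varp1 prior variance of `ln N` (study default 3).
#' @param rhocorn adjacent-epoch log-size correlation in `[0, 1)`. The
#'   default 0.8 was calibrated on constant-size simulations so that the
#'   posterior does not infer spurious size swings (see the methods
#'   vignette); lower values give the step function more freedom.
#' @param varp2 prior variance of log transition times.
#' @param gbar time horizon in generations.
#' @param mu mutation rate per locus per generation (study default
#'   0.00015).
#' @param J number of transitions (J + 1 epochs).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(nbar = 5000, varp1 = 3, rhocorn = 0.8, varp2 = 3,
                       gbar = 10000, mu = 0.00015, J = 3L) {
  stopifnot(mu > 0, varp1 > 0, varp2 > 0, gbar > 0,
            rhocorn >= 0, rhocorn < 1, J >= 0)
  structure(list(nbar = nbar, varp1 = varp1, rhocorn = rhocorn,
                 varp2 = varp2, gbar = gbar, mu = mu, J = as.integer(J)),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_iter total iterations (study-scale default 1,000,000).
#' @param n_burnin dememorisation steps (study default 10,000).
#' @param n_retained states kept, evenly thinned after burn-in (study
#'   default 10,000).
#' @param n_chains parallel chains (run sequentially; chain 1 provides the
#'   retained ensemble, all chains feed convergence diagnostics).
#' @param seed RNG seed.
#' @param n_panels,n_nodes quadrature resolution of the likelihood kernel.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 1e6, n_burnin = 1e4, n_retained = 1e4,
                        n_chains = 1L, seed = 1L, n_panels = 20L,
                        n_nodes = 6L) {
  if (n_iter <= 0) stop("n_iter must be positive")
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  n_retained <- min(n_retained, n_iter - n_burnin)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 n_retained = as.integer(n_retained),
                 n_chains = as.integer(n_chains), seed = seed,
                 n_panels = n_panels, n_nodes = n_nodes),
            class = "mcmc_config")
}

log_prior <- function(lt, ltau, prior) {
  m <- log(4 * prior$nbar * prior$mu)
  v <- prior$varp1; rho <- prior$rhocorn
  lp <- stats::dnorm(lt[1], m, sqrt(v), log = TRUE)
  if (length(lt) > 1L)
    lp <- lp + sum(stats::dnorm(lt[-1], m + rho * (lt[-length(lt)] - m),
                                sqrt(v * (1 - rho^2)), log = TRUE))
  if (length(ltau)) {
    J <- length(ltau)
    centres <- log(prior$gbar * prior$mu * seq_len(J) / (J + 1))
    if (any(diff(ltau) <= 0)) return(-Inf)
    lp <- lp + sum(stats::dnorm(ltau, centres, sqrt(prior$varp2), log = TRUE))
  }
  lp
}

#' Posterior sampling of step demographies (Metropolis-Hastings)
#'
#' Random-walk Metropolis over `(ln theta_0..J, ln tau_1..J)` combining the
#' composite spectrum likelihood ([composite_loglik()]) with the priors of
#' [prior_spec()]. Proposal scales are adapted during burn-in toward a
#' 25-45\% acceptance rate; retained states are evenly thinned after
#' burn-in. Runs are exactly reproducible under a fixed seed.
#'
#' @param spectra a [distance_spectrum()].
#' @param prior a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return a `posterior_ensemble`: list with matrices `theta`
#'   (samples x epochs) and `tau` (samples x transitions), `log_post`,
#'   `acceptance`, `mu`, `prior`, `config`, and `chains_theta0` (ln theta_0
#'   traces of every chain, for convergence diagnostics).
#' @export
sample_posterior <- function(spectra, prior, config = mcmc_config()) {
  J <- prior$J
  agg <- aggregate_spectrum(spectra)
  dmax <- spectra$dmax
  loglik <- function(lt, ltau) {
    demog <- step_demography(exp(lt), exp(ltau))
    P <- expected_spectrum(demog, dmax, config$n_panels, config$n_nodes)
    sum(agg * log(pmax(P, 1e-12)))
  }
  m0 <- log(4 * prior$nbar * prior$mu)
  centres <- if (J > 0) log(prior$gbar * prior$mu * seq_len(J) / (J + 1)) else numeric(0)
  run_chain <- function(chain_seed, jitter) {
    withr_seed(chain_seed, {
      lt <- rep(m0, J + 1) + jitter * stats::rnorm(J + 1, 0, 0.5)
      ltau <- centres + if (J > 0) jitter * stats::rnorm(J, 0, 0.2) else numeric(0)
      if (J > 0) ltau <- sort(ltau)
      lp <- log_prior(lt, ltau, prior) + loglik(lt, ltau)
      np <- 2L * J + 1L
      ## one randomly chosen coordinate is perturbed per iteration, with
      ## per-coordinate scales adapted during burn-in toward 25-45%
      scale <- rep(0.4, np)
      acc_w <- win <- integer(np)
      n_acc <- 0L
      keep_idx <- unique(round(seq(config$n_burnin + 1L, config$n_iter,
                                   length.out = config$n_retained)))
      TH <- matrix(NA_real_, length(keep_idx), J + 1)
      TAU <- matrix(NA_real_, length(keep_idx), max(J, 1))
      LP <- numeric(length(keep_idx))
      trace0 <- numeric(config$n_iter)
      ki <- 1L
      coords <- sample.int(np, config$n_iter, replace = TRUE)
      steps <- stats::rnorm(config$n_iter)
      lus <- log(stats::runif(config$n_iter))
      for (it in seq_len(config$n_iter)) {
        j <- coords[it]
        prop_lt <- lt; prop_ltau <- ltau
        if (j <= J + 1L) prop_lt[j] <- lt[j] + scale[j] * steps[it]
        else prop_ltau[j - J - 1L] <- ltau[j - J - 1L] + scale[j] * steps[it]
        lpp <- log_prior(prop_lt, prop_ltau, prior)
        if (is.finite(lpp)) lpp <- lpp + loglik(prop_lt, prop_ltau)
        acc <- is.finite(lpp) && lus[it] < lpp - lp
        if (acc) {
          lt <- prop_lt; ltau <- prop_ltau; lp <- lpp
          n_acc <- n_acc + 1L; acc_w[j] <- acc_w[j] + 1L
        }
        win[j] <- win[j] + 1L
        if (it <= config$n_burnin && win[j] == 50L) {
          rate <- acc_w[j] / win[j]
          if (rate > 0.45) scale[j] <- scale[j] * 1.4
          if (rate < 0.25) scale[j] <- scale[j] / 1.4
          acc_w[j] <- 0L; win[j] <- 0L
        }
        trace0[it] <- lt[1]
        if (ki <= length(keep_idx) && it == keep_idx[ki]) {
          TH[ki, ] <- exp(lt)
          if (J > 0) TAU[ki, ] <- exp(ltau)
          LP[ki] <- lp
          ki <- ki + 1L
        }
      }
      acc_rate <- n_acc / config$n_iter
      if (acc_rate < 0.01)
        stop("acceptance collapse (", round(100 * acc_rate, 2),
             "%) after adaptation; check spectra and priors")
      list(theta = TH, tau = if (J > 0) TAU else matrix(numeric(0), nrow(TH), 0),
           log_post = LP, acceptance = acc_rate, trace0 = trace0)
    })
  }
  chains <- lapply(seq_len(config$n_chains), function(cc)
    run_chain(config$seed + 1000L * (cc - 1L), jitter = as.numeric(cc > 1L)))
  main <- chains[[1]]
  structure(list(
    theta = main$theta, tau = main$tau, log_post = main$log_post,
    acceptance = main$acceptance, mu = prior$mu, prior = prior,
    config = config,
    chains_theta0 = vapply(chains, `[[`, numeric(config$n_iter), "trace0")
  ), class = "posterior_ensemble")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard PSRF from between- and within-chain variances of equal-length
#' scalar traces; values near 1 indicate convergence.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors, at least 2 chains of length >= 10.
#' @return the PSRF (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  m <- ncol(chains); n <- nrow(chains)
  if (is.null(m) || m < 2L) stop("need >= 2 chains")
  if (n < 10L) stop("chains must have length >= 10")
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
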