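make_spectra <- function(demog, n_ind = 50, n_loci = 30, seed = 1,
                         dmax = 30) {
  gm <- simulate_genotypes(sim_scenario(demog, n_ind, n_loci, seed = seed))
  distance_spectrum(gm, dmax = dmax)
}

small_cfg <- function(n_iter = 4000, seed = 1, n_chains = 1L)
  mcmc_config(n_iter = n_iter, n_burnin = 1000, n_retained = 500,
              n_chains = n_chains, seed = seed)

test_that("posterior sampling is reproducible and recovers a constant size", {
  sp <- make_spectra(step_demography(1.2), seed = 42)
  pr <- prior_spec(nbar = 2000, J = 1L)
  ens1 <- sample_posterior(sp, pr, small_cfg(seed = 9))
  ens2 <- sample_posterior(sp, pr, small_cfg(seed = 9))
  expect_identical(ens1$theta, ens2$theta)
  expect_identical(ens1$tau, ens2$tau)
  expect_equal(nrow(ens1$theta), 500)
  expect_true(ens1$acceptance > 0.05 && ens1$acceptance < 0.9)
  ## present-epoch theta within a factor ~2 of the generating value
  med <- median(ens1$theta[, 1])
  expect_gt(med, 1.2 / 2.5)
  expect_lt(med, 1.2 * 2.5)
  expect_error(sample_posterior(sp, pr, mcmc_config(n_iter = 0)), "positive")
})

test_that("priors and config invariants are enforced", {
  expect_error(prior_spec(mu = 0), "mu")
  expect_error(prior_spec(varp1 = -1))
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "burn")
  pr <- prior_spec(J = 2L)
  ## ordered-time constraint: decreasing times get zero prior mass
  expect_identical(msatdemog:::log_prior(c(0, 0, 0), log(c(0.5, 0.2)), pr),
                   -Inf)
})

test_that("trajectory summaries keep harmonic <= arithmetic and order quantiles", {
  sp <- make_spectra(step_demography(c(0.5, 6), 0.2), seed = 7)
  pr <- prior_spec(nbar = 3000, J = 2L)
  ens <- sample_posterior(sp, pr, small_cfg(seed = 3))
  ts <- trajectory_summaries(ens)
  expect_true(all(ts$trajectory$harmonic <= ts$trajectory$arithmetic + 1e-9))
  expect_true(all(ts$trajectory$q025 <= ts$trajectory$median + 1e-9))
  expect_true(all(ts$trajectory$median <= ts$trajectory$q975 + 1e-9))
  expect_equal(ts$trajectory$years, ts$trajectory$generations * 8.75)
  expect_true(all(unlist(ts$global) > 0))
  ## single-sample ensemble: all four summaries coincide
  e1 <- ens
  e1$theta <- ens$theta[1, , drop = FALSE]
  e1$tau <- ens$tau[1, , drop = FALSE]
  t1 <- trajectory_summaries(e1)
  expect_equal(t1$trajectory$arithmetic, t1$trajectory$harmonic)
  expect_equal(t1$trajectory$arithmetic, t1$trajectory$median)
  ## hand-computed two-sample summaries: Ne {100, 400}
  mu <- ens$mu
  e2 <- ens
  e2$theta <- matrix(c(100, 400) * 4 * mu, 2, ncol(ens$theta))
  e2$tau <- matrix(rep(ens$tau[1, ], each = 2), 2)
  t2 <- trajectory_summaries(e2)
  expect_equal(t2$trajectory$arithmetic[1], 250)
  expect_equal(t2$trajectory$harmonic[1], 160)
  expect_equal(t2$trajectory$median[1], 250)
})

test_that("TMRCA density averages the coalescence density with unit mass", {
  ## constant-theta ensemble: exponential density, mode at the grid start
  mu <- 0.00015
  pr <- prior_spec(mu = mu, gbar = 20000, J = 0L)
  ens <- structure(list(
    theta = matrix(1.2, 50, 1), tau = matrix(numeric(0), 50, 0),
    log_post = numeric(50), acceptance = 0.3, mu = mu, prior = pr,
    config = NULL, chains_theta0 = NULL
  ), class = "posterior_ensemble")
  td <- tmrca_density(ens)
  expect_equal(td$density$density,
               (2 / 1.2) * exp(-2 * td$density$generations * mu / 1.2) * mu,
               tolerance = 1e-12)
  ## density integrates to ~1 over the support (long tail truncated)
  g <- td$density$generations
  mass <- sum(diff(g) * (td$density$density[-1] + td$density$density[-length(g)]) / 2)
  expect_equal(mass, 1 - exp(-2 * max(g) * mu / 1.2), tolerance = 0.01)
  ## bottleneck demography: coalescence concentrates in the bottleneck
  ## window - the density spikes at the window entry and is depleted
  ## afterwards (checked exactly against the closed-form density)
  prb <- prior_spec(mu = mu, gbar = 5000, J = 2L)
  ensb <- structure(list(
    theta = matrix(rep(c(10, 0.1, 10), each = 30), 30, 3),
    tau = matrix(rep(c(0.1, 0.3), each = 30), 30, 2),
    log_post = numeric(30), acceptance = 0.3, mu = mu, prior = prb,
    config = NULL, chains_theta0 = NULL
  ), class = "posterior_ensemble")
  grid <- seq(1, 5000, length.out = 400)
  tdb <- tmrca_density(ensb, grid = grid)
  dd <- tdb$density
  inside <- dd$generations > 0.1 / mu & dd$generations < 0.3 / mu
  before <- dd$generations < 0.1 / mu
  after <- dd$generations > 0.3 / mu
  expect_gt(max(dd$density[inside]), 10 * max(dd$density[before]))
  expect_lt(max(dd$density[after]), min(dd$density[before]))
  ## oracle check: averaged density equals the closed-form density
  demog <- step_demography(c(10, 0.1, 10), c(0.1, 0.3))
  expect_equal(dd$density,
               coalescence_density(demog, dd$generations * mu) * mu)
})

test_that("Gelman-Rubin PSRF flags separated chains and accepts identical ones", {
  x <- matrix(rnorm(2000), 1000, 2)
  x[, 2] <- x[, 1]
  expect_equal(gelman_rubin(x), 1, tolerance = 2e-3)
  set.seed(4)
  y <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  n <- 1000
  W <- mean(apply(y, 2, var)); B <- n * var(colMeans(y))
  expect_equal(gelman_rubin(y), sqrt(((n - 1) / n * W + B / n) / W))
  expect_gt(gelman_rubin(y), 3)
  set.seed(5)
  z <- matrix(rnorm(4000), 1000, 4)
  expect_lt(gelman_rubin(z), 1.1)
  expect_error(gelman_rubin(matrix(1:10, 10, 1)), "2 chains")
})

test_that("constant-size data does not yield spurious size swings", {
  ## calibration guard: on mutation-drift-equilibrium data the max/min
  ## ratio of the posterior-median trajectory stays below 5 in >= 90% of
  ## seeded runs
  scn <- scenario_presets("constant")
  pr <- prior_spec(nbar = 2000, J = 3L)
  ok <- 0L
  for (s in 1:10) {
    gm <- simulate_genotypes(scn, seed = 800 + s)
    ens <- sample_posterior(distance_spectrum(gm), pr,
                            mcmc_config(n_iter = 8000, n_burnin = 3000,
                                        n_retained = 500, seed = s))
    ts <- trajectory_summaries(ens)
    ratio <- max(ts$trajectory$median) / min(ts$trajectory$median)
    if (ratio < 5) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("multi-chain runs expose convergent theta_0 traces", {
  sp <- make_spectra(step_demography(1.2), seed = 5, n_loci = 15)
  pr <- prior_spec(nbar = 2000, J = 1L)
  ens <- sample_posterior(sp, pr, small_cfg(n_iter = 3000, seed = 2,
                                            n_chains = 2L))
  tr <- ens$chains_theta0[1001:3000, ]
  expect_lt(gelman_rubin(tr), 1.5)
})
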