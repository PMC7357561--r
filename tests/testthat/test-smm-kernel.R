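test_that("distance spectrum counts all unordered pairs with tail pooling", {
  ## monomorphic locus, 6 genes: all 15 pairs in class 0
  gm <- gm_from_calls(list(L = rep(10L, 3)), list(L = rep(10L, 3)))
  sp <- distance_spectrum(gm, dmax = 4)
  expect_equal(unname(sp$counts["L", ]), c(15, 0, 0, 0, 0))
  ## alleles {10, 12, 12}: one 0-pair, two 2-pairs
  gm2 <- genotype_matrix("i1", "L", matrix(10L), matrix(12L))
  gm2b <- gm_from_calls(list(L = c(10L, 12L)), list(L = c(12L, 12L)))
  sp2 <- distance_spectrum(gm2b, dmax = 3)
  ## genes 10,12,12,12: pairs |d|: 0 x3 (within 12s), 2 x3
  expect_equal(unname(sp2$counts["L", ]), c(3, 0, 3, 0))
  ## pair-count invariant sum = n(n-1)/2 and pooling beyond dmax
  gm3 <- random_gm(n = 15, L = 4, missing_rate = 0.2, seed = 6)
  sp3 <- distance_spectrum(gm3, dmax = 2)
  for (l in rownames(sp3$counts)) {
    n <- sp3$n_genes[[l]]
    expect_equal(sum(sp3$counts[l, ]), n * (n - 1) / 2)
  }
})

test_that("SMM kernel is the scaled Bessel form, symmetric and normalised", {
  expect_equal(smm_pair_probability(0, 0), 1)
  expect_equal(smm_pair_probability(3, 0), 0)
  expect_equal(smm_pair_probability(0, 1), exp(-2) * besselI(2, 0),
               tolerance = 1e-12)
  expect_equal(smm_pair_probability(0, 1), 0.30851, tolerance = 1e-5)
  expect_equal(smm_pair_probability(-4, 2.5), smm_pair_probability(4, 2.5))
  expect_lt(abs(sum(smm_pair_probability(-60:60, 3)) - 1), 1e-10)
  expect_error(smm_pair_probability(0, -1), "tau")
})

test_that("coalescence density is exponential under constant size and normalised generally", {
  th <- 2.5
  tau <- seq(0, 10, by = 0.37)
  expect_equal(coalescence_density(step_demography(th), tau),
               (2 / th) * exp(-2 * tau / th))
  ## two-epoch density matches numerical integration of the hazard
  d2 <- step_demography(c(0.5, 8), 0.2)
  f <- function(t) coalescence_density(d2, t)
  for (tt in c(0.05, 0.19, 0.21, 1, 3)) {
    hz <- integrate(function(s) 2 / ifelse(s < 0.2, 0.5, 8), 0, tt,
                    rel.tol = 1e-12)$value
    rate <- 2 / ifelse(tt < 0.2, 0.5, 8)
    expect_equal(f(tt), rate * exp(-hz), tolerance = 1e-10)
  }
  ## integrates to 1 for random step demographies
  set.seed(8)
  for (i in 1:5) {
    J <- sample(0:3, 1)
    demog <- step_demography(exp(runif(J + 1, -2, 3)),
                             sort(runif(J, 0.01, 2)))
    val <- integrate(function(s) coalescence_density(demog, s), 0, Inf,
                     subdivisions = 5000L, rel.tol = 1e-10)$value
    expect_equal(val, 1, tolerance = 1e-8)
  }
})

test_that("expected spectrum matches the constant-theta geometric closed form to 1e-6", {
  for (th in c(0.1, 1, 10)) {
    got <- expected_spectrum(step_demography(th), 30)
    want <- msatdemog:::constant_theta_spectrum(th, 30)
    expect_lt(max(abs(got - want)), 1e-6)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
  ## theta = 1 head values: P(0) = 1/sqrt(3), unfolded ratio rho = 0.2679
  P <- expected_spectrum(step_demography(1), 10)
  expect_equal(P[1], 1 / sqrt(3), tolerance = 1e-9)
  expect_equal((P[3] / P[2]), (1 + 1 - sqrt(3)), tolerance = 1e-6)
  ## theta -> 0: all mass at k = 0
  P0 <- expected_spectrum(step_demography(1e-8), 5)
  expect_gt(P0[1], 1 - 1e-6)
  ## two-epoch spectrum agrees with Monte-Carlo pair-difference
  ## frequencies from the coalescent simulator
  demog <- step_demography(c(0.5, 6), 0.15)
  scn <- sim_scenario(demog, 100, 300, seed = 12)
  gm <- simulate_genotypes(scn)
  sp <- distance_spectrum(gm, dmax = 20)
  obs <- colSums(sp$counts) / sum(sp$counts)
  want <- expected_spectrum(demog, 20)
  ## loci share genealogies across pairs, so allow a generous MC band
  expect_lt(max(abs(obs - want)), 0.02)
})

test_that("composite log-likelihood reduces to the weighted class sum and prefers truth", {
  sp <- structure(list(
    counts = matrix(c(3, 1, 0), 1, dimnames = list("L", NULL)),
    n_genes = c(L = 4), dmax = 2
  ), class = "distance_spectrum")
  ## hand value with P = (0.7, 0.2, 0.1), gene-count weighting:
  ## 4 * (0.75 log .7 + 0.25 log .2)
  agg <- msatdemog:::aggregate_spectrum(sp, "genes")
  expect_equal(sum(agg * log(c(0.7, 0.2, 0.1))), -2.680, tolerance = 1e-3)
  ## default weighting uses sqrt(n_genes)
  expect_equal(msatdemog:::aggregate_spectrum(sp), agg / 2)
  ## the generating demography outscores +-50% perturbations of theta_0
  demog <- step_demography(c(1, 10), 0.2)
  scn <- sim_scenario(demog, 100, 30, seed = 3)
  gm <- simulate_genotypes(scn)
  spec <- distance_spectrum(gm, dmax = 30)
  ll <- function(d) composite_loglik(spec, d)
  expect_gt(ll(demog), ll(step_demography(c(0.5, 10), 0.2)))
  expect_gt(ll(demog), ll(step_demography(c(1.5, 10), 0.2)))
  expect_error(composite_loglik(structure(list(counts = matrix(numeric(0), 0, 3),
                                               n_genes = integer(0), dmax = 2),
                                          class = "distance_spectrum"), demog),
               "empty")
})
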