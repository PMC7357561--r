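#' Piecewise-constant scaled demography
#'
#' A step demography holds epoch sizes on the mutation scale,
#' `theta_j = 4 N_j mu`, and strictly increasing transition times
#' `tau_j = g_j mu` (generations times mutation rate). Epoch `j` spans
#' `[tau_j, tau_{j+1})` looking backwards from sampling time, with
#' `tau_0 = 0` and the last epoch extending to infinity. `J = 0` (no
#' transitions) is a constant-size population.
#'
#' @param theta positive epoch sizes, length `J + 1` (present first).
#' @param tau strictly increasing transition times, length `J` (may be
#'   empty).
#' @return a `step_demography` object.
#' @export
step_demography <- function(theta, tau = numeric(0)) {
  theta <- as.numeric(theta); tau <- as.numeric(tau)
  if (any(theta <= 0)) stop("all epoch sizes theta must be positive")
  if (length(tau) != length(theta) - 1L)
    stop("need length(tau) == length(theta) - 1")
  if (length(tau) && (any(tau <= 0) || any(diff(tau) <= 0)))
    stop("transition times must be positive and strictly increasing")
  structure(list(theta = theta, tau = tau, J = length(tau)),
            class = "step_demography")
}

#' @export
print.step_demography <- function(x, ...) {
  cat("step_demography with", x$J, "transition(s)\n")
  bounds <- c(0, x$tau, Inf)
  for (j in seq_along(x$theta))
    cat(sprintf("  epoch %d: theta = %.4g on tau [%.4g, %.4g)\n",
                j - 1L, x$theta[j], bounds[j], bounds[j + 1]))
  invisible(x)
}

## cumulative pair-coalescence hazard H(t) = int_0^t 2/theta(s) ds,
## its epoch-boundary values, and the inverse
pair_hazard_breaks <- function(demog) {
  bounds <- c(0, demog$tau)
  H <- c(0, cumsum(2 * diff(bounds) / demog$theta[seq_len(demog$J)]))
  list(bounds = bounds, H = H)
}

pair_hazard <- function(demog, t) {
  hb <- pair_hazard_breaks(demog)
  j <- findInterval(t, hb$bounds)
  hb$H[j] + 2 * (t - hb$bounds[j]) / demog$theta[j]
}

## inverse of the cumulative pair hazard (vectorised)
pair_hazard_inverse <- function(demog, H) {
  hb <- pair_hazard_breaks(demog)
  j <- findInterval(H, hb$H)
  j <- pmin(j, length(demog$theta))
  hb$bounds[j] + (H - hb$H[j]) * demog$theta[j] / 2
}

#' Pair-coalescence (TMRCA) density under a step demography
#'
#' In mutation-scaled time the coalescence rate of a pair of lineages is
#' `2 / theta(tau)` within each epoch, so the TMRCA density is
#' `f(tau) = (2 / theta_j) exp(-H(tau))` with `H` the cumulative hazard.
#' Under constant theta this is exponential with mean `theta / 2`.
#'
#' @param demog a [step_demography()].
#' @param tau nonnegative scaled times.
#' @return density values at `tau`.
#' @export
coalescence_density <- function(demog, tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  j <- findInterval(tau, c(0, demog$tau))
  (2 / demog$theta[j]) * exp(-pair_hazard(demog, tau))
}

## Simulate a Kingman genealogy of n genes under a step demography.
## Returns parent pointers and branch lengths (mutation-scaled time) for
## nodes 1..(2n-1); node 2n-1 is the root. With k lineages the total
## coalescence rate is k(k-1)/theta(tau); times come from unit-exponential
## waiting times pushed through the inverse cumulative hazard.
sim_genealogy <- function(n, demog) {
  if (demog$J == 0L) return(sim_genealogy_constant(n, demog$theta))
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    ## k-lineage hazard = C(k,2) * pair hazard; invert via pair hazard
    E <- stats::rexp(1)
    Hp <- pair_hazard(demog, t) + E / (k * (k - 1) / 2)
    t <- pair_hazard_inverse(demog, Hp)
    pick <- sample.int(k, 2L)
    c1 <- active[pick[1]]; c2 <- active[pick[2]]
    parent[c1] <- nxt; parent[c2] <- nxt
    node_time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  list(parent = parent, node_time = node_time, n = n)
}

## constant-size fast path: all inter-coalescence waits are independent
## exponentials with rate k(k-1)/theta, drawn in one vectorised call
sim_genealogy_constant <- function(n, theta) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  ks <- n:2
  node_time <- c(numeric(n), cumsum(stats::rexp(n - 1L) * theta /
                                      (ks * (ks - 1L))))
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    k <- n - step + 1L
    pick <- sample.int(k, 2L)
    nxt <- n + step
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
  }
  list(parent = parent, node_time = node_time, n = n)
}

## Overlay stepwise (or generalised stepwise) mutations on a genealogy and
## return the n leaf allele states. Mutations are Poisson with rate 1 per
## lineage per mutation-scaled time unit; each mutation moves the repeat
## count by +-1 (SMM) or a +-geometric(1 - c) step (GSM). The root allele
## is fixed at `root` with an unconstrained walk.
drop_mutations <- function(gen, model = c("SMM", "GSM"), gsm_c = 0.2,
                           root = 100L) {
  model <- match.arg(model)
  n_nodes <- 2L * gen$n - 1L
  blen <- numeric(n_nodes)
  nz <- gen$parent > 0L
  blen[nz] <- gen$node_time[gen$parent[nz]] - gen$node_time[nz]
  m <- stats::rpois(n_nodes, blen)
  if (model == "SMM") {
    ## net displacement of m unit steps: 2 Binomial(m, 1/2) - m
    disp <- 2L * stats::rbinom(n_nodes, m, 0.5) - m
  } else {
    disp <- integer(n_nodes)
    for (i in which(m > 0L)) {
      sizes <- stats::rgeom(m[i], 1 - gsm_c) + 1L
      signs <- sample(c(-1L, 1L), m[i], replace = TRUE)
      disp[i] <- sum(sizes * signs)
    }
  }
  state <- integer(n_nodes)
  state[n_nodes] <- root
  for (i in seq(n_nodes - 1L, 1L))  # children precede parents in creation
    state[i] <- state[gen$parent[i]] + disp[i]
  state[seq_len(gen$n)]
}

sim_locus_alleles <- function(n_genes, demog, model = "SMM", gsm_c = 0.2,
                              root = 100L) {
  drop_mutations(sim_genealogy(n_genes, demog), model, gsm_c, root)
}

## Structured coalescent for `demes` equally sized demes (constant theta
## per deme) with symmetric island migration at scaled lineage rate
## M = 4Nm / theta per unit tau. `deme_of` gives the starting deme of each
## of the n genes.
sim_genealogy_island <- function(deme_of, theta, four_Nm, demes) {
  n <- length(deme_of)
  M <- four_Nm / theta
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  loc <- deme_of
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    nd <- tabulate(loc, demes)
    coal_rates <- nd * (nd - 1) / theta
    mig_rate <- length(active) * M
    tot <- sum(coal_rates) + mig_rate
    t <- t + stats::rexp(1, tot)
    if (stats::runif(1) < mig_rate / tot) {
      i <- sample.int(length(active), 1L)
      loc[i] <- if (demes == 2L) 3L - loc[i] else
        sample(setdiff(seq_len(demes), loc[i]), 1L)
    } else {
      d <- sample.int(demes, 1L, prob = coal_rates / sum(coal_rates))
      here <- which(loc == d)
      pick <- here[sample.int(length(here), 2L)]
      c1 <- active[pick[1]]; c2 <- active[pick[2]]
      parent[c1] <- nxt; parent[c2] <- nxt
      node_time[nxt] <- t
      active <- c(active[-pick], nxt)
      loc <- c(loc[-pick], d)
      nxt <- nxt + 1L
    }
  }
  list(parent = parent, node_time = node_time, n = n)
}
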