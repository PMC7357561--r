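## cache of standardised genealogies (constant theta = 1) per n_genes:
## branch lengths scale linearly in theta, so one set of genealogies serves
## every theta during calibration - and every locus with the same sample
## size.
.genealogy_env <- new.env(parent = emptyenv())

std_genealogies <- function(n_genes, n_gen, seed) {
  key <- paste(n_genes, n_gen, seed, sep = ":")
  if (!is.null(.genealogy_env[[key]])) return(.genealogy_env[[key]])
  g <- withr_seed(seed, {
    lapply(seq_len(n_gen), function(i)
      sim_genealogy(n_genes, step_demography(1)))
  })
  .genealogy_env[[key]] <- g
  g
}

count_alleles_at_theta <- function(gens, theta, model, gsm_c, seed) {
  withr_seed(seed, {
    vapply(gens, function(g) {
      g2 <- g
      g2$node_time <- g$node_time * theta
      length(unique(drop_mutations(g2, model, gsm_c)))
    }, numeric(1))
  })
}

## Bisection on log(theta) so that the mean simulated allele count matches
## k (tolerance in alleles). Deterministic given the seed: genealogies are
## shared across evaluations and mutation draws are re-seeded per theta.
## Calibration is deterministic for a given (n_genes, k, model, n_cal):
## the genealogy set and the per-theta mutation overlays use seeds derived
## from the sample size only, so every locus with the same sample size
## shares one cached genealogy set. Bisection stops on the allele-count
## tolerance or when the log-theta bracket is numerically tight.
calibrate_theta <- function(n_genes, k, model = "SMM", gsm_c = 0.2,
                            n_cal = 400L, tol = 0.05) {
  cal_seed <- 1000000L + n_genes
  gens <- std_genealogies(n_genes, n_cal, cal_seed)
  mean_k <- function(lth)
    mean(count_alleles_at_theta(gens, exp(lth), model, gsm_c,
                                cal_seed + 1L))
  lo <- log(1e-4); hi <- log(5e3)
  f_lo <- mean_k(lo) - k; f_hi <- mean_k(hi) - k
  if (f_lo > 0 || f_hi < 0)
    stop("theta calibration failed for n_genes = ", n_genes, ", k = ", k,
         ": mean allele count spans [", round(f_lo + k, 2), ", ",
         round(f_hi + k, 2), "]")
  while (hi - lo > 0.02) {
    mid <- (lo + hi) / 2
    fm <- mean_k(mid) - k
    if (abs(fm) < tol) return(exp(mid))
    if (fm > 0) hi <- mid else lo <- mid
  }
  exp((lo + hi) / 2)
}

#' Equilibrium heterozygosity distribution conditional on allele count
#'
#' Simulates constant-size coalescent genealogies of `n_genes` gene copies
#' under the stepwise (or generalised stepwise) mutation model, with theta
#' calibrated by bisection so the expected allele count equals `k_alleles`,
#' then retains only replicates whose realised allele count is exactly
#' `k_alleles`. The replicate heterozygosities (unbiased gene diversity
#' `n/(n-1) (1 - sum p^2)`) form the mutation-drift-equilibrium reference
#' distribution used by the heterozygosity-excess bottleneck tests.
#'
#' @param n_genes gene copies sampled (2 x typed individuals).
#' @param k_alleles observed allele count, `2 <= k_alleles <= n_genes`.
#' @param model `"SMM"` or `"GSM"`.
#' @param n_sim retained replicates (paper-scale default 10,000).
#' @param seed RNG seed.
#' @param gsm_c geometric parameter for GSM steps.
#' @return list with `het` (replicate vector), `mean`, `sd`, `theta`
#'   (calibrated), `n_genes`, `k_alleles`, `model`, `n_sim`.
#' @export
equilibrium_het_distribution <- function(n_genes, k_alleles,
                                         model = c("SMM", "GSM"),
                                         n_sim = 1000L, seed = 1L,
                                         gsm_c = 0.2) {
  model <- match.arg(model)
  if (k_alleles > n_genes) stop("k_alleles cannot exceed n_genes")
  if (k_alleles < 2L) stop("k_alleles must be >= 2")
  theta <- calibrate_theta(n_genes, k_alleles, model, gsm_c)
  demog <- step_demography(theta)
  het <- numeric(n_sim)
  withr_seed(seed + 2L, {
    got <- 0L; tries <- 0L
    max_tries <- 200L * n_sim
    while (got < n_sim && tries < max_tries) {
      tries <- tries + 1L
      alle <- sim_locus_alleles(n_genes, demog, model, gsm_c)
      if (length(unique(alle)) == k_alleles) {
        got <- got + 1L
        p <- as.numeric(table(alle)) / n_genes
        het[got] <- n_genes / (n_genes - 1) * (1 - sum(p^2))
      }
    }
    if (got < n_sim)
      stop("conditioning on k = ", k_alleles, " alleles failed: only ", got,
           " of ", n_sim, " replicates accepted in ", tries, " simulations")
  })
  list(het = het, mean = mean(het), sd = stats::sd(het), theta = theta,
       n_genes = n_genes, k_alleles = k_alleles, model = model,
       n_sim = n_sim)
}

## Poisson-binomial tail probabilities by direct convolution
poisson_binomial_cdf <- function(probs) {
  dist <- 1
  for (p in probs) dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  dist
}

#' Heterozygosity-excess bottleneck tests
#'
#' Compares, locus by locus, the observed unbiased heterozygosity with its
#' mutation-drift-equilibrium distribution conditional on the observed
#' allele count and sample size ([equilibrium_het_distribution()]). A
#' recent bottleneck reduces allele counts faster than heterozygosity, so
#' post-bottleneck samples show heterozygosity excess. Three tests are
#' reported: the sign test (Poisson-binomial over the per-locus excess
#' probabilities taken from the simulated distributions), the standardized
#' differences test `T2 = sum(DH) / sqrt(L)` against a standard normal, and
#' the Wilcoxon signed-rank test on `DH` (exact for <= 15 loci).
#'
#' @param gm a [genotype_matrix()] in repeat units with >= 4 polymorphic
#'   loci.
#' @param model mutation model for the equilibrium simulations.
#' @param n_sim equilibrium replicates per locus.
#' @param seed RNG seed.
#' @param heq_cache optional environment reusing equilibrium distributions
#'   across calls (keyed by sample size, allele count, model and n_sim).
#' @return list with per-locus data frame `loci` (n_genes, k, mean and sd
#'   of the equilibrium heterozygosity, observed He, DH), excess/deficit
#'   counts, and the three tests' p-values.
#' @export
bottleneck_tests <- function(gm, model = c("SMM", "GSM"), n_sim = 1000L,
                             seed = 1L, heq_cache = NULL) {
  model <- match.arg(model)
  prof <- polymorphism_profile(gm)$loci
  loci <- prof$locus[prof$polymorphic]
  if (length(loci) < 4L) stop("need >= 4 polymorphic loci")
  ## loci sharing (sample size, allele count) share one equilibrium
  ## distribution even without a user-supplied cache
  if (is.null(heq_cache)) heq_cache <- new.env(parent = emptyenv())
  rows <- list(); excl <- character(0)
  for (locus in loci) {
    l <- match(locus, gm$loci)
    genes <- c(gm$a1[, l], gm$a2[, l])
    genes <- genes[!is.na(genes)]
    ng <- length(genes)
    k <- length(unique(genes))
    p <- as.numeric(table(genes)) / ng
    he_obs <- ng / (ng - 1) * (1 - sum(p^2))
    key <- paste(ng, k, model, n_sim, sep = ":")
    heq <- if (!is.null(heq_cache) && !is.null(heq_cache[[key]])) {
      heq_cache[[key]]
    } else {
      h <- tryCatch(
        equilibrium_het_distribution(ng, k, model, n_sim,
                                     seed = seed + l),
        error = function(e) e
      )
      if (inherits(h, "error")) { excl <- c(excl, locus); next }
      if (!is.null(heq_cache)) heq_cache[[key]] <- h
      h
    }
    dh <- (he_obs - heq$mean) / heq$sd
    p_excess <- mean(heq$het < he_obs)
    rows[[locus]] <- data.frame(
      locus = locus, n_genes = ng, k = k, heq_mean = heq$mean,
      heq_sd = heq$sd, he_obs = he_obs, DH = dh, p_excess = p_excess,
      stringsAsFactors = FALSE
    )
  }
  if (length(excl))
    warning("excluded loci failing equilibrium calibration: ",
            paste(excl, collapse = ", "))
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 4L)
    stop("fewer than 4 loci with usable equilibrium distributions")
  L <- nrow(tab)
  n_excess <- sum(tab$DH > 0)
  ## sign test against the simulated excess probabilities
  dist <- poisson_binomial_cdf(tab$p_excess)
  sign_p_excess <- sum(dist[(n_excess + 1L):(L + 1L)])
  sign_p_deficit <- sum(dist[1:(n_excess + 1L)])
  t2 <- sum(tab$DH) / sqrt(L)
  wx <- function(alt) stats::wilcox.test(tab$DH, mu = 0, alternative = alt,
                                         exact = L <= 15, correct = TRUE)$p.value
  list(
    loci = tab, n_excess = n_excess, n_deficit = L - n_excess,
    sign_test = list(expected_excess = sum(tab$p_excess),
                     p_excess = sign_p_excess, p_deficit = sign_p_deficit),
    standardized = list(T2 = t2,
                        p_excess = stats::pnorm(t2, lower.tail = FALSE),
                        p_deficit = stats::pnorm(t2),
                        p_two_sided = 2 * stats::pnorm(-abs(t2))),
    wilcoxon = list(p_excess = wx("greater"), p_deficit = wx("less"),
                    p_two_sided = wx("two.sided")),
    model = model, n_sim = n_sim
  )
}
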