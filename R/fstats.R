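## Weir & Cockerham (1984) variance components.
##
## For a single sample (FIS) only the within-population components are
## needed: per locus and allele, with n typed individuals, allele frequency
## p and heterozygote frequency h (proportion of individuals carrying the
## allele heterozygously),
##   b = n/(n-1) * (p(1-p) - (2n-1)/(4n) h),   c = h/2,
## and the multilocus inbreeding estimate is f = 1 - sum(c)/sum(b + c).
wc_within_components <- function(gm, loci = NULL) {
  if (is.null(loci)) loci <- gm$loci
  B <- 0; C <- 0
  per_locus <- matrix(NA_real_, length(loci), 2,
                      dimnames = list(loci, c("b", "c")))
  for (locus in loci) {
    l <- match(locus, gm$loci)
    called <- !is.na(gm$a1[, l])
    n <- sum(called)
    if (n < 2L) next
    g1 <- gm$a1[called, l]; g2 <- gm$a2[called, l]
    alle <- unique(c(g1, g2))
    if (length(alle) < 2L) next
    bl <- 0; cl <- 0
    for (a in alle) {
      p <- (sum(g1 == a) + sum(g2 == a)) / (2 * n)
      h <- mean((g1 == a) != (g2 == a))
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      bl <- bl + b; cl <- cl + h / 2
    }
    per_locus[locus, ] <- c(bl, cl)
    B <- B + bl; C <- C + cl
  }
  list(b = B, c = C, per_locus = per_locus)
}

wc_f_from_components <- function(comp) {
  if (comp$b + comp$c == 0) return(NA_real_)
  1 - comp$c / (comp$b + comp$c)
}

#' Multilocus inbreeding coefficient (Weir & Cockerham f)
#'
#' Ratio-of-summed-variance-components estimate of FIS over the polymorphic
#' loci, with a bootstrap confidence interval over individuals (all loci
#' retained per resample) and a jackknife over loci.
#'
#' @param gm a [genotype_matrix()].
#' @param n_boot bootstrap resamples (paper-scale default 10,000).
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list with `estimate`, `ci` (lower/upper), `jackknife` estimate
#'   and variance, and `n_boot`.
#' @export
fis_multilocus <- function(gm, n_boot = 1000L, seed = 1L, conf = 0.95) {
  prof <- polymorphism_profile(gm)$loci
  loci <- prof$locus[prof$polymorphic]
  if (length(loci) < 2L) stop("need >= 2 polymorphic loci for multilocus FIS")
  comp <- wc_within_components(gm, loci)
  if (comp$b + comp$c == 0) stop("FIS undefined: all loci monomorphic")
  f <- wc_f_from_components(comp)
  n <- nrow(gm$ind)
  boot <- numeric(n_boot)
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      gmb <- list(ind = gm$ind[idx, , drop = FALSE], loci = gm$loci,
                  a1 = gm$a1[idx, , drop = FALSE],
                  a2 = gm$a2[idx, , drop = FALSE])
      class(gmb) <- "genotype_matrix"
      boot[b] <- wc_f_from_components(wc_within_components(gmb, loci))
    }
  })
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  ## jackknife over loci
  pl <- comp$per_locus[stats::complete.cases(comp$per_locus), , drop = FALSE]
  L <- nrow(pl)
  jk <- vapply(seq_len(L), function(l) {
    1 - sum(pl[-l, "c"]) / sum(pl[-l, "b"] + pl[-l, "c"])
  }, numeric(1))
  jk_est <- mean(jk)
  jk_var <- (L - 1) / L * sum((jk - jk_est)^2)
  list(estimate = f, ci = ci, jackknife = jk_est, jackknife_var = jk_var,
       n_boot = n_boot, loci = loci)
}

## Full W&C (1984) theta for r >= 2 samples; genotypes as lists of
## (g1, g2, group) per locus.
wc_theta <- function(gm, groups, loci = NULL) {
  if (is.null(loci)) loci <- gm$loci
  glev <- unique(groups)
  r <- length(glev)
  A_sum <- 0; D_sum <- 0  # sum of a and of a+b+c
  for (locus in loci) {
    l <- match(locus, gm$loci)
    called <- !is.na(gm$a1[, l])
    g1 <- gm$a1[called, l]; g2 <- gm$a2[called, l]
    gr <- groups[called]
    ni <- vapply(glev, function(g) sum(gr == g), numeric(1))
    if (any(ni < 1) || sum(ni) < 2) next
    alle <- unique(c(g1, g2))
    if (length(alle) < 2L) next
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (a in alle) {
      pi <- vapply(glev, function(g) {
        s <- gr == g
        (sum(g1[s] == a) + sum(g2[s] == a)) / (2 * sum(s))
      }, numeric(1))
      hi <- vapply(glev, function(g) {
        s <- gr == g
        mean((g1[s] == a) != (g2[s] == a))
      }, numeric(1))
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      a_comp <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                     hbar / 4) / (nbar - 1))
      b_comp <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_comp <- hbar / 2
      A_sum <- A_sum + a_comp
      D_sum <- D_sum + a_comp + b_comp + c_comp
    }
  }
  if (D_sum == 0) return(NA_real_)
  A_sum / D_sum
}

#' Pairwise Weir & Cockerham FST with permutation tests
#'
#' Multilocus theta-hat for every pair of localities, with a p-value from
#' permuting individuals between the two groups being compared (pairwise
#' testing semantics). Raw and Bonferroni-adjusted p-values are reported.
#'
#' @param gm a [genotype_matrix()].
#' @param n_perm permutations per pair (paper-scale default 10,000).
#' @param seed RNG seed.
#' @return list with matrices `theta`, `p`, `p_bonferroni`, and `n_perm`.
#' @export
pairwise_fst <- function(gm, n_perm = 1000L, seed = 1L) {
  glev <- unique(gm$ind$locality)
  if (length(glev) < 2L) stop("need >= 2 localities")
  sizes <- table(gm$ind$locality)
  small <- names(sizes)[sizes < 2]
  if (length(small)) stop("locality with < 2 typed individuals: ",
                          paste(small, collapse = ", "))
  k <- length(glev)
  theta <- p <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  withr_seed(seed, {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sel <- gm$ind$locality %in% glev[c(i, j)]
      sub <- subset_genotypes(gm, individuals = which(sel))
      obs <- wc_theta(sub, sub$ind$locality)
      perm <- numeric(n_perm)
      for (b in seq_len(n_perm))
        perm[b] <- wc_theta(sub, sample(sub$ind$locality))
      theta[i, j] <- theta[j, i] <- obs
      pv <- (sum(perm >= obs, na.rm = TRUE) + 1) / (n_perm + 1)
      p[i, j] <- p[j, i] <- pv
    }
  })
  npair <- k * (k - 1) / 2
  list(theta = theta, p = p,
       p_bonferroni = pmin(p * npair, 1), n_perm = n_perm)
}
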