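#' Observed, expected and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of typed individuals that are heterozygous; `He` is
#' Nei's gene diversity `1 - sum(p_i^2)`; `Hnb` is the small-sample
#' unbiased version `2S/(2S - 1) * He` with `S` the number of typed
#' individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name.
#' @return named numeric vector `c(Ho, He, Hnb)`.
#' @export
heterozygosities <- function(gm, locus) {
  l <- match(locus, gm$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  called <- !is.na(gm$a1[, l])
  S <- sum(called)
  if (S == 0L) stop("heterozygosity undefined: no typed individuals at ", locus)
  Ho <- mean(gm$a1[called, l] != gm$a2[called, l])
  p <- as.numeric(table(c(gm$a1[called, l], gm$a2[called, l]))) / (2 * S)
  He <- 1 - sum(p^2)
  c(Ho = Ho, He = He, Hnb = 2 * S / (2 * S - 1) * He)
}

check_freqs <- function(p, tol = 1e-8) {
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop("allele frequencies must be nonnegative and sum to 1")
  p
}

#' Polymorphism information content (Botstein convention)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p allele frequency vector.
#' @return PIC in \[0, 1\].
#' @export
pic <- function(p) {
  check_freqs(p)
  a2 <- sum(p^2); a4 <- sum(p^4)
  1 - a2 - (a2^2 - a4)
}

#' Probability of identity (unrelated and sibling) per locus and cumulative
#'
#' `PI = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2` is the probability that two
#' random unrelated individuals share a genotype; `PIsibs` is the sibling
#' version `0.25 + 0.5 a2 + 0.5 a2^2 - 0.25 a4` (`a_k = sum p^k`).
#' Cumulative values are running products over loci (unlinked loci assumed).
#'
#' @param freqs named list of allele frequency vectors, one per locus, in
#'   the combination order.
#' @return data frame with per-locus `PI`, `PIsibs` and cumulative products.
#' @export
identity_probabilities <- function(freqs) {
  if (length(freqs) < 1L) stop("at least one locus required")
  one <- function(p) {
    check_freqs(p)
    a2 <- sum(p^2); a4 <- sum(p^4)
    c(PI = 2 * a2^2 - a4,
      PIsibs = 0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4)
  }
  m <- t(vapply(freqs, one, numeric(2)))
  data.frame(
    locus = if (is.null(names(freqs))) seq_along(freqs) else names(freqs),
    PI = m[, "PI"], PIsibs = m[, "PIsibs"],
    PI_cum = cumprod(m[, "PI"]), PIsibs_cum = cumprod(m[, "PIsibs"]),
    row.names = NULL
  )
}

#' Parentage exclusion probabilities
#'
#' Exact exclusion probabilities under Hardy-Weinberg random union of
#' gametes, evaluated directly from allele frequencies:
#' * `PE1` - probability of excluding a random non-parent as a candidate
#'   single parent when the other parent is unknown (candidate shares no
#'   allele with the offspring);
#' * `PE2` - probability of excluding a random non-parent as the second
#'   parent when the first parent is known;
#' * `PE3` - probability of excluding a random unrelated parent pair.
#' These are the quantities whose power-sum expansions are the classical
#' Jamieson & Taylor formulas.
#'
#' @param p allele frequency vector.
#' @return named numeric vector `c(PE1, PE2, PE3)`.
#' @export
exclusion_probabilities <- function(p) {
  check_freqs(p)
  A <- length(p)
  if (A == 1L) return(c(PE1 = 0, PE2 = 0, PE3 = 0))
  ## PE1: candidate excluded iff it carries no allele of the offspring.
  pe1 <- 0
  for (x in seq_len(A)) pe1 <- pe1 + p[x]^2 * (1 - p[x])^2
  for (x in seq_len(A - 1)) for (y in (x + 1):A)
    pe1 <- pe1 + 2 * p[x] * p[y] * (1 - p[x] - p[y])^2
  ## PE2: true mother M and offspring O from HWE + Mendel; candidate father
  ## excluded iff he carries no allele in the compatible paternal set R(M,O).
  ## PE3: random pair (C1, C2) cannot jointly produce O.
  pe2 <- 0; pe3 <- 0
  q_has <- 1 - (1 - p)^2            # P(genotype contains allele x)
  for (mx in seq_len(A)) for (my in mx:A) {
    pm <- if (mx == my) p[mx]^2 else 2 * p[mx] * p[my]
    for (f in seq_len(A)) {          # paternal transmitted allele ~ p
      for (m in unique(c(mx, my))) { # maternal transmitted allele
        pt <- pm * p[f] * (if (mx == my) 1 else 0.5)
        o <- sort(c(m, f))
        ## compatible paternal alleles given M and O
        R <- integer(0)
        for (split in 1:2) {
          om <- o[split]; of <- o[3 - split]
          if (om %in% c(mx, my)) R <- c(R, of)
        }
        R <- unique(R)
        pe2 <- pe2 + pt * (1 - sum(p[R]))^2
      }
    }
  }
  ## PE3 depends on offspring genotype distribution only
  for (x in seq_len(A)) pe3 <- pe3 + p[x]^2 * (1 - q_has[x]^2)
  for (x in seq_len(A - 1)) for (y in (x + 1):A) {
    compat <- 2 * q_has[x] * q_has[y] - (2 * p[x] * p[y])^2
    pe3 <- pe3 + 2 * p[x] * p[y] * (1 - compat)
  }
  c(PE1 = unname(pe1), PE2 = unname(pe2), PE3 = unname(pe3))
}

#' Null-allele frequency estimators
#'
#' Closed-form estimators of the null-allele frequency from the
#' heterozygote deficit: Chakraborty `r = (He - Ho) / (He + Ho)` and
#' Brookfield `r = (He - Ho) / (1 + He)`. Negative raw values are reported
#' as 0 with `floored = TRUE`. An optional permutation check re-pairs gene
#' copies into random genotypes to assess whether the observed He - Ho gap
#' exceeds sampling noise.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name.
#' @param method `"chakraborty"` or `"brookfield"`.
#' @param n_perm permutations for the significance check (0 = skip).
#' @param seed RNG seed for the permutation check.
#' @return list with `estimate`, `raw`, `floored`, and `p_value` (NA when
#'   `n_perm = 0`).
#' @export
null_allele_frequency <- function(gm, locus,
                                  method = c("chakraborty", "brookfield"),
                                  n_perm = 0L, seed = 1L) {
  method <- match.arg(method)
  h <- heterozygosities(gm, locus)
  if (h[["He"]] + h[["Ho"]] == 0)
    stop("null-allele estimate undefined at monomorphic locus ", locus)
  est <- function(He, Ho) switch(method,
    chakraborty = (He - Ho) / (He + Ho),
    brookfield = (He - Ho) / (1 + He)
  )
  raw <- est(h[["He"]], h[["Ho"]])
  p_value <- NA_real_
  if (n_perm > 0L) {
    l <- match(locus, gm$loci)
    called <- !is.na(gm$a1[, l])
    genes <- c(gm$a1[called, l], gm$a2[called, l])
    S <- sum(called)
    obs_gap <- h[["He"]] - h[["Ho"]]
    hits <- 0L
    withr_seed(seed, {
      for (b in seq_len(n_perm)) {
        g <- sample(genes)
        Ho_b <- mean(g[seq_len(S)] != g[S + seq_len(S)])
        gap <- h[["He"]] - Ho_b
        if (gap >= obs_gap) hits <- hits + 1L
      }
    })
    p_value <- (hits + 1) / (n_perm + 1)
  }
  list(estimate = max(raw, 0), raw = raw, floored = raw < 0,
       method = method, p_value = p_value)
}

## evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
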