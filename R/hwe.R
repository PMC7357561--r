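## Conditional probability of a genotype table given its allele counts
## (Levene): P(table) = n! * prod(m_a!) * 2^h / ((2n)! * prod(n_ab!)).
## Only log(2^h / prod(n_ab!)) varies over tables with fixed margins.
table_logprob_kernel <- function(counts) {
  sum(counts[upper.tri(counts)]) * log(2) - sum(lfactorial(counts))
}

genotype_counts <- function(g1, g2, A) {
  C <- matrix(0L, A, A)
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  for (i in seq_along(lo)) C[lo[i], hi[i]] <- C[lo[i], hi[i]] + 1L
  C
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Guo-Thompson style Markov chain over diploid genotype tables with the
#' observed allele counts held fixed: one gene copy is swapped between two
#' random individuals per step, which leaves the chain uniform over
#' labelled gene pairings and therefore gives tables their Levene
#' conditional probabilities under Hardy-Weinberg random union. The p-value is the chain fraction of tables whose conditional
#' probability is at or below the observed table's (probability ordering of
#' "more extreme"), with a batch-means Monte-Carlo standard error.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name.
#' @param n_steps total chain length (paper-scale default 1e6).
#' @param n_burnin dememorisation steps (paper-scale default 1e5).
#' @param seed RNG seed.
#' @return list with `p_value`, `se`, `n_steps`, and the observed table
#'   log-kernel.
#' @export
hwe_exact <- function(gm, locus, n_steps = 1e6, n_burnin = 1e5, seed = 1L) {
  l <- match(locus, gm$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  called <- !is.na(gm$a1[, l])
  alle <- sort(unique(c(gm$a1[called, l], gm$a2[called, l])))
  A <- length(alle)
  if (A < 2L) {
    warning("locus ", locus, " is monomorphic; HWE p = 1")
    return(list(p_value = 1, se = 0, n_steps = 0L, obs_kernel = 0))
  }
  g1 <- match(gm$a1[called, l], alle)
  g2 <- match(gm$a2[called, l], alle)
  n <- length(g1)
  obs <- table_logprob_kernel(genotype_counts(g1, g2, A))
  eps <- 1e-9
  hits <- integer(0)
  withr_seed(seed, {
    cur <- obs
    C <- genotype_counts(g1, g2, A)
    hit_buf <- logical(n_steps)
    ii <- sample.int(n, n_steps, replace = TRUE)
    jj <- sample.int(n - 1L, n_steps, replace = TRUE)
    si <- sample.int(2L, n_steps, replace = TRUE)
    sj <- sample.int(2L, n_steps, replace = TRUE)
    for (t in seq_len(n_steps)) {
      i <- ii[t]; j <- jj[t]; if (j >= i) j <- j + 1L
      ai <- if (si[t] == 1L) g1[i] else g2[i]
      aj <- if (sj[t] == 1L) g1[j] else g2[j]
      if (ai != aj) {
        oi <- if (si[t] == 1L) g2[i] else g1[i]
        oj <- if (sj[t] == 1L) g2[j] else g1[j]
        ## categories before/after the swap
        rm1 <- sort(c(ai, oi)); rm2 <- sort(c(aj, oj))
        ad1 <- sort(c(aj, oi)); ad2 <- sort(c(ai, oj))
        dlog <- 0
        dlog <- dlog + log(C[rm1[1], rm1[2]]); C[rm1[1], rm1[2]] <- C[rm1[1], rm1[2]] - 1L
        dlog <- dlog + log(C[rm2[1], rm2[2]]); C[rm2[1], rm2[2]] <- C[rm2[1], rm2[2]] - 1L
        C[ad1[1], ad1[2]] <- C[ad1[1], ad1[2]] + 1L; dlog <- dlog - log(C[ad1[1], ad1[2]])
        C[ad2[1], ad2[2]] <- C[ad2[1], ad2[2]] + 1L; dlog <- dlog - log(C[ad2[1], ad2[2]])
        dh <- (ad1[1] != ad1[2]) + (ad2[1] != ad2[2]) -
              (rm1[1] != rm1[2]) - (rm2[1] != rm2[2])
        dlog <- dlog + dh * log(2)
        ## The chain state is the slot-ordered labelled genotype
        ## assignment. Each table corresponds to n!/prod(n_ab!) * 2^h such
        ## states, exactly cancelling the Levene weight 2^h/prod(n_ab!),
        ## so the target on these states is uniform and every gene swap is
        ## accepted. The table kernel `dlog` is tracked only to order
        ## tables by conditional probability for the p-value.
        cur <- cur + dlog
        if (si[t] == 1L) g1[i] <- aj else g2[i] <- aj
        if (sj[t] == 1L) g1[j] <- ai else g2[j] <- ai
      }
      hit_buf[t] <- cur <= obs + eps
    }
    hits <- hit_buf[(n_burnin + 1L):n_steps]
  })
  p <- mean(hits)
  nb <- 50L
  bsize <- floor(length(hits) / nb)
  bm <- vapply(seq_len(nb), function(b)
    mean(hits[((b - 1L) * bsize + 1L):(b * bsize)]), numeric(1))
  se <- stats::sd(bm) / sqrt(nb)
  list(p_value = p, se = se, n_steps = n_steps, obs_kernel = obs)
}

#' Combine per-locus HWE p-values (Fisher's method)
#'
#' @param p vector of per-locus p-values.
#' @return combined p-value via `-2 sum(log p) ~ chi^2_{2k}`.
#' @export
global_hwe <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values to combine")
  p <- pmax(p, 1e-300)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
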