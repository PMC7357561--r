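## Small genotype fixtures and independent oracles used across tests.

## genotype_matrix from a list of (a1, a2) integer vectors per locus
gm_from_calls <- function(calls1, calls2, ...) {
  n <- length(calls1[[1]])
  genotype_matrix(
    ids = sprintf("i%02d", seq_len(n)),
    loci = names(calls1),
    a1 = do.call(cbind, calls1), a2 = do.call(cbind, calls2),
    ...
  )
}

random_gm <- function(n = 10, L = 5, missing_rate = 0.1, n_pops = 2,
                      seed = 42) {
  set.seed(seed)
  a1 <- matrix(sample(5:15, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(5:15, n * L, replace = TRUE), n, L)
  miss <- matrix(runif(n * L) < missing_rate, n, L)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_matrix(
    ids = sprintf("ind%03d", seq_len(n)),
    loci = sprintf("L%02d", seq_len(L)), a1 = a1, a2 = a2,
    sex = sample(c("F", "M", "unknown"), n, replace = TRUE),
    locality = sample(sprintf("Pop%d", seq_len(n_pops)), n, replace = TRUE),
    lat = runif(n, 57, 58), lon = runif(n, -4.5, -3.5)
  )
}

## Brute-force Mendelian enumeration of exclusion probabilities: iterate
## over mother, father, transmitted alleles, and candidate genotypes with
## their Hardy-Weinberg probabilities.
enumerate_exclusion <- function(p) {
  A <- length(p)
  genos <- expand.grid(x = 1:A, y = 1:A)
  genos <- genos[genos$x <= genos$y, ]
  gp <- ifelse(genos$x == genos$y, p[genos$x]^2, 2 * p[genos$x] * p[genos$y])
  pe1 <- pe2 <- pe3 <- 0
  for (mi in seq_len(nrow(genos))) for (fi in seq_len(nrow(genos))) {
    pmf <- gp[mi] * gp[fi]
    for (ma in c(genos$x[mi], genos$y[mi])) for (fa in c(genos$x[fi], genos$y[fi])) {
      pt <- pmf * 0.25
      o <- sort(c(ma, fa))
      for (ci in seq_len(nrow(genos))) {
        cg <- c(genos$x[ci], genos$y[ci])
        ## PE1: candidate single parent must share an allele with offspring
        if (!any(cg %in% o)) pe1 <- pe1 + pt * gp[ci]
        ## PE2: candidate second parent given the mother known
        compat2 <- FALSE
        for (s in 1:2) {
          om <- o[s]; of <- o[3 - s]
          if (om %in% c(genos$x[mi], genos$y[mi]) && of %in% cg)
            compat2 <- TRUE
        }
        if (!compat2) pe2 <- pe2 + pt * gp[ci]
        ## PE3: candidate pair (ci, cj)
        for (cj in seq_len(nrow(genos))) {
          dg <- c(genos$x[cj], genos$y[cj])
          compat3 <- FALSE
          for (s in 1:2) {
            if (o[s] %in% cg && o[3 - s] %in% dg) compat3 <- TRUE
          }
          if (!compat3) pe3 <- pe3 + pt * gp[ci] * gp[cj]
        }
      }
    }
  }
  c(PE1 = pe1, PE2 = pe2, PE3 = pe3)
}

## Exact Hardy-Weinberg test by complete enumeration of all pairings of
## the 2n labelled gene copies (each pairing equally likely given allele
## counts); p = total probability of tables no more probable than observed.
enumerate_hwe_p <- function(g1, g2) {
  genes <- c(rbind(g1, g2))
  n <- length(g1)
  tables <- new.env()
  pairings <- function(idx) {
    if (length(idx) == 0L) return(list(integer(0)))
    first <- idx[1]
    out <- list()
    for (j in idx[-1]) {
      rest <- setdiff(idx, c(first, j))
      for (sub in pairings(rest)) out[[length(out) + 1L]] <- c(first, j, sub)
    }
    out
  }
  key_of <- function(perm) {
    m <- matrix(genes[perm], nrow = 2)
    paste(sort(paste(pmin(m[1, ], m[2, ]), pmax(m[1, ], m[2, ]))),
          collapse = ";")
  }
  all_p <- pairings(seq_along(genes))
  keys <- vapply(all_p, key_of, character(1))
  tab <- table(keys) / length(keys)
  obs_key <- paste(sort(paste(pmin(g1, g2), pmax(g1, g2))), collapse = ";")
  obs_pr <- tab[[obs_key]]
  sum(tab[tab <= obs_pr + 1e-12])
}

## Direct evaluation of Weir & Cockerham's (1984) theta on a two-sample
## genotype table, allele by allele, without the package's bookkeeping.
oracle_wc_theta_locus <- function(g1, g2, groups) {
  glev <- unique(groups)
  r <- length(glev)
  ni <- sapply(glev, function(g) sum(groups == g))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  alle <- unique(c(g1, g2))
  A <- D <- 0
  for (a in alle) {
    pi <- sapply(glev, function(g) {
      s <- groups == g
      (sum(g1[s] == a) + sum(g2[s] == a)) / (2 * sum(s))
    })
    hi <- sapply(glev, function(g) {
      s <- groups == g
      mean((g1[s] == a) != (g2[s] == a))
    })
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    av <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    bv <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cv <- hbar / 2
    A <- A + av; D <- D + av + bv + cv
  }
  A / D
}
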