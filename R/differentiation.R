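## Barton & Slatkin private-allele regressions ln p(1) = a ln(Nm) + b at
## reference per-deme sample sizes 10 / 25 / 50, as used for the
## size-corrected gene-flow estimate.
bs_constants <- data.frame(
  n = c(10, 25, 50),
  a = c(-0.505, -0.576, -0.612),
  b = c(-2.440, -2.609, -2.712)
)

#' Gene flow from private alleles (Barton-Slatkin method)
#'
#' A private allele occurs in exactly one group. The mean frequency of
#' private alleles (within the group that carries them) is converted to an
#' effective number of migrants per generation Nm via the published
#' regressions at reference sample sizes 10, 25 and 50, interpolated
#' log-linearly in sample size to the observed mean per-group gene sample
#' size.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping grouping passed to [allele_frequencies()]; default
#'   localities.
#' @return list with `Nm`, `p1_mean` (mean private-allele frequency),
#'   `n_mean` (mean per-group sample size, individuals), `n_private`, and a
#'   `panmixia` flag (TRUE when no private allele exists, leaving Nm
#'   undefined/infinite).
#' @export
private_allele_nm <- function(gm, grouping = "by_locality") {
  ft <- allele_frequencies(gm, grouping)
  groups <- unique(group_vector(gm, grouping))
  if (length(groups) < 2L) stop("need >= 2 groups for private alleles")
  p1 <- numeric(0)
  for (locus in names(ft$freq)) {
    fl <- ft$freq[[locus]]
    present <- lapply(fl, function(f) names(f)[f > 0])
    alle <- unique(unlist(present))
    for (a in alle) {
      carriers <- which(vapply(present, function(x) a %in% x, logical(1)))
      if (length(carriers) == 1L)
        p1 <- c(p1, fl[[carriers]][[a]])
    }
  }
  ## mean per-group sample size in individuals (gene copies / 2), averaged
  ## over loci and groups
  nvals <- unlist(ft$n_genes) / 2
  n_mean <- mean(nvals[nvals > 0])
  if (length(p1) == 0L)
    return(list(Nm = Inf, p1_mean = NA_real_, n_mean = n_mean,
                n_private = 0L, panmixia = TRUE))
  p1_mean <- mean(p1)
  ln_nm_ref <- (log(p1_mean) - bs_constants$b) / bs_constants$a
  ## log-linear interpolation of ln(Nm) against ln(reference size)
  ln_nm <- stats::approx(log(bs_constants$n), ln_nm_ref, xout = log(n_mean),
                         rule = 2)$y
  list(Nm = exp(ln_nm), p1_mean = p1_mean, n_mean = n_mean,
       n_private = length(p1), panmixia = FALSE)
}

## log10 likelihood of individual i's multilocus genotype under the allele
## frequencies of group `home`, removing the focal individual first when
## leave_one_out. Zero-frequency alleles get the GeneClass surrogate 0.01.
genotype_loglik <- function(gm, i, home, groups, leave_one_out = TRUE,
                            surrogate = 0.01, bayesian = FALSE) {
  sel <- groups == home
  if (leave_one_out) sel[i] <- FALSE
  ll <- 0
  for (l in seq_along(gm$loci)) {
    x1 <- gm$a1[i, l]; x2 <- gm$a2[i, l]
    if (is.na(x1)) next
    genes <- c(gm$a1[sel, l], gm$a2[sel, l])
    genes <- genes[!is.na(genes)]
    n <- length(genes)
    if (n == 0L) next
    if (bayesian) {
      ## Rannala-Mountain posterior-predictive genotype probability with a
      ## uniform 1/k Dirichlet prior over the k alleles seen in the data set
      k <- length(unique(c(gm$a1[, l], gm$a2[, l])[!is.na(c(gm$a1[, l], gm$a2[, l]))]))
      n1 <- sum(genes == x1)
      n2 <- sum(genes == x2)
      if (x1 == x2) {
        pr <- (n1 + 1 / k) / (n + 1) * (n1 + 1 + 1 / k) / (n + 2)
      } else {
        pr <- 2 * (n1 + 1 / k) / (n + 1) * (n2 + 1 / k) / (n + 2)
      }
    } else {
      p1 <- sum(genes == x1) / n
      p2 <- sum(genes == x2) / n
      if (p1 == 0) p1 <- surrogate
      if (p2 == 0) p2 <- surrogate
      pr <- if (x1 == x2) p1 * p2 else 2 * p1 * p2
    }
    ll <- ll + log10(pr)
  }
  ll
}

#' Assignment index correction (AIc) and sex-biased dispersal test
#'
#' For each individual, the log10 likelihood of its multilocus genotype in
#' its home locality (leave-one-out frequencies, zero-frequency surrogate
#' 0.01) is centred by the locality mean, giving AIc. Negative AIc marks
#' likely immigrants; under sex-biased dispersal the dispersing sex has
#' lower mean AIc. Sexes are compared with a two-sided Mann-Whitney U-test.
#'
#' @param gm a [genotype_matrix()] with sex known for >= 80\% of
#'   individuals and >= 2 localities.
#' @return list with per-individual data frame `aic` (id, sex, locality,
#'   AIc), per-sex means, `U` statistic and `p_value`.
#' @export
assignment_indices <- function(gm) {
  known <- gm$ind$sex %in% c("F", "M")
  if (mean(known) < 0.8)
    stop("sex must be known for >= 80% of individuals")
  groups <- gm$ind$locality
  sizes <- table(groups)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warning("excluding single-individual localit(ies): ",
            paste(singles, collapse = ", "))
    keep <- !groups %in% singles
    gm <- subset_genotypes(gm, individuals = which(keep))
    groups <- gm$ind$locality
  }
  if (length(unique(groups)) < 2L) stop("need >= 2 localities")
  n <- nrow(gm$ind)
  ai <- vapply(seq_len(n), function(i)
    genotype_loglik(gm, i, groups[i], groups), numeric(1))
  aic <- ai - stats::ave(ai, groups)
  df <- data.frame(id = gm$ind$id, sex = gm$ind$sex, locality = groups,
                   AIc = aic, stringsAsFactors = FALSE)
  f <- df$AIc[df$sex == "F"]; m <- df$AIc[df$sex == "M"]
  if (length(unique(c(f, m))) <= 1L) {
    U <- length(f) * length(m) / 2; pv <- 1
  } else {
    wt <- stats::wilcox.test(f, m, exact = FALSE)
    U <- unname(wt$statistic); pv <- wt$p.value
  }
  list(aic = df,
       mean_F = mean(f), mean_M = mean(m),
       U = U, p_value = pv)
}

#' First-generation migrant detection (GeneClass-style)
#'
#' Each individual's genotype likelihood in its home locality is compared
#' with a Monte-Carlo null distribution of likelihoods of genotypes
#' simulated from the home allele frequencies (Hardy-Weinberg draws). An
#' individual with likelihood in the lower `alpha` tail is flagged as an
#' immigrant.
#'
#' Criteria: `"frequency"` (Paetkau leave-one-out frequency likelihood,
#' surrogate 0.01 for unseen alleles), `"bayesian"` (Rannala-Mountain
#' posterior-predictive likelihood), `"distance"` (Nei standard distance to
#' the locality centroid, flagged when the home distance is in the upper
#' `alpha` tail of simulated home genotypes).
#'
#' @param gm a [genotype_matrix()] with >= 2 localities.
#' @param criterion `"frequency"`, `"bayesian"`, or `"distance"`.
#' @param alpha flagging level in (0, 1).
#' @param n_mc simulated genotypes per locality (paper-scale default
#'   10,000).
#' @param seed RNG seed.
#' @return list with per-individual data frame (`id`, `locality`, score,
#'   `p_value`, `migrant` flag), the immigration proportion `m`, `criterion`
#'   and `alpha`.
#' @export
detect_migrants <- function(gm, criterion = c("frequency", "bayesian",
                                              "distance"),
                            alpha = 0.01, n_mc = 1000L, seed = 1L) {
  criterion <- match.arg(criterion)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  groups <- gm$ind$locality
  glev <- unique(groups)
  if (length(glev) < 2L)
    return(list(individuals = data.frame(), m = 0, criterion = criterion,
                alpha = alpha))
  sizes <- table(groups)
  if (any(sizes < 5))
    warning("group(s) smaller than 5 individuals: unstable reference frequencies")
  n <- nrow(gm$ind)
  score <- numeric(n); pval <- numeric(n)
  withr_seed(seed, {
    ft <- allele_frequencies(gm, "by_locality")
    null_parts <- lapply(glev, function(g)
      simulate_null_parts(gm, g, ft, n_mc, criterion))
    names(null_parts) <- glev
    for (i in seq_len(n)) {
      g <- groups[i]
      score[i] <- individual_score(gm, i, g, groups, criterion, ft)
      typed <- which(!is.na(gm$a1[i, ]))
      ns <- combine_null_parts(null_parts[[g]], typed, criterion)
      if (criterion == "distance") {
        pval[i] <- (sum(ns >= score[i]) + 1) / (length(ns) + 1)
      } else {
        pval[i] <- (sum(ns <= score[i]) + 1) / (length(ns) + 1)
      }
    }
  })
  flag <- pval < alpha
  list(individuals = data.frame(id = gm$ind$id, locality = groups,
                                score = score, p_value = pval,
                                migrant = flag, stringsAsFactors = FALSE),
       m = mean(flag), criterion = criterion, alpha = alpha)
}

individual_score <- function(gm, i, home, groups, criterion, ft) {
  if (criterion == "distance") {
    nei_distance_to_centroid(gm, i, home, ft)
  } else {
    genotype_loglik(gm, i, home, groups,
                    bayesian = criterion == "bayesian")
  }
}

## Nei (1972) standard distance between an individual's allele profile
## (frequencies 0 / 0.5 / 1) and the locality centroid frequencies.
nei_distance_to_centroid <- function(gm, i, home, ft) {
  jxy <- 0; jx <- 0; jy <- 0
  for (l in seq_along(gm$loci)) {
    locus <- gm$loci[l]
    f <- ft$freq[[locus]][[home]]
    if (is.null(f)) next
    x1 <- gm$a1[i, l]; x2 <- gm$a2[i, l]
    if (is.na(x1)) next
    prof <- if (x1 == x2) stats::setNames(1, x1) else
      stats::setNames(c(0.5, 0.5), c(x1, x2))
    alle <- union(names(f), names(prof))
    fx <- stats::setNames(rep(0, length(alle)), alle); fx[names(prof)] <- prof
    fy <- stats::setNames(rep(0, length(alle)), alle); fy[names(f)] <- f
    jxy <- jxy + sum(fx * fy); jx <- jx + sum(fx^2); jy <- jy + sum(fy^2)
  }
  if (jxy <= 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

## Monte-Carlo null: the score distribution of an exchangeable resident.
## Per locus and replicate, the focal genotype's two genes are drawn
## WITHOUT replacement from the observed home gene pool and scored against
## the remaining pool - exactly mirroring the leave-one-out scoring of a
## real member, so the test is calibrated on panmictic data. Per-locus
## score contributions are kept separate so each individual's null uses
## only the loci it was typed at.
simulate_null_parts <- function(gm, home, ft, n_mc, criterion) {
  L <- length(gm$loci)
  surrogate <- 0.01
  loglik_parts <- matrix(0, n_mc, L)
  jxy <- jx <- jy <- array(0, c(n_mc, L))
  for (l in seq_len(L)) {
    locus <- gm$loci[l]
    f <- ft$freq[[locus]][[home]]
    if (is.null(f)) next
    ng <- ft$n_genes[[locus]][[home]]
    if (ng < 3L) next
    cnt <- round(f * ng)
    A <- length(cnt)
    ## gene 1 from the pool, gene 2 from the pool minus gene 1
    i1 <- sample.int(A, n_mc, replace = TRUE, prob = cnt)
    i2 <- integer(n_mc)
    for (a in seq_len(A)) {
      sel <- i1 == a
      if (!any(sel)) next
      c2 <- cnt; c2[a] <- c2[a] - 1L
      i2[sel] <- sample.int(A, sum(sel), replace = TRUE, prob = c2)
    }
    r1 <- cnt[i1] - 1L - (i1 == i2)          # reference count of allele 1
    r2 <- cnt[i2] - 1L - (i1 == i2)          # reference count of allele 2
    het <- i1 != i2
    n_ref <- ng - 2L
    if (criterion == "distance") {
      ## components of the Nei standard distance to the home centroid
      prof1 <- ifelse(het, 0.5, 1)
      jxy[, l] <- prof1 * f[i1] + ifelse(het, 0.5 * f[i2], 0)
      jx[, l] <- ifelse(het, 0.5, 1)
      jy[, l] <- sum(f^2)
    } else if (criterion == "bayesian") {
      ## same Dirichlet dimension as the observed-individual scoring:
      ## alleles seen anywhere in the data set at this locus
      k <- length(unique(c(gm$a1[, l], gm$a2[, l])[
        !is.na(c(gm$a1[, l], gm$a2[, l]))]))
      p1 <- (r1 + 1 / k) / (n_ref + 1)
      p2 <- ifelse(het, (r2 + 1 / k) / (n_ref + 2),
                   (r1 + 1 + 1 / k) / (n_ref + 2))
      loglik_parts[, l] <- log10(ifelse(het, 2, 1) * p1 * p2)
    } else {
      p1 <- ifelse(r1 > 0, r1 / n_ref, surrogate)
      p2 <- ifelse(het, ifelse(r2 > 0, r2 / n_ref, surrogate), p1)
      loglik_parts[, l] <- log10(ifelse(het, 2, 1) * p1 * p2)
    }
  }
  list(loglik = loglik_parts, jxy = jxy, jx = jx, jy = jy)
}

combine_null_parts <- function(parts, typed, criterion) {
  if (criterion == "distance") {
    num <- rowSums(parts$jxy[, typed, drop = FALSE])
    den <- sqrt(rowSums(parts$jx[, typed, drop = FALSE]) *
                  rowSums(parts$jy[, typed, drop = FALSE]))
    out <- -log(num / den)
    out[!is.finite(out)] <- Inf
    out
  } else {
    rowSums(parts$loglik[, typed, drop = FALSE])
  }
}

#' Mantel test of isolation by distance
#'
#' Correlates the Cavalli-Sforza & Edwards chord distance between
#' individuals with the great-circle (haversine) distance between their
#' coordinates, with a permutation p-value (via \pkg{vegan}). Individuals
#' lacking coordinates inherit their locality centroid.
#'
#' @param gm a [genotype_matrix()] with coordinates on individuals or
#'   localities.
#' @param n_perm Mantel permutations (paper-scale default 10,000).
#' @param seed RNG seed.
#' @return list with Mantel `r`, `p_value`, and `n_perm`.
#' @export
mantel_ibd <- function(gm, n_perm = 999L, seed = 1L) {
  lat <- gm$ind$lat; lon <- gm$ind$lon
  miss <- is.na(lat) | is.na(lon)
  if (any(miss)) {
    cen <- stats::aggregate(cbind(lat, lon) ~ locality, data = gm$ind,
                            FUN = mean, na.action = stats::na.omit)
    j <- match(gm$ind$locality[miss], cen$locality)
    lat[miss] <- cen$lat[j]; lon[miss] <- cen$lon[j]
  }
  if (anyNA(lat) || anyNA(lon)) stop("coordinates missing and no locality centroid available")
  n <- nrow(gm$ind)
  geo <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                  cbind(lon[(i + 1):n], lat[(i + 1):n]))
    geo[i, (i + 1):n] <- d; geo[(i + 1):n, i] <- d
  }
  if (all(geo == 0)) stop("all coordinates identical: no geographic variance")
  gen <- chord_distance_matrix(gm)
  withr_seed(seed, {
    mt <- vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                        permutations = n_perm)
  })
  list(r = unname(mt$statistic), p_value = mt$signif, n_perm = n_perm)
}

## Cavalli-Sforza & Edwards chord distance between individual allele
## profiles: D(x, y) = sqrt(sum_l (1 - sum_a sqrt(x_a y_a))).
chord_distance_matrix <- function(gm) {
  n <- nrow(gm$ind)
  L <- length(gm$loci)
  ## per-locus individual profiles as sparse two-column representation
  D <- matrix(0, n, n)
  cnt <- matrix(0, n, n)  # loci jointly typed
  for (l in seq_len(L)) {
    called <- which(!is.na(gm$a1[, l]))
    if (length(called) < 2L) next
    alle <- sort(unique(c(gm$a1[called, l], gm$a2[called, l])))
    P <- matrix(0, n, length(alle))
    i1 <- match(gm$a1[called, l], alle); i2 <- match(gm$a2[called, l], alle)
    for (k in seq_along(called)) {
      P[called[k], i1[k]] <- P[called[k], i1[k]] + 0.5
      P[called[k], i2[k]] <- P[called[k], i2[k]] + 0.5
    }
    SQ <- sqrt(P)
    cos_l <- SQ %*% t(SQ)
    typed <- outer(seq_len(n) %in% called, seq_len(n) %in% called, "&")
    D <- D + ifelse(typed, pmax(1 - cos_l, 0), 0)
    cnt <- cnt + typed
  }
  out <- sqrt(ifelse(cnt > 0, D / cnt * L, 0))
  diag(out) <- 0
  out
}
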