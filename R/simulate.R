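#' Simulation scenario for the coalescent microsatellite generator
#'
#' Bundles the demography and sampling design used by
#' [simulate_genotypes()]: L unlinked microsatellite loci evolving by
#' stepwise (or generalised stepwise) mutation on a Kingman coalescent with
#' piecewise-constant effective size, sampled as diploids with sex and
#' locality labels, optional missing data, and optionally several demes
#' exchanging migrants (island model, constant size) with planted
#' first-generation immigrants.
#'
#' @param demography a [step_demography()] (per-deme size when
#'   `demes > 1`).
#' @param n_individuals diploids sampled per deme.
#' @param n_loci unlinked loci.
#' @param model `"SMM"` or `"GSM"`.
#' @param gsm_c geometric step parameter for GSM.
#' @param demes number of demes (island model; `demes > 1` requires a
#'   constant-size demography).
#' @param four_Nm scaled island migration `4 N m` between demes.
#' @param planted_migrants individuals of the first deme whose genes are
#'   drawn from `migrant_origin` (first-generation immigrants).
#' @param migrant_origin deme index the planted migrants come from.
#' @param sex_ratio probability an individual is female.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed default RNG seed for [simulate_genotypes()].
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(demography, n_individuals, n_loci,
                         model = c("SMM", "GSM"), gsm_c = 0.2,
                         demes = 1L, four_Nm = 0,
                         planted_migrants = 0L, migrant_origin = 2L,
                         sex_ratio = 0.5, missing_rate = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_individuals >= 1, n_loci >= 1, demes >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (demes > 1L && demography$J > 0L)
    stop("multi-deme simulation supports constant-size demographies only")
  if (planted_migrants > 0L &&
      (demes < 2L || migrant_origin > demes || planted_migrants > n_individuals))
    stop("incompatible deme / planted-migrant configuration")
  structure(list(demography = demography, n_individuals = n_individuals,
                 n_loci = n_loci, model = model, gsm_c = gsm_c,
                 demes = as.integer(demes), four_Nm = four_Nm,
                 planted_migrants = as.integer(planted_migrants),
                 migrant_origin = as.integer(migrant_origin),
                 sex_ratio = sex_ratio, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_scenario")
}

#' Simulate diploid microsatellite genotypes under a coalescent scenario
#'
#' Per locus, a Kingman genealogy of `2 x n_individuals x demes` gene
#' copies is simulated under the scenario demography (structured island
#' coalescent when `demes > 1`), stepwise mutations are overlaid at rate 1
#' per lineage per mutation-scaled time unit from a root allele of 100
#' repeats, and gene copies are paired into diploids. Planted migrants are
#' individuals labelled in deme 1 whose lineages start in the origin deme.
#' Sexes are drawn from the sex ratio and genotype calls are masked at the
#' missing rate. Identical scenario and seed give identical output.
#'
#' @param scn a [sim_scenario()].
#' @param seed RNG seed (defaults to the scenario seed).
#' @return a [genotype_matrix()] with localities `Deme1..DemeK`.
#' @export
simulate_genotypes <- function(scn, seed = scn$seed) {
  S <- scn$n_individuals * scn$demes
  n_genes <- 2L * S
  deme_of_ind <- rep(seq_len(scn$demes), each = scn$n_individuals)
  is_migrant <- rep(FALSE, S)
  if (scn$planted_migrants > 0L) {
    mig <- which(deme_of_ind == 1L)[seq_len(scn$planted_migrants)]
    is_migrant[mig] <- TRUE
  }
  lineage_deme <- rep(deme_of_ind, each = 2L)
  lineage_deme[rep(is_migrant, each = 2L)] <- scn$migrant_origin
  a1 <- matrix(NA_integer_, S, scn$n_loci)
  a2 <- matrix(NA_integer_, S, scn$n_loci)
  withr_seed(seed, {
    for (l in seq_len(scn$n_loci)) {
      gen <- if (scn$demes == 1L) {
        sim_genealogy(n_genes, scn$demography)
      } else {
        sim_genealogy_island(lineage_deme, scn$demography$theta[1],
                             scn$four_Nm, scn$demes)
      }
      alle <- drop_mutations(gen, scn$model, scn$gsm_c)
      a1[, l] <- alle[seq(1L, n_genes, by = 2L)]
      a2[, l] <- alle[seq(2L, n_genes, by = 2L)]
    }
    sex <- ifelse(stats::runif(S) < scn$sex_ratio, "F", "M")
    if (scn$missing_rate > 0) {
      mask <- matrix(stats::runif(S * scn$n_loci) < scn$missing_rate,
                     S, scn$n_loci)
      a1[mask] <- NA_integer_
      a2[mask] <- NA_integer_
    }
    gm <- genotype_matrix(
      ids = sprintf("ind%03d", seq_len(S)),
      loci = sprintf("loc%02d", seq_len(scn$n_loci)),
      a1 = a1, a2 = a2, sex = sex,
      locality = sprintf("Deme%d", deme_of_ind)
    )
  })
  attr(gm, "planted_migrants") <- gm$ind$id[is_migrant]
  gm
}

#' Named simulation presets
#'
#' Fully parameterised scenarios used throughout the package's tests and
#' examples (`mu = 0.00015` everywhere):
#' * `"constant"` - constant scaled size `theta = 1.2` (Ne = 2,000), 30
#'   loci, 50 diploids; mutation-drift equilibrium baseline.
#' * `"recent_bottleneck"` - 50-fold instantaneous decline 50 generations
#'   ago (`theta` 5 to 0.1), 30 loci, 50 diploids; drives the
#'   heterozygosity-excess power checks.
#' * `"moray_decline"` - decline from Ne 65,000 to 700 completed 2,000
#'   generations ago (`theta` 39 to 0.42), 17 loci, 93 diploids; emulates
#'   the study population's scale.
#' * `"two_demes"` - island pair at `theta = 2` per deme with `4Nm = 3.5`
#'   (calibrated by simulation to a realised multilocus Weir & Cockerham
#'   FST of about 0.1), 40 loci, 25 diploids per deme, 2 planted
#'   first-generation immigrants; a validation scenario sized so that a
#'   first-generation migrant carries detectable multilocus information at
#'   this FST.
#'
#' @param name preset name.
#' @return a [sim_scenario()] with a fixed default seed.
#' @export
scenario_presets <- function(name = c("constant", "recent_bottleneck",
                                      "moray_decline", "two_demes")) {
  if (!is.character(name) || !name[1] %in%
      c("constant", "recent_bottleneck", "moray_decline", "two_demes"))
    stop("unknown preset '", name[1], "'; available: constant, ",
         "recent_bottleneck, moray_decline, two_demes")
  name <- match.arg(name)
  mu <- 0.00015
  switch(name,
    constant = sim_scenario(
      demography = step_demography(1.2),
      n_individuals = 50L, n_loci = 30L, seed = 101L
    ),
    recent_bottleneck = sim_scenario(
      demography = step_demography(c(0.1, 5), 50 * mu),
      n_individuals = 50L, n_loci = 30L, seed = 102L
    ),
    moray_decline = sim_scenario(
      demography = step_demography(c(4 * 700 * mu, 4 * 65000 * mu),
                                   2000 * mu),
      n_individuals = 93L, n_loci = 17L, missing_rate = 0.032, seed = 103L
    ),
    two_demes = sim_scenario(
      demography = step_demography(2),
      n_individuals = 25L, n_loci = 40L, demes = 2L, four_Nm = 3.5,
      planted_migrants = 2L, migrant_origin = 2L, seed = 104L
    )
  )
}
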