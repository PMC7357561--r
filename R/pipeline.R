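#' Pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list) with per-stage blocks
#' and fills in defaults mirroring the study settings: `mu = 0.00015`,
#' generation time 8.75 years, 10,000 bottleneck iterations, 1,000,000
#' MCMC iterations. Command-line style overrides can be supplied as a
#' named list and take precedence over file values.
#'
#' @param path YAML file path, or `NULL` to start from defaults.
#' @param overrides named list of `block$key` overrides, e.g.
#'   `list(nehistory = list(n_iter = 1e5))`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    input = list(path = NULL, format = "table", metadata = NULL),
    output_dir = "msatdemog_output",
    seed = 1L,
    mu = 0.00015,
    gen_years = 8.75,
    simulate = list(preset = "constant"),
    diversity = list(hwe_steps = 1e6, hwe_burnin = 1e5, n_boot = 10000),
    differentiation = list(n_perm = 10000, n_mc = 10000, alpha = 0.01),
    bottleneck = list(n_sim = 10000, model = "SMM"),
    nehistory = list(n_iter = 1e6, n_burnin = 1e4, n_retained = 1e4,
                     nbar = 5000, varp1 = 3, varp2 = 3, rhocorn = 0.8,
                     gbar = 10000, J = 3)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, user, prefix) {
  for (k in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, "$", k) else k
    if (!k %in% names(base))
      stop("invalid config key: ", full)
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_hash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% .Machine$integer.max)
}

stage_log <- function(outdir, stage, cfg, extra = list()) {
  log <- c(
    sprintf("[%s] stage=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage),
    sprintf("package=msatdemog %s", as.character(utils::packageVersion("msatdemog"))),
    sprintf("config_hash=%s seed=%s mu=%g gen_years=%g",
            config_hash(cfg), cfg$seed, cfg$mu, cfg$gen_years),
    vapply(names(extra), function(k) sprintf("%s=%s", k, extra[[k]]),
           character(1))
  )
  cat(log, sep = "\n", file = file.path(outdir, paste0(stage, ".log")))
  message(paste(log, collapse = "\n"))
}

load_pipeline_input <- function(cfg) {
  sim_path <- file.path(cfg$output_dir, "simulated.csv")
  if (!is.null(cfg$input$path)) {
    load_genotypes(cfg$input$path, cfg$input$format,
                   metadata = cfg$input$metadata)
  } else if (file.exists(sim_path)) {
    load_genotypes(sim_path, "table")
  } else {
    stop("no input: set input$path or run the 'simulate' stage first")
  }
}

write_stage_json <- function(x, outdir, name, cfg) {
  x$config_hash <- config_hash(cfg)
  x$seed <- cfg$seed
  jsonlite::write_json(x, file.path(outdir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a pipeline stage
#'
#' Commands: `"simulate"` (write a preset's genotypes), `"diversity"`
#' (per-locus summary table and multilocus FIS), `"differentiation"`
#' (pairwise FST, private-allele Nm, AIc, migrant detection),
#' `"bottleneck"` (heterozygosity-excess tests), `"nehistory"` (distance
#' spectra, posterior sampling, trajectory and TMRCA summaries), and
#' `"report"` (aggregate previous stages' JSON artifacts). Every stage
#' writes CSV/JSON artifacts carrying the config hash and seed into
#' `config$output_dir` plus a log file.
#'
#' @param command stage name.
#' @param config a [pipeline_config()].
#' @return invisibly, the stage's main result object.
#' @export
pipeline_run <- function(command = c("simulate", "diversity",
                                     "differentiation", "bottleneck",
                                     "nehistory", "report"),
                         config = pipeline_config()) {
  command <- match.arg(command)
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(command,
    simulate = stage_simulate(config, outdir),
    diversity = stage_diversity(config, outdir),
    differentiation = stage_differentiation(config, outdir),
    bottleneck = stage_bottleneck(config, outdir),
    nehistory = stage_nehistory(config, outdir),
    report = stage_report(config, outdir)
  )
  invisible(res)
}

stage_simulate <- function(cfg, outdir) {
  scn <- scenario_presets(cfg$simulate$preset)
  gm <- simulate_genotypes(scn, seed = cfg$seed)
  write_genotypes(gm, file.path(outdir, "simulated.csv"), "table")
  write_genotypes(gm, file.path(outdir, "simulated.gen"), "genepop")
  write_stage_json(list(preset = cfg$simulate$preset,
                        n_individuals = n_individuals(gm),
                        n_loci = n_loci(gm)),
                   outdir, "simulate", cfg)
  stage_log(outdir, "simulate", cfg, list(preset = cfg$simulate$preset))
  gm
}

#' Per-locus diversity summary table
#'
#' One row per polymorphic locus with the classical marker-characterisation
#' columns: S, A, He, Hnb, Ho, HWE p (Monte-Carlo exact test), PIC, PI,
#' PE1-PE3, and the null-allele estimate.
#'
#' @param gm a [genotype_matrix()].
#' @param hwe_steps,hwe_burnin,seed Monte-Carlo settings for [hwe_exact()].
#' @return data frame, one row per polymorphic locus.
#' @export
locus_summary_table <- function(gm, hwe_steps = 2e4, hwe_burnin = 2e3,
                                seed = 1L) {
  prof <- polymorphism_profile(gm)$loci
  loci <- prof$locus[prof$polymorphic]
  ft <- allele_frequencies(gm, "pooled")
  rows <- lapply(loci, function(locus) {
    h <- heterozygosities(gm, locus)
    p <- ft$freq[[locus]][["all"]]
    hw <- hwe_exact(gm, locus, hwe_steps, hwe_burnin,
                    seed = seed + match(locus, gm$loci))
    pe <- exclusion_probabilities(p)
    ids <- identity_probabilities(stats::setNames(list(p), locus))
    fn <- null_allele_frequency(gm, locus, "chakraborty")
    data.frame(
      locus = locus, S = prof$S[prof$locus == locus],
      A = prof$A[prof$locus == locus],
      He = h[["He"]], Hnb = h[["Hnb"]], Ho = h[["Ho"]],
      P_hwe = hw$p_value, P_hwe_se = hw$se, PIC = pic(p),
      PI = ids$PI[1], PE1 = pe[["PE1"]], PE2 = pe[["PE2"]],
      PE3 = pe[["PE3"]], Fnull = fn$estimate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

stage_diversity <- function(cfg, outdir) {
  gm <- load_pipeline_input(cfg)
  tab <- locus_summary_table(gm, cfg$diversity$hwe_steps,
                             cfg$diversity$hwe_burnin, seed = cfg$seed)
  utils::write.csv(tab, file.path(outdir, "locus_table.csv"),
                   row.names = FALSE)
  fis <- tryCatch(fis_multilocus(gm, n_boot = cfg$diversity$n_boot,
                                 seed = cfg$seed),
                  error = function(e) NULL)
  out <- list(
    mean_A = mean(tab$A), mean_Ho = mean(tab$Ho), mean_He = mean(tab$He),
    global_hwe_p = global_hwe(tab$P_hwe),
    missing_fraction = polymorphism_profile(gm)$missing_fraction,
    fis = if (is.null(fis)) NULL else
      list(estimate = fis$estimate, ci_lower = fis$ci[1],
           ci_upper = fis$ci[2], jackknife = fis$jackknife)
  )
  write_stage_json(out, outdir, "diversity", cfg)
  stage_log(outdir, "diversity", cfg,
            list(loci = nrow(tab), mean_Ho = round(out$mean_Ho, 3)))
  list(table = tab, summary = out)
}

stage_differentiation <- function(cfg, outdir) {
  gm <- load_pipeline_input(cfg)
  fst <- pairwise_fst(gm, n_perm = cfg$differentiation$n_perm,
                      seed = cfg$seed)
  utils::write.csv(fst$theta, file.path(outdir, "fst_theta.csv"))
  utils::write.csv(fst$p, file.path(outdir, "fst_p.csv"))
  nm <- tryCatch(private_allele_nm(gm), error = function(e) NULL)
  aic <- tryCatch(assignment_indices(gm), error = function(e) NULL)
  mig <- detect_migrants(gm, "frequency", alpha = cfg$differentiation$alpha,
                         n_mc = cfg$differentiation$n_mc, seed = cfg$seed)
  utils::write.csv(mig$individuals,
                   file.path(outdir, "migrants_frequency.csv"),
                   row.names = FALSE)
  if (!is.null(aic))
    utils::write.csv(aic$aic, file.path(outdir, "aic.csv"),
                     row.names = FALSE)
  out <- list(
    max_fst = max(fst$theta, na.rm = TRUE),
    Nm = if (is.null(nm)) NULL else nm$Nm,
    immigration_m = mig$m,
    aic_p = if (is.null(aic)) NULL else aic$p_value
  )
  write_stage_json(out, outdir, "differentiation", cfg)
  stage_log(outdir, "differentiation", cfg, list(m = mig$m))
  list(fst = fst, nm = nm, aic = aic, migrants = mig, summary = out)
}

stage_bottleneck <- function(cfg, outdir) {
  gm <- load_pipeline_input(cfg)
  bt <- bottleneck_tests(gm, model = cfg$bottleneck$model,
                         n_sim = cfg$bottleneck$n_sim, seed = cfg$seed)
  utils::write.csv(bt$loci, file.path(outdir, "bottleneck_loci.csv"),
                   row.names = FALSE)
  out <- list(
    n_excess = bt$n_excess, n_deficit = bt$n_deficit,
    sign_p_excess = bt$sign_test$p_excess,
    T2 = bt$standardized$T2,
    wilcoxon_p_excess = bt$wilcoxon$p_excess,
    wilcoxon_p_two_sided = bt$wilcoxon$p_two_sided
  )
  write_stage_json(out, outdir, "bottleneck", cfg)
  stage_log(outdir, "bottleneck", cfg,
            list(wilcoxon_p_excess = signif(out$wilcoxon_p_excess, 3)))
  bt
}

stage_nehistory <- function(cfg, outdir) {
  gm <- load_pipeline_input(cfg)
  sp <- distance_spectrum(gm)
  spec_df <- data.frame(
    locus = rep(rownames(sp$counts), each = ncol(sp$counts)),
    k = rep(0:sp$dmax, nrow(sp$counts)),
    count = as.vector(t(sp$counts))
  )
  utils::write.csv(spec_df, file.path(outdir, "distance_spectrum.csv"),
                   row.names = FALSE)
  pr <- prior_spec(nbar = cfg$nehistory$nbar, varp1 = cfg$nehistory$varp1,
                   rhocorn = cfg$nehistory$rhocorn,
                   varp2 = cfg$nehistory$varp2, gbar = cfg$nehistory$gbar,
                   mu = cfg$mu, J = cfg$nehistory$J)
  conf <- mcmc_config(n_iter = cfg$nehistory$n_iter,
                      n_burnin = cfg$nehistory$n_burnin,
                      n_retained = cfg$nehistory$n_retained,
                      seed = cfg$seed)
  ens <- sample_posterior(sp, pr, conf)
  ts <- trajectory_summaries(ens, gen_years = cfg$gen_years)
  td <- tmrca_density(ens, gen_years = cfg$gen_years)
  utils::write.csv(ts$trajectory, file.path(outdir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(td$density, file.path(outdir, "tmrca.csv"),
                   row.names = FALSE)
  samp <- cbind(as.data.frame(ens$theta), as.data.frame(ens$tau),
                log_post = ens$log_post)
  utils::write.csv(samp, file.path(outdir, "posterior_samples.csv"),
                   row.names = FALSE)
  out <- c(ts$global,
           list(No_harmonic = ts$horizons$N0[["harmonic"]],
                No_arithmetic = ts$horizons$N0[["arithmetic"]],
                No_median = ts$horizons$N0[["median"]],
                No_mode = ts$horizons$N0[["mode"]],
                No_q025 = ts$horizons$N0[["q025"]],
                No_q975 = ts$horizons$N0[["q975"]],
                acceptance = ens$acceptance,
                tmrca_peaks_generations = I(td$peaks)))
  write_stage_json(out, outdir, "nehistory", cfg)
  stage_log(outdir, "nehistory", cfg,
            list(acceptance = round(ens$acceptance, 3)))
  list(ensemble = ens, trajectory = ts, tmrca = td, summary = out)
}

stage_report <- function(cfg, outdir) {
  stages <- c("diversity", "differentiation", "bottleneck", "nehistory")
  paths <- file.path(outdir, paste0(stages, ".json"))
  missing <- stages[!file.exists(paths)]
  if (length(missing))
    stop("missing upstream artifact(s); run stage(s): ",
         paste(missing, collapse = ", "))
  report <- stats::setNames(lapply(paths, jsonlite::read_json), stages)
  write_stage_json(report, outdir, "report", cfg)
  stage_log(outdir, "report", cfg)
  report
}
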