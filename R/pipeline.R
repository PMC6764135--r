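#' Run configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' the simulation settings, QC thresholds, blending weight, REML settings
#' and allocation settings, each defaulting to the values of the reference
#' analysis (call rate 0.98, MAF 0.05, HWE alpha 0.05, blend weight 0.95,
#' 120 preselected boars, 600 matings, 15 sows per boar).
#'
#' @param sim a [sim_config()] (or a list of arguments for one).
#' @param qc list: `callrate_min`, `maf_min`, `hwe_alpha`,
#'   `conflict_rate_max`.
#' @param blend_weight weight for [blend()] applied to G and D before REML.
#' @param model list: `fixed`, `covariates`, `use_pe`, `direction`.
#' @param reml list: `tol`, `max_iter`, `method`.
#' @param allocation list: `n_matings`, `boar_capacity`, `n_boars_keep`,
#'   `preselect` ("gebv" or "random").
#' @param seed master seed (overrides `sim$seed` when given).
#' @param out_dir optional directory where stage artifacts are persisted.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), qc = list(), blend_weight = 0.95,
                       model = list(), reml = list(), allocation = list(),
                       seed = NULL, out_dir = NULL) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(
    sim = sim,
    qc = utils::modifyList(list(callrate_min = 0.98, maf_min = 0.05,
                                hwe_alpha = 0.05, conflict_rate_max = 0.02), qc),
    blend_weight = blend_weight,
    model = utils::modifyList(list(fixed = "batch", covariates = character(),
                                   use_pe = sim$repeated_records,
                                   direction = "lower_better"), model),
    reml = utils::modifyList(list(tol = 1e-6, max_iter = 2000, method = "ai"),
                             reml),
    allocation = utils::modifyList(list(n_matings = 600, boar_capacity = 15,
                                        n_boars_keep = 120,
                                        preselect = "gebv"), allocation),
    seed = sim$seed, out_dir = out_dir
  )
  stopifnot(cfg$blend_weight > 0, cfg$blend_weight <= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()] (top-level keys
#' `sim`, `qc`, `blend_weight`, `model`, `reml`, `allocation`, `seed`,
#' `out_dir`).
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw),
                                    names(formals(run_config)))])
}

#' Run the end-to-end mate-allocation pipeline
#'
#' Sequences all stages on a simulated population: genotype/phenotype
#' simulation, quality control, relationship matrices and genomic
#' inbreeding, REML under models A, G and GD, AIC comparison, marker
#' effects from the GD fit, GEBV-based boar preselection, the full mating
#' grid, and mate allocation optimised on expected breeding value (u) and
#' on expected total genetic value (g), with expected gains for both plans.
#'
#' @param config a [run_config()]
#' @param models which variance-component models to fit.
#' @param verbose print stage progress.
#' @return a `run_report` list: `qc_report`, `fits`, `aic_table`,
#'   `inbreeding` (mean/SD of f, `b_hat` per unit f and per 10% f),
#'   `marker_effects`, `gains` (both plans x both gain measures),
#'   `plans`, `grid`, `config`.
#' @export
run_pipeline <- function(config = run_config(),
                         models = c("A", "G", "GD"), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("simulate: %d boars x %d sows, %d SNPs",
      config$sim$n_boars, config$sim$n_sows, config$sim$m_snps)
  pop <- stage("simulate", simulate_population(config$sim))

  say("qc")
  qcres <- stage("qc", {
    g <- subset_geno(pop$geno, animals = pop$offspring_ids)
    fa <- filter_animals(g, config$qc$callrate_min)
    fs <- filter_snps(fa$geno, config$qc$callrate_min, config$qc$maf_min,
                      config$qc$hwe_alpha)
    mend <- mendelian_check(
      subset_geno(pop$geno, snps = snp_ids(fs$geno)), pop$ped,
      config$qc$conflict_rate_max)
    keep <- setdiff(animal_ids(fs$geno), mend$flagged)
    geno <- freeze_freq(subset_geno(fs$geno, animals = keep))
    report <- dplyr::mutate(fs$report,
                            n_animals_removed = length(fa$removed),
                            n_mendelian_removed = length(intersect(
                              mend$flagged, animal_ids(fs$geno))))
    list(geno = geno, report = report)
  })
  geno <- qcres$geno

  say("relationship matrices (blend weight %.2f)", config$blend_weight)
  mats <- stage("relmat", {
    list(G = blend(build_G(geno), config$blend_weight),
         D = blend(build_D(geno), config$blend_weight),
         A = build_A(pop$ped[, c("animal", "sire", "dam")]),
         f = genomic_inbreeding(geno))
  })

  pheno <- dplyr::filter(pop$pheno, animal %in% animal_ids(geno))
  mspec <- config$model
  fits <- list()
  for (mod in models) {
    say("reml model %s", mod)
    fits[[mod]] <- stage(paste0("reml_", mod), {
      random <- switch(mod,
        A = list(additive = mats$A),
        G = list(additive = mats$G),
        GD = list(additive = mats$G, dominance = mats$D))
      if (isTRUE(mspec$use_pe)) random$pe <- "identity"
      em_reml(pheno, random,
              fixed = mspec$fixed, covariates = mspec$covariates,
              f = if (mod == "A") NULL else mats$f,
              tol = config$reml$tol, max_iter = config$reml$max_iter,
              method = config$reml$method)
    })
  }
  aic_table <- compare_models(fits)

  ref_fit <- fits[[if ("GD" %in% names(fits)) "GD" else names(fits)[length(fits)]]]
  say("marker effects")
  fx <- stage("markerfx", {
    th <- ref_fit$theta
    getc <- function(nm) if (nm %in% names(th)) th[[nm]] else 0
    mv <- genetic_to_marker_variance(th[["additive"]], getc("dominance"),
                                     geno_freq(geno))
    solve_snp_blup(pheno, geno,
                   sigma2_a = mv$sigma2_a, sigma2_d = mv$sigma2_d,
                   sigma2_pe = getc("pe"),
                   sigma2_e = th[["residual"]],
                   fixed = mspec$fixed, covariates = mspec$covariates,
                   include_f = TRUE)
  })

  say("mating grid and allocation")
  sexes <- pop$ped$sex[match(animal_ids(geno), pop$ped$animal)]
  boars_all <- animal_ids(geno)[sexes == "male"]
  sows <- animal_ids(geno)[sexes == "female"]
  gtab <- gebv(geno, fx)
  boars <- preselect_boars(dplyr::filter(gtab, animal %in% boars_all),
                           n_keep = config$allocation$n_boars_keep,
                           direction = mspec$direction,
                           method = config$allocation$preselect,
                           seed = config$seed)
  grid <- stage("grid", build_mating_grid(geno, fx, boars, sows))

  alloc <- config$allocation
  n_mat <- min(alloc$n_matings,
               length(sows), length(boars) * alloc$boar_capacity)
  plans <- list(
    u = stage("allocate_u", allocate_matings(grid, "u", n_mat,
                                             alloc$boar_capacity,
                                             mspec$direction)),
    g = stage("allocate_g", allocate_matings(grid, "g", n_mat,
                                             alloc$boar_capacity,
                                             mspec$direction))
  )
  sigma2_A <- ref_fit$theta[["additive"]]
  gains <- dplyr::bind_rows(
    dplyr::mutate(mating_gains(plans$u, grid, sigma2_A), plan = "on_u"),
    dplyr::mutate(mating_gains(plans$g, grid, sigma2_A), plan = "on_g")
  )
  gains <- dplyr::relocate(gains, plan)

  inb <- list(mean_f = mean(mats$f$f), sd_f = stats::sd(mats$f$f),
              b_per_unit_f = ref_fit$b_hat,
              b_per_10pct_f = ref_fit$b_hat * 0.1,
              b_se_per_10pct_f = ref_fit$b_se * 0.1)

  report <- structure(list(
    qc_report = qcres$report, fits = fits, aic_table = aic_table,
    inbreeding = inb, marker_effects = fx, gains = gains,
    plans = plans, grid = grid, geno = geno, pheno = pheno,
    truth = pop$truth, config = config, seed = config$seed
  ), class = "run_report")
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

#' Compare fitted models by AIC
#'
#' @param fits named list of `reml_fit` objects (e.g. models A, G, GD).
#' @return tibble `model`, `logL`, `n_var_params`, `aic`, `delta_aic`,
#'   sorted best (minimum AIC) first; ties keep the input order.
#' @export
compare_models <- function(fits) {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  tab <- tibble::tibble(
    model = names(fits),
    logL = unname(vapply(fits, function(f) f$logL, numeric(1))),
    n_var_params = unname(vapply(fits, function(f) f$n_var_params, numeric(1))),
    aic = unname(vapply(fits, function(f) f$aic, numeric(1)))
  )
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab
}

persist_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$qc_report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  vc <- dplyr::bind_rows(lapply(names(report$fits), function(mod) {
    dplyr::mutate(tidy(report$fits[[mod]]), model = mod)
  }))
  utils::write.csv(vc, file.path(out_dir, "variance_components.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aic_table, file.path(out_dir, "aic_table.csv"),
                   row.names = FALSE)
  write_marker_effects(report$marker_effects,
                       file.path(out_dir, "marker_effects.csv"))
  utils::write.csv(as_tibble(report$grid), file.path(out_dir, "mating_grid.csv"),
                   row.names = FALSE)
  for (nm in names(report$plans)) {
    utils::write.csv(as.data.frame(report$plans[[nm]]),
                     file.path(out_dir, paste0("plan_on_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$gains, file.path(out_dir, "gains.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$inbreeding, file.path(out_dir, "inbreeding.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Genomic mate-allocation run ==\n")
  cat(sprintf("QC: %d -> %d SNPs\n", x$qc_report$n_snps_in,
              x$qc_report$n_snps_out))
  cat("\nAIC comparison:\n"); print(x$aic_table)
  cat(sprintf("\nGenomic inbreeding: mean f = %.3f (SD %.4f); b = %.3f per 10%% f\n",
              x$inbreeding$mean_f, x$inbreeding$sd_f,
              x$inbreeding$b_per_10pct_f))
  cat("\nExpected gains (trait units and genetic-SD units):\n")
  print(x$gains)
  invisible(x)
}
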