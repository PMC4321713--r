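# Orchestration across the five analysis stages. A config is a plain R
# list (or YAML file); each stage runs on synthetic data generated under
# the global seed unless the config points at input files, and the
# aggregated report is written as JSON with provenance (config hash,
# package version, seed).

.pipeline_stages <- c("seq", "afm", "pmf", "collapse", "ftir")
.pipeline_keys <- c("stages", "seed", "out_dir", "log_level",
                    .pipeline_stages)

#' Validate a pipeline configuration
#'
#' @param config A named list, or path to a YAML file holding one.
#'   Recognised top-level keys: `stages` (subset of `"seq"`, `"afm"`,
#'   `"pmf"`, `"collapse"`, `"ftir"`), `seed`, `out_dir`, `log_level`,
#'   plus one optional parameter table per stage. Unknown keys are
#'   rejected; referenced input paths must exist.
#' @return The validated config (invisibly usable by [run_pipeline()]).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stages <- config$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  for (st in stages) {
    paths <- config[[st]]
    for (key in grep("(_path|_dir|_file)$", names(paths), value = TRUE))
      if (!file.exists(paths[[key]]))
        stop(sprintf("stage '%s': path '%s' does not exist", st,
                     paths[[key]]), call. = FALSE)
  }
  config
}

.log_stage <- function(stage, msg)
  message(sprintf("[nanospring:%s] %s", stage, msg))

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`seq`, `afm`, `pmf`,
#' `collapse`, `ftir`), each over synthetic data generated from the
#' study's conditions (or over input files named in the config), and
#' aggregates per-stage summaries into one JSON report with provenance.
#' A failing stage is recorded in the report and does not stop
#' subsequent stages. Identical config and seed give identical reports
#' apart from the timestamp.
#'
#' @param config See [pipeline_config()].
#' @return The report list (invisibly written to
#'   `out_dir/report.json` when `out_dir` is set). `$ok` is `FALSE` when
#'   any stage failed.
#' @export
run_pipeline <- function(config = list()) {
  config <- pipeline_config(config)
  seed <- config$seed
  report <- list(schema = "nanospring-report/1",
                 package_version = as.character(utils::packageVersion("nanospring")),
                 seed = seed,
                 config_hash = .config_hash(config),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 stages = list())
  ok <- TRUE
  for (st in config$stages) {
    .log_stage(st, "running")
    res <- tryCatch(.run_stage(st, config[[st]] %||% list(), seed),
                    error = function(e) {
                      .log_stage(st, paste("FAILED:", conditionMessage(e)))
                      list(error = conditionMessage(e))
                    })
    if (!is.null(res$error)) ok <- FALSE
    report$stages[[st]] <- res
  }
  report$ok <- ok
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.run_stage <- function(stage, p, seed) {
  switch(stage,
    seq = {
      recs <- if (!is.null(p$fasta_path)) read_fasta_records(p$fasta_path)
              else read_fasta_records(system.file("extdata",
                                                  "cnidoin_peptides.fasta",
                                                  package = "nanospring"))
      motif <- p$motif %||% "GXGQQ"
      per <- lapply(recs, function(r) {
        m <- uversky_metrics(r)
        list(id = r$id, mean_hydropathy = m$mean_hydropathy,
             mean_net_charge = m$mean_net_charge,
             classification = m$classification,
             motif_positions = scan_motif(r, motif))
      })
      list(n_records = length(recs), motif = motif, records = per)
    },
    afm = {
      n <- p$n_traces %||% 100L
      sim <- gen_fd_traces(n_traces = n,
                           lc_mean_nm = p$lc_mean_nm %||% 94,
                           lc_sd_nm = p$lc_sd_nm %||% 43,
                           lp_nm = p$lp_nm %||% 0.37,
                           noise_sd_pN = p$noise_sd_pN %||% 5,
                           specific_fraction = p$specific_fraction %||% 0.8,
                           seed = seed)
      res <- analyze_afm_cohort(sim$traces,
                                persistence_length_nm = p$lp_transform %||% 0.4)
      s <- res$summary
      list(n_traces = n, n_accepted = s$n_accepted,
           contour_mean_nm = s$contour_mean_nm,
           contour_sd_nm = s$contour_sd_nm,
           persistence_mean_nm = s$persistence_mean_nm,
           persistence_sd_nm = s$persistence_sd_nm)
    },
    pmf = {
      lp <- p$lp_nm %||% 0.89
      lc <- p$lc_nm %||% 7.5
      wp <- wlc_params(lp, lc)
      U <- function(z) .wlc_pmf_kJ_mol(wp, z)
      sim <- gen_umbrella_samples(U,
                                  window_centers_nm = p$window_centers_nm %||%
                                    seq(0.4, 7, by = 0.4),
                                  spring_kJ_mol_nm2 = p$spring_kJ_mol_nm2 %||% 500,
                                  n_samples_per_window = p$n_samples_per_window %||% 2000,
                                  seed = seed)
      pmf <- wham(sim$windows, max_iter = p$max_iter %||% 500000L)
      mf <- mean_force_profile(pmf)
      rng <- pmf_supported_range(pmf)
      sel <- mf$z_nm >= rng[1] & mf$z_nm <= rng[2]
      fit <- fit_wlc(data.frame(extension_nm = mf$z_nm[sel],
                                force_pN = mf$force_pN[sel]),
                     fixed = list(contour_length_nm = lc))
      plateau <- mf$z_nm >= 1 & mf$z_nm <= 3.5
      list(converged = pmf$converged, n_iterations = pmf$n_iterations,
           fitted_lp_nm = fit$params$persistence_length_nm,
           true_lp_nm = lp,
           mean_force_low_ext_pN = mean(mf$force_pN[plateau]))
    },
    collapse = {
      sim <- gen_collapse_trajectories(
        n_traj = p$n_traj %||% 20L,
        target_tau_ns = p$target_tau_ns %||% 5.7,
        seed = seed)
      fpt <- first_passage_times(sim$trajectories,
                                 threshold_nm = p$threshold_nm %||% 1.5)
      fit <- fit_lifetime(fpt, boot_seed = seed)
      list(tau_ns = fit$tau_ns, tau_ci_ns = fit$tau_ci_ns,
           n_events = fit$n_events, n_censored = fit$n_censored)
    },
    ftir = {
      sim <- gen_amide1_spectra(n_carriers = p$n_carriers %||% 2L,
                                seed = seed)
      carriers <- split(sim$spectra,
                        vapply(sim$spectra, `[[`, character(1), "carrier_id"))
      res <- lapply(seq_along(carriers), function(i)
        analyze_amide1_carrier(carriers[[i]],
                               k_max = p$k_max %||% 6L,
                               n_starts = p$n_starts %||% 10L,
                               seed = seed + i))
      width <- peak_width_analysis(lapply(res, `[[`, "best_fit"))
      list(n_carriers = length(carriers),
           weighted_mean_k = mean(vapply(res, function(r)
             r$selection$weighted_mean_k, numeric(1))),
           peak_width_cm1 = width$mean_fwhm_cm1,
           width_p_value = width$p_value)
    },
    stop("unknown stage: ", stage, call. = FALSE))
}

# free-energy profile of a WLC: the integral of its force-extension curve
# converted to kJ/mol (used to build mean-force-shaped synthetic PMFs)
.wlc_pmf_kJ_mol <- function(params, z) {
  kBT <- .kB_pN_nm * params$temperature_K
  Lc <- params$contour_length_nm
  Lp <- params$persistence_length_nm
  u <- pmin(pmax(z, 0) / Lc, 1 - 1e-9)
  # closed-form integral of the Marko-Siggia factor, in pN nm, then
  # converted to kJ/mol (1 pN nm = kB[kJ/mol] / kB[pN nm] kJ/mol)
  (kBT / Lp) * Lc * (0.25 / (1 - u) - u / 4 + u^2 / 2 - 0.25) *
    .kB_kJ_mol / .kB_pN_nm
}
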