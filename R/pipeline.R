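# End-to-end orchestration: simulate -> perfusion-fit -> pk -> biodist ->
# dosimetry, one JSON report per stage plus a combined summary. The run is
# a pure function of the configuration (seed included), so a repeated run
# writes byte-identical numeric payloads.

#' Pipeline configuration
#'
#' Collects everything \code{\link{run_pipeline}} needs: the simulation
#' config (or paths to measured input tables), phantom mass tables, the
#' S-value matrix, fit and dosimetry options, the seed and the output
#' directory.
#'
#' @param seed Integer seed; recorded in every output.
#' @param outdir Output directory (created if absent).
#' @param sim A \code{\link{sim_config}}; default built from \code{seed}.
#' @param masses_rabbit,masses_human \code{\link{phantom_masses}};
#'   defaults read from the packaged synthetic tables.
#' @param smatrix An \code{\link{s_matrix}}; default the packaged
#'   synthetic 70-kg table.
#' @param fit_frame_value Frame representation used when fitting
#'   (\code{"midpoint"} matches the generator's sampling).
#' @param noisy_tacs Simulate measurement noise on tissue TACs?
#' @param planned_activity_MBq Administration for the projected human
#'   effective dose (default 37 MBq).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("petdosim-run-"),
                            sim = sim_config(seed = seed),
                            masses_rabbit = read_masses_yaml(
                              system.file("extdata", "masses_rabbit_synthetic.yaml",
                                          package = "petdosim")),
                            masses_human = read_masses_yaml(
                              system.file("extdata", "masses_human_synthetic.yaml",
                                          package = "petdosim")),
                            smatrix = read_smatrix_csv(
                              system.file("extdata", "s_values_human_synthetic.csv",
                                          package = "petdosim"),
                              phantom = "synthetic-adult-70kg"),
                            fit_frame_value = "midpoint",
                            noisy_tacs = TRUE,
                            planned_activity_MBq = 37) {
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 masses_rabbit = masses_rabbit, masses_human = masses_human,
                 smatrix = smatrix, fit_frame_value = fit_frame_value,
                 noisy_tacs = noisy_tacs,
                 planned_activity_MBq = planned_activity_MBq),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the five stages in study order: synthetic-data generation,
#' one-tissue-compartment perfusion fitting of every configured region,
#' plasma noncompartmental pharmacokinetics, ex vivo biodistribution
#' quantification, and residence-time/dose estimation scaled to a human
#' phantom. Each stage writes a JSON report into \code{config$outdir};
#' a stage failure aborts with the stage name while earlier outputs are
#' retained. Deterministic for a fixed seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  paths <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("stage %-13s done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  # -- simulate ------------------------------------------------------------
  simres <- stage("simulate", {
    input <- sim_input_function(cfg)
    tacs <- lapply(names(cfg$tissue_params), function(r)
      sim_tissue_tac(cfg, r, input, noisy = config$noisy_tacs))
    names(tacs) <- names(cfg$tissue_params)
    plasma <- sim_plasma_series(cfg)
    bio <- sim_organ_biokinetics(cfg)
    paths$input_tac <- write_tac_csv(input, file.path(config$outdir, "input_tac.csv"))
    paths$tissue_tacs <- write_tac_csv(tacs, file.path(config$outdir, "tissue_tacs.csv"))
    paths$plasma <- file.path(config$outdir, "plasma.csv")
    utils::write.csv(plasma, paths$plasma, row.names = FALSE)
    paths$biokinetics <- write_biokinetics_csv(bio, file.path(config$outdir, "organ_biokinetics.csv"))
    truth <- list(seed = cfg$seed,
                  tissue_params = cfg$tissue_params,
                  plasma_analytic = sim_plasma_analytic(cfg),
                  organ_uptake_fractions = as.list(
                    cfg$organ_biokinetics_params$uptake_fractions))
    paths$truth <- write_report_json(truth,
      file.path(config$outdir, "ground_truth.json"), seed = cfg$seed,
      config = cfg)
    list(input = input, tacs = tacs, plasma = plasma, bio = bio)
  })

  # -- perfusion fit -------------------------------------------------------
  perf <- stage("perfusion-fit", {
    fits <- lapply(simres$tacs, function(tc)
      fit_1tcm(tc, simres$input, frame_value = config$fit_frame_value))
    report <- lapply(fits, unclass)
    paths$perfusion <- write_report_json(report,
      file.path(config$outdir, "perfusion_fits.json"), seed = cfg$seed,
      config = cfg, nuclide = o15())
    fits
  })

  # -- plasma pk -----------------------------------------------------------
  pk <- stage("pk", {
    p <- simres$plasma
    res <- auc_and_clearance(p$time_h, p$plasma_kBq_per_mL, cfg$subject,
                             blood_kBq_per_mL = p$blood_kBq_per_mL,
                             intact_pct = p$intact_pct)
    paths$pk <- write_report_json(unclass(res),
      file.path(config$outdir, "plasma_pk.json"), seed = cfg$seed, config = cfg)
    res
  })

  # -- biodistribution -----------------------------------------------------
  biodist <- stage("biodist", {
    bio <- simres$bio
    t_meas <- 24
    organs <- unique(bio$organ)
    a0_kBq <- cfg$subject$injected_activity_MBq * 1000
    rows <- do.call(rbind, lapply(organs, function(o) {
      d <- bio[bio$organ == o, ]
      f24 <- stats::approx(d$time_h, d$fraction_of_injected, xout = t_meas)$y
      m_g <- config$masses_rabbit$organ_masses_kg[[o]] * 1000
      data.frame(tissue = o, wet_weight_g = m_g,
                 activity_kBq = f24 * a0_kBq, time_h = t_meas)
    }))
    rows$SUV <- exvivo_suv(rows$activity_kBq, rows$wet_weight_g, rows$time_h,
                           cfg$subject)
    rows$pid_per_g <- exvivo_pid_per_g(rows$activity_kBq, rows$wet_weight_g,
                                       rows$time_h, cfg$subject)
    paths$biodist <- write_report_json(rows,
      file.path(config$outdir, "biodistribution.json"), seed = cfg$seed,
      config = cfg)
    rows
  })

  # -- dosimetry -----------------------------------------------------------
  dose <- stage("dosimetry", {
    human_bio <- scale_rabbit_to_human(simres$bio, config$masses_rabbit,
                                       config$masses_human)
    taus <- residence_times(human_bio)
    rt <- remainder_and_total(taus)
    od <- organ_doses(rt, config$smatrix)
    ed <- effective_dose(od)
    proj <- administered_dose(ed, config$planned_activity_MBq)
    rep <- list(residence_times_h = as.list(c(rt$organ_tau_h,
                                              remainder = rt$remainder_h,
                                              total = rt$total_h)),
                organ_doses_mGy_per_MBq = as.list(od),
                effective_dose_mSv_per_MBq = ed,
                planned_activity_MBq = config$planned_activity_MBq,
                projected_effective_dose_mSv = proj,
                phantom = config$smatrix$phantom)
    paths$dosimetry <- write_report_json(rep,
      file.path(config$outdir, "dosimetry.json"), seed = cfg$seed, config = cfg)
    rep
  })

  summary <- list(
    seed = cfg$seed,
    perfusion_K1 = lapply(perf, function(f) f$K1),
    CL_total_mL_per_h = pk$CL_total_mL_per_h,
    blood_to_plasma_ratio = pk$blood_to_plasma_ratio,
    effective_dose_mSv_per_MBq = dose$effective_dose_mSv_per_MBq,
    projected_effective_dose_mSv = dose$projected_effective_dose_mSv)
  paths$summary <- write_report_json(summary,
    file.path(config$outdir, "summary.json"), seed = cfg$seed, config = cfg)

  invisible(list(simulate = simres, perfusion = perf, pk = pk,
                 biodist = biodist, dosimetry = dose, summary = summary,
                 paths = paths))
}
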