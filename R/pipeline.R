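## Study orchestration: simulate -> extract -> calibrate -> estimate ->
## filter -> agreement, as a pure function of a serializable configuration.

#' Study configuration
#'
#' A run of the pipeline is a pure function of this object: the same
#' configuration (including `master_seed`) reproduces the report exactly.
#'
#' @param n_subjects number of simulated subjects.
#' @param master_seed integer seed controlling every random draw.
#' @param priors parameter priors, see [default_priors()].
#' @param noise_free disable cardiac oscillation and measurement noise.
#' @param n_breaths ordinary breaths per condition record.
#' @param validity_band occlusion-test transmission-ratio validity band.
#' @param eps_cvp minimum usable occlusion-test CVP swing (cmH2O).
#' @param avg_frac plateau averaging fraction.
#' @param restrict_volume,restrict_ccw optionally restrict the analysis to
#'   one volume-status or chest-wall level (the full study is still
#'   simulated, so restricted runs are consistent subsets of full runs).
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_subjects = 10, master_seed = 1,
                         priors = default_priors(), noise_free = FALSE,
                         n_breaths = 5, validity_band = c(0.8, 1.2),
                         eps_cvp = 0.5, avg_frac = 0.5,
                         restrict_volume = NULL, restrict_ccw = NULL) {
  structure(
    list(n_subjects = n_subjects, master_seed = master_seed,
         priors = priors, noise_free = noise_free, n_breaths = n_breaths,
         validity_band = validity_band, eps_cvp = eps_cvp,
         avg_frac = avg_frac, restrict_volume = restrict_volume,
         restrict_ccw = restrict_ccw),
    class = "study_config"
  )
}

COMPARISONS <- list(
  cdcvp_vs_dppl = list(est = "est_dppl", ref = "d_dppl",
                       set = "cdcvp_vs_dppl",
                       label = "corrected dCVP-derived dPpl vs direct dPpl"),
  pes_vs_dppl = list(est = "d_pes", ref = "d_dppl", set = "pes_vs_dppl",
                     label = "dPes vs direct dPpl"),
  pes_vs_cdcvp = list(est = "d_pes", ref = "est_dppl", set = "pes_vs_cdcvp",
                      label = "dPes vs corrected dCVP-derived dPpl")
)

#' Run a full simulated study
#'
#' Simulates the cohort, processes every condition record, applies the
#' exclusion cascade, and computes the agreement statistics: Bland-Altman
#' overall and stratified by volume status and chest-wall level for the two
#' comparisons against the directly measured swing, and repeated-measures
#' correlations for all three pairings.
#'
#' @param config a [study_config()].
#' @return an object of class `study_report`: `conditions` (one row per
#'   condition), `exclusions`, `agreement` (tibble over comparisons and
#'   strata), `rmcorr` (named list), `summary` (condition-level summary
#'   table), `config` and `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  records <- draw_study(
    n_subjects = config$n_subjects, priors = config$priors,
    master_seed = config$master_seed, noise_free = config$noise_free,
    n_breaths = config$n_breaths
  )
  conditions <- dplyr::bind_rows(lapply(records, function(r) {
    tryCatch(
      process_record(r, band = config$validity_band,
                     eps_cvp = config$eps_cvp, avg_frac = config$avg_frac),
      error = function(e) {
        stop("stage `process_record` failed for subject ",
             r$truth$subject_id, " (", r$truth$condition$volume_status, "/",
             r$truth$condition$ccw_level, "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }))
  if (!is.null(config$restrict_volume)) {
    conditions <- conditions[conditions$volume_status %in%
                               config$restrict_volume, , drop = FALSE]
  }
  if (!is.null(config$restrict_ccw)) {
    conditions <- conditions[conditions$ccw_level %in% config$restrict_ccw,
                             , drop = FALSE]
  }
  exclusions <- apply_exclusions(conditions)

  agreement <- list()
  rm_res <- list()
  for (cmp in names(COMPARISONS)) {
    spec <- COMPARISONS[[cmp]]
    dat <- exclusions$sets[[spec$set]]
    if (nrow(dat) >= 2) {
      ba <- dplyr::bind_rows(
        bland_altman(dat[[spec$est]], dat[[spec$ref]]),
        if (length(unique(dat$volume_status)) > 1) {
          dplyr::filter(
            bland_altman(dat[[spec$est]], dat[[spec$ref]],
                         strata = dat$volume_status),
            .data$stratum != "overall")
        },
        if (length(unique(dat$ccw_level)) > 1) {
          dplyr::filter(
            bland_altman(dat[[spec$est]], dat[[spec$ref]],
                         strata = dat$ccw_level),
            .data$stratum != "overall")
        }
      )
      ba$comparison <- cmp
      agreement[[cmp]] <- ba
      rm_res[[cmp]] <- tryCatch(
        rmcorr(dat$subject, dat[[spec$ref]], dat[[spec$est]]),
        error = function(e) NULL
      )
    }
  }
  agreement <- dplyr::bind_rows(agreement)

  structure(
    list(
      conditions = conditions, exclusions = exclusions,
      agreement = agreement, rmcorr = rm_res,
      summary = summarize_study(conditions),
      config = config,
      provenance = list(
        master_seed = config$master_seed,
        n_records = length(records),
        package_version = as.character(utils::packageVersion("pplcvp")),
        config_hash = rlang::hash(config)
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d conditions from %d subjects (seed %d)\n",
              nrow(x$conditions), x$config$n_subjects,
              x$config$master_seed))
  acc <- x$exclusions$accounting
  cat(sprintf("  excluded: %s\n",
              paste(sprintf("%d %s", acc$n_excluded, acc$cause),
                    collapse = ", ")))
  for (cmp in names(x$rmcorr)) {
    ba <- x$agreement[x$agreement$comparison == cmp &
                        x$agreement$stratum == "overall", ]
    cat(sprintf(
      "  %s: n = %d, bias %.2f, precision %.2f cmH2O, rmcorr r = %.3f\n",
      cmp, ba$n, ba$bias, ba$precision, x$rmcorr[[cmp]]$r))
  }
  invisible(x)
}

#' Sweep one study axis
#'
#' Re-runs the study at each level of one axis and stacks the overall
#' agreement results, the pipeline's version of asking whether accuracy
#' depends on volume status, chest-wall compliance, measurement noise, or a
#' volume-dependent transmission (a deliberate model violation).
#'
#' @param config base [study_config()].
#' @param axis one of `"volume"`, `"ccw"`, `"noise"`, `"T"`.
#' @param levels levels to sweep. Defaults: the three volume states, the
#'   two chest-wall states, noise SDs `c(0, 0.3, 0.6)`, transmission
#'   volume-gradients `c(0, 0.25)`.
#' @return list with `reports` (one [run_study()] report per level) and
#'   `comparison` (tibble of overall bias/precision per level and
#'   comparison).
#' @export
scenario_sweep <- function(config = study_config(),
                           axis = c("volume", "ccw", "noise", "T"),
                           levels = NULL) {
  axis <- match.arg(axis)
  if (is.null(levels)) {
    levels <- switch(axis,
      volume = c("low", "normal", "high"),
      ccw = c("N", "L"),
      noise = c(0, 0.3, 0.6),
      T = c(0, 0.25)
    )
  }
  reports <- lapply(levels, function(lv) {
    cfg <- config
    if (axis == "volume") cfg$restrict_volume <- lv
    if (axis == "ccw") cfg$restrict_ccw <- lv
    if (axis == "noise") {
      cfg$priors$noise_sd[] <- as.numeric(lv)
      if (as.numeric(lv) == 0) cfg$noise_free <- TRUE
    }
    if (axis == "T") {
      cfg$priors$transmission_drift_gradient <- as.numeric(lv)
    }
    run_study(cfg)
  })
  names(reports) <- as.character(levels)
  comparison <- dplyr::bind_rows(lapply(names(reports), function(lv) {
    ov <- reports[[lv]]$agreement
    ov <- ov[ov$stratum == "overall", , drop = FALSE]
    ov$axis <- axis
    ov$level <- lv
    ov
  }))
  list(axis = axis, reports = reports, comparison = comparison)
}

#' Write a study report to disk
#'
#' Emits `report.json` (agreement, correlations, exclusion accounting,
#' provenance), plus TSV tables for the per-condition results, the summary
#' table and the agreement results.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rm_tbl <- dplyr::bind_rows(lapply(names(report$rmcorr), function(cmp) {
    res <- report$rmcorr[[cmp]]
    tibble::tibble(comparison = cmp, r = res$r, df = res$df, p = res$p,
                   n = res$n, n_subjects = res$n_subjects)
  }))
  jsonlite::write_json(
    list(agreement = report$agreement, rmcorr = rm_tbl,
         exclusions = report$exclusions$accounting,
         n_total = report$exclusions$n_total,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  readr::write_tsv(report$conditions, file.path(dir, "conditions.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$agreement, file.path(dir, "agreement.tsv"),
                   progress = FALSE)
  if (nrow(rm_tbl)) {
    readr::write_tsv(rm_tbl, file.path(dir, "rmcorr.tsv"), progress = FALSE)
  }
  invisible(dir)
}
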