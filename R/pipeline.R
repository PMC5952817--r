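#' Quantify perfusion for a long-format curve table
#'
#' Runs the full segment-level quantification for every patient and phase
#' in a curve table: baseline correction, dual-bolus reference AIF from
#' the pre-bolus, arrival-delay estimation, Fermi-constrained
#' deconvolution, and flow evaluation.
#'
#' @param curve_table Long-format table with columns `patient_id`,
#'   `region` (`AIF_pre`, `AIF_main`, or segment labels), `phase`,
#'   `t_seconds`, `signal`.
#' @param taud `"auto"` to estimate the delay per segment via
#'   [estimate_delay()], or a fixed value in seconds.
#' @param dose_ratio Main/pre-bolus dose ratio (default 10).
#' @param n_baseline_frames Leading pre-contrast frames for baseline
#'   correction.
#' @param aif_denoise How to denoise the measured pre-bolus before
#'   scaling it to the reference: `"gamma_variate"` (default; causal
#'   parametric bolus fit, see [fit_gamma_variate()], falling back to
#'   Savitzky-Golay when the fit is rejected), `"savgol"`
#'   ([smooth_curve()]), or `"none"`.
#' @return A `data.frame` with one row per (patient, segment, phase):
#'   `patient_id`, `region`, `phase`, `taud`, `mbf`, `rss`, `converged`.
#' @export
quantify_perfusion <- function(curve_table, taud = "auto", dose_ratio = 10,
                               n_baseline_frames = 5L,
                               aif_denoise = c("gamma_variate", "savgol",
                                               "none")) {
  aif_denoise <- match.arg(aif_denoise)
  curves <- curves_from_table(curve_table)
  meta <- do.call(rbind, lapply(curves, function(cv)
    data.frame(region = cv$region, phase = cv$phase, stringsAsFactors = FALSE)))
  meta$patient_id <- sub("^([^.]+)\\..*$", "\\1",
                         names(curves))
  out <- list()
  for (pid in unique(meta$patient_id)) {
    for (ph in unique(meta$phase[meta$patient_id == pid])) {
      sel <- meta$patient_id == pid & meta$phase == ph
      these <- curves[sel]
      regs <- meta$region[sel]
      pre <- these[[which(regs == "AIF_pre")[1]]]
      if (is.null(pre)) stop("no AIF_pre curve for patient ", pid)
      pre <- baseline_correct(pre, n_baseline_frames)
      if (aif_denoise == "gamma_variate") {
        gv <- fit_gamma_variate(pre)
        pre <- if (gv$converged) gv$curve else smooth_curve(pre)
      } else if (aif_denoise == "savgol") {
        pre <- smooth_curve(pre)
      }
      aif <- build_reference_aif(pre, dose_ratio)
      seg_idx <- which(!(regs %in% c("AIF_pre", "AIF_main", "AIF_ref")))
      for (i in seg_idx) {
        tis <- baseline_correct(these[[i]], n_baseline_frames)
        fit <- if (identical(taud, "auto"))
          fit_fermi_auto_delay(aif, tis)
        else fit_fermi_deconvolution(aif, tis, as.numeric(taud))
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, region = regs[i], phase = ph,
          taud = fit$taud,
          mbf = myocardial_blood_flow(fit),
          rss = fit$rss, converged = isTRUE(fit$converged),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Join stress and rest flow estimates into an MPR table
#'
#' @param estimates Output of [quantify_perfusion()] containing both
#'   phases.
#' @return A `data.frame` with `patient_id`, `region`, `mbf_stress`,
#'   `mbf_rest`, `mpr` (`NA` where either phase is non-analyzable) and
#'   `analyzable`.
#' @export
mpr_table <- function(estimates) {
  st <- estimates[estimates$phase == "stress",
                  c("patient_id", "region", "mbf")]
  rs <- estimates[estimates$phase == "rest",
                  c("patient_id", "region", "mbf")]
  names(st)[3] <- "mbf_stress"
  names(rs)[3] <- "mbf_rest"
  m <- merge(st, rs, by = c("patient_id", "region"), all = TRUE)
  m$mpr <- mapply(myocardial_perfusion_reserve, m$mbf_stress, m$mbf_rest)
  m$analyzable <- !is.na(m$mpr)
  m
}

#' Assemble the covariate table for the risk models
#'
#' Renames cohort-table columns to the covariate names the model
#' specifications use and derives the dichotomized perfusion covariates.
#' Quantitative burden is dichotomized at >= 10% of myocardium; the
#' visual >= 2-of-16-segments rule is applied as burden fraction >= 2/16
#' when only the fraction is available (equal-mass approximation),
#' or from `n_visual_segments` when a burden table is supplied.
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param survival Optional adjudicated survival table
#'   ([adjudicate_cohort()]); defaults to the cohort's own
#'   `time_days`/`event`.
#' @param burden Optional per-patient burden table
#'   ([compute_cohort_burden()]) overriding the cohort's burden columns.
#' @return A `data.frame` with columns `patient_id`, `age`, `sex`, `lge`,
#'   `visual_burden`, `mpr_burden`, `visual_positive`, `mpr_positive`,
#'   `time_days`, `event`.
#' @export
assemble_risk_data <- function(cohort, survival = NULL, burden = NULL) {
  d <- data.frame(patient_id = cohort$patient_id,
                  age = cohort$age_years, sex = cohort$sex,
                  lge = cohort$lge,
                  visual_burden = cohort$visual_burden_fraction,
                  mpr_burden = cohort$mpr_burden_fraction,
                  stringsAsFactors = FALSE)
  if (!is.null(burden)) {
    i <- match(d$patient_id, burden$patient_id)
    d$visual_burden <- burden$visual_burden[i]
    d$mpr_burden <- burden$mpr_burden[i]
    d$visual_positive <- as.numeric(burden$visual_positive[i])
    d$mpr_positive <- as.numeric(burden$mpr_positive[i])
  } else {
    d$visual_positive <- as.numeric(d$visual_burden >= 2 / 16)
    d$mpr_positive <- as.numeric(d$mpr_burden >= 0.10)
  }
  if (is.null(survival)) {
    d$time_days <- cohort$time_days
    d$event <- cohort$event
  } else {
    i <- match(d$patient_id, survival$patient_id)
    d$time_days <- survival$time_days[i]
    d$event <- survival$event[i]
  }
  d
}
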