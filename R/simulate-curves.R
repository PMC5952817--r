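#' Acquisition specification for simulated perfusion series
#'
#' Describes the sampling grid, contrast doses and noise of a simulated
#' first-pass perfusion acquisition. The dual-bolus scheme uses a dilute
#' pre-bolus (default 0.0075 mmol/kg) to sample the arterial input
#' function in the linear signal range and a main bolus at ten times that
#' dose (0.075 mmol/kg) for the tissue passage.
#'
#' @param frame_interval Frame spacing in seconds (> 0).
#' @param n_frames Number of frames (>= 20).
#' @param noise_sd Additive Gaussian noise sd in signal units (>= 0).
#' @param prebolus_dose,main_dose Contrast doses in mmol/kg; their ratio
#'   must equal `dilution_factor`.
#' @param saturation_ceiling Signal ceiling of the saturating main-bolus
#'   AIF measurement, in signal units.
#' @param dilution_factor Required main/pre-bolus dose ratio (default 10).
#' @param signal_per_dose Linear gain from dose (mmol/kg) to peak AIF
#'   signal (signal units) before saturation.
#' @param onset Bolus arrival time in seconds.
#' @param alpha,beta Gamma-variate shape and time constants of the bolus.
#' @param rng_seed Integer seed used by the generators that consume the
#'   spec.
#'
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval = 1, n_frames = 60,
                             noise_sd = 0, prebolus_dose = 0.0075,
                             main_dose = 0.075, saturation_ceiling = 120,
                             dilution_factor = 10, signal_per_dose = 1000,
                             onset = 5, alpha = 3, beta = 2.5,
                             rng_seed = 1L) {
  if (frame_interval <= 0) stop("'frame_interval' must be > 0")
  if (n_frames < 20) stop("'n_frames' must be >= 20")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (prebolus_dose <= 0 || main_dose <= 0) stop("doses must be > 0")
  if (abs(main_dose / prebolus_dose - dilution_factor) > 1e-9)
    stop("main_dose / prebolus_dose must equal the dilution factor")
  if (saturation_ceiling <= 0) stop("'saturation_ceiling' must be > 0")
  structure(list(frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, prebolus_dose = prebolus_dose,
                 main_dose = main_dose, saturation_ceiling = saturation_ceiling,
                 dilution_factor = dilution_factor,
                 signal_per_dose = signal_per_dose, onset = onset,
                 alpha = alpha, beta = beta, rng_seed = as.integer(rng_seed)),
            class = "acquisition_spec")
}

spec_times <- function(spec) (seq_len(spec$n_frames) - 1) * spec$frame_interval

#' Tissue ground truth for the forward perfusion model
#'
#' Holds the true Fermi impulse-response parameters of a simulated
#' segment. The amplitude is derived from the target flow so that
#' `mbf = R / (exp(-tau0 * k) + 1)`, the evaluation convention of
#' [myocardial_blood_flow()], holds exactly.
#'
#' @param mbf True myocardial blood flow (relative units, > 0).
#' @param k Washout rate, 1/s.
#' @param tau0 Shoulder width, s.
#' @param taud Arrival delay, s.
#' @return An object of class `tissue_truth` holding `mbf`, `r`, `k`,
#'   `tau0`, `taud`.
#' @export
tissue_truth <- function(mbf, k = 0.2, tau0 = 3, taud = 0) {
  if (mbf <= 0) stop("'mbf' must be > 0")
  if (k <= 0 || tau0 < 0 || taud < 0) stop("invalid Fermi ground truth")
  structure(list(mbf = mbf, r = mbf * (exp(-tau0 * k) + 1),
                 k = k, tau0 = tau0, taud = taud),
            class = "tissue_truth")
}

#' Simulate an arterial input function
#'
#' Gamma-variate bolus model
#' `A (t - onset)^alpha exp(-(t - onset)/beta)` for `t > onset`, zero
#' before arrival, with amplitude proportional to dose: the peak signal is
#' `signal_per_dose * dose`. Noise is not added here; the study generator
#' adds measurement noise per curve.
#'
#' @param spec An [acquisition_spec()].
#' @param dose Contrast dose in mmol/kg (> 0).
#' @param onset Bolus arrival in seconds; defaults to `spec$onset`.
#' @return A [signal_curve()] with region `"AIF"`.
#' @export
generate_aif <- function(spec, dose, onset = spec$onset) {
  stopifnot(inherits(spec, "acquisition_spec"))
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("'dose' must be a positive scalar")
  t <- spec_times(spec)
  if (onset < 0 || onset > max(t)) stop("'onset' must lie in the sampled window")
  tau <- pmax(t - onset, 0)
  shape <- tau^spec$alpha * exp(-tau / spec$beta)
  peak_unit <- (spec$alpha * spec$beta)^spec$alpha * exp(-spec$alpha)
  signal <- spec$signal_per_dose * dose * shape / peak_unit
  signal[t <= onset] <- 0
  signal_curve(t, signal, region = "AIF", phase = "stress")
}

#' Apply signal saturation to a curve
#'
#' Smooth compressive map `s -> ceiling * (1 - exp(-s / ceiling))`:
#' identity in the low-signal limit, bounded above by the ceiling, never
#' increases signal. Models the AIF signal saturation the dual-bolus
#' scheme is designed to correct.
#'
#' @param curve A [signal_curve()].
#' @param ceiling Saturation ceiling in signal units (> 0).
#' @return The compressed `signal_curve`.
#' @export
apply_saturation <- function(curve, ceiling) {
  stopifnot(inherits(curve, "signal_curve"))
  if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling <= 0)
    stop("'ceiling' must be a positive scalar")
  signal_curve(curve$t, ceiling * (1 - exp(-curve$signal / ceiling)),
               curve$region, curve$phase)
}

#' Simulate a tissue curve from the forward Fermi model
#'
#' Convolves the driving AIF with the Fermi impulse response at the true
#' parameters (rectangle rule, same discretization as the fitter; see
#' [fermi_tissue_model()]) and adds Gaussian noise of sd `spec$noise_sd`.
#' An optional finer internal grid (`upsample`) exposes discretization
#' bias: the AIF is linearly interpolated, convolved at step
#' `dt / upsample`, and subsampled back.
#'
#' @param aif Driving [signal_curve()] on the spec grid.
#' @param truth A [tissue_truth()].
#' @param spec An [acquisition_spec()]; supplies grid and noise sd.
#' @param region,phase Labels for the output curve.
#' @param upsample Integer >= 1 internal refinement factor (default 1).
#' @return A [signal_curve()]; noiseless when `spec$noise_sd == 0`.
#' @export
generate_tissue_curve <- function(aif, truth, spec, region = "segment",
                                  phase = "stress", upsample = 1L) {
  stopifnot(inherits(aif, "signal_curve"), inherits(truth, "tissue_truth"),
            inherits(spec, "acquisition_spec"))
  t <- spec_times(spec)
  if (length(aif$t) != length(t) || max(abs(aif$t - t)) > 1e-6)
    stop("AIF and acquisition spec do not share the time grid")
  p <- fermi_params(truth$r, truth$k, truth$tau0, truth$taud)
  upsample <- as.integer(upsample)
  if (upsample <= 1L) {
    clean <- fermi_tissue_model(aif, p)
  } else {
    tf <- seq(min(t), max(t), by = spec$frame_interval / upsample)
    aif_f <- signal_curve(tf, stats::approx(aif$t, aif$signal, xout = tf)$y,
                          aif$region, aif$phase)
    clean <- fermi_tissue_model(aif_f, p)[match(round(t, 9), round(tf, 9))]
  }
  noise <- if (spec$noise_sd > 0)
    stats::rnorm(length(clean), 0, spec$noise_sd) else 0
  signal_curve(t, clean + noise, region = region, phase = phase)
}

#' Simulate a dual-bolus perfusion study
#'
#' Emits, for one patient and one phase, the dilute pre-bolus AIF
#' (unsaturated, measured with noise), the main-bolus AIF (ten-fold dose,
#' passed through the saturation map, with noise), and per-segment tissue
#' curves driven by the *true* unsaturated full-dose AIF through the Fermi
#' forward model.
#'
#' @param spec An [acquisition_spec()].
#' @param truth_per_segment Named (or unnamed) list of [tissue_truth()]
#'   objects, one per segment; names become region labels (default
#'   `"1_endo"`, `"2_endo"`, ... style labels must be supplied by the
#'   caller, otherwise segments are labelled `seg1`, `seg2`, ...).
#' @param patient_id Patient identifier for the output table.
#' @param phase Phase label.
#' @param seed Integer seed for the measurement noise; default
#'   `spec$rng_seed`.
#'
#' @return A list with `curves` (a long-format `data.frame` with columns
#'   `patient_id`, `region`, `phase`, `t_seconds`, `signal`), `true_aif`
#'   (the noiseless unsaturated full-dose AIF as a `signal_curve`) and
#'   `truth` (the input list).
#' @export
generate_dual_bolus_study <- function(spec, truth_per_segment,
                                      patient_id = "P001",
                                      phase = "stress",
                                      seed = spec$rng_seed) {
  stopifnot(inherits(spec, "acquisition_spec"))
  if (length(truth_per_segment) < 1L)
    stop("'truth_per_segment' must contain at least one segment")
  set.seed(seed)
  labels <- names(truth_per_segment)
  if (is.null(labels)) labels <- paste0("seg", seq_along(truth_per_segment))

  pre_clean <- generate_aif(spec, spec$prebolus_dose)
  main_clean <- generate_aif(spec, spec$main_dose)
  main_sat <- apply_saturation(main_clean, spec$saturation_ceiling)

  add_noise <- function(curve, region) {
    s <- curve$signal
    if (spec$noise_sd > 0) s <- s + stats::rnorm(length(s), 0, spec$noise_sd)
    signal_curve(curve$t, s, region, phase)
  }
  pre <- add_noise(pre_clean, "AIF_pre")
  main <- add_noise(main_sat, "AIF_main")

  curves <- list(pre, main)
  for (i in seq_along(truth_per_segment)) {
    curves[[2L + i]] <- generate_tissue_curve(
      main_clean, truth_per_segment[[i]], spec,
      region = labels[i], phase = phase)
  }
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(patient_id = patient_id, region = cv$region, phase = cv$phase,
               t_seconds = cv$t, signal = cv$signal,
               stringsAsFactors = FALSE)
  }))
  list(curves = tab, true_aif = main_clean, truth = truth_per_segment)
}

#' Rebuild signal_curve objects from a long-format curve table
#'
#' @param tab Curve table with columns `patient_id`, `region`, `phase`,
#'   `t_seconds`, `signal`.
#' @return Named list of [signal_curve()]s, one per (patient, region,
#'   phase), names `patient.region.phase`.
#' @export
curves_from_table <- function(tab) {
  need <- c("patient_id", "region", "phase", "t_seconds", "signal")
  if (!all(need %in% names(tab))) stop("curve table is missing columns")
  key <- interaction(tab$patient_id, tab$region, tab$phase, drop = TRUE)
  out <- lapply(split(tab, key), function(d) {
    d <- d[order(d$t_seconds), ]
    signal_curve(d$t_seconds, d$signal, region = d$region[1],
                 phase = d$phase[1])
  })
  out
}
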