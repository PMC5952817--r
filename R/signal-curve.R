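#' Signal-intensity curve
#'
#' Container for a sampled time--signal-intensity series from one region
#' (arterial blood pool or a myocardial segment) in one perfusion phase.
#' The time grid must be uniform: the deconvolution machinery relies on a
#' constant frame interval.
#'
#' @param t Numeric vector of frame times in seconds, strictly increasing
#'   on a uniform grid with at least 20 frames.
#' @param signal Numeric vector of signal intensities (arbitrary units),
#'   same length as `t`.
#' @param region Region label, e.g. `"AIF_pre"`, `"AIF_main"` or a segment
#'   label such as `"7_endo"`.
#' @param phase Phase label, `"stress"` or `"rest"`.
#'
#' @return An object of class `signal_curve`: a list with elements `t`,
#'   `signal`, `region`, `phase` and the frame interval `dt` (seconds).
#' @export
signal_curve <- function(t, signal, region = "unknown", phase = "stress") {
  t <- as.numeric(t)
  signal <- as.numeric(signal)
  if (length(t) != length(signal))
    stop("'t' and 'signal' must have the same length")
  if (length(t) < 20L)
    stop("a signal curve needs at least 20 frames")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("'t' must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("'t' must be a uniform grid (relative tolerance 1e-6)")
  if (any(!is.finite(signal)))
    stop("'signal' contains non-finite values")
  structure(
    list(t = t, signal = signal, region = as.character(region),
         phase = as.character(phase), dt = dt[1]),
    class = "signal_curve"
  )
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve> %s / %s: %d frames, dt = %.3g s, peak = %.3g\n",
              x$region, x$phase, length(x$t), x$dt, max(x$signal)))
  invisible(x)
}

#' @export
length.signal_curve <- function(x) length(x$t)

same_grid <- function(a, b) {
  length(a$t) == length(b$t) && max(abs(a$t - b$t)) <= 1e-6 * a$dt
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("curves are not on the same time grid")
  invisible(TRUE)
}

#' Baseline-correct a curve
#'
#' Subtracts the mean of the pre-contrast baseline frames from the whole
#' curve, the curve-level analogue of surface-coil/pre-contrast intensity
#' correction applied before quantification.
#'
#' @param curve A [signal_curve()].
#' @param n_baseline_frames Number of leading frames taken as pre-contrast
#'   baseline (>= 3 and fewer than the curve length). They must precede
#'   contrast arrival.
#'
#' @return The baseline-corrected `signal_curve`; the mean over the
#'   baseline frames of the result is 0 (to within 1e-9).
#' @export
baseline_correct <- function(curve, n_baseline_frames = 5L) {
  stopifnot(inherits(curve, "signal_curve"))
  n <- as.integer(n_baseline_frames)
  if (n < 3L || n >= length(curve$t))
    stop("'n_baseline_frames' must be >= 3 and less than the curve length")
  base <- mean(curve$signal[seq_len(n)])
  signal_curve(curve$t, curve$signal - base, curve$region, curve$phase)
}

#' Build the dual-bolus reference arterial input function
#'
#' The dual-bolus scheme measures the arterial input function (AIF) from a
#' dilute pre-bolus whose signal stays in the linear range, then rescales
#' it by the dose ratio to stand in for the (saturated, hence unusable)
#' full-dose AIF.
#'
#' @param prebolus Baseline-corrected pre-bolus AIF, a [signal_curve()].
#' @param dose_ratio Main dose / pre-bolus dose; default 10
#'   (0.075 / 0.0075 mmol/kg).
#'
#' @return A `signal_curve` with signal scaled by `dose_ratio`, region
#'   relabelled `"AIF_ref"`.
#' @export
build_reference_aif <- function(prebolus, dose_ratio = 10) {
  stopifnot(inherits(prebolus, "signal_curve"))
  if (!is.numeric(dose_ratio) || length(dose_ratio) != 1L || dose_ratio <= 0)
    stop("'dose_ratio' must be a positive scalar")
  signal_curve(prebolus$t, prebolus$signal * dose_ratio,
               region = "AIF_ref", phase = prebolus$phase)
}

#' Savitzky-Golay smoothing of a signal curve
#'
#' Local polynomial smoothing used to denoise the measured pre-bolus AIF
#' before it is scaled to the full-dose reference: amplitude errors in the
#' reference propagate multiplicatively into the flow estimate, so the
#' AIF is smoothed while tissue curves are fitted as measured.
#'
#' @param curve A [signal_curve()].
#' @param window Odd filter length in frames (default 9).
#' @param degree Polynomial degree (default 3).
#' @return The smoothed `signal_curve`.
#' @export
smooth_curve <- function(curve, window = 9L, degree = 3L) {
  stopifnot(inherits(curve, "signal_curve"))
  sm <- signal::sgolayfilt(curve$signal, p = degree, n = window)
  signal_curve(curve$t, sm, curve$region, curve$phase)
}

#' Fit a gamma-variate bolus model to a measured AIF
#'
#' Classic parametric denoising of a first-pass arterial input function:
#' the curve is fitted to
#' `A ((t-t0)/tp)^alpha exp(alpha (1 - (t-t0)/tp))` for `t > t0` (zero
#' before arrival), where `A` is the peak amplitude and `tp` the time to
#' peak after arrival. Unlike running smoothers this model is causal: it
#' cannot leak signal before the bolus onset, which matters because the
#' deconvolution's delay selection is sensitive to the reference AIF's
#' onset.
#'
#' @param curve A baseline-corrected [signal_curve()].
#' @param min_r2 Minimum variance explained for the fit to be accepted
#'   (default 0.8).
#' @return A list: `curve` (the fitted `signal_curve`), `params`
#'   (`A`, `t0`, `alpha`, `tp`), `rss`, `r2`, `converged`. When the fit
#'   fails the input curve is returned unchanged with
#'   `converged = FALSE`.
#' @export
fit_gamma_variate <- function(curve, min_r2 = 0.8) {
  stopifnot(inherits(curve, "signal_curve"))
  t <- curve$t; y <- curve$signal
  model <- function(par) {
    tau <- pmax(t - par[2], 0) / par[4]
    par[1] * tau^par[3] * exp(par[3] * (1 - tau))
  }
  resid_fun <- function(par) y - model(par)
  pk <- max(y)
  if (pk <= 0) return(list(curve = curve, converged = FALSE))
  t_pk <- t[which.max(y)]
  onset0 <- {
    above <- which(y > 0.1 * pk)
    if (length(above)) t[above[1]] else t[1]
  }
  starts <- expand.grid(A = pk, t0 = onset0 + c(-2, -1, 0) * curve$dt,
                        alpha = c(2, 3, 5),
                        tp = pmax(t_pk - onset0, 2 * curve$dt))
  starts$t0 <- pmax(starts$t0, 0)
  lower <- c(pk * 0.2, 0, 0.5, curve$dt)
  upper <- c(pk * 5, max(t), 12, max(t) / 2)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss))
      best <- list(par = fit$par, rss = rss, ok = fit$info %in% 1:4)
  }
  if (is.null(best)) return(list(curve = curve, converged = FALSE))
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  if (!best$ok || r2 < min_r2)
    return(list(curve = curve, converged = FALSE))
  fitted <- signal_curve(t, model(best$par), curve$region, curve$phase)
  list(curve = fitted,
       params = c(A = best$par[1], t0 = best$par[2], alpha = best$par[3],
                  tp = best$par[4]),
       rss = best$rss, r2 = r2, converged = TRUE)
}

#' Estimate the blood-pool to myocardium arrival delay
#'
#' Onset of each curve is the first frame whose signal exceeds
#' `threshold_fraction` of that curve's peak; the delay is the tissue
#' onset minus the AIF onset, floored at zero. Because onsets fall on the
#' shared frame grid the result is an integer multiple of the frame
#' interval.
#'
#' @param aif,tissue Baseline-corrected [signal_curve()]s on the same grid.
#' @param threshold_fraction Onset threshold as a fraction of peak signal
#'   (default 0.1).
#'
#' @return Delay in seconds, or `NA_real_` when either curve has no
#'   positive peak (non-analyzable).
#' @export
estimate_delay <- function(aif, tissue, threshold_fraction = 0.1) {
  stopifnot(inherits(aif, "signal_curve"), inherits(tissue, "signal_curve"))
  stopifnot_same_grid(aif, tissue)
  onset <- function(curve) {
    pk <- max(curve$signal)
    if (!is.finite(pk) || pk <= 0) return(NA_real_)
    above <- curve$signal > threshold_fraction * pk
    # an isolated noise spike is not an onset: require the crossing to
    # start a run of two supra-threshold frames (the peak frame qualifies)
    sustained <- above & (c(above[-1], TRUE) | seq_along(above) ==
                            which.max(curve$signal))
    idx <- which(sustained)[1]
    curve$t[idx]
  }
  on_a <- onset(aif)
  on_t <- onset(tissue)
  if (is.na(on_a) || is.na(on_t)) return(NA_real_)
  max(0, on_t - on_a)
}
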