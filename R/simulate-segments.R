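#' Simulate per-patient segment ground truth
#'
#' Builds the 32-sub-segment map (16 AHA segments, each split into an
#' endocardial and epicardial half) with known myocardial perfusion
#' reserve. Ischemic sub-segments draw MPR from Uniform(0.5, 1.4), normal
#' ones from Uniform(1.8, 4.0), leaving a clear margin around the 1.5
#' classification threshold. Sub-segments of AHA segments carrying late
#' gadolinium enhancement (LGE) are flagged and are never assigned
#' ischemic status (they are excluded from ischemia assessment
#' downstream). Visual-ischemia flags mirror the MPR ground truth.
#'
#' @param n_ischemic Number of ischemic sub-segments (0 to 32, among
#'   non-LGE sub-segments).
#' @param lge_segments Integer vector of AHA segment ids (1-16) with LGE;
#'   both halves of such a segment are flagged.
#' @param mass_profile Length-16 vector of per-AHA-segment mass fractions
#'   summing to 1 (default equal masses).
#' @param patient_id Identifier for the output table.
#' @param ischemic_range,normal_range MPR sampling ranges.
#' @param seed Integer RNG seed.
#'
#' @return A `data.frame` with one row per sub-segment (32 rows):
#'   `patient_id`, `aha_segment`, `half`, `mass_fraction`, `lge`,
#'   `visual_ischemic`, `mpr` (ground-truth reserve) and `ischemic_true`.
#' @export
generate_segment_truth <- function(n_ischemic, lge_segments = integer(0),
                                   mass_profile = rep(1 / 16, 16),
                                   patient_id = "P001",
                                   ischemic_range = c(0.5, 1.4),
                                   normal_range = c(1.8, 4.0),
                                   seed = 1L) {
  if (length(mass_profile) != 16L)
    stop("'mass_profile' must have 16 entries (AHA segments 1-16)")
  if (abs(sum(mass_profile) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (tolerance 1e-9)")
  lge_segments <- as.integer(lge_segments)
  if (length(lge_segments) && (any(lge_segments < 1L | lge_segments > 16L)))
    stop("'lge_segments' must be AHA ids in 1..16")
  set.seed(seed)

  seg <- data.frame(
    patient_id = patient_id,
    aha_segment = rep(1:16, each = 2L),
    half = rep(c("endo", "epi"), times = 16L),
    mass_fraction = rep(mass_profile / 2, each = 2L),
    lge = as.integer(rep(1:16 %in% lge_segments, each = 2L)),
    stringsAsFactors = FALSE
  )
  eligible <- which(seg$lge == 0L)
  n_ischemic <- as.integer(n_ischemic)
  if (n_ischemic < 0L || n_ischemic > length(eligible))
    stop(sprintf("'n_ischemic' must be between 0 and %d (non-LGE sub-segments)",
                 length(eligible)))
  isch <- if (n_ischemic > 0L) sample(eligible, n_ischemic) else integer(0)
  seg$ischemic_true <- 0L
  seg$ischemic_true[isch] <- 1L
  seg$mpr <- stats::runif(32, normal_range[1], normal_range[2])
  seg$mpr[isch] <- stats::runif(n_ischemic, ischemic_range[1],
                                ischemic_range[2])
  seg$visual_ischemic <- seg$ischemic_true
  seg[, c("patient_id", "aha_segment", "half", "mass_fraction", "lge",
          "visual_ischemic", "mpr", "ischemic_true")]
}
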