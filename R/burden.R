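#' Subdivide the 16-segment AHA model into 32 sub-segments
#'
#' Splits each AHA segment into an endocardial and an epicardial half for
#' finer-grained ischemic-burden calculation. Mass is conserved; by
#' default each half receives 50% of the segment mass.
#'
#' @param aha A `data.frame` with one row per AHA segment: columns
#'   `aha_segment` (exactly 1..16) and `mass_fraction` (summing to 1),
#'   plus optional `lge` and `visual_ischemic` flags carried onto both
#'   halves.
#' @param endo_share Fraction of segment mass assigned to the endocardial
#'   half (default 0.5).
#' @return A 32-row `data.frame` with columns `aha_segment`, `half`,
#'   `mass_fraction` (and any carried flags).
#' @export
subdivide_segments <- function(aha, endo_share = 0.5) {
  if (!all(c("aha_segment", "mass_fraction") %in% names(aha)))
    stop("'aha' needs columns aha_segment and mass_fraction")
  if (!setequal(aha$aha_segment, 1:16) || nrow(aha) != 16L)
    stop("'aha' must contain AHA segments 1..16 exactly once")
  if (endo_share <= 0 || endo_share >= 1) stop("'endo_share' must be in (0,1)")
  aha <- aha[order(aha$aha_segment), ]
  carry <- setdiff(names(aha), c("aha_segment", "mass_fraction"))
  out <- aha[rep(seq_len(16L), each = 2L), , drop = FALSE]
  out$half <- rep(c("endo", "epi"), times = 16L)
  share <- rep(c(endo_share, 1 - endo_share), times = 16L)
  out$mass_fraction <- out$mass_fraction * share
  rownames(out) <- NULL
  out[, c("aha_segment", "half", "mass_fraction", carry)]
}

#' Classify a sub-segment's ischemia status
#'
#' LGE takes precedence: scarred sub-segments are excluded from ischemia
#' assessment regardless of their perfusion reserve. Otherwise MPR below
#' the threshold (strict inequality, default 1.5) is ischemic, at or above
#' it is normal, and missing MPR is non-analyzable.
#'
#' @param mpr Numeric vector of myocardial perfusion reserve values
#'   (`NA` = non-analyzable).
#' @param lge Integer/logical vector of LGE flags.
#' @param mpr_threshold Ischemia threshold on MPR (default 1.5).
#' @return Character vector in
#'   `{"ischemic", "normal", "excluded_lge", "non_analyzable"}`.
#' @export
classify_segment_ischemia <- function(mpr, lge, mpr_threshold = 1.5) {
  n <- max(length(mpr), length(lge))
  mpr <- rep_len(mpr, n)
  lge <- rep_len(as.integer(lge), n)
  out <- rep("normal", n)
  out[!is.na(mpr) & mpr < mpr_threshold] <- "ischemic"
  out[is.na(mpr)] <- "non_analyzable"
  out[lge == 1L] <- "excluded_lge"
  out
}

#' Compute patient-level ischemic burden
#'
#' Mass-weighted fraction of left-ventricular myocardium that is ischemic.
#' In `mpr` mode a sub-segment counts when its MPR classification is
#' `ischemic`; in `visual` mode when its visual flag is set. LGE-excluded
#' sub-segments never contribute to the numerator; by default the
#' denominator remains total LV mass (1.0), with an option to renormalize
#' to the non-LGE mass.
#'
#' @param segments A 32-row per-patient sub-segment table with columns
#'   `aha_segment`, `half`, `mass_fraction`, `lge`, `visual_ischemic` and
#'   (for `mpr` mode) `mpr`.
#' @param mode `"mpr"` or `"visual"`.
#' @param mpr_threshold Ischemia threshold on MPR (default 1.5).
#' @param renormalize_denominator If `TRUE`, divide by non-LGE mass
#'   instead of total mass (default `FALSE`).
#' @return A list of class `burden_result`: `burden` (fraction in [0,1]),
#'   `mode`, `n_ischemic_subsegments`, `n_visual_segments` (16-level AHA
#'   count of visually ischemic segments, LGE excluded).
#' @export
compute_ischemic_burden <- function(segments, mode = c("mpr", "visual"),
                                    mpr_threshold = 1.5,
                                    renormalize_denominator = FALSE) {
  mode <- match.arg(mode)
  if (nrow(segments) != 32L)
    stop("expected exactly 32 sub-segment records")
  if (abs(sum(segments$mass_fraction) - 1) > 1e-9)
    stop("sub-segment mass fractions must sum to 1 (tolerance 1e-9)")
  lge <- as.integer(segments$lge)
  if (mode == "mpr") {
    status <- classify_segment_ischemia(segments$mpr, lge, mpr_threshold)
    isch <- status == "ischemic"
  } else {
    isch <- as.integer(segments$visual_ischemic) == 1L & lge == 0L
  }
  denom <- if (renormalize_denominator)
    sum(segments$mass_fraction[lge == 0L]) else 1.0
  if (denom <= 0) stop("no assessable myocardium in denominator")
  burden <- sum(segments$mass_fraction[isch]) / denom

  vis <- as.integer(segments$visual_ischemic) == 1L & lge == 0L
  n_visual <- length(unique(segments$aha_segment[vis]))
  structure(list(burden = burden, mode = mode,
                 n_ischemic_subsegments = sum(isch),
                 n_visual_segments = n_visual),
            class = "burden_result")
}

#' Dichotomize ischemic burden by the consensus thresholds
#'
#' Applies the accepted prognostic thresholds: visual ischemia in >= 2 AHA
#' segments (counted at the 16-segment level: a segment counts if either
#' half is flagged and not LGE-excluded) and quantitative (MPR) burden
#' >= 10% of myocardium. Both thresholds are inclusive.
#'
#' @param visual_burden,mpr_burden Burden fractions in [0, 1].
#' @param n_visual_segments 16-level count of visually ischemic AHA
#'   segments.
#' @param visual_segment_threshold Segment-count threshold (default 2).
#' @param mpr_burden_threshold Burden-fraction threshold (default 0.10).
#' @return A list with `visual_positive` and `mpr_positive` logical flags.
#' @export
dichotomize_burden <- function(visual_burden, mpr_burden, n_visual_segments,
                               visual_segment_threshold = 2L,
                               mpr_burden_threshold = 0.10) {
  if (visual_segment_threshold <= 0 || mpr_burden_threshold <= 0)
    stop("thresholds must be > 0")
  list(visual_positive = n_visual_segments >= visual_segment_threshold,
       mpr_positive = mpr_burden >= mpr_burden_threshold)
}

#' Per-patient burden table for a cohort of segment records
#'
#' Convenience wrapper applying [compute_ischemic_burden()] and
#' [dichotomize_burden()] patient by patient.
#'
#' @param segments Sub-segment table for many patients (32 rows each) with
#'   a `patient_id` column.
#' @param mpr_threshold,visual_segment_threshold,mpr_burden_threshold
#'   Thresholds as in the underlying functions.
#' @return A `data.frame`: `patient_id`, `visual_burden`, `mpr_burden`,
#'   `n_visual_segments`, `visual_positive`, `mpr_positive`.
#' @export
compute_cohort_burden <- function(segments, mpr_threshold = 1.5,
                                  visual_segment_threshold = 2L,
                                  mpr_burden_threshold = 0.10) {
  out <- lapply(split(segments, segments$patient_id), function(d) {
    bm <- compute_ischemic_burden(d, "mpr", mpr_threshold)
    bv <- compute_ischemic_burden(d, "visual")
    flags <- dichotomize_burden(bv$burden, bm$burden, bv$n_visual_segments,
                                visual_segment_threshold,
                                mpr_burden_threshold)
    data.frame(patient_id = d$patient_id[1],
               visual_burden = bv$burden, mpr_burden = bm$burden,
               n_visual_segments = bv$n_visual_segments,
               visual_positive = flags$visual_positive,
               mpr_positive = flags$mpr_positive,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
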