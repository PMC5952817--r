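qualifying_any_time <- c("cv_death", "nonfatal_mi", "aborted_scd")
revasc_types <- c("pci", "cabg")

#' Adjudicate the composite primary endpoint for one patient
#'
#' The composite endpoint comprises cardiovascular death, nonfatal
#' myocardial infarction, aborted sudden cardiac death, and late
#' revascularization (PCI or CABG more than `blanking_days` after the
#' scan). Revascularizations inside the blanking window do not qualify;
#' when several events qualify only the earliest counts. Ties on the same
#' day resolve in favour of the harder endpoint (death / MI / aborted SCD
#' before revascularization), so an infarction leading to same-day
#' revascularization counts once, as infarction.
#'
#' @param events A `data.frame` with columns `type` (one of `cv_death`,
#'   `nonfatal_mi`, `aborted_scd`, `pci`, `cabg`) and `day_offset` (days
#'   from the scan, >= 0). Zero rows = no events.
#' @param last_followup Last follow-up day (> 0).
#' @param blanking_days Blanking window length in days (default 90);
#'   procedures with `day_offset <= blanking_days` are excluded.
#' @return A list of class `endpoint_result`: `event` (0/1), `time_days`,
#'   `event_type` (`"censored"` when none), `early_revasc` flag.
#' @export
adjudicate_primary_endpoint <- function(events, last_followup,
                                        blanking_days = 90) {
  if (blanking_days < 0) stop("'blanking_days' must be >= 0")
  if (!is.numeric(last_followup) || last_followup <= 0)
    stop("'last_followup' must be > 0")
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(type = character(0), day_offset = numeric(0))
  }
  if (!all(events$type %in% c(qualifying_any_time, revasc_types)))
    stop("unknown event type")
  if (any(events$day_offset < 0)) stop("'day_offset' must be >= 0")
  if (any(events$day_offset > last_followup))
    stop("event recorded after last follow-up: data inconsistency")

  is_revasc <- events$type %in% revasc_types
  early_revasc <- any(is_revasc & events$day_offset <= blanking_days)
  qualifies <- (!is_revasc) | (events$day_offset > blanking_days)
  cand <- events[qualifies, , drop = FALSE]
  if (nrow(cand) == 0L) {
    res <- list(event = 0L, time_days = last_followup,
                event_type = "censored", early_revasc = early_revasc)
  } else {
    # earliest qualifying event; same-day ties go to the harder endpoint
    sev <- match(cand$type, c(qualifying_any_time, revasc_types))
    ord <- order(cand$day_offset, sev)
    first <- cand[ord[1L], ]
    res <- list(event = 1L, time_days = first$day_offset,
                event_type = as.character(first$type),
                early_revasc = early_revasc)
  }
  class(res) <- "endpoint_result"
  res
}

#' Adjudicate a cohort table
#'
#' Reconstructs each patient's event list from the cohort-table columns
#' (`event_type`/`time_days` for the terminating event, `revasc_days` for
#' additional procedures) and applies [adjudicate_primary_endpoint()].
#'
#' @param cohort A cohort table as produced by [generate_cohort()].
#' @param blanking_days Blanking window (default 90).
#' @param exclude_early_revasc_patients If `TRUE`, drop patients with a
#'   procedure inside the blanking window entirely (sensitivity analysis);
#'   default keeps them in the risk set.
#' @return A survival `data.frame`: `patient_id`, `time_days`, `event`,
#'   `event_type`, `early_revasc`.
#' @export
adjudicate_cohort <- function(cohort, blanking_days = 90,
                              exclude_early_revasc_patients = FALSE) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    ev <- data.frame(type = character(0), day_offset = numeric(0))
    if (r$event == 1L)
      ev <- rbind(ev, data.frame(type = r$event_type,
                                 day_offset = r$time_days))
    if (nzchar(r$revasc_days)) {
      days <- as.numeric(strsplit(r$revasc_days, ";")[[1]])
      ev <- rbind(ev, data.frame(type = "pci", day_offset = days))
    }
    a <- adjudicate_primary_endpoint(ev, last_followup = r$time_days,
                                     blanking_days = blanking_days)
    data.frame(patient_id = r$patient_id, time_days = a$time_days,
               event = a$event, event_type = a$event_type,
               early_revasc = a$early_revasc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (exclude_early_revasc_patients) out <- out[!out$early_revasc, ]
  rownames(out) <- NULL
  out
}

#' Cohort accounting after exclusions
#'
#' @param n_eligible Patients meeting inclusion criteria.
#' @param n_lost Lost to follow-up.
#' @param n_poor_quality Excluded for poor image quality.
#' @return A list: `final` cohort size, `lost_pct` and `poor_quality_pct`
#'   (percentages of the eligible cohort, 1 decimal place).
#' @export
cohort_filter <- function(n_eligible, n_lost, n_poor_quality) {
  if (n_lost + n_poor_quality > n_eligible)
    stop("exclusions exceed the eligible cohort")
  list(final = n_eligible - n_lost - n_poor_quality,
       lost_pct = round(100 * n_lost / n_eligible, 1),
       poor_quality_pct = round(100 * n_poor_quality / n_eligible, 1))
}

#' Count first events by type
#'
#' @param results Survival table with `event` and `event_type` columns
#'   (e.g. from [adjudicate_cohort()]).
#' @return A list with `by_type` (named integer vector over the five
#'   clinical types) and `total`.
#' @export
composite_event_count <- function(results) {
  types <- c(qualifying_any_time, revasc_types)
  ev <- results[results$event == 1L, , drop = FALSE]
  by_type <- vapply(types, function(tp) sum(ev$event_type == tp), integer(1))
  list(by_type = by_type, total = sum(by_type))
}
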