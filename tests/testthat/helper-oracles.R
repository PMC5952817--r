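# Independent brute-force oracles used to cross-check the implementation.
# Deliberately naive: enumeration and direct counting, no shared code with
# the package internals they verify.

# Mann-Whitney AUC by explicit pairwise counting
oracle_pairwise_auc <- function(score, is_case) {
  ca <- score[is_case]
  co <- score[!is_case]
  tot <- 0
  for (x in ca) for (y in co)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(ca) * length(co))
}

# categorical NRI by direct counting over category moves
oracle_counting_nri <- function(cat_base, cat_new, is_event) {
  up <- as.integer(cat_new) > as.integer(cat_base)
  down <- as.integer(cat_new) < as.integer(cat_base)
  e <- is_event
  (sum(up & e) / sum(e) - sum(down & e) / sum(e)) +
    (sum(down & !e) / sum(!e) - sum(up & !e) / sum(!e))
}

# Kaplan-Meier by explicit risk-set counting at each distinct event time
oracle_km <- function(time, event, at) {
  dtimes <- sort(unique(time[event == 1]))
  s <- 1
  for (td in dtimes) {
    if (td > at) break
    d <- sum(time == td & event == 1)
    r <- sum(time >= td)
    s <- s * (1 - d / r)
  }
  s
}

# endpoint adjudication by enumerating every qualifying event
oracle_adjudicate <- function(events, last_followup, blanking_days) {
  hard <- c("cv_death", "nonfatal_mi", "aborted_scd")
  qual_times <- c()
  for (i in seq_len(nrow(events))) {
    tp <- events$type[i]; d <- events$day_offset[i]
    if (tp %in% hard || d > blanking_days) qual_times <- c(qual_times, d)
  }
  if (length(qual_times) == 0)
    list(event = 0L, time = last_followup)
  else
    list(event = 1L, time = min(qual_times))
}

# random event list for the adjudication property tests
random_event_list <- function(n_max = 4, fu = 1000) {
  n <- sample(0:n_max, 1)
  if (n == 0)
    return(data.frame(type = character(0), day_offset = numeric(0)))
  data.frame(
    type = sample(c("cv_death", "nonfatal_mi", "aborted_scd", "pci", "cabg"),
                  n, replace = TRUE),
    day_offset = sample(1:fu, n, replace = TRUE))
}

# one simulated dual-bolus acquisition with known per-segment flow
make_noiseless_study <- function(mbf = 2, k = 0.25, tau0 = 3, taud = 2,
                                 spec = acquisition_spec()) {
  truth <- tissue_truth(mbf, k = k, tau0 = tau0, taud = taud)
  aif <- generate_aif(spec, spec$main_dose)
  tissue <- generate_tissue_curve(aif, truth, spec)
  list(spec = spec, truth = truth, aif = aif, tissue = tissue)
}
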