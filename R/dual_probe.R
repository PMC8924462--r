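# Dual-probe (CEP8 + CEP12) co-detection: per-cell ploidy pattern, per-patient
# summaries, single-probe false negativity and the paired probe comparison.

dual_patterns <- c("aneu8_di12", "di8_aneu12", "aneu8_aneu12", "di8_di12", "qc")

#' Combine the two probe calls of one cell
#'
#' Each probe's spot count is ploidy-called independently; the joint pattern
#' records which probes show aneuploidy. If either hybridisation failed
#' (0 spots) the pattern is `qc`. Cells counted diploid by CEP8 but aneuploid
#' by CEP12 (`di8_aneu12`) are the single-probe false negatives: a CEP8-only
#' assay would have missed them.
#'
#' @param cep8_spots,cep12_spots non-negative integer vectors (must both be
#'   present; single-probe events have no pattern and must be skipped by the
#'   caller).
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return data.frame with columns `chr8`, `chr12` (ploidy classes) and
#'   `pattern`.
#' @export
dual_pattern <- function(cep8_spots, cep12_spots, aneuploid_min3 = FALSE) {
  assert_that(!anyNA(cep8_spots) && !anyNA(cep12_spots),
              "single-probe event: cep12_spots missing, caller must skip")
  chr8 <- ploidy_call(cep8_spots)
  chr12 <- ploidy_call(cep12_spots)
  a8 <- is_aneuploid(chr8, aneuploid_min3)
  a12 <- is_aneuploid(chr12, aneuploid_min3)
  pattern <- ifelse(chr8 == "qc_fail" | chr12 == "qc_fail", "qc",
             ifelse(a8 & a12, "aneu8_aneu12",
             ifelse(a8 & !a12, "aneu8_di12",
             ifelse(!a8 & a12, "di8_aneu12", "di8_di12"))))
  data.frame(chr8 = chr8, chr12 = chr12, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Per-patient dual-probe summaries
#'
#' For every patient with at least one dual-probe event, counts the CD45-
#' cells aneuploid by each probe and flags whether the patient harbours at
#' least one CEP8-diploid / CEP12-aneuploid cell (the patient-level
#' single-probe false-negative flag: CEP8 must be exactly diploid, not a QC
#' failure). Only CD45- events contribute — the compared quantity is tumor
#' and tumor-derived endothelial cells with chromosome aneuploidy, not
#' leukocytes. Events without a CEP12 count are skipped.
#'
#' @param events validated event data.frame.
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return data.frame with columns `patient_id`, `n_aneu8`, `n_aneu12`,
#'   `has_di8_aneu12`, one row per patient with >= 1 dual-probe event.
#' @export
probe_patient_summaries <- function(events, aneuploid_min3 = FALSE) {
  events <- validate_events(events)
  events <- events[!is.na(events$cep12_spots), , drop = FALSE]
  assert_that(nrow(events) > 0, "no dual-probe events (cep12_spots all missing)")
  pat <- dual_pattern(events$cep8_spots, events$cep12_spots, aneuploid_min3)
  neg <- !events$cd45
  a8 <- neg & is_aneuploid(pat$chr8, aneuploid_min3)
  a12 <- neg & is_aneuploid(pat$chr12, aneuploid_min3)
  fn <- neg & pat$chr8 == "diploid" & is_aneuploid(pat$chr12, aneuploid_min3)
  ids <- factor(events$patient_id, levels = unique(events$patient_id))
  data.frame(
    patient_id = levels(ids),
    n_aneu8 = as.integer(tapply(a8, ids, sum)),
    n_aneu12 = as.integer(tapply(a12, ids, sum)),
    has_di8_aneu12 = as.logical(tapply(fn, ids, any)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Patient-level single-probe false-negative rate
#'
#' Fraction of patients carrying at least one CD45- cell that is diploid by
#' CEP8 but aneuploid by CEP12 — i.e. patients whose rare-cell burden a
#' CEP8-only assay would under-call.
#'
#' @param summaries output of [probe_patient_summaries()].
#' @return fraction in `[0, 1]`.
#' @export
single_probe_fn_rate <- function(summaries) {
  assert_that(is.data.frame(summaries) && nrow(summaries) > 0,
              "need a non-empty summary table")
  assert_that(!anyDuplicated(summaries$patient_id),
              "duplicate patient_id in probe summaries")
  mean(summaries$has_di8_aneu12)
}

#' Compare per-patient aneuploid-cell totals between the two probes
#'
#' Reports the median per-patient count of CD45- aneuploid cells detected by
#' each probe and a two-tailed t-test of the per-patient difference. Both
#' totals come from the same patients, so the default is a paired test on
#' the within-patient differences; `paired = FALSE` gives Welch's unpaired
#' test instead.
#'
#' @param summaries output of [probe_patient_summaries()] (>= 2 patients).
#' @param paired paired t-test (default) or Welch.
#' @return list with `median8`, `median12`, `t`, `df`, `p`.
#' @export
probe_totals_comparison <- function(summaries, paired = TRUE) {
  assert_that(is.data.frame(summaries) && nrow(summaries) >= 2,
              "need >= 2 patients for a probe comparison")
  x <- summaries$n_aneu8
  y <- summaries$n_aneu12
  if (paired) {
    d <- x - y
    n <- length(d)
    s <- sd(d)
    if (s == 0) {
      if (mean(d) != 0) {
        abort("degenerate paired t-test: constant nonzero difference")
      }
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- mean(d) / (s / sqrt(n))
      p <- 2 * pt(-abs(t_stat), df = n - 1)
    }
    dfree <- n - 1
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    dfree <- unname(ht$parameter)
    p <- ht$p.value
  }
  list(median8 = median(x), median12 = median(y),
       t = t_stat, df = dfree, p = p)
}
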