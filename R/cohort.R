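# Per-patient aggregation and cohort-level statistics: positivity rates,
# group medians, tie-corrected Kruskal-Wallis H.

#' Aggregate one patient's classified events
#'
#' Counts CTCs and CTECs by the phenotype predicates, tallies atlas-leaf
#' subtypes, and flags CTC positivity (CTC count > 0 — positivity is defined
#' on CTCs alone, not CTC+CTEC). Events whose CEP8 hybridisation failed
#' (`qc_fail`) are excluded from every count. When a patient contributed
#' several samples, only the first sample (order of appearance) is used, so
#' repeat draws do not inflate per-patient totals.
#'
#' @param classified output of [classify_events()] for a single patient.
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return one-row data.frame: `patient_id`, `disease_group`, `n_ctc`,
#'   `n_ctec`, `n_total_ctc_ctec`, `n_crc_leaves`, `ctc_positive`, plus a
#'   list-column `subtype_histogram` (named integer vector).
#' @export
aggregate_patient <- function(classified, aneuploid_min3 = FALSE) {
  assert_that("category" %in% names(classified),
              "aggregate_patient expects the output of classify_events")
  ids <- unique(classified$patient_id)
  assert_that(length(ids) <= 1,
              "mixed patient_ids in aggregate_patient: ",
              paste(utils::head(ids, 3), collapse = ", "))
  if (nrow(classified) > 0) {
    first_sample <- classified$sample_id[1]
    classified <- classified[classified$sample_id == first_sample, ,
                             drop = FALSE]
  }
  keep <- classified$ploidy != "qc_fail" & classified$category != "qc_fail"
  ev <- classified[keep, , drop = FALSE]
  ploidy <- ev$ploidy
  n_ctc <- sum(is_ctc(ev, ploidy, aneuploid_min3))
  n_ctec <- sum(is_ctec(ev, ploidy, aneuploid_min3))
  leaves <- ev$leaf_canonical[ev$category == "atlas_leaf"]
  hist <- table(leaves)
  out <- data.frame(
    patient_id = if (length(ids)) ids else NA_character_,
    disease_group = if (nrow(classified)) classified$disease_group[1]
                    else NA_character_,
    n_ctc = n_ctc,
    n_ctec = n_ctec,
    n_total_ctc_ctec = n_ctc + n_ctec,
    n_crc_leaves = length(leaves),
    ctc_positive = n_ctc > 0,
    stringsAsFactors = FALSE
  )
  out$subtype_histogram <- list(setNames(as.integer(hist), names(hist)))
  out
}

#' Aggregate all patients in a classified event table
#'
#' Splits by `patient_id` (order of first appearance preserved) and applies
#' [aggregate_patient()]. Patients with no event rows at all are absent from
#' the result — the platform emits no record for them.
#'
#' @param classified output of [classify_events()].
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return data.frame with one row per patient.
#' @export
aggregate_patients <- function(classified, aneuploid_min3 = FALSE) {
  if (nrow(classified) == 0) {
    out <- aggregate_patient(classified, aneuploid_min3)
    return(out[0, , drop = FALSE])
  }
  ids <- factor(classified$patient_id, levels = unique(classified$patient_id))
  parts <- split(seq_len(nrow(classified)), ids)
  out <- do.call(rbind, lapply(parts, function(i) {
    aggregate_patient(classified[i, , drop = FALSE], aneuploid_min3)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort CTC positivity rate
#'
#' Percentage of patients with at least one CTC, rounded half-up to one
#' decimal (the convention of printed clinical tables: 2157/2360 -> 91.4).
#'
#' @param summaries data.frame with a logical `ctc_positive` column
#'   (one row per patient).
#' @return percentage with one decimal.
#' @export
positivity_rate <- function(summaries) {
  assert_that(is.data.frame(summaries) && nrow(summaries) > 0,
              "need a non-empty patient summary table")
  round_half_up(100 * mean(summaries$ctc_positive), 1)
}

#' Kruskal-Wallis H-test with tie correction
#'
#' Rank-based k-sample location test on the pooled mid-ranks:
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - \tfrac{N+1}{2})^2 \Big/ C,}
#' with tie correction \eqn{C = 1 - \sum_t (t^3 - t) / (N^3 - N)} over tie
#' group sizes \eqn{t}. The p-value uses the chi-square upper tail with
#' \eqn{k - 1} degrees of freedom (the standard large-sample approximation,
#' applied regardless of group size; no exact permutation p-value).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need >= 2 groups")
  sizes <- lengths(groups)
  assert_that(all(sizes > 0), "every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  assert_that(!anyNA(x), "NA values in Kruskal-Wallis input")
  N <- length(x)
  r <- rank(x, ties.method = "average")
  g <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  H_raw <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  assert_that(C > 0, "undefined test: all pooled values identical")
  H <- H_raw / C
  df <- length(groups) - 1
  list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE))
}

#' Per-group cohort summary and overall group comparison
#'
#' For each disease group: patient count, CTC-positive count, positivity
#' percentage (half-up, 1 decimal) and the median per-patient CTC+CTEC total
#' (even-n median = mean of the two central order statistics; reported to 2
#' decimals). With two or more groups the Kruskal-Wallis H-test compares the
#' per-patient totals across groups; with a single group the test is skipped
#' with a message.
#'
#' @param summaries output of [aggregate_patients()].
#' @return list with `groups` (data.frame, one row per group in order of
#'   first appearance) and `kw` (list `H`, `df`, `p`, or `NULL` when skipped).
#' @export
group_summary <- function(summaries) {
  assert_that(is.data.frame(summaries) && nrow(summaries) > 0,
              "need a non-empty patient summary table")
  ids <- factor(summaries$disease_group,
                levels = unique(summaries$disease_group))
  parts <- split(summaries, ids)
  groups <- do.call(rbind, lapply(parts, function(s) {
    data.frame(
      disease_group = s$disease_group[1],
      n_patients = nrow(s),
      n_positive = sum(s$ctc_positive),
      positivity_pct = positivity_rate(s),
      median_total = round_half_up(median(s$n_total_ctc_ctec), 2),
      stringsAsFactors = FALSE
    )
  }))
  rownames(groups) <- NULL
  kw <- NULL
  if (nlevels(ids) >= 2) {
    kw <- kruskal_wallis(lapply(parts, function(s) s$n_total_ctc_ctec))
  } else {
    message("single disease group: Kruskal-Wallis comparison skipped")
  }
  list(groups = groups, kw = kw)
}
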