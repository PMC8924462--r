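# The unit of analysis is one detected nucleated cell ("event"). Events are
# held in a plain data.frame with one row per event and a fixed set of
# columns; all operations are vectorised over rows.

# ---- schema ----------------------------------------------------------------

#' Canonical event-table columns
#'
#' Column names, in serialisation order, of a per-cell event table. Stain
#' calls (`cd45`, `pm`, `cd31`, `vim`, `cd133`) are logical; `pm` is the
#' call for the panel-marker channel, which carries the tumor marker
#' (EpCAM/CK18/PD-L1/AFP/HER2/CA19-9) on the tumor panel and CD133 on the
#' stem panel. `diameter_um` and `size_class` are alternative size encodings
#' (at least one must be present per event). `cep8_spots` is the chromosome-8
#' enumeration-probe spot count; `cep12_spots` is optional (dual-probe runs
#' only). `cluster_id` is shared by members of one cell cluster / CTM.
#'
#' @return character vector of column names.
#' @export
event_columns <- function() {
  c("patient_id", "sample_id", "disease_group", "event_id", "cluster_id",
    "panel", "panel_marker_name", "cd45", "pm", "cd31", "vim", "cd133",
    "diameter_um", "size_class", "cep8_spots", "cep12_spots")
}

#' Build an event table from vectors
#'
#' Convenience constructor used by tests and the simulator; recycles length-1
#' arguments, fills optional columns with `NA`, and validates the result.
#'
#' @param patient_id,sample_id,disease_group,event_id identifiers.
#' @param cluster_id optional cluster identifier (`NA` = unclustered).
#' @param panel `"tumor_panel"` or `"stem_panel"`.
#' @param panel_marker_name marker carried on the panel channel.
#' @param cd45,pm,cd31,vim,cd133 logical stain calls.
#' @param diameter_um cell diameter in micrometres (`NA` if `size_class` given).
#' @param size_class `"small"`, `"large"`, or `NA`.
#' @param cep8_spots,cep12_spots FISH spot counts (`cep12_spots` optional).
#' @return validated event data.frame.
#' @export
new_events <- function(patient_id, sample_id = "S1", disease_group = "synthetic",
                       event_id = NULL, cluster_id = NA_character_,
                       panel = "tumor_panel", panel_marker_name = "EpCAM",
                       cd45 = FALSE, pm = FALSE, cd31 = FALSE, vim = FALSE,
                       cd133 = FALSE, diameter_um = NA_real_,
                       size_class = NA_character_, cep8_spots = 2L,
                       cep12_spots = NA_integer_) {
  n <- if (length(patient_id) == 0) 0L else {
    max(lengths(list(patient_id, cd45, pm, cd31, vim, cep8_spots,
                     cep12_spots, diameter_um, size_class, cluster_id)))
  }
  if (is.null(event_id)) event_id <- sprintf("E%05d", seq_len(n))
  df <- data.frame(
    patient_id = rep_len(as.character(patient_id), n),
    sample_id = rep_len(as.character(sample_id), n),
    disease_group = rep_len(as.character(disease_group), n),
    event_id = rep_len(as.character(event_id), n),
    cluster_id = rep_len(as.character(cluster_id), n),
    panel = rep_len(as.character(panel), n),
    panel_marker_name = rep_len(as.character(panel_marker_name), n),
    cd45 = rep_len(as.logical(cd45), n),
    pm = rep_len(as.logical(pm), n),
    cd31 = rep_len(as.logical(cd31), n),
    vim = rep_len(as.logical(vim), n),
    cd133 = rep_len(as.logical(cd133), n),
    diameter_um = rep_len(as.numeric(diameter_um), n),
    size_class = rep_len(as.character(size_class), n),
    cep8_spots = rep_len(as.integer(cep8_spots), n),
    cep12_spots = rep_len(as.integer(cep12_spots), n),
    stringsAsFactors = FALSE
  )
  validate_events(df)
}

#' Validate an event table
#'
#' Checks the schema and the per-event invariants: all mandatory columns
#' present and typed; spot counts non-negative integers; at least one of
#' `diameter_um` / `size_class` present per row; `size_class` (when present)
#' in `{small, large}`; `panel` in `{tumor_panel, stem_panel}`; stem-panel
#' events carry `panel_marker_name == "CD133"`. Offending rows are reported
#' by row number.
#'
#' @param events data.frame with the columns of [event_columns()].
#' @return `events`, invisibly coerced to canonical column order.
#' @export
validate_events <- function(events) {
  assert_that(is.data.frame(events), "events must be a data.frame")
  missing <- setdiff(event_columns(), names(events))
  assert_that(length(missing) == 0,
              "event table missing mandatory column(s): ",
              paste(missing, collapse = ", "))
  events <- events[, event_columns()]
  if (nrow(events) == 0) return(events)

  bad_rows <- function(ok, what) {
    assert_that(all(ok), "invalid event row(s) [", what, "]: rows ",
                paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  for (col in c("cd45", "pm", "cd31", "vim", "cd133")) {
    bad_rows(!is.na(events[[col]]) & is.logical(events[[col]]),
             paste0(col, " must be a non-missing 0/1 call"))
  }
  spots_ok <- function(x) is.na(x) | (x >= 0 & x == trunc(x))
  assert_that(is.numeric(events$cep8_spots), "cep8_spots must be integer")
  bad_rows(!is.na(events$cep8_spots) & spots_ok(events$cep8_spots),
           "cep8_spots must be a non-negative integer")
  bad_rows(spots_ok(events$cep12_spots),
           "cep12_spots must be a non-negative integer when present")
  bad_rows(!is.na(events$diameter_um) | !is.na(events$size_class),
           "at least one of diameter_um / size_class required")
  bad_rows(is.na(events$diameter_um) | events$diameter_um > 0,
           "diameter_um must be positive")
  bad_rows(is.na(events$size_class) | events$size_class %in% c("small", "large"),
           "size_class must be 'small' or 'large'")
  bad_rows(events$panel %in% c("tumor_panel", "stem_panel"),
           "panel must be tumor_panel or stem_panel")
  bad_rows(events$panel != "stem_panel" | events$panel_marker_name == "CD133",
           "stem_panel events must carry panel_marker_name CD133")
  events
}

# ---- ploidy ----------------------------------------------------------------

#' Ploidy class labels in order
#' @keywords internal
ploidy_levels <- function() {
  c("qc_fail", "haploid", "diploid", "triploid", "tetraploid", "multiploid")
}

#' Call chromosome ploidy from a FISH spot count
#'
#' A centromeric enumeration probe yields one fluorescent spot per chromosome
#' copy, so the spot count is read directly as copy number: 1 haploid,
#' 2 diploid, 3 triploid, 4 tetraploid, 5 or more multiploid. Zero spots is a
#' hybridisation failure (`qc_fail`), not a haploid call; such events never
#' count as aneuploid.
#'
#' @param spots non-negative integer vector of spot counts (`NA` allowed,
#'   propagated).
#' @return character vector of ploidy classes.
#' @export
ploidy_call <- function(spots) {
  assert_that(is.numeric(spots), "spot counts must be numeric integers")
  ok <- is.na(spots) | (spots >= 0 & spots == trunc(spots))
  assert_that(all(ok), "spot counts must be non-negative integers")
  out <- rep(NA_character_, length(spots))
  out[!is.na(spots) & spots == 0] <- "qc_fail"
  out[!is.na(spots) & spots == 1] <- "haploid"
  out[!is.na(spots) & spots == 2] <- "diploid"
  out[!is.na(spots) & spots == 3] <- "triploid"
  out[!is.na(spots) & spots == 4] <- "tetraploid"
  out[!is.na(spots) & spots >= 5] <- "multiploid"
  out
}

#' Is a ploidy call aneuploid?
#'
#' Default rule: any class other than diploid or qc_fail, so haploid cells
#' count as aneuploid (CD45+ haploid clusters are observed among circulating
#' rare cells). With `aneuploid_min3 = TRUE` the definition is restricted to
#' three or more copies for sensitivity analyses.
#'
#' @param ploidy character vector of classes from [ploidy_call()].
#' @param aneuploid_min3 if `TRUE`, require >= 3 copies.
#' @return logical vector (`NA` ploidy gives `NA`).
#' @export
is_aneuploid <- function(ploidy, aneuploid_min3 = FALSE) {
  if (aneuploid_min3) {
    ploidy %in% c("triploid", "tetraploid", "multiploid") &
      !is.na(ploidy)
  } else {
    !is.na(ploidy) & !(ploidy %in% c("diploid", "qc_fail"))
  }
}

# ---- size gate -------------------------------------------------------------

#' WBC size reference
#'
#' The small/large boundary is the average white-blood-cell diameter on the
#' slide; 10 um is the default when no per-slide reference is supplied.
#'
#' @param mean_wbc_diameter_um positive real, micrometres.
#' @return list of class `wbc_reference`.
#' @export
wbc_reference <- function(mean_wbc_diameter_um = 10.0) {
  assert_that(is.numeric(mean_wbc_diameter_um) &&
                length(mean_wbc_diameter_um) == 1 &&
                mean_wbc_diameter_um > 0,
              "mean_wbc_diameter_um must be a single positive number")
  structure(list(mean_wbc_diameter_um = mean_wbc_diameter_um),
            class = "wbc_reference")
}

#' Classify cell size against the WBC boundary
#'
#' An explicit `size_class` takes precedence over the measured diameter;
#' otherwise a cell is `small` iff its diameter is less than or equal to the
#' mean WBC diameter (ties are small: the small-cell branch is "<= WBC size").
#'
#' @param events event data.frame (or any data.frame with `diameter_um`,
#'   `size_class`).
#' @param ref a [wbc_reference()].
#' @return character vector `"small"`/`"large"`, one per row.
#' @export
classify_size <- function(events, ref = wbc_reference()) {
  stopifnot(inherits(ref, "wbc_reference"))
  has_class <- !is.na(events$size_class)
  has_diam <- !is.na(events$diameter_um)
  assert_that(all(has_class | has_diam),
              "events without diameter_um or size_class: rows ",
              paste(utils::head(which(!(has_class | has_diam)), 5),
                    collapse = ", "))
  out <- ifelse(events$diameter_um <= ref$mean_wbc_diameter_um,
                "small", "large")
  out[has_class] <- events$size_class[has_class]
  out
}

# ---- CTC / CTEC predicates -------------------------------------------------

#' CTC predicate
#'
#' A circulating tumor cell is CD45-negative and CD31-negative, on the tumor
#' marker panel, and either tumor-marker-positive or chromosome-8 aneuploid.
#' Vimentin does not veto the call: mesenchymal (Vim+) CTCs are counted, with
#' the Vim- phenotype kept as the "classical" annotation.
#'
#' @param events event data.frame.
#' @param ploidy chromosome-8 ploidy calls (defaults to
#'   `ploidy_call(events$cep8_spots)`).
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return logical vector.
#' @export
is_ctc <- function(events, ploidy = ploidy_call(events$cep8_spots),
                   aneuploid_min3 = FALSE) {
  !events$cd45 & !events$cd31 & events$panel == "tumor_panel" &
    (events$pm | is_aneuploid(ploidy, aneuploid_min3))
}

#' CTEC predicate
#'
#' A circulating tumor-derived endothelial cell is CD45-negative,
#' CD31-positive and chromosome-8 aneuploid; the tumor marker may be positive
#' or negative and Vimentin is again non-restrictive.
#'
#' @inheritParams is_ctc
#' @return logical vector.
#' @export
is_ctec <- function(events, ploidy = ploidy_call(events$cep8_spots),
                    aneuploid_min3 = FALSE) {
  !events$cd45 & events$cd31 & is_aneuploid(ploidy, aneuploid_min3)
}

# Effective CD133 positivity: the dedicated column, or the panel-marker
# channel when the stem panel (whose marker is CD133) is in use.
cd133_positive <- function(events) {
  events$cd133 | (events$panel == "stem_panel" & events$pm)
}
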