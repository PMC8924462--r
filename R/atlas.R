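# 71-leaf subtype atlas and the event -> category decision procedure.
#
# Leaf space (reconstruction of the published total of 71):
#   {small, large} x {haploid, triploid, tetraploid, multiploid} x 8 marker
#   combinations (PM, CD31, Vim each +/-)          = 64 aneuploid leaves
#   {any-size diploid} x 7 combinations with >= 1 positive marker = 7 leaves
# CD45+ aberrant cells, residual WBCs, marker-negative diploids and QC
# failures are explicit non-leaf categories, outside the 71.

atlas_ploidy_order <- c("haploid", "triploid", "tetraploid", "multiploid")

# marker combos in a fixed binary order: PM is the high bit, Vim the low bit
marker_combo_grid <- function() {
  g <- expand.grid(vim = c(FALSE, TRUE), cd31 = c(FALSE, TRUE),
                   pm = c(FALSE, TRUE))
  g[, c("pm", "cd31", "vim")]
}

sign_chr <- function(x) ifelse(x, "+", "-")

#' Canonical rendering of a subtype label
#'
#' `"size|ploidy|PM<s>CD31<s>Vim<s>"` with `<s>` in `{+, -}`, e.g.
#' `"large|triploid|PM+CD31-Vim-"` or `"any|diploid|PM+CD31+Vim+"`.
#'
#' @param size_axis `"small"`, `"large"` or `"any"`.
#' @param ploidy_axis ploidy class.
#' @param pm,cd31,vim logical marker calls.
#' @return character vector of canonical strings.
#' @export
subtype_string <- function(size_axis, ploidy_axis, pm, cd31, vim) {
  paste0(size_axis, "|", ploidy_axis, "|",
         "PM", sign_chr(pm), "CD31", sign_chr(cd31), "Vim", sign_chr(vim))
}

#' Parse a canonical subtype string back to its components
#'
#' Inverse of [subtype_string()]; errors on strings that are not atlas
#' renderings.
#'
#' @param x character vector of canonical strings.
#' @return data.frame with columns `size_axis`, `ploidy_axis`, `pm`, `cd31`,
#'   `vim`.
#' @export
parse_subtype <- function(x) {
  m <- regmatches(x, regexec(
    "^(small|large|any)\\|(haploid|diploid|triploid|tetraploid|multiploid)\\|PM([+-])CD31([+-])Vim([+-])$",
    x))
  bad <- vapply(m, length, 1L) == 0
  assert_that(!any(bad), "not a canonical subtype string: ",
              paste(utils::head(x[bad], 3), collapse = ", "))
  data.frame(
    size_axis = vapply(m, `[`, "", 2),
    ploidy_axis = vapply(m, `[`, "", 3),
    pm = vapply(m, `[`, "", 4) == "+",
    cd31 = vapply(m, `[`, "", 5) == "+",
    vim = vapply(m, `[`, "", 6) == "+",
    stringsAsFactors = FALSE
  )
}

#' Enumerate the subtype atlas
#'
#' Returns the full, deterministically ordered leaf table: 64 aneuploid
#' leaves (small then large; within size, haploid, triploid, tetraploid,
#' multiploid; within ploidy, the 8 marker combinations in binary order with
#' PM as the most significant axis) followed by the 7 size-agnostic diploid
#' leaves that carry at least one positive marker. 71 rows in total, each
#' with a unique canonical string.
#'
#' @return data.frame with columns `index`, `size_axis`, `ploidy_axis`,
#'   `pm`, `cd31`, `vim`, `canonical_string`.
#' @export
enumerate_atlas <- function() {
  combos <- marker_combo_grid()
  aneu <- do.call(rbind, lapply(c("small", "large"), function(sz) {
    do.call(rbind, lapply(atlas_ploidy_order, function(pl) {
      data.frame(size_axis = sz, ploidy_axis = pl, combos,
                 stringsAsFactors = FALSE)
    }))
  }))
  dip <- combos[rowSums(combos) >= 1, ]
  dip <- data.frame(size_axis = "any", ploidy_axis = "diploid", dip,
                    stringsAsFactors = FALSE)
  atlas <- rbind(aneu, dip)
  atlas$canonical_string <- subtype_string(atlas$size_axis, atlas$ploidy_axis,
                                           atlas$pm, atlas$cd31, atlas$vim)
  data.frame(index = seq_len(nrow(atlas)), atlas, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- event classification ---------------------------------------------------

classification_categories <- c("atlas_leaf", "normal_wbc", "hematologic_crc",
                               "diploid_null", "qc_fail")

annotation_flags <- c("classical_CTC", "classical_CTEC", "EMT_CTC",
                      "mesenchymal_CTEC", "fusion_cluster", "CTM_member",
                      "stem_like", "endothelial_progenitor_like",
                      "naked_nuclei")

join_flags <- function(flag_mat) {
  apply(flag_mat, 1, function(r) paste(annotation_flags[r], collapse = ";"))
}

#' Classify events into atlas leaves and non-leaf categories
#'
#' Implements the published gating order. Small cells (<= WBC size) are
#' gated on the hemocyte marker first: a CD45+ cell that is chromosome-8
#' diploid (or QC-failed) with no lineage marker is a residual normal WBC,
#' while a CD45+ cell with aneuploidy or any of PM/CD31/Vim positive is a
#' hematologic circulating rare cell. Large cells (> WBC size) are gated on
#' ploidy first, then by the same CD45 rules — the resulting partition is
#' identical, so one vectorised rule set serves both branches. Remaining
#' CD45- events map to: an aneuploid atlas leaf (size x ploidy x marker
#' combination); the size-agnostic diploid leaf when at least one marker is
#' positive; `diploid_null` when diploid and marker-negative; `qc_fail` when
#' the CEP8 hybridisation failed (0 spots).
#'
#' Per-event annotation flags (reporting only, never used for counting):
#' `classical_CTC` / `classical_CTEC` (the Vim- textbook phenotypes),
#' `EMT_CTC` / `mesenchymal_CTEC` (the Vim+ variants), `stem_like`
#' (CD45- aneuploid stem-panel CD133+), `endothelial_progenitor_like`
#' (CD133+ CD31+ aneuploid), `naked_nuclei` (CD45- aneuploid with no
#' lineage marker), and `fusion_cluster` (clustered CD45- aneuploid
#' PM+CD31+Vim+). Cluster-level flags (`CTM_member`) are added by
#' [annotate_clusters()].
#'
#' @param events validated event data.frame.
#' @param ref [wbc_reference()] used when `size_class` is absent.
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return `events` with added columns `size_resolved`, `ploidy`, `category`,
#'   `leaf_canonical` (`NA` unless `category == "atlas_leaf"`) and
#'   `annotations` (semicolon-joined flags).
#' @export
classify_events <- function(events, ref = wbc_reference(),
                            aneuploid_min3 = FALSE) {
  events <- validate_events(events)
  n <- nrow(events)
  if (n == 0) {
    events$size_resolved <- character(0)
    events$ploidy <- character(0)
    events$category <- character(0)
    events$leaf_canonical <- character(0)
    events$annotations <- character(0)
    return(events)
  }
  size <- classify_size(events, ref)
  ploidy <- ploidy_call(events$cep8_spots)
  aneu <- is_aneuploid(ploidy, aneuploid_min3)
  any_marker <- events$pm | events$cd31 | events$vim
  ctc <- is_ctc(events, ploidy, aneuploid_min3)
  ctec <- is_ctec(events, ploidy, aneuploid_min3)
  cd133 <- cd133_positive(events)

  category <- rep(NA_character_, n)
  leaf <- rep(NA_character_, n)

  # CD45 gate (small cells: first; large cells: after the ploidy read-out —
  # same outcome either way because the rules are a pure function of the row)
  hema <- events$cd45 & (aneu | any_marker)
  wbc <- events$cd45 & !hema
  category[wbc] <- "normal_wbc"
  category[hema] <- "hematologic_crc"

  neg <- !events$cd45
  qc <- neg & ploidy == "qc_fail"
  category[qc] <- "qc_fail"
  on_leaf <- neg & !qc & aneu
  category[on_leaf] <- "atlas_leaf"
  leaf[on_leaf] <- subtype_string(size[on_leaf], ploidy[on_leaf],
                                  events$pm[on_leaf], events$cd31[on_leaf],
                                  events$vim[on_leaf])
  dip_leaf <- neg & !qc & !aneu & any_marker
  category[dip_leaf] <- "atlas_leaf"
  leaf[dip_leaf] <- subtype_string("any", "diploid", events$pm[dip_leaf],
                                   events$cd31[dip_leaf], events$vim[dip_leaf])
  category[neg & !qc & !aneu & !any_marker] <- "diploid_null"

  flags <- matrix(FALSE, n, length(annotation_flags),
                  dimnames = list(NULL, annotation_flags))
  flags[, "classical_CTC"] <- ctc & !events$vim
  flags[, "EMT_CTC"] <- ctc & events$vim
  flags[, "classical_CTEC"] <- ctec & !events$vim
  flags[, "mesenchymal_CTEC"] <- ctec & events$vim
  flags[, "stem_like"] <- !events$cd45 & aneu &
    events$panel == "stem_panel" & events$pm
  flags[, "endothelial_progenitor_like"] <- cd133 & events$cd31 & aneu
  flags[, "naked_nuclei"] <- !events$cd45 & aneu & !any_marker
  flags[, "fusion_cluster"] <- !is.na(events$cluster_id) & !events$cd45 &
    aneu & events$pm & events$cd31 & events$vim

  events$size_resolved <- size
  events$ploidy <- ploidy
  events$category <- category
  events$leaf_canonical <- leaf
  events$annotations <- join_flags(flags)
  events
}

#' Add cluster-level annotation flags
#'
#' Within every cluster of two or more events (shared non-missing
#' `cluster_id`) that contains at least one atlas-leaf or hematologic member,
#' all members gain `CTM_member` (circulating tumor microembolus membership).
#' Cluster members additionally gain `fusion_cluster` when CD45- aneuploid
#' PM+CD31+Vim+, `endothelial_progenitor_like` when CD133+CD31+ aneuploid,
#' and `naked_nuclei` when CD45- aneuploid with no lineage marker. Singleton
#' or unclustered events are returned unchanged.
#'
#' @param classified output of [classify_events()].
#' @param aneuploid_min3 passed to [is_aneuploid()].
#' @return `classified` with updated `annotations`.
#' @export
annotate_clusters <- function(classified, aneuploid_min3 = FALSE) {
  req <- c("category", "annotations", "cluster_id", "ploidy")
  assert_that(all(req %in% names(classified)),
              "annotate_clusters expects the output of classify_events")
  n <- nrow(classified)
  if (n == 0) return(classified)
  cl <- classified$cluster_id
  solo <- is.na(cl) | cl == ""
  cl[solo] <- paste0(".solo", seq_len(n))[solo]  # unique sentinel per row
  in_cluster <- !solo & ave(seq_len(n), cl, FUN = length) >= 2
  if (!any(in_cluster)) return(classified)

  aneu <- is_aneuploid(classified$ploidy, aneuploid_min3)
  any_marker <- classified$pm | classified$cd31 | classified$vim
  tumorish <- classified$category %in% c("atlas_leaf", "hematologic_crc")
  cluster_tumor <- as.logical(ave(tumorish, cl, FUN = any))

  flags <- matrix(FALSE, n, length(annotation_flags),
                  dimnames = list(NULL, annotation_flags))
  have <- strsplit(classified$annotations, ";", fixed = TRUE)
  for (i in seq_len(n)) flags[i, have[[i]][have[[i]] != ""]] <- TRUE

  flags[, "CTM_member"] <- flags[, "CTM_member"] |
    (in_cluster & cluster_tumor)
  flags[, "fusion_cluster"] <- flags[, "fusion_cluster"] |
    (in_cluster & !classified$cd45 & aneu & classified$pm &
       classified$cd31 & classified$vim)
  flags[, "endothelial_progenitor_like"] <-
    flags[, "endothelial_progenitor_like"] |
    (in_cluster & cd133_positive(classified) & classified$cd31 & aneu)
  flags[, "naked_nuclei"] <- flags[, "naked_nuclei"] |
    (in_cluster & !classified$cd45 & aneu & !any_marker)

  classified$annotations <- join_flags(flags)
  classified
}
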