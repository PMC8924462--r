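# TSV readers/writers for event tables and derived tables, plus the shipped
# published cohort-count table and JSON (de)serialisation of simulation
# parameters. All tables are tab-separated, UTF-8, Unix newlines; booleans
# are serialised as 0/1 and missing optional values as empty strings.

bool_cols <- c("cd45", "pm", "cd31", "vim", "cd133")

#' Read a per-cell event table
#'
#' Expects the exact mandatory columns of [event_columns()] (extra columns
#' are preserved and passed through). Malformed boolean or spot-count cells
#' are reported with their 1-based data row numbers; a missing mandatory
#' column is reported by name.
#'
#' @param path TSV file path.
#' @return validated event data.frame.
#' @export
read_events <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "")
  missing <- setdiff(event_columns(), names(raw))
  assert_that(length(missing) == 0, "event table missing mandatory column(s): ",
              paste(missing, collapse = ", "))
  n <- nrow(raw)
  blank <- function(x) is.na(x) | x == ""
  parse_fail <- function(bad, col) {
    assert_that(!any(bad), "unparseable ", col, " at row(s): ",
                paste(utils::head(which(bad), 5), collapse = ", "))
  }
  out <- raw
  for (col in bool_cols) {
    x <- raw[[col]]
    parse_fail(!(x %in% c("0", "1")), col)
    out[[col]] <- x == "1"
  }
  for (col in c("cep8_spots", "cep12_spots")) {
    x <- raw[[col]]
    v <- suppressWarnings(as.integer(x))
    ok_blank <- if (col == "cep12_spots") blank(x) else rep(FALSE, n)
    parse_fail(!ok_blank & (is.na(v) | as.character(v) != trimws(x)), col)
    v[ok_blank] <- NA_integer_
    out[[col]] <- v
  }
  d <- suppressWarnings(as.numeric(raw$diameter_um))
  parse_fail(!blank(raw$diameter_um) & is.na(d), "diameter_um")
  out$diameter_um <- d
  for (col in c("cluster_id", "size_class")) {
    out[[col]][blank(out[[col]])] <- NA_character_
  }
  extra <- setdiff(names(out), event_columns())
  out <- cbind(validate_events(out[, event_columns(), drop = FALSE]),
               out[, extra, drop = FALSE])
  out
}

#' Write a per-cell event table
#'
#' Inverse of [read_events()]: booleans become 0/1, `NA` optional values
#' become empty strings, column order is canonical (extra columns appended).
#' `write_events(read_events(p))` is the identity on valid tables.
#'
#' @param events event data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- cbind(validate_events(events[, event_columns(), drop = FALSE]),
                  events[, setdiff(names(events), event_columns()),
                         drop = FALSE])
  out <- events
  for (col in bool_cols) out[[col]] <- as.integer(out[[col]])
  write_tsv(out, path)
}

# shared TSV writer: NA -> "", no quoting, Unix newlines
write_tsv <- function(df, path) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), "",
                          format(df[[col]], trim = TRUE, scientific = FALSE))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Published cohort counts shipped with the package
#'
#' Per-disease-group patient totals and CTC-positive patient counts of the
#' published 2,360-patient cohort, shipped as a plain-text fixture; the
#' basis of the positivity arithmetic checks and of
#' [shipped_cohort_params()].
#'
#' @return data.frame with `disease_group`, `n_patients`, `n_positive`.
#' @export
shipped_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.tsv", package = "crcatlas",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", check.names = FALSE, quote = "",
             stringsAsFactors = FALSE)
}

#' Serialise / deserialise simulation parameters
#'
#' JSON round-trip for a named list of [cohort_params()]; field names in the
#' file mirror the constructor arguments exactly.
#'
#' @param params named list of `cohort_group_params`.
#' @param path JSON file path.
#' @return `write_params`: `path` invisibly; `read_params`: named list of
#'   `cohort_group_params`.
#' @export
write_params <- function(params, path) {
  plain <- lapply(params, function(p) {
    p <- unclass(p)
    p$marker_combo_freqs <- as.list(p$marker_combo_freqs)
    p$ploidy_freqs <- as.list(p$ploidy_freqs)
    p
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(plain, function(p) {
    cohort_params(
      positivity = p$positivity, target_median = p$target_median,
      dispersion = p$dispersion,
      marker_combo_freqs = unlist(p$marker_combo_freqs),
      ploidy_freqs = unlist(p$ploidy_freqs),
      p_di8_aneu12 = p$p_di8_aneu12, wbc_background = p$wbc_background,
      dual_probe = p$dual_probe
    )
  })
}
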