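# End-to-end pipeline (simulate -> classify -> aggregate -> stats ->
# dualprobe) and a small subcommand CLI, so the whole analysis can be driven
# from Rscript with files piped between stages.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed for simulation.
#' @param n_patients passed to [generate_cohort()].
#' @param params named list of [cohort_params()] or a JSON path for
#'   [read_params()]; default [shipped_cohort_params()].
#' @param events_path optional existing event TSV; skips the simulate stage.
#' @param wbc_reference_um small/large boundary, micrometres.
#' @param aneuploid_min3 restrict aneuploidy to >= 3 copies.
#' @param paired_ttest paired (default) vs Welch probe comparison.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_patients = 50,
                       params = shipped_cohort_params(), events_path = NULL,
                       wbc_reference_um = 10, aneuploid_min3 = FALSE,
                       paired_ttest = TRUE) {
  if (is.character(params)) params <- read_params(params)
  structure(list(out_dir = out_dir, seed = seed, n_patients = n_patients,
                 params = params, events_path = events_path,
                 wbc_reference_um = wbc_reference_um,
                 aneuploid_min3 = aneuploid_min3,
                 paired_ttest = paired_ttest),
            class = "run_config")
}

log_stage <- function(stage, ...) message("[", stage, "] ", ...)

write_patients_tsv <- function(patients, path) {
  flat <- patients
  flat$subtype_histogram <- vapply(patients$subtype_histogram, function(h) {
    paste(sprintf("%s:%d", names(h), h), collapse = ";")
  }, "")
  flat$ctc_positive <- as.integer(flat$ctc_positive)
  write_tsv(flat, path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing one TSV per stage into
#' `config$out_dir`: `events.tsv` (simulated unless `events_path` is given),
#' `labeled.tsv` (classification + cluster annotation), `patients.tsv`,
#' `groups.tsv` (per-group summaries; the Kruskal-Wallis line is logged),
#' and, when the events carry CEP12 counts, `probe_summary.tsv` with the
#' probe-comparison statistics logged. Every stage logs its record counts;
#' any stage error propagates with the stage name prefixed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the stage outputs (`events`, `labeled`,
#'   `patients`, `groups`, `kw`, `probe`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  events <- stage("simulate", {
    if (!is.null(config$events_path)) {
      ev <- read_events(config$events_path)
    } else {
      ev <- generate_cohort(config$params, config$n_patients, config$seed)
      write_events(ev, file.path(config$out_dir, "events.tsv"))
    }
    log_stage("simulate", nrow(ev), " events in")
    ev
  })
  labeled <- stage("classify", {
    lab <- classify_events(events, wbc_reference(config$wbc_reference_um),
                           config$aneuploid_min3)
    lab <- annotate_clusters(lab, config$aneuploid_min3)
    if (nrow(lab) == 0) warning("classify: empty event table")
    write_events(lab, file.path(config$out_dir, "labeled.tsv"))
    log_stage("classify", nrow(lab), " events labeled")
    lab
  })
  patients <- stage("aggregate", {
    p <- aggregate_patients(labeled, config$aneuploid_min3)
    write_patients_tsv(p, file.path(config$out_dir, "patients.tsv"))
    log_stage("aggregate", nrow(p), " patients out")
    p
  })
  gs <- kw <- NULL
  if (nrow(patients) > 0) {
    res <- stage("stats", group_summary(patients))
    gs <- res$groups
    kw <- res$kw
    write_tsv(gs, file.path(config$out_dir, "groups.tsv"))
    if (!is.null(kw)) {
      log_stage("stats", sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g",
                                 kw$H, kw$df, kw$p))
    }
  }
  probe <- NULL
  if (nrow(labeled) > 0 && any(!is.na(labeled$cep12_spots))) {
    probe <- stage("dualprobe", {
      s <- probe_patient_summaries(labeled, config$aneuploid_min3)
      cmp <- probe_totals_comparison(s, paired = config$paired_ttest)
      out <- s
      out$has_di8_aneu12 <- as.integer(out$has_di8_aneu12)
      write_tsv(out, file.path(config$out_dir, "probe_summary.tsv"))
      log_stage("dualprobe", sprintf(
        "median8 = %.1f, median12 = %.1f, t = %.3f, p = %.3g, fn_rate = %.4f",
        cmp$median8, cmp$median12, cmp$t, cmp$p, single_probe_fn_rate(s)))
      list(summaries = s, comparison = cmp,
           fn_rate = single_probe_fn_rate(s))
    })
  }
  invisible(list(events = events, labeled = labeled, patients = patients,
                 groups = gs, kw = kw, probe = probe))
}

# ---- command-line interface --------------------------------------------------

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  assert_that(i[1] < length(args), "missing value for ", flag)
  args[i[1] + 1]
}

#' Subcommand CLI entry point
#'
#' `crc_cli(c("simulate", "--n", "50", "--seed", "1", "-o", "events.tsv"))`
#' etc. Subcommands: `simulate` (`--params` JSON optional, default shipped),
#' `classify` (`<events.tsv> -o labeled.tsv`), `aggregate`
#' (`<labeled.tsv> -o patients.tsv`), `stats` (`<patients.tsv> -o groups.tsv`),
#' `dualprobe` (`<labeled.tsv> -o probe_summary.tsv`), `atlas`
#' (`export -o atlas.tsv`), `run` (`--out-dir DIR --n N --seed S`). Invoked
#' by the `inst/cli/crc` Rscript wrapper.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
crc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    assert_that(length(args) >= 1, "usage: crc <subcommand> [options]")
    cmd <- args[1]
    rest <- args[-1]
    out <- cli_opt(rest, "-o", cli_opt(rest, "--out"))
    seed <- as.integer(cli_opt(rest, "--seed", "1"))
    pos <- rest[!rest %in% c("-o", "--out", "--seed", "--n", "--params",
                             "--out-dir") &
                  !seq_along(rest) %in% (which(rest %in%
                    c("-o", "--out", "--seed", "--n", "--params",
                      "--out-dir")) + 1)]
    if (cmd == "simulate") {
      params <- cli_opt(rest, "--params")
      params <- if (is.null(params)) shipped_cohort_params()
                else read_params(params)
      n <- as.integer(cli_opt(rest, "--n", "50"))
      write_events(generate_cohort(params, n, seed), out)
    } else if (cmd == "classify") {
      lab <- annotate_clusters(classify_events(read_events(pos[1])))
      write_events(lab, out)
    } else if (cmd == "aggregate") {
      write_patients_tsv(aggregate_patients(read_events(pos[1])), out)
    } else if (cmd == "stats") {
      pat <- read.delim(pos[1], sep = "\t", quote = "", check.names = FALSE)
      pat$ctc_positive <- pat$ctc_positive == 1
      res <- group_summary(pat)
      write_tsv(res$groups, out)
      if (!is.null(res$kw)) {
        log_stage("stats", sprintf("H = %.3f, df = %d, p = %.3g",
                                   res$kw$H, res$kw$df, res$kw$p))
      }
    } else if (cmd == "dualprobe") {
      s <- probe_patient_summaries(read_events(pos[1]))
      cmp <- probe_totals_comparison(s)
      s$has_di8_aneu12 <- as.integer(s$has_di8_aneu12)
      write_tsv(s, out)
      log_stage("dualprobe", sprintf(
        "median8 = %.1f, median12 = %.1f, t = %.3f, p = %.3g, fn_rate = %.4f",
        cmp$median8, cmp$median12, cmp$t, cmp$p,
        mean(s$has_di8_aneu12)))
    } else if (cmd == "atlas") {
      assert_that(identical(pos[1], "export"), "usage: crc atlas export -o F")
      write_tsv(enumerate_atlas(), out)
    } else if (cmd == "run") {
      cfg <- run_config(out_dir = cli_opt(rest, "--out-dir", "."),
                        seed = seed,
                        n_patients = as.integer(cli_opt(rest, "--n", "50")))
      run_pipeline(cfg)
    } else {
      abort("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
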