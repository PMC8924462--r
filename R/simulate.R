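# Seeded synthetic cohort generator: a hurdle negative-binomial count model
# per disease group plus per-cell marker-combination and ploidy sampling,
# with optional dual-probe (CEP8+CEP12) read-outs and patient-level probe
# discordance injection.

marker_combo_names <- function() {
  g <- marker_combo_grid()
  paste0("PM", sign_chr(g$pm), "CD31", sign_chr(g$cd31), "Vim", sign_chr(g$vim))
}

#' Default per-cell marker-combination frequencies
#'
#' Invented defaults encoding the qualitative picture of SE-iFISH cohorts:
#' endothelial-feature (CD31+) combinations carry most of the mass (0.55
#' total), epithelial/tumor-marker-positive combinations are rare (0.10
#' total), and triple-negative "naked" phenotypes get 0.15. These are
#' placeholder frequencies for simulation, not measured data.
#'
#' @return named 8-vector summing to 1, in [marker_combo_grid()] order.
#' @export
default_marker_freqs <- function() {
  setNames(c(0.15, 0.22, 0.35, 0.18, 0.04, 0.04, 0.01, 0.01),
           marker_combo_names())
}

#' Default chromosome-8 ploidy-class frequencies among rare cells
#'
#' Trisomy-dominated aneuploidy with a minority of diploid (marker-positive)
#' cells; invented simulation defaults.
#'
#' @return named 5-vector over haploid/diploid/triploid/tetraploid/multiploid.
#' @export
default_ploidy_freqs <- function() {
  c(haploid = 0.05, diploid = 0.10, triploid = 0.45, tetraploid = 0.20,
    multiploid = 0.20)
}

#' Parameters for one simulated disease group
#'
#' @param positivity fraction of patients with a nonzero rare-cell count.
#' @param target_median target median of the per-patient CTC+CTEC total
#'   among the pipeline's output (cells per 6 ml draw).
#' @param dispersion negative-binomial size parameter of the positive count
#'   branch (smaller = heavier tail); default 1.5.
#' @param marker_combo_freqs named 8-vector over PM/CD31/Vim combinations.
#' @param ploidy_freqs named 5-vector over ploidy classes.
#' @param p_di8_aneu12 patient-level probability of carrying >= 1
#'   CEP8-diploid / CEP12-aneuploid CD45- cell (dual-probe groups only).
#' @param wbc_background Poisson mean of residual CD45+ WBC events.
#' @param dual_probe emit CEP12 spot counts for every event?
#' @return validated list of class `cohort_group_params`.
#' @export
cohort_params <- function(positivity, target_median, dispersion = 1.5,
                          marker_combo_freqs = default_marker_freqs(),
                          ploidy_freqs = default_ploidy_freqs(),
                          p_di8_aneu12 = 0, wbc_background = 8,
                          dual_probe = FALSE) {
  assert_that(positivity >= 0 && positivity <= 1,
              "positivity must be in [0,1]")
  assert_that(target_median >= 0, "target_median must be >= 0")
  assert_that(dispersion > 0, "dispersion must be > 0")
  assert_that(length(marker_combo_freqs) == 8 &&
                abs(sum(marker_combo_freqs) - 1) < 1e-9 &&
                all(marker_combo_freqs >= 0),
              "marker_combo_freqs must be 8 non-negative values summing to 1")
  assert_that(length(ploidy_freqs) == 5 &&
                abs(sum(ploidy_freqs) - 1) < 1e-9 && all(ploidy_freqs >= 0),
              "ploidy_freqs must be 5 non-negative values summing to 1")
  assert_that(p_di8_aneu12 >= 0 && p_di8_aneu12 <= 1,
              "p_di8_aneu12 must be in [0,1]")
  assert_that(wbc_background >= 0, "wbc_background must be >= 0")
  if (positivity > 0) {
    aneu_mass <- sum(ploidy_freqs[c("haploid", "triploid", "tetraploid",
                                    "multiploid")])
    assert_that(aneu_mass > 0,
                "ploidy_freqs must give aneuploid classes nonzero mass")
  }
  structure(list(positivity = positivity, target_median = target_median,
                 dispersion = dispersion,
                 marker_combo_freqs = marker_combo_freqs,
                 ploidy_freqs = ploidy_freqs, p_di8_aneu12 = p_di8_aneu12,
                 wbc_background = wbc_background, dual_probe = dual_probe),
            class = "cohort_group_params")
}

#' Fit the hurdle count model for one group
#'
#' The per-patient rare-cell total is modelled as a hurdle: 0 with
#' probability `1 - positivity`, otherwise `1 + NegBin(size = dispersion,
#' mu)`. `mu` is chosen by a deterministic grid search so that the analytic
#' median of the mixture equals `round(target_median)`; the analytic median
#' of the integer mixture is `1 + qnbinom(q, size, mu)` with
#' `q = (0.5 - (1 - positivity)) / positivity`, the smallest integer whose
#' mixture CDF reaches 0.5. A positive target median is infeasible when
#' `positivity <= 0.5` (the zero mass alone pins the median at 0), and a
#' zero target is infeasible when `positivity > 0.5` (every positive draw is
#' >= 1). When the median is unconstrained (target 0, positivity <= 0.5)
#' `mu` defaults to 5.
#'
#' @param positivity,target_median,dispersion see [cohort_params()].
#' @return list with `p_pos`, `mu`, `size`, `analytic_median`.
#' @export
fit_count_model <- function(positivity, target_median, dispersion = 1.5) {
  assert_that(positivity >= 0 && positivity <= 1 && target_median >= 0 &&
                dispersion > 0, "invalid count-model parameters")
  M <- as.integer(round_half_up(target_median, 0))
  if (positivity == 0) {
    return(list(p_pos = 0, mu = 0, size = dispersion, analytic_median = 0L))
  }
  if (M > 0 && positivity <= 0.5) {
    abort("infeasible (positivity, median) pair: zero-inflation ",
          positivity, " forces the mixture median to 0")
  }
  if (M == 0 && positivity > 0.5) {
    abort("infeasible (positivity, median) pair: positivity > 0.5 forces ",
          "a mixture median >= 1")
  }
  if (M == 0) {
    return(list(p_pos = positivity, mu = 5, size = dispersion,
                analytic_median = 0L))
  }
  q <- (0.5 - (1 - positivity)) / positivity
  grid <- seq(0.01, 500, by = 0.01)
  med <- 1L + qnbinom(q, size = dispersion, mu = grid)
  hit <- which(med == M)
  assert_that(length(hit) > 0,
              "no NegBin mean on the search grid attains median ", M)
  mu <- mean(range(grid[hit]))  # midpoint of the feasible mean interval
  list(p_pos = positivity, mu = mu, size = dispersion, analytic_median = M)
}

# sample ploidy classes; optionally restricted (renormalised) to aneuploid
sample_ploidy <- function(n, freqs, aneuploid_only = FALSE) {
  if (aneuploid_only) freqs["diploid"] <- 0
  names(freqs)[sample.int(5, n, replace = TRUE, prob = freqs)]
}

spots_for_ploidy <- function(classes) {
  base <- c(haploid = 1L, diploid = 2L, triploid = 3L, tetraploid = 4L)
  out <- unname(base[classes])
  multi <- is.na(out)
  out[multi] <- sample(5:8, sum(multi), replace = TRUE)
  out
}

aneuploid_spots <- function(n, freqs) {
  spots_for_ploidy(sample_ploidy(n, freqs, aneuploid_only = TRUE))
}

#' Generate a synthetic multi-group cohort of cell events
#'
#' For every patient (independent RNG substream derived from
#' `rng_substream(seed, group, patient_index)`, so generation is
#' reproducible and order-independent): the rare-cell total is drawn from
#' the group's fitted hurdle model; each cell receives a marker combination
#' from `marker_combo_freqs` and a ploidy class from `ploidy_freqs`, with
#' CD31+ or fully marker-negative cells restricted to aneuploid classes so
#' that every generated rare cell satisfies the CTC or CTEC predicate and
#' the drawn total is recovered by the classify/aggregate pipeline; the
#' first cell of a positive patient is drawn from the CD31- combinations so
#' that count positivity coincides with CTC positivity. Spot counts encode
#' the ploidy class (multiploid uniform on 5..8). Residual leukocytes are
#' added as Poisson(`wbc_background`) CD45+ diploid events. In dual-probe
#' groups every event also carries a CEP12 count (concordant-aneuploid with
#' probability 0.6, else diploid; WBCs diploid), and with patient-level
#' probability `p_di8_aneu12` one extra CD45- CEP8-diploid/CEP12-aneuploid
#' tumor-marker-positive cell is injected.
#'
#' @param params named list of [cohort_params()], one per disease group.
#' @param n_patients named integer vector (names must be a subset of
#'   `names(params)`), or a single unnamed count applied to every group.
#' @param seed integer master seed.
#' @return validated event data.frame (header-only when all counts are 0).
#' @export
generate_cohort <- function(params, n_patients, seed) {
  assert_that(is.list(params) && length(names(params)) == length(params),
              "params must be a named list of cohort_params()")
  if (is.null(names(n_patients)) && length(n_patients) == 1) {
    n_patients <- setNames(rep(n_patients, length(params)), names(params))
  }
  assert_that(all(names(n_patients) %in% names(params)),
              "n_patients names must match params: ",
              paste(setdiff(names(n_patients), names(params)), collapse = ", "))
  cols <- c("patient_id", "cluster_id", "cd45", "pm", "cd31", "vim",
            "diameter_um", "cep8_spots", "cep12_spots")
  acc <- list()
  for (g in names(n_patients)) {
    pp <- params[[g]]
    assert_that(inherits(pp, "cohort_group_params"),
                "params[['", g, "']] is not cohort_params()")
    n_g <- n_patients[[g]]
    if (n_g == 0) next
    model <- fit_count_model(pp$positivity, pp$target_median, pp$dispersion)
    combos <- marker_combo_grid()
    ctc_combos <- which(!combos$cd31)  # candidate first-cell combinations
    for (i in seq_len(n_g)) {
      set.seed(rng_substream(seed, g, i))
      pid <- sprintf("%s_P%04d", gsub("[^A-Za-z0-9]+", "_", g), i)
      total <- if (runif(1) < model$p_pos) {
        1L + rnbinom(1, size = model$size, mu = model$mu)
      } else 0L
      pm <- cd31 <- vim <- logical(0)
      cep8 <- integer(0)
      if (total > 0) {
        idx <- integer(total)
        w1 <- pp$marker_combo_freqs[ctc_combos]
        idx[1] <- ctc_combos[sample.int(length(ctc_combos), 1, prob = w1)]
        if (total > 1) {
          idx[-1] <- sample.int(8, total - 1, replace = TRUE,
                                prob = pp$marker_combo_freqs)
        }
        pm <- combos$pm[idx]
        cd31 <- combos$cd31[idx]
        vim <- combos$vim[idx]
        # diploid chromosome 8 is only compatible with the CTC predicate via
        # a positive tumor marker; all other cells must be aneuploid
        forced <- cd31 | (!cd31 & !pm)
        pl <- character(total)
        if (any(forced)) {
          pl[forced] <- sample_ploidy(sum(forced), pp$ploidy_freqs, TRUE)
        }
        if (any(!forced)) {
          pl[!forced] <- sample_ploidy(sum(!forced), pp$ploidy_freqs, FALSE)
        }
        cep8 <- spots_for_ploidy(pl)
      }
      n_crc <- length(cep8)
      n_wbc <- rpois(1, pp$wbc_background)
      cd45 <- c(rep(FALSE, n_crc), rep(TRUE, n_wbc))
      pm <- c(pm, rep(FALSE, n_wbc))
      cd31 <- c(cd31, rep(FALSE, n_wbc))
      vim <- c(vim, rep(FALSE, n_wbc))
      cep8 <- c(cep8, rep(2L, n_wbc))
      diam <- c(pmax(5, rnorm(n_crc, 13.5, 3)), pmax(5, rnorm(n_wbc, 10, 1)))
      cep12 <- rep(NA_integer_, n_crc + n_wbc)
      if (pp$dual_probe) {
        conc <- runif(n_crc) < 0.6
        cep12[seq_len(n_crc)][conc] <-
          aneuploid_spots(sum(conc), pp$ploidy_freqs)
        cep12[seq_len(n_crc)][!conc] <- 2L
        if (n_wbc > 0) cep12[n_crc + seq_len(n_wbc)] <- 2L
        if (runif(1) < pp$p_di8_aneu12) {
          cd45 <- c(cd45, FALSE); pm <- c(pm, TRUE)
          cd31 <- c(cd31, FALSE); vim <- c(vim, FALSE)
          cep8 <- c(cep8, 2L)
          cep12 <- c(cep12, aneuploid_spots(1, pp$ploidy_freqs))
          diam <- c(diam, pmax(5, rnorm(1, 13.5, 3)))
        }
      }
      n_ev <- length(cep8)
      if (n_ev == 0) next
      acc[[length(acc) + 1]] <- list(
        patient_id = rep(pid, n_ev), disease_group = rep(g, n_ev),
        cd45 = cd45, pm = pm, cd31 = cd31, vim = vim,
        diameter_um = round(diam, 1), cep8_spots = cep8, cep12_spots = cep12
      )
    }
  }
  if (length(acc) == 0) {
    return(new_events(patient_id = character(0), cep8_spots = integer(0)))
  }
  pull <- function(nm) unlist(lapply(acc, `[[`, nm), use.names = FALSE)
  pid <- pull("patient_id")
  new_events(
    patient_id = pid,
    sample_id = "S1",
    disease_group = pull("disease_group"),
    event_id = paste0(pid, "_E", stats::ave(seq_along(pid), pid,
                                            FUN = seq_along)),
    panel = "tumor_panel", panel_marker_name = "EpCAM",
    cd45 = pull("cd45"), pm = pull("pm"), cd31 = pull("cd31"),
    vim = pull("vim"), cd133 = FALSE,
    diameter_um = pull("diameter_um"),
    cep8_spots = pull("cep8_spots"), cep12_spots = pull("cep12_spots")
  )
}

#' Shipped per-group simulation parameters
#'
#' One [cohort_params()] entry per published disease group, with the
#' printed CTC positivity of each group and the printed group medians where
#' the source reports them (infectious diseases 22.00, pancreatic cancer
#' 19.00, maxillofacial tumors 7.00, gastric 14.00, colorectal and ampulla
#' 15.00); all remaining groups get a neutral default median of 8. A
#' `codetection` pseudo-group configures the dual-probe simulation: CEP8
#' aneuploid-cell median 12 (its ploidy frequencies carry no diploid mass,
#' so the per-patient CEP8-aneuploid total equals the drawn count) and
#' patient-level probe-discordance probability 0.5727.
#'
#' @return named list of `cohort_group_params`.
#' @export
shipped_cohort_params <- function() {
  tab <- shipped_cohort_counts()
  med <- c("Infectious diseases" = 22, "Pancreatic cancer" = 19,
           "Maxillofacial tumors" = 7, "Gastric cancer" = 14,
           "Colorectal cancer" = 15, "Ampulla cancer" = 15)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- tab$disease_group[i]
    cohort_params(
      positivity = tab$n_positive[i] / tab$n_patients[i],
      target_median = if (g %in% names(med)) med[[g]] else 8
    )
  })
  names(out) <- tab$disease_group
  codet_ploidy <- c(haploid = 0.05, diploid = 0, triploid = 0.50,
                    tetraploid = 0.22, multiploid = 0.23)
  out$codetection <- cohort_params(
    positivity = 0.95, target_median = 12, ploidy_freqs = codet_ploidy,
    p_di8_aneu12 = 0.5727, dual_probe = TRUE
  )
  out
}
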