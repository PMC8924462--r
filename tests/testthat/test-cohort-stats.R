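# cohort_stats: aggregation, positivity, Kruskal-Wallis, group summaries

classified <- function(...) classify_events(new_events(...))

test_that("aggregate_patient counts predicate hits and excludes QC failures", {
  # one CTEC-style event (CD45- CD31+ AFP+ aneuploid)
  got <- aggregate_patient(classified(
    "P1", panel_marker_name = "AFP", pm = TRUE, cd31 = TRUE,
    cep8_spots = 5, diameter_um = 13))
  expect_equal(got$n_ctec, 1)
  expect_equal(got$n_ctc, 0)
  expect_equal(got$n_total_ctc_ctec, 1)
  expect_false(got$ctc_positive)

  # 2 CTCs + 1 WBC + 1 QC failure: totals count CTCs only
  got <- aggregate_patient(classified(
    rep("P1", 4), cd45 = c(FALSE, FALSE, TRUE, FALSE),
    pm = c(TRUE, TRUE, FALSE, TRUE),
    cep8_spots = c(3, 2, 2, 0), diameter_um = 9))
  expect_equal(got$n_ctc, 2)
  expect_equal(got$n_total_ctc_ctec, 2)
  expect_true(got$ctc_positive)
  expect_equal(got$subtype_histogram[[1]],
               c("any|diploid|PM+CD31-Vim-" = 1L,
                 "small|triploid|PM+CD31-Vim-" = 1L))

  # empty list -> all-zero summary
  got <- aggregate_patient(classify_events(new_events(character(0))))
  expect_equal(got$n_total_ctc_ctec, 0)
  expect_false(got$ctc_positive)

  expect_error(aggregate_patient(classified(c("P1", "P2"), diameter_um = 9)),
               "mixed patient_ids")
})

test_that("aggregation is invariant to event and patient permutation", {
  set.seed(3)
  n <- 120
  ev <- new_events(
    patient_id = sample(sprintf("P%02d", 1:12), n, TRUE),
    cd45 = sample(c(TRUE, FALSE), n, TRUE),
    pm = sample(c(TRUE, FALSE), n, TRUE),
    cd31 = sample(c(TRUE, FALSE), n, TRUE),
    cep8_spots = sample(0:6, n, TRUE), diameter_um = runif(n, 6, 18)
  )
  a <- aggregate_patients(classify_events(ev))
  b <- aggregate_patients(classify_events(ev[sample(n), ]))
  b <- b[match(a$patient_id, b$patient_id), ]
  rownames(b) <- NULL
  expect_equal(a[, setdiff(names(a), "subtype_histogram")],
               b[, setdiff(names(b), "subtype_histogram")])
})

test_that("positivity_rate reproduces printed-style percentages", {
  mk <- function(pos, n) data.frame(ctc_positive = seq_len(n) <= pos)
  expect_equal(positivity_rate(mk(350, 373)), 93.8)
  expect_equal(positivity_rate(mk(2157, 2360)), 91.4)
  expect_equal(positivity_rate(mk(0, 50)), 0.0)
  expect_error(positivity_rate(mk(0, 0)), "non-empty")

  # brute-force count/divide oracle on 1,000 random cohorts
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    flags <- sample(c(TRUE, FALSE), n, TRUE)
    got <- positivity_rate(data.frame(ctc_positive = flags))
    expect_identical(got, round_half_up(sum(flags) / n * 100, 1))
  }
})

test_that("kruskal_wallis matches hand-derived values", {
  got <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(got$H, 7.2)
  expect_equal(got$df, 2)
  expect_equal(got$p, pchisq(7.2, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$H, 0)

  # monotone transforms leave H unchanged
  g <- list(c(3, 1, 4, 1), c(5, 9, 2), c(6, 5, 3, 5))
  expect_equal(kruskal_wallis(lapply(g, exp))$H, kruskal_wallis(g)$H)

  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("kruskal_wallis agrees with the explicit-sorting oracle on 200 tied instances", {
  set.seed(19)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) sample(0:6, sample(2:12, 1), TRUE))
    if (length(unique(unlist(groups))) < 2) next
    got <- kruskal_wallis(groups)
    expect_equal(got$H, oracle_kruskal(groups), tolerance = 1e-9)
    # and with the reference implementation in stats
    ref <- kruskal.test(unlist(groups),
                        rep(seq_len(k), lengths(groups)))
    expect_equal(got$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("group_summary reports medians, positivity and the overall test", {
  pat <- data.frame(
    patient_id = sprintf("P%d", 1:10),
    disease_group = rep(c("g1", "g2"), each = 5),
    n_ctc = c(2, 0, 5, 1, 3, 0, 0, 1, 2, 0),
    n_ctec = 0,
    n_total_ctc_ctec = c(22, 22, 25, 19, 30, 1, 0, 3, 2, 0),
    ctc_positive = c(TRUE, FALSE, TRUE, TRUE, TRUE,
                     FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  res <- group_summary(pat)
  expect_equal(res$groups$median_total, c(22.00, 1.00))
  expect_equal(res$groups$positivity_pct, c(80.0, 40.0))
  expect_equal(res$groups$n_positive, c(4, 2))
  expect_false(is.null(res$kw))

  # even-n median: mean of the central order statistics, to 2 decimals
  one <- group_summary(pat[1:4, ])
  expect_equal(one$groups$median_total, 22.00)

  # disjoint supports across two groups: decisive H
  pat2 <- data.frame(patient_id = sprintf("Q%d", 1:21),
                     disease_group = rep(c("a", "b"), c(10, 11)),
                     n_ctc = 1, n_ctec = 0,
                     n_total_ctc_ctec = c(1:10, 100:110),
                     ctc_positive = TRUE)
  expect_lt(group_summary(pat2)$kw$p, 0.05)

  # single group: medians still reported, test skipped with a notice
  expect_message(res1 <- group_summary(pat[pat$disease_group == "g1", ]),
                 "skipped")
  expect_null(res1$kw)
  expect_equal(res1$groups$median_total, 22.00)
})
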