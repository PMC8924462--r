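# events_model: ploidy calling, size gate, CTC/CTEC predicates

test_that("ploidy_call maps spot counts to classes and is a total partition", {
  expect_equal(ploidy_call(c(2, 3, 7, 0)),
               c("diploid", "triploid", "multiploid", "qc_fail"))
  expect_equal(ploidy_call(c(1, 4, 5, 100)),
               c("haploid", "tetraploid", "multiploid", "multiploid"))

  # totality + monotone boundaries on 0..50: exactly one class per count,
  # class changes only at 1, 2, 3, 4, 5
  counts <- 0:50
  classes <- ploidy_call(counts)
  expect_false(anyNA(classes))
  expect_true(all(classes %in%
    c("qc_fail", "haploid", "diploid", "triploid", "tetraploid", "multiploid")))
  boundaries <- counts[-1][classes[-1] != classes[-length(classes)]]
  expect_equal(boundaries, 1:5)

  expect_error(ploidy_call(-1), "non-negative")
  expect_error(ploidy_call(2.5), "non-negative integers")
})

test_that("aneuploidy excludes diploid and qc_fail; min3 switch tightens it", {
  pl <- ploidy_call(0:6)
  expect_equal(is_aneuploid(pl),
               c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(is_aneuploid(pl, aneuploid_min3 = TRUE),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("classify_size honours the WBC boundary and explicit size_class", {
  ev <- new_events(patient_id = "P1", diameter_um = c(10.0, 14.2, 14.2),
                   size_class = c(NA, NA, "small"))
  expect_equal(classify_size(ev), c("small", "large", "small"))

  # direct-comparison oracle on 1,000 random (diameter, ref) pairs
  set.seed(42)
  d <- runif(1000, 4, 25)
  refs <- runif(1000, 8, 14)
  got <- vapply(seq_along(d), function(i) {
    classify_size(new_events("P", diameter_um = d[i]), wbc_reference(refs[i]))
  }, "")
  expect_equal(got, ifelse(d <= refs, "small", "large"))
})

test_that("CTC and CTEC predicates follow the phenotype definitions", {
  # CD45- CD31- Vim+ EpCAM+ triploid: an EMT CTC, still a CTC
  ev <- new_events("P1", cd45 = FALSE, cd31 = FALSE, vim = TRUE, pm = TRUE,
                   cep8_spots = 3, diameter_um = 8)
  expect_true(is_ctc(ev))
  expect_false(is_ctec(ev))

  # hematologic gate: CD45+ is never a CTC/CTEC
  ev$cd45 <- TRUE
  expect_false(is_ctc(ev))
  expect_false(is_ctec(ev))

  # no marker, no aneuploidy -> nothing
  ev <- new_events("P1", cep8_spots = 2, diameter_um = 8)
  expect_false(is_ctc(ev))
  expect_false(is_ctec(ev))

  # marker-negative but aneuploid CD45-/CD31- cell is a CTC
  ev <- new_events("P1", cep8_spots = 4, diameter_um = 8)
  expect_true(is_ctc(ev))

  # CD45- CD31+ AFP+ aneuploid -> CTEC; mesenchymal (Vim+) variant too
  ev <- new_events("P1", panel_marker_name = "AFP", pm = TRUE, cd31 = TRUE,
                   cep8_spots = 5, diameter_um = 12)
  expect_true(is_ctec(ev))
  ev2 <- new_events("P1", pm = FALSE, cd31 = TRUE, vim = TRUE,
                    cep8_spots = 3, diameter_um = 12)
  expect_true(is_ctec(ev2))

  # aneuploidy required for CTEC
  ev3 <- new_events("P1", cd31 = TRUE, cep8_spots = 2, diameter_um = 12)
  expect_false(is_ctec(ev3))

  # stem-panel events are outside the CTC (tumor-panel) definition
  ev4 <- new_events("P1", panel = "stem_panel", panel_marker_name = "CD133",
                    pm = TRUE, cep8_spots = 3, diameter_um = 12)
  expect_false(is_ctc(ev4))
})

test_that("is_ctc and is_ctec are mutually exclusive on a random sweep", {
  set.seed(7)
  n <- 500
  ev <- new_events(
    patient_id = "P", cd45 = sample(c(TRUE, FALSE), n, TRUE),
    pm = sample(c(TRUE, FALSE), n, TRUE),
    cd31 = sample(c(TRUE, FALSE), n, TRUE),
    vim = sample(c(TRUE, FALSE), n, TRUE),
    panel = sample(c("tumor_panel", "stem_panel"), n, TRUE),
    panel_marker_name = "CD133",
    cep8_spots = sample(0:8, n, TRUE), diameter_um = runif(n, 5, 20)
  )
  expect_false(any(is_ctc(ev) & is_ctec(ev)))
})

test_that("event validation enforces the schema invariants", {
  expect_error(new_events("P1", cep8_spots = -1), "non-negative")
  expect_error(new_events("P1", diameter_um = NA, size_class = NA),
               "diameter_um / size_class")
  expect_error(new_events("P1", panel = "stem_panel",
                          panel_marker_name = "EpCAM", diameter_um = 9),
               "CD133")
  expect_error(new_events("P1", size_class = "medium", diameter_um = NA),
               "size_class")
  ev <- new_events("P1", diameter_um = 9)
  expect_error(validate_events(ev[, -which(names(ev) == "cep8_spots")]),
               "cep8_spots")
})
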