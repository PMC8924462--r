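# atlas_classifier: enumeration, event classification, cluster annotation

test_that("the atlas has 71 unique leaves with the expected factorisation", {
  atlas <- enumerate_atlas()
  expect_equal(nrow(atlas), 71)
  expect_false(anyDuplicated(atlas$canonical_string) > 0)
  expect_equal(sum(atlas$ploidy_axis != "diploid"), 64)  # 2 x 4 x 8
  expect_equal(sum(atlas$ploidy_axis == "diploid"), 7)   # >= 1 marker
  expect_true("large|triploid|PM+CD31-Vim-" %in% atlas$canonical_string)
  # diploid leaves are size-agnostic and never fully marker-negative
  dip <- atlas[atlas$ploidy_axis == "diploid", ]
  expect_true(all(dip$size_axis == "any"))
  expect_true(all(dip$pm | dip$cd31 | dip$vim))
})

test_that("canonical strings round-trip through parse_subtype", {
  atlas <- enumerate_atlas()
  parsed <- parse_subtype(atlas$canonical_string)
  expect_equal(parsed$size_axis, atlas$size_axis)
  expect_equal(parsed$ploidy_axis, atlas$ploidy_axis)
  expect_equal(parsed$pm, atlas$pm)
  expect_equal(parsed$cd31, atlas$cd31)
  expect_equal(parsed$vim, atlas$vim)
  expect_error(parse_subtype("large|pentaploid|PM+CD31-Vim-"), "canonical")
})

test_that("classification agrees with the branch-by-branch oracle on the 224-case grid", {
  g <- feature_grid()
  expect_equal(nrow(g), 224)
  got <- classify_events(grid_events(g))
  want_cat <- vapply(seq_len(nrow(g)), function(i) {
    oracle_classify(g$size[i], g$cd45[i], g$spots[i], g$pm[i], g$cd31[i],
                    g$vim[i])
  }, "")
  expect_equal(got$category, want_cat)

  # every leaf is in the atlas and matches the oracle's leaf rendering
  atlas <- enumerate_atlas()$canonical_string
  on_leaf <- which(got$category == "atlas_leaf")
  expect_true(all(got$leaf_canonical[on_leaf] %in% atlas))
  expect_true(all(is.na(got$leaf_canonical[-on_leaf])))
  want_leaf <- vapply(on_leaf, function(i) {
    oracle_leaf(g$size[i], g$spots[i], g$pm[i], g$cd31[i], g$vim[i])
  }, "")
  expect_equal(got$leaf_canonical[on_leaf], want_leaf)
})

test_that("worked examples classify as published", {
  ref <- wbc_reference()
  # large multiploid PM+(EpCAM) CD31+ Vim+ clustered: fusion cluster leaf
  ev <- new_events("P1", cluster_id = "cl1", pm = TRUE, cd31 = TRUE,
                   vim = TRUE, cep8_spots = 6, diameter_um = 16)
  got <- classify_events(ev, ref)
  expect_equal(got$leaf_canonical, "large|multiploid|PM+CD31+Vim+")
  expect_match(got$annotations, "fusion_cluster")

  # diploid CK18+ CD31+ Vim+ cell: the size-agnostic diploid leaf
  ev <- new_events("P1", panel_marker_name = "CK18", pm = TRUE, cd31 = TRUE,
                   vim = TRUE, cep8_spots = 2, diameter_um = 12)
  expect_equal(classify_events(ev, ref)$leaf_canonical,
               "any|diploid|PM+CD31+Vim+")

  # small CD45+ diploid marker-negative: residual leukocyte
  ev <- new_events("P1", cd45 = TRUE, cep8_spots = 2, diameter_um = 8)
  expect_equal(classify_events(ev, ref)$category, "normal_wbc")

  # large CD45+ triploid CK18+ CD31+: hematologic rare cell
  ev <- new_events("P1", cd45 = TRUE, panel_marker_name = "CK18", pm = TRUE,
                   cd31 = TRUE, cep8_spots = 3, diameter_um = 15)
  expect_equal(classify_events(ev, ref)$category, "hematologic_crc")

  # aneuploid stem-panel CD133+ cell: leaf + stem_like flag
  ev <- new_events("P1", panel = "stem_panel", panel_marker_name = "CD133",
                   pm = TRUE, cep8_spots = 3, diameter_um = 12)
  got <- classify_events(ev, ref)
  expect_equal(got$category, "atlas_leaf")
  expect_match(got$annotations, "stem_like")
})

test_that("classical/EMT annotation flags are consistent with the predicates", {
  g <- feature_grid()
  ev <- grid_events(g)
  got <- classify_events(ev)
  flags <- strsplit(got$annotations, ";", fixed = TRUE)
  has <- function(f) vapply(flags, function(x) f %in% x, TRUE)
  expect_equal(has("classical_CTC") | has("EMT_CTC"), is_ctc(ev))
  expect_equal(has("classical_CTEC") | has("mesenchymal_CTEC"), is_ctec(ev))
  expect_equal(has("EMT_CTC"), is_ctc(ev) & ev$vim)
  expect_equal(has("naked_nuclei"),
               !ev$cd45 & is_aneuploid(got$ploidy) & !ev$pm & !ev$cd31 & !ev$vim)
})

test_that("cluster annotation adds CTM and cluster-phenotype flags", {
  # two clustered CD45- aneuploid CD133+CD31+ cells: endothelial-progenitor
  # cluster, both CTM members
  ev <- new_events(c("P1", "P1"), cluster_id = "c1", panel = "stem_panel",
                   panel_marker_name = "CD133", pm = TRUE, cd31 = TRUE,
                   cep8_spots = c(3, 4), diameter_um = 12)
  got <- annotate_clusters(classify_events(ev))
  expect_true(all(grepl("endothelial_progenitor_like", got$annotations)))
  expect_true(all(grepl("CTM_member", got$annotations)))

  # null microembolus: clustered aneuploid triple-negative cells
  ev <- new_events(c("P1", "P1", "P1"), cluster_id = "c2",
                   cep8_spots = 3, diameter_um = 9)
  got <- annotate_clusters(classify_events(ev))
  expect_true(all(grepl("naked_nuclei", got$annotations)))
  expect_true(all(grepl("CTM_member", got$annotations)))

  # singleton: annotations unchanged
  ev <- new_events("P1", pm = TRUE, cep8_spots = 3, diameter_um = 9)
  cls <- classify_events(ev)
  expect_identical(annotate_clusters(cls)$annotations, cls$annotations)

  # a cluster of only normal WBCs is not a CTM
  ev <- new_events(c("P1", "P1"), cluster_id = "c3", cd45 = TRUE,
                   cep8_spots = 2, diameter_um = 9)
  got <- annotate_clusters(classify_events(ev))
  expect_false(any(grepl("CTM_member", got$annotations)))

  expect_error(annotate_clusters(data.frame(x = 1)), "classify_events")
})
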