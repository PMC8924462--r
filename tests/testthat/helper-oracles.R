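# Independent oracles. These re-derive expected results along different code
# paths from the package (scalar branch-by-branch rules, explicit sorting)
# and must stay independent of the implementations they check.

# Scalar classification oracle: the published gate order written as literal
# branches. Small cells: hemocyte-marker gate first. Large cells: ploidy
# read-out first, then the same CD45 rules.
oracle_classify <- function(size, cd45, spots, pm, cd31, vim) {
  aneuploid <- spots >= 1 && spots != 2
  any_marker <- pm || cd31 || vim
  cd45_gate <- function() {
    if (aneuploid || any_marker) "hematologic_crc" else "normal_wbc"
  }
  cd45_negative <- function() {
    if (spots == 0) return("qc_fail")
    if (aneuploid) return("atlas_leaf")
    if (any_marker) return("atlas_leaf")  # size-agnostic diploid leaf
    "diploid_null"
  }
  if (size == "small") {
    if (cd45) cd45_gate() else cd45_negative()
  } else {
    # ploidy first: the read-out precedes the CD45 gate but feeds the same
    # rules, so the branch structure differs while the partition agrees
    if (spots == 0) {
      if (cd45) cd45_gate() else "qc_fail"
    } else if (cd45) {
      cd45_gate()
    } else {
      cd45_negative()
    }
  }
}

oracle_leaf <- function(size, spots, pm, cd31, vim) {
  cls <- c("1" = "haploid", "3" = "triploid", "4" = "tetraploid")
  s <- function(b) if (b) "+" else "-"
  mk <- paste0("PM", s(pm), "CD31", s(cd31), "Vim", s(vim))
  if (spots == 2) return(paste0("any|diploid|", mk))
  pl <- if (spots >= 5) "multiploid" else cls[[as.character(spots)]]
  paste0(size, "|", pl, "|", mk)
}

# Kruskal-Wallis oracle with ranks computed by explicit sorting: the rank of
# x_i is the mean position of its value in the sorted pooled sample.
oracle_kruskal <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  sorted <- sort(x)
  r <- vapply(x, function(v) mean(which(sorted == v)), 0)
  g <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  runs <- rle(sorted)$lengths
  C <- 1 - sum(runs^3 - runs) / (N^3 - N)
  H / C
}

# 224-case feature grid: 2 sizes x 2 CD45 x spot counts 0..6 x 8 marker combos
feature_grid <- function() {
  expand.grid(size = c("small", "large"), cd45 = c(FALSE, TRUE),
              spots = 0:6, pm = c(FALSE, TRUE), cd31 = c(FALSE, TRUE),
              vim = c(FALSE, TRUE), stringsAsFactors = FALSE)
}

grid_events <- function(g) {
  new_events(
    patient_id = sprintf("P%03d", seq_len(nrow(g))),
    cd45 = g$cd45, pm = g$pm, cd31 = g$cd31, vim = g$vim,
    size_class = g$size, cep8_spots = g$spots
  )
}
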