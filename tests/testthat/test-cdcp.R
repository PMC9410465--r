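test_that("fit_counts matches a brute-force recount and conserves deaths", {
  fx <- three_record_fixture()
  cts <- fit_counts(fx)
  expect_equal(cts$death["X10", "G2:male"], 2L)
  expect_equal(cts$death["Y20", "G2:male"], 1L)
  expect_equal(cts$occur["X10", "G2:male"], 2L)
  expect_equal(cts$occur["Y20", "G2:male"], 2L)
  expect_equal(cts$total_records, 3L)
  # conservation: deaths over all causes and strata == number of records
  expect_equal(sum(cts$death), nrow(fx))

  # brute-force oracle on a generated registry
  reg <- small_registry(n = 150, seed = 3)
  cts <- fit_counts(reg)
  oracle <- brute_counts(reg)
  for (key in names(oracle$occur)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(cts$occur[parts[1], parts[2]], oracle$occur[[key]],
                 ignore_attr = TRUE)
  }
  for (key in names(oracle$death)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(cts$death[parts[1], parts[2]], oracle$death[[key]],
                 ignore_attr = TRUE)
  }
  expect_equal(sum(cts$death), nrow(reg))
  expect_true(all(cts$death <= cts$occur))
})

test_that("empty and unlabeled inputs are handled", {
  empty <- small_registry(10)[0, ]
  cts <- fit_counts(empty)
  expect_equal(sum(cts$occur), 0)
  expect_equal(cts$total_records, 0L)

  bad <- small_registry(5)
  bad$underlying[3] <- NA
  expect_error(fit_counts(bad), bad$id[3])
})

test_that("regional death cause proportions are normalized ratios", {
  reg <- small_registry(n = 200, seed = 9)
  cts <- fit_counts(reg)
  # direct ratio
  expect_equal(rdcp(cts, "A41.9", "north"),
               sum(reg$underlying == "A41.9" & reg$region == "north") /
                 sum(reg$region == "north"))
  # sum over causes in one region is 1
  tot <- sum(vapply(rownames(cts$region_underlying),
                    function(c) rdcp(cts, c, "south"), 0))
  expect_equal(tot, 1)
  # absent cause -> 0; unknown region -> error
  expect_equal(rdcp(cts, "Z99", "north"), 0)
  expect_error(rdcp(cts, "A41.9", "atlantis"), "atlantis")
})

test_that("cdcp is the bits-scaled smoothed count ratio", {
  causes <- c("Q10", "Q20", "Q30")
  # ratio 1 (death == occur), ratio 0.1 ((9+1)/(99+1)), unseen (0/0)
  cts <- mk_counts(causes, occur_s = c(50L, 99L, 0L), death_s = c(50L, 9L, 0L))
  m <- cdcp_model(cts, smoothing = 1)
  expect_equal(cdcp(m, "Q10", "G2", "male"), log2(10))
  expect_equal(cdcp(m, "Q20", "G2", "male"), 0, tolerance = 1e-9)
  expect_equal(cdcp(m, "Q30", "G2", "male"), log2(10))
  # a code outside the table behaves like the unseen cell
  expect_equal(cdcp(m, "Z99", "G2", "male"), log2(10))
})

test_that("cdcp recovers the unsmoothed ratio as smoothing vanishes", {
  cts <- mk_counts(c("Q10", "Q20"), occur_s = c(40L, 80L),
                   death_s = c(10L, 60L))
  m <- cdcp_model(cts, smoothing = 1e-9)
  expect_equal(cdcp(m, "Q10", "G2", "male"), log2(10 * 10 / 40),
               tolerance = 1e-6)
  expect_equal(cdcp(m, "Q20", "G2", "male"), log2(10 * 60 / 80),
               tolerance = 1e-6)
})

test_that("cdcp is monotone in the counts", {
  base <- function(d, o) {
    m <- cdcp_model(mk_counts("Q10", as.integer(o), as.integer(d)))
    cdcp(m, "Q10", "G2", "male")
  }
  # non-decreasing in deaths at fixed occurrences
  v <- vapply(0:20, base, 0, o = 20)
  expect_true(all(diff(v) >= 0))
  # non-increasing in occurrences at fixed deaths
  v <- vapply(5:40, function(o) base(5, o), 0)
  expect_true(all(diff(v) <= 0))
})

test_that("occurrence weights follow the damped log-frequency scheme", {
  # occ_totals {9, 99}: damped weight log(10)/log(100) = 0.5 for the rare one
  cts <- mk_counts(c("R10", "R20"), occur_s = c(9L, 99L), death_s = c(9L, 99L))
  m <- cdcp_model(cts, weight_scheme = "damped")
  expect_equal(m$weights[["R10"]], log(10) / log(100))
  expect_equal(m$weights[["R20"]], 1)  # the most frequent cause anchors at 1
  expect_equal(weighted_cdcp(m, "R20", "G2", "male"),
               pmax(cdcp(m, "R20", "G2", "male"), 0))
  # a cause with no occurrences anywhere gets weight 0
  expect_equal(weighted_cdcp(m, "Z99", "G2", "male"), 0)

  m_rel <- cdcp_model(cts, weight_scheme = "relative")
  expect_equal(m_rel$weights[["R10"]], 9 / 99)
  m_none <- cdcp_model(cts, weight_scheme = "none")
  expect_equal(unname(m_none$weights), c(1, 1))
})

test_that("negative cdcp scores are floored before weighting", {
  # death 0 of 999 occurrences: raw cdcp is negative
  cts <- mk_counts("R10", 999L, 0L)
  m <- cdcp_model(cts)
  expect_lt(cdcp(m, "R10", "G2", "male"), 0)
  expect_equal(weighted_cdcp(m, "R10", "G2", "male"), 0)
})

test_that("counts_table enforces its invariants", {
  occur <- matrix(1L, 1, 6, dimnames = list("Q10", STRATA))
  death <- matrix(2L, 1, 6, dimnames = list("Q10", STRATA))
  expect_error(counts_table(occur, death), "exceeds")
  ru <- matrix(3L, 1, 1, dimnames = list("Q10", "r1"))
  expect_error(counts_table(occur, occur, ru, c(r1 = 5)), "region")
})
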