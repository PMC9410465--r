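# 3-cause toy universe with closed-form structure for oracle cross-checks
toy_config <- function(p_E = 0, p_offchain = 0, length_dist = c(0, 1, 0, 0)) {
  causes <- c("A00", "B00", "C00")
  u <- matrix(rep(c(0.6, 0.4, 0), 6), nrow = 3,
              dimnames = list(causes, STRATA))
  t_ <- matrix(0, 3, 3, dimnames = list(causes, causes))
  t_["A00", c("B00", "C00")] <- c(0.7, 0.3)
  t_["B00", "C00"] <- 1
  generator_config(causes, u, t_, length_dist = length_dist,
                   p_E = p_E, p_offchain = p_offchain)
}

test_that("configuration invariants are enforced", {
  cfg <- default_generator_config()
  expect_silent(validate_generator_config(cfg))
  bad <- cfg; bad$underlying[1, 1] <- bad$underlying[1, 1] + 0.5
  expect_error(validate_generator_config(bad), "sum to 1")
  bad <- cfg
  bad$transitions[2, ] <- 0; bad$transitions[2, 1] <- 1  # backward edge
  expect_error(validate_generator_config(bad), "acyclic")
  bad <- cfg; bad$p_offchain <- 1.5
  expect_error(validate_generator_config(bad), "0, 1")
  expect_error(sample_records(bad, 10), "0, 1")
})

test_that("sampling is reproducible and respects the requested size", {
  cfg <- default_generator_config()
  reg <- sample_records(cfg, 1000, seed = 4)
  expect_equal(nrow(reg$records), 1000)
  expect_true(all(!is.na(reg$records$underlying)))
  reg2 <- sample_records(cfg, 1000, seed = 4)
  expect_identical(as.data.frame(reg$records), as.data.frame(reg2$records))
  expect_identical(reg$truth, reg2$truth)
  expect_false(identical(as.data.frame(reg$records),
                         as.data.frame(sample_records(cfg, 1000, seed = 5)$records)))
  # the label always matches the generative trace
  expect_identical(reg$records$underlying, reg$truth$label)
})

test_that("with p_offchain = 0 the label is the earliest antecedent", {
  cfg <- default_generator_config(p_offchain = 0)
  reg <- sample_records(cfg, 500, seed = 6)
  long <- chain_long(reg$records, include_e = FALSE)
  earliest <- vapply(split(long$code, long$row), function(v) v[length(v)], "")
  expect_identical(unname(earliest), reg$records$underlying)
  expect_true(all(!reg$truth$relabeled))
})

test_that("chains are grown forward through the transition graph", {
  cfg <- default_generator_config()
  reg <- sample_records(cfg, 400, seed = 8)
  ord <- match(cfg$causes, cfg$causes)  # topological order = index order
  long <- chain_long(reg$records, include_e = FALSE)
  # certificate order A (direct) first; reversing gives the causal path,
  # which must be strictly increasing in topological index
  for (chain in split(long$code, long$row)) {
    path <- rev(match(chain, cfg$causes))
    expect_true(all(diff(path) > 0))
  }
  # E is never on the Part I chain of its own record
  has_e <- !is.na(reg$records$cause_E)
  p1 <- as.matrix(reg$records[paste0("cause_", c("A", "B", "C", "D"))])
  clash <- rowSums(p1 == reg$records$cause_E, na.rm = TRUE) > 0
  expect_false(any(clash[has_e]))
})

test_that("the exact conditional ratio oracle handles degenerate universes", {
  # a cause that can only ever be the seed (no incoming edges, no E, no
  # relabeling) is always the label when it occurs
  cfg <- toy_config()
  expect_equal(true_cdcp_ratio(cfg, "A00", "G2", "male"), 1)
  # C00 is never the seed and never relabeled: conditional ratio 0
  expect_equal(true_cdcp_ratio(cfg, "C00", "G2", "male"), 0)
  expect_error(true_cdcp_ratio(cfg, "Z99", "G2", "male"), "universe")
})

test_that("enumeration agrees with closed-form and Monte Carlo oracles", {
  # length-2 chains, p_E = 0, p_offchain = 0.5: B00 occurs as seed (0.4) or
  # as successor of A00 (0.6 * 0.7); it is the label when seeded and kept
  # (0.5) or when a seeded A00->B00 chain is relabeled (0.5)
  cfg <- toy_config(p_offchain = 0.5)
  p_occ <- 0.4 + 0.6 * 0.7
  # seeded B00 chain is B00->C00: relabel candidate {C00}, so B00 keeps its
  # label with prob 0.5; a seeded A00->B00 chain relabels to B00 with prob 0.5
  p_lab <- 0.4 * 0.5 + 0.6 * 0.7 * 0.5
  exact <- p_lab / p_occ
  expect_equal(true_cdcp_ratio(cfg, "B00", "G1", "female"), exact)
  # Monte Carlo cross-check within 3 sigma of the binomial error
  mc <- true_cdcp_ratio(cfg, "B00", "G1", "female", method = "mc",
                        mc_samples = 2e5, seed = 11)
  p_stratum <- 0.30 * (1 - cfg$p_male)  # G1, female
  sigma <- sqrt(exact * (1 - exact) / (2e5 * p_stratum * p_occ))
  expect_lt(abs(mc - exact), 3 * sigma)
})

test_that("empirical underlying-cause frequencies match the configuration", {
  cfg <- default_generator_config()
  reg <- sample_records(cfg, 50000, seed = 1)
  strat <- paste(age_group(reg$records$age), reg$records$gender, sep = ":")
  # chi-square GOF of the seeded underlying causes against the configured
  # stratified distribution, conditional on the drawn strata
  n_strat <- table(factor(strat, levels = STRATA))
  expected <- as.vector(cfg$underlying %*% as.numeric(n_strat))
  observed <- as.vector(table(factor(reg$truth$seeded_underlying,
                                     levels = cfg$causes)))
  stat <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(stat, df = length(cfg$causes) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("fitted count ratios recover the generator's true conditionals", {
  cfg <- default_generator_config()
  reg <- sample_records(cfg, 20000, seed = 3)
  cts <- fit_counts(reg$records)
  checked <- 0
  for (cause in c("C22.0", "J18.9", "A41.9", "I25.1")) {
    for (s in c("G2:male", "G2:female", "G1:male")) {
      if (cts$occur[cause, s] >= 200) {
        est <- cts$death[cause, s] / cts$occur[cause, s]
        tru <- true_cdcp_ratio(cfg, cause, sub(":.*", "", s), sub(".*:", "", s))
        expect_lt(abs(est - tru), 0.05)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 5)
})

test_that("the worked certificate fixtures are faithful", {
  fx <- fixture_cases()
  expect_equal(nrow(fx), 2)
  # case 1: four Part I causes, labeled with the mid-chain aspiration
  # pneumonia, not the chain-initiating liver cancer
  expect_equal(unname(unlist(fx[1, paste0("cause_", c("A", "B", "C", "D"))])),
               c("A41.9", "J18.9", "J69.0", "C22.0"))
  expect_equal(fx$underlying[1], "J69.0")
  # case 2: the drug allergy, not the earliest antecedent (J18.9)
  expect_equal(fx$underlying[2], "T88.7")
  expect_false(fx$underlying[2] == fx$cause_D[2])
  expect_true(all(fx$label_in_chain))
  # durations decay toward the direct cause
  expect_true(all(diff(unlist(fx[1, paste0("dur_", c("A", "B", "C", "D"))])) > 0))
})
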