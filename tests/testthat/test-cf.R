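test_that("alignment matches codes across positions (dimension transposition)", {
  # identical chains in reversed order: everything matches
  al <- align_chains(c("I10", "I25.1", "I21.9"), c("I21.9", "I25.1", "I10"))
  expect_equal(nrow(al$matched), 3)
  expect_length(al$unmatched_a, 0)
  # disjoint code sets: nothing matches
  al <- align_chains(c("I10", "I25.1"), c("J18.9", "A41.9"))
  expect_equal(nrow(al$matched), 0)
  expect_equal(al$unmatched_b, 1:2)
  # duplicated codes match up to the multiset intersection
  al <- align_chains(c("I10", "I10", "J18.9"), c("I10", "C22.0"))
  expect_equal(nrow(al$matched), 1)
  # matched pairs always carry equal codes and are one-to-one
  a <- c("I10", "J18.9", "I10"); b <- c("I10", "I10", "I10")
  al <- align_chains(a, b)
  expect_equal(a[al$matched[, 1]], b[al$matched[, 2]])
  expect_false(any(duplicated(al$matched[, 1])))
  expect_false(any(duplicated(al$matched[, 2])))
})

test_that("alignment cardinality equals the exhaustive-search optimum", {
  # random chains up to length 5 (the certificate cap incl. E) over a tiny
  # alphabet rich in collisions
  codes <- c("A00", "A01", "A02")
  set.seed(101)
  for (i in 1:300) {
    a <- sample(codes, sample(1:5, 1), replace = TRUE)
    b <- sample(codes, sample(1:5, 1), replace = TRUE)
    expect_equal(nrow(align_chains(a, b)$matched), brute_align_max(a, b))
  }
})

test_that("similarity reproduces the hand-computed weighted Jaccard", {
  m <- hand_sim_model()
  # shared cause scores 2 in both records' strata, unique causes 1 each:
  # sim = 2 / (2 + 1 + 1) = 0.5
  ra <- death_record("a", 70, "male", c(A = "S00", B = "U01"))
  rb <- death_record("b", 70, "male", c(A = "S00", B = "U02"))
  expect_equal(similarity(m, ra, rb)$value, 0.5)
  # self-similarity 1 with positive weight; disjoint chains 0
  expect_equal(similarity(m, ra, ra)$value, 1)
  ru <- death_record("c", 70, "male", c(A = "U02"))
  expect_equal(similarity(m, ra, ru)$value, 0)
})

test_that("all-zero weights fall back to the unweighted Jaccard index", {
  # occur without ever being the underlying cause: weighted CDCP 0 everywhere
  cts <- mk_counts(c("U01", "U02"), c(99L, 99L), c(0L, 0L))
  m <- cdcp_model(cts)
  ra <- death_record("a", 70, "male", c(A = "U01", B = "U02"))
  rb <- death_record("b", 70, "male", c(A = "U01"))
  expect_equal(similarity(m, ra, rb)$value, 1 / 2)
})

test_that("similarity axioms hold on random record pairs", {
  reg <- small_registry(n = 500, seed = 17)
  m <- cdcp_model(fit_counts(reg))
  set.seed(99)
  idx <- matrix(sample.int(nrow(reg), 400, replace = TRUE), ncol = 2)
  for (r in seq_len(nrow(idx))) {
    a <- reg[idx[r, 1], ]; b <- reg[idx[r, 2], ]
    sab <- similarity(m, a, b)$value
    sba <- similarity(m, b, a)$value
    expect_equal(sab, sba)            # symmetry
    expect_gte(sab, 0); expect_lte(sab, 1)
  }
  # self-similarity 1
  for (i in sample.int(nrow(reg), 25)) {
    expect_equal(similarity(m, reg[i, ], reg[i, ])$value, 1)
  }
})

test_that("similarity is invariant to chain-internal transposition", {
  reg <- small_registry(n = 400, seed = 23)
  m <- cdcp_model(fit_counts(reg))
  a <- death_record("a", 70, "male",
                    c(A = "R57.0", B = "A41.9", C = "J18.9"))
  a_perm <- death_record("a", 70, "male",
                         c(A = "J18.9", B = "R57.0", C = "A41.9"))
  set.seed(7)
  for (i in sample.int(nrow(reg), 50)) {
    expect_equal(similarity(m, a, reg[i, ])$value,
                 similarity(m, a_perm, reg[i, ])$value)
  }
})

test_that("neighbor retrieval is ranked, thresholded and deterministic", {
  m <- hand_sim_model()
  lib_records <- death_records(rbind(
    death_record("n1", 70, "male", c(A = "S00", B = "U01"), underlying = "S00"),
    death_record("n2", 70, "male", c(A = "S00", B = "U02"), underlying = "S00"),
    death_record("n3", 70, "male", c(A = "S00"), underlying = "S00"),
    death_record("n4", 70, "male", c(A = "U02"), underlying = "U02"),
    death_record("n5", 70, "male", c(A = "U01", B = "U02"), underlying = "U01")))
  lib <- case_library(lib_records)
  query <- death_record("q", 70, "male", c(A = "S00", B = "U01"))

  # oracle: score every case with similarity() and sort (sim desc, id asc)
  sims <- vapply(seq_len(nrow(lib_records)), function(i)
    similarity(m, query, lib_records[i, ])$value, 0)
  ord <- order(-sims, lib_records$id)

  nb <- retrieve_neighbors(lib, m, query, k = 2, min_sim = 0)
  expect_equal(nb$id, lib_records$id[ord[1:2]])
  expect_equal(nb$sim, sims[ord[1:2]])

  # exact duplicate of the query comes first with similarity 1
  expect_equal(nb$id[1], "n1")
  expect_equal(nb$sim[1], 1)

  # min_sim filters; empty library yields an empty result
  nb2 <- retrieve_neighbors(lib, m, query, k = 10, min_sim = 0.9)
  expect_true(all(nb2$sim >= 0.9))
  empty <- case_library(lib_records[0, ])
  expect_equal(nrow(retrieve_neighbors(empty, m, query, k = 3)), 0)

  # exclusion by id removes the self-match
  nb3 <- retrieve_neighbors(lib, m, query, k = 5, min_sim = 0,
                            exclude_ids = "n1")
  expect_false("n1" %in% nb3$id)
})

test_that("cf_infer takes a similarity-weighted, chain-restricted vote", {
  query <- death_record("q", 70, "male", c(A = "S00", B = "U01"))
  nb <- data.frame(case = 1:2, id = c("a", "b"),
                   label = c("S00", "U01"), sim = c(0.9, 0.1),
                   stringsAsFactors = FALSE)
  expect_equal(cf_infer(nb, query), "S00")
  # single neighbor
  expect_equal(cf_infer(nb[2, ], query), "U01")
  # no neighbors: abstain
  expect_true(is.na(cf_infer(nb[0, ], query)))
  # neighbor labels outside the query chain: vote becomes unrestricted
  nb_out <- data.frame(case = 1:2, id = c("a", "b"),
                       label = c("Z98", "Z99"), sim = c(0.2, 0.7),
                       stringsAsFactors = FALSE)
  expect_equal(cf_infer(nb_out, query), "Z99")
  # tie on summed similarity: higher best single-neighbor similarity wins
  nb_tie <- data.frame(case = 1:3, id = c("a", "b", "c"),
                       label = c("S00", "U01", "U01"), sim = c(0.5, 0.25, 0.25),
                       stringsAsFactors = FALSE)
  expect_equal(cf_infer(nb_tie, query), "S00")
})
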