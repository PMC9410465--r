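# shared fixtures and independent oracles

STRATA <- as.vector(outer(c("G0", "G1", "G2"), c("male", "female"),
                          function(g, s) paste(g, s, sep = ":")))

# counts_table with all-zero region info and the six stratum columns
mk_counts <- function(causes, occur_s, death_s, stratum = "G2:male") {
  occur <- matrix(0L, length(causes), 6, dimnames = list(causes, STRATA))
  death <- occur
  occur[, stratum] <- occur_s
  death[, stratum] <- death_s
  counts_table(occur, death, total_records = sum(death_s))
}

# three labeled records over codes X10/Y20, one stratum
three_record_fixture <- function() {
  death_records(rbind(
    death_record("r1", 70, "male", c(A = "X10"), underlying = "X10"),
    death_record("r2", 70, "male", c(A = "X10", B = "Y20"), underlying = "X10"),
    death_record("r3", 70, "male", c(A = "Y20"), underlying = "Y20")))
}

# brute-force recount of occur/death per (cause, stratum): loops over
# records, independent of fit_counts internals
brute_counts <- function(records) {
  strata <- paste(age_group(records$age), records$gender, sep = ":")
  occur <- list(); death <- list()
  for (i in seq_len(nrow(records))) {
    codes <- unlist(records[i, paste0("cause_", c("A", "B", "C", "D", "E"))])
    codes <- unique(c(codes[!is.na(codes)], records$underlying[i]))
    for (code in codes) {
      key <- paste(code, strata[i])
      occur[[key]] <- (occur[[key]] %||% 0) + 1
    }
    key <- paste(records$underlying[i], strata[i])
    death[[key]] <- (death[[key]] %||% 0) + 1
  }
  list(occur = occur, death = death)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive maximum matching between equal-code positions: tries every
# injective position map
brute_align_max <- function(a, b) {
  best <- 0L
  lb <- length(b)
  rec <- function(i, usedb, cnt) {
    if (cnt + (length(a) - i + 1) <= best) return()
    if (i > length(a)) {
      best <<- max(best, cnt)
      return()
    }
    rec(i + 1L, usedb, cnt)
    for (j in seq_len(lb)) {
      if (!usedb[j] && b[j] == a[i]) {
        usedb[j] <- TRUE
        rec(i + 1L, usedb, cnt + 1L)
        usedb[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, lb), 0L)
  best
}

# model over codes S00 (shared), U01/U02 (unique), with unit weights and
# integer CDCP scores: S00 -> 2, U01/U02 -> 1 (weight scheme "none")
hand_sim_model <- function() {
  causes <- c("S00", "U01", "U02")
  cdcp_model(mk_counts(causes, occur_s = c(9L, 9L, 9L),
                       death_s = c(3L, 1L, 1L)),
             weight_scheme = "none")
}

# small random labeled registry for property tests
small_registry <- function(n = 300, seed = 42, p_offchain = 0.2) {
  sample_records(default_generator_config(p_offchain = p_offchain), n,
                 seed = seed)$records
}
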