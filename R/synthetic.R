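## Synthetic mortality-registry generator.
##
## Emulates the statistical structure Sink-CF assumes: each death starts
## from an underlying cause U drawn from a stratified (age group x gender)
## categorical distribution, progresses forward through an acyclic
## cause-to-cause transition matrix to the direct cause, may pick up an
## off-chain contributing cause E, and — with probability p_offchain — has
## its adjudicated label moved from the earliest antecedent to a mid-chain
## cause or to E (the certificates where the chain start is NOT the
## underlying cause, the regime the CF strategy exists for). Because the
## transition graph is acyclic and chains are short, the ground-truth
## conditional death-cause proportion P(label = i | i on chain) is exactly
## enumerable, giving an analytic oracle for parameter-recovery tests.

#' Construct a generator configuration
#'
#' @param causes Character vector of ICD-10 codes, in topological order of
#'   the progression graph (transitions only flow toward later entries).
#' @param underlying Matrix `[cause, stratum]` of underlying-cause
#'   probabilities per age-gender stratum; columns must sum to 1.
#' @param transitions Row-stochastic matrix `[cause, cause]` of progression
#'   probabilities; each row sums to 1 (or to 0 for a terminal cause) and
#'   may only place mass on strictly later causes (acyclic).
#' @param length_dist Probabilities of drawn chain length 1..4. A path
#'   reaching a terminal cause early stops there, so realized length can be
#'   shorter than drawn.
#' @param p_E Probability of attaching a contributing cause E, drawn
#'   uniformly from causes not on the Part I chain.
#' @param p_offchain Probability that the adjudicated label is moved off
#'   the earliest antecedent, uniformly to one of the other chain causes or
#'   E.
#' @param age_group_probs Probabilities of the three age groups.
#' @param age_ranges List of `c(lo, hi)` integer age ranges per group.
#' @param p_male Probability of gender `"male"`.
#' @param regions Character vector of region identifiers.
#' @param region_probs Sampling probabilities of the regions.
#' @param duration_base_min Base duration in minutes by distance from the
#'   direct cause (position 1 = direct); durations decay toward the direct
#'   cause and carry lognormal jitter.
#' @return A validated `generator_config`.
#' @export
generator_config <- function(causes, underlying, transitions,
                             length_dist = c(0.10, 0.30, 0.35, 0.25),
                             p_E = 0.3, p_offchain = 0.2,
                             age_group_probs = c(G0 = 0.05, G1 = 0.30, G2 = 0.65),
                             age_ranges = list(G0 = c(0, 17), G1 = c(18, 54),
                                               G2 = c(55, 95)),
                             p_male = 0.52,
                             regions = c("north", "central", "south"),
                             region_probs = c(0.5, 0.3, 0.2),
                             duration_base_min = c(120, 2880, 43200, 525600)) {
  causes <- validate_code(causes)
  cfg <- structure(list(
    causes = causes, underlying = underlying, transitions = transitions,
    length_dist = length_dist, p_E = p_E, p_offchain = p_offchain,
    age_group_probs = age_group_probs, age_ranges = age_ranges,
    p_male = p_male, regions = regions, region_probs = region_probs,
    duration_base_min = duration_base_min), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants: distributions sum to one (tolerance
#' 1e-9), the transition matrix is row-stochastic (or zero for terminal
#' causes) and strictly upper-triangular in the cause order (acyclic), and
#' probabilities lie in \[0, 1\].
#'
#' @param config A `generator_config`.
#' @return Invisibly `config`; errors name the violated invariant.
#' @export
validate_generator_config <- function(config) {
  tol <- 1e-9
  nc <- length(config$causes)
  if (anyDuplicated(config$causes)) stop("duplicate causes", call. = FALSE)
  u <- config$underlying
  if (!is.matrix(u) || nrow(u) != nc ||
      !identical(colnames(u), all_strata()) ||
      !identical(rownames(u), config$causes)) {
    stop("underlying must be a [cause, stratum] matrix with rows in cause ",
         "order and the six stratum columns", call. = FALSE)
  }
  if (any(u < 0) || any(abs(colSums(u) - 1) > tol)) {
    stop("underlying-cause distributions must sum to 1 per stratum",
         call. = FALSE)
  }
  t_ <- config$transitions
  if (!is.matrix(t_) || !all(dim(t_) == nc) ||
      !identical(rownames(t_), config$causes) ||
      !identical(colnames(t_), config$causes)) {
    stop("transitions must be a square [cause, cause] matrix", call. = FALSE)
  }
  if (any(t_ < 0)) stop("negative transition probability", call. = FALSE)
  rs <- rowSums(t_)
  if (!all(abs(rs - 1) < tol | abs(rs) < tol)) {
    stop("transition rows must sum to 1 (or 0 for terminal causes)",
         call. = FALSE)
  }
  if (any(t_[lower.tri(t_, diag = TRUE)] > 0)) {
    stop("transitions must be acyclic: mass only on strictly later causes",
         call. = FALSE)
  }
  if (length(config$length_dist) != 4 || any(config$length_dist < 0) ||
      abs(sum(config$length_dist) - 1) > tol) {
    stop("length_dist must be 4 probabilities summing to 1", call. = FALSE)
  }
  for (p in c(config$p_E, config$p_offchain, config$p_male)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("p_E, p_offchain and p_male must lie in [0, 1]", call. = FALSE)
    }
  }
  if (abs(sum(config$age_group_probs) - 1) > tol ||
      abs(sum(config$region_probs) - 1) > tol) {
    stop("age-group and region probabilities must sum to 1", call. = FALSE)
  }
  invisible(config)
}

#' Default synthetic registry configuration
#'
#' A 12-cause, 3-region universe spanning common chronic seeds (cancers,
#' diabetes, hypertension, ischaemic heart disease, COPD, stroke) that
#' progress toward terminal events (pneumonias, myocardial infarction,
#' sepsis, shock). The underlying-cause mix shifts with age — infections
#' dominate child deaths, chronic disease dominates old age — and is tilted
#' slightly by gender (more cancer and ischaemic deaths among men). One
#' fifth of certificates have their adjudicated label off the earliest
#' antecedent (`p_offchain = 0.2`), the low-confidence regime that
#' motivates the CF strategy.
#'
#' @param p_offchain Override for the off-chain labeling rate.
#' @param p_E Override for the contributing-cause rate.
#' @return A `generator_config`.
#' @export
default_generator_config <- function(p_offchain = 0.2, p_E = 0.3) {
  causes <- c("C22.0",  # primary liver cancer
              "C34.9",  # lung cancer
              "E11.9",  # type 2 diabetes
              "I10",    # essential hypertension
              "I25.1",  # ischaemic heart disease
              "J44.9",  # COPD
              "I63.9",  # cerebral infarction
              "J69.0",  # aspiration pneumonia
              "I21.9",  # acute myocardial infarction
              "J18.9",  # pneumonia, unspecified
              "A41.9",  # sepsis
              "R57.0")  # cardiogenic shock (terminal)
  nc <- length(causes)
  t_ <- matrix(0, nc, nc, dimnames = list(causes, causes))
  edge <- function(from, to, p) t_[from, to] <<- p
  edge("C22.0", c("J69.0", "J18.9", "A41.9"), c(0.35, 0.35, 0.30))
  edge("C34.9", c("J18.9", "A41.9", "R57.0"), c(0.45, 0.25, 0.30))
  edge("E11.9", c("I25.1", "I63.9", "I21.9", "A41.9"), c(0.40, 0.30, 0.20, 0.10))
  edge("I10",   c("I25.1", "I63.9", "I21.9"), c(0.35, 0.35, 0.30))
  edge("I25.1", c("I21.9", "R57.0"), c(0.60, 0.40))
  edge("J44.9", c("J18.9", "A41.9", "R57.0"), c(0.55, 0.25, 0.20))
  edge("I63.9", c("J69.0", "J18.9", "A41.9"), c(0.45, 0.35, 0.20))
  edge("J69.0", c("J18.9", "A41.9", "R57.0"), c(0.50, 0.30, 0.20))
  edge("I21.9", "R57.0", 1.0)
  edge("J18.9", c("A41.9", "R57.0"), c(0.60, 0.40))
  edge("A41.9", "R57.0", 1.0)

  ## underlying-cause mix per age group (columns sum to 1)
  base <- cbind(
    G0 = c(0.03, 0.02, 0.05, 0.03, 0.04, 0.04, 0.05, 0.08, 0.06, 0.25, 0.30, 0.05),
    G1 = c(0.10, 0.10, 0.12, 0.10, 0.12, 0.06, 0.08, 0.03, 0.10, 0.09, 0.08, 0.02),
    G2 = c(0.08, 0.12, 0.10, 0.12, 0.16, 0.10, 0.12, 0.02, 0.07, 0.06, 0.04, 0.01))
  rownames(base) <- causes
  ## gender tilt: men get ~20% more cancer/ischaemic mass, renormalized
  tilt <- ifelse(causes %in% c("C22.0", "C34.9", "I25.1", "I21.9"), 1.2, 1.0)
  underlying <- matrix(0, nc, 6, dimnames = list(causes, all_strata()))
  for (g in AGE_GROUPS) {
    m <- base[, g] * tilt
    underlying[, stratum_id(g, "male")] <- m / sum(m)
    f <- base[, g] / tilt
    underlying[, stratum_id(g, "female")] <- f / sum(f)
  }
  generator_config(causes, underlying, t_, p_E = p_E,
                   p_offchain = p_offchain)
}

terminal_causes <- function(config) {
  config$causes[abs(rowSums(config$transitions)) < 1e-12]
}

#' Sample a synthetic death registry
#'
#' Per record: draw demographics; draw the underlying cause U from the
#' stratum's distribution; grow a forward path from U through the
#' transition matrix, stopping at the drawn chain length or at a terminal
#' cause; with probability `p_E` attach a contributing cause E not on the
#' chain; with probability `p_offchain` move the adjudicated label from U
#' to a uniformly chosen other chain cause or E. The last path element
#' becomes the direct cause A, with antecedents B-D behind it; durations
#' decay geometrically from the earliest antecedent toward the direct
#' cause. Fully reproducible from the seed.
#'
#' @param config A [generator_config()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A `synthetic_registry`: list with `records` (labeled
#'   `death_records`), `truth` (per-record generative trace: seeded
#'   underlying cause, realized chain length, relabel flag), `config`,
#'   `seed`.
#' @export
sample_records <- function(config, n, seed = 1) {
  validate_generator_config(config)
  stopifnot(n >= 1)
  causes <- config$causes
  nc <- length(causes)
  term <- abs(rowSums(config$transitions)) < 1e-12

  with_seed(seed, {
    grp <- sample(AGE_GROUPS, n, replace = TRUE, prob = config$age_group_probs)
    age <- integer(n)
    for (g in AGE_GROUPS) {
      idx <- which(grp == g)
      r <- config$age_ranges[[g]]
      age[idx] <- sample(r[1]:r[2], length(idx), replace = TRUE)
    }
    gender <- ifelse(runif(n) < config$p_male, "male", "female")
    region <- sample(config$regions, n, replace = TRUE,
                     prob = config$region_probs)
    strat <- stratum_id(grp, gender)

    u <- integer(n)
    for (s in all_strata()) {
      idx <- which(strat == s)
      if (length(idx) > 0) {
        u[idx] <- sample.int(nc, length(idx), replace = TRUE,
                             prob = config$underlying[, s])
      }
    }
    drawn_len <- sample.int(4, n, replace = TRUE, prob = config$length_dist)

    ## forward path growth, vectorized by current cause
    path <- matrix(NA_integer_, n, 4)
    path[, 1] <- u
    cur <- u
    for (step in 2:4) {
      active <- which(drawn_len >= step & !term[cur])
      if (length(active) == 0) break
      for (ci in unique(cur[active])) {
        idx <- active[cur[active] == ci]
        nxt <- sample.int(nc, length(idx), replace = TRUE,
                          prob = config$transitions[ci, ])
        path[idx, step] <- nxt
      }
      cur[active] <- path[active, step]
    }
    len <- rowSums(!is.na(path))

    ## contributing cause E: uniform over causes off the chain (rejection)
    has_e <- runif(n) < config$p_E
    e <- rep(NA_integer_, n)
    pending <- which(has_e)
    while (length(pending) > 0) {
      draw <- sample.int(nc, length(pending), replace = TRUE)
      onchain <- path[pending, , drop = FALSE] == draw
      clash <- rowSums(onchain, na.rm = TRUE) > 0
      e[pending[!clash]] <- draw[!clash]
      pending <- pending[clash]
    }

    ## off-chain relabeling: uniformly one of the non-seed chain causes or E
    ncand <- (len - 1L) + as.integer(has_e)
    relabel <- runif(n) < config$p_offchain & ncand > 0
    label <- u
    ridx <- which(relabel)
    if (length(ridx) > 0) {
      pick <- ceiling(runif(length(ridx)) * ncand[ridx])
      to_e <- pick > (len[ridx] - 1L)
      label[ridx[to_e]] <- e[ridx[to_e]]
      notE <- ridx[!to_e]
      label[notE] <- path[cbind(notE, pick[!to_e] + 1L)]
    }

    ## durations: geometric decay toward the direct cause, lognormal jitter
    jitter <- function(m) pmax(1, round(m * exp(stats::rnorm(length(m), 0, 0.5))))

    df <- data.frame(id = sprintf("S%06d", seq_len(n)), age = age,
                     gender = gender, region = region,
                     stringsAsFactors = FALSE)
    for (role in ROLES) {
      df[[paste0("cause_", role)]] <- NA_character_
      df[[paste0("dur_", role)]] <- NA_real_
    }
    ## certificate order: A = last path element (direct), D-ward = earlier
    for (pos in 1:4) {  # pos = distance from direct cause (1 = A)
      idx <- which(len >= pos)
      role <- ROLES[pos]
      df[[paste0("cause_", role)]][idx] <- causes[path[cbind(idx, len[idx] - pos + 1L)]]
      df[[paste0("dur_", role)]][idx] <- jitter(rep(config$duration_base_min[pos],
                                                    length(idx)))
    }
    eidx <- which(has_e)
    df$cause_E[eidx] <- causes[e[eidx]]
    df$underlying <- causes[label]
    records <- death_records(df)

    truth <- data.frame(id = df$id, seeded_underlying = causes[u],
                        drawn_length = drawn_len, length = len,
                        relabeled = relabel,
                        label = causes[label], stringsAsFactors = FALSE)
    structure(list(records = records, truth = truth, config = config,
                   seed = seed), class = "synthetic_registry")
  })
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("<synthetic_registry> ", nrow(x$records), " records, ",
      length(x$config$causes), " causes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## Enumerate every generable (path, E) outcome for one stratum with its
## probability, calling f(path_idx, e_idx_or_NA, prob) for each.
enumerate_outcomes <- function(config, stratum, f) {
  nc <- length(config$causes)
  term <- abs(rowSums(config$transitions)) < 1e-12
  pu <- config$underlying[, stratum]
  walk <- function(path, prob, steps_left) {
    cur <- path[length(path)]
    if (steps_left == 0 || term[cur]) {
      emit(path, prob)
      return(invisible())
    }
    row <- config$transitions[cur, ]
    for (nxt in which(row > 0)) {
      walk(c(path, nxt), prob * row[nxt], steps_left - 1)
    }
  }
  emit <- function(path, prob) {
    offchain <- setdiff(seq_len(nc), path)
    ## E absent
    f(path, NA_integer_, prob * (1 - config$p_E))
    ## E uniform over off-chain causes
    if (config$p_E > 0 && length(offchain) > 0) {
      pe <- prob * config$p_E / length(offchain)
      for (e in offchain) f(path, e, pe)
    }
  }
  for (u in which(pu > 0)) {
    for (L in 1:4) {
      pL <- config$length_dist[L]
      if (pL > 0) walk(u, pu[u] * pL, L - 1)
    }
  }
  invisible()
}

#' Ground-truth conditional death-cause proportion
#'
#' The exact probability that a cause is the adjudicated underlying cause
#' given that it appears on the certificate (chain or E), under the
#' generator: `P(label = i | i on chain or E)`. Computed by exhaustive
#' enumeration of all generable paths (finite because the transition graph
#' is acyclic and chains have at most 4 causes), or by Monte Carlo with
#' `method = "mc"`.
#'
#' @param config A [generator_config()].
#' @param cause ICD-10 code in the config's universe.
#' @param group Age group (`"G0"`, `"G1"`, `"G2"`).
#' @param gender `"male"` or `"female"`.
#' @param method `"enumerate"` (exact) or `"mc"`.
#' @param mc_samples Monte Carlo sample count (default 1e6).
#' @param seed Seed for the Monte Carlo draw.
#' @return Probability in \[0, 1\] (`NaN` if the cause can never occur in
#'   the stratum).
#' @export
true_cdcp_ratio <- function(config, cause, group, gender,
                            method = c("enumerate", "mc"),
                            mc_samples = 1e6, seed = 1) {
  validate_generator_config(config)
  method <- match.arg(method)
  cause <- validate_code(cause)
  if (!cause %in% config$causes) {
    stop("cause ", sQuote(cause), " is not in the generator universe",
         call. = FALSE)
  }
  stratum <- stratum_id(group, gender)
  if (!stratum %in% all_strata()) stop("unknown stratum", call. = FALSE)

  if (method == "mc") {
    ## conditional draw: sample records and keep the stratum of interest
    reg <- sample_records(config, mc_samples, seed = seed)
    rec <- reg$records
    keep <- stratum_id(age_group(rec$age), rec$gender) == stratum
    rec <- rec[keep, , drop = FALSE]
    long <- chain_long(rec)
    occ <- length(unique(long$row[long$code == cause]))
    dth <- sum(rec$underlying == cause)
    return(dth / occ)
  }

  ci <- match(cause, config$causes)
  occ_p <- 0; death_p <- 0
  p_off <- config$p_offchain
  collect <- function(path, e, prob) {
    onchain <- ci %in% path || (!is.na(e) && e == ci)
    if (onchain) occ_p <<- occ_p + prob
    ## label distribution for this outcome
    ncand <- (length(path) - 1L) + as.integer(!is.na(e))
    if (ncand == 0) {
      if (path[1] == ci) death_p <<- death_p + prob
    } else {
      if (path[1] == ci) death_p <<- death_p + prob * (1 - p_off)
      cands <- c(path[-1], if (!is.na(e)) e)
      hits <- sum(cands == ci)
      if (hits > 0) death_p <<- death_p + prob * p_off * hits / ncand
    }
  }
  enumerate_outcomes(config, stratum, collect)
  unname(death_p / occ_p)
}

#' Worked certificate fixtures: the two causality-gap cases
#'
#' Two certificates whose chains contain a causality gap, i.e. where the
#' earliest antecedent is not the adjudicated underlying cause — the
#' situation in which a pure highest-CDCP (sink) ranking picks the wrong
#' cause and case-based verification is needed.
#'
#' Case 1: primary liver cancer (C22.0, 5y) -> aspiration pneumonia
#' (J69.0, 2d) -> pulmonary infection (J18.9, 1d) -> infectious shock
#' (A41.9, 6h) -> death; the lung infection arose from gastric-secretion
#' aspiration, not from the cancer, so the underlying cause is the
#' aspiration pneumonia, not the chain-initiating cancer.
#'
#' Case 2: pulmonary infection (J18.9, 2y) -> acute lower respiratory
#' tract infection (J22, 6d) -> drug (Ammetran) allergy (T88.7, 1h) ->
#' anaphylactic shock (T78.2, 20min) -> death; death followed from the
#' misused drug, so the underlying cause is the drug allergy, a mid-chain
#' cause. (Codes are ICD-10 category assignments made for these fixtures:
#' T88.7 "unspecified adverse effect of drug", T78.2 "anaphylactic shock,
#' unspecified".)
#'
#' @param age Age in years given to both fixture records (default 70).
#' @param gender Gender for both records (default `"male"`).
#' @return A two-row labeled `death_records`; chains in certificate order
#'   (direct cause at role A, earliest antecedent at role D).
#' @export
fixture_cases <- function(age = 70, gender = "male") {
  death_records(rbind(
    death_record(
      id = "case1", age = age, gender = gender, region = "fixture",
      chain = c(A = "A41.9",   # infectious shock
                B = "J18.9",   # pulmonary infection
                C = "J69.0",   # aspiration pneumonia
                D = "C22.0"),  # primary liver cancer
      durations = c(A = 6 * 60, B = 1440, C = 2 * 1440, D = 5 * 525600),
      underlying = "J69.0"),
    death_record(
      id = "case2", age = age, gender = gender, region = "fixture",
      chain = c(A = "T78.2",   # anaphylactic shock
                B = "T88.7",   # drug (Ammetran) allergy
                C = "J22",     # acute lower respiratory tract infection
                D = "J18.9"),  # pulmonary infection
      durations = c(A = 20, B = 60, C = 6 * 1440, D = 2 * 525600),
      underlying = "T88.7")))
}
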