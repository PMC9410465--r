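## Certificate roles: A is the direct cause of death, B..D its antecedents in
## certificate order (earliest antecedent last), E the contributing cause
## recorded off the Part I chain.
ROLES <- c("A", "B", "C", "D", "E")
PART1_ROLES <- c("A", "B", "C", "D")

AGE_GROUPS <- c("G0", "G1", "G2")
GENDERS <- c("male", "female")

## Evaluate `code` with the RNG seeded at `seed`, restoring any prior RNG
## state afterwards so library code never perturbs the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## All six (age group, gender) strata in a fixed order.
stratum_id <- function(group, gender) paste(group, gender, sep = ":")

all_strata <- function() {
  as.vector(outer(AGE_GROUPS, GENDERS, stratum_id))
}
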