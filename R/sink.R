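## Sink strategy: rank the chain causes of one certificate by weighted
## CDCP, declare the top cause, and gate the answer with the trigonometric
## confidence measure
##
##   C_sink = round(sin(pi * n / 2))  in {-1, 0, 1},
##
## where n is the number of chain causes whose weighted CDCP strictly
## exceeds the chain's mean weighted CDCP. C_sink = 1 (exactly one clearly
## dominant cause) means the sink answer stands; 0 or -1 (the weighted
## values converge) routes the record to the CF strategy.

#' Sink confidence gate
#'
#' `round(sin(pi * n / 2))` for `n` above-threshold causes: 1, 0, -1, 0, 1
#' for n = 1..5. `n = 1` signals high confidence in the sink answer; 0 and
#' -1 signal that the weighted CDCP values of the chain converge and the CF
#' strategy should be consulted.
#'
#' @param n_above Non-negative integer count(s) of causes with weighted
#'   CDCP strictly above the chain-mean threshold.
#' @return Integer confidence value(s) in `{-1, 0, 1}`.
#' @examples
#' sink_confidence(0:5)
#' @export
sink_confidence <- function(n_above) {
  if (any(is.na(n_above)) || any(n_above < 0) || any(n_above != round(n_above))) {
    stop("n_above must be a non-negative integer", call. = FALSE)
  }
  as.integer(round(sin(pi * n_above / 2)))
}

## role preference for ties at the top of the ranking: the earliest
## antecedent wins (D over C over B over A), the off-chain contributing
## cause E last — the underlying cause is the condition that initiated the
## chain of events.
ROLE_TIE_RANK <- c(D = 1, C = 2, B = 3, A = 4, E = 5)

#' Rank one certificate's chain by weighted CDCP
#'
#' Scores every cause on the record's chain (A-D plus E when present) with
#' [weighted_cdcp()] in the record's own (age group, gender) stratum, sorts
#' descending, and computes the confidence gate: the threshold is the
#' arithmetic mean of the chain's weighted values, `n_above` the number of
#' causes strictly above it, and `confidence = sink_confidence(n_above)`.
#' Ties in the ranking are broken toward the earliest antecedent (role D
#' before C before B before A, E last).
#'
#' @param model A [cdcp_model()].
#' @param record A one-row `death_records` data.frame.
#' @return A `sink_ranking` object: list with `entries` (data.frame of
#'   `code`, `role`, `weighted`, sorted), `top` (the sink answer),
#'   `threshold`, `n_above`, `confidence`.
#' @export
rank_chain <- function(model, record) {
  stopifnot(inherits(model, "cdcp_model"))
  record <- death_records(record)
  if (nrow(record) != 1) stop("rank_chain expects a single record", call. = FALSE)
  long <- chain_long(record)
  if (nrow(long) == 0) stop("empty cause chain", call. = FALSE)

  w <- weighted_cdcp(model, long$code, age_group(record$age), record$gender)
  ord <- order(-w, ROLE_TIE_RANK[long$role])
  entries <- data.frame(code = long$code[ord], role = long$role[ord],
                        weighted = w[ord], stringsAsFactors = FALSE)
  threshold <- mean(w)
  n_above <- sum(w > threshold)
  structure(list(entries = entries, top = entries$code[1],
                 threshold = threshold, n_above = n_above,
                 confidence = sink_confidence(n_above)),
            class = "sink_ranking")
}

#' @export
print.sink_ranking <- function(x, ...) {
  cat("<sink_ranking> top =", x$top, " n_above =", x$n_above,
      " confidence =", x$confidence, "\n")
  print(x$entries)
  invisible(x)
}
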