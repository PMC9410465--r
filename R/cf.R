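## CF strategy: collaborative filtering over a library of adjudicated
## historical cases. Chain similarity is a CDCP-weighted Jaccard index
## computed after "dimension transposition": equal causes are matched
## across chain positions first (the same disease appearing at different
## positions in two chains still counts as shared), then
##
##   sim(a, b) = sum_matched mean(r_a, r_b) /
##               (sum_matched mean(r_a, r_b) + sum_unmatched r_own)
##
## where r are the records' own-stratum weighted CDCP values. Prediction is
## a similarity-weighted vote over the nearest neighbors' labels.

#' Build a case library
#'
#' Stores labeled historical records together with an inverted index
#' (cause code -> case positions) used to restrict similarity computations
#' to cases sharing at least one cause with the query. The index is purely
#' an accelerator: a case sharing no code has similarity 0 and could never
#' be retrieved.
#'
#' @param records Labeled `death_records`.
#' @return A `case_library` object.
#' @export
case_library <- function(records) {
  records <- death_records(records)
  if (any(is.na(records$underlying))) {
    stop("all library cases must be labeled", call. = FALSE)
  }
  long <- chain_long(records)
  index <- split(long$row, long$code)
  index <- lapply(index, function(v) sort(unique(v)))
  ## per-case caches for fast scalar similarity
  chains <- split(stats::setNames(long$code, long$role),
                  factor(long$row, levels = seq_len(nrow(records))))
  strata <- stratum_id(age_group(records$age), records$gender)
  structure(list(cases = records, index = index,
                 chains = chains, strata = strata),
            class = "case_library")
}

#' @export
print.case_library <- function(x, ...) {
  cat("<case_library> ", nrow(x$cases), " cases, ",
      length(x$index), " distinct causes\n", sep = "")
  invisible(x)
}

## chains as position-indexed code vectors (certificate role order, E last)
chain_vector <- function(record) {
  long <- chain_long(death_records(record))
  stats::setNames(long$code, long$role)
}

#' Align two cause chains by dimension transposition
#'
#' Finds a maximum-cardinality one-to-one matching between positions of the
#' two chains carrying equal codes (the multiset intersection), regardless
#' of position: the same cause sitting at different places in two
#' certificates is still a shared dimension. For equality matchings every
#' maximum matching of a given code carries the same weight, so matching
#' proceeds in position order within each code.
#'
#' @param a,b Chains: character vectors of codes (possibly named by role),
#'   or one-row `death_records`.
#' @return A `chain_alignment`: list with `matched` (two-column integer
#'   matrix of positions in `a` and `b`), `unmatched_a`, `unmatched_b`
#'   (integer position vectors).
#' @export
align_chains <- function(a, b) {
  if (is.data.frame(a)) a <- chain_vector(a)
  if (is.data.frame(b)) b <- chain_vector(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  matched <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("pos_a", "pos_b")))
  used_b <- rep(FALSE, length(b))
  for (code in unique(a)) {
    ia <- which(a == code)
    ib <- which(b == code & !used_b)
    m <- min(length(ia), length(ib))
    if (m > 0) {
      matched <- rbind(matched, cbind(pos_a = ia[seq_len(m)],
                                      pos_b = ib[seq_len(m)]))
      used_b[ib[seq_len(m)]] <- TRUE
    }
  }
  structure(list(matched = matched,
                 unmatched_a = setdiff(seq_along(a), matched[, "pos_a"]),
                 unmatched_b = setdiff(seq_along(b), matched[, "pos_b"])),
            class = "chain_alignment")
}

#' Weighted Jaccard similarity between two certificates
#'
#' Aligns the two chains with [align_chains()] and computes the
#' CDCP-weighted Jaccard index: each matched pair contributes the mean of
#' the two records' own-stratum weighted CDCP values to the intersection
#' term; each unmatched cause contributes its own-record weight to the
#' union term. When every weight is zero the unweighted Jaccard index
#' (matched / union cardinality) is used so that structural similarity is
#' still distinguished.
#'
#' @param model A [cdcp_model()].
#' @param rec_a,rec_b One-row `death_records`.
#' @return A `similarity_score`: list with `value` in \[0, 1\] and
#'   `alignment`.
#' @export
similarity <- function(model, rec_a, rec_b) {
  rec_a <- death_records(rec_a); rec_b <- death_records(rec_b)
  a <- chain_vector(rec_a); b <- chain_vector(rec_b)
  al <- align_chains(a, b)
  wa <- weighted_cdcp(model, a, age_group(rec_a$age), rec_a$gender)
  wb <- weighted_cdcp(model, b, age_group(rec_b$age), rec_b$gender)
  structure(list(value = sim_value(al, a, b, wa, wb), alignment = al),
            class = "similarity_score")
}

sim_value <- function(al, a, b, wa, wb) {
  num <- if (nrow(al$matched) > 0) {
    sum((wa[al$matched[, "pos_a"]] + wb[al$matched[, "pos_b"]]) / 2)
  } else 0
  den <- num + sum(wa[al$unmatched_a]) + sum(wb[al$unmatched_b])
  if (den > 0) num / den
  else nrow(al$matched) / (length(a) + length(b) - nrow(al$matched))
}

## lean similarity on raw code vectors + strata; set fast path when both
## chains are duplicate-free, exact multiset alignment otherwise
sim_codes <- function(model, a, sa, b, sb) {
  wa <- fast_weighted(model, a, rep(sa, length(a)))
  wb <- fast_weighted(model, b, rep(sb, length(b)))
  if (!anyDuplicated(a) && !anyDuplicated(b)) {
    ina <- a %in% b
    if (!any(ina)) return(0)
    num <- (sum(wa[ina]) + sum(wb[b %in% a])) / 2
    den <- sum(wa) + sum(wb) - num
    if (den > 0) num / den
    else sum(ina) / (length(a) + length(b) - sum(ina))
  } else {
    sim_value(align_chains(a, b), a, b, wa, wb)
  }
}

#' Retrieve the nearest library cases for a query record
#'
#' Candidate cases are generated through the library's inverted index (only
#' cases sharing at least one cause code), scored with [similarity()], and
#' the top `k` with similarity at least `min_sim` are returned in
#' deterministic order: similarity descending, then case id ascending.
#'
#' @param library A [case_library()].
#' @param model A [cdcp_model()].
#' @param query A one-row `death_records`.
#' @param k Maximum number of neighbors (default 10).
#' @param min_sim Minimum similarity to count as a neighbor (default 0.2).
#' @param exclude_ids Case ids to ignore (e.g. the query itself when it is
#'   part of the library).
#' @return data.frame with columns `case` (library row), `id`, `label`,
#'   `sim`, sorted; zero rows when nothing qualifies.
#' @export
retrieve_neighbors <- function(library, model, query, k = 10, min_sim = 0.2,
                               exclude_ids = NULL) {
  stopifnot(inherits(library, "case_library"), k >= 1)
  query <- death_records(query)
  codes <- unique(chain_vector(query))
  cand <- sort(unique(unlist(library$index[codes], use.names = FALSE)))
  empty <- data.frame(case = integer(0), id = character(0),
                      label = character(0), sim = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0) return(empty)
  if (!is.null(exclude_ids)) {
    cand <- cand[!library$cases$id[cand] %in% exclude_ids]
    if (length(cand) == 0) return(empty)
  }
  qcodes <- chain_vector(query)
  qstr <- stratum_id(age_group(query$age), query$gender)
  sims <- vapply(cand, function(i) {
    sim_codes(model, qcodes, qstr, library$chains[[i]], library$strata[i])
  }, 0)
  keep <- sims >= min_sim
  cand <- cand[keep]; sims <- sims[keep]
  if (length(cand) == 0) return(empty)
  ord <- order(-sims, library$cases$id[cand])
  take <- utils::head(ord, k)
  data.frame(case = cand[take], id = library$cases$id[cand[take]],
             label = library$cases$underlying[cand[take]],
             sim = sims[take], stringsAsFactors = FALSE)
}

#' Similarity-weighted vote over retrieved neighbors
#'
#' Votes are neighbor similarities summed per underlying-cause label,
#' restricted to labels that appear on the query's own chain (including E);
#' if no neighbor label appears on the query chain the vote is
#' unrestricted. Ties are broken by the higher best single-neighbor
#' similarity, then lexicographically by code. With no neighbors the CF
#' strategy abstains (`NA`), signalling the pipeline to fall back to the
#' sink answer.
#'
#' @param neighbors Retrieval result from [retrieve_neighbors()].
#' @param query The query record.
#' @return The winning ICD-10 code, or `NA_character_` on abstention.
#' @export
cf_infer <- function(neighbors, query) {
  if (nrow(neighbors) == 0) return(NA_character_)
  query_codes <- unique(chain_vector(death_records(query)))
  nb <- neighbors[neighbors$label %in% query_codes, , drop = FALSE]
  if (nrow(nb) == 0) nb <- neighbors
  votes <- tapply(nb$sim, nb$label, sum)
  best <- tapply(nb$sim, nb$label, max)
  labs <- names(votes)
  ord <- order(-unname(votes), -unname(best), labs)
  labs[ord[1]]
}
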