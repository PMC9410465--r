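## Sink-CF pipeline: train the CDCP model and the case library from the
## same labeled records, then route each query through the confidence gate:
##   confidence 1        -> sink answer               (route "sink")
##   confidence 0 or -1  -> CF strategy               (route "cf")
##   CF abstains         -> sink answer regardless    (route "fallback")
## An inference is always produced.

#' Sink-CF configuration
#'
#' Collects every tunable of the pipeline in one place; all randomness in
#' downstream tooling flows from `seed`.
#'
#' @param smoothing Pseudo-count for the CDCP estimator (default 1).
#' @param weight_scheme Occurrence-weighting scheme, see [cdcp_model()].
#' @param k Neighbors retrieved by the CF strategy (default 10).
#' @param min_sim Minimum similarity for a neighbor (default 0.2).
#' @param seed Integer seed recorded in model metadata.
#' @return A `sinkcf_config` list.
#' @export
sinkcf_config <- function(smoothing = 1, weight_scheme = "damped",
                          k = 10, min_sim = 0.2, seed = 1L) {
  stopifnot(smoothing > 0, k >= 1, min_sim >= 0, min_sim <= 1)
  structure(list(smoothing = smoothing, weight_scheme = weight_scheme,
                 k = as.integer(k), min_sim = min_sim,
                 seed = as.integer(seed)),
            class = "sinkcf_config")
}

#' Train a Sink-CF model
#'
#' Fits the stratified CDCP counts and builds the historical case library
#' from the same labeled record set. Deterministic given records and
#' configuration.
#'
#' @param records Labeled `death_records` (at least one).
#' @param config A [sinkcf_config()].
#' @return A `sinkcf_model` object.
#' @export
sinkcf_train <- function(records, config = sinkcf_config()) {
  records <- death_records(records)
  if (nrow(records) == 0) stop("no training records", call. = FALSE)
  counts <- fit_counts(records)
  model <- cdcp_model(counts, smoothing = config$smoothing,
                      weight_scheme = config$weight_scheme)
  structure(list(cdcp_model = model, library = case_library(records),
                 config = config,
                 meta = list(n_records = nrow(records),
                             n_causes = nrow(counts$occur))),
            class = "sinkcf_model")
}

#' @export
print.sinkcf_model <- function(x, ...) {
  cat("<sinkcf_model> trained on ", x$meta$n_records, " records, ",
      x$meta$n_causes, " causes; k = ", x$config$k,
      ", min_sim = ", x$config$min_sim, "\n", sep = "")
  invisible(x)
}

#' Predict the underlying cause for one record (reference path)
#'
#' Runs the full sink ranking, consults the CF strategy when the
#' confidence gate is 0 or -1, and falls back to the sink answer when CF
#' abstains. The query's own id is excluded from neighbor retrieval so a
#' record present in the library cannot vote for itself.
#'
#' @param model A [sinkcf_train()] model.
#' @param record A one-row `death_records`.
#' @return A `prediction` list: `cause`, `route` (`"sink"`, `"cf"`,
#'   `"fallback"`), `confidence`, `ranking` (the [rank_chain()] result),
#'   `neighbors_used`.
#' @export
predict_one <- function(model, record) {
  stopifnot(inherits(model, "sinkcf_model"))
  record <- death_records(record)
  ranking <- rank_chain(model$cdcp_model, record)
  if (ranking$confidence == 1) {
    return(structure(list(cause = ranking$top, route = "sink",
                          confidence = ranking$confidence, ranking = ranking,
                          neighbors_used = 0L), class = "prediction"))
  }
  nb <- retrieve_neighbors(model$library, model$cdcp_model, record,
                           k = model$config$k, min_sim = model$config$min_sim,
                           exclude_ids = record$id)
  cause <- cf_infer(nb, record)
  if (is.na(cause)) {
    structure(list(cause = ranking$top, route = "fallback",
                   confidence = ranking$confidence, ranking = ranking,
                   neighbors_used = 0L), class = "prediction")
  } else {
    structure(list(cause = cause, route = "cf",
                   confidence = ranking$confidence, ranking = ranking,
                   neighbors_used = nrow(nb)), class = "prediction")
  }
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", x$cause, " via ", x$route,
      " (confidence ", x$confidence, ")\n", sep = "")
  invisible(x)
}

#' Predict underlying causes for a batch of records
#'
#' Element-wise equivalent of [predict_one()], order preserving, using a
#' vectorized scoring path: chains are grouped by (code set, stratum) and
#' the weighted Jaccard similarities between query groups and library
#' groups are computed as matrix products. Chains carrying a duplicated
#' code (a multiset, where the set-based matrix form is inexact) are routed
#' through the reference path.
#'
#' @param object A `sinkcf_model`.
#' @param newdata `death_records` to predict.
#' @param ... Unused.
#' @return data.frame with one row per record: `id`, `cause`, `route`,
#'   `confidence`, `n_above`, `sink_top`, `neighbors_used`.
#' @export
predict.sinkcf_model <- function(object, newdata, ...) {
  model <- object
  records <- death_records(newdata)
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(id = character(0), cause = character(0),
                      route = character(0), confidence = integer(0),
                      n_above = integer(0), sink_top = character(0),
                      neighbors_used = integer(0), stringsAsFactors = FALSE))
  }
  cm <- model$cdcp_model
  strata <- stratum_id(age_group(records$age), records$gender)
  long <- chain_long(records)

  ## sink scoring, vectorized: weighted CDCP per chain entry
  w <- fast_weighted(cm, long$code, strata[long$row])
  ord <- order(long$row, -w, ROLE_TIE_RANK[long$role])
  first <- !duplicated(long$row[ord])
  sink_top <- long$code[ord][first]
  chain_sizes <- tabulate(long$row, nbins = n)
  mean_w <- as.vector(rowsum(w, long$row)) / chain_sizes
  n_above <- as.vector(rowsum(as.numeric(w > mean_w[long$row]), long$row))
  confidence <- sink_confidence(n_above)

  cause <- sink_top
  route <- ifelse(confidence == 1, "sink", "fallback")
  neighbors_used <- integer(n)

  low <- which(confidence != 1)
  if (length(low) > 0 && nrow(model$library$cases) > 0) {
    has_dup <- function(df) {
      lg <- chain_long(df)
      any(stats::ave(seq_len(nrow(lg)), lg$row, lg$code, FUN = length) > 1)
    }
    if (has_dup(records[low, , drop = FALSE]) || has_dup(model$library$cases)) {
      for (i in low) {
        p <- predict_one(model, records[i, ])
        cause[i] <- p$cause; route[i] <- p$route
        neighbors_used[i] <- p$neighbors_used
      }
    } else {
      cfres <- cf_batch(model, records, strata, low)
      got <- !is.na(cfres$cause)
      cause[low[got]] <- cfres$cause[got]
      route[low[got]] <- "cf"
      neighbors_used[low] <- cfres$neighbors_used
    }
  }
  data.frame(id = records$id, cause = cause, route = route,
             confidence = confidence, n_above = as.integer(n_above),
             sink_top = sink_top, neighbors_used = neighbors_used,
             stringsAsFactors = FALSE)
}

## weighted CDCP lookup without per-call validation; codes absent from the
## model score pmax(log2(10), 0) * unseen-weight, as in weighted_cdcp()
fast_weighted <- function(model, code, stratum) {
  known <- code %in% rownames(model$weighted_matrix)
  out <- numeric(length(code))
  if (any(known)) {
    out[known] <- model$weighted_matrix[cbind(code[known], stratum[known])]
  }
  if (any(!known) && model$weight_scheme == "none") {
    out[!known] <- log2(10)
  }
  out
}

## Batch CF over duplicate-free chains. Groups query records and library
## cases by (code set, stratum); similarity between a query group and a
## case group is then
##   num = (sum of query weights over the intersection
##          + sum of case weights over the intersection) / 2
##   den = total query weight + total case weight - num
## which is a pair of matrix products over code-incidence matrices. Cells
## with zero den fall back to the unweighted Jaccard index.
cf_batch <- function(model, records, strata, low) {
  cm <- model$cdcp_model
  lib <- model$library$cases
  lib_strata <- stratum_id(age_group(lib$age), lib$gender)
  k <- model$config$k
  min_sim <- model$config$min_sim

  qlong <- chain_long(records[low, , drop = FALSE])
  qlong$rec <- low[qlong$row]
  tlong <- chain_long(lib)

  sig_by_rec <- vapply(split(qlong$code, factor(qlong$rec, levels = low)),
                       function(v) paste(sort(v), collapse = "|"), "")
  qkey <- paste(sig_by_rec, strata[low], sep = "@")
  tsig <- vapply(split(tlong$code, factor(tlong$row, levels = seq_len(nrow(lib)))),
                 function(v) paste(sort(v), collapse = "|"), "")
  tkey <- paste(tsig, lib_strata, sep = "@")

  qgroups <- unique(qkey); tgroups <- unique(tkey)
  qg_of <- match(qkey, qgroups); tg_of <- match(tkey, tgroups)

  alphabet <- sort(unique(c(qlong$code, tlong$code)))
  inc <- function(keys) {
    parts <- strsplit(sub("@.*$", "", keys), "|", fixed = TRUE)
    strat <- sub("^.*@", "", keys)
    B <- matrix(0, nrow = length(keys), ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
    W <- B
    for (g in seq_along(keys)) {
      codes <- parts[[g]]
      B[g, codes] <- 1
      W[g, codes] <- fast_weighted(cm, codes, rep(strat[g], length(codes)))
    }
    list(B = B, W = W, size = lengths(parts))
  }
  q <- inc(qgroups); t_ <- inc(tgroups)

  num <- (q$W %*% t(t_$B) + q$B %*% t(t_$W)) / 2
  den <- outer(rowSums(q$W), rowSums(t_$W), "+") - num
  inter <- q$B %*% t(t_$B)
  uni <- outer(q$size, t_$size, "+") - inter
  sim <- ifelse(den > 0, num / den, inter / uni)
  sim[inter == 0] <- 0

  ## per low record: expand group similarities to cases, take top-k, vote
  lib_ids <- lib$id
  lib_labels <- lib$underlying
  out_cause <- rep(NA_character_, length(low))
  out_nb <- integer(length(low))
  qcodes_list <- split(qlong$code, factor(qlong$rec, levels = low))
  for (j in seq_along(low)) {
    sims_case <- sim[qg_of[j], tg_of]
    cand <- which(sims_case >= min_sim & sims_case > 0 &
                    lib_ids != records$id[low[j]])
    if (length(cand) == 0) next
    ordc <- cand[order(-sims_case[cand], lib_ids[cand])]
    take <- utils::head(ordc, k)
    labs <- lib_labels[take]; s <- sims_case[take]
    qc <- qcodes_list[[j]]
    inchain <- labs %in% qc
    if (any(inchain)) { labs2 <- labs[inchain]; s2 <- s[inchain] }
    else { labs2 <- labs; s2 <- s }
    votes <- tapply(s2, labs2, sum)
    best <- tapply(s2, labs2, max)
    nm <- names(votes)
    out_cause[j] <- nm[order(-unname(votes), -unname(best), nm)[1]]
    out_nb[j] <- length(take)
  }
  list(cause = out_cause, neighbors_used = out_nb)
}

#' Order-preserving batch prediction
#'
#' Thin alias for the `predict()` method, matching the pipeline's
#' element-wise contract.
#'
#' @inheritParams predict.sinkcf_model
#' @param records `death_records` to predict.
#' @export
predict_batch <- function(object, records) predict(object, records)
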