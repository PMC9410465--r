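## Conditional Death Cause Proportion (CDCP) statistics.
##
## For cause i, CDCP_i = P(S_i | T_i): the probability that i is the
## underlying cause of death given that i appears on the cause-of-death
## chain. It is estimated, stratified by age group and gender, as the
## bits-scaled log count ratio
##
##   cdcp = log2( (death_count + s) / (occur_count + s) * 10 )
##
## with an additive pseudo-count s guarding empty strata. A ratio of 1
## scores log2(10) ~ 3.32; a ratio of 0.1 scores 0. The Regional Death
## Cause Proportion (RDCP) n_ij / N_j is carried as a descriptive
## statistic; it plays no part in inference.

#' Construct a counts table
#'
#' Low-level constructor for the stratified occurrence/death counts that
#' drive CDCP estimation. Usually produced by [fit_counts()]; exposed so
#' that scoring scenarios (e.g. worked certificate examples) can be set up
#' with hand-specified counts.
#'
#' @param occur Integer matrix `[cause, stratum]` of records in which the
#'   cause appears anywhere on the chain (including E); strata are the six
#'   `"G0:male"`-style age-gender combinations from [age_group()].
#' @param death Integer matrix of the same shape: records in which the
#'   cause is the adjudicated underlying cause. Must satisfy
#'   `death <= occur` cellwise.
#' @param region_underlying Optional matrix `[cause, region]` of underlying-
#'   cause counts per region (the RDCP numerator n_ij).
#' @param region_total Optional named vector of deaths per region (N_j);
#'   must equal the column sums of `region_underlying`.
#' @param total_records Number of records counted.
#' @return A `counts_table` object.
#' @export
counts_table <- function(occur, death, region_underlying = NULL,
                         region_total = NULL, total_records = 0L) {
  stopifnot(is.matrix(occur), is.matrix(death),
            identical(dim(occur), dim(death)),
            identical(rownames(occur), rownames(death)))
  if (is.null(colnames(occur)) || !all(colnames(occur) == all_strata())) {
    stop("occur/death columns must be the six strata: ",
         paste(all_strata(), collapse = ", "), call. = FALSE)
  }
  if (any(occur < 0) || any(death < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(death > occur)) {
    stop("death count exceeds occurrence count for some (cause, stratum)",
         call. = FALSE)
  }
  if (is.null(region_underlying)) {
    region_underlying <- matrix(0L, nrow = nrow(occur), ncol = 0,
                                dimnames = list(rownames(occur), NULL))
  }
  if (is.null(region_total)) {
    region_total <- colSums(region_underlying)
  }
  if (ncol(region_underlying) > 0 &&
      !isTRUE(all.equal(unname(colSums(region_underlying)),
                        unname(region_total[colnames(region_underlying)])))) {
    stop("region totals must equal per-region sums of underlying counts",
         call. = FALSE)
  }
  structure(list(occur = occur, death = death,
                 region_underlying = region_underlying,
                 region_total = region_total,
                 total_records = as.integer(total_records)),
            class = "counts_table")
}

#' Fit occurrence and death counts from labeled records
#'
#' Counts, per (cause, age group, gender): `occur` — the number of records
#' in which the cause appears anywhere on the chain (A-D or E), with set
#' semantics per record (a code repeated within one chain counts once);
#' `death` — the number of records in which the cause is the labeled
#' underlying cause. A label absent from its own chain still occurs for
#' that record (the adjudicated cause was operative even if the certifier
#' left it off the chain), which keeps `death <= occur` everywhere. Also
#' tallies per-region underlying-cause counts for the RDCP statistic.
#'
#' @param records Labeled `death_records` (every `underlying` present).
#' @return A [counts_table()].
#' @export
fit_counts <- function(records) {
  records <- death_records(records)
  unlabeled <- is.na(records$underlying)
  if (any(unlabeled)) {
    stop("unlabeled record(s): ",
         paste(utils::head(records$id[unlabeled], 5), collapse = ", "),
         call. = FALSE)
  }
  strata <- all_strata()
  rec_stratum <- stratum_id(age_group(records$age), records$gender)

  long <- chain_long(records)
  ## per-record code sets, including the label itself
  sets <- data.frame(row = c(long$row, seq_len(nrow(records))),
                     code = c(long$code, records$underlying),
                     stringsAsFactors = FALSE)
  sets <- unique(sets)
  causes <- sort(unique(sets$code))

  occ <- table(factor(sets$code, levels = causes),
               factor(rec_stratum[sets$row], levels = strata))
  dth <- table(factor(records$underlying, levels = causes),
               factor(rec_stratum, levels = strata))
  occur <- matrix(as.integer(occ), nrow = length(causes),
                  ncol = length(strata), dimnames = list(causes, strata))
  death <- matrix(as.integer(dth), nrow = length(causes),
                  ncol = length(strata), dimnames = list(causes, strata))

  regions <- sort(unique(records$region))
  reg <- table(factor(records$underlying, levels = causes),
               factor(records$region, levels = regions))
  region_underlying <- matrix(as.integer(reg), nrow = length(causes),
                              ncol = length(regions),
                              dimnames = list(causes, regions))

  counts_table(occur, death, region_underlying,
               colSums(region_underlying), nrow(records))
}

#' Regional death cause proportion
#'
#' `rdcp(counts, cause, region)` is the fraction of the region's deaths
#' whose underlying cause is `cause`: n_ij / N_j. Descriptive only; not
#' used by the inference path.
#'
#' @param counts A [counts_table()].
#' @param cause ICD-10 code (vectorized).
#' @param region Region identifier (single value).
#' @return Proportion(s) in \[0, 1\].
#' @export
rdcp <- function(counts, cause, region) {
  stopifnot(inherits(counts, "counts_table"))
  if (!region %in% colnames(counts$region_underlying)) {
    stop("unknown region: ", sQuote(region), call. = FALSE)
  }
  n_j <- counts$region_total[[region]]
  if (n_j <= 0) stop("region ", sQuote(region), " has no deaths", call. = FALSE)
  cause <- validate_code(cause)
  n_ij <- ifelse(cause %in% rownames(counts$region_underlying),
                 counts$region_underlying[cause, region], 0)
  unname(n_ij / n_j)
}

#' Build a CDCP model from a counts table
#'
#' Precomputes, for every (cause, stratum), the bits-scaled CDCP score and
#' its occurrence-weighted version used by the sink and CF strategies.
#'
#' The occurrence weight reflects how often a cause is seen at all, so that
#' a high conditional lethality estimated from a handful of records does
#' not outrank well-attested causes. Schemes:
#' \describe{
#'   \item{`"damped"`}{(default) `log(1 + occ_total) / log(1 + max occ_total)`,
#'     a damped normalized frequency in \[0, 1\]; the globally most frequent
#'     cause gets weight 1, an unseen cause 0.}
#'   \item{`"relative"`}{raw relative frequency `occ_total / max occ_total`.}
#'   \item{`"none"`}{weight 1 for every cause.}
#' }
#' Negative CDCP scores (ratio below 0.1) are floored at 0 before
#' weighting, so weights act as non-negative importances.
#'
#' @param counts A [counts_table()] (or labeled `death_records`, which are
#'   passed through [fit_counts()]).
#' @param smoothing Positive pseudo-count added to both numerator and
#'   denominator of the count ratio. Default 1.
#' @param weight_scheme One of `"damped"`, `"relative"`, `"none"`.
#' @return A `cdcp_model` object.
#' @export
cdcp_model <- function(counts, smoothing = 1,
                       weight_scheme = c("damped", "relative", "none")) {
  if (inherits(counts, "death_records")) counts <- fit_counts(counts)
  stopifnot(inherits(counts, "counts_table"), smoothing > 0)
  weight_scheme <- match.arg(weight_scheme)

  s <- smoothing
  cdcp_mat <- log2((counts$death + s) / (counts$occur + s) * 10)
  occ_total <- rowSums(counts$occur)
  max_occ <- if (length(occ_total) > 0) max(occ_total) else 0
  w <- switch(weight_scheme,
    damped = if (max_occ > 0) log1p(occ_total) / log1p(max_occ)
             else rep(0, length(occ_total)),
    relative = if (max_occ > 0) occ_total / max_occ
               else rep(0, length(occ_total)),
    none = rep(1, length(occ_total))
  )
  names(w) <- rownames(counts$occur)
  weighted_mat <- pmax(cdcp_mat, 0) * w

  structure(list(counts = counts, smoothing = s,
                 weight_scheme = weight_scheme,
                 cdcp_matrix = cdcp_mat, occ_total = occ_total,
                 weights = w, weighted_matrix = weighted_mat),
            class = "cdcp_model")
}

## stratum-wise lookup helpers; unknown causes fall back to the smoothed
## zero-count cell: ratio (0+s)/(0+s) = 1, i.e. cdcp = log2(10), weight per
## scheme (0 for frequency-based schemes, 1 for "none").
lookup_cdcp <- function(model, cause, stratum) {
  known <- cause %in% rownames(model$cdcp_matrix)
  out <- rep(log2(10), length(cause))
  if (any(known)) {
    out[known] <- model$cdcp_matrix[cbind(cause[known], stratum[known])]
  }
  out
}

lookup_weight <- function(model, cause) {
  known <- cause %in% names(model$weights)
  out <- rep(if (model$weight_scheme == "none") 1 else 0, length(cause))
  out[known] <- model$weights[cause[known]]
  out
}

#' CDCP score of a cause in a stratum
#'
#' The bits-scaled conditional death cause proportion
#' `log2((death + s)/(occur + s) * 10)` for the cause in the given age
#' group and gender. Total by construction: a cause never observed in the
#' stratum has a smoothed ratio of 1 and scores `log2(10)`.
#'
#' @param model A [cdcp_model()].
#' @param cause ICD-10 code(s).
#' @param group Age group (`"G0"`, `"G1"`, `"G2"`).
#' @param gender `"male"` or `"female"`.
#' @return Numeric score(s); 0 corresponds to a death/occurrence ratio of
#'   0.1, `log2(10)` to a ratio of 1.
#' @export
cdcp <- function(model, cause, group, gender) {
  stopifnot(inherits(model, "cdcp_model"))
  cause <- validate_code(cause)
  stratum <- stratum_id(group, gender)
  if (!all(stratum %in% all_strata())) stop("unknown stratum", call. = FALSE)
  if (length(stratum) == 1) stratum <- rep(stratum, length(cause))
  lookup_cdcp(model, cause, stratum)
}

#' Occurrence-weighted CDCP score
#'
#' `max(cdcp, 0)` multiplied by the model's occurrence weight for the
#' cause (see [cdcp_model()] for the schemes). This is the per-cause
#' importance used by the sink ranking and by the weighted Jaccard
#' similarity.
#'
#' @inheritParams cdcp
#' @return Non-negative numeric score(s).
#' @export
weighted_cdcp <- function(model, cause, group, gender) {
  pmax(cdcp(model, cause, group, gender), 0) *
    lookup_weight(model, validate_code(cause))
}

#' @export
print.cdcp_model <- function(x, ...) {
  cat("<cdcp_model> ", nrow(x$counts$occur), " causes, ",
      x$counts$total_records, " records, smoothing = ", x$smoothing,
      ", weight scheme = ", x$weight_scheme, "\n", sep = "")
  invisible(x)
}
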