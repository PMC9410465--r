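## Death-certificate records.
##
## The canonical in-memory representation is a data.frame of class
## "death_records" in the same wide layout as the CSV dialect:
##   id, age, gender, region,
##   cause_A, dur_A, ..., cause_E, dur_E,   (codes as character, durations in
##                                           minutes as numeric; NA = absent)
##   underlying, label_in_chain
## cause_A is the direct cause of death; cause_D (when present) the earliest
## antecedent; cause_E the contributing cause off the Part I chain.

RECORD_COLUMNS <- c(
  "id", "age", "gender", "region",
  as.vector(rbind(paste0("cause_", ROLES), paste0("dur_", ROLES))),
  "underlying"
)

#' Validate and normalize ICD-10 category codes
#'
#' Codes are uppercased and trimmed, then checked against the ICD-10
#' category pattern: one letter, two digits, and an optional "." followed by
#' one or two digits (e.g. `"C22.0"`, `"J18"`). Comparison elsewhere in the
#' package is exact string equality on the normalized form.
#'
#' @param raw Character vector of candidate codes.
#' @return Character vector of normalized codes.
#' @examples
#' validate_code(c("c22.0", " J18 "))
#' @export
validate_code <- function(raw) {
  if (length(raw) == 0) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  code <- toupper(trimws(raw))
  bad <- is.na(code) | !grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", code)
  if (any(bad)) {
    stop("invalid ICD-10 code(s): ",
         paste(sQuote(raw[bad]), collapse = ", "), call. = FALSE)
  }
  code
}

#' Assign ages to the three model age groups
#'
#' The population is stratified into three age groups: `G0` = \[0, 18),
#' `G1` = \[18, 55), `G2` = \[55, Inf). Intervals are half-open so every
#' non-negative age maps to exactly one group; ages 18 and 55 fall in the
#' older group.
#'
#' @param age Numeric vector of ages in whole years, all >= 0.
#' @return Character vector of group labels (`"G0"`, `"G1"`, `"G2"`).
#' @examples
#' age_group(c(0, 17, 18, 54, 55, 70))
#' @export
age_group <- function(age) {
  if (any(is.na(age)) || any(age < 0)) {
    stop("age must be a non-negative number of years", call. = FALSE)
  }
  ifelse(age < 18, "G0", ifelse(age < 55, "G1", "G2"))
}

#' Construct a set of death records
#'
#' Validates and normalizes a data.frame in the wide certificate layout
#' (see [read_records()] for the column dialect). Codes are normalized with
#' [validate_code()]; missing optional columns are added as `NA`. Records
#' whose `underlying` label does not appear among the chain codes (including
#' the contributing cause E) are legal — the contributing cause or an
#' unlisted cause can be the adjudicated underlying cause — and are only
#' flagged via the `label_in_chain` column.
#'
#' @param df A data.frame with at least `id`, `age`, `gender`, `cause_A`.
#' @return A `death_records` data.frame.
#' @export
death_records <- function(df) {
  ## objects are validated at construction; subsets keep the class, so a
  ## death_records input passes through untouched
  if (inherits(df, "death_records")) return(df)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- c("id", "age", "gender", "cause_A")
  miss <- setdiff(mandatory, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(RECORD_COLUMNS, names(df))) {
    df[[col]] <- if (startsWith(col, "dur_")) NA_real_ else NA_character_
  }
  df <- df[RECORD_COLUMNS]

  df$id <- as.character(df$id)
  if (any(is.na(df$id) | df$id == "")) {
    stop("record id must be a non-empty string (row ",
         which(is.na(df$id) | df$id == "")[1], ")", call. = FALSE)
  }
  df$age <- as.integer(df$age)
  if (any(is.na(df$age) | df$age < 0)) {
    stop("age must be a non-negative integer (row ",
         which(is.na(df$age) | df$age < 0)[1], ")", call. = FALSE)
  }
  df$gender <- as.character(df$gender)
  if (!all(df$gender %in% GENDERS)) {
    stop("gender must be one of ", paste(GENDERS, collapse = ", "),
         " (row ", which(!df$gender %in% GENDERS)[1], ")", call. = FALSE)
  }
  df$region <- as.character(df$region)
  df$region[is.na(df$region) | df$region == ""] <- "unknown"

  for (role in ROLES) {
    cc <- paste0("cause_", role)
    dc <- paste0("dur_", role)
    v <- as.character(df[[cc]])
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    present <- !is.na(v)
    if (any(present)) v[present] <- validate_code(v[present])
    df[[cc]] <- v
    d <- suppressWarnings(as.numeric(df[[dc]]))
    if (any(!is.na(d) & d <= 0)) {
      stop("duration for role ", role, " must be positive (row ",
           which(!is.na(d) & d <= 0)[1], ")", call. = FALSE)
    }
    df[[dc]] <- d
  }
  if (any(is.na(df$cause_A))) {
    stop("cause_A (direct cause) is mandatory (row ",
         which(is.na(df$cause_A))[1], ")", call. = FALSE)
  }
  u <- as.character(df$underlying)
  u[!is.na(u) & trimws(u) == ""] <- NA_character_
  if (any(!is.na(u))) u[!is.na(u)] <- validate_code(u[!is.na(u)])
  df$underlying <- u

  chain <- as.matrix(df[paste0("cause_", ROLES)])
  df$label_in_chain <- is.na(u) | rowSums(chain == u, na.rm = TRUE) > 0
  rownames(df) <- NULL
  class(df) <- c("death_records", "data.frame")
  df
}

#' Build a single death record
#'
#' Convenience constructor for one certificate. `chain` is a named character
#' vector or list of ICD-10 codes keyed by role (`A` mandatory, `B`-`D`
#' antecedents, `E` contributing); `durations` an optional named numeric
#' vector of durations in minutes keyed the same way.
#'
#' @param id Record identifier.
#' @param age Age in years.
#' @param gender `"male"` or `"female"`.
#' @param chain Named codes by role, e.g. `c(A = "A41.9", B = "C22.0")`.
#' @param region Region identifier (opaque string).
#' @param durations Optional named durations in minutes.
#' @param underlying Optional adjudicated underlying-cause code.
#' @return A one-row `death_records` data.frame.
#' @export
death_record <- function(id, age, gender, chain, region = "unknown",
                         durations = NULL, underlying = NA) {
  chain <- unlist(chain)
  if (is.null(names(chain)) || !all(names(chain) %in% ROLES)) {
    stop("chain must be named with roles ", paste(ROLES, collapse = ","),
         call. = FALSE)
  }
  row <- data.frame(id = id, age = age, gender = gender, region = region,
                    underlying = if (is.na(underlying)) NA_character_ else underlying,
                    stringsAsFactors = FALSE)
  for (role in ROLES) {
    row[[paste0("cause_", role)]] <-
      if (role %in% names(chain)) unname(chain[[role]]) else NA_character_
    row[[paste0("dur_", role)]] <-
      if (!is.null(durations) && role %in% names(durations))
        unname(durations[[role]]) else NA_real_
  }
  death_records(row)
}

#' Long view of the cause chains
#'
#' Expands the wide record layout into one row per (record, role, code),
#' dropping absent roles. Used internally by scoring and counting.
#'
#' @param records A `death_records` data.frame.
#' @param include_e Include the contributing cause E? Default `TRUE`.
#' @return data.frame with columns `row` (record index), `id`, `role`,
#'   `code`, `dur_min`.
#' @export
chain_long <- function(records, include_e = TRUE) {
  roles <- if (include_e) ROLES else PART1_ROLES
  out <- lapply(roles, function(role) {
    code <- records[[paste0("cause_", role)]]
    keep <- !is.na(code)
    data.frame(row = which(keep), id = records$id[keep],
               role = rep(role, sum(keep)),
               code = code[keep],
               dur_min = records[[paste0("dur_", role)]][keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$row, match(out$role, ROLES)), , drop = FALSE]
}

## ---- duration strings ("<number><unit>", unit in min|h|d|mo|y) ----

DUR_UNIT_MIN <- c(min = 1, h = 60, d = 1440, mo = 43200, y = 525600)

parse_duration <- function(x) {
  out <- rep(NA_real_, length(x))
  present <- !is.na(x) & trimws(x) != ""
  if (!any(present)) return(out)
  s <- trimws(x[present])
  m <- regmatches(s, regexec("^([0-9]*\\.?[0-9]+)(min|h|d|mo|y)$", s))
  bad <- vapply(m, length, 0L) != 3
  if (any(bad)) {
    stop("malformed duration(s): ", paste(sQuote(s[bad]), collapse = ", "),
         call. = FALSE)
  }
  val <- vapply(m, function(g) as.numeric(g[2]) * DUR_UNIT_MIN[[g[3]]], 0)
  if (any(val <= 0)) stop("duration must be positive", call. = FALSE)
  out[present] <- val
  out
}

format_duration <- function(minutes) {
  out <- rep("", length(minutes))
  present <- !is.na(minutes)
  out[present] <- vapply(minutes[present], function(m) {
    for (u in c("y", "mo", "d", "h")) {
      if (m %% DUR_UNIT_MIN[[u]] == 0) {
        return(paste0(format(m / DUR_UNIT_MIN[[u]], scientific = FALSE), u))
      }
    }
    paste0(format(m, scientific = FALSE), "min")
  }, "")
  out
}

## ---- readers / writers ----

#' Read death records from CSV or JSON
#'
#' CSV dialect (UTF-8, header required): columns
#' `id,age,gender,region,cause_A,dur_A,...,cause_E,dur_E,underlying`; the
#' empty string means absent; durations are written `<number><unit>` with
#' unit one of `min`, `h`, `d`, `mo`, `y` (e.g. `5y`, `6h`, `20min`).
#' JSON dialect: an array of objects with the same scalar fields and the
#' chain as a nested array of `{code, role, duration: {value, unit}}`.
#'
#' @param source Path to the input file.
#' @param format `"csv"` or `"json"`.
#' @return A `death_records` data.frame, input order preserved.
#' @export
read_records <- function(source, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.character(source) && !file.exists(source)) {
    stop("cannot open records file: ", source, call. = FALSE)
  }
  if (format == "csv") {
    df <- utils::read.csv(source, colClasses = "character",
                          stringsAsFactors = FALSE)
    mandatory <- c("id", "age", "gender", "cause_A")
    miss <- setdiff(mandatory, names(df))
    if (length(miss) > 0) {
      stop("CSV is missing mandatory column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (nrow(df) > 0) {
      blank_a <- is.na(df$cause_A) | trimws(df$cause_A) == ""
      if (any(blank_a)) {
        stop("missing cause_A at row ", which(blank_a)[1], call. = FALSE)
      }
      for (role in ROLES) {
        dc <- paste0("dur_", role)
        if (dc %in% names(df)) df[[dc]] <- parse_duration(df[[dc]])
      }
    }
    death_records(df)
  } else {
    objs <- jsonlite::fromJSON(source, simplifyVector = FALSE)
    rows <- lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      for (f in c("id", "age", "gender")) {
        if (is.null(o[[f]])) {
          stop("record ", i, " is missing mandatory field ", sQuote(f),
               call. = FALSE)
        }
      }
      row <- data.frame(
        id = as.character(o$id), age = o$age, gender = o$gender,
        region = if (is.null(o$region)) NA_character_ else o$region,
        underlying = if (is.null(o$underlying)) NA_character_ else o$underlying,
        stringsAsFactors = FALSE)
      for (role in ROLES) {
        row[[paste0("cause_", role)]] <- NA_character_
        row[[paste0("dur_", role)]] <- NA_real_
      }
      for (entry in o$chain) {
        role <- entry$role
        if (is.null(role) || !role %in% ROLES) {
          stop("record ", i, ": chain entry with missing or invalid role",
               call. = FALSE)
        }
        row[[paste0("cause_", role)]] <- entry$code
        if (!is.null(entry$duration)) {
          row[[paste0("dur_", role)]] <-
            entry$duration$value * DUR_UNIT_MIN[[entry$duration$unit]]
        }
      }
      row
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(df)) {
      df <- data.frame(id = character(0), age = integer(0),
                       gender = character(0), cause_A = character(0),
                       stringsAsFactors = FALSE)
    }
    death_records(df)
  }
}

#' Write death records to CSV or JSON
#'
#' Emits the dialect documented in [read_records()]; the output re-reads to
#' an identical `death_records` object. Durations are written in the largest
#' exact unit (e.g. 2880 minutes as `2d`).
#'
#' @param records A `death_records` data.frame.
#' @param sink Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `sink`.
#' @export
write_records <- function(records, sink, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- death_records(records)
  if (format == "csv") {
    out <- records[RECORD_COLUMNS]
    for (role in ROLES) {
      dc <- paste0("dur_", role)
      out[[dc]] <- format_duration(out[[dc]])
    }
    for (col in names(out)) {
      v <- out[[col]]
      if (is.character(v)) v[is.na(v)] <- ""
      out[[col]] <- v
    }
    utils::write.csv(out, sink, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    objs <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      chain <- list()
      for (role in ROLES) {
        code <- r[[paste0("cause_", role)]]
        if (is.na(code)) next
        entry <- list(code = code, role = role)
        dur <- r[[paste0("dur_", role)]]
        if (!is.na(dur)) {
          s <- format_duration(dur)
          unit <- sub("^[0-9.]+", "", s)
          entry$duration <- list(value = as.numeric(sub("[a-z]+$", "", s)),
                                 unit = unit)
        }
        chain[[length(chain) + 1]] <- entry
      }
      o <- list(id = r$id, age = r$age, gender = r$gender,
                region = r$region, chain = chain)
      if (!is.na(r$underlying)) o$underlying <- r$underlying
      o
    })
    jsonlite::write_json(objs, sink, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(sink)
}

#' @export
print.death_records <- function(x, ...) {
  cat("<death_records> ", nrow(x), " record(s), ",
      sum(!is.na(x$underlying)), " labeled\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
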