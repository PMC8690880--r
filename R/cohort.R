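#' Build a cohort of LIS-style records
#'
#' A cohort is a tibble of one row per subject visit with the columns
#' `subject_id`, `name_key`, `sex`, `age`, `visit_date` and the six analyte
#' columns of [ri_analytes()]. Analyte cells may be `NA` (missing); a record
#' then simply does not participate in that analyte's estimation, which is
#' why per-analyte n differ downstream.
#'
#' @param records A data frame with the cohort columns.
#' @param provenance Free-text source label stored as an attribute.
#' @param seed Optional integer seed recorded for synthetic cohorts.
#' @return A `lis_cohort` tibble.
#' @export
as_cohort <- function(records, provenance = "unspecified", seed = NULL) {
  required <- cohort_columns()
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("missing cohort column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(records)[required]
  out$subject_id <- as.character(out$subject_id)
  out$name_key <- as.character(out$name_key)
  out$sex <- validate_sex(out$sex)
  out$age <- as.integer(out$age)
  out$visit_date <- as.Date(out$visit_date)
  for (a in analyte_codes()) out[[a]] <- as.numeric(out[[a]])
  structure(out,
            class = c("lis_cohort", class(tibble::tibble())),
            provenance = provenance, seed = seed)
}

cohort_columns <- function() {
  c("subject_id", "name_key", "sex", "age", "visit_date", analyte_codes())
}

#' @export
print.lis_cohort <- function(x, ...) {
  cat(sprintf("<lis_cohort> %d records, provenance: %s\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-level validity per the record invariants. Returns a character reason
# per row, NA when valid.
record_reject_reason <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- msg
  }
  flag(is.na(df$subject_id) | df$subject_id == "", "missing subject_id")
  flag(!(toupper(as.character(df$sex)) %in% c("M", "F", "MALE", "FEMALE")),
       "invalid sex")
  flag(is.na(df$age), "non-numeric age")
  flag(df$age < 0, "negative age")
  flag(is.na(df$visit_date), "unparseable visit_date")
  for (a in c("cd3_pct", "cd4_pct", "cd8_pct")) {
    flag(df[[a]] < 0 | df[[a]] > 100, paste0(a, " outside [0, 100]"))
  }
  for (a in c("cd3_count", "cd4_count", "cd8_count")) {
    flag(df[[a]] < 0, paste0("negative ", a))
  }
  subset_ok <- df$cd4_count + df$cd8_count <= df$cd3_count + 1e-9
  complete <- !is.na(df$cd3_count) & !is.na(df$cd4_count) & !is.na(df$cd8_count)
  flag(complete & !subset_ok, "cd4_count + cd8_count exceeds cd3_count")
  reason
}

#' Read a cohort from CSV
#'
#' Reads a UTF-8 CSV with header
#' `subject_id,name_key,sex,age,visit_date,cd3_pct,cd4_pct,cd8_pct,cd3_count,cd4_count,cd8_count`
#' (sex `M`/`F`, ISO-8601 dates, empty cell = missing analyte). Malformed
#' rows — non-numeric analyte cells, negative ages, percentages outside
#' \[0, 100\], CD4+CD8 counts exceeding the CD3 count — are rejected, counted
#' and reported in the `rejects` attribute (a tibble of `row`, `reason`),
#' never silently dropped.
#'
#' @param path CSV file path.
#' @param provenance Source label; defaults to the file path.
#' @return A `lis_cohort`; `attr(, "rejects")` holds the rejects report and
#'   `attr(, "n_rejected")` its size.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cohort_columns(), names(raw))
  if (length(missing)) {
    stop("cohort CSV lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[cohort_columns()]
  df <- tibble::as_tibble(raw)
  suppressWarnings({
    df$age <- as.numeric(df$age)
    df$visit_date <- as.Date(df$visit_date, format = "%Y-%m-%d")
    for (a in analyte_codes()) {
      cell <- trimws(df[[a]])
      val <- as.numeric(cell)
      val[cell == ""] <- NA_real_
      # distinguish empty (missing, allowed) from garbage (reject)
      attr(val, "garbage") <- cell != "" & is.na(val)
      df[[a]] <- val
    }
  })
  garbage <- Reduce(`|`, lapply(analyte_codes(),
                                function(a) attr(df[[a]], "garbage")))
  reason <- record_reject_reason(df)
  reason[garbage & is.na(reason)] <- "non-numeric analyte cell"
  keep <- is.na(reason)
  rejects <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  cohort <- as_cohort(df[keep, ], provenance = provenance)
  attr(cohort, "rejects") <- rejects
  attr(cohort, "n_rejected") <- nrow(rejects)
  cohort
}

#' Write a cohort (and its rejects report) to CSV
#'
#' Round-trips through [read_cohort()]: record order and every field are
#' preserved for well-formed cohorts.
#'
#' @param cohort A `lis_cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[cohort_columns()]
  df$visit_date <- format(df$visit_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_rejects <- function(cohort, path) {
  rej <- attr(cohort, "rejects") %||% tibble::tibble(row = integer(),
                                                     reason = character())
  utils::write.csv(as.data.frame(rej), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove duplicate individuals
#'
#' LIS extracts contain repeat visits; following routine practice for
#' indirect reference-interval studies, one record is kept per individual,
#' identified by the key (`subject_id`, `name_key`, `age`). The retained
#' record is the earliest by `visit_date` (first presentation), with ties
#' broken by input order. Idempotent.
#'
#' @param cohort A `lis_cohort`.
#' @param keep `"earliest"` (default) or `"latest"` visit per key.
#' @return A list with `cohort` (deduplicated, original relative order) and
#'   `removed` (number of records dropped).
#' @examples
#' spec <- default_cohort_spec(n_per_stratum = 30, seed = 1)
#' dd <- deduplicate(generate_cohort(spec))
#' dd$removed
#' @export
deduplicate <- function(cohort, keep = c("earliest", "latest")) {
  keep <- match.arg(keep)
  key <- paste(cohort$subject_id, cohort$name_key, cohort$age, sep = "\r")
  date_key <- as.numeric(cohort$visit_date)
  if (keep == "latest") date_key <- -date_key
  ord <- order(key, date_key, seq_len(nrow(cohort)))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  out <- cohort[sel, ]
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "seed") <- attr(cohort, "seed")
  list(cohort = out, removed = nrow(cohort) - length(sel))
}

#' Stratify a cohort by sex and age band
#'
#' @param cohort A `lis_cohort`.
#' @return The cohort with `band` and `stratum` columns appended (`NA` for
#'   ages outside 14-100, which are excluded from estimation); the count of
#'   out-of-range records is in `attr(, "n_out_of_range")`.
#' @export
cohort_strata <- function(cohort) {
  s <- assign_stratum(cohort$sex, cohort$age)
  cohort$band <- s$band
  cohort$stratum <- s$stratum
  attr(cohort, "n_out_of_range") <- sum(is.na(s$band))
  cohort
}
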