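#' Cohort validation filters
#'
#' Before any model is fitted, records with incomplete input data or with
#' values outside common clinical ranges are excluded: ASA grade must be
#' 1, 2 or 3; age must lie in \[30, 100\] years; BMI in \[15, 55\] kg/m^2
#' (all bounds inclusive). Each rejected record carries a single reason
#' code, determined by the first failing rule in the order: completeness,
#' ASA, age, BMI.
#'
#' @name cohort_filters
NULL

filter_reasons <- c("incomplete", "asa_out_of_range",
                    "age_out_of_range", "bmi_out_of_range")

#' Apply the exclusion rules to a cohort table
#'
#' @param records data frame, one row per surgical episode.
#' @param required character vector of fields that must be present and
#'   non-missing for a record to count as complete. Defaults to the core
#'   biometric fields; model bundles may extend this list.
#' @return An object of class `filter_report`: a list with `kept`
#'   (data frame), `rejected` (data frame with an extra `reason` column),
#'   and `counts` (named integer vector over all reason codes).
#' @export
apply_filters <- function(records,
                          required = c("age", "sex", "bmi", "asa",
                                       "joint", "surgery_group", "prom_pre")) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  is_missing <- function(v) is.na(v) | (is.character(v) & !is.na(v) & v == "")
  absent_cols <- setdiff(required, names(records))
  incomplete <- if (length(absent_cols)) rep(TRUE, n) else {
    if (n == 0L) logical(0) else
      Reduce(`|`, lapply(records[required], is_missing))
  }
  reason[incomplete] <- "incomplete"

  asa <- suppressWarnings(as.numeric(records$asa %||% rep(NA, n)))
  age <- suppressWarnings(as.numeric(records$age %||% rep(NA, n)))
  bmi <- suppressWarnings(as.numeric(records$bmi %||% rep(NA, n)))
  flag <- function(bad) is.na(reason) & !is.na(bad) & bad
  reason[flag(ifelse(is.na(asa), NA, !asa %in% c(1, 2, 3)))] <- "asa_out_of_range"
  reason[flag(age < 30 | age > 100)] <- "age_out_of_range"
  reason[flag(bmi < 15 | bmi > 55)] <- "bmi_out_of_range"

  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  counts <- vapply(filter_reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  structure(list(kept = kept, rejected = rejected, counts = counts),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d of %d record(s)\n",
              nrow(x$kept), nrow(x$kept) + nrow(x$rejected)))
  for (r in names(x$counts))
    if (x$counts[[r]] > 0) cat(sprintf("  %-18s %d\n", r, x$counts[[r]]))
  invisible(x)
}

#' Export a filter report as a plain-text summary
#'
#' @param report a `filter_report`.
#' @param path file to write; when `NULL`, the lines are returned invisibly.
#' @return Character vector of report lines, invisibly.
#' @export
write_filter_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  lines <- c(sprintf("kept\t%d", nrow(report$kept)),
             sprintf("rejected\t%d", nrow(report$rejected)),
             sprintf("%s\t%d", names(report$counts), report$counts))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Recode the competing event as censoring
#'
#' Death and revision are modelled separately as cause-specific hazards:
#' when modelling one event the other is treated as censoring at its
#' occurrence time. If both events are recorded at the same time, the
#' target event wins (counted as observed).
#'
#' @param records data frame with `time` (follow-up, years) and indicator
#'   columns `death` and `revision` (0/1).
#' @param target_event `"death"` or `"revision"`.
#' @return The input data frame with an `event` column for the target
#'   event (other columns preserved).
#' @export
recode_competing_event <- function(records, target_event = c("death", "revision")) {
  target_event <- match.arg(target_event)
  stopifnot(is.data.frame(records))
  needed <- c("time", "death", "revision")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records must carry follow-up and both event indicators; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- records
  out$event <- as.numeric(records[[target_event]])
  if (!all(out$event %in% c(0, 1)))
    stop("event indicators must be 0/1", call. = FALSE)
  out
}

#' Read a cohort table from delimited text
#'
#' Cohort tables are comma-separated UTF-8 text with a header row; missing
#' values are empty fields.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Write a cohort table to delimited text
#'
#' @param cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
}
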