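# Strict CSV I/O for the three table schemas. Fixed dialect: header, UTF-8,
# "." decimal, empty string for a missing RT — chosen for bit-exact
# round-trips.

TRIAL_SCHEMAS <- list(
  ant = list(
    columns = c(
      "subject_id", "block", "alerting", "orienting", "congruency",
      "responded", "rt_ms", "correct"
    ),
    classes = c(
      "character", "integer", "character", "character",
      "integer", "numeric", "integer"
    )
  ),
  mft = list(
    columns = c(
      "subject_id", "block", "set_size", "majority_n", "minority_n",
      "exposure_s", "responded", "rt_ms", "correct"
    )
  ),
  subjects = list(
    columns = c(
      "subject_id", "group", "sex", "age", "school",
      "snap_inatt_n", "snap_hyper_n", "asq_parent", "asq_teacher"
    )
  )
)

check_columns <- function(found, expected, path) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) > 0) {
    stop(
      sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  if (length(extra) > 0) {
    stop(
      sprintf("%s: unexpected column(s): %s", path, paste(extra, collapse = ", ")),
      call. = FALSE
    )
  }
}

#' Write a trial or subject table to CSV
#'
#' Logical columns (`responded`, `correct`) are written as 0/1; the ANT
#' `alerting` factor is written as 1 (signal present) / 0 (absent); a missing
#' RT (no response) is written as an empty field.
#'
#' @param x Data.frame in internal representation.
#' @param path Output path.
#' @param schema One of `"ant"`, `"mft"`, `"subjects"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path, schema = c("ant", "mft", "subjects")) {
  schema <- match.arg(schema)
  cols <- TRIAL_SCHEMAS[[schema]]$columns
  x <- as.data.frame(x)
  if (schema == "ant" && !is.null(x$alerting) && is.character(x$alerting)) {
    x$alerting <- as.integer(x$alerting == "present")
  }
  if (schema == "subjects") {
    # latent generative columns are optional extras; keep only if present
    extra <- intersect(c("intended_group", "true_ccc", "ceiling_acc", "lapse_rate"), names(x))
    cols <- c(cols, extra)
  }
  check_columns(intersect(names(x), cols), cols, path)
  x <- x[, cols, drop = FALSE]
  for (nm in names(x)) {
    if (is.logical(x[[nm]])) x[[nm]] <- as.integer(x[[nm]])
  }
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a trial or subject table from CSV
#'
#' Columns are validated strictly against the schema (an error names any
#' missing or unexpected column). An empty RT field with `responded = 0` is
#' parsed as a non-response (`rt_ms = NA`); an empty RT on a responded trial
#' is an error, reported with its line number.
#'
#' @param path CSV file path.
#' @param schema One of `"ant"`, `"mft"`, `"subjects"`.
#' @return Data.frame in internal representation (logical `responded` /
#'   `correct`, ANT `alerting` as `"present"`/`"absent"`).
#' @export
read_trials <- function(path, schema = c("ant", "mft", "subjects")) {
  schema <- match.arg(schema)
  cols <- TRIAL_SCHEMAS[[schema]]$columns
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (schema == "subjects") {
    extra <- intersect(c("intended_group", "true_ccc", "ceiling_acc", "lapse_rate"), names(x))
    cols <- c(cols, extra)
  }
  check_columns(names(x), cols, path)
  if (schema %in% c("ant", "mft")) {
    x$responded <- x$responded == 1
    x$correct <- x$correct == 1
    x$rt_ms <- suppressWarnings(as.numeric(x$rt_ms))
    bad <- which(x$responded & is.na(x$rt_ms))
    if (length(bad) > 0) {
      stop(
        sprintf(
          "%s: responded trial without RT at data line %d", path, bad[1] + 1L
        ),
        call. = FALSE
      )
    }
    not_resp_rt <- which(!x$responded & !is.na(x$rt_ms))
    if (length(not_resp_rt) > 0) {
      stop(
        sprintf(
          "%s: RT present on non-responded trial at data line %d",
          path, not_resp_rt[1] + 1L
        ),
        call. = FALSE
      )
    }
  }
  if (schema == "ant") {
    x$alerting <- ifelse(x$alerting == 1, "present", "absent")
  }
  x
}
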