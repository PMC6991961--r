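#' CHW activity diary datasets
#'
#' A diary dataset holds one row per timed activity episode recorded by a
#' community health worker: who (CHW id), where (district, site class), when
#' (day 1-10 of the two-week collection window), what (activity code), how
#' long (travel and activity minutes) and, for home visits, what the visit
#' involved (content codes), which conditions were addressed and who was seen
#' (up to three recipients). Multi-valued fields are stored as
#' semicolon-delimited strings so the dataset round-trips through delimited
#' text unchanged.
#'
#' @param entries A data.frame with columns `chw_id`, `district`,
#'   `site_class`, `day_index`, `activity_code`, `travel_minutes`,
#'   `activity_minutes`, `content_codes`, `condition_codes`,
#'   `recipient_types`.
#' @param provenance Character scalar describing where the entries came from
#'   (a file path or a generator seed description).
#' @param validate If `TRUE` (default), rows failing validation are dropped
#'   and recorded in the `rejected` attribute.
#' @return An object of class `chw_diaries`: the accepted entries with
#'   attributes `provenance`, `rejected` (a data.frame of row, reason) and
#'   `n_input`.
#' @seealso [read_diaries()], [write_diaries()], [generate_diaries()]
#' @export
diary_dataset <- function(entries, provenance = "in-memory",
                          validate = TRUE) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  missing <- setdiff(diary_columns(), names(entries))
  if (length(missing) > 0) {
    stop("diary data is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  entries <- entries[diary_columns()]
  entries$day_index <- as.integer(entries$day_index)
  entries$travel_minutes <- as.numeric(entries$travel_minutes)
  entries$activity_minutes <- as.numeric(entries$activity_minutes)
  for (col in c("chw_id", "district", "site_class", "activity_code",
                "content_codes", "condition_codes", "recipient_types")) {
    entries[[col]] <- as.character(entries[[col]])
    entries[[col]][is.na(entries[[col]])] <- ""
  }
  n_input <- nrow(entries)
  rejected <- data.frame(row = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (validate && n_input > 0) {
    reasons <- validate_diary_rows(entries)
    bad <- !is.na(reasons)
    rejected <- data.frame(row = which(bad), reason = reasons[bad],
                           stringsAsFactors = FALSE)
    entries <- entries[!bad, , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(entries,
            class = c("chw_diaries", "data.frame"),
            provenance = provenance,
            rejected = rejected,
            n_input = n_input)
}

#' Standard diary column order
#'
#' The fixed, documented column order used by [read_diaries()] and
#' [write_diaries()].
#'
#' @return Character vector of column names.
#' @export
diary_columns <- function() {
  c("chw_id", "district", "site_class", "day_index", "activity_code",
    "travel_minutes", "activity_minutes", "content_codes",
    "condition_codes", "recipient_types")
}

# Per-row validation. Returns NA for accepted rows, otherwise a categorised
# reason string. Validation is total: every row is accepted or rejected with
# exactly one (first-failing) reason.
validate_diary_rows <- function(entries) {
  n <- nrow(entries)
  reasons <- rep(NA_character_, n)
  flag <- function(idx, reason) {
    new <- idx & is.na(reasons)
    reasons[new] <<- reason
  }

  dist_ok <- tolower(entries$district) %in% districts()
  flag(!dist_ok, "unknown district")

  flag(!(entries$site_class %in% site_classes()), "unknown site_class")

  flag(is.na(entries$day_index) | entries$day_index < 1 |
         entries$day_index > 10, "day_index outside 1..10 window")

  # Both duration fields are required: medians over silently-imputed zeros
  # would bias the time analysis.
  flag(is.na(entries$travel_minutes), "missing travel_minutes")
  flag(is.na(entries$activity_minutes), "missing activity_minutes")
  flag(entries$travel_minutes < 0, "negative travel_minutes")
  flag(entries$activity_minutes < 0, "negative activity_minutes")

  # District-specific activity vocabulary: unknown codes are rejected, not
  # pooled into "other".
  for (d in districts()) {
    in_d <- dist_ok & tolower(entries$district) == d & is.na(reasons)
    if (any(in_d)) {
      flag(in_d & !(entries$activity_code %in% activity_codes(d)),
           "unknown activity_code")
    }
  }

  check_multi <- function(col, valid, label) {
    vals <- entries[[col]]
    nonempty <- !is.na(vals) & nzchar(vals) & is.na(reasons)
    if (!any(nonempty)) return(invisible())
    ok <- vapply(strsplit(vals[nonempty], ";", fixed = TRUE),
                 function(x) all(trimws(x) %in% valid), logical(1))
    idx <- rep(FALSE, length(vals))
    idx[which(nonempty)[!ok]] <- TRUE
    flag(idx, paste0("unknown ", label, " code"))
  }
  check_multi("content_codes", content_codes(), "content")
  check_multi("condition_codes", condition_codes(), "condition")
  check_multi("recipient_types", recipient_codes(), "recipient")

  # Diaries allow at most three recipients per visit.
  n_rec <- vapply(strsplit(entries$recipient_types, ";", fixed = TRUE),
                  function(x) sum(nzchar(trimws(x))), integer(1))
  flag(n_rec > 3, "more than 3 recipients")

  reasons
}

#' Read a CHW diary file
#'
#' Reads a delimited diary table (comma by default, tab accepted), maps
#' columns through an optional schema, validates every row and returns the
#' accepted episodes. A missing mandatory column is a hard error naming the
#' column; invalid rows are dropped individually and logged in the `rejected`
#' attribute of the result.
#'
#' @param path Path to the diary file.
#' @param schema_config Optional named character vector mapping standard
#'   column names (see [diary_columns()]) to the names used in the file,
#'   e.g. `c(chw_id = "worker")`.
#' @param sep Field separator; `NULL` (default) picks tab for `.tsv`/`.tab`
#'   files and comma otherwise.
#' @return A [diary_dataset()] with provenance set to `path`.
#' @export
read_diaries <- function(path, schema_config = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop("diary file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  if (!is.null(schema_config)) {
    for (std in names(schema_config)) {
      src <- schema_config[[std]]
      if (!src %in% names(raw)) {
        stop("schema_config maps '", std, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  missing <- setdiff(diary_columns(), names(raw))
  if (length(missing) > 0) {
    stop("diary file ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  suppressWarnings({
    raw$day_index <- as.integer(raw$day_index)
    raw$travel_minutes <- as.numeric(raw$travel_minutes)
    raw$activity_minutes <- as.numeric(raw$activity_minutes)
  })
  diary_dataset(raw, provenance = path)
}

#' Write a CHW diary file
#'
#' Writes the dataset in the fixed column order of [diary_columns()] so that
#' `read_diaries(write_diaries(d))` reproduces `d` exactly.
#'
#' @param dataset A `chw_diaries` object.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_diaries <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "chw_diaries"))
  df <- as.data.frame(dataset)[diary_columns()]
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write diary file '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Combined travel and activity time
#'
#' Total episode duration: travel plus activity minutes. Share-of-time and
#' workforce calculations combine the two because a CHW's duty time is
#' consumed by both.
#'
#' @param entry A `chw_diaries` dataset or any data.frame with
#'   `travel_minutes` and `activity_minutes` columns.
#' @return Numeric vector of combined minutes, one per episode.
#' @export
combined_minutes <- function(entry) {
  stopifnot(all(c("travel_minutes", "activity_minutes") %in% names(entry)))
  as.numeric(entry$travel_minutes) + as.numeric(entry$activity_minutes)
}

#' Rows rejected during diary validation
#'
#' @param dataset A `chw_diaries` object.
#' @return data.frame with columns `row` (input row number) and `reason`.
#' @export
rejected_rows <- function(dataset) {
  attr(dataset, "rejected")
}

#' @export
as.data.frame.chw_diaries <- function(x, ...) {
  df <- x
  attr(df, "provenance") <- NULL
  attr(df, "rejected") <- NULL
  attr(df, "n_input") <- NULL
  class(df) <- "data.frame"
  df
}

#' @export
print.chw_diaries <- function(x, ...) {
  rej <- attr(x, "rejected")
  cat("CHW diary dataset: ", nrow(x), " episode(s), ",
      length(unique(x$chw_id)), " CHW(s)\n", sep = "")
  cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  cat("  rejected rows: ", if (is.null(rej)) 0L else nrow(rej), " of ",
      attr(x, "n_input"), " input rows\n", sep = "")
  invisible(x)
}
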