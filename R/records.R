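# Person records: reading, normalization, truth sets.
#
# A person_records object is a data.frame with a record_id column plus the
# eight identifier fields.  Missingness is explicit: NA_character_ is the
# MISSING marker, distinct from the empty string (which normalizes to NA).
# All stored values are normalized (see normalize_field), so encoding and
# blocking operate on a canonical representation.

NAME_LIKE_FIELDS <- c("first_name", "middle_name", "last_name",
                      "suburb", "address")

#' Normalize a raw field value
#'
#' Canonicalizes raw text before CLK encoding: uppercase, trim, collapse
#' internal whitespace.  Name and address fields additionally drop
#' non-alphanumeric characters; dates are canonicalized to `YYYYMMDD`
#' digits (accepted input forms: `YYYYMMDD`, `YYYY-MM-DD`, `YYYY/MM/DD`,
#' `DD/MM/YYYY`, `DD-MM-YYYY`); sex becomes a single-character token
#' (`M`/`F`, other values as their first character).  An empty result is
#' the explicit missing marker `NA_character_`.
#'
#' The function is idempotent: normalizing an already-normalized value is a
#' no-op.  An unparseable or impossible date yields `NA` with a warning and
#' never aborts a load.
#'
#' @param raw Character vector of raw values (NAs allowed).
#' @param field_name One of [person_fields()].
#' @return Character vector of normalized values, `NA` where missing.
#' @examples
#' normalize_field("  smith ", "last_name")   # "SMITH"
#' normalize_field("1990-07-03", "dob")       # "19900703"
#' normalize_field("", "first_name")          # NA
#' @export
normalize_field <- function(raw, field_name) {
  field_name <- match.arg(field_name, PERSON_FIELDS)
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- toupper(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  if (field_name %in% NAME_LIKE_FIELDS) {
    x <- gsub("[^A-Z0-9 ]", "", x)
    x <- trimws(gsub(" +", " ", x))
  } else if (field_name == "dob") {
    x <- normalize_dob(x)
  } else if (field_name == "sex") {
    x <- gsub("[^A-Z0-9]", "", x)
    x <- ifelse(x %in% c("M", "MALE"), "M",
         ifelse(x %in% c("F", "FEMALE"), "F", substr(x, 1L, 1L)))
  } else {  # postcode
    x <- gsub("[^A-Z0-9]", "", x)
  }
  x[!nzchar(x)] <- NA_character_
  x
}

normalize_dob <- function(x) {
  out <- character(length(x))
  # digits-only and separator forms, tried in order
  ymd8 <- grepl("^[0-9]{8}$", x)
  out[ymd8] <- x[ymd8]
  iso <- grepl("^[0-9]{4}[-/][0-9]{1,2}[-/][0-9]{1,2}$", x)
  out[iso] <- vapply(strsplit(x[iso], "[-/]"), function(p)
    sprintf("%04d%02d%02d", as.integer(p[1]), as.integer(p[2]),
            as.integer(p[3])), "")
  dmy <- grepl("^[0-9]{1,2}[-/][0-9]{1,2}[-/][0-9]{4}$", x)
  out[dmy] <- vapply(strsplit(x[dmy], "[-/]"), function(p)
    sprintf("%04d%02d%02d", as.integer(p[3]), as.integer(p[2]),
            as.integer(p[1])), "")
  nonempty <- nzchar(x)
  valid <- nzchar(out) &
    !is.na(as.Date(ifelse(nzchar(out), out, "19000101"), format = "%Y%m%d"))
  bad <- nonempty & !valid
  if (any(bad)) {
    warning("unparseable date value(s) mapped to MISSING: ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    clk_log("warn", "unparseable dates -> MISSING: ",
            paste(unique(x[bad]), collapse = ", "))
  }
  out[!valid] <- ""
  out
}

#' Construct a person_records object from a data frame
#'
#' Values are assumed already normalized; use [read_records()] to load and
#' normalize raw files.  Fields absent from `df` are filled with `NA`
#' (MISSING).
#'
#' @param df Data frame with a `record_id` column and any subset of
#'   [person_fields()].
#' @return A `person_records` data frame with all eight fields.
#' @export
person_records <- function(df) {
  if (!"record_id" %in% names(df)) stop_data("column 'record_id' is required")
  rid <- as.character(df$record_id)
  if (any(is.na(rid) | !nzchar(rid))) stop_data("record_id must be non-empty")
  if (anyDuplicated(rid)) {
    stop_data("duplicate record_id: ",
              paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  out <- data.frame(record_id = rid, stringsAsFactors = FALSE)
  for (f in PERSON_FIELDS) {
    out[[f]] <- if (f %in% names(df)) as.character(df[[f]]) else
      rep(NA_character_, nrow(out))
  }
  class(out) <- c("person_records", "data.frame")
  out
}

#' Read and normalize person records from a delimited file
#'
#' @param path CSV path with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`record_id` plus any of [person_fields()]) to column names in the
#'   file.  Unmapped fields load as MISSING.
#' @param delimiter Field delimiter (default ",").
#' @return A `person_records` data frame; row count equals the file's data
#'   row count (loading never silently drops rows).
#' @export
read_records <- function(path, column_map = NULL, delimiter = ",") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (is.null(column_map)) {
    keep <- intersect(c("record_id", PERSON_FIELDS), names(raw))
    column_map <- setNames(keep, keep)
  }
  if (!"record_id" %in% names(column_map)) {
    stop_data("column_map must map 'record_id'")
  }
  bad_keys <- setdiff(names(column_map), c("record_id", PERSON_FIELDS))
  if (length(bad_keys)) {
    stop_data("unknown field(s) in column_map: ",
              paste(bad_keys, collapse = ", "))
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop_data("mapped column(s) absent from ", path, ": ",
              paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(record_id = raw[[column_map[["record_id"]]]],
                   stringsAsFactors = FALSE)
  for (f in intersect(PERSON_FIELDS, names(column_map))) {
    df[[f]] <- normalize_field(raw[[column_map[[f]]]], f)
  }
  recs <- person_records(df)
  clk_log("info", "read_records: ", path, " rows in=", nrow(raw),
          " records out=", nrow(recs))
  recs
}

#' Write person records to CSV
#'
#' MISSING values are written as empty strings; [read_records()] on the
#' output restores identical normalized values (round-trip property).
#'
#' @param records A `person_records` data frame.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_records <- function(records, path, delimiter = ",") {
  utils::write.table(records, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Construct a truth set from record/entity assignments
#'
#' @param record_id,entity_id Equal-length character vectors; each record
#'   must be assigned exactly one entity.
#' @return A `truth_set` data frame.
#' @export
truth_set <- function(record_id, entity_id) {
  record_id <- as.character(record_id)
  entity_id <- as.character(entity_id)
  if (length(record_id) != length(entity_id)) {
    stop_data("record_id and entity_id lengths differ")
  }
  if (any(is.na(record_id)) || any(is.na(entity_id))) {
    stop_data("truth set entries must be non-missing")
  }
  dup <- duplicated(record_id)
  if (any(dup)) {
    # the same (record, entity) row twice is harmless; conflicts are not
    first <- entity_id[match(record_id, record_id)]
    if (any(entity_id != first)) {
      stop_data("conflicting entity assignment for record(s): ",
                paste(unique(record_id[entity_id != first]), collapse = ", "))
    }
    record_id <- record_id[!dup]
    entity_id <- entity_id[!dup]
  }
  out <- data.frame(record_id = record_id, entity_id = entity_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_set", "data.frame")
  out
}

#' Read a truth set (record_id, entity_id) from CSV
#'
#' @param path Two-column delimited file with header.  An empty file yields
#'   an empty truth set.  A record listed twice with different entities is a
#'   hard error.
#' @param delimiter Field delimiter.
#' @return A `truth_set` data frame.
#' @export
read_truth <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (file.size(path) == 0) return(truth_set(character(0), character(0)))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_data("truth file needs two columns: ", path)
  truth_set(df[[1]], df[[2]])
}

#' Write a truth set to CSV
#' @param truth A `truth_set`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_truth <- function(truth, path, delimiter = ",") {
  utils::write.table(truth, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}
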