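#' Remove records that fall outside their admission window
#'
#' Keeps only event records whose `hadm_id` exists in the admission table and
#' whose timestamp lies within `[admit_time, min(discharge_time, death_time)]`
#' for that admission. Records timestamped after discharge or death are
#' treated as data errors and dropped. Input row order is preserved for the
#' surviving rows.
#'
#' @param records Event table with at least `hadm_id`, `timestamp`.
#' @param admissions Admission table with `hadm_id`, `admit_time`,
#'   `discharge_time`, and optionally `death_time`.
#' @return The filtered event table (same columns, subset of rows).
#' @export
clean_records <- function(records, admissions) {
  assert_columns(records, c("hadm_id", "timestamp"), "event table")
  assert_columns(admissions, c("hadm_id", "admit_time", "discharge_time"),
                 "admission table")
  if (nrow(records) == 0L) return(records)
  idx <- match(records$hadm_id, admissions$hadm_id)
  ts <- parse_timestamp(records$timestamp)
  admit <- parse_timestamp(admissions$admit_time)[idx]
  disc <- parse_timestamp(admissions$discharge_time)[idx]
  if ("death_time" %in% names(admissions)) {
    death <- parse_timestamp(admissions$death_time)[idx]
    end <- pmin(disc, death, na.rm = TRUE)
  } else end <- disc
  keep <- !is.na(idx) & !is.na(ts) & ts >= admit & ts <= end
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Restrict an event table to a clinical context
#'
#' Keeps only records whose `event_id` or `category` is in `include`
#' (numeric entries are matched against event ids, character entries against
#' both category names and vocabulary labels when a vocabulary is supplied).
#' Row order is preserved.
#'
#' @param records Event table.
#' @param include Nonempty vector of event ids and/or category names (labels
#'   allowed when `vocabulary` given).
#' @param vocabulary Optional vocabulary table used to resolve labels.
#' @return Filtered event table.
#' @export
filter_context <- function(records, include, vocabulary = NULL) {
  if (length(include) == 0L)
    stop("'include' must be nonempty", call. = FALSE)
  assert_columns(records, "event_id", "event table")
  ids <- suppressWarnings(as.numeric(include))
  num_ids <- ids[!is.na(ids)]
  chr <- as.character(include[is.na(ids)])
  cats <- unique(records$category %||% character(0))
  lab_ids <- numeric(0)
  if (!is.null(vocabulary)) {
    hit <- chr %in% vocabulary$label
    lab_ids <- vocabulary$event_id[match(chr[hit], vocabulary$label)]
    chr <- chr[!hit]
    cats <- unique(c(cats, vocabulary$category))
  }
  unknown <- chr[!chr %in% cats]
  if (length(unknown) > 0L) {
    warning("ignoring unknown include entries: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    chr <- setdiff(chr, unknown)
  }
  sel_ids <- c(num_ids, lab_ids)
  keep <- records$event_id %in% sel_ids
  if ("category" %in% names(records) && length(chr) > 0L)
    keep <- keep | records$category %in% chr
  records[keep, , drop = FALSE]
}

#' Roll event codes up a vocabulary hierarchy
#'
#' Replaces each `event_id` by its ancestor at depth `level` of the
#' vocabulary's slash-separated hierarchy path. Ids whose path is at most
#' `level` deep (including leaves at exactly that depth) pass through
#' unchanged; ids without a hierarchy path pass through with a warning.
#' Rolled-up ancestors receive deterministic synthetic ids (offset by
#' 1,000,000, assigned in sorted path order); the mapping is attached as the
#' `"rollup_map"` attribute.
#'
#' @param records Event table.
#' @param hierarchy Vocabulary table with `event_id` and `hierarchy` columns.
#' @param level Depth (1 = hierarchy root) at which to cut.
#' @return Event table with rolled-up `event_id`s.
#' @export
rollup_granularity <- function(records, hierarchy, level) {
  assert_columns(records, "event_id", "event table")
  assert_columns(hierarchy, c("event_id", "hierarchy"), "vocabulary")
  stopifnot(level >= 1)
  idx <- match(records$event_id, hierarchy$event_id)
  paths <- hierarchy$hierarchy[idx]
  unmapped <- is.na(idx) | is.na(paths) | paths == ""
  if (any(unmapped))
    warning(sum(unmapped), " record(s) with no hierarchy path pass through ",
            "unchanged", call. = FALSE)
  parts <- strsplit(ifelse(unmapped, "", paths), "/", fixed = TRUE)
  depth <- lengths(parts)
  cut <- !unmapped & depth > level
  prefix <- rep(NA_character_, nrow(records))
  prefix[cut] <- vapply(parts[cut], function(p)
    paste(p[seq_len(level)], collapse = "/"), character(1))
  new_ids <- records$event_id
  if (any(cut)) {
    upaths <- sort(unique(prefix[cut]))
    map <- setNames(1000000L + seq_along(upaths), upaths)
    new_ids[cut] <- unname(map[prefix[cut]])
    attr(records, "rollup_map") <- data.frame(
      event_id = unname(map), hierarchy = upaths, stringsAsFactors = FALSE)
  }
  records$event_id <- new_ids
  records
}

#' Bucket event timestamps by time resolution
#'
#' Adds a numeric `bucket` column used downstream to group events into
#' sequence elements: `"none"` keeps the original timestamp (seconds),
#' `"day"` truncates to the calendar date (and truncates the `timestamp`
#' column accordingly), and `"admission"` collapses each admission to one
#' bucket (positioned at the admission's earliest event so that admissions of
#' the same patient stay ordered in time).
#'
#' @param records Event table.
#' @param resolution One of `"none"`, `"day"`, `"admission"`.
#' @return Event table with a `bucket` column.
#' @export
bucket_time <- function(records, resolution = c("none", "day", "admission")) {
  resolution <- match.arg(resolution)
  assert_columns(records, "timestamp", "event table")
  ts <- parse_timestamp(records$timestamp)
  if (resolution == "none") {
    records$bucket <- as.numeric(ts)
  } else if (resolution == "day") {
    d <- as.Date(ts, tz = "UTC")
    records$timestamp <- as.POSIXct(d, tz = "UTC")
    records$bucket <- as.numeric(d)
  } else {
    assert_columns(records, "hadm_id", "event table")
    first <- tapply(as.numeric(ts), records$hadm_id, min)
    records$bucket <- unname(first[as.character(records$hadm_id)])
  }
  records
}

#' Build a sequence database from an event table
#'
#' Produces one ordered sequence per patient (`unit = "patient"`) or per
#' admission (`unit = "admission"`). Records are ordered by (bucketed
#' timestamp, input row order, event id). In `"event"` mode every record
#' becomes its own single-event element (the convention that reproduces a
#' printed per-row sequence such as (2), (6185), (30)); in `"itemset"` mode
#' all records sharing a bucket form one element whose event ids are
#' de-duplicated and sorted ascending, the standard sequence-mining
#' semantics.
#'
#' @param records Event table (ideally cleaned and bucketed first; without a
#'   `bucket` column the raw timestamp is used).
#' @param unit `"patient"` or `"admission"`.
#' @param mode `"event"` (element per event) or `"itemset"` (element per
#'   bucket).
#' @param vocabulary Optional vocabulary carried along for labeling.
#' @return A `sequence_db`: list with `sequences` (named list; each has
#'   `elements`, a list of integer vectors, and `times`, the element bucket
#'   values), `vocabulary`, `unit`, `n`.
#' @export
#' @examples
#' tab <- data.frame(subject_id = 18803, hadm_id = c(233, 233, 254),
#'                   timestamp = "2189-12-24 07:15:00",
#'                   event_id = c(2, 6185, 30), event_value = 1)
#' db <- build_sequences(tab, unit = "patient", mode = "event")
#' db$sequences[["18803"]]$elements
build_sequences <- function(records, unit = c("admission", "patient"),
                            mode = c("event", "itemset"),
                            vocabulary = NULL) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  key_col <- if (unit == "patient") "subject_id" else "hadm_id"
  assert_columns(records, c(key_col, "event_id"), "event table")
  db <- structure(list(sequences = list(), vocabulary = vocabulary,
                       unit = unit, n = 0L), class = "sequence_db")
  if (nrow(records) == 0L) return(db)
  bucket <- if ("bucket" %in% names(records)) records$bucket
            else as.numeric(parse_timestamp(records$timestamp))
  ord <- order(bucket, seq_len(nrow(records)), records$event_id)
  key <- as.character(records[[key_col]])[ord]
  eid <- as.integer(records$event_id)[ord]
  bkt <- bucket[ord]
  seqs <- list()
  for (k in unique(key)) {
    sel <- key == k
    if (mode == "event") {
      elements <- lapply(eid[sel], function(e) e)
      times <- bkt[sel]
    } else {
      b <- bkt[sel]; e <- eid[sel]
      ub <- unique(b)  # already sorted nondecreasing
      elements <- lapply(ub, function(x) sort(unique(e[b == x])))
      times <- ub
    }
    seqs[[k]] <- list(elements = elements, times = times)
  }
  db$sequences <- seqs
  db$n <- length(seqs)
  db
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("sequence database: %d sequence(s), unit = %s\n", x$n, x$unit))
  ks <- head(names(x$sequences), 5L)
  for (k in ks)
    cat(" ", k, ": ", format_pattern(x$sequences[[k]]$elements), "\n", sep = "")
  if (x$n > 5L) cat("  ...\n")
  invisible(x)
}

#' Serialize / restore a sequence database
#'
#' The on-disk form is JSON: `{unit, n, sequences: {key: {elements, times}},
#' vocabulary}`. `read_sequence_db(write_sequence_db(db, f))` reproduces the
#' database exactly.
#'
#' @param db A `sequence_db`.
#' @param path File path.
#' @return `write_sequence_db` returns `path` invisibly; `read_sequence_db`
#'   returns the `sequence_db`.
#' @export
write_sequence_db <- function(db, path) {
  stopifnot(inherits(db, "sequence_db"))
  payload <- list(
    unit = db$unit, n = db$n,
    sequences = lapply(db$sequences, function(s)
      list(elements = lapply(s$elements, as.integer),
           times = as.numeric(s$times))),
    vocabulary = db$vocabulary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sequence_db
#' @export
read_sequence_db <- function(path) {
  payload <- jsonlite::read_json(path)
  seqs <- lapply(payload$sequences, function(s)
    list(elements = lapply(s$elements, function(e)
           as.integer(unlist(e))),
         times = as.numeric(unlist(s$times))))
  vocab <- payload$vocabulary
  if (!is.null(vocab)) {
    vocab <- do.call(rbind, lapply(vocab, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  structure(list(sequences = seqs, vocabulary = vocab,
                 unit = payload$unit, n = as.integer(payload$n)),
            class = "sequence_db")
}

# "(2), (6185), (30)" rendering used by print methods and the pattern table
format_pattern <- function(elements) {
  paste(vapply(elements, function(e) paste0("(", paste(e, collapse = ","), ")"),
               character(1)), collapse = ", ")
}
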