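#' Count database sequences containing a sequential pattern
#'
#' A sequence contains a pattern when the pattern's elements can be matched
#' to strictly increasing sequence positions with each pattern element a
#' subset of the sequence element it matches (order-preserving, gap-allowed
#' containment). Implemented as a pure-R greedy earliest-match scan,
#' independent of the compiled miner, so it doubles as a recount oracle.
#'
#' @param db A `sequence_db`.
#' @param pattern Pattern elements: a list of integer vectors, or a plain
#'   integer vector which is interpreted as a chain of single-event elements.
#' @return Integer count of containing sequences.
#' @export
#' @examples
#' tab <- data.frame(subject_id = 1:3, hadm_id = 1:3,
#'                   timestamp = "2120-01-01", event_id = 1, event_value = 1)
#' db <- build_sequences(tab, unit = "patient")
#' pattern_support(db, c(1))
pattern_support <- function(db, pattern) {
  stopifnot(inherits(db, "sequence_db"))
  pattern <- as_pattern_elements(pattern)
  if (length(pattern) == 0L)
    stop("pattern must be nonempty", call. = FALSE)
  sum(vapply(db$sequences, function(s)
    contains_pattern(s$elements, pattern), logical(1)))
}

# normalize pattern input: vector -> singleton elements; sort within elements
as_pattern_elements <- function(pattern) {
  if (!is.list(pattern)) pattern <- lapply(pattern, identity)
  lapply(pattern, function(e) sort(as.integer(e)))
}

# greedy earliest-match containment, pure R
contains_pattern <- function(elements, pattern) {
  pos <- 1L
  n <- length(elements)
  for (pe in pattern) {
    found <- FALSE
    while (pos <= n) {
      if (all(pe %in% elements[[pos]])) { found <- TRUE; pos <- pos + 1L; break }
      pos <- pos + 1L
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Mine closed frequent sequential patterns
#'
#' Finds every sequential pattern whose support count is at least
#' `ceiling(min_support_rate * n)` and that is *closed*: no super-pattern
#' (one containing it as a subsequence, elementwise subset) has equal
#' support. The search is a depth-first prefix-growth over itemset sequences
#' with per-sequence earliest-occurrence projection, followed by a closedness
#' filter over equal-support groups; results are deterministic and sorted by
#' descending support, then ascending pattern size, then event ids.
#'
#' @param db A `sequence_db`.
#' @param min_support_rate Minimum support as a fraction in (0, 1].
#' @param max_len Optional cap on total pattern items (default unlimited).
#' @return A `mining_result`: list with `patterns` (each a list with
#'   `elements`, `support_count`, `support_rate`, `closed`),
#'   `min_support_rate`, `min_support_count`, `db_size`, `elapsed` (seconds,
#'   informational only).
#' @export
mine_closed_patterns <- function(db, min_support_rate, max_len = Inf) {
  stopifnot(inherits(db, "sequence_db"))
  if (!is.numeric(min_support_rate) || length(min_support_rate) != 1L ||
      min_support_rate <= 0 || min_support_rate > 1)
    stop("min_support_rate must lie in (0, 1]", call. = FALSE)
  if (db$n == 0L) stop("sequence database is empty", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  min_count <- as.integer(ceiling(min_support_rate * db$n))
  raw <- lapply(db$sequences, function(s) lapply(s$elements, as.integer))
  res <- cpp_mine_frequent(unname(raw), min_count,
                           if (is.finite(max_len)) as.integer(max_len) else 0L)
  keep <- cpp_filter_closed(res$patterns, res$supports)
  pats <- res$patterns[keep]
  sups <- res$supports[keep]
  make_mining_result(pats, sups, db$n, min_support_rate, min_count,
                     proc.time()[["elapsed"]] - t0)
}

make_mining_result <- function(pats, sups, n, rate, min_count, elapsed) {
  ord <- pattern_order(pats, sups)
  pats <- pats[ord]; sups <- sups[ord]
  patterns <- mapply(function(p, s) {
    list(elements = lapply(p, as.integer), support_count = as.integer(s),
         support_rate = s / n, closed = TRUE)
  }, pats, sups, SIMPLIFY = FALSE)
  structure(list(patterns = patterns, min_support_rate = rate,
                 min_support_count = min_count, db_size = n,
                 elapsed = elapsed),
            class = "mining_result")
}

# canonical sort: support desc, total items asc, then event ids
pattern_order <- function(pats, sups) {
  if (length(pats) == 0L) return(integer(0))
  size <- vapply(pats, function(p) sum(lengths(p)), integer(1))
  key <- vapply(pats, pattern_key, character(1))
  order(-sups, size, key)
}

pattern_key <- function(p) {
  paste(vapply(p, function(e) paste(sprintf("%09d", e), collapse = ","),
               character(1)), collapse = "|")
}

#' Brute-force closed-pattern oracle
#'
#' Independent reference for [mine_closed_patterns()] on tiny databases:
#' enumerates every candidate pattern occurring in the database (all element
#' subsequences crossed with all nonempty item subsets per element), counts
#' support with the pure-R [pattern_support()], keeps the frequent ones, and
#' removes any pattern with an equal-support super-pattern among all
#' candidates. Guarded to databases with at most 64 total events.
#'
#' @inheritParams mine_closed_patterns
#' @return A `mining_result` with the same sort order as the miner.
#' @export
brute_force_closed_patterns <- function(db, min_support_rate, max_len = Inf) {
  stopifnot(inherits(db, "sequence_db"))
  if (min_support_rate <= 0 || min_support_rate > 1)
    stop("min_support_rate must lie in (0, 1]", call. = FALSE)
  total <- sum(vapply(db$sequences, function(s) sum(lengths(s$elements)),
                      integer(1)))
  if (total > 64L)
    stop("database too large for brute force (", total, " events > 64)",
         call. = FALSE)
  cand <- new.env(parent = emptyenv())
  for (s in db$sequences) enumerate_subsequences(s$elements, max_len, cand)
  keys <- ls(cand)
  pats <- lapply(keys, function(k) get(k, envir = cand))
  sups <- vapply(pats, function(p) pattern_support(db, p), integer(1))
  min_count <- as.integer(ceiling(min_support_rate * db$n))
  closed <- vapply(seq_along(pats), function(i) {
    !any(vapply(seq_along(pats), function(j) {
      j != i && sups[j] == sups[i] &&
        sum(lengths(pats[[j]])) > sum(lengths(pats[[i]])) &&
        contains_pattern(pats[[j]], pats[[i]])
    }, logical(1)))
  }, logical(1))
  keep <- sups >= min_count & closed
  make_mining_result(pats[keep], sups[keep], db$n, min_support_rate,
                     min_count, NA_real_)
}

# all nonempty subsequence patterns of one sequence, deduplicated into `env`
enumerate_subsequences <- function(elements, max_len, env) {
  n <- length(elements)
  subsets_of <- function(x) {
    out <- list()
    for (m in seq_len(2^length(x) - 1L))
      out[[m]] <- x[as.logical(bitwAnd(m, 2^(seq_along(x) - 1L)))]
    out
  }
  elem_subsets <- lapply(elements, function(e) subsets_of(sort(e)))
  recurse <- function(pos, acc, size) {
    if (pos > n) {
      if (length(acc) > 0L) {
        k <- pattern_key(acc)
        if (!exists(k, envir = env, inherits = FALSE))
          assign(k, acc, envir = env)
      }
      return(invisible())
    }
    recurse(pos + 1L, acc, size)                      # skip this element
    for (sub in elem_subsets[[pos]]) {
      if (size + length(sub) <= max_len)
        recurse(pos + 1L, c(acc, list(sub)), size + length(sub))
    }
    invisible()
  }
  recurse(1L, list(), 0L)
  invisible(env)
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf(
    "mining result: %d closed pattern(s), min support %.3f (count >= %d) over %d sequence(s)\n",
    length(x$patterns), x$min_support_rate, x$min_support_count, x$db_size))
  for (p in head(x$patterns, 10L))
    cat(sprintf("  %-40s support %d (%.1f%%)\n",
                format_pattern(p$elements), p$support_count,
                100 * p$support_rate))
  if (length(x$patterns) > 10L) cat("  ...\n")
  invisible(x)
}

#' Serialize a mining result
#'
#' `write_mining_result` writes the JSON form
#' `{db_size, min_support_rate, patterns: [{elements, support_count,
#' support_rate}]}`; `pattern_table` renders the flat two-column
#' "Pattern / Support (%)" table with events joined by `->`, resolving labels
#' through a vocabulary when given.
#'
#' @param result A `mining_result`.
#' @param path Output file.
#' @param vocabulary Optional vocabulary for labels.
#' @return `write_mining_result`: `path`, invisibly. `pattern_table`: a
#'   data.frame with columns `pattern` and `support_pct`.
#' @export
write_mining_result <- function(result, path) {
  stopifnot(inherits(result, "mining_result"))
  jsonlite::write_json(
    list(db_size = result$db_size,
         min_support_rate = result$min_support_rate,
         patterns = lapply(result$patterns, function(p)
           list(elements = p$elements, support_count = p$support_count,
                support_rate = p$support_rate))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mining_result
#' @export
pattern_table <- function(result, vocabulary = NULL) {
  stopifnot(inherits(result, "mining_result"))
  lab <- function(ids) {
    if (!is.null(vocabulary)) {
      m <- match(ids, vocabulary$event_id)
      ifelse(is.na(m), as.character(ids), vocabulary$label[m])
    } else as.character(ids)
  }
  data.frame(
    pattern = vapply(result$patterns, function(p)
      paste(vapply(p$elements, function(e) paste(lab(e), collapse = "+"),
                   character(1)), collapse = " -> "), character(1)),
    support_pct = vapply(result$patterns, function(p)
      round(100 * p$support_rate, 3), numeric(1)),
    stringsAsFactors = FALSE)
}
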