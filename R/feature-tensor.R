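#' Build the samples x timesteps x features tensor
#'
#' One sample per admission. Hospital day `t` (day 1 = admission date) and
#' feature `f` hold the summed event value of event `f` on that day (for
#' 0/1-valued events this is the occurrence count). Stays longer than
#' `max_len` days are truncated to the first `max_len` days
#' (`overflow = "truncate"`, the default) or removed (`overflow = "drop"`);
#' shorter stays are zero-padded, and the mask is a prefix of ones (observed
#' days) followed by zeros (padding).
#'
#' @param records Cleaned event table (`hadm_id`, `timestamp`, `event_id`,
#'   optionally `event_value`).
#' @param admissions Admission table (defines the sample set and stay
#'   lengths).
#' @param labels Optional per-admission binary labels: a data.frame
#'   (`hadm_id`, `label`) or a named vector keyed by `hadm_id`.
#' @param max_len Maximum number of timesteps (days); default 15.
#' @param overflow `"truncate"` or `"drop"` for stays longer than `max_len`.
#' @param feature_ids Optional fixed feature set (event ids); defaults to
#'   all vocabulary ids when `vocabulary` is given, else the observed ids.
#' @param vocabulary Optional vocabulary table.
#' @param max_features Upper bound on the feature count; exceeding it is a
#'   configuration error (default 251).
#' @return A `feature_tensor`: list with `values` (`n x T x F` array),
#'   `mask` (`n x T` 0/1 matrix), `labels`, `feature_index` (event id ->
#'   column), `keys` (hadm ids), `T`, `F`.
#' @export
build_tensor <- function(records, admissions, labels = NULL, max_len = 15L,
                         overflow = c("truncate", "drop"),
                         feature_ids = NULL, vocabulary = NULL,
                         max_features = 251L) {
  overflow <- match.arg(overflow)
  assert_columns(records, c("hadm_id", "timestamp", "event_id"),
                 "event table")
  assert_columns(admissions, c("hadm_id", "admit_time", "discharge_time"),
                 "admission table")
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(vocabulary)) sort(vocabulary$event_id)
                   else sort(unique(records$event_id))
  feature_ids <- sort(as.integer(unique(feature_ids)))
  if (length(feature_ids) > max_features)
    stop(sprintf(
      "feature count %d exceeds the configured maximum of %d",
      length(feature_ids), max_features), call. = FALSE)

  admit <- parse_timestamp(admissions$admit_time)
  disc <- parse_timestamp(admissions$discharge_time)
  stay <- day_index(disc, admit)  # hospital days, day 1 = admission date
  keep <- rep(TRUE, nrow(admissions))
  if (overflow == "drop") keep <- stay <= max_len
  hadm <- admissions$hadm_id[keep]
  stay <- pmin(stay[keep], max_len)
  n <- length(hadm)
  T_ <- as.integer(max_len)
  F_ <- length(feature_ids)
  values <- array(0, dim = c(n, T_, F_))
  mask <- matrix(0, n, T_)
  for (i in seq_len(n)) mask[i, seq_len(stay[i])] <- 1

  idx_adm <- match(records$hadm_id, hadm)
  day <- day_index(parse_timestamp(records$timestamp),
                   admit[keep][pmax(idx_adm, 1L)])
  col <- match(records$event_id, feature_ids)
  val <- if ("event_value" %in% names(records)) {
    v <- suppressWarnings(as.numeric(records$event_value))
    ifelse(is.na(v), 1, v)  # categorical payloads count as occurrences
  } else rep(1, nrow(records))
  ok <- !is.na(idx_adm) & !is.na(col) & !is.na(day) &
    day >= 1L & day <= T_
  # only days inside the (possibly truncated) observed stay
  ok[ok] <- day[ok] <= stay[idx_adm[ok]]
  for (r in which(ok))
    values[idx_adm[r], day[r], col[r]] <-
      values[idx_adm[r], day[r], col[r]] + val[r]

  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels))
      labels <- setNames(labels$label, as.character(labels$hadm_id))
    lab <- as.integer(unname(labels[as.character(hadm)]))
  }
  structure(list(values = values, mask = mask, labels = lab,
                 feature_index = setNames(seq_len(F_), feature_ids),
                 keys = as.character(hadm), T = T_, F = F_),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("feature tensor: %d sample(s) x %d timestep(s) x %d feature(s)\n",
              dim(x$values)[1], x$T, x$F))
  if (!is.null(x$labels))
    cat(sprintf("labels: %d positive / %d total\n",
                sum(x$labels), length(x$labels)))
  invisible(x)
}

# index a feature_tensor by sample positions
subset_tensor <- function(tensor, idx) {
  structure(list(values = tensor$values[idx, , , drop = FALSE],
                 mask = tensor$mask[idx, , drop = FALSE],
                 labels = tensor$labels[idx],
                 feature_index = tensor$feature_index,
                 keys = tensor$keys[idx], T = tensor$T, F = tensor$F),
            class = "feature_tensor")
}

#' Stratified train/validation/test split
#'
#' Splits samples into disjoint, exhaustive subsets with sizes matching the
#' fractions up to rounding, stratified by label: within each class the
#' (seeded) shuffled samples are allocated by largest remainder, so each
#' split's class ratio is within one sample of the overall ratio. The same
#' seed always reproduces the same split.
#'
#' @param tensor A labeled `feature_tensor`.
#' @param fractions Length-3 positive vector `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer seed.
#' @return Named list of three `feature_tensor`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(tensor, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (is.null(tensor$labels))
    stop("tensor has no labels; supply them to build_tensor()", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1",
         call. = FALSE)
  n <- length(tensor$labels)
  classes <- sort(unique(tensor$labels))
  sizes <- stratified_sizes(vapply(classes, function(cl)
    sum(tensor$labels == cl), integer(1)), fractions)
  assign_split <- integer(n)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(tensor$labels == classes[ci])
      idx <- idx[sample.int(length(idx))]
      assign_split[idx] <- rep(1:3, times = sizes[ci, ])
    }
  })
  out <- list(train = subset_tensor(tensor, which(assign_split == 1L)),
              val = subset_tensor(tensor, which(assign_split == 2L)),
              test = subset_tensor(tensor, which(assign_split == 3L)))
  for (part in names(out)) {
    l <- out[[part]]$labels
    if (length(l) == 0L || length(unique(l)) < 2L)
      warning(sprintf("split '%s' lacks one of the classes", part),
              call. = FALSE)
  }
  out
}

# integer apportionment of n by fractions (sums exactly to n)
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# classes x splits allocation: split totals follow largest-remainder sizes
# for the whole sample exactly, while each class stays within one sample of
# its proportional share (base floor + at most one remainder unit)
stratified_sizes <- function(class_n, fractions) {
  totals <- largest_remainder(sum(class_n), fractions)
  raw <- outer(class_n, fractions)
  base <- floor(raw)
  cap_class <- class_n - rowSums(base)     # leftover units per class
  cap_split <- totals - colSums(base)      # leftover slots per split
  frac <- raw - base
  ord <- order(frac, decreasing = TRUE)
  for (cell in ord) {
    ci <- (cell - 1L) %% nrow(base) + 1L
    sj <- (cell - 1L) %/% nrow(base) + 1L
    if (cap_class[ci] > 0L && cap_split[sj] > 0L) {
      base[ci, sj] <- base[ci, sj] + 1L
      cap_class[ci] <- cap_class[ci] - 1L
      cap_split[sj] <- cap_split[sj] - 1L
    }
  }
  # sweep up any units the remainder-ordered pass could not place
  while (any(cap_class > 0L)) {
    ci <- which(cap_class > 0L)[1]
    sj <- which(cap_split > 0L)[1]
    base[ci, sj] <- base[ci, sj] + 1L
    cap_class[ci] <- cap_class[ci] - 1L
    cap_split[sj] <- cap_split[sj] - 1L
  }
  storage.mode(base) <- "integer"
  base
}
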