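#' Average attention over a patient group
#'
#' Entrywise mean of the per-sample attention maps over the selected
#' samples, giving the timesteps x features group heat map. With a single
#' selected sample this is that sample's own (individual) map. Note that
#' when samples have different stay lengths, rows beyond some samples' stays
#' average observed weights with structural zeros, so a mean row sums to at
#' most 1; rows sum to exactly 1 only where all selected samples are
#' unmasked.
#'
#' @param maps An `attention_map` from [extract_attention()].
#' @param subset Optional sample selection: keys or integer positions
#'   (default: all samples). Must be nonempty.
#' @param kind Payload kind recorded on the result (`"mean"` by default;
#'   use `"individual"` when selecting one sample).
#' @return A `heatmap_payload`: list with `matrix` (`T x F`), `days`,
#'   `variables`, `kind`.
#' @export
mean_attention <- function(maps, subset = NULL,
                           kind = c("mean", "individual")) {
  stopifnot(inherits(maps, "attention_map"))
  kind <- match.arg(kind)
  d <- dim(maps$weights)
  idx <- if (is.null(subset)) seq_len(d[1])
         else if (is.character(subset)) match(subset, maps$keys)
         else as.integer(subset)
  if (length(idx) == 0L || anyNA(idx) || any(idx < 1L | idx > d[1]))
    stop("subset must select at least one existing sample", call. = FALSE)
  M <- apply(maps$weights[idx, , , drop = FALSE], c(2, 3), mean)
  heatmap_payload(M, maps$feature_index, kind = kind)
}

heatmap_payload <- function(M, feature_index, kind) {
  structure(list(matrix = M, days = seq_len(nrow(M)),
                 variables = names(feature_index), kind = kind),
            class = "heatmap_payload")
}

#' @export
print.heatmap_payload <- function(x, ...) {
  cat(sprintf("%s attention heat map: %d day(s) x %d variable(s)\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Difference heat map (individual minus group)
#'
#' Entrywise `individual - group`, highlighting where a specific patient's
#' attention deviates from the group average; entries may be negative.
#'
#' @param group Group-average `heatmap_payload`.
#' @param individual Individual (or second group) `heatmap_payload` of the
#'   same shape.
#' @return A `heatmap_payload` with `kind = "difference"`.
#' @export
attention_difference <- function(group, individual) {
  stopifnot(inherits(group, "heatmap_payload"),
            inherits(individual, "heatmap_payload"))
  if (!identical(dim(group$matrix), dim(individual$matrix)))
    stop("heat-map shapes do not match", call. = FALSE)
  out <- group
  out$matrix <- individual$matrix - group$matrix
  out$kind <- "difference"
  out
}

#' Filter heat-map entries above a weight threshold
#'
#' @param payload A `heatmap_payload`.
#' @param threshold Minimum value to keep.
#' @return data.frame (`day`, `variable`, `value`) with entries
#'   `>= threshold`, sorted by descending value (ties by day then variable).
#' @export
threshold_filter <- function(payload, threshold) {
  stopifnot(inherits(payload, "heatmap_payload"))
  M <- payload$matrix
  keep <- which(M >= threshold, arr.ind = TRUE)
  out <- data.frame(day = payload$days[keep[, 1]],
                    variable = payload$variables[keep[, 2]],
                    value = M[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$value, out$day, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank variables by aggregated attention
#'
#' Aggregates each variable's heat-map values over days (`"sum"` by default,
#' `"mean"` over days as an option) and returns the top `k`, with ties broken
#' by variable label. With `group_by_category = TRUE` the ranked events are
#' nested under their vocabulary category with category totals (the treemap
#' payload).
#'
#' @param payload A `heatmap_payload`.
#' @param k Number of variables to return; `k` greater than the number of
#'   variables returns all of them with a warning.
#' @param group_by_category Nest results by vocabulary category.
#' @param vocabulary Vocabulary table (required when grouping).
#' @param agg `"sum"` or `"mean"` aggregation over days.
#' @return Ungrouped: data.frame (`variable`, `value`) in rank order.
#'   Grouped: list with `categories`, each `(name, total, events)`.
#' @export
top_k_variables <- function(payload, k, group_by_category = FALSE,
                            vocabulary = NULL, agg = c("sum", "mean")) {
  stopifnot(inherits(payload, "heatmap_payload"))
  agg <- match.arg(agg)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  val <- if (agg == "sum") colSums(payload$matrix)
         else colMeans(payload$matrix)
  ranked <- data.frame(variable = payload$variables, value = unname(val),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$value, ranked$variable), , drop = FALSE]
  rownames(ranked) <- NULL
  if (k > nrow(ranked)) {
    warning(sprintf("k = %d exceeds the %d available variables; returning all",
                    k, nrow(ranked)), call. = FALSE)
    k <- nrow(ranked)
  }
  top <- ranked[seq_len(k), , drop = FALSE]
  if (!group_by_category) return(top)
  if (is.null(vocabulary))
    stop("vocabulary is required when group_by_category = TRUE",
         call. = FALSE)
  m <- match(top$variable, as.character(vocabulary$event_id))
  m2 <- match(top$variable, vocabulary$label)
  cat_ <- ifelse(!is.na(m), vocabulary$category[m],
                 ifelse(!is.na(m2), vocabulary$category[m2], "other"))
  cats <- lapply(unique(cat_), function(cn) {
    rows <- top[cat_ == cn, , drop = FALSE]
    list(name = cn, total = sum(rows$value),
         events = unname(Map(function(v, x) list(label = v, value = x),
                             rows$variable, rows$value)))
  })
  totals <- vapply(cats, `[[`, numeric(1), "total")
  list(categories = cats[order(-totals)])
}

#' Seeded sampling of attention maps
#'
#' Uniformly samples a fraction of the samples (without replacement) before
#' aggregation, the way large cohorts are thinned for a treemap view.
#'
#' @param maps An `attention_map`.
#' @param fraction Fraction of samples to keep, in (0, 1].
#' @param seed Integer seed.
#' @return An `attention_map` over the sampled subset.
#' @export
sample_attention <- function(maps, fraction, seed = 1L) {
  stopifnot(inherits(maps, "attention_map"),
            fraction > 0, fraction <= 1)
  n <- dim(maps$weights)[1]
  keep <- with_seed(seed, sort(sample.int(n, max(1L, round(fraction * n)))))
  structure(list(weights = maps$weights[keep, , , drop = FALSE],
                 mask = maps$mask[keep, , drop = FALSE],
                 feature_index = maps$feature_index,
                 keys = maps$keys[keep]),
            class = "attention_map")
}

#' Export heat-map and treemap payloads as JSON
#'
#' Heat map: `{kind, days, variables, matrix}` with days on the horizontal
#' axis (one matrix row per day). Treemap: `{categories: [{name, total,
#' events: [{label, value}]}]}`.
#'
#' @param payload A `heatmap_payload`, or for `export_treemap` the grouped
#'   result of [top_k_variables()].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
export_heatmap <- function(payload, path = NULL) {
  stopifnot(inherits(payload, "heatmap_payload"))
  json <- jsonlite::toJSON(
    list(kind = payload$kind, days = payload$days,
         variables = payload$variables,
         matrix = unname(apply(payload$matrix, 1, as.numeric,
                               simplify = FALSE))),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(as.character(json))) }
  as.character(json)
}

#' @rdname export_heatmap
#' @export
export_treemap <- function(payload, path = NULL) {
  if (!is.list(payload) || is.null(payload$categories))
    stop("payload must be the grouped result of top_k_variables()",
         call. = FALSE)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(as.character(json))) }
  as.character(json)
}
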