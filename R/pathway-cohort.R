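#' Merge mined patterns into a staged pathway graph
#'
#' Builds the Sankey-style flow graph behind a set of sequential patterns:
#' nodes are keyed by (stage = position within the pattern, event label), so
#' an event recurring at two positions yields two nodes; a node's weight is
#' the summed support count of all patterns whose element at that stage
#' bears that label, and a link's weight is the summed support of patterns
#' containing that consecutive label pair at those stages.
#'
#' @param patterns A `mining_result`, or a list of patterns each with
#'   `elements` and `support_count`.
#' @param vocabulary Optional vocabulary; event ids are rendered as labels
#'   when available (itemset elements are joined with `+`).
#' @return A `pathway_graph`: list with `nodes` (data.frame `id`, `stage`,
#'   `label`, `weight`) and `links` (data.frame `source`, `target`, `weight`
#'   referring to node ids).
#' @export
merge_patterns <- function(patterns, vocabulary = NULL) {
  if (inherits(patterns, "mining_result")) patterns <- patterns$patterns
  if (length(patterns) == 0L)
    stop("patterns must be nonempty", call. = FALSE)
  lab <- function(e) {
    if (!is.null(vocabulary)) {
      m <- match(e, vocabulary$event_id)
      e <- ifelse(is.na(m), as.character(e), vocabulary$label[m])
    }
    paste(e, collapse = "+")
  }
  node_w <- list(); link_w <- list()
  for (p in patterns) {
    labs <- vapply(p$elements, lab, character(1))
    sup <- p$support_count
    for (s in seq_along(labs)) {
      k <- paste0(s - 1L, "\r", labs[s])
      node_w[[k]] <- (node_w[[k]] %||% 0) + sup
    }
    if (length(labs) > 1L) for (s in seq_len(length(labs) - 1L)) {
      k <- paste0(s - 1L, "\r", labs[s], "\r", labs[s + 1L])
      link_w[[k]] <- (link_w[[k]] %||% 0) + sup
    }
  }
  nk <- names(node_w)
  parts <- strsplit(nk, "\r", fixed = TRUE)
  nodes <- data.frame(
    stage = vapply(parts, function(x) as.integer(x[1]), integer(1)),
    label = vapply(parts, `[[`, character(1), 2),
    weight = unlist(node_w, use.names = FALSE),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$stage, nodes$label), , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes)) - 1L
  rownames(nodes) <- NULL
  node_id <- setNames(nodes$id, paste0(nodes$stage, "\r", nodes$label))
  lk <- names(link_w)
  if (length(lk) > 0L) {
    lp <- strsplit(lk, "\r", fixed = TRUE)
    links <- data.frame(
      source = vapply(lp, function(x)
        unname(node_id[paste0(x[1], "\r", x[2])]), integer(1)),
      target = vapply(lp, function(x)
        unname(node_id[paste0(as.integer(x[1]) + 1L, "\r", x[3])]),
        integer(1)),
      weight = unlist(link_w, use.names = FALSE))
    links <- links[order(links$source, links$target), , drop = FALSE]
    rownames(links) <- NULL
  } else {
    links <- data.frame(source = integer(0), target = integer(0),
                        weight = numeric(0))
  }
  structure(list(nodes = nodes[, c("id", "stage", "label", "weight")],
                 links = links),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway graph: %d node(s) over %d stage(s), %d link(s)\n",
              nrow(x$nodes),
              if (nrow(x$nodes)) max(x$nodes$stage) + 1L else 0L,
              nrow(x$links)))
  invisible(x)
}

#' Select a patient cohort by pathway containment
#'
#' Labels every sequence in the database by whether it contains the chosen
#' pathway as an order-preserving, gap-allowed subsequence, with each
#' pathway event treated as a singleton element. The empty pathway matches
#' every sequence. Pathway entries may be event ids or vocabulary labels
#' (resolved through the database's vocabulary).
#'
#' @param db A `sequence_db`.
#' @param pathway Ordered vector of event ids or labels.
#' @return A `cohort_selection`: list with `pathway` (event ids),
#'   `matched_keys`, and `labels`, a named 0/1 integer vector over all
#'   database keys (1 iff matched). Labels are per the database's unit.
#' @export
match_pathway <- function(db, pathway) {
  stopifnot(inherits(db, "sequence_db"))
  ids <- resolve_events(pathway, db$vocabulary)
  keys <- names(db$sequences)
  if (length(ids) == 0L) {
    matched <- keys
  } else {
    pat <- lapply(ids, function(e) e)
    hit <- vapply(db$sequences, function(s)
      contains_pattern(s$elements, pat), logical(1))
    matched <- keys[hit]
  }
  labels <- setNames(as.integer(keys %in% matched), keys)
  structure(list(pathway = ids, matched_keys = matched, labels = labels),
            class = "cohort_selection")
}

# map labels/ids to integer event ids; error listing unknown labels
resolve_events <- function(pathway, vocabulary = NULL) {
  if (length(pathway) == 0L) return(integer(0))
  if (is.numeric(pathway)) return(as.integer(pathway))
  pathway <- as.character(pathway)
  if (is.null(vocabulary))
    stop("pathway given as labels but the database has no vocabulary",
         call. = FALSE)
  m <- match(pathway, vocabulary$label)
  if (anyNA(m))
    stop("unknown event label(s): ",
         paste(pathway[is.na(m)], collapse = ", "), call. = FALSE)
  as.integer(vocabulary$event_id[m])
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("cohort selection: pathway [%s], %d of %d keys matched\n",
              paste(x$pathway, collapse = " -> "),
              length(x$matched_keys), length(x$labels)))
  invisible(x)
}

#' Write cohort labels to a delimited file
#'
#' Two comma-separated columns, `key` and `label`, with a header row.
#'
#' @param selection A `cohort_selection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_labels <- function(selection, path) {
  stopifnot(inherits(selection, "cohort_selection"))
  write.csv(data.frame(key = names(selection$labels),
                       label = unname(selection$labels)),
            path, row.names = FALSE)
  invisible(path)
}

#' Export / import a pathway graph as Sankey JSON
#'
#' The payload is `{nodes: [{id, stage, label, weight}], links: [{source,
#' target, weight}]}` with links referring to node ids. A round trip through
#' `import_sankey(export_sankey(g))` reproduces the graph exactly.
#'
#' @param graph A `pathway_graph`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return `export_sankey`: the JSON string (invisibly when written to file).
#'   `import_sankey`: a `pathway_graph`.
#' @export
export_sankey <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  payload <- list(
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i)
      list(id = graph$nodes$id[i], stage = graph$nodes$stage[i],
           label = graph$nodes$label[i], weight = graph$nodes$weight[i])),
    links = lapply(seq_len(nrow(graph$links)), function(i)
      list(source = graph$links$source[i], target = graph$links$target[i],
           weight = graph$links$weight[i])))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname export_sankey
#' @param json JSON string or file path produced by `export_sankey`.
#' @export
import_sankey <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  nodes <- payload$nodes
  links <- payload$links
  if (length(nodes) == 0L)
    nodes <- data.frame(id = integer(0), stage = integer(0),
                        label = character(0), weight = numeric(0))
  if (length(links) == 0L)
    links <- data.frame(source = integer(0), target = integer(0),
                        weight = numeric(0))
  nodes$id <- as.integer(nodes$id); nodes$stage <- as.integer(nodes$stage)
  nodes$weight <- as.numeric(nodes$weight)
  links$source <- as.integer(links$source)
  links$target <- as.integer(links$target)
  links$weight <- as.numeric(links$weight)
  structure(list(nodes = nodes[, c("id", "stage", "label", "weight")],
                 links = links[, c("source", "target", "weight")]),
            class = "pathway_graph")
}
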