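#' Build the bipartite predictor-condition association multigraph
#'
#' One node per canonical condition label and per canonical predictor
#' label, one edge per corpus record (so parallel edges accumulate when
#' the same pair is studied repeatedly). A label appearing in both roles
#' yields two role-tagged nodes rather than one merged node, preserving
#' bipartiteness; such labels are surfaced by [dual_role_variables()].
#'
#' @param corpus A `corpus`.
#' @param synonyms Optional synonym map for label normalization.
#' @return An undirected `igraph` multigraph with vertex attributes
#'   `label`, `role` (`"condition"` or `"predictor"`), `papers` (edge
#'   degree), `type` (logical bipartite marker, `TRUE` for predictors),
#'   and edge attribute `study_id`.
#' @examples
#' g <- build_network(read_corpus(nhanesaudit_example("table2_depression.csv")))
#' igraph::ecount(g)
#' @export
build_network <- function(corpus, synonyms = NULL) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "label", value = character())
    g <- igraph::set_vertex_attr(g, "role", value = character())
    g <- igraph::set_vertex_attr(g, "papers", value = numeric())
    g <- igraph::set_vertex_attr(g, "type", value = logical())
    return(g)
  }
  pred <- normalize_label(corpus$predictor, synonyms)
  cond <- normalize_label(corpus$outcome, synonyms)
  cond_nodes <- sort(unique(cond))
  pred_nodes <- sort(unique(pred))
  vertices <- data.frame(
    name = c(paste0("condition::", cond_nodes), paste0("predictor::", pred_nodes)),
    label = c(cond_nodes, pred_nodes),
    role = rep(c("condition", "predictor"), c(length(cond_nodes), length(pred_nodes))),
    type = rep(c(FALSE, TRUE), c(length(cond_nodes), length(pred_nodes))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = paste0("predictor::", pred),
    to = paste0("condition::", cond),
    study_id = corpus$study_id,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  igraph::set_vertex_attr(g, "papers", value = igraph::degree(g))
}

vertex_index <- function(graph, label, role, synonyms = NULL) {
  nm <- paste0(role, "::", normalize_label(label, synonyms))
  match(nm, igraph::V(graph)$name)
}

#' Number of papers (or distinct predictors) attached to a condition
#'
#' @param graph Graph from [build_network()].
#' @param condition Condition label (normalized before lookup).
#' @param distinct If `TRUE`, count distinct predictor partners instead
#'   of papers (parallel edges collapsed).
#' @param synonyms Optional synonym map.
#' @return Non-negative integer; 0 for labels absent from the graph.
#' @export
condition_degree <- function(graph, condition, distinct = FALSE, synonyms = NULL) {
  i <- vertex_index(graph, condition, "condition", synonyms)
  if (is.na(i)) {
    return(0L)
  }
  if (distinct) {
    length(unique(igraph::neighbors(graph, i)))
  } else {
    as.integer(igraph::degree(graph, i))
  }
}

#' Per-node degree table
#'
#' @param graph Graph from [build_network()].
#' @return A tibble with `label`, `role`, `papers` (edge degree, parallel
#'   edges counted) and `distinct_partners`, sorted by role then label.
#' @export
degree_table <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(tibble::tibble(
      label = character(), role = character(),
      papers = integer(), distinct_partners = integer()
    ))
  }
  tbl <- tibble::tibble(
    label = igraph::V(graph)$label,
    role = igraph::V(graph)$role,
    papers = as.integer(igraph::degree(graph)),
    distinct_partners = vapply(
      seq_len(n),
      function(i) length(unique(igraph::neighbors(graph, i))), integer(1)
    )
  )
  dplyr::arrange(tbl, .data$role, .data$label)
}

#' Conditions with evidence of multifactorial structure
#'
#' Conditions attached to at least `min_edges` papers (default 4, the
#' conventional reporting threshold for "multifactorial" in this kind of
#' audit) — i.e., conditions that several single-factor studies each
#' linked to a different predictor, which a joint multivariable analysis
#' should have modelled together.
#'
#' @inheritParams condition_degree
#' @param min_edges Minimum degree, `>= 1`.
#' @return Tibble of `label`, `papers`, `distinct_partners`, sorted by
#'   the chosen degree measure descending with ties broken by label.
#' @export
multifactorial_conditions <- function(graph, min_edges = 4, distinct = FALSE) {
  if (length(min_edges) != 1 || is.na(min_edges) || min_edges < 1) {
    stop("min_edges must be a single integer >= 1", call. = FALSE)
  }
  tbl <- dplyr::filter(degree_table(graph), .data$role == "condition")
  tbl$measure <- if (distinct) tbl$distinct_partners else tbl$papers
  tbl <- dplyr::filter(tbl, .data$measure >= min_edges)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$measure), .data$label)
  tbl[c("label", "papers", "distinct_partners")]
}

#' Variables used as both predictor and outcome
#'
#' Flags labels that appear as a predictor in at least one record and as
#' an outcome in at least one other — the reversible-arrow pattern (e.g.,
#' an inflammation marker predicting a condition in one study while being
#' the predicted outcome in another) that inflates the number of
#' publishable combinations without physiological justification.
#'
#' @param corpus A `corpus`.
#' @param synonyms Optional synonym map.
#' @return Tibble of `label`, `predictor_ids`, `outcome_ids`
#'   (semicolon-joined study ids), sorted by label, with an attribute
#'   `reversed_pairs`: a tibble of unordered label pairs `(a, b)` for
#'   which both directions a->b and b->a occur.
#' @export
dual_role_variables <- function(corpus, synonyms = NULL) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0) {
    out <- tibble::tibble(
      label = character(), predictor_ids = character(),
      outcome_ids = character()
    )
    attr(out, "reversed_pairs") <- tibble::tibble(
      label_a = character(), label_b = character()
    )
    return(out)
  }
  pred <- normalize_label(corpus$predictor, synonyms)
  cond <- normalize_label(corpus$outcome, synonyms)
  both <- sort(intersect(unique(pred), unique(cond)))
  out <- tibble::tibble(
    label = both,
    predictor_ids = vapply(both, function(l) {
      paste(corpus$study_id[pred == l], collapse = ";")
    }, character(1), USE.NAMES = FALSE),
    outcome_ids = vapply(both, function(l) {
      paste(corpus$study_id[cond == l], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  )
  pairs <- unique(data.frame(a = pred, b = cond, stringsAsFactors = FALSE))
  rev_hit <- pairs[paste(pairs$b, pairs$a, sep = "\r") %in%
    paste(pairs$a, pairs$b, sep = "\r") & pairs$a < pairs$b, ]
  attr(out, "reversed_pairs") <- tibble::tibble(
    label_a = rev_hit$a, label_b = rev_hit$b
  )
  out
}

#' Export / re-import the association graph as GraphML
#'
#' Parallel edges, the `role` and `papers` node attributes, and the
#' `study_id` edge attribute are preserved losslessly.
#'
#' @param graph Graph from [build_network()].
#' @param path Output file path.
#' @return `path`, invisibly (`export_graphml`); an igraph
#'   (`read_graphml`).
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
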