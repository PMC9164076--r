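#' Build the tripartite pathway-target-drug network
#'
#' Nodes come in three layers — pathways, targets, drugs — with edges only
#' between adjacent layers (pathway-target and target-drug). Entities that
#' appear in no pair are simply absent, so a drug whose every predicted
#' target dropped out of the final set never enters the network. An
#' identifier appearing in two different layers is a structure error, since
#' it would smuggle in a within-layer or pathway-drug edge.
#'
#' @param pt_pairs Data frame with columns `pathway`, `target`.
#' @param td_pairs Data frame with columns `target`, `drug`.
#' @return An undirected `igraph` with vertex attribute `role` in
#'   `c("pathway", "target", "drug")`.
#' @export
build_pta <- function(pt_pairs, td_pairs) {
  pt_pairs <- unique(data.frame(pathway = as.character(pt_pairs$pathway),
                                target = normalize_symbol0(pt_pairs$target),
                                stringsAsFactors = FALSE))
  td_pairs <- unique(data.frame(target = normalize_symbol0(td_pairs$target),
                                drug = as.character(td_pairs$drug),
                                stringsAsFactors = FALSE))
  pathways <- unique(pt_pairs$pathway)
  targets <- unique(c(pt_pairs$target, td_pairs$target))
  drugs <- unique(td_pairs$drug)
  clash <- c(intersect(pathways, targets), intersect(pathways, drugs),
             intersect(targets, drugs))
  if (length(clash) > 0L) {
    stop(sprintf("structure error: identifier(s) present in two layers: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  nodes <- data.frame(
    name = c(pathways, targets, drugs),
    role = rep(c("pathway", "target", "drug"),
               c(length(pathways), length(targets), length(drugs))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = pt_pairs$pathway, to = pt_pairs$target,
               stringsAsFactors = FALSE),
    data.frame(from = td_pairs$target, to = td_pairs$drug,
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

# normalize_symbol for possibly-empty vectors
normalize_symbol0 <- function(x) {
  if (length(x) == 0L) character(0) else normalize_symbol(x)
}

#' Degree centrality table
#'
#' Raw adjacency counts (not normalized). For tripartite networks the
#' per-layer degree breakdown of target nodes is attached as attribute
#' `layer_degrees`, since a target's pathway links and drug links carry
#' different meaning.
#'
#' @param graph An `igraph` object.
#' @return A `centrality_table` data frame with columns `node`, `role`
#'   (when present), `dc`, sorted by decreasing degree.
#' @export
degree_table <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) {
    return(structure(data.frame(node = character(0), dc = integer(0)),
                     class = c("centrality_table", "data.frame")))
  }
  dc <- igraph::degree(graph)
  tab <- data.frame(node = names(dc), dc = as.integer(dc),
                    stringsAsFactors = FALSE)
  roles <- igraph::vertex_attr(graph, "role")
  if (!is.null(roles)) {
    tab$role <- roles
    if (length(unique(roles)) > 1L) {
      tab <- cbind(tab, layer_degree_breakdown(graph))
    }
  }
  tab <- tab[order(-tab$dc, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("centrality_table", "data.frame"))
}

layer_degree_breakdown <- function(graph) {
  roles <- igraph::vertex_attr(graph, "role")
  names(roles) <- igraph::V(graph)$name
  el <- igraph::as_edgelist(graph)
  count_to <- function(node, role) {
    sum((el[, 1] == node & roles[el[, 2]] == role) |
        (el[, 2] == node & roles[el[, 1]] == role))
  }
  nodes <- igraph::V(graph)$name
  data.frame(
    dc_pathway = vapply(nodes, count_to, integer(1), role = "pathway"),
    dc_drug = vapply(nodes, count_to, integer(1), role = "drug"),
    row.names = NULL)
}

#' Betweenness centrality table
#'
#' Shortest-path betweenness on a simple undirected graph, with pair
#' dependencies split equally among multiple shortest paths, normalized by
#' `(n-1)(n-2)/2` so a node lying on every shortest path between every
#' other pair scores exactly 1.
#'
#' @param graph An undirected `igraph` object.
#' @return A `centrality_table` data frame with columns `node`, `bc`.
#' @export
betweenness_table <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) {
    return(structure(data.frame(node = character(0), bc = numeric(0)),
                     class = c("centrality_table", "data.frame")))
  }
  n <- igraph::vcount(graph)
  raw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  tab <- data.frame(node = names(raw), bc = as.numeric(raw) / denom,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$bc, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("centrality_table", "data.frame"))
}

#' Top-fraction centrality filter
#'
#' The rank filter used at each stage of hub isolation: nodes with metric 0
#' are excluded first (they contribute no topology), then the top
#' `ceiling(fraction * n)` nodes by the metric are selected, where `n` is
#' the ORIGINAL table size including the zeros; every node tied with the
#' boundary value is included. The zero-exclusion and tie policies are
#' configurable, but the default combination is the one under which the
#' two-stage filter behaves consistently across both of its stages.
#'
#' @param table A `centrality_table` (or data frame) with a `node` column
#'   and the metric column.
#' @param metric Column name, `"dc"` or `"bc"`.
#' @param fraction Fraction of nodes to keep, in `(0, 1]` (default 0.30).
#' @param zero_policy `"exclude"` (default) or `"keep"`.
#' @param tie_policy `"include"` (default) or `"exclude"` boundary ties.
#' @return A `filter_outcome`: list with `selected` (node names, ranked),
#'   `cutoff` (the rank count `ceiling(fraction * n)`), `boundary`
#'   (metric value at the cutoff), `n_zero_excluded`, `n_input`.
#' @export
top_fraction_filter <- function(table, metric = c("dc", "bc"),
                                fraction = 0.30,
                                zero_policy = c("exclude", "keep"),
                                tie_policy = c("include", "exclude")) {
  metric <- match.arg(metric)
  zero_policy <- match.arg(zero_policy)
  tie_policy <- match.arg(tie_policy)
  stopifnot(nrow(table) > 0L, fraction > 0, fraction <= 1)
  vals <- table[[metric]]
  n0 <- nrow(table)
  keep <- if (zero_policy == "exclude") vals > 0 else rep(TRUE, n0)
  if (!any(keep)) {
    warning("all centrality values are zero; empty selection", call. = FALSE)
    return(structure(list(selected = character(0),
                          cutoff = as.integer(ceiling(fraction * n0)),
                          boundary = NA_real_,
                          n_zero_excluded = n0, n_input = n0),
                     class = "filter_outcome"))
  }
  nodes <- table$node[keep]
  vals <- vals[keep]
  ord <- order(-vals, nodes)
  nodes <- nodes[ord]
  vals <- vals[ord]
  cutoff <- as.integer(ceiling(fraction * n0))
  take <- min(cutoff, length(nodes))
  boundary <- vals[take]
  sel <- if (tie_policy == "include") nodes[vals >= boundary]
         else nodes[seq_len(take)]
  structure(list(selected = sel, cutoff = cutoff, boundary = boundary,
                 n_zero_excluded = n0 - length(table$node[keep]),
                 n_input = n0),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf("filter_outcome: %d of %d selected (cutoff %d, boundary %g, %d zero-metric excluded)\n",
              length(x$selected), x$n_input, x$cutoff,
              ifelse(is.na(x$boundary), NaN, x$boundary), x$n_zero_excluded))
  invisible(x)
}

#' Two-stage topological hub isolation
#'
#' The PPI double filter: stage 1 ranks the full graph by degree centrality
#' and keeps the top fraction; the induced subgraph on the survivors is
#' built; stage 2 recomputes degree and betweenness within that subgraph
#' and keeps the top fraction by betweenness. The surviving node(s) are the
#' core target(s). All intermediate artifacts are returned for reporting.
#'
#' @param ppi Edge list data frame (`from`, `to`, optional `confidence`) or
#'   an `igraph` object.
#' @param fraction Fraction kept at each stage (default 0.30).
#' @param nodes Optional character vector of all node names, so isolated
#'   proteins (degree 0) that an edge list cannot carry are represented.
#' @return A `hub_result`: list with `hub` (character vector), `stage1`
#'   and `stage2` (`filter_outcome`s), `graph`, `subgraph`,
#'   `centrality_full` (DC and BC on the full graph) and `centrality_sub`
#'   (recomputed within the subgraph).
#' @export
isolate_hub <- function(ppi, fraction = 0.30, nodes = NULL) {
  g <- if (igraph::is_igraph(ppi)) ppi else ppi_graph(ppi, nodes = nodes)
  if (igraph::vcount(g) == 0L) stop("empty PPI graph", call. = FALSE)
  dct <- degree_table(g)
  bct <- betweenness_table(g)
  full <- merge(dct[c("node", "dc")], bct, by = "node")
  stage1 <- top_fraction_filter(dct, "dc", fraction)
  if (length(stage1$selected) == 0L) {
    return(structure(list(hub = character(0), stage1 = stage1, stage2 = NULL,
                          graph = g, subgraph = NULL,
                          centrality_full = full, centrality_sub = NULL),
                     class = "hub_result"))
  }
  sub <- igraph::induced_subgraph(g, stage1$selected)
  sub_dc <- degree_table(sub)
  sub_bc <- betweenness_table(sub)
  sub_tab <- merge(sub_dc[c("node", "dc")], sub_bc, by = "node")
  stage2 <- top_fraction_filter(sub_bc, "bc", fraction)
  structure(list(hub = sort(stage2$selected), stage1 = stage1,
                 stage2 = stage2, graph = g, subgraph = sub,
                 centrality_full = full, centrality_sub = sub_tab),
            class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("hub_result: %d-node PPI -> %d-node subnetwork -> hub {%s}\n",
              igraph::vcount(x$graph),
              if (is.null(x$subgraph)) 0L else igraph::vcount(x$subgraph),
              paste(x$hub, collapse = ", ")))
  invisible(x)
}

#' Build a PPI graph from an edge list
#'
#' @param edges Edge list data frame with columns `from`, `to`.
#' @param nodes Optional full node roster (isolated nodes get degree 0).
#' @return Undirected simple `igraph` with `role = "target"` vertices.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  edges <- as_edge_list(edges)
  vnames <- unique(c(edges$from, edges$to, if (!is.null(nodes))
                     normalize_symbol0(nodes)))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = vnames))
  igraph::V(g)$role <- "target"
  g
}

#' Write a centrality table as TSV
#'
#' @param table A `centrality_table` or merged DC/BC data frame.
#' @param path Output path.
#' @export
write_centrality <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
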