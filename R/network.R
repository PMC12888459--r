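#' Build the herb-constituent-indicator consensus network
#'
#' Constructs the undirected typed graph whose nodes are the consensus
#' compounds, the efficacy indicators (optionally including the composite
#' overall-rating indicator, which is required to reproduce published
#' compound degrees) and the source herbs.  Each compound is connected to
#' every indicator whose consensus set contains it and to exactly one herb
#' of origin, so a compound's degree equals its number of indicator
#' memberships plus one.
#'
#' Centralities are computed on the full typed graph: degree (edge count),
#' normalised shortest-path betweenness and normalised closeness
#' ((reachable nodes)/(sum of distances) within the component).
#'
#' @param table a [consensus_table()].
#' @param herb_map data frame with columns `peak_id` and `herb` (see
#'   [load_fixture()]`("herb_map")`).
#' @param include_overall keep the overall-rating indicator as a node
#'   (default `TRUE`); when `FALSE`, indicators whose name matches
#'   "overall" case-insensitively are dropped.
#' @return an object of class `consensus_network`: the `igraph` graph plus
#'   a `centrality` data frame over compound nodes (peak_id, betweenness,
#'   closeness, degree, source).
#' @export
build_network <- function(table, herb_map, include_overall = TRUE) {
  stopifnot(inherits(table, "consensus_table"))
  sets <- table$sets
  if (!include_overall)
    sets <- sets[!grepl("overall", names(sets), ignore.case = TRUE)]
  compounds <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(compounds)) stop("the consensus table is empty")
  hm <- stats::setNames(as.character(herb_map$herb), herb_map$peak_id)
  missing <- setdiff(compounds, names(hm))
  if (length(missing))
    stop("compounds without a herb assignment: ",
         paste(missing, collapse = ", "))
  herbs <- unique(unname(hm[compounds]))

  edges <- character()
  for (ind in names(sets))
    for (cmp in sets[[ind]]) edges <- c(edges, cmp, ind)
  for (cmp in compounds) edges <- c(edges, cmp, hm[[cmp]])

  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(compounds), name = compounds,
                            type = "compound")
  g <- igraph::add_vertices(g, length(sets), name = names(sets),
                            type = "indicator")
  g <- igraph::add_vertices(g, length(herbs), name = herbs, type = "herb")
  g <- igraph::add_edges(g, edges)
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")

  btw <- igraph::betweenness(g, normalized = TRUE)
  cls <- igraph::closeness(g, normalized = TRUE)
  deg <- igraph::degree(g)
  centrality <- data.frame(peak_id = compounds,
                           betweenness = unname(btw[compounds]),
                           closeness = unname(cls[compounds]),
                           degree = unname(deg[compounds]),
                           source = unname(hm[compounds]),
                           stringsAsFactors = FALSE)
  structure(list(graph = g, centrality = centrality),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  g <- x$graph
  type <- igraph::V(g)$type
  cat(sprintf(
    "<consensus_network> %d nodes (%d compounds, %d indicators, %d herbs), %d edges\n",
    igraph::vcount(g), sum(type == "compound"), sum(type == "indicator"),
    sum(type == "herb"), igraph::ecount(g)))
  invisible(x)
}

#' Median filter on compound centralities
#'
#' Flags a compound when at least `k_of_3` of its three centralities
#' (betweenness, closeness, degree) are strictly above the compound-wise
#' median of that centrality.  Medians of an even number of compounds are
#' the midpoint of the two central order statistics.  The flag set is
#' monotone decreasing in `k_of_3`.
#'
#' @param centralities data frame with columns `peak_id`, `betweenness`,
#'   `closeness`, `degree` (e.g. the `centrality` slot of
#'   [build_network()] or the packaged centrality fixture).
#' @param k_of_3 how many of the three features must exceed their median
#'   (default 2).
#' @return character vector of flagged compound ids, sorted by peak id.
#' @export
median_filter <- function(centralities, k_of_3 = 2) {
  need <- c("peak_id", "betweenness", "closeness", "degree")
  if (!all(need %in% names(centralities)))
    stop("centralities must have columns ",
         paste(need, collapse = ", "))
  if (!nrow(centralities)) stop("at least one compound is required")
  if (!k_of_3 %in% 1:3) stop("k_of_3 must be 1, 2 or 3")
  feats <- centralities[c("betweenness", "closeness", "degree")]
  above <- sapply(feats, function(v) v > stats::median(v))
  above <- matrix(above, nrow = nrow(centralities))
  flagged <- centralities$peak_id[rowSums(above) >= k_of_3]
  sort(flagged)
}

#' Export a consensus network for external viewers
#'
#' `write_network_graphml()` writes GraphML (via igraph);
#' `write_network_sif()` writes a simple-interaction-format file with
#' `compound-indicator` and `compound-herb` relations, the plain-text
#' interchange format of common network viewers.
#'
#' @param network a [build_network()] result.
#' @param path output file path.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "consensus_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "consensus_network"))
  g <- network$graph
  type <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  rel <- paste0(type[el[, 1L]], "-", type[el[, 2L]])
  writeLines(paste(el[, 1L], rel, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Centrality table mirroring the published layout
#'
#' @param network a [build_network()] result.
#' @param path optional CSV output path.
#' @return the compound centrality data frame (invisibly when written).
#' @export
centrality_table <- function(network, path = NULL) {
  stopifnot(inherits(network, "consensus_network"))
  tab <- network$centrality
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
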