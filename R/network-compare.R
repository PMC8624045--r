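# canonical "a--b" edge keys of an undirected igraph graph
.edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  .dyad_key(el[, 1], el[, 2])
}

.check_same_nodes <- function(g1, g2) {
  if (!setequal(igraph::V(g1)$name, igraph::V(g2)$name))
    stop("networks must share the same node set")
}

#' Hamming distance between two networks
#'
#' The number of edges present in exactly one of the two graphs (the edge
#' symmetric difference, `|E1 union E2| - |E1 intersect E2|`), normalized by
#' the number of possible undirected edges `N(N-1)/2` over the shared node
#' set. 0 means identical edge sets; edge weights are ignored. Note that a
#' swap of one edge for another counts as two differing edges.
#'
#' @param g1,g2 undirected igraph graphs over the same node set.
#' @return A number in \[0, 1\].
#' @seealso [edge_symmetric_difference()] for the unnormalized count.
#' @export
hamming <- function(g1, g2) {
  .check_same_nodes(g1, g2)
  n <- igraph::vcount(g1)
  edge_symmetric_difference(g1, g2) / (n * (n - 1) / 2)
}

#' @rdname hamming
#' @return `edge_symmetric_difference`: the integer number of differing
#'   edges.
#' @export
edge_symmetric_difference <- function(g1, g2) {
  .check_same_nodes(g1, g2)
  e1 <- .edge_keys(g1); e2 <- .edge_keys(g2)
  length(union(e1, e2)) - length(intersect(e1, e2))
}

#' Edge presence table across several networks
#'
#' Builds the union of all edges of the given networks and flags, per dyad,
#' in which networks the edge is present — the table used to compare
#' networks built at different contact thresholds or activity strata.
#'
#' @param networks named list of at least two undirected igraph graphs over
#'   the same node set.
#' @return data.frame with `animal_a`, `animal_b` (lexicographic) and one
#'   logical column per network, in deterministic dyad order.
#' @export
edge_overlap <- function(networks) {
  if (length(networks) < 2) stop("need at least two networks")
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("networks must be a named list")
  for (g in networks[-1]) .check_same_nodes(networks[[1]], g)
  keys <- lapply(networks, .edge_keys)
  all_keys <- sort(unique(unlist(keys)))
  parts <- strsplit(all_keys, "--", fixed = TRUE)
  out <- data.frame(animal_a = vapply(parts, `[`, "", 1),
                    animal_b = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  for (nm in names(networks)) out[[nm]] <- all_keys %in% keys[[nm]]
  out
}

#' Write / read a social network
#'
#' GraphML preserves isolated nodes and the `weight` edge attribute and
#' round-trips exactly; the edge-list CSV (`animal_a,animal_b,weight`) is a
#' lightweight interchange format that only carries connected nodes.
#'
#' @param net an undirected igraph graph.
#' @param path file path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @return `path` (write) or an igraph graph (read), invisibly for write.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist_csv")) {
  stopifnot(inherits(net, "igraph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    w <- if (igraph::ecount(net) > 0 && "weight" %in% igraph::edge_attr_names(net))
      igraph::E(net)$weight else rep(1, nrow(el))
    df <- data.frame(animal_a = pmin(el[, 1], el[, 2]),
                     animal_b = pmax(el[, 1], el[, 2]), weight = w)
    df <- df[order(df$animal_a, df$animal_b), , drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "edgelist_csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE)
  }
}
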