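# Hub ranking and compartment-bridge detection: which nodes have neighbors
# in every subcellular district of a target set?

#' Hub table (most connected nodes)
#'
#' @param net A `signaling_network`.
#' @param top_n Number of rows to return (fewer if the network is smaller).
#' @return Data frame with columns `node`, `degree`, sorted by degree
#'   descending with ties broken by node id (C collation), so the ordering
#'   is deterministic.
#' @export
hub_table <- function(net, top_n = 10L) {
  if (n_nodes(net) == 0L) stop("empty network")
  if (top_n < 1L) stop("top_n must be >= 1")
  deg <- degree_sequence(net)
  df <- data.frame(node = names(deg), degree = unname(deg),
                   stringsAsFactors = FALSE)
  df <- df[order_c(-df$degree, df$node), , drop = FALSE]
  df <- utils::head(df, top_n)
  rownames(df) <- NULL
  df
}

#' Compartments covered by a node's neighborhood
#'
#' The set of subcellular compartments in which the node's distinct
#' neighbors reside; optionally the node's own compartment is added.
#'
#' @param net A `signaling_network`.
#' @param node A node id.
#' @param include_self Add the node's own compartment to the set.
#' @return Character vector of compartment names (C-collation sorted);
#'   empty for an isolated node with `include_self = FALSE`.
#' @export
neighbor_compartments <- function(net, node, include_self = FALSE) {
  if (!node %in% node_ids(net)) stop("unknown node id: ", node)
  g <- as_igraph(net)
  nb <- igraph::neighbors(g, node)
  comps <- unique(nb$compartment)
  if (include_self) {
    comps <- unique(c(comps, node_compartments(net)[[node]]))
  }
  sort_c(comps)
}

#' Default compartment target set for bridge detection
#'
#' All compartments present in the network except `nucleus` and
#' `extracellular`: the districts engaged by post-ejaculatory signaling.
#' The nucleus is excluded because it is the one compartment that stays
#' molecularly stable until fertilization (the male germ cell nucleus is
#' transcriptionally silent), and the extracellular space is not a
#' subcellular district.
#'
#' @param net A `signaling_network`.
#' @return Character vector of compartment names.
#' @export
default_target_set <- function(net) {
  sort_c(setdiff(unique(net$nodes$compartment),
                 c("nucleus", "extracellular")))
}

#' Detect compartment-bridging nodes
#'
#' A node bridges a target set of compartments when its distinct neighbors
#' collectively reside in every compartment of the set — i.e. a signal at
#' that node is one step away from all the target districts. By default the
#' node's own compartment does not count (bridging is about what the node's
#' links reach); set `include_self = TRUE` for the other convention.
#'
#' @param net A `signaling_network`.
#' @param target_set Compartments to cover; defaults to
#'   [default_target_set()].
#' @param include_self Count the node's own compartment as covered.
#' @return Data frame with one row per node (C-collation order): `node`,
#'   `own_compartment`, `covered` (the neighbor compartment sets, a list
#'   column), `n_covered` (how many *target* compartments are covered) and
#'   `is_bridge`.
#' @export
find_bridging_nodes <- function(net, target_set = NULL,
                                include_self = FALSE) {
  if (is.null(target_set)) target_set <- default_target_set(net)
  if (!length(target_set)) stop("target_set must be non-empty")
  outside <- setdiff(target_set, net$vocabulary)
  if (length(outside)) {
    stop("target compartment(s) outside the vocabulary: ",
         paste(outside, collapse = ", "))
  }
  ids <- sort_c(node_ids(net))
  comp <- node_compartments(net)
  covered <- lapply(ids, function(id)
    neighbor_compartments(net, id, include_self = include_self))
  n_cov <- vapply(covered, function(s) sum(target_set %in% s), integer(1))
  data.frame(
    node = ids,
    own_compartment = unname(comp[ids]),
    covered = I(covered),
    n_covered = n_cov,
    is_bridge = n_cov == length(target_set),
    stringsAsFactors = FALSE)
}

#' Ids of the bridging nodes
#'
#' Convenience wrapper around [find_bridging_nodes()] returning just the
#' ids of the nodes that cover the full target set.
#'
#' @inheritParams find_bridging_nodes
#' @return Character vector (C-collation sorted).
#' @export
bridging_node_ids <- function(net, target_set = NULL, include_self = FALSE) {
  rep <- find_bridging_nodes(net, target_set, include_self)
  rep$node[rep$is_bridge]
}
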