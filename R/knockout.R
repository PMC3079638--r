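# Virtual node knockouts: remove nodes, recompute topology, and identify
# the nodes "lost" from the giant component.

# Members of the largest connected component. Ties in size are broken by
# (1) most members of `prefer` (the pre-knockout giant component), then
# (2) the component whose lexicographically smallest member sorts first
# (C collation), so knockout screens are deterministic.
giant_component_members <- function(net, prefer = NULL) {
  if (n_nodes(net) == 0L) return(character(0))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  cand <- which(comp$csize == max(comp$csize))
  if (length(cand) > 1L && !is.null(prefer)) {
    overlap <- vapply(cand, function(ci)
      sum(ids[comp$membership == ci] %in% prefer), integer(1))
    cand <- cand[overlap == max(overlap)]
  }
  if (length(cand) > 1L) {
    mins <- vapply(cand, function(ci)
      sort_c(ids[comp$membership == ci])[[1]], character(1))
    cand <- cand[order_c(mins)]
  }
  sort_c(ids[comp$membership == cand[[1]]])
}

#' Remove nodes from a network
#'
#' Returns a new network without the given nodes and all their incident
#' interactions; the input network is unchanged. Removing the empty set is
#' the identity.
#'
#' @param net A `signaling_network`.
#' @param ids Character vector of node ids to remove; all must exist.
#' @return A `signaling_network`.
#' @export
remove_nodes <- function(net, ids) {
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, node_ids(net))
  if (length(unknown)) {
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  }
  nodes <- net$nodes[!net$nodes$id %in% ids, , drop = FALSE]
  inter <- net$interactions
  inter <- inter[!(inter$source %in% ids | inter$target %in% ids), ,
                 drop = FALSE]
  signaling_network(nodes, inter, name = net$name,
                    vocabulary = net$vocabulary,
                    allow_extra_compartments = TRUE)
}

#' Nodes orphaned by a knockout
#'
#' The "lost" nodes of a knockout experiment: nodes that belonged to the
#' largest connected component (giant component) of the pre-removal network
#' and lie outside the giant component of the post-removal network, while
#' still being present in it. Orphans stay in the network — the knockout
#' detaches them; they are never the removed nodes themselves. When the
#' post-removal network has several components of maximal size, the giant
#' is the one sharing the most members with the pre-removal giant, with a
#' final lexicographic tie-break, so the result is deterministic.
#'
#' @param pre_net Network before removal.
#' @param post_net Network after removal; its node set must be a subset of
#'   `pre_net`'s.
#' @return Character vector of orphaned node ids (C-collation sorted).
#' @export
orphan_nodes <- function(pre_net, post_net) {
  extra <- setdiff(node_ids(post_net), node_ids(pre_net))
  if (length(extra)) {
    stop("post-removal network contains node(s) absent from the ",
         "pre-removal network: ", paste(extra, collapse = ", "))
  }
  pre_giant <- giant_component_members(pre_net)
  post_giant <- giant_component_members(post_net, prefer = pre_giant)
  sort_c(setdiff(intersect(pre_giant, node_ids(post_net)), post_giant))
}

#' Knockout report
#'
#' Performs a virtual knockout: removes the given nodes, recomputes the
#' full topology statistic bundle, and identifies the orphaned nodes. The
#' result satisfies `post$n_nodes == pre$n_nodes - length(removed)` and
#' `edges_lost == pre$n_edges_simple - post$n_edges_simple` (edges internal
#' to the removed set count once).
#'
#' @param net A `signaling_network`.
#' @param ids Node ids to remove.
#' @return An object of class `knockout_result`: list with fields
#'   `removed`, `orphans`, `edges_lost`, `pre` and `post` (both
#'   [topology_report()]s), and `post_net` (the post-removal network).
#' @export
knockout_report <- function(net, ids) {
  ids <- sort_c(unique(as.character(ids)))
  post_net <- remove_nodes(net, ids)
  pre <- topology_report(net)
  post <- topology_report(post_net)
  structure(
    list(
      removed = ids,
      orphans = orphan_nodes(net, post_net),
      edges_lost = pre$n_edges_simple - post$n_edges_simple,
      pre = pre,
      post = post,
      post_net = post_net
    ),
    class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("<knockout_result>\n")
  cat(sprintf("  removed (%d): %s\n", length(x$removed),
              paste(x$removed, collapse = ", ")))
  cat(sprintf("  orphans (%d): %s\n", length(x$orphans),
              if (length(x$orphans)) paste(x$orphans, collapse = ", ")
              else "none"))
  cat(sprintf("  edges lost: %d\n", x$edges_lost))
  cat(sprintf("  nodes %d -> %d, simple edges %d -> %d\n",
              x$pre$n_nodes, x$post$n_nodes,
              x$pre$n_edges_simple, x$post$n_edges_simple))
  invisible(x)
}

#' All-single-node knockout screen
#'
#' Systematizes the single-node experiment: knocks out every node in turn
#' and summarizes the damage. Rows are sorted by orphan count (descending),
#' then degree (descending), then id, so the most disruptive knockouts —
#' the candidates for coordinating nodes — rise to the top.
#'
#' @param net A non-empty `signaling_network`.
#' @return Data frame with columns `node`, `degree`, `orphan_count`,
#'   `delta_char_path_length` (post minus pre; `NA` when either is
#'   undefined).
#' @export
knockout_screen <- function(net) {
  if (n_nodes(net) == 0L) stop("empty network")
  pre_cpl <- characteristic_path_length(net)
  deg <- degree_sequence(net)
  pre_giant <- giant_component_members(net)
  rows <- lapply(node_ids(net), function(id) {
    post_net <- remove_nodes(net, id)
    orphans <- {
      post_giant <- giant_component_members(post_net, prefer = pre_giant)
      setdiff(intersect(pre_giant, node_ids(post_net)), post_giant)
    }
    post_cpl <- characteristic_path_length(post_net)
    data.frame(node = id, degree = unname(deg[[id]]),
               orphan_count = length(orphans),
               delta_char_path_length =
                 if (is.na(pre_cpl) || is.na(post_cpl)) NA_real_
                 else post_cpl - pre_cpl,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order_c(-df$orphan_count, -df$degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}
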