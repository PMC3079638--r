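# Core domain type: an undirected signaling network whose nodes carry a
# subcellular-compartment annotation, plus SIF / node-attribute I/O.

#' Default subcellular compartment vocabulary
#'
#' The seven-district vocabulary used throughout the package: plasma
#' membrane, cytosol, cytoskeleton, mitochondria, acrosome, nucleus and
#' extracellular space.
#'
#' @return Character vector of compartment names.
#' @export
default_compartments <- function() {
  c("membrane", "cytosol", "cytoskeleton", "mitochondria", "acrosome",
    "nucleus", "extracellular")
}

# locale-independent (C collation) sort used for every deterministic ordering
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

#' Construct a compartment-annotated signaling network
#'
#' Builds and validates the central container consumed by every analysis in
#' the package: an undirected network of uniquely named nodes, each assigned
#' to a subcellular compartment drawn from a declared vocabulary, together
#' with a multiset of interactions. Interactions are undirected: `(a, b)`
#' and `(b, a)` denote the same link, and self-loops or parallel edges are
#' permitted in the raw interaction list (topology statistics are computed
#' on the simple view, see [simple_view()]).
#'
#' @param nodes Data frame with columns `id` (unique, non-empty, character),
#'   `compartment`, and optionally `label`. A character vector of ids is also
#'   accepted when `compartments` is given.
#' @param interactions Data frame with columns `source`, `target` and
#'   optionally `kind` (defaults to `"pp"`). May be `NULL` for an edgeless
#'   network.
#' @param name Network name.
#' @param vocabulary Declared compartment vocabulary; defaults to
#'   [default_compartments()].
#' @param compartments Optional named character vector mapping id to
#'   compartment, used when `nodes` is a bare id vector.
#' @param allow_extra_compartments If `TRUE`, compartments outside the
#'   vocabulary are accepted (and appended to the network's vocabulary)
#'   instead of raising an error.
#' @return An object of class `signaling_network`.
#' @examples
#' net <- signaling_network(
#'   nodes = data.frame(id = c("A", "B"),
#'                      compartment = c("cytosol", "membrane")),
#'   interactions = data.frame(source = "A", target = "B")
#' )
#' n_nodes(net)
#' @export
signaling_network <- function(nodes, interactions = NULL, name = "network",
                              vocabulary = default_compartments(),
                              compartments = NULL,
                              allow_extra_compartments = FALSE) {
  if (is.character(nodes)) {
    if (is.null(compartments)) {
      stop("when `nodes` is an id vector, `compartments` must map id -> compartment")
    }
    nodes <- data.frame(id = nodes,
                        compartment = unname(compartments[nodes]),
                        stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("id", "compartment") %in% names(nodes))) {
    stop("`nodes` must have columns `id` and `compartment`")
  }
  nodes$id <- trimws(as.character(nodes$id))
  nodes$compartment <- as.character(nodes$compartment)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "compartment", "label")]

  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty")
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    stop("duplicate node id(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(nodes$compartment)) {
    stop("missing compartment for node(s): ",
         paste(nodes$id[is.na(nodes$compartment)], collapse = ", "))
  }
  unknown <- setdiff(unique(nodes$compartment), vocabulary)
  if (length(unknown)) {
    if (allow_extra_compartments) {
      vocabulary <- c(vocabulary, sort_c(unknown))
    } else {
      stop("compartment(s) outside the declared vocabulary: ",
           paste(unknown, collapse = ", "),
           " (set allow_extra_compartments = TRUE to accept)")
    }
  }

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    interactions <- data.frame(source = character(), target = character(),
                               kind = character(), stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(interactions))) {
      stop("`interactions` must have columns `source` and `target`")
    }
    if (is.null(interactions$kind)) interactions$kind <- "pp"
    interactions <- interactions[, c("source", "target", "kind")]
    interactions$source <- trimws(as.character(interactions$source))
    interactions$target <- trimws(as.character(interactions$target))
    interactions$kind <- as.character(interactions$kind)
    bad <- setdiff(unique(c(interactions$source, interactions$target)),
                   nodes$id)
    if (length(bad)) {
      stop("interaction endpoint(s) not in node set: ",
           paste(bad, collapse = ", "))
    }
  }
  rownames(nodes) <- NULL
  rownames(interactions) <- NULL
  structure(
    list(nodes = nodes, interactions = interactions, name = name,
         vocabulary = vocabulary),
    class = "signaling_network"
  )
}

#' @export
print.signaling_network <- function(x, ...) {
  sv <- simple_view(x)
  cat(sprintf(
    "<signaling_network> %s: %d nodes, %d simple edges (%d raw interactions), %d compartments in use\n",
    x$name, nrow(x$nodes), nrow(sv$interactions), nrow(x$interactions),
    length(unique(x$nodes$compartment))))
  invisible(x)
}

#' Number of nodes in a network
#' @param net A `signaling_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' Number of edges in the simple view
#'
#' Self-loops are dropped and parallel edges collapsed before counting.
#'
#' @param net A `signaling_network`.
#' @return Integer count of simple (distinct, non-loop) edges.
#' @export
n_edges_simple <- function(net) nrow(simple_view(net)$interactions)

#' Number of raw interactions
#'
#' The size of the interaction multiset as loaded, including self-loops and
#' parallel edges. Reported separately from the simple-edge count because
#' neighbor-based statistics collapse duplicates.
#'
#' @param net A `signaling_network`.
#' @return Integer count.
#' @export
n_interactions_raw <- function(net) nrow(net$interactions)

#' Node ids of a network
#' @param net A `signaling_network`.
#' @return Character vector in storage order.
#' @export
node_ids <- function(net) net$nodes$id

#' Compartment assignment of nodes
#' @param net A `signaling_network`.
#' @return Named character vector, id -> compartment.
#' @export
node_compartments <- function(net) {
  stats::setNames(net$nodes$compartment, net$nodes$id)
}

# canonical (unordered) edge key, locale independent
canonical_edges <- function(interactions, ids) {
  key <- match(interactions$source, ids)
  key2 <- match(interactions$target, ids)
  # order endpoints by C-collation rank of the id strings
  rank_of <- match(ids, sort_c(ids))
  swap <- rank_of[key] > rank_of[key2]
  a <- ifelse(swap, interactions$target, interactions$source)
  b <- ifelse(swap, interactions$source, interactions$target)
  data.frame(source = a, target = b, kind = interactions$kind,
             stringsAsFactors = FALSE)
}

#' Simple view of a network
#'
#' Drops self-loops and collapses parallel (and reversed-duplicate)
#' interactions to a single undirected edge; the node set is unchanged.
#' All topology statistics in the package are computed on this view, while
#' the raw interaction count is reported separately. Idempotent.
#'
#' @param net A `signaling_network`.
#' @return A `signaling_network` whose interaction list is simple.
#' @export
simple_view <- function(net) {
  inter <- net$interactions
  if (nrow(inter)) {
    inter <- inter[inter$source != inter$target, , drop = FALSE]
    if (nrow(inter)) {
      inter <- canonical_edges(inter, net$nodes$id)
      keep <- !duplicated(paste(inter$source, inter$target, sep = "\r"))
      inter <- inter[keep, , drop = FALSE]
      inter <- inter[order_c(inter$source, inter$target), , drop = FALSE]
    }
  }
  rownames(inter) <- NULL
  out <- net
  out$interactions <- inter
  out
}

#' Convert to an igraph graph
#'
#' @param net A `signaling_network`.
#' @param simple If `TRUE` (default) the simple view is converted, which is
#'   what every topology statistic operates on.
#' @return An undirected `igraph` graph with a `compartment` vertex attribute.
#' @export
as_igraph <- function(net, simple = TRUE) {
  if (simple) net <- simple_view(net)
  vertices <- data.frame(name = net$nodes$id,
                         compartment = net$nodes$compartment,
                         stringsAsFactors = FALSE)
  edges <- net$interactions[, c("source", "target"), drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

# --- SIF + node-attribute I/O ------------------------------------------------

# `tab_file`: whether any line of the file contains a tab. In a
# tab-delimited file a tab-free line is a single field (an isolated node,
# possibly with spaces in its name); only in a fully tab-free file do we
# fall back to whitespace splitting, mirroring Cytoscape's SIF handling.
parse_sif_line <- function(line, lineno, tab_file = TRUE) {
  if (grepl("\t", line, fixed = TRUE)) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  } else if (tab_file) {
    fields <- trimws(line)
  } else {
    fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  }
  fields <- trimws(fields)
  fields <- fields[nzchar(fields)]
  if (length(fields) == 0L) return(NULL)
  if (length(fields) == 1L) {
    return(list(node = fields[[1]], edges = NULL))
  }
  if (length(fields) == 2L) {
    stop(sprintf("malformed SIF line %d: 2 fields (need 1 or >= 3)", lineno))
  }
  src <- fields[[1]]
  kind <- fields[[2]]
  targets <- fields[-(1:2)]
  list(node = NULL,
       edges = data.frame(source = src, target = targets, kind = kind,
                          stringsAsFactors = FALSE))
}

#' Read a SIF edge list with node compartment attributes
#'
#' Reads a Cytoscape simple-interaction-format (SIF) file together with a
#' tab-separated node attribute table mapping node id to subcellular
#' compartment, and assembles a validated [signaling_network]. SIF dialect:
#' lines containing a tab character are split on tabs (so node names may
#' contain spaces, e.g. `"actin polymerization"`); otherwise they are split
#' on runs of whitespace. Lines of the form `A<TAB>pp<TAB>B<TAB>C` expand to
#' the two interactions (A,B) and (A,C); a single-field line declares an
#' isolated node.
#'
#' The attribute file has a header row `node<TAB>compartment`, optionally
#' preceded by a comment line `#compartments: a, b, c` declaring the
#' vocabulary (overridden by the `vocabulary` argument if supplied).
#'
#' @param path Path to the SIF file.
#' @param attrs_path Path to the node-attribute TSV.
#' @param vocabulary Compartment vocabulary; `NULL` (default) takes the
#'   vocabulary from the attrs-file header comment, falling back to
#'   [default_compartments()].
#' @param default_compartment Compartment assigned to SIF nodes missing from
#'   the attribute table; if `NULL` (default) such nodes raise an error.
#' @param allow_extra_compartments Accept compartments outside the
#'   vocabulary.
#' @param name Network name; defaults to the SIF file name.
#' @return A `signaling_network`. The node set is the union of SIF and
#'   attribute-file nodes.
#' @export
read_sif <- function(path, attrs_path, vocabulary = NULL,
                     default_compartment = NULL,
                     allow_extra_compartments = FALSE,
                     name = NULL) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  if (!file.exists(attrs_path)) stop("attribute file not found: ", attrs_path)
  if (is.null(name)) name <- sub("\\.sif$", "", basename(path))

  attr_lines <- readLines(attrs_path, encoding = "UTF-8")
  vocab_line <- grep("^#compartments:", attr_lines, value = TRUE)
  if (is.null(vocabulary)) {
    if (length(vocab_line)) {
      vocabulary <- trimws(strsplit(
        sub("^#compartments:", "", vocab_line[[1]]), ",")[[1]])
    } else {
      vocabulary <- default_compartments()
    }
  }
  attr_lines <- attr_lines[!grepl("^#", attr_lines)]
  attr_lines <- attr_lines[nzchar(trimws(attr_lines))]
  if (length(attr_lines) == 0L) {
    stop("attribute file has no header row: ", attrs_path)
  }
  header <- trimws(strsplit(attr_lines[[1]], "\t", fixed = TRUE)[[1]])
  if (length(header) < 2L || header[[1]] != "node" ||
      header[[2]] != "compartment") {
    stop("attribute file header must be 'node<TAB>compartment', got: ",
         attr_lines[[1]])
  }
  comp_map <- character(0)
  if (length(attr_lines) > 1L) {
    parts <- strsplit(attr_lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      stop(sprintf("malformed attribute line %d: need node<TAB>compartment",
                   bad[[1]] + 1L))
    }
    ids <- trimws(vapply(parts, `[[`, "", 1L))
    comps <- trimws(vapply(parts, `[[`, "", 2L))
    per_id <- split(comps, ids)
    conflicted <- names(per_id)[vapply(per_id, function(v)
      length(unique(v)) > 1L, logical(1))]
    if (length(conflicted)) {
      first <- conflicted[[1L]]
      stop("conflicting compartment for node '", first, "': ",
           paste(unique(per_id[[first]]), collapse = " vs "))
    }
    comp_map <- stats::setNames(comps, ids)[!duplicated(ids)]
  }

  sif_lines <- readLines(path, encoding = "UTF-8")
  tab_file <- any(grepl("\t", sif_lines, fixed = TRUE))
  iso <- character(0)
  edge_list <- list()
  for (i in seq_along(sif_lines)) {
    parsed <- parse_sif_line(sif_lines[[i]], i, tab_file)
    if (is.null(parsed)) next
    if (!is.null(parsed$node)) iso <- c(iso, parsed$node)
    if (!is.null(parsed$edges)) edge_list[[length(edge_list) + 1L]] <- parsed$edges
  }
  interactions <- if (length(edge_list)) do.call(rbind, edge_list) else NULL

  sif_nodes <- unique(c(iso, if (!is.null(interactions))
    c(interactions$source, interactions$target)))
  all_ids <- unique(c(sif_nodes, names(comp_map)))
  missing <- setdiff(all_ids, names(comp_map))
  if (length(missing)) {
    if (is.null(default_compartment)) {
      stop("node(s) present in SIF but absent from attribute file: ",
           paste(missing, collapse = ", "))
    }
    comp_map[missing] <- default_compartment
  }
  nodes <- data.frame(id = all_ids, compartment = unname(comp_map[all_ids]),
                      stringsAsFactors = FALSE)
  signaling_network(nodes, interactions, name = name, vocabulary = vocabulary,
                    allow_extra_compartments = allow_extra_compartments)
}

#' Write a network as SIF plus node-attribute TSV
#'
#' Writes the simple view of the network, deterministically ordered
#' (C-collation by node id), so that two writes of the same simple view are
#' byte-identical and `read_sif()` of the output reproduces the same node
#' set, compartment map and simple edge set. Nodes with no simple edge are
#' written as single-field SIF lines, which keeps isolated (e.g. knocked
#' out or orphaned) nodes representable.
#'
#' @param net A `signaling_network`.
#' @param path Output SIF path.
#' @param attrs_path Output attribute TSV path; a `#compartments:` header
#'   comment records the vocabulary.
#' @return Invisibly, `net`.
#' @export
write_sif <- function(net, path, attrs_path) {
  sv <- simple_view(net)
  inter <- sv$interactions
  lines <- character(0)
  if (nrow(inter)) {
    lines <- sprintf("%s\t%s\t%s", inter$source, inter$kind, inter$target)
  }
  connected <- unique(c(inter$source, inter$target))
  isolated <- sort_c(setdiff(sv$nodes$id, connected))
  lines <- c(lines, isolated)
  writeLines(lines, path, useBytes = TRUE)

  nodes <- sv$nodes[order_c(sv$nodes$id), , drop = FALSE]
  attr_lines <- c(
    paste0("#compartments: ", paste(sv$vocabulary, collapse = ", ")),
    "node\tcompartment",
    sprintf("%s\t%s", nodes$id, nodes$compartment)
  )
  writeLines(attr_lines, attrs_path, useBytes = TRUE)
  invisible(net)
}
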