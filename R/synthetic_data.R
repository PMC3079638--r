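# Seeded generators standing in for unpublished signaling networks:
# compartment-labeled preferential-attachment (scale-free) networks,
# planted-bridge networks with known ground truth, and the documented
# capacitation-core fixture.

#' Default compartment sampling weights
#'
#' A plausible distribution of signaling molecules over subcellular
#' districts: most species live in the cytosol or at the plasma membrane,
#' with smaller cytoskeletal, mitochondrial and acrosomal contingents and a
#' small nuclear/extracellular remainder.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_compartment_weights <- function() {
  c(membrane = 0.25, cytosol = 0.35, cytoskeleton = 0.10,
    mitochondria = 0.10, acrosome = 0.10, nucleus = 0.05,
    extracellular = 0.05)
}

#' Generate a compartment-labeled preferential-attachment network
#'
#' Barabasi-Albert-style growth: the network starts from a clique of
#' `edges_per_new_node + 1` nodes; each subsequent node attaches to
#' `edges_per_new_node` distinct existing nodes chosen with probability
#' proportional to their current degree. The result is connected and, for
#' large `n_nodes`, has the heavy-tailed degree distribution of a
#' scale-free network (a few highly connected hubs, most nodes scarcely
#' linked). Compartments are drawn independently from
#' `compartment_weights`. Deterministic for a fixed seed; the global RNG
#' state is left untouched.
#'
#' For `edges_per_new_node = 1` the edge count is `n_nodes - 1` (a tree
#' rooted in the initial 2-clique); in general it is
#' `choose(m + 1, 2) + m * (n - m - 1)` with `m = edges_per_new_node`.
#'
#' @param n_nodes Number of nodes; must exceed `edges_per_new_node`.
#' @param edges_per_new_node Links added by each incoming node (>= 1).
#' @param compartment_weights Named probability vector over compartments;
#'   defaults to [default_compartment_weights()]. Must sum to 1 (within
#'   1e-9).
#' @param seed Integer seed.
#' @param name Network name.
#' @return A `signaling_network` with nodes `n001`, `n002`, ...
#' @export
generate_pa_network <- function(n_nodes = 153L, edges_per_new_node = 1L,
                                compartment_weights = NULL, seed = 1L,
                                name = "pa_network") {
  m <- as.integer(edges_per_new_node)
  n <- as.integer(n_nodes)
  if (m < 1L) stop("edges_per_new_node must be >= 1")
  if (n < m + 1L) stop("n_nodes must be >= edges_per_new_node + 1")
  if (is.null(compartment_weights)) {
    compartment_weights <- default_compartment_weights()
  }
  if (abs(sum(compartment_weights) - 1) > 1e-9) {
    stop("compartment_weights must sum to 1")
  }
  ids <- sprintf("n%03d", seq_len(n))
  withr::with_seed(seed, {
    comp <- sample(names(compartment_weights), n, replace = TRUE,
                   prob = compartment_weights)
    # seed clique on the first m + 1 nodes
    seed_pairs <- utils::combn(seq_len(m + 1L), 2L)
    src <- seed_pairs[1L, ]
    tgt <- seed_pairs[2L, ]
    deg <- integer(n)
    deg[seq_len(m + 1L)] <- m
    if (n > m + 1L) {
      for (v in seq.int(m + 2L, n)) {
        existing <- seq_len(v - 1L)
        picks <- sample(existing, m, replace = FALSE, prob = deg[existing])
        src <- c(src, rep.int(v, m))
        tgt <- c(tgt, picks)
        deg[picks] <- deg[picks] + 1L
        deg[v] <- m
      }
    }
  })
  nodes <- data.frame(id = ids, compartment = comp, stringsAsFactors = FALSE)
  inter <- data.frame(source = ids[src], target = ids[tgt], kind = "pp",
                      stringsAsFactors = FALSE)
  signaling_network(nodes, inter, name = name)
}

#' Generate a planted-bridge network with known ground truth
#'
#' Builds a network in which the compartment-bridging nodes and the orphans
#' of each hub knockout are known by construction, for use as an oracle:
#'
#' * one connected random module per compartment (the first `n_modules`
#'   entries of [default_compartments()]), each module a random spanning
#'   tree over `module_size` same-compartment nodes;
#' * a backbone chaining consecutive modules through pairs of
#'   nucleus-compartment linker nodes (two linkers per junction, so no
#'   linker's neighborhood spans two module compartments);
#' * `n_hubs` hub nodes (nucleus compartment), each wired to one random
#'   node in every module — these are the planted bridges, and the only
#'   nodes whose neighbors cover all module compartments;
#' * per hub, a pendant chain of `pendants_per_hub` nucleus nodes reachable
#'   only through that hub — the planted orphans of its knockout.
#'
#' The planted truth is verified against [bridging_node_ids()] and
#' [orphan_nodes()] before returning (a self-consistency gate), so a
#' returned object is guaranteed coherent.
#'
#' @param n_modules Number of compartment modules (>= 2, <= 5 so that
#'   module compartments stay disjoint from the nucleus used for hubs,
#'   linkers and pendants).
#' @param module_size Nodes per module (>= 2).
#' @param n_hubs Number of planted bridge hubs (>= 1).
#' @param pendants_per_hub Length of each hub's pendant chain (>= 1).
#' @param seed Integer seed.
#' @return List with elements `network` (a `signaling_network`) and `truth`
#'   (list with `bridge_ids`, `orphan_map` mapping hub id -> planted orphan
#'   ids, and `target_set`, the module compartments).
#' @export
generate_planted_bridge_network <- function(n_modules = 3L, module_size = 4L,
                                            n_hubs = 1L,
                                            pendants_per_hub = 2L,
                                            seed = 1L) {
  n_modules <- as.integer(n_modules)
  module_size <- as.integer(module_size)
  if (n_modules < 2L || n_modules > 5L) stop("n_modules must be in 2..5")
  if (module_size < 2L) stop("module_size must be >= 2")
  if (n_hubs < 1L) stop("n_hubs must be >= 1")
  if (pendants_per_hub < 1L) stop("pendants_per_hub must be >= 1")

  comps <- default_compartments()[seq_len(n_modules)]
  nodes <- list()
  edges <- list()
  add_edge <- function(a, b) {
    edges[[length(edges) + 1L]] <<- data.frame(
      source = a, target = b, kind = "pp", stringsAsFactors = FALSE)
  }

  module_nodes <- list()
  withr::with_seed(seed, {
    for (ci in seq_along(comps)) {
      ids <- sprintf("%s_%02d", comps[[ci]], seq_len(module_size))
      module_nodes[[comps[[ci]]]] <- ids
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = ids, compartment = comps[[ci]], stringsAsFactors = FALSE)
      # random spanning tree: node j attaches to a uniform earlier node
      for (j in seq.int(2L, module_size)) {
        add_edge(ids[[sample.int(j - 1L, 1L)]], ids[[j]])
      }
    }
    # backbone: module i -- linker pair -- module i + 1
    if (n_modules > 1L) {
      for (ci in seq_len(n_modules - 1L)) {
        l1 <- sprintf("linker_%02da", ci)
        l2 <- sprintf("linker_%02db", ci)
        nodes[[length(nodes) + 1L]] <- data.frame(
          id = c(l1, l2), compartment = "nucleus", stringsAsFactors = FALSE)
        a <- sample(module_nodes[[comps[[ci]]]], 1L)
        b <- sample(module_nodes[[comps[[ci + 1L]]]], 1L)
        add_edge(a, l1); add_edge(l1, l2); add_edge(l2, b)
      }
    }
    hub_ids <- sprintf("hub_%02d", seq_len(n_hubs))
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = hub_ids, compartment = "nucleus", stringsAsFactors = FALSE)
    orphan_map <- list()
    for (h in hub_ids) {
      for (cm in comps) add_edge(h, sample(module_nodes[[cm]], 1L))
      chain <- sprintf("%s_pendant_%02d", h, seq_len(pendants_per_hub))
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = chain, compartment = "nucleus", stringsAsFactors = FALSE)
      prev <- h
      for (p in chain) { add_edge(prev, p); prev <- p }
      orphan_map[[h]] <- sort_c(chain)
    }
  })

  net <- signaling_network(do.call(rbind, nodes), do.call(rbind, edges),
                           name = "planted_bridge_network")
  truth <- list(bridge_ids = sort_c(sprintf("hub_%02d", seq_len(n_hubs))),
                orphan_map = orphan_map,
                target_set = sort_c(comps))

  # self-consistency gate: the analysis modules must recover the plant
  found <- bridging_node_ids(net, target_set = truth$target_set,
                             include_self = FALSE)
  if (!identical(found, truth$bridge_ids)) {
    stop("planted-bridge generator failed self-check: bridges ",
         paste(found, collapse = ", "))
  }
  for (h in names(truth$orphan_map)) {
    got <- orphan_nodes(net, remove_nodes(net, h))
    if (!identical(got, truth$orphan_map[[h]])) {
      stop("planted-bridge generator failed self-check: knockout of ", h,
           " orphaned ", paste(got, collapse = ", "))
    }
  }
  list(network = net, truth = truth)
}

#' The capacitation-core fixture network
#'
#' A deterministic 17-node, 19-edge network encoding the documented
#' neighborhood of the actin-polymerization node in the sperm capacitation
#' signaling machinery. The actin-polymerization node (cytoskeleton) has
#' exactly eight distinct neighbors spanning five subcellular districts:
#' phosphatidic acid (membrane), ATP (cytosol), intracellular calcium
#' `[Ca2+]i` (cytosol), F-actin and G-actin (cytoskeleton), outer-acrosomal
#' and plasma-membrane fusion (acrosome, membrane), and mitochondrial
#' protein translation (mitochondria). A PKA/PLD1 backbone wires
#' phosphatidic acid, `[Ca2+]i` and ATP together (PLD activation runs
#' through the cAMP/PKA pathway), F-actin and G-actin are joined, and the
#' fusion and translation nodes hang off actin polymerization alone — so
#' its knockout orphans exactly those five nodes.
#'
#' Six satellite nodes (`membrane Ca channel`, `mitochondrial Ca store`,
#' `acrosomal Ca store`, `membrane ATPase`, `mitochondrial ATP synthesis`,
#' `acrosomal ATPase`) are **synthetic**: they are invented here, named for
#' plausibility only, and serve solely to give `[Ca2+]i` and ATP one
#' neighbor in each of the membrane, mitochondria and acrosome districts,
#' making those two nodes (with actin polymerization) the only
#' five-compartment bridges — which mirrors the capacitation network's
#' published behavior without reproducing its unpublished edge list.
#'
#' @return A `signaling_network` named `"capacitation_core"`.
#' @examples
#' net <- capacitation_core_fixture()
#' degree_sequence(net)[["actin polymerization"]]  # 8
#' bridging_node_ids(net)                          # the three bridges
#' @export
capacitation_core_fixture <- function() {
  nodes <- data.frame(
    id = c("actin polymerization", "phosphatidic acid", "ATP", "[Ca2+]i",
           "F-actin", "G-actin", "OAM fusion", "PM fusion",
           "mitochondrial protein translation", "PKA", "PLD1",
           "membrane Ca channel", "mitochondrial Ca store",
           "acrosomal Ca store", "membrane ATPase",
           "mitochondrial ATP synthesis", "acrosomal ATPase"),
    compartment = c("cytoskeleton", "membrane", "cytosol", "cytosol",
                    "cytoskeleton", "cytoskeleton", "acrosome", "membrane",
                    "mitochondria", "cytosol", "membrane",
                    "membrane", "mitochondria",
                    "acrosome", "membrane",
                    "mitochondria", "acrosome"),
    stringsAsFactors = FALSE)
  edges <- matrix(c(
    # the eight links of actin polymerization
    "actin polymerization", "phosphatidic acid",
    "actin polymerization", "ATP",
    "actin polymerization", "[Ca2+]i",
    "actin polymerization", "F-actin",
    "actin polymerization", "G-actin",
    "actin polymerization", "OAM fusion",
    "actin polymerization", "PM fusion",
    "actin polymerization", "mitochondrial protein translation",
    # PKA/PLD1 backbone
    "phosphatidic acid", "PLD1",
    "PLD1", "PKA",
    "PKA", "[Ca2+]i",
    "PKA", "ATP",
    # actin monomer/filament link
    "F-actin", "G-actin",
    # synthetic satellites completing [Ca2+]i and ATP as bridges
    "[Ca2+]i", "membrane Ca channel",
    "[Ca2+]i", "mitochondrial Ca store",
    "[Ca2+]i", "acrosomal Ca store",
    "ATP", "membrane ATPase",
    "ATP", "mitochondrial ATP synthesis",
    "ATP", "acrosomal ATPase"
  ), ncol = 2L, byrow = TRUE)
  inter <- data.frame(source = edges[, 1L], target = edges[, 2L],
                      kind = "pp", stringsAsFactors = FALSE)
  signaling_network(nodes, inter, name = "capacitation_core")
}
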