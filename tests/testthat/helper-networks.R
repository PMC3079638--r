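# Small network builders used across the test files.

net_from_edges <- function(edges, compartments = NULL, nodes = NULL) {
  ids <- unique(c(nodes, edges))
  if (is.null(compartments)) {
    comp <- rep(capnet::default_compartments(),
                length.out = length(ids))
    compartments <- stats::setNames(comp, ids)
  }
  inter <- if (length(edges)) {
    m <- matrix(edges, ncol = 2L, byrow = TRUE)
    data.frame(source = m[, 1L], target = m[, 2L],
               stringsAsFactors = FALSE)
  } else NULL
  signaling_network(ids, inter, compartments = compartments)
}

triangle_net <- function() net_from_edges(c("A","B", "B","C", "A","C"))

star_net <- function(leaves = 3L) {
  ids <- c("hub", sprintf("leaf%d", seq_len(leaves)))
  net_from_edges(as.vector(rbind("hub", ids[-1L])))
}

path_net <- function(n = 3L) {
  ids <- LETTERS[seq_len(n)]
  net_from_edges(as.vector(rbind(ids[-n], ids[-1L])))
}

# Erdos-Renyi-ish network with random compartments; optionally salted with
# self-loops and parallel interactions to exercise the raw-vs-simple split
random_test_network <- function(n, p = 0.12, seed = 1L,
                                loops = FALSE, parallel = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("v%02d", seq_len(n))
    comp <- stats::setNames(
      sample(capnet::default_compartments(), n, replace = TRUE), ids)
    pairs <- utils::combn(ids, 2L)
    keep <- stats::runif(ncol(pairs)) < p
    src <- pairs[1L, keep]
    tgt <- pairs[2L, keep]
    if (parallel && length(src)) {
      dup <- sample(seq_along(src), min(3L, length(src)))
      src <- c(src, tgt[dup])   # reversed duplicates
      tgt <- c(tgt, src[dup])
    }
    if (loops) {
      lo <- sample(ids, min(2L, n))
      src <- c(src, lo); tgt <- c(tgt, lo)
    }
    inter <- if (length(src)) {
      data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
    } else NULL
    signaling_network(ids, inter, compartments = comp)
  })
}

expect_same_network_view <- function(a, b) {
  a <- simple_view(a); b <- simple_view(b)
  ord_a <- order(a$nodes$id, method = "radix")
  ord_b <- order(b$nodes$id, method = "radix")
  expect_identical(a$nodes$id[ord_a], b$nodes$id[ord_b])
  expect_identical(a$nodes$compartment[ord_a], b$nodes$compartment[ord_b])
  key <- function(n) sort(paste(n$interactions$source,
                                n$interactions$target, sep = "\r"),
                          method = "radix")
  expect_identical(key(a), key(b))
}
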