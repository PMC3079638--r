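# Independent brute-force oracles. These deliberately avoid the package's
# igraph-backed code paths: adjacency matrices are built directly from the
# raw interaction table, distances come from Floyd-Warshall, components
# from a hand-rolled BFS, and the log-log fit from the textbook OLS
# formulas. They are the reference the fast implementations are checked
# against.

oracle_adjacency <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  inter <- net$interactions
  for (r in seq_len(nrow(inter))) {
    s <- inter$source[[r]]; t <- inter$target[[r]]
    if (s != t) { A[s, t] <- 1L; A[t, s] <- 1L }
  }
  A
}

oracle_distances <- function(net) {
  A <- oracle_adjacency(net)
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      through_k <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], through_k)
    }
  }
  D
}

oracle_clustering <- function(net) {
  A <- oracle_adjacency(net)
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1)) |> stats::setNames(rownames(A))
}

oracle_closeness <- function(net) {
  D <- oracle_distances(net)
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1)) |> stats::setNames(rownames(D))
}

oracle_components <- function(net) {
  A <- oracle_adjacency(net)
  n <- nrow(A)
  label <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(label[[s]])) next
    cur <- cur + 1L
    queue <- s
    label[[s]] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nxt <- which(A[v, ] == 1L & is.na(label))
      label[nxt] <- cur
      queue <- c(queue, nxt)
    }
  }
  stats::setNames(label, rownames(A))
}

# same giant-component rule as the package, coded independently:
# max size, then max overlap with `prefer`, then lexicographically
# smallest member (C collation)
oracle_giant <- function(net, prefer = NULL) {
  if (nrow(net$nodes) == 0L) return(character(0))
  lab <- oracle_components(net)
  comps <- split(names(lab), lab)
  sizes <- lengths(comps)
  comps <- comps[sizes == max(sizes)]
  if (length(comps) > 1L && !is.null(prefer)) {
    ov <- vapply(comps, function(m) sum(m %in% prefer), integer(1))
    comps <- comps[ov == max(ov)]
  }
  if (length(comps) > 1L) {
    mins <- vapply(comps, function(m) sort(m, method = "radix")[[1L]], "")
    comps <- comps[order(mins, method = "radix")]
  }
  sort(comps[[1L]], method = "radix")
}

oracle_orphans <- function(pre_net, post_net) {
  pre_giant <- oracle_giant(pre_net)
  post_giant <- oracle_giant(post_net, prefer = pre_giant)
  sort(setdiff(intersect(pre_giant, post_net$nodes$id), post_giant),
       method = "radix")
}

oracle_bridges <- function(net, target_set, include_self = FALSE) {
  A <- oracle_adjacency(net)
  comp <- stats::setNames(net$nodes$compartment, net$nodes$id)
  ids <- rownames(A)
  hits <- vapply(ids, function(id) {
    covered <- unique(comp[ids[A[id, ] == 1L]])
    if (include_self) covered <- unique(c(covered, comp[[id]]))
    all(target_set %in% covered)
  }, logical(1))
  sort(ids[hits], method = "radix")
}

# textbook OLS of ln y on ln x, no lm()
oracle_loglog_ols <- function(x, y) {
  lx <- log(x); ly <- log(y)
  mx <- mean(lx); my <- mean(ly)
  slope <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
  intercept <- my - slope * mx
  r <- sum((lx - mx) * (ly - my)) /
    sqrt(sum((lx - mx)^2) * sum((ly - my)^2))
  list(b = slope, a = exp(intercept), r = r, r2 = r^2)
}
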