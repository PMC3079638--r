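# Spring-embedded (force-directed) layout: nodes repel like charges,
# edges pull like springs, and a cooling schedule settles the system.

#' Spring-embedded network layout
#'
#' Fruchterman-Reingold-style force-directed layout on the simple view.
#' Every node pair repels with force `k^2 / d`, every edge attracts its
#' endpoints with force `d^2 / k`, where `d` is the current distance and
#' `k = sqrt(area / n)` is the ideal edge length; displacements are capped
#' by a temperature that cools linearly to zero, so the iteration settles
#' into a configuration that (locally) minimizes the residual forces.
#' Deterministic for a fixed seed; the global RNG state is untouched.
#'
#' @param net A non-empty `signaling_network`.
#' @param iterations Number of iterations (>= 1).
#' @param seed Integer seed for the random initial placement in the unit
#'   square.
#' @param area Layout area (default 1, the unit square).
#' @return An object of class `layout_result`: list with `coordinates`
#'   (data frame `node`, `x`, `y`), `iterations_run`, `final_energy` (sum
#'   of residual net-force magnitudes after the last iteration) and
#'   `energy_history`.
#' @export
spring_embedded_layout <- function(net, iterations = 100L, seed = 1L,
                                   area = 1) {
  n <- n_nodes(net)
  if (n == 0L) stop("empty network")
  if (iterations < 1L) stop("iterations must be >= 1")
  sv <- simple_view(net)
  ids <- node_ids(sv)
  k <- sqrt(area / n)
  ei <- match(sv$interactions$source, ids)
  ej <- match(sv$interactions$target, ids)

  pos <- withr::with_seed(seed, {
    matrix(stats::runif(2L * n, 0, sqrt(area)), ncol = 2L)
  })
  energy_history <- numeric(iterations)
  t0 <- sqrt(area) / 10
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2L)
    # pairwise repulsion k^2 / d
    dx <- outer(pos[, 1L], pos[, 1L], `-`)
    dy <- outer(pos[, 2L], pos[, 2L], `-`)
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    f <- k^2 / d^2   # force k^2/d along the unit vector (dx, dy)/d
    diag(f) <- 0
    disp[, 1L] <- rowSums(dx * f)
    disp[, 2L] <- rowSums(dy * f)
    # edge attraction d^2 / k
    if (length(ei)) {
      ex <- pos[ei, 1L] - pos[ej, 1L]
      ey <- pos[ei, 2L] - pos[ej, 2L]
      ed <- sqrt(ex^2 + ey^2)
      ed[ed < 1e-9] <- 1e-9
      fa <- ed / k     # (d^2/k) / d along the unit vector
      ax <- ex * fa; ay <- ey * fa
      for (r in seq_along(ei)) {
        disp[ei[r], ] <- disp[ei[r], ] - c(ax[r], ay[r])
        disp[ej[r], ] <- disp[ej[r], ] + c(ax[r], ay[r])
      }
    }
    mag <- sqrt(rowSums(disp^2))
    energy_history[it] <- sum(mag)
    temp <- t0 * (iterations - it + 1L) / iterations
    step <- pmin(mag, temp) / pmax(mag, 1e-12)
    pos <- pos + disp * step
  }
  structure(
    list(coordinates = data.frame(node = ids, x = pos[, 1L], y = pos[, 2L],
                                  stringsAsFactors = FALSE),
         iterations_run = iterations,
         final_energy = energy_history[iterations],
         energy_history = energy_history),
    class = "layout_result")
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf(
    "<layout_result> %d nodes, %d iterations, final energy %.4g\n",
    nrow(x$coordinates), x$iterations_run, x$final_energy))
  invisible(x)
}
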