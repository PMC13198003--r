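#' Default resolution schedule
#'
#' Eight uniformly spaced Leiden resolutions from 0.95 down to 0.15, the
#' conventional sweep for Visium-scale tissues; coarser tissue structure
#' appears as the resolution decreases.
#' @param n number of resolutions.
#' @return Decreasing numeric vector.
#' @export
default_resolutions <- function(n = 8L) seq(0.95, 0.15, length.out = n)

#' Multi-resolution clustering sweep over an embedding
#'
#' Adapter from a per-spot embedding (e.g. a spatially-aware latent space
#' from GraphST, SCAN-IT or Banksy, computed upstream) to a
#' [clustering_sequence()]: builds a k-nearest-neighbor graph on the
#' embedding and runs Leiden community detection (modularity objective) at
#' each resolution of the schedule. Any other clustering pipeline can be
#' used instead — the rest of the package only consumes label matrices.
#'
#' @param spots a [spot_set()].
#' @param embedding numeric matrix, one row per spot.
#' @param resolutions decreasing resolution schedule (default
#'   [default_resolutions()]).
#' @param k neighbors in the kNN graph (default 15).
#' @param seed integer seed; output is reproducible given the seed.
#' @return A [clustering_sequence()].
#' @export
cluster_sweep <- function(spots, embedding,
                          resolutions = default_resolutions(),
                          k = 15L, seed = 1L) {
  stopifnot(inherits(spots, "spot_set"))
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != nrow(spots))
    stop("embedding must have one row per spot")
  if (length(resolutions) == 0L) stop("empty resolution schedule")
  n <- nrow(embedding)
  k <- min(k, n - 1L)

  d <- as.matrix(stats::dist(embedding))
  nn <- apply(d, 1L, function(row) order(row)[2:(k + 1L)])
  el <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labels <- vapply(resolutions, function(r) {
    as.integer(igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = r,
      n_iterations = 5L)))
  }, integer(n))
  colnames(labels) <- format(resolutions, trim = TRUE)
  clustering_sequence(spots, labels, resolutions = resolutions)
}
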