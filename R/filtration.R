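#' Containment dissimilarity between two clusters
#'
#' `1 - |A n B| / |A|`, where `A` is the finer-scale cluster: 0 iff `A` is
#' contained in `B`, 1 iff the clusters are disjoint. Asymmetric; intended
#' for sweeps whose clusters are largely nested.
#'
#' @param a,b vectors of spot identifiers (or indices); `a` must be
#'   non-empty.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' containment_dissimilarity(1:4, 3:5)  # 0.5
#' @export
containment_dissimilarity <- function(a, b) {
  if (length(a) == 0L) stop("containment dissimilarity undefined for empty A")
  1 - length(intersect(a, b)) / length(unique(a))
}

#' Jaccard dissimilarity between two clusters
#'
#' `1 - |A n B| / |A u B|`: symmetric, 0 iff equal, 1 iff disjoint. Applies
#' to any pair of clusterings, nested or not. Always at least as large as
#' [containment_dissimilarity()].
#'
#' @param a,b vectors of spot identifiers (or indices), not both empty.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' jaccard_dissimilarity(1:4, 3:5)  # 0.6
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("Jaccard dissimilarity undefined for two empty sets")
  1 - length(intersect(a, b)) / u
}

#' Build the cross-scale cluster overlap graph and its filtration
#'
#' One node per cluster at every scale; for each pair of clusters at
#' consecutive scales with non-empty intersection, an edge weighted by the
#' chosen dissimilarity of their spot sets. Disjoint pairs (dissimilarity
#' exactly 1) are not materialized: such an edge can never merge components
#' before the terminal filtration value, so omitting it changes no death and
#' keeps the graph sparse. Edges are sorted by increasing weight with the
#' deterministic tie key (source scale, source label, target label), which
#' fixes the order simultaneous merges resolve in.
#'
#' Weights are ratios of integer overlap counts, computed by bucketing spots
#' by their label pair at consecutive scales (each spot touched once per
#' scale step, never via all-pairs set intersection).
#'
#' @param seq a [clustering_sequence()] with at least 2 scales.
#' @param index `"containment"` (default; for largely nested sweeps) or
#'   `"jaccard"` (general, e.g. tumor tissue without nested organization).
#' @return An object of class `cluster_filtration`: list with
#'   `nodes` (data.frame `node`, `scale`, `label`, `size`), `members`
#'   (list of spot-index vectors per node), `edges` (data.frame `source`,
#'   `target`, `weight`, `overlap`, sorted), `index`, and `spots`.
#' @export
build_overlap_graph <- function(seq, index = c("containment", "jaccard")) {
  stopifnot(inherits(seq, "clustering_sequence"))
  index <- match.arg(index)
  K <- seq$n_scales
  n_per_scale <- apply(seq$labels, 2L, max)
  offset <- cumsum(c(0L, n_per_scale[-K]))  # node id = offset[i] + label

  members <- vector("list", sum(n_per_scale))
  nodes <- data.frame(
    node = seq_len(sum(n_per_scale)),
    scale = rep(seq_len(K), n_per_scale),
    label = unlist(lapply(n_per_scale, seq_len), use.names = FALSE)
  )
  for (i in seq_len(K)) {
    cl <- scale_clusters(seq, i)
    for (j in seq_along(cl)) members[[offset[i] + j]] <- cl[[j]]
  }
  nodes$size <- lengths(members)

  edges <- vector("list", K - 1L)
  for (i in seq_len(K - 1L)) {
    li <- seq$labels[, i]
    lj <- seq$labels[, i + 1L]
    # co-occurrence counts: spots bucketed by (fine label, coarse label)
    tab <- table(factor(li, levels = seq_len(n_per_scale[i])),
                 factor(lj, levels = seq_len(n_per_scale[i + 1L])))
    idx <- which(tab > 0L, arr.ind = TRUE)
    ov <- tab[idx]
    sz_a <- nodes$size[offset[i] + idx[, 1L]]
    sz_b <- nodes$size[offset[i + 1L] + idx[, 2L]]
    w <- if (index == "containment") 1 - ov / sz_a
         else 1 - ov / (sz_a + sz_b - ov)
    keep <- w < 1  # disjoint pairs never occur here (ov > 0) but keep guard
    edges[[i]] <- data.frame(
      source = offset[i] + idx[keep, 1L],
      target = offset[i + 1L] + idx[keep, 2L],
      weight = w[keep],
      overlap = as.integer(ov[keep]))
  }
  edges <- do.call(rbind, edges)
  ord <- order(edges$weight,
               nodes$scale[edges$source],
               nodes$label[edges$source],
               nodes$label[edges$target])
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(nodes = nodes, members = members, edges = edges, index = index,
         spots = seq$spots, resolutions = seq$resolutions),
    class = "cluster_filtration"
  )
}

#' @export
print.cluster_filtration <- function(x, ...) {
  cat("Cluster filtration (", x$index, " index)\n", sep = "")
  cat("  scales:", max(x$nodes$scale), " nodes:", nrow(x$nodes),
      " edges:", nrow(x$edges), "\n")
  if (nrow(x$edges))
    cat("  weight range: [", format(min(x$edges$weight), digits = 4), ", ",
        format(max(x$edges$weight), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Dump filtration edges to CSV (debug aid)
#' @param filt a [build_overlap_graph()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(filt, path) {
  stopifnot(inherits(filt, "cluster_filtration"))
  out <- data.frame(
    scale_i = filt$nodes$scale[filt$edges$source],
    label_i = filt$nodes$label[filt$edges$source],
    label_j = filt$nodes$label[filt$edges$target],
    weight = filt$edges$weight,
    intersection_size = filt$edges$overlap)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
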