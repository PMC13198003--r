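# 0-dimensional persistence of an edge-filtered graph by union-find.
#
# All vertices enter the filtration at value 0; edges enter at their weight
# in the given (already sorted) order. When an edge joins two distinct
# classes the class with the larger elder key dies at that weight; classes
# alive after the last edge die at +Inf. Membership and internal edges are
# snapshotted immediately before death (internal edges strictly below the
# death value; all accumulated edges for survivors).
#
# `elder_key` is a per-node total order (smaller = survives a merge). It
# never changes the diagram, only which class each membership snapshot is
# attributed to.
persistence_from_edges <- function(n_nodes, edges, elder_key) {
  stopifnot(n_nodes >= 1L, length(elder_key) == n_nodes)
  parent <- seq_len(n_nodes)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  best <- seq_len(n_nodes)            # node with min elder key per class
  members <- as.list(seq_len(n_nodes))
  internal <- rep(list(integer(0)), n_nodes)

  comps <- list()
  births <- deaths <- numeric(0)
  ne <- if (is.null(edges)) 0L else nrow(edges)
  for (e in seq_len(ne)) {
    u <- find(edges$source[e]); v <- find(edges$target[e])
    w <- edges$weight[e]
    if (u == v) {
      internal[[u]] <- c(internal[[u]], e)
      next
    }
    die <- if (elder_key[best[u]] > elder_key[best[v]]) u else v
    live <- if (die == u) v else u
    ie <- internal[[die]]
    comps[[length(comps) + 1L]] <- list(
      representative = best[die],
      death = w,
      member_nodes = members[[die]],
      internal_edges = ie[edges$weight[ie] < w])
    deaths <- c(deaths, w)
    parent[die] <- live
    members[[live]] <- c(members[[live]], members[[die]])
    internal[[live]] <- c(internal[[live]], internal[[die]], e)
    members[die] <- list(NULL); internal[die] <- list(NULL)
  }
  roots <- unique(vapply(seq_len(n_nodes), find, integer(1)))
  roots <- roots[order(elder_key[best[roots]])]
  for (r in roots) {
    comps[[length(comps) + 1L]] <- list(
      representative = best[r],
      death = Inf,
      member_nodes = members[[r]],
      internal_edges = internal[[r]])
    deaths <- c(deaths, Inf)
  }
  comps
}

#' Zero-dimensional persistent homology of a cluster filtration
#'
#' Runs union-find persistence over the sorted edges of the cross-scale
#' overlap graph. Every cluster node is born at filtration value 0; a
#' connected component dies when an edge merges it into an older component,
#' and components still alive at the end of the filtration receive death
#' `Inf` and persistence lifetime 1. Each component records the clusters
#' merged into it strictly before its death (its membership snapshot) and
#' the edges internal to that snapshot, from which coreness is computed.
#'
#' At a merge both classes have birth 0, so the classical elder rule needs a
#' tie-break. The survivor is the class containing the coarsest-scale node
#' (largest scale index; ties to the smaller cluster label). Coarse-preferred
#' survival makes a nested hierarchy decompose into one component per
#' planted domain — each finer domain dies, with support exactly itself, at
#' the edge linking it to its parent — while the diagram itself is identical
#' under any tie-break.
#'
#' @param filt a [build_overlap_graph()] result.
#' @param drop_zero drop zero-persistence points (death exactly 0, from
#'   weight-0 merges) from the reported diagram and component list (default
#'   `TRUE`); they carry no multiscale information.
#' @return An object of class `phdms_persistence`: list with `diagram`
#'   (data.frame `component_id`, `birth`, `death`, `lifetime`, `n_clusters`,
#'   `n_spots`), `components` (list of component records), and the
#'   originating `filtration`.
#' @export
compute_persistence <- function(filt, drop_zero = TRUE) {
  stopifnot(inherits(filt, "cluster_filtration"))
  nd <- filt$nodes
  elder <- order(order(-nd$scale, nd$label))  # rank: coarse first, low label
  comps <- persistence_from_edges(nrow(nd), filt$edges, elder)
  if (drop_zero)
    comps <- comps[vapply(comps, function(cp) cp$death > 0, logical(1))]
  for (i in seq_along(comps)) {
    comps[[i]]$id <- i
    comps[[i]]$birth <- 0
    comps[[i]]$lifetime <- min(comps[[i]]$death, 1)
    comps[[i]]$spots <- sort(unique(unlist(
      filt$members[comps[[i]]$member_nodes], use.names = FALSE)))
  }
  diagram <- data.frame(
    component_id = vapply(comps, `[[`, integer(1), "id"),
    birth = 0,
    death = vapply(comps, `[[`, numeric(1), "death"),
    lifetime = vapply(comps, `[[`, numeric(1), "lifetime"),
    n_clusters = vapply(comps, function(cp) length(cp$member_nodes),
                        integer(1)),
    n_spots = vapply(comps, function(cp) length(cp$spots), integer(1)))
  structure(list(diagram = diagram, components = comps, filtration = filt),
            class = "phdms_persistence")
}

#' @export
print.phdms_persistence <- function(x, ...) {
  cat("0-dimensional persistence of a cluster filtration\n")
  cat("  components:", nrow(x$diagram),
      " (", sum(is.infinite(x$diagram$death)), " never die)\n", sep = "")
  fin <- x$diagram$death[is.finite(x$diagram$death)]
  if (length(fin))
    cat("  finite deaths in [", format(min(fin), digits = 4), ", ",
        format(max(fin), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Filter persistent components by lifetime and size
#'
#' @param pers a [compute_persistence()] result.
#' @param min_lifetime keep components with persistence lifetime at least
#'   this value (in `[0, 1]`).
#' @param min_clusters keep components whose membership snapshot holds at
#'   least this many clusters; the default 2 hides singleton components.
#' @return A `phdms_persistence` restricted to the kept components, order
#'   preserved.
#' @export
filter_components <- function(pers, min_lifetime = 0, min_clusters = 2L) {
  stopifnot(inherits(pers, "phdms_persistence"),
            min_lifetime >= 0, min_lifetime <= 1, min_clusters >= 1)
  keep <- pers$diagram$lifetime >= min_lifetime &
    pers$diagram$n_clusters >= min_clusters
  out <- pers
  out$diagram <- pers$diagram[keep, , drop = FALSE]
  rownames(out$diagram) <- NULL
  out$components <- pers$components[keep]
  out
}

#' Write a persistence diagram to CSV
#'
#' Infinite deaths are printed as `inf`.
#' @param pers a [compute_persistence()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(pers, path) {
  stopifnot(inherits(pers, "phdms_persistence"))
  d <- pers$diagram
  d$death <- ifelse(is.infinite(d$death), "inf",
                    format(d$death, digits = 15, trim = TRUE,
                           scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
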