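#' Plant a nested hierarchy of spatial domains on a grid
#'
#' Simulates the ground truth the pipeline is meant to recover: a tissue of
#' spots on a regular grid, partitioned by seeded Voronoi regions whose
#' cells are recursively split so each level strictly refines the one
#' above, the way a large anatomical region contains smaller specialized
#' subregions. Voronoi growth (rather than, say, concentric rings) gives
#' domains with irregular shapes and boundaries. Spots close to any planted
#' boundary are flagged as frontier spots; label noise later acts only
#' there, emulating mixing at region borders.
#'
#' @param grid_side grid side length (at least 8); the tissue has
#'   `grid_side^2` spots at unit spacing.
#' @param n_levels number of hierarchy levels (at least 2), level 1 the
#'   coarsest.
#' @param branching children per parent at each split (at least 2).
#' @param seed integer RNG seed; the hierarchy is a deterministic function
#'   of its arguments.
#' @param frontier_radius spots with a differently-labelled neighbor within
#'   this distance (any level) are frontier spots; the default 1.5 spans
#'   the 8-neighborhood of the unit grid.
#' @return An object of class `planted_hierarchy`: list with `spots`
#'   ([spot_set()]), `levels` (N x n_levels integer matrix, column 1
#'   coarsest), `frontier` (logical per spot), `params`.
#' @export
generate_hierarchy <- function(grid_side, n_levels = 2L, branching = 2L,
                               seed = 1L, frontier_radius = 1.5) {
  stopifnot(grid_side >= 8, n_levels >= 2, branching >= 2)
  n <- grid_side^2
  gx <- rep(seq_len(grid_side), each = grid_side)
  gy <- rep(seq_len(grid_side), times = grid_side)
  spots <- spot_set(sprintf("s%04d", seq_len(n)), gx, gy)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  levels <- matrix(NA_integer_, n, n_levels)
  voronoi_split <- function(idx) {
    seeds <- sample(idx, min(branching, length(idx)))
    d2 <- outer(gx[idx], gx[seeds], "-")^2 + outer(gy[idx], gy[seeds], "-")^2
    max.col(-d2, ties.method = "first")
  }
  levels[, 1] <- {
    assign_all <- integer(n)
    assign_all[seq_len(n)] <- voronoi_split(seq_len(n))
    assign_all
  }
  for (l in seq_len(n_levels - 1L) + 1L) {
    nxt <- integer(n)
    off <- 0L
    for (p in sort(unique(levels[, l - 1L]))) {
      idx <- which(levels[, l - 1L] == p)
      ch <- voronoi_split(idx)
      nxt[idx] <- off + ch
      off <- off + max(ch)
    }
    levels[, l] <- nxt
  }
  # dense relabel per level (prunes label gaps from empty cells)
  for (l in seq_len(n_levels)) levels[, l] <- match(levels[, l],
                                                    sort(unique(levels[, l])))

  frontier <- rep(FALSE, n)
  r2 <- frontier_radius^2
  steps <- expand.grid(dx = -floor(frontier_radius):floor(frontier_radius),
                       dy = -floor(frontier_radius):floor(frontier_radius))
  steps <- steps[steps$dx^2 + steps$dy^2 <= r2 &
                   (steps$dx != 0 | steps$dy != 0), ]
  pos <- matrix(seq_len(n), grid_side, grid_side)  # pos[y, x]
  for (k in seq_len(nrow(steps))) {
    sx <- gx + steps$dx[k]; sy <- gy + steps$dy[k]
    ok <- sx >= 1 & sx <= grid_side & sy >= 1 & sy <= grid_side
    nb <- pos[cbind(sy[ok], sx[ok])]
    diff_any <- rowSums(levels[which(ok), , drop = FALSE] !=
                          levels[nb, , drop = FALSE]) > 0
    frontier[which(ok)[diff_any]] <- TRUE
  }

  structure(
    list(spots = spots, levels = levels, frontier = frontier,
         params = list(grid_side = grid_side, n_levels = n_levels,
                       branching = branching, seed = seed,
                       frontier_radius = frontier_radius)),
    class = "planted_hierarchy"
  )
}

#' @export
print.planted_hierarchy <- function(x, ...) {
  cat("Planted hierarchy: ", nrow(x$spots), " spots on a ",
      x$params$grid_side, "x", x$params$grid_side, " grid\n", sep = "")
  cat("  domains per level (coarse -> fine): ",
      paste(apply(x$levels, 2L, max), collapse = ", "), "\n", sep = "")
  cat("  frontier spots: ", sum(x$frontier), "\n", sep = "")
  invisible(x)
}

#' Observe a planted hierarchy as a noisy multi-resolution clustering
#'
#' Emits the clustering sequence an upstream resolution sweep would
#' produce: each hierarchy level is observed at `scales_per_level`
#' consecutive scales (fine to coarse), and at every scale each frontier
#' spot independently flips, with probability `rho`, to a uniformly chosen
#' spatially adjacent domain of that level. Because the noise is redrawn
#' per scale, frontier spots oscillate between domains across scales —
#' which is exactly what depresses their coreness and raises their
#' heterogeneity — while interior spots are always stable. With `rho = 0`
#' the sequence is perfectly nested.
#'
#' @param h a [generate_hierarchy()] result.
#' @param scales_per_level scales per hierarchy level (at least 1).
#' @param rho frontier flip probability, in `[0, 0.5)`.
#' @param seed integer RNG seed for the noise draws.
#' @return A [clustering_sequence()] with `n_levels * scales_per_level`
#'   scales, synthetic resolutions on the conventional 0.95 to 0.15 grid.
#' @export
degrade_to_clusterings <- function(h, scales_per_level = 2L, rho = 0,
                                   seed = 1L) {
  stopifnot(inherits(h, "planted_hierarchy"),
            scales_per_level >= 1, rho >= 0, rho < 0.5)
  n <- nrow(h$spots)
  n_levels <- ncol(h$levels)
  K <- n_levels * scales_per_level

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  gs <- h$params$grid_side
  gx <- h$spots$x; gy <- h$spots$y
  r <- h$params$frontier_radius
  steps <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
  steps <- steps[steps$dx^2 + steps$dy^2 <= r^2 &
                   (steps$dx != 0 | steps$dy != 0), ]
  pos <- matrix(seq_len(n), gs, gs)
  neighbors <- lapply(seq_len(n), function(i) {
    sx <- gx[i] + steps$dx; sy <- gy[i] + steps$dy
    ok <- sx >= 1 & sx <= gs & sy >= 1 & sy <= gs
    pos[cbind(sy[ok], sx[ok])]
  })

  labels <- matrix(NA_integer_, n, K)
  col <- 0L
  for (l in rev(seq_len(n_levels))) {      # finest level first
    for (s in seq_len(scales_per_level)) {
      col <- col + 1L
      lab <- h$levels[, l]
      if (rho > 0) {
        flip <- which(h$frontier & stats::runif(n) < rho)
        base <- h$levels[, l]
        for (i in flip) {
          alt <- unique(base[neighbors[[i]]])
          alt <- alt[alt != base[i]]
          if (length(alt)) lab[i] <- alt[sample.int(length(alt), 1L)]
        }
      }
      labels[, col] <- lab
    }
  }
  clustering_sequence(h$spots, labels,
                      resolutions = seq(0.95, 0.15, length.out = K))
}

#' Ground-truth annotation at one hierarchy level
#'
#' @param h a [generate_hierarchy()] result.
#' @param level hierarchy level (1 = coarsest).
#' @return A [ground_truth()] labelling every spot with its planted domain
#'   at that level (labels are prefixed with the level so domains from
#'   different levels never collide).
#' @export
truth_from_hierarchy <- function(h, level = 1L) {
  stopifnot(inherits(h, "planted_hierarchy"),
            level >= 1, level <= ncol(h$levels))
  ground_truth(h$spots, sprintf("L%d.%d", level, h$levels[, level]))
}

#' Spot sets of every planted domain
#'
#' @param h a [generate_hierarchy()] result.
#' @param levels which hierarchy levels to include (default all).
#' @return Named list of spot-index vectors, one per planted domain.
#' @export
planted_domains <- function(h, levels = seq_len(ncol(h$levels))) {
  out <- list()
  for (l in levels) {
    sp <- split(seq_len(nrow(h$spots)), h$levels[, l])
    names(sp) <- sprintf("L%d.%s", l, names(sp))
    out <- c(out, sp)
  }
  out
}
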