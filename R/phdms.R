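#' Fit persistent multiscale domains to a clustering sequence
#'
#' The main entry point. Given partitions of one tissue at several
#' resolutions, links clusters at consecutive scales by containment or
#' Jaccard dissimilarity, computes 0-dimensional persistent homology of the
#' resulting cluster filtration, and turns each sufficiently persistent
#' connected component into a multiscale domain with a per-spot coreness
#' score. Domains may overlap; the per-spot heterogeneity score (lifetime-
#' weighted sum of normalized coreness over all kept domains) estimates how
#' many persistent domains contain each spot.
#'
#' The containment index suits sweeps whose clusters are largely nested
#' (typical anatomical organization); the Jaccard index applies to any
#' clusterings, e.g. tumor tissue without nested subregions.
#'
#' @param x a [clustering_sequence()] (fine to coarse).
#' @param index `"containment"` (default) or `"jaccard"` filtration.
#' @param min_lifetime report components with persistence lifetime at least
#'   this (default 0).
#' @param min_clusters report components spanning at least this many
#'   clusters (default 2: hides single-cluster components).
#' @param top_k how many domains to keep after ranking by size-weighted
#'   persistence (default 25).
#' @return An object of class `phdms`: list with `sequence`, `filtration`,
#'   `persistence` (full), `kept` (filtered persistence), `domains`
#'   (all kept domains, normalized coreness), `ranked` (top `top_k`),
#'   `heterogeneity` (per-spot), `assignment` (argmax-coreness hard labels
#'   over the ranked domains), `config`, `call`.
#' @seealso [summary.phdms()], [plot.phdms()], [coreness()],
#'   [write_phdms()]
#' @examples
#' h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 7)
#' cs <- degrade_to_clusterings(h, scales_per_level = 2, rho = 0)
#' fit <- phdms(cs, index = "jaccard")
#' summary(fit)
#' @export
phdms <- function(x, index = c("containment", "jaccard"),
                  min_lifetime = 0, min_clusters = 2L, top_k = 25L) {
  stopifnot(inherits(x, "clustering_sequence"))
  index <- match.arg(index)
  filt <- build_overlap_graph(x, index = index)
  pers <- compute_persistence(filt)
  kept <- filter_components(pers, min_lifetime = min_lifetime,
                            min_clusters = min_clusters)
  domains <- lapply(kept$components, function(cp)
    normalize_coreness(compute_coreness(cp, filt)))
  het <- if (length(domains)) heterogeneity_map(domains)
         else numeric(nrow(x$spots))
  ranked <- if (length(domains)) rank_domains(domains, top_k = top_k)
            else list()
  structure(
    list(sequence = x, filtration = filt, persistence = pers, kept = kept,
         domains = domains, ranked = ranked, heterogeneity = het,
         assignment = if (length(ranked)) assign_by_coreness(ranked)
                      else rep(NA_integer_, nrow(x$spots)),
         config = list(index = index, min_lifetime = min_lifetime,
                       min_clusters = min_clusters, top_k = top_k),
         call = match.call()),
    class = "phdms"
  )
}

#' @export
print.phdms <- function(x, ...) {
  cat("Persistent multiscale domains (", x$config$index,
      " filtration)\n", sep = "")
  cat("  spots: ", nrow(x$sequence$spots), ", scales: ",
      x$sequence$n_scales, "\n", sep = "")
  cat("  components: ", nrow(x$persistence$diagram), " total, ",
      length(x$domains), " kept, ", length(x$ranked),
      " reported\n", sep = "")
  invisible(x)
}

#' Summarize a fitted multiscale-domain decomposition
#'
#' @param object a [phdms()] fit.
#' @param ... unused.
#' @return A `summary.phdms` object: the ranked-domain table (id, death,
#'   lifetime, clusters, spots, size-weighted persistence score) plus
#'   heterogeneity quantiles.
#' @export
summary.phdms <- function(object, ...) {
  tab <- data.frame(
    domain = vapply(object$ranked, `[[`, integer(1), "id"),
    death = vapply(object$ranked, `[[`, numeric(1), "death"),
    lifetime = vapply(object$ranked, `[[`, numeric(1), "lifetime"),
    n_spots = vapply(object$ranked, function(d) length(d$support),
                     integer(1)))
  tab$score <- tab$lifetime * tab$n_spots
  structure(list(config = object$config, table = tab,
                 n_components = nrow(object$persistence$diagram),
                 heterogeneity = stats::quantile(object$heterogeneity)),
            class = "summary.phdms")
}

#' @export
print.summary.phdms <- function(x, ...) {
  cat("Persistent multiscale domains (", x$config$index,
      " filtration)\n", sep = "")
  cat("Reported domains (ranked by lifetime x support size):\n")
  print(x$table, row.names = FALSE)
  cat("Heterogeneity quantiles:\n")
  print(round(x$heterogeneity, 3))
  invisible(x)
}

#' Normalized coreness matrix of the reported domains
#'
#' @param object a [phdms()] fit.
#' @param ... unused.
#' @return Spots-by-domains matrix of normalized coreness (see
#'   [domain_matrix()]).
#' @export
coreness <- function(object, ...) UseMethod("coreness")

#' @rdname coreness
#' @export
coreness.phdms <- function(object, ...) {
  if (!length(object$ranked)) stop("fit reports no domains")
  m <- domain_matrix(object$ranked)
  rownames(m) <- object$sequence$spots$spot_id
  m
}

#' Per-spot heterogeneity score of a fit
#' @param object a [phdms()] fit.
#' @param ... unused.
#' @return Named numeric vector, one score per spot.
#' @export
heterogeneity <- function(object, ...) UseMethod("heterogeneity")

#' @rdname heterogeneity
#' @export
heterogeneity.phdms <- function(object, ...) {
  stats::setNames(object$heterogeneity, object$sequence$spots$spot_id)
}

#' Domains covering a tissue location
#'
#' Headless equivalent of point-and-click exploration: find the spot
#' nearest to `(x, y)` and list every reported domain whose support
#' contains it, ordered by the domain's coreness there.
#'
#' @param object a [phdms()] fit.
#' @param x,y query coordinates (tissue units).
#' @return data.frame with `domain`, `coreness`, `lifetime`, plus the
#'   matched `spot_id` as an attribute.
#' @export
domains_at <- function(object, x, y) {
  stopifnot(inherits(object, "phdms"))
  sp <- object$sequence$spots
  i <- which.min((sp$x - x)^2 + (sp$y - y)^2)
  hit <- Filter(function(d) d$normalized[i] > 0, object$ranked)
  out <- data.frame(
    domain = vapply(hit, `[[`, integer(1), "id"),
    coreness = vapply(hit, function(d) d$normalized[i], numeric(1)),
    lifetime = vapply(hit, `[[`, numeric(1), "lifetime"))
  out <- out[order(-out$coreness, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spot_id") <- sp$spot_id[i]
  out
}

#' Write the result bundle of a fit
#'
#' Writes `diagram.csv` (kept components: `component_id`, `birth`,
#' `death`, `lifetime`, `n_clusters`, `n_spots`; infinite deaths printed
#' as `inf`), `coreness.csv` (`spot_id` plus one normalized-coreness
#' column per reported domain), `heterogeneity.csv` (`spot_id`, `h`), and
#' optionally `edges.csv`. Identical fits produce byte-identical files.
#'
#' @param object a [phdms()] fit.
#' @param dir output directory (created if needed).
#' @param edges also dump the filtration edge list.
#' @return `dir`, invisibly.
#' @export
write_phdms <- function(object, dir, edges = FALSE) {
  stopifnot(inherits(object, "phdms"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_diagram(object$kept, file.path(dir, "diagram.csv"))
  cm <- data.frame(spot_id = object$sequence$spots$spot_id,
                   if (length(object$ranked)) domain_matrix(object$ranked)
                   else NULL,
                   check.names = FALSE)
  utils::write.csv(cm, file.path(dir, "coreness.csv"), row.names = FALSE,
                   quote = FALSE)
  hm <- data.frame(spot_id = object$sequence$spots$spot_id,
                   h = object$heterogeneity)
  utils::write.csv(hm, file.path(dir, "heterogeneity.csv"),
                   row.names = FALSE, quote = FALSE)
  if (edges) write_edges(object$filtration, file.path(dir, "edges.csv"))
  invisible(dir)
}
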