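#' Coreness of a persistent component
#'
#' Turns a persistent component into a multiscale domain by scoring every
#' spot: `c_D(x)` is one minus the smallest filtration value of an internal
#' edge whose pair of clusters contains `x`, and 0 for spots touched by no
#' internal edge. Spots with coreness near 1 are the domain's stable core
#' (they join it at low dissimilarity and stay for most of its lifetime);
#' spots near 0 are its unstable frontier. Components with no internal edge
#' (a single cluster) score 1 on that cluster's spots — the limit as overlap
#' information vanishes.
#'
#' @param component one element of `pers$components`.
#' @param filt the [build_overlap_graph()] result the component came from.
#' @return An object of class `multiscale_domain`: list with `id`,
#'   `lifetime`, `death`, `coreness` (length-N vector), `normalized`
#'   (filled by [normalize_coreness()]), `support` (spot indices with
#'   positive coreness).
#' @export
compute_coreness <- function(component, filt) {
  stopifnot(inherits(filt, "cluster_filtration"))
  n <- nrow(filt$spots)
  cs <- numeric(n)
  ie <- component$internal_edges
  if (length(ie) == 0L) {
    cs[unlist(filt$members[component$member_nodes], use.names = FALSE)] <- 1
  } else {
    # ascending weights: first assignment per spot is its minimum
    ie <- ie[order(filt$edges$weight[ie])]
    for (e in ie) {
      sp <- c(filt$members[[filt$edges$source[e]]],
              filt$members[[filt$edges$target[e]]])
      sp <- sp[cs[sp] == 0]
      cs[sp] <- 1 - filt$edges$weight[e]
    }
  }
  structure(
    list(id = component$id, lifetime = component$lifetime,
         death = component$death, coreness = cs, normalized = NULL,
         support = which(cs > 0)),
    class = "multiscale_domain"
  )
}

#' Normalize coreness over a domain's support
#'
#' Affinely rescales coreness over the spots belonging to the domain so the
#' stable core scores exactly 1 and the least stable supported spot scores
#' 0; off-support spots stay at 0. When coreness is constant on the support
#' the whole support scores 1. The min and max are taken over the support
#' only — over all spots the minimum would be 0 whenever the domain is a
#' strict subset of the tissue and the rescaling would be vacuous. The
#' normalized score is the proportion of the domain's lifetime during which
#' the domain contains the spot. Idempotent.
#'
#' @param domain a [compute_coreness()] result.
#' @return The domain with `normalized` filled in.
#' @export
normalize_coreness <- function(domain) {
  stopifnot(inherits(domain, "multiscale_domain"))
  if (length(domain$support) == 0L) stop("domain has empty support")
  cs <- domain$coreness
  rng <- range(cs[domain$support])
  nrm <- numeric(length(cs))
  nrm[domain$support] <-
    if (rng[2] > rng[1]) (cs[domain$support] - rng[1]) / (rng[2] - rng[1])
    else 1
  domain$normalized <- nrm
  domain
}

#' @export
print.multiscale_domain <- function(x, ...) {
  cat("Multiscale domain ", x$id, ": ", length(x$support), " spots, ",
      "lifetime ", format(x$lifetime, digits = 4),
      if (is.infinite(x$death)) " (never dies)" else "", "\n", sep = "")
  invisible(x)
}

#' Heterogeneity map of a set of multiscale domains
#'
#' Per spot, the sum over domains of persistence lifetime times normalized
#' coreness: an estimate of how many distinct persistent domains contain the
#' spot. The score is minimal where a spot sits in the stable core of a
#' single domain and high where it oscillates between several persistent
#' domains, e.g. on mixed tissue frontiers.
#'
#' @param domains non-empty list of normalized [compute_coreness()] domains.
#' @return Numeric vector, one value per spot; bounded above by the sum of
#'   lifetimes.
#' @export
heterogeneity_map <- function(domains) {
  if (length(domains) == 0L) stop("need at least one domain")
  h <- numeric(length(domains[[1]]$coreness))
  for (d in domains) {
    stopifnot(inherits(d, "multiscale_domain"), !is.null(d$normalized))
    h <- h + d$lifetime * d$normalized
  }
  h
}

#' Rank domains by size-weighted persistence
#'
#' Orders domains by persistence lifetime times support size, descending
#' (ties to the smaller component id), and keeps the top `k`. Weighting by
#' size keeps tiny long-lived outlier components from crowding out the
#' domains that describe the tissue.
#'
#' @param domains list of [compute_coreness()] domains.
#' @param top_k number of domains to keep (default 25).
#' @return Reordered, truncated list of domains.
#' @export
rank_domains <- function(domains, top_k = 25L) {
  stopifnot(top_k >= 1)
  score <- vapply(domains, function(d) d$lifetime * length(d$support),
                  numeric(1))
  id <- vapply(domains, `[[`, integer(1), "id")
  domains[order(-score, id)][seq_len(min(top_k, length(domains)))]
}

#' Hard assignment of spots by maximum coreness
#'
#' Assigns each spot to the domain in which its normalized coreness is
#' largest (ties to the earlier domain in the list), the region assignment
#' used to feed downstream per-region analyses. Spots with zero coreness in
#' every domain get `NA`.
#'
#' @param domains list of normalized domains.
#' @return Integer vector of domain ids (one per spot), `NA` where
#'   unassigned.
#' @export
assign_by_coreness <- function(domains) {
  stopifnot(length(domains) >= 1L)
  mat <- vapply(domains, `[[`, numeric(length(domains[[1]]$coreness)),
                "normalized")
  mat <- matrix(mat, ncol = length(domains))
  best <- max.col(mat, ties.method = "first")
  ids <- vapply(domains, `[[`, integer(1), "id")
  out <- ids[best]
  out[rowSums(mat) == 0] <- NA_integer_
  out
}
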