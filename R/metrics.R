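#' Represent a domain as a spatial probability distribution
#'
#' A multiscale domain becomes a distribution over spot coordinates by
#' normalizing its coreness to unit mass; a binary domain (logical mask or
#' spot indices) becomes the uniform distribution on its members. These are
#' the objects the spatial Wasserstein metric compares.
#'
#' @param x a normalized `multiscale_domain`, a logical vector over spots,
#'   or a vector of spot indices.
#' @param spots the [spot_set()] carrying the coordinates.
#' @return An object of class `spatial_distribution`: list with `weights`
#'   (length-N, sums to 1) and `coords` (N x 2 matrix).
#' @export
to_distribution <- function(x, spots) {
  stopifnot(inherits(spots, "spot_set"))
  n <- nrow(spots)
  if (inherits(x, "multiscale_domain")) {
    if (is.null(x$normalized)) x <- normalize_coreness(x)
    w <- x$normalized
  } else if (is.logical(x)) {
    stopifnot(length(x) == n)
    w <- as.numeric(x)
  } else {
    idx <- as.integer(x)
    stopifnot(all(idx >= 1L), all(idx <= n))
    w <- numeric(n)
    w[idx] <- 1
  }
  s <- sum(w)
  if (s <= 0) stop("cannot normalize an all-zero domain to a distribution")
  structure(
    list(weights = w / s, coords = cbind(x = spots$x, y = spots$y)),
    class = "spatial_distribution"
  )
}

#' Exact 2-Wasserstein distance between spatial distributions
#'
#' Minimizes the squared-Euclidean transport cost between two per-spot
#' probability distributions over the same coordinate frame and returns its
#' square root, in the units of the coordinates (microns for micron-scaled
#' input). The optimal coupling is computed exactly by a transportation
#' simplex — no entropic regularization — so reported distances are true
#' metric values: zero iff the distributions coincide, symmetric, and
#' satisfying the triangle inequality.
#'
#' For very large supports the problem is reduced by seeded uniform
#' subsampling: each distribution is replaced by the empirical measure of
#' `max_support` draws from it. The default threshold leaves typical
#' Visium-scale tissues untouched.
#'
#' @param d1,d2 [to_distribution()] objects over the same spot set.
#' @param max_support subsample threshold on the support size (default
#'   5000).
#' @return Non-negative distance in coordinate units.
#' @export
wasserstein2 <- function(d1, d2, max_support = 5000L) {
  stopifnot(inherits(d1, "spatial_distribution"),
            inherits(d2, "spatial_distribution"))
  if (nrow(d1$coords) != nrow(d2$coords) ||
      any(d1$coords != d2$coords))
    stop("distributions must share one coordinate frame")
  if (identical(d1$weights, d2$weights)) return(0)

  s1 <- which(d1$weights > 0)
  s2 <- which(d2$weights > 0)
  a <- d1$weights[s1]; xa <- d1$coords[s1, , drop = FALSE]
  b <- d2$weights[s2]; xb <- d2$coords[s2, , drop = FALSE]
  if (length(s1) > max_support) {
    pick <- sample(length(a), max_support, replace = TRUE, prob = a)
    xa <- xa[pick, , drop = FALSE]
    a <- rep(1 / max_support, max_support)
  }
  if (length(s2) > max_support) {
    pick <- sample(length(b), max_support, replace = TRUE, prob = b)
    xb <- xb[pick, , drop = FALSE]
    b <- rep(1 / max_support, max_support)
  }
  cost <- outer(xa[, 1], xb[, 1], "-")^2 + outer(xa[, 2], xb[, 2], "-")^2
  a <- a / sum(a); b <- b / sum(b)
  if (length(a) == 1L) return(sqrt(sum(b * cost[1, ])))
  if (length(b) == 1L) return(sqrt(sum(a * cost[, 1])))
  sol <- transport_simplex_cpp(a, b, cost)
  sqrt(max(sol$cost, 0))
}

#' Generalized normalized mutual information for multiscale domains
#'
#' Extends NMI to soft, overlapping domains. Each input is a spots-by-
#' domains matrix of coreness scores (a binary partition enters as its
#' one-hot matrix). Rows are normalized to unit sum; spots with zero
#' coreness in every domain of either input carry no membership information
#' and are dropped from both, with the retained spot count as N. Mutual
#' information sums, over domain pairs, the co-membership mass against the
#' product of marginal memberships (natural log, with the `0 ln 0 = 0`
#' convention); normalization is by the arithmetic mean of the Shannon
#' entropies of the two domain-mass profiles. For binary partitions this is
#' exactly classical arithmetic-mean NMI.
#'
#' @param D,E numeric matrices with one row per spot and one column per
#'   domain, entries in `[0, 1]` (see [domain_matrix()] and
#'   [truth_matrix()]).
#' @return NMI value; 0 (with a warning) when both entropies vanish, i.e.
#'   neither input distinguishes any domains.
#' @export
multiscale_nmi <- function(D, E) {
  D <- as.matrix(D); E <- as.matrix(E)
  if (nrow(D) != nrow(E))
    stop("domain matrices must have one row per spot, equal in both")
  keep <- rowSums(D) > 0 & rowSums(E) > 0
  if (!any(keep))
    stop("no spot has positive membership in both inputs")
  D <- D[keep, , drop = FALSE]
  E <- E[keep, , drop = FALSE]
  N <- nrow(D)
  D <- D / rowSums(D)
  E <- E / rowSums(E)
  sD <- colSums(D); sE <- colSums(E)
  Tm <- crossprod(D, E)                    # co-membership mass per pair
  lg <- log(N * Tm) - log(outer(sD, sE))   # log of the ratio, -Inf at 0
  mi <- sum(ifelse(Tm > 0, Tm / N * lg, 0))
  ent <- function(s) { p <- s[s > 0] / N; -sum(p * log(p)) }
  denom <- (ent(sD) + ent(sE)) / 2
  if (denom == 0) {
    warning("both inputs have zero entropy; NMI undefined, returning 0")
    return(0)
  }
  mi / denom
}

#' Spots-by-domains coreness matrix
#'
#' @param domains list of normalized `multiscale_domain` objects.
#' @return Matrix with one row per spot and one column per domain (named
#'   `domain_<id>`) holding normalized coreness.
#' @export
domain_matrix <- function(domains) {
  stopifnot(length(domains) >= 1L)
  m <- vapply(domains, function(d) {
    if (is.null(d$normalized)) d <- normalize_coreness(d)
    d$normalized
  }, numeric(length(domains[[1]]$coreness)))
  m <- matrix(m, ncol = length(domains))
  colnames(m) <- paste0("domain_", vapply(domains, `[[`, integer(1), "id"))
  m
}

#' One-hot matrix of a ground-truth annotation
#'
#' Unassigned spots yield all-zero rows (dropped inside
#' [multiscale_nmi()]).
#' @param truth a [ground_truth()].
#' @return Binary matrix, one row per spot, one column per truth domain.
#' @export
truth_matrix <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  doms <- sort(unique(truth$labels[!is.na(truth$labels)]))
  m <- vapply(doms, function(d) as.numeric(!is.na(truth$labels) &
                                             truth$labels == d),
              numeric(length(truth$labels)))
  m <- matrix(m, ncol = length(doms))
  colnames(m) <- doms
  m
}

#' Match multiscale domains to ground-truth domains by Wasserstein distance
#'
#' For each ground-truth domain (as a uniform spatial distribution), finds
#' the candidate multiscale domain minimizing the exact 2-Wasserstein
#' distance, reporting how closely — in tissue coordinate units — the
#' recovered domains reproduce each annotated region.
#'
#' @param domains non-empty list of normalized `multiscale_domain` objects.
#' @param truth a [ground_truth()] over the same spot set.
#' @param max_support passed to [wasserstein2()].
#' @return data.frame with columns `truth_domain`, `domain_id`, `w2`.
#' @export
match_to_truth <- function(domains, truth, max_support = 5000L) {
  stopifnot(length(domains) >= 1L, inherits(truth, "ground_truth"))
  spots <- truth$spots
  cand <- lapply(domains, to_distribution, spots = spots)
  ids <- vapply(domains, `[[`, integer(1), "id")
  doms <- sort(unique(truth$labels[!is.na(truth$labels)]))
  res <- lapply(doms, function(dl) {
    td <- to_distribution(which(!is.na(truth$labels) & truth$labels == dl),
                          spots)
    w <- vapply(cand, wasserstein2, numeric(1), d2 = td,
                max_support = max_support)
    best <- which.min(w)  # ties to the lower domain id (list order)
    data.frame(truth_domain = dl, domain_id = ids[best], w2 = w[best])
  })
  do.call(rbind, res)
}

#' Greedy NMI-maximizing subset of domains
#'
#' Forward selection of the top-performing subset: starting empty,
#' repeatedly add the domain whose inclusion most increases the generalized
#' NMI against the annotation; stop when no addition improves it or when
#' `max_size` domains are selected. Because spots uncovered by every
#' selected domain are excluded from the NMI, an addition that leaves the
#' NMI unchanged but extends coverage of annotated spots is still accepted
#' (it refines the agreement over a larger tissue fraction); only additions
#' that neither raise the NMI nor extend coverage stop the search.
#'
#' @inheritParams match_to_truth
#' @param max_size largest subset considered.
#' @return List with `domains` (the selected subset, in selection order),
#'   `ids`, and `nmi`.
#' @export
select_best_subset <- function(domains, truth, max_size = length(domains)) {
  stopifnot(length(domains) >= 1L, max_size >= 1)
  E <- truth_matrix(truth)
  full <- domain_matrix(domains)
  annotated <- rowSums(E) > 0
  tol <- 1e-12
  chosen <- integer(0)
  best_nmi <- -Inf
  best_cov <- 0L
  repeat {
    avail <- setdiff(seq_along(domains), chosen)
    if (length(avail) == 0L || length(chosen) >= max_size) break
    trial_nmi <- vapply(avail, function(i) {
      # a candidate disjoint from every annotated spot carries no signal
      tryCatch(
        suppressWarnings(multiscale_nmi(full[, c(chosen, i),
                                             drop = FALSE], E)),
        error = function(e) -Inf)
    }, numeric(1))
    trial_cov <- vapply(avail, function(i) {
      sum(annotated & rowSums(full[, c(chosen, i), drop = FALSE]) > 0)
    }, integer(1))
    pick <- order(-trial_nmi, -trial_cov)[1L]
    improved_nmi <- trial_nmi[pick] > best_nmi + tol
    extended <- trial_nmi[pick] >= best_nmi - tol &&
      trial_cov[pick] > best_cov
    if (!improved_nmi && !extended) break
    chosen <- c(chosen, avail[pick])
    best_nmi <- trial_nmi[pick]
    best_cov <- trial_cov[pick]
  }
  list(domains = domains[chosen],
       ids = vapply(domains[chosen], `[[`, integer(1), "id"),
       nmi = best_nmi)
}

#' Single scale best matching the ground-truth domain count
#'
#' Benchmarking helper for comparing against single-resolution clusterings:
#' picks the scale whose cluster count is closest to the number of
#' annotated domains, ties to the finer scale.
#'
#' @param seq a [clustering_sequence()].
#' @param truth a [ground_truth()].
#' @return Scale index (1 = finest).
#' @export
best_matching_scale <- function(seq, truth) {
  stopifnot(inherits(seq, "clustering_sequence"),
            inherits(truth, "ground_truth"))
  counts <- apply(seq$labels, 2L, max)
  target <- length(unique(truth$labels[!is.na(truth$labels)]))
  unname(which.min(abs(counts - target)))  # which.min: first (finest) on ties
}
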