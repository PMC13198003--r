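toy_infinite_domain <- function(index = "containment") {
  filt <- build_overlap_graph(toy_sequence(), index)
  pers <- compute_persistence(filt)
  inf_i <- which(is.infinite(pers$diagram$death))
  list(domain = compute_coreness(pers$components[[inf_i]], filt),
       filt = filt, pers = pers)
}

test_that("coreness of the toy component is 1 on spots 1-4 and 0.5 on spot 5", {
  d <- toy_infinite_domain()$domain
  expect_equal(d$coreness, c(1, 1, 1, 1, 0.5))
  expect_equal(d$support, 1:5)
})

test_that("spots outside every internal edge get coreness zero", {
  res <- toy_infinite_domain()
  # component that died at 0.5 with a single member cluster A2 = {4,5}
  cp <- res$pers$components[[1]]
  expect_length(cp$internal_edges, 0)
  d <- compute_coreness(cp, res$filt)
  expect_equal(which(d$coreness > 0), 4:5)  # singleton rule: 1 on its spots
  expect_equal(d$coreness[4:5], c(1, 1))
})

test_that("normalization rescales support to [0, 1] and is idempotent", {
  d <- normalize_coreness(toy_infinite_domain()$domain)
  expect_equal(d$normalized, c(1, 1, 1, 1, 0))
  expect_equal(normalize_coreness(d)$normalized, d$normalized)
  # constant coreness on support -> 1 everywhere on support
  d$coreness[] <- c(rep(0.7, 4), 0)
  d$support <- 1:4
  expect_equal(normalize_coreness(d)$normalized, c(1, 1, 1, 1, 0))
})

test_that("coreness is bounded by the component death", {
  set.seed(60)
  sp <- spot_set(paste0("s", 1:60), 1:60, rep(0, 60))
  cs <- clustering_sequence(sp, cbind(random_partition(60, 8),
                                      random_partition(60, 4),
                                      random_partition(60, 2)),
                            resolutions = c(0.9, 0.5, 0.2))
  filt <- build_overlap_graph(cs, "jaccard")
  pers <- compute_persistence(filt)
  for (cp in pers$components) {
    d <- compute_coreness(cp, filt)
    expect_true(all(d$coreness >= 0 & d$coreness <= 1))
    if (length(cp$internal_edges))
      expect_true(all(d$coreness[d$support] >= 1 - min(cp$death, 1) - 1e-12))
  }
})

test_that("heterogeneity is the lifetime-weighted coreness sum", {
  res <- toy_infinite_domain()
  doms <- lapply(res$pers$components, function(cp)
    normalize_coreness(compute_coreness(cp, res$filt)))
  h <- heterogeneity_map(doms)
  # independent per-spot re-summation
  manual <- Reduce(`+`, lapply(doms, function(d) d$lifetime * d$normalized))
  expect_equal(h, manual)
  expect_true(all(h <= sum(vapply(doms, `[[`, numeric(1), "lifetime")) + 1e-12))
  # order invariance
  expect_equal(heterogeneity_map(rev(doms)), h)
})

test_that("single full-support domain gives h = 1 on support, 0 elsewhere", {
  d <- structure(list(id = 1L, lifetime = 1, death = Inf,
                      coreness = c(1, 1, 1, 0, 0),
                      normalized = c(1, 1, 1, 0, 0), support = 1:3),
                 class = "multiscale_domain")
  expect_equal(heterogeneity_map(list(d)), c(1, 1, 1, 0, 0))
})

test_that("domains are ranked by size-weighted persistence with id ties", {
  mk <- function(id, p, ns) structure(
    list(id = id, lifetime = p, death = p, coreness = numeric(ns),
         normalized = numeric(ns), support = seq_len(ns)),
    class = "multiscale_domain")
  doms <- list(mk(1L, 1, 100), mk(2L, 0.9, 50), mk(3L, 1, 10))
  r <- rank_domains(doms, top_k = 3)
  expect_equal(vapply(r, `[[`, integer(1), "id"), c(1L, 2L, 3L))
  expect_length(rank_domains(doms, top_k = 10), 3)
  expect_length(rank_domains(doms, top_k = 2), 2)
  tie <- list(mk(5L, 1, 10), mk(4L, 1, 10))
  expect_equal(vapply(rank_domains(tie, 2), `[[`, integer(1), "id"),
               c(4L, 5L))
})

test_that("argmax-coreness assignment picks the strongest domain per spot", {
  res <- toy_infinite_domain()
  doms <- lapply(res$pers$components, function(cp)
    normalize_coreness(compute_coreness(cp, res$filt)))
  lab <- assign_by_coreness(doms)
  expect_length(lab, 5)
  expect_true(all(!is.na(lab)))
})
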