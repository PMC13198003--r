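onehot <- function(p) {
  ks <- sort(unique(p))
  m <- vapply(ks, function(k) as.numeric(p == k), numeric(length(p)))
  matrix(m, ncol = length(ks))
}

test_that("identical binary partitions give NMI 1, independent ones 0", {
  p <- c(1, 1, 2, 2, 3, 3)
  expect_equal(multiscale_nmi(onehot(p), onehot(p)), 1)
  # N = 4 cross design: MI = 0 exactly
  D <- onehot(c(1, 1, 2, 2))
  E <- onehot(c(1, 2, 1, 2))
  expect_equal(multiscale_nmi(D, E), 0)
})

test_that("generalized NMI reduces to classical NMI on binary partitions", {
  set.seed(80)
  for (rep in 1:40) {
    n <- sample(20:200, 1)
    p <- random_partition(n, sample(2:8, 1))
    q <- random_partition(n, sample(2:8, 1))
    expect_equal(multiscale_nmi(onehot(p), onehot(q)), classic_nmi(p, q),
                 tolerance = 1e-10)
  }
})

test_that("NMI is symmetric and invariant to column order", {
  set.seed(81)
  D <- matrix(runif(60), 20, 3); D[D < 0.4] <- 0
  E <- matrix(runif(40), 20, 2); E[E < 0.4] <- 0
  keep <- rowSums(D) > 0 & rowSums(E) > 0
  D <- D[keep, , drop = FALSE]; E <- E[keep, , drop = FALSE]
  expect_equal(multiscale_nmi(D, E), multiscale_nmi(E, D))
  expect_equal(multiscale_nmi(D[, c(3, 1, 2)], E), multiscale_nmi(D, E))
})

test_that("degenerate single-domain inputs yield NMI 0 with a warning", {
  D <- matrix(1, 10, 1)
  expect_warning(v <- multiscale_nmi(D, D), "entropy")
  expect_equal(v, 0)
})

test_that("all-zero rows are dropped from both matrices", {
  p <- c(1, 1, 2, 2)
  D <- rbind(onehot(p), c(0, 0))      # 5th spot unassigned in D
  E <- rbind(onehot(p), c(1, 0))
  expect_equal(multiscale_nmi(D, E), 1)
  expect_error(multiscale_nmi(matrix(0, 3, 1), matrix(1, 3, 1)),
               "positive membership")
})

test_that("truth matrices are one-hot with zero rows for unassigned spots", {
  sp <- spot_set(paste0("s", 1:4), 1:4, rep(0, 4))
  tr <- ground_truth(sp, c("A", "B", NA, "A"))
  M <- truth_matrix(tr)
  expect_equal(dim(M), c(4L, 2L))
  expect_equal(rowSums(M), c(1, 1, 0, 1))
})

test_that("match_to_truth finds exact copies at distance zero", {
  set.seed(82)
  n <- 50
  sp <- spot_set(paste0("s", 1:n), runif(n, 0, 20), runif(n, 0, 20))
  truth_lab <- rep(c("A", "B"), each = 25)
  tr <- ground_truth(sp, truth_lab)
  mk <- function(id, supp) structure(
    list(id = id, lifetime = 1, death = Inf,
         coreness = as.numeric(seq_len(n) %in% supp),
         normalized = as.numeric(seq_len(n) %in% supp),
         support = supp),
    class = "multiscale_domain")
  doms <- list(mk(1L, 1:25), mk(2L, 26:50), mk(3L, 10:40))
  res <- match_to_truth(doms, tr)
  expect_equal(res$domain_id[res$truth_domain == "A"], 1L)
  expect_equal(res$domain_id[res$truth_domain == "B"], 2L)
  expect_equal(res$w2, c(0, 0))
  # a single candidate matches every truth domain
  one <- match_to_truth(doms[3], tr)
  expect_equal(one$domain_id, c(3L, 3L))
  expect_true(all(one$w2 > 0))
})

test_that("greedy subset selection recovers a perfect candidate set", {
  n <- 60
  sp <- spot_set(paste0("s", 1:n), runif(n, 0, 20), runif(n, 0, 20))
  lab <- rep(c("A", "B", "C"), each = 20)
  tr <- ground_truth(sp, lab)
  mk <- function(id, supp) structure(
    list(id = id, lifetime = 1, death = Inf,
         coreness = as.numeric(seq_len(n) %in% supp),
         normalized = as.numeric(seq_len(n) %in% supp), support = supp),
    class = "multiscale_domain")
  doms <- list(mk(1L, 1:20), mk(2L, 21:40), mk(3L, 41:60))
  sel <- select_best_subset(doms, tr)
  expect_setequal(sel$ids, 1:3)
  expect_equal(sel$nmi, 1)
  # max_size = 1 picks the single best domain; greedy never loses to it
  one <- select_best_subset(doms, tr, max_size = 1)
  expect_length(one$ids, 1)
  expect_gte(sel$nmi, one$nmi)
})

test_that("greedy subset NMI dominates every single domain", {
  set.seed(83)
  for (rep in 1:10) {
    n <- 40
    sp <- spot_set(paste0("s", 1:n), runif(n), runif(n))
    tr <- ground_truth(sp, as.character(random_partition(n, 3)))
    mk <- function(id) {
      supp <- sample(n, sample(5:20, 1))
      structure(list(id = id, lifetime = runif(1), death = 1,
                     coreness = as.numeric(seq_len(n) %in% supp),
                     normalized = as.numeric(seq_len(n) %in% supp),
                     support = supp), class = "multiscale_domain")
    }
    doms <- lapply(1:5, mk)
    sel <- select_best_subset(doms, tr)
    singles <- vapply(doms, function(d)
      tryCatch(suppressWarnings(
        multiscale_nmi(domain_matrix(list(d)), truth_matrix(tr))),
        error = function(e) -Inf), numeric(1))
    expect_gte(sel$nmi, max(singles) - 1e-12)
  }
})

test_that("best_matching_scale picks the closest cluster count, ties finer", {
  sp <- spot_set(paste0("s", 1:24), 1:24, rep(0, 24))
  mk_scale <- function(k) rep(seq_len(k), length.out = 24)
  cs <- suppressWarnings(clustering_sequence(
    sp, cbind(mk_scale(12), mk_scale(9), mk_scale(7), mk_scale(5)),
    resolutions = c(0.9, 0.6, 0.4, 0.2)))
  tr <- ground_truth(sp, as.character(mk_scale(7)))
  expect_equal(best_matching_scale(cs, tr), 3L)
  cs2 <- suppressWarnings(clustering_sequence(
    sp, cbind(mk_scale(8), mk_scale(6)), resolutions = c(0.9, 0.2)))
  expect_equal(best_matching_scale(cs2, tr), 1L)  # tie -> finer scale
})
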