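test_that("planted hierarchies strictly refine across levels", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  expect_equal(max(h$levels[, 1]), 2)
  expect_lte(max(h$levels[, 2]), 4)
  # every fine domain sits inside exactly one coarse domain
  for (child in unique(h$levels[, 2])) {
    parents <- unique(h$levels[h$levels[, 2] == child, 1])
    expect_length(parents, 1)
  }
  # determinism
  h2 <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  expect_identical(h$levels, h2$levels)
  h3 <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 2)
  expect_false(identical(h$levels, h3$levels))
})

test_that("deeper hierarchies stay within the branching bounds", {
  h <- generate_hierarchy(16, n_levels = 3, branching = 3, seed = 4)
  counts <- apply(h$levels, 2L, max)
  expect_lte(counts[1], 3)
  expect_lte(counts[2], 9)
  expect_lte(counts[3], 27)
  expect_true(all(diff(counts) >= 0))
  expect_error(generate_hierarchy(4, 2, 2), "grid_side")
})

test_that("frontier spots are a strict subset and hug the boundaries", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  expect_gt(sum(h$frontier), 0)
  expect_lt(sum(h$frontier), nrow(h$spots))
  # every frontier spot has a neighbor with a different label at some level
  gs <- h$params$grid_side
  for (i in which(h$frontier)[1:10]) {
    nb <- which(abs(h$spots$x - h$spots$x[i]) <= 1.5 &
                  abs(h$spots$y - h$spots$y[i]) <= 1.5)
    nb <- setdiff(nb, i)
    expect_true(any(h$levels[nb, 1] != h$levels[i, 1] |
                      h$levels[nb, 2] != h$levels[i, 2]))
  }
})

test_that("noise-free degradation yields perfectly nested clusterings", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  cs <- degrade_to_clusterings(h, scales_per_level = 2, rho = 0)
  expect_equal(cs$n_scales, 4)
  # containment weights between consecutive scales are exactly 0 (nested)
  filt <- build_overlap_graph(cs, "containment")
  expect_true(all(filt$edges$weight == 0))
})

test_that("noise-free Jaccard weights equal the size-ratio closed form", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  cs <- degrade_to_clusterings(h, scales_per_level = 1, rho = 0)
  filt <- build_overlap_graph(cs, "jaccard")
  # every child -> parent edge weighs 1 - |child| / |parent|
  for (e in seq_len(nrow(filt$edges))) {
    a <- filt$nodes$size[filt$edges$source[e]]
    b <- filt$nodes$size[filt$edges$target[e]]
    expect_equal(filt$edges$weight[e], 1 - a / b)
  }
})

test_that("noise redraws independently per scale and per seed", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  c1 <- degrade_to_clusterings(h, 2, rho = 0.2, seed = 1)
  c2 <- degrade_to_clusterings(h, 2, rho = 0.2, seed = 2)
  expect_false(identical(c1$labels, c2$labels))
  expect_identical(degrade_to_clusterings(h, 2, rho = 0.2, seed = 1)$labels,
                   c1$labels)
  # the two observations of the same level differ at frontiers only
  diff_spots <- which(c1$labels[, 1] != c1$labels[, 2])
  expect_gt(length(diff_spots), 0)
  expect_true(all(h$frontier[diff_spots]))
  expect_error(degrade_to_clusterings(h, 2, rho = 0.7), "rho")
})

test_that("planted domains enumerate every level", {
  h <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 1)
  pd <- planted_domains(h)
  expect_equal(sum(lengths(pd[grep("^L1", names(pd))])), 256)
  expect_equal(sum(lengths(pd[grep("^L2", names(pd))])), 256)
  tr <- truth_from_hierarchy(h, level = 1)
  expect_equal(length(unique(tr$labels)), max(h$levels[, 1]))
})
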