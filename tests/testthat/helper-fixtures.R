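# Shared fixtures and independent oracles, built in code.

# the 5-spot, 2-scale worked example:
# scale 1 {A1 = {1,2,3}, A2 = {4,5}}, scale 2 {B1 = {1,2,3,4}, B2 = {5}}
toy_sequence <- function() {
  sp <- spot_set(paste0("s", 1:5), x = 1:5, y = rep(0, 5))
  clustering_sequence(sp, cbind(c(1, 1, 1, 2, 2), c(1, 1, 1, 1, 2)),
                      resolutions = c(0.9, 0.2))
}

random_partition <- function(n, k) sample(seq_len(k), n, replace = TRUE)

# classical arithmetic-mean NMI from the contingency table (independent of
# the package's soft-membership route)
classic_nmi <- function(p, q) {
  tab <- table(p, q)
  N <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / N * log(N * tab[i, j] / (a[i] * b[j]))
  ent <- function(s) { p <- s[s > 0] / N; -sum(p * log(p)) }
  d <- (ent(a) + ent(b)) / 2
  if (d == 0) 0 else unname(mi / d)
}

# brute-force minimum-cost transport via boot::simplex (dense LP on vec(P))
lp_transport_cost <- function(a, b, C) {
  m <- length(a); n <- length(b)
  rows <- t(sapply(seq_len(m), function(i)
    as.numeric(rep(seq_len(m), n) == i)))
  cols <- t(sapply(seq_len(n), function(j)
    as.numeric(rep(seq_len(n), each = m) == j)))
  A3 <- rbind(rows, cols)[-1, , drop = FALSE]  # one constraint is redundant
  unname(boot::simplex(a = as.vector(C), A3 = A3, b3 = c(a, b)[-1],
                       maxi = FALSE)$value)
}

# connected components of the subgraph with edge weight <= t (brute force)
components_at <- function(n_nodes, edges, t) {
  keep <- edges$weight <= t
  g <- igraph::graph_from_edgelist(
    cbind(edges$source[keep], edges$target[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  igraph::count_components(g)
}

random_filtration_graph <- function(max_nodes = 30L, max_edges = 60L) {
  n <- sample(2:max_nodes, 1)
  ne <- sample(1:max_edges, 1)
  edges <- data.frame(source = sample(n, ne, replace = TRUE),
                      target = sample(n, ne, replace = TRUE),
                      weight = runif(ne))
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  edges <- edges[order(edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  list(n = n, edges = edges)
}
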