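# Independent oracles and small in-code fixtures shared across tests.

# brute-force upper-tail hypergeometric probability by direct summation
brute_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# draw a random valid contingency table (N <= nmax)
random_table <- function(nmax = 200) {
  N <- sample(5:nmax, 1)
  K <- sample(1:(N - 1), 1)
  n <- sample(1:(N - 1), 1)
  k <- sample(max(0, K + n - N):min(K, n), 1)
  list(k = k, K = K, n = n, N = N)
}

# quick network builder from an edge data.frame
toy_network <- function(gene_a, gene_b, weight = 1) {
  df <- data.frame(gene_a = gene_a, gene_b = gene_b, weight = weight,
                   stringsAsFactors = FALSE)
  xgrkit:::new_network(xgrkit:::canonical_edges(df), "custom")
}

# random connected graph on n nodes: random spanning tree + extra edges
random_connected_graph <- function(n, p_extra = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n))
  a <- integer(0); b <- integer(0)
  for (i in 2:n) { a <- c(a, sample(i - 1, 1)); b <- c(b, i) }
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- runif(nrow(extra)) < p_extra
  a <- c(a, extra[pick, 1]); b <- c(b, extra[pick, 2])
  toy_network(nodes[a], nodes[b])
}

# exhaustive PCST optimum: max prize sum over the empty set and all
# connected node subsets (bitmask BFS connectivity, independent of igraph)
brute_pcst_opt <- function(net, prizes) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  ia <- match(net$edges$gene_a, nodes)
  ib <- match(net$edges$gene_b, nodes)
  adj[cbind(ia, ib)] <- TRUE
  adj[cbind(ib, ia)] <- TRUE
  pr <- prizes[nodes]
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) > 1) {
      seen <- members[1]
      repeat {
        nb <- members[members %in% which(apply(adj[seen, , drop = FALSE], 2, any))]
        nb <- setdiff(nb, seen)
        if (length(nb) == 0) break
        seen <- c(seen, nb)
      }
      if (length(seen) < length(members)) next
    }
    best <- max(best, sum(pr[members]))
  }
  best
}

# reachability oracle for annotation propagation: genes of all DAG
# descendants (via repeated edge joins, independent of the topo-sort route)
brute_propagated <- function(direct, dag, term) {
  desc <- term
  repeat {
    more <- dag$child[dag$parent %in% desc]
    new <- setdiff(more, desc)
    if (length(new) == 0) break
    desc <- c(desc, new)
  }
  sort(unique(unlist(direct[desc], use.names = FALSE)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

expect_tree <- function(sub, net) {
  expect_true(all(sub$nodes %in% net$nodes))
  if (length(sub$nodes) >= 1) {
    expect_identical(nrow(sub$edges), length(sub$nodes) - 1L)
    if (length(sub$nodes) > 1) {
      g <- igraph::graph_from_data_frame(sub$edges[, 1:2], directed = FALSE,
                                         vertices = sub$nodes)
      expect_true(igraph::is_connected(g))
    }
  }
}
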