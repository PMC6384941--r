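# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own implementation paths.

library(igraph)

# random simple graph with n nodes (named letters/numbers), edge prob p
random_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, sample_gnp(n, p))
  V(g)$name <- paste0("n", seq_len(n))
  g
}

# brute-force modularity: explicit double loop over node pairs, with optional
# belonging coefficients (crisp partitions are covers with all b = 1)
bruteforce_modularity <- function(g, membership_list) {
  nodes <- V(g)$name
  A <- as.matrix(as_adjacency_matrix(simplify(g)))
  k <- rowSums(A)
  m <- sum(A) / 2
  labs <- unique(unlist(lapply(membership_list, names)))
  q <- 0
  for (cc in labs) {
    b <- vapply(nodes, function(v) {
      mm <- membership_list[[v]]
      if (cc %in% names(mm)) mm[[cc]] else 0
    }, numeric(1))
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        q <- q + (A[i, j] - k[i] * k[j] / (2 * m)) * b[i] * b[j]
      }
    }
  }
  unname(q) / (2 * m)
}

crisp_to_membership <- function(part) {
  lapply(stats::setNames(as.character(part), names(part)),
         function(l) stats::setNames(1, l))
}

# brute-force betweenness: per source BFS layering plus explicit path-count
# dynamic program, accumulated pairwise
bruteforce_betweenness <- function(g) {
  g <- simplify(g)
  n <- vcount(g)
  adj <- lapply(seq_len(n), function(i) as.integer(neighbors(g, i)))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    order_v <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_v <- c(order_v, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (v in rev(order_v)) {
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] + 1) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  stats::setNames(bc / 2, V(g)$name)
}

# exhaustive sample-based rarefaction: average observed richness over all
# C(N, n) sample subsets
enumerate_rarefaction <- function(mat, n) {
  N <- ncol(mat)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(cols)
    sum(rowSums(mat[, cols, drop = FALSE]) > 0)))
}

# incidence matrix with prescribed per-taxon incidence counts Y over N samples
incidence_from_counts <- function(Y, N, seed = 1) {
  withr::with_seed(seed, {
    mat <- t(vapply(Y, function(y) {
      row <- integer(N)
      row[sample.int(N, y)] <- 1L
      row
    }, integer(N)))
  })
  rownames(mat) <- paste0("t", seq_along(Y))
  colnames(mat) <- paste0("s", seq_len(N))
  structure(mat, class = c("incidence_matrix", "matrix", "array"),
            sample_unit = "collection_point")
}

# small occurrence data frame builder
occ_df <- function(taxon, point, formation = paste0("F_", point), ...) {
  data.frame(taxon = taxon, collection_id = point, formation = formation,
             stringsAsFactors = FALSE, ...)
}

# planted 4-block unipartite network
planted_block_network <- function(n_per_block = 10, k = 4, p_in = 0.5,
                                  p_out = 0.03, seed = 1) {
  g <- withr::with_seed(seed, sample_sbm(
    n_per_block * k,
    pref.matrix = matrix(p_out, k, k) + diag(p_in - p_out, k),
    block.sizes = rep(n_per_block, k)))
  V(g)$name <- paste0("v", seq_len(vcount(g)))
  V(g)$block <- rep(seq_len(k), each = n_per_block)
  g
}

# degree map helper used to assert degree preservation
degree_map <- function(g) sort(degree(simplify(g))[order(V(g)$name)])
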