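# Newman-Girvan modularity for crisp partitions and its extension to
# overlapping covers via belonging coefficients.

# membership matrix (nodes x communities) for a cover, aligned to `nodes`
cover_matrix <- function(cover, nodes) {
  miss <- setdiff(nodes, names(cover$membership))
  if (length(miss)) stop("cover does not assign node(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  mm <- cover$membership[nodes]
  labs <- sort(unique(unlist(lapply(mm, names))))
  i <- rep(seq_along(nodes), lengths(mm))
  j <- match(unlist(lapply(mm, names)), labs)
  Matrix::sparseMatrix(i = i, j = j, x = unlist(mm, use.names = FALSE),
                       dims = c(length(nodes), length(labs)),
                       dimnames = list(nodes, labs))
}

#' Modularity of a crisp partition
#'
#' Newman-Girvan modularity `Q = sum_c [ L_c/m - (d_c/(2m))^2 ]`, where `L_c`
#' is the number of intra-community links and `d_c` the total degree of
#' community `c`. Self-loops and multi-edges are removed before evaluation.
#'
#' @param net An `igraph` network.
#' @param part Named character vector (node -> community label) or a crisp
#'   `copra_cover`.
#' @return The modularity score.
#' @export
crisp_modularity <- function(net, part) {
  part <- as_partition(part)
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  nodes <- V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(vcount(g)))
  miss <- setdiff(nodes, names(part))
  if (length(miss)) stop("partition does not cover node(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  m <- ecount(g)
  if (m == 0L) stop("modularity undefined: network has no links")
  lab <- part[nodes]
  el <- as_edgelist(g, names = TRUE)
  intra <- lab[el[, 1]] == lab[el[, 2]]
  deg <- degree(g)
  dc <- tapply(deg[nodes], lab, sum)
  unname(sum(intra) / m - sum((dc / (2 * m))^2))
}

#' Extended (overlap) modularity of a cover
#'
#' Generalizes crisp modularity to overlapping covers: each node pair's
#' contribution within a community is weighted by the product of the two
#' endpoints' belonging coefficients,
#' `Q_ov = (1/2m) sum_c sum_ij (A_ij - k_i k_j / 2m) b_ic b_jc`.
#' For a crisp cover (all coefficients 1) this reduces exactly to
#' [crisp_modularity()].
#'
#' @param net An `igraph` network.
#' @param cover A `copra_cover` over the network's nodes.
#' @return The extended modularity score.
#' @export
extended_modularity <- function(net, cover) {
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  nodes <- V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(vcount(g)))
  m <- ecount(g)
  if (m == 0L) stop("modularity undefined: network has no links")
  B <- cover_matrix(cover, nodes)
  A <- as_adjacency_matrix(g, sparse = TRUE)
  k <- Matrix::rowSums(A)
  term_links <- sum(B * (A %*% B)) / (2 * m)
  term_null <- sum(as.numeric(Matrix::crossprod(B, k))^2) / (4 * m^2)
  term_links - term_null
}
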