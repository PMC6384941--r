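# Statistical validation of community structure: degree-preserving
# randomization (P, Z on modularity) and link-subsampling sensitivity
# analysis scored by normalized mutual information.

#' Degree-preserving network randomization
#'
#' Rewires a simple network by double-edge swaps, preserving every node's
#' degree exactly. For bipartite networks the swap orientation preserves both
#' node classes, so projections keep their degree sequences too. Attempts
#' `swap_factor * m` successful swaps; if no swap is achievable (the degree
#' sequence admits only the input graph) the input is returned with a
#' warning.
#'
#' @param net A simple `igraph` network.
#' @param seed Integer seed.
#' @param swap_factor Successful swaps per link (default 10).
#' @return A randomized `igraph` network with identical degree map.
#' @export
randomize_network <- function(net, seed = 1L, swap_factor = 10L) {
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  nodes <- V(g)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(vcount(g)))
    V(g)$name <- nodes
  }
  el <- as_edgelist(g, names = FALSE)
  m <- nrow(el)
  if (m < 2L) {
    warning("too few links to rewire; returning input")
    return(net)
  }
  bip <- is_bipartite_network(net)
  if (bip) {
    # orient every edge class1 -> class2
    cls1 <- V(g)$node_class == graph_attr(net, "fossil_classes")[1L]
    flip <- !cls1[el[, 1L]]
    el[flip, ] <- el[flip, c(2L, 1L)]
  }
  edge_key <- function(a, b) {
    if (bip) paste(a, b) else paste(pmin(a, b), pmax(a, b))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(m)) seen[[edge_key(el[r, 1L], el[r, 2L])]] <- TRUE

  target <- swap_factor * m
  max_attempts <- 100L * target
  done <- 0L
  with_seed(seed, {
    attempts <- 0L
    while (done < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      pick <- sample.int(m, 2L)
      a <- el[pick[1L], ]; b <- el[pick[2L], ]
      # propose (a1-b2), (b1-a2)
      n1 <- c(a[1L], b[2L]); n2 <- c(b[1L], a[2L])
      if (!bip && (n1[1L] == n1[2L] || n2[1L] == n2[2L])) next
      k1 <- edge_key(n1[1L], n1[2L]); k2 <- edge_key(n2[1L], n2[2L])
      if (!is.null(seen[[k1]]) || !is.null(seen[[k2]]) || k1 == k2) next
      rm(list = c(edge_key(a[1L], a[2L]), edge_key(b[1L], b[2L])), envir = seen)
      seen[[k1]] <- TRUE; seen[[k2]] <- TRUE
      el[pick[1L], ] <- n1
      el[pick[2L], ] <- n2
      done <- done + 1L
    }
    invisible(NULL)
  })
  if (done == 0L) {
    warning("degree sequence admits no rewiring; returning input")
    return(net)
  }
  g2 <- graph_from_edgelist(el, directed = FALSE)
  # carry over vertices (incl. any isolated ones) and their attributes
  if (vcount(g2) < vcount(g)) g2 <- add_vertices(g2, vcount(g) - vcount(g2))
  for (at in vertex_attr_names(g)) {
    vertex_attr(g2, at) <- vertex_attr(g, at)
  }
  V(g2)$name <- nodes
  if (bip) {
    as_fossil_network(g2, bipartite = TRUE,
                      classes = graph_attr(net, "fossil_classes"))
  } else {
    as_fossil_network(g2, bipartite = FALSE)
  }
}

#' Randomization test of community-structure modularity
#'
#' Compares the observed best-of-restarts modularity against `reps`
#' degree-preserving randomizations, each partitioned with the same `v` and
#' restart budget. For bipartite networks one null distribution is produced
#' per one-mode projection. The one-sided `P` is the fraction of null scores
#' greater than or equal to the observed score (ties count as exceeding);
#' `Z = (observed - mean(null)) / sd(null)`.
#'
#' @param net An `igraph` network.
#' @param v Maximum communities per node for COPRA.
#' @param reps Number of randomizations.
#' @param restarts COPRA restarts per partitioning.
#' @param seed Master seed.
#' @return A `null_modularity_result`: `observed_q`, `null_q` (matrix
#'   reps x projections), `P`, `Z`, `reps`, and the significance verdicts at
#'   alpha 0.10 / 0.05 / 0.01.
#' @export
modularity_significance <- function(net, v, reps = 100L, restarts = 100L,
                                    seed = 1L) {
  obs_cover <- copra_best(net, v = v, restarts = restarts, seed = seed)
  bip <- is_bipartite_network(net)
  obs <- if (bip) projection_modularity(net, obs_cover) else
    c(network = extended_modularity(net, obs_cover))
  null_q <- matrix(NA_real_, nrow = reps, ncol = length(obs),
                   dimnames = list(NULL, names(obs)))
  for (r in seq_len(reps)) {
    rnd <- randomize_network(net, seed = derive_seed(seed, 2L * r))
    cov_r <- copra_best(rnd, v = v, restarts = restarts,
                        seed = derive_seed(seed, 2L * r + 1L))
    null_q[r, ] <- if (bip) projection_modularity(rnd, cov_r) else
      extended_modularity(rnd, cov_r)
  }
  P <- colMeans(sweep(null_q, 2L, obs, ">=") * 1)
  sds <- apply(null_q, 2L, stats::sd)
  if (any(sds == 0)) warning("null distribution has zero variance; Z undefined")
  Z <- ifelse(sds > 0, (obs - colMeans(null_q)) / sds, NA_real_)
  structure(
    list(observed_q = obs, null_q = null_q, P = P, Z = Z, reps = reps,
         significant = sapply(c(`0.10` = 0.10, `0.05` = 0.05, `0.01` = 0.01),
                              function(a) all(P <= a)),
         cover = obs_cover),
    class = "null_modularity_result"
  )
}

#' @export
print.null_modularity_result <- function(x, ...) {
  cat("<null_modularity_result>", x$reps, "randomizations\n")
  for (i in seq_along(x$observed_q)) {
    cat(sprintf("  %s: Q = %.4f, P = %.3f, Z = %.3f\n",
                names(x$observed_q)[i], x$observed_q[i], x$P[i], x$Z[i]))
  }
  invisible(x)
}

# round-half-up, documented convention for link counts
round_half_up <- function(x) floor(x + 0.5)

#' Randomly subsample links
#'
#' Retains `round(fraction * m)` links chosen uniformly (half-up rounding).
#' Nodes left without any retained link are omitted from the subnetwork and
#' reported.
#'
#' @param net An `igraph` network.
#' @param fraction Fraction of links to retain, in (0, 1].
#' @param seed Integer seed.
#' @return List with `subnet` and `omitted_nodes` (character vector).
#' @export
subsample_links <- function(net, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- ecount(net)
  keep_n <- round_half_up(fraction * m)
  if (keep_n < 1L) stop("input error: zero links retained")
  keep <- with_seed(seed, sample.int(m, keep_n))
  sub <- subgraph_from_edges(net, E(net)[keep], delete.vertices = FALSE)
  omitted <- V(sub)$name[degree(sub) == 0]
  sub <- delete_vertices(sub, which(degree(sub) == 0))
  list(subnet = sub, omitted_nodes = omitted)
}

# entropy (nats) of a count vector
count_entropy <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' Shannon NMI with sum normalization `2 I / (H_a + H_b)` by default (`"max"`
#' and `"sqrt"` normalizations are available). Nodes of `universe` missing
#' from a partition are added to it as singleton communities before scoring,
#' the convention used when comparing a subnetwork partition with a full
#' network partition. Two trivial partitions (a single identical cluster)
#' score 1.
#'
#' @param a,b Named character vectors (node -> community label) or crisp
#'   `copra_cover` objects.
#' @param universe Node set over which to compare; defaults to the union of
#'   the two partitions' nodes.
#' @param normalization `"sum"`, `"max"`, or `"sqrt"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b, universe = NULL,
                normalization = c("sum", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  a <- as_partition(a)
  b <- as_partition(b)
  if (is.null(universe)) universe <- union(names(a), names(b))
  complete <- function(p, tag) {
    miss <- setdiff(universe, names(p))
    if (length(miss)) {
      p <- c(p, stats::setNames(paste0(".", tag, ".singleton.", miss), miss))
    }
    p[universe]
  }
  a <- complete(a, "a")
  b <- complete(b, "b")
  tab <- table(a, b)
  n <- sum(tab)
  Ha <- count_entropy(rowSums(tab))
  Hb <- count_entropy(colSums(tab))
  p_ij <- tab / n
  p_i <- rowSums(tab) / n
  p_j <- colSums(tab) / n
  nz <- p_ij > 0
  I <- sum(p_ij[nz] * log(p_ij[nz] / outer(p_i, p_j)[nz]))
  denom <- switch(normalization,
                  sum = (Ha + Hb) / 2,
                  max = max(Ha, Hb),
                  sqrt = sqrt(Ha * Hb))
  if (denom == 0) return(1)  # both partitions trivial over the same set
  max(0, min(1, I / denom))
}

#' Link-subsampling sensitivity analysis
#'
#' Measures how stable the best crisp partition is under random link loss.
#' At each sampling level, links are subsampled `reps` times; the subnetwork
#' is partitioned (`v = 1`) and compared to the reference partition by NMI,
#' with omitted nodes treated as their own modules. A matched null NMI is
#' produced per repetition from a pair of degree-preserving randomizations of
#' the network and the subnetwork, partitioned identically. A level is judged
#' `robust` when at least 95% of observed NMI scores exceed their matched
#' null scores (one-sided test).
#'
#' @param net An `igraph` network.
#' @param levels Fractions of links to retain.
#' @param reps Repetitions per level.
#' @param restarts COPRA restarts per partitioning.
#' @param seed Master seed.
#' @return A `sensitivity_profile`: per level, NMI scores, omitted-node
#'   counts, null NMI scores, and a verdict (`"robust"` / `"not_robust"` /
#'   `"error"`).
#' @export
sensitivity_profile <- function(net, levels = c(1.0, 0.95, 0.9, 0.8, 0.7),
                                reps = 100L, restarts = 100L, seed = 1L) {
  ref <- as_partition(copra_best(net, v = 1L, restarts = restarts, seed = seed))
  universe <- V(net)$name
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (li in seq_along(levels)) {
    lev <- levels[li]
    nmis <- numeric(reps); omitted <- integer(reps); null_nmis <- numeric(reps)
    err <- NULL
    for (r in seq_len(reps)) {
      s_base <- derive_seed(seed, li * 100000L + r * 10L)
      res <- tryCatch({
        ss <- subsample_links(net, lev, seed = s_base)
        part_sub <- as_partition(
          copra_best(ss$subnet, v = 1L, restarts = restarts,
                     seed = derive_seed(s_base, 1L)))
        obs <- nmi(ref, part_sub, universe = universe)
        rnd_full <- suppressWarnings(
          randomize_network(net, seed = derive_seed(s_base, 2L)))
        rnd_sub <- suppressWarnings(
          randomize_network(ss$subnet, seed = derive_seed(s_base, 3L)))
        p1 <- as_partition(copra_best(rnd_full, v = 1L, restarts = restarts,
                                      seed = derive_seed(s_base, 4L)))
        p2 <- as_partition(copra_best(rnd_sub, v = 1L, restarts = restarts,
                                      seed = derive_seed(s_base, 5L)))
        list(nmi = obs, omitted = length(ss$omitted_nodes),
             null = nmi(p1, p2, universe = universe))
      }, error = function(e) e)
      if (inherits(res, "error")) { err <- conditionMessage(res); break }
      nmis[r] <- res$nmi; omitted[r] <- res$omitted; null_nmis[r] <- res$null
    }
    out[[li]] <- if (is.null(err)) {
      list(level = lev, nmi = nmis, omitted_nodes = omitted,
           null_nmi = null_nmis,
           verdict = if (mean(nmis > null_nmis) >= 0.95) "robust"
                     else "not_robust")
    } else {
      list(level = lev, error = err, verdict = "error")
    }
  }
  structure(list(levels = out, reference = ref), class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat("<sensitivity_profile>\n")
  for (lv in x$levels) {
    if (identical(lv$verdict, "error")) {
      cat(sprintf("  level %.2f: error (%s)\n", lv$level, lv$error))
    } else {
      cat(sprintf("  level %.2f: median NMI %.3f, null %.3f, %s\n",
                  lv$level, stats::median(lv$nmi), stats::median(lv$null_nmi),
                  lv$verdict))
    }
  }
  invisible(x)
}
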