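# Overlapping community detection by label propagation with belonging
# coefficients (COPRA), plus the leave-one-out procedure used to choose the
# maximum number of communities per node (v).

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-restart seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

new_cover <- function(membership, v, singletons = character(0)) {
  structure(list(membership = membership, v = v, singletons = singletons),
            class = "copra_cover")
}

#' Communities of a cover
#'
#' @param cover A `copra_cover`.
#' @return Named list: community label -> character vector of member nodes.
#' @export
cover_communities <- function(cover) {
  labs <- unique(unlist(lapply(cover$membership, names)))
  comms <- lapply(labs, function(l) {
    names(cover$membership)[vapply(cover$membership,
                                   function(mm) l %in% names(mm), logical(1))]
  })
  stats::setNames(comms, labs)
}

#' Crisp a cover into a partition
#'
#' Assigns each node to its maximum-belonging community (ties broken by
#' lexicographically smallest label, for determinism).
#'
#' @param cover A `copra_cover` (a named membership vector is passed through).
#' @return Named character vector: node -> community label.
#' @export
as_partition <- function(cover) {
  if (is.atomic(cover) && !is.null(names(cover))) {
    return(stats::setNames(as.character(cover), names(cover)))
  }
  stopifnot(inherits(cover, "copra_cover"))
  out <- vapply(cover$membership, function(mm) {
    cand <- names(mm)[mm >= max(mm) - 1e-12]
    sort(cand)[1L]
  }, character(1))
  stats::setNames(out, names(cover$membership))
}

#' Validate the belonging-coefficient invariants of a cover
#'
#' @param cover A `copra_cover`.
#' @param v Optional maximum label count per node to enforce.
#' @return `cover`, invisibly; stops on violation.
#' @export
validate_cover <- function(cover, v = cover$v) {
  sums <- vapply(cover$membership, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-9)) stop("belonging coefficients do not sum to 1")
  if (!is.null(v) && any(lengths(cover$membership) > v)) {
    stop("node carries more than v labels")
  }
  invisible(cover)
}

# group sums over a sorted key vector: returns sums per run of equal keys
# plus the index of each run's first element
sorted_group_sums <- function(keys, vals) {
  nb <- length(keys)
  firsts <- c(TRUE, keys[-1L] != keys[-nb])
  ends <- which(c(firsts[-1L], TRUE))
  cs <- cumsum(vals)
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  list(firsts = firsts, sums = sums)
}

# one propagation half-sweep over the triplet state (bi, bj, bx; sorted by
# bi): rows in the update set are replaced by the thresholded, renormalized
# average of their neighbors' label maps; other rows pass through. Runs on
# plain vectors (no matrix objects) for speed.
copra_half_sweep <- function(state, eu, ev, upd_mask, deg, n, v, L) {
  bi <- state$bi; bj <- state$bj; bx <- state$bx
  cnt <- tabulate(bi, n)
  start <- cumsum(c(1L, cnt))[seq_len(n)]
  sizes <- cnt[ev]
  pos <- sizes > 0L
  rows_exp <- rep.int(eu[pos], sizes[pos])
  idx <- sequence(sizes[pos], from = start[ev[pos]])
  cols <- bj[idx]
  vals <- bx[idx]
  key <- (as.numeric(rows_exp) - 1) * L + cols
  o <- order(key)
  gs <- sorted_group_sums(key[o], vals[o])
  r2 <- rows_exp[o][gs$firsts]
  c2 <- cols[o][gs$firsts]
  x2 <- gs$sums / deg[r2]

  thr <- 1 / v
  tol <- 1e-12
  keep <- x2 >= thr - tol
  # rows whose every label fell below threshold keep one maximal label
  # (uniform random among ties)
  o3 <- order(r2, -x2)
  fr <- !duplicated(r2[o3])
  rowmax <- numeric(n)
  rowmax[r2[o3][fr]] <- x2[o3][fr]
  kept_rows <- unique.default(r2[keep])
  empty <- setdiff(unique.default(r2), kept_rows)
  if (length(empty)) {
    cand <- which(x2 >= rowmax[r2] - tol & (r2 %in% empty))
    cand <- cand[sample.int(length(cand))]
    sel <- cand[!duplicated(r2[cand])]
    keep[sel] <- TRUE
  }
  r3 <- r2[keep]; c3 <- c2[keep]; x3 <- x2[keep]
  # renormalize updated rows (r3 is sorted)
  gs3 <- sorted_group_sums(r3, x3)
  rowtot <- numeric(n)
  rowtot[r3[gs3$firsts]] <- gs3$sums
  x3 <- x3 / rowtot[r3]
  # merge with untouched rows and restore bi ordering
  untq <- !upd_mask[bi]
  bi <- c(bi[untq], r3); bj <- c(bj[untq], c3); bx <- c(bx[untq], x3)
  o4 <- order(bi)
  list(bi = bi[o4], bj = bj[o4], bx = bx[o4])
}

# one full propagation sweep: synchronous for unipartite networks; for
# bipartite networks the two node classes update in alternating half-sweeps
# (one class from the other's previous labels, then the reverse), which
# avoids the two-phase oscillation of fully synchronous updates on bipartite
# structure. Returns the compacted state, surviving labels, and per-label
# node counts.
copra_step <- function(state, edges, deg, n, v, lab, check = FALSE) {
  L <- length(lab)
  for (h in seq_along(edges)) {
    e <- edges[[h]]
    state <- copra_half_sweep(state, e$eu, e$ev, e$upd_mask, deg, n, v, L)
  }
  keepc <- sort(unique.default(state$bj))
  if (length(keepc) < L) {
    map <- integer(L)
    map[keepc] <- seq_along(keepc)
    state$bj <- map[state$bj]
    lab <- lab[keepc]
    L <- length(keepc)
  }
  if (check) {
    s <- rowsum(state$bx, state$bi)
    if (any(abs(s - 1) > 1e-9)) stop("invariant violated: row sums != 1")
    if (any(tabulate(state$bi, nbins = n) > v)) {
      stop("invariant violated: > v labels")
    }
  }
  counts <- stats::setNames(tabulate(state$bj, L), lab)
  list(state = state, lab = lab, counts = counts)
}

#' Overlapping label propagation (single run)
#'
#' Synchronous label propagation with belonging coefficients. Every node
#' starts with its own label (coefficient 1); at each step a node's label map
#' becomes the average of its neighbors' maps, labels with coefficient below
#' `1/v` are deleted (if all fall below, one maximum-coefficient label is
#' retained, ties broken at random), and the remainder renormalized.
#' Propagation stops when the sorted vector of per-label minimum membership
#' counts repeats a previously seen value, or after `max_iters` sweeps (with a
#' warning). Isolated nodes become singleton communities, reported in the
#' `singletons` field. Communities wholly contained in others are removed
#' (extra-simplification) unless `simplify_cover = FALSE`.
#'
#' @param net An `igraph` network.
#' @param v Maximum number of communities per node (`v = 1` gives a crisp
#'   partition).
#' @param seed Integer seed for the run's random tie-breaks.
#' @param max_iters Safety cap on propagation sweeps.
#' @param simplify_cover Apply [extra_simplify()] to the result.
#' @param check_invariants Assert the coefficient invariants after every
#'   sweep (used by tests).
#' @return A `copra_cover`: `membership` (node -> named coefficient vector),
#'   `v`, and `singletons`.
#' @export
copra_run <- function(net, v = 1L, seed = 1L, max_iters = 1000L,
                      simplify_cover = TRUE, check_invariants = FALSE) {
  if (v < 1L) stop("v must be >= 1")
  g <- simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  if (vcount(g) == 0L) stop("empty network")
  nodes <- V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(vcount(g)))
  deg <- degree(g)
  iso <- which(deg == 0)
  act <- which(deg > 0)
  singles <- nodes[iso]

  membership <- list()
  if (length(act)) {
    gs <- induced_subgraph(g, act)
    n <- length(act)
    lab <- nodes[act]
    degs <- degree(gs)
    el <- as_edgelist(gs, names = FALSE)
    eu <- c(el[, 1L], el[, 2L])
    ev <- c(el[, 2L], el[, 1L])
    o <- order(eu)
    eu <- eu[o]; ev <- ev[o]
    edges <- if (is_bipartite_network(net)) {
      side1 <- V(net)$node_class[act] == graph_attr(net, "fossil_classes")[1L]
      m1 <- side1; m2 <- !side1
      e1 <- side1[eu]
      list(list(eu = eu[e1], ev = ev[e1], upd_mask = m1),
           list(eu = eu[!e1], ev = ev[!e1], upd_mask = m2))
    } else {
      list(list(eu = eu, ev = ev, upd_mask = rep(TRUE, n)))
    }
    state <- list(bi = seq_len(n), bj = seq_len(n), bx = rep(1, n))
    membership <- with_seed(seed, {
      seen <- new.env(hash = TRUE, parent = emptyenv())
      mincnt <- NULL
      converged <- FALSE
      for (iter in seq_len(max_iters)) {
        st <- copra_step(state, edges, degs, n, v, lab,
                         check = check_invariants)
        state <- st$state
        lab <- st$lab
        cur <- st$counts
        if (is.null(mincnt)) {
          mincnt <- cur
        } else {
          common <- intersect(names(mincnt), names(cur))
          mincnt <- pmin(mincnt[common], cur[common])
        }
        key <- paste(sort(unname(mincnt)), collapse = ",")
        if (!is.null(seen[[key]])) { converged <- TRUE; break }
        seen[[key]] <- TRUE
      }
      if (!converged) warning("copra_run: max_iters reached before convergence")
      mm <- split(stats::setNames(state$bx, lab[state$bj]), state$bi)
      stats::setNames(mm, nodes[act][as.integer(names(mm))])
    })
  }
  for (s in singles) membership[[s]] <- stats::setNames(1, s)
  cover <- new_cover(membership[order(match(names(membership), nodes))], v,
                     singletons = singles)
  if (simplify_cover) cover <- extra_simplify(cover)
  cover
}

#' Remove communities contained within others
#'
#' Deletes any community whose node set is a subset of (or equal to) another
#' community's node set, then renormalizes each node's remaining belonging
#' coefficients. Of two communities with identical node sets, the
#' lexicographically smallest label survives.
#'
#' @param cover A `copra_cover`.
#' @return The simplified `copra_cover`.
#' @export
extra_simplify <- function(cover) {
  comms <- cover_communities(cover)
  if (length(comms) <= 1L) return(cover)
  labs <- names(comms)[order(-lengths(comms), names(comms))]
  comms <- comms[labs]
  sizes <- lengths(comms)
  drop <- logical(length(comms))
  for (a in seq_along(comms)) {
    if (drop[a]) next
    for (b in seq_along(comms)) {
      if (a == b || drop[b]) next
      if (sizes[b] <= sizes[a] && all(comms[[b]] %in% comms[[a]])) {
        drop[b] <- TRUE
      }
    }
  }
  keep <- names(comms)[!drop]
  membership <- lapply(cover$membership, function(mm) {
    mm <- mm[names(mm) %in% keep]
    mm / sum(mm)
  })
  new_cover(membership, cover$v, cover$singletons)
}

#' Best-of-restarts COPRA
#'
#' Runs [copra_run()] with seeds derived from `seed` and returns the cover
#' maximizing extended modularity (for bipartite networks, the mean of the
#' two one-mode projection scores). Ties go to the earliest restart.
#'
#' @param net An `igraph` network.
#' @param v Maximum communities per node.
#' @param restarts Number of independent runs.
#' @param seed Master seed for the restart stream.
#' @param ... Passed to [copra_run()].
#' @return The best `copra_cover`, with attributes `q` (its score) and
#'   `q_values` (the full score distribution over restarts).
#' @export
copra_best <- function(net, v = 1L, restarts = 100L, seed = 1L, ...) {
  if (restarts < 1L) stop("restarts must be >= 1")
  projs <- if (is_bipartite_network(net)) network_projections(net) else NULL
  best <- NULL
  best_q <- -Inf
  qs <- numeric(restarts)
  for (r in seq_len(restarts)) {
    cov <- copra_run(net, v = v, seed = derive_seed(seed, r), ...)
    q <- if (is.null(projs)) extended_modularity(net, cov)
         else mean(projection_modularity(net, cov, projections = projs))
    qs[r] <- q
    if (q > best_q + 1e-12) {
      best <- cov
      best_q <- q
    }
  }
  attr(best, "q") <- best_q
  attr(best, "q_values") <- qs
  best
}

# modularity score used to rank covers: extended modularity on the network
# itself, or the mean over one-mode projections for bipartite networks
cover_score <- function(net, cover) {
  if (is_bipartite_network(net)) {
    mean(projection_modularity(net, cover))
  } else {
    extended_modularity(net, cover)
  }
}

# both one-mode projections of a bipartite network, by node class
network_projections <- function(net) {
  classes <- graph_attr(net, "fossil_classes")
  stats::setNames(lapply(classes, function(cl)
    one_mode_projection(net, cl)), classes)
}

#' Extended modularity of a cover on each one-mode projection
#'
#' For a bipartite network partitioned as a whole, evaluates the extended
#' modularity of the induced cover on each one-mode projection.
#'
#' @param net A bipartite `igraph` network.
#' @param cover A `copra_cover` on the bipartite node set.
#' @param projections Optional precomputed projections (internal reuse).
#' @return Named numeric vector, one score per node class.
#' @export
projection_modularity <- function(net, cover,
                                  projections = network_projections(net)) {
  vapply(projections, function(proj) {
    sub <- cover$membership[intersect(V(proj)$name, names(cover$membership))]
    extended_modularity(proj, new_cover(sub, cover$v))
  }, numeric(1))
}

#' Choose v by leave-one-out jackknife
#'
#' For each node in turn: remove it, partition the remaining network with
#' crisp label propagation (`v = 1`), and record the number of non-singleton
#' communities. The selected `v` is the maximum count over all leave-one-out
#' runs.
#'
#' @param net An `igraph` network with at least 3 nodes.
#' @param seed Master seed.
#' @param restarts_per_leave Restarts for each leave-one-out partition.
#' @return List with `v` and `distribution` (one count per node, named).
#' @export
select_v <- function(net, seed = 1L, restarts_per_leave = 3L) {
  if (vcount(net) < 3L) stop("network must have at least 3 nodes")
  nodes <- V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(vcount(net)))
  ns <- vapply(seq_along(nodes), function(i) {
    sub <- delete_vertices(net, i)
    cov <- if (restarts_per_leave == 1L) {
      # single run: no ranking needed, skip modularity scoring
      copra_run(sub, v = 1L, seed = derive_seed(derive_seed(seed, i), 1L))
    } else {
      copra_best(sub, v = 1L, restarts = restarts_per_leave,
                 seed = derive_seed(seed, i))
    }
    sum(lengths(cover_communities(cov)) >= 2L)
  }, numeric(1))
  list(v = as.integer(max(ns)),
       distribution = stats::setNames(as.integer(ns), nodes))
}

#' Serialize a cover to JSON
#'
#' @param cover A `copra_cover`.
#' @param path Output path (`node -> {label: coefficient}` object).
#' @return `path`, invisibly.
#' @export
write_cover <- function(cover, path) {
  jsonlite::write_json(lapply(cover$membership, as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.copra_cover <- function(x, ...) {
  comms <- cover_communities(x)
  cat("<copra_cover> v =", x$v, "|", length(comms), "communities over",
      length(x$membership), "nodes\n")
  sizes <- sort(lengths(comms), decreasing = TRUE)
  cat("  sizes:", paste(utils::head(sizes, 12), collapse = ", "),
      if (length(sizes) > 12) "..." else "", "\n")
  if (length(x$singletons)) cat("  isolated singletons:",
                                length(x$singletons), "\n")
  invisible(x)
}
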