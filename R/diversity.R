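# Biozone diversity comparison: taxonomic dissimilarity and clustering,
# sample-based rarefaction/extrapolation, and nonparametric richness
# estimators for incidence data.

#' Pairwise taxonomic dissimilarity between samples
#'
#' Binary (presence/absence) dissimilarities between the samples (columns) of
#' an incidence matrix. With shared-taxon count `a` and unique counts `b`,
#' `c`: Jaccard is `1 - a/(a+b+c)`; Kulczynski-2 is
#' `1 - (a/(a+b) + a/(a+c))/2`.
#'
#' @param inc An `incidence_matrix` (taxa rows, sample columns).
#' @param index `"kulczynski2"` or `"jaccard"`.
#' @return A `dissimilarity_matrix`: symmetric matrix in `[0, 1]` with zero
#'   diagonal and an `index` attribute. Pairs involving a sample with no taxa
#'   are `NA` with a warning.
#' @export
pairwise_dissimilarity <- function(inc, index = c("kulczynski2", "jaccard")) {
  index <- match.arg(index)
  m <- unclass(inc)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (any(colSums(m) == 0)) {
    warning("sample(s) with zero taxa: dissimilarities undefined for those pairs")
  }
  method <- if (index == "jaccard") "jaccard" else "kulczynski"
  d <- suppressWarnings(
    vegan::vegdist(t(m), method = method, binary = TRUE))
  dm <- as.matrix(d)
  diag(dm) <- 0
  structure(dm, class = c("dissimilarity_matrix", "matrix", "array"),
            index = index)
}

#' Average-linkage (UPGMA) clustering
#'
#' Iteratively merges the closest pair of clusters, with inter-cluster
#' distance the unweighted average of member pairwise dissimilarities.
#' Samples are ordered by label before clustering so merge ties resolve
#' deterministically.
#'
#' @param D A `dissimilarity_matrix`.
#' @return An `hclust` tree (heights are average-linkage dissimilarities).
#' @export
upgma <- function(D) {
  dm <- unclass(D)
  if (anyNA(dm)) stop("dissimilarity matrix contains undefined pairs")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  stats::hclust(stats::as.dist(dm), method = "average")
}

#' Cophenetic correlation
#'
#' Pearson correlation between the observed pairwise dissimilarities and the
#' cophenetic distances implied by a dendrogram (the merge height of each
#' pair's smallest containing cluster).
#'
#' @param D A `dissimilarity_matrix`.
#' @param tree An `hclust` tree over the same labels (computed from `D` when
#'   omitted).
#' @return The correlation coefficient.
#' @export
cophenetic_correlation <- function(D, tree = upgma(D)) {
  dm <- unclass(D)
  if (nrow(dm) < 3L) stop("cophenetic correlation undefined for < 3 labels")
  coph <- as.matrix(stats::cophenetic(tree))
  labs <- tree$labels
  obs <- stats::as.dist(dm[labs, labs])
  stats::cor(as.numeric(obs), as.numeric(stats::as.dist(coph[labs, labs])))
}

# clades (sets of leaf labels per internal node) of an hclust tree
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[k]] <- sort(c(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L])))
  }
  members
}

#' Bootstrap support for dendrogram clades
#'
#' Resamples taxa (rows) with replacement, reclusters the samples, and scores
#' each internal node of the original tree by the proportion of bootstrap
#' trees in which its exact leaf set reappears as a clade. Samples that lose
#' all taxa in a resample are placed at maximal dissimilarity (1) from all
#' others for that replicate.
#'
#' @param inc An `incidence_matrix`.
#' @param index Dissimilarity index, as in [pairwise_dissimilarity()].
#' @param reps Bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `tree` (the original `hclust`), `clades` (leaf sets) and
#'   `support` (proportion per internal node).
#' @export
bootstrap_support <- function(inc, index = "kulczynski2", reps = 1000L,
                              seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  m <- unclass(inc)
  D0 <- pairwise_dissimilarity(inc, index)
  hc0 <- upgma(D0)
  clades <- hclust_clades(hc0)
  hits <- integer(length(clades))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      mb <- m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE]
      empty <- colSums(mb) == 0
      Db <- suppressWarnings(pairwise_dissimilarity(
        structure(mb, class = class(inc),
                  sample_unit = attr(inc, "sample_unit")), index))
      dmb <- unclass(Db)
      dmb[empty, ] <- 1; dmb[, empty] <- 1; diag(dmb) <- 0
      hcb <- upgma(structure(dmb, class = class(Db), index = index))
      cb <- hclust_clades(hcb)
      keys <- vapply(cb, paste, character(1), collapse = "\r")
      hit <- vapply(clades, function(cl)
        paste(cl, collapse = "\r") %in% keys, logical(1))
      hits <- hits + hit
    }
  })
  list(tree = hc0, clades = clades, support = hits / reps)
}

# log-scale "species absent from all n chosen samples" probability:
# alpha_i = C(N - Y_i, n) / C(N, n)
alpha_absent <- function(Y, N, n) {
  ifelse(N - Y < n, 0, exp(lchoose(N - Y, n) - lchoose(N, n)))
}

# classic Chao2 point estimate (bias-corrected form when Q2 = 0), used both
# as a richness estimator and as the assemblage-size term of the
# unconditional rarefaction variance
chao2_estimate <- function(S_obs, Q1, Q2, N) {
  A <- (N - 1) / N
  if (Q2 > 0) S_obs + A * Q1^2 / (2 * Q2)
  else S_obs + A * Q1 * (Q1 - 1) / 2
}

#' Sample-based rarefaction
#'
#' Expected richness when `n` of the `N` reference samples are drawn at
#' random without replacement:
#' `S(n) = S_obs - sum_i C(N - Y_i, n) / C(N, n)`. The unconditional
#' variance follows the moment estimator
#' `var(n) = sum_i (1 - alpha_i)^2 - S(n)^2 / S_est`, with `S_est` the Chao2
#' estimate of total richness; it does not vanish at `n = N`, so the 95%
#' normal confidence interval remains informative at full sampling.
#'
#' @param inc An `incidence_matrix`.
#' @param n Number of samples, `1 <= n <= N` (vectorized).
#' @return Data frame with columns `n`, `S`, `variance`, `lower`, `upper`,
#'   `ci_type = "unconditional"`.
#' @export
rarefy_incidence <- function(inc, n) {
  st <- incidence_stats(inc)
  if (any(n < 1 | n > st$N)) stop("n out of range 1..N")
  S_est <- chao2_estimate(st$S_obs, st$Q[1], if (st$N >= 2) st$Q[2] else 0,
                          st$N)
  rows <- lapply(n, function(h) {
    a <- alpha_absent(st$Y, st$N, h)
    S <- st$S_obs - sum(a)
    v <- sum((1 - a)^2) - S^2 / S_est
    v <- max(v, 0)
    data.frame(n = h, S = S, variance = v,
               lower = max(S - 1.96 * sqrt(v), 0),
               upper = S + 1.96 * sqrt(v),
               ci_type = "unconditional", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extrapolated richness beyond the reference sampling
#'
#' Chao2-based extrapolation to `N + m` samples:
#' `S(N + m) = S_obs + Q0 * (1 - (1 - Q1 / (Q1 + N * Q0))^m)`, where `Q0` is
#' the Chao2 estimate of undetected richness (bias-corrected when `Q2 = 0`).
#' With `Q1 = 0` the curve is flat at `S_obs`. The 95% CI is derived from a
#' taxon-resampling bootstrap of the whole extrapolation.
#'
#' @param inc An `incidence_matrix`.
#' @param m Additional samples, `>= 1` (vectorized).
#' @param ci_reps Bootstrap replicates for the CI (0 disables).
#' @param seed Seed for the CI bootstrap.
#' @return Data frame as in [rarefy_incidence()].
#' @export
extrapolate_incidence <- function(inc, m, ci_reps = 200L, seed = 1L) {
  st <- incidence_stats(inc)
  if (any(m < 1)) stop("m must be >= 1")
  point <- function(S_obs, Q1, Q2, N, m) {
    Q0 <- chao2_estimate(S_obs, Q1, Q2, N) - S_obs
    if (Q1 == 0 || Q0 <= 0) return(rep(S_obs, length(m)))
    S_obs + Q0 * (1 - (1 - Q1 / (Q1 + N * Q0))^m)
  }
  S <- point(st$S_obs, st$Q[1], if (st$N >= 2) st$Q[2] else 0, st$N, m)
  v <- rep(NA_real_, length(m))
  if (ci_reps > 0) {
    mat <- unclass(inc)
    boot <- with_seed(seed, {
      replicate(ci_reps, {
        mb <- mat[sample.int(nrow(mat), nrow(mat), replace = TRUE), ,
                  drop = FALSE]
        sb <- incidence_stats(structure(mb, class = class(inc)))
        point(sb$S_obs, sb$Q[1], if (sb$N >= 2) sb$Q[2] else 0, sb$N, m)
      })
    })
    boot <- matrix(boot, nrow = length(m))
    v <- apply(boot, 1L, stats::var)
  }
  data.frame(n = st$N + m, S = S, variance = v,
             lower = pmax(S - 1.96 * sqrt(v), 0),
             upper = S + 1.96 * sqrt(v),
             ci_type = "unconditional", stringsAsFactors = FALSE)
}

#' Rarefaction/extrapolation curve
#'
#' Convenience wrapper combining [rarefy_incidence()] over `1..N` and
#' [extrapolate_incidence()] out to `extrapolate_to` samples.
#'
#' @param inc An `incidence_matrix`.
#' @param extrapolate_to Total sampling intensity to extrapolate to
#'   (`<= N` disables extrapolation).
#' @param ... Passed to [extrapolate_incidence()].
#' @return A `rarefaction_curve`: data frame with an added `type` column
#'   (`interpolated` / `extrapolated`) and attributes `N`, `S_obs`.
#' @export
rarefaction_curve <- function(inc, extrapolate_to = 0L, ...) {
  st <- incidence_stats(inc)
  curve <- rarefy_incidence(inc, seq_len(st$N))
  curve$type <- "interpolated"
  if (extrapolate_to > st$N) {
    ext <- extrapolate_incidence(inc, seq_len(extrapolate_to - st$N), ...)
    ext$type <- "extrapolated"
    curve <- rbind(curve, ext)
  }
  structure(curve, class = c("rarefaction_curve", "data.frame"),
            N = st$N, S_obs = st$S_obs)
}

# ICE: incidence-based coverage estimator with infrequent threshold
ice_estimate <- function(mat, threshold = 10L) {
  Y <- rowSums(mat > 0)
  Y <- Y[Y > 0]
  infreq <- Y[Y <= threshold]
  S_freq <- sum(Y > threshold)
  S_inf <- length(infreq)
  if (S_inf == 0L) return(S_freq)
  Q1 <- sum(infreq == 1L)
  N_inf <- sum(infreq)
  if (N_inf == Q1) return(NA_real_)  # coverage zero: undefined
  C_ice <- 1 - Q1 / N_inf
  # number of samples holding at least one infrequent taxon
  inf_taxa <- names(Y)[Y <= threshold]
  m_inf <- sum(colSums(mat[rownames(mat) %in% inf_taxa, , drop = FALSE]) > 0)
  if (m_inf < 2L) return(NA_real_)
  Qj <- tabulate(infreq, nbins = threshold)
  j <- seq_len(threshold)
  gamma2 <- max(
    (S_inf / C_ice) * (m_inf / (m_inf - 1)) * sum(j * (j - 1) * Qj) /
      N_inf^2 - 1, 0)
  S_freq + S_inf / C_ice + (Q1 / C_ice) * gamma2
}

#' Nonparametric richness estimators for incidence data
#'
#' Computes the classic Chao2, first- and second-order jackknife, bootstrap,
#' and incidence-based coverage (ICE, infrequent threshold 10) estimators:
#' \itemize{
#'   \item chao2: `S_obs + ((N-1)/N) Q1^2 / (2 Q2)` (bias-corrected
#'     `Q1(Q1-1)/2 * (N-1)/N` when `Q2 = 0`), with the classic analytic
#'     variance;
#'   \item jackknife1: `S_obs + Q1 (N-1)/N`;
#'   \item jackknife2: `S_obs + Q1 (2N-3)/N - Q2 (N-2)^2 / (N (N-1))`;
#'   \item bootstrap: `S_obs + sum_i (1 - Y_i/N)^N`.
#' }
#'
#' @param inc An `incidence_matrix`.
#' @param ice_threshold Incidence count at or below which a taxon counts as
#'   infrequent for ICE.
#' @return Data frame with columns `estimator`, `estimate`, `variance`
#'   (`NA` where no analytic form is provided), `lower`, `upper`.
#' @export
richness_estimators <- function(inc, ice_threshold = 10L) {
  st <- incidence_stats(inc)
  if (st$N < 2L) stop("need at least 2 samples")
  S <- st$S_obs; N <- st$N; Y <- st$Y
  Q1 <- st$Q[1]; Q2 <- st$Q[2]
  A <- (N - 1) / N

  chao2 <- chao2_estimate(S, Q1, Q2, N)
  # classic Chao2 variance (undefined pieces give NA)
  chao2_var <- if (Q2 > 0) {
    r <- Q1 / Q2
    Q2 * (A * r^2 / 2 + A^2 * r^3 + A^2 * r^4 / 4)
  } else if (Q1 > 1) {
    A * Q1 * (Q1 - 1) / 2 + A^2 * Q1 * (2 * Q1 - 1)^2 / 4 -
      A^2 * Q1^4 / (4 * chao2)
  } else NA_real_

  jack1 <- S + Q1 * A
  jack2 <- S + Q1 * (2 * N - 3) / N - Q2 * (N - 2)^2 / (N * (N - 1))
  boot <- S + sum((1 - Y / N)^N)
  ice <- ice_estimate(unclass(inc), ice_threshold)

  out <- data.frame(
    estimator = c("chao2", "ice", "jackknife1", "jackknife2", "bootstrap"),
    estimate = c(chao2, ice, jack1, jack2, boot),
    variance = c(chao2_var, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  out$lower <- ifelse(is.na(out$variance), NA,
                      pmax(out$estimate - 1.96 * sqrt(out$variance), S))
  out$upper <- ifelse(is.na(out$variance), NA,
                      out$estimate + 1.96 * sqrt(out$variance))
  out
}

#' Richness-estimator curves vs sampling intensity
#'
#' Randomly subsamples `n = 1..N` samples without replacement, `reps` times
#' per intensity, recomputes each estimator, and reports the mean curve with
#' conditional 95% CIs (empirical quantiles of the iterated distribution,
#' which collapse to a point at `n = N`). For Chao2 an unconditional CI from
#' its analytic variance is also reported.
#'
#' @param inc An `incidence_matrix`.
#' @param reps Subsampling repetitions per intensity.
#' @param seed Integer seed.
#' @param estimators Subset of estimator names to compute.
#' @return Data frame: `n`, `estimator`, `mean`, `cond_lower`, `cond_upper`,
#'   `uncond_lower`, `uncond_upper` (Chao2 only).
#' @export
estimator_curves <- function(inc, reps = 100L, seed = 1L,
                             estimators = c("chao2", "ice", "jackknife1",
                                            "jackknife2", "bootstrap")) {
  if (reps < 1L) stop("reps must be >= 1")
  mat <- unclass(inc)
  N <- ncol(mat)
  rows <- list()
  with_seed(seed, {
    for (n in seq_len(N)) {
      nrep <- if (n == N) 1L else reps
      vals <- matrix(NA_real_, nrow = nrep, ncol = length(estimators),
                     dimnames = list(NULL, estimators))
      uvar <- numeric(nrep)
      for (r in seq_len(nrep)) {
        sub <- mat[, sample.int(N, n), drop = FALSE]
        sub <- sub[rowSums(sub) > 0, , drop = FALSE]
        if (n < 2L || nrow(sub) == 0L) next
        est <- richness_estimators(
          structure(sub, class = class(inc),
                    sample_unit = attr(inc, "sample_unit")))
        vals[r, ] <- est$estimate[match(estimators, est$estimator)]
        uvar[r] <- est$variance[est$estimator == "chao2"]
      }
      for (e in estimators) {
        v <- vals[, e]
        if (all(is.na(v))) next
        qs <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        row <- data.frame(n = n, estimator = e, mean = mean(v, na.rm = TRUE),
                          cond_lower = qs[1], cond_upper = qs[2],
                          uncond_lower = NA_real_, uncond_upper = NA_real_,
                          stringsAsFactors = FALSE)
        if (e == "chao2" && any(!is.na(uvar))) {
          se <- sqrt(mean(uvar, na.rm = TRUE))
          row$uncond_lower <- row$mean - 1.96 * se
          row$uncond_upper <- row$mean + 1.96 * se
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  })
  do.call(rbind, rows)
}

#' Compare two biozones by rarefaction curves
#'
#' Tests the null hypothesis of equal richness: at the current sampling level
#' of the less-sampled biozone, non-overlapping unconditional 95% CIs reject
#' the null. Touching intervals count as overlap.
#'
#' @param a,b `rarefaction_curve` objects for the two biozones.
#' @return List with `verdict` (`"significantly_different"` /
#'   `"not_distinguishable"`), the comparison level `n`, per-curve `S` and CI
#'   bounds, and `richness_ratio` (larger / smaller expected richness at the
#'   matched intensity).
#' @export
compare_biozones <- function(a, b) {
  n_star <- min(attr(a, "N"), attr(b, "N"))
  ra <- a[a$n == n_star & a$type == "interpolated", ]
  rb <- b[b$n == n_star & b$type == "interpolated", ]
  if (nrow(ra) != 1L || nrow(rb) != 1L) {
    stop("curves do not both cover the comparison level n = ", n_star)
  }
  overlap <- ra$lower <= rb$upper && rb$lower <= ra$upper
  list(
    verdict = if (overlap) "not_distinguishable" else "significantly_different",
    n = n_star,
    S = c(a = ra$S, b = rb$S),
    ci = rbind(a = c(ra$lower, ra$upper), b = c(rb$lower, rb$upper)),
    richness_ratio = max(ra$S, rb$S) / min(ra$S, rb$S)
  )
}

#' Export a dendrogram as Newick
#'
#' @param tree An `hclust` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
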