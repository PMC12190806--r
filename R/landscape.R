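#' Scale effectiveness points onto the unit-square landscape
#'
#' Min-max scales the quantity (x) and quality (y) components of a set of
#' effectiveness points to `[0, 1]`, the common window in which the
#' spatial-pattern statistics are computed. Scaling both axes to equal
#' units is required for Euclidean nearest-neighbour distances between
#' points to be meaningful; the original values and axis ranges are kept
#' so the transform is invertible.
#'
#' @param points an [effectiveness_points()] table (typically one morph).
#' @return object of class `"landscape"`: data.frame `group`, `morph`,
#'   `x`, `y`, `qtc`, `qlc` plus attributes `xrange`, `yrange` and the
#'   unit-square `window`.
#' @export
build_landscape <- function(points) {
  stopifnot(inherits(points, "effectiveness_points"))
  if (nrow(points) < 3) stop_bad("need at least 3 effectiveness points")
  xr <- range(points$qtc)
  yr <- range(points$qlc)
  if (diff(xr) == 0 || diff(yr) == 0)
    stop_bad("degenerate axis: all points share the same %s",
             if (diff(xr) == 0) "quantity" else "quality")
  out <- data.frame(group = points$group, morph = points$morph,
                    x = (points$qtc - xr[1]) / diff(xr),
                    y = (points$qlc - yr[1]) / diff(yr),
                    qtc = points$qtc, qlc = points$qlc,
                    stringsAsFactors = FALSE)
  structure(out, xrange = xr, yrange = yr, window = c(0, 1, 0, 1),
            class = c("landscape", "data.frame"))
}

landscape_xy <- function(x) {
  if (inherits(x, "landscape")) cbind(x$x, x$y)
  else as.matrix(x)
}

nn_dist <- function(xy) {
  dm <- as.matrix(stats::dist(xy))
  diag(dm) <- Inf
  apply(dm, 1, min)
}

runif_window <- function(n, window)
  cbind(stats::runif(n, window[1], window[2]),
        stats::runif(n, window[3], window[4]))

mc_pvalue <- function(obs, sims) {
  n <- length(sims)
  p_lo <- (1 + sum(sims <= obs)) / (1 + n)
  p_hi <- (1 + sum(sims >= obs)) / (1 + n)
  min(1, 2 * min(p_lo, p_hi))
}

#' Clark-Evans nearest-neighbour index with Donnelly edge correction
#'
#' The ratio of the mean observed nearest-neighbour distance to its
#' expectation under complete spatial randomness (CSR) in the window.
#' `R < 1` indicates clumping, `R > 1` regularity. The Donnelly correction
#' inflates the CSR expectation for edge effects in a bounded window:
#' \deqn{E[d] = 0.5\sqrt{A/n} + (0.0514 + 0.041/\sqrt{n})\,P/n}
#' with `A` the window area and `P` its perimeter. Significance is
#' assessed by a two-sided Monte Carlo test against `n_mc` CSR patterns of
#' the same size in the same window.
#'
#' @param x a `"landscape"` object or an n x 2 coordinate matrix.
#' @param window rectangle `c(xmin, xmax, ymin, ymax)`; default unit
#'   square.
#' @param correction `"donnelly"` (default) or `"none"`.
#' @param n_mc CSR simulations for the p-value.
#' @param seed RNG seed for the simulations.
#' @return list of class `"spatial_test"`: `statistic` (R), `p`,
#'   `expected`, `n`, `n_mc`, `seed`, `method`.
#' @export
clark_evans <- function(x, window = c(0, 1, 0, 1),
                        correction = c("donnelly", "none"),
                        n_mc = 1000, seed = NULL) {
  correction <- match.arg(correction)
  xy <- landscape_xy(x)
  n <- nrow(xy)
  if (n < 3) stop_bad("need at least 3 points")
  area <- (window[2] - window[1]) * (window[4] - window[3])
  perim <- 2 * ((window[2] - window[1]) + (window[4] - window[3]))
  expd <- 0.5 * sqrt(area / n) +
    if (correction == "donnelly") (0.0514 + 0.041 / sqrt(n)) * perim / n else 0
  stat_fun <- function(pts) mean(nn_dist(pts)) / expd
  obs <- stat_fun(xy)
  if (!is.null(seed)) set.seed(seed)
  sims <- vapply(seq_len(n_mc), function(i) stat_fun(runif_window(n, window)),
                 numeric(1))
  structure(list(statistic = obs, p = mc_pvalue(obs, sims), expected = expd,
                 n = n, n_mc = n_mc, seed = seed,
                 method = paste0("Clark-Evans R (", correction, ")")),
            class = "spatial_test")
}

#' Hopkins-Skellam clustering index
#'
#' Compares squared nearest-neighbour distances among the events
#' (\eqn{\sum_i d_{ee,i}^2}) with squared distances from `m` random
#' sampling origins to their nearest event (\eqn{\sum_j d_{oe,j}^2}),
#' reported on the bounded scale
#' \deqn{A = \frac{2\sum_i d_{ee,i}^2}{\sum_i d_{ee,i}^2 + \sum_j d_{oe,j}^2},}
#' i.e. twice the complement of the classical Hopkins fraction. Under CSR
#' the fraction is Beta-distributed with mean 1/2, so `A` is centred on 1;
#' clustered patterns shrink the event-to-event distances and give
#' `A < 1` (0 in the limit of coincident points), regular patterns push it
#' toward 2. The bounded form avoids the upward small-sample bias of the
#' raw sum ratio. Because the origins are resampled identically in the
#' null simulations, the Monte Carlo test is calibrated regardless of the
#' scale chosen.
#'
#' One further small-sample symmetrisation: an event's nearest neighbour
#' is found among the other `n - 1` events, so each origin's distance is
#' likewise measured to the nearest of `n - 1` events (one event dropped
#' at random per origin), making the two distance sets share a common
#' null distribution.
#'
#' @inheritParams clark_evans
#' @param m number of random sampling origins (default `n`).
#' @return list of class `"spatial_test"`.
#' @export
hopkins_skellam <- function(x, window = c(0, 1, 0, 1), m = NULL,
                            n_mc = 1000, seed = NULL) {
  xy <- landscape_xy(x)
  n <- nrow(xy)
  if (n < 3) stop_bad("need at least 3 points")
  if (is.null(m)) m <- n
  stat_fun <- function(pts) {
    k <- nrow(pts)
    origins <- runif_window(m, window)
    cross <- sqrt(outer(origins[, 1], pts[, 1], "-")^2 +
                  outer(origins[, 2], pts[, 2], "-")^2)
    # drop one random event per origin: n - 1 candidates on both sides
    cross[cbind(seq_len(m), sample.int(k, m, replace = TRUE))] <- Inf
    dee <- sum(nn_dist(pts)^2)
    doe <- sum(apply(cross, 1, min)^2)
    2 * dee / (dee + doe)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- stat_fun(xy)
  sims <- vapply(seq_len(n_mc), function(i) stat_fun(runif_window(n, window)),
                 numeric(1))
  structure(list(statistic = obs, p = mc_pvalue(obs, sims), expected = 1,
                 n = n, n_mc = n_mc, seed = seed,
                 method = "Hopkins-Skellam A"), class = "spatial_test")
}

#' @export
print.spatial_test <- function(x, ...) {
  cat(sprintf("%s = %.3f (n = %d), Monte Carlo p = %.4f (%d simulations)\n",
              x$method, x$statistic, x$n, x$p, x$n_mc))
  invisible(x)
}

## ---- cluster-validity index panel ------------------------------------
## Each index inspects Ward partitions over the candidate k range and
## votes for one k. All are deterministic; the gap statistic draws its
## uniform reference sets from a private RNG stream so the vote does not
## depend on (or disturb) the caller's RNG state.

wss_by_k <- function(xy, labels_by_k) {
  vapply(labels_by_k, function(lab) {
    sum(vapply(split(seq_len(nrow(xy)), lab), function(idx) {
      centred <- scale(xy[idx, , drop = FALSE], scale = FALSE)
      sum(centred^2)
    }, numeric(1)))
  }, numeric(1))
}

vote_max <- function(vals, ks) ks[which.max(vals)]
vote_min <- function(vals, ks) ks[which.min(vals)]

index_values <- function(xy, d, labels_by_k, ks) {
  n <- nrow(xy)
  dm <- as.matrix(d)
  dvec <- as.numeric(d)   # column-major lower triangle, matches lower.tri()
  tot_ss <- sum(scale(xy, scale = FALSE)^2)
  w <- wss_by_k(xy, labels_by_k)

  per_k <- lapply(seq_along(ks), function(i) {
    k <- ks[i]; lab <- labels_by_k[[i]]
    same <- outer(lab, lab, "==")[lower.tri(dm)]
    within <- dvec[same]; between <- dvec[!same]
    sizes <- table(lab)
    cent <- do.call(rbind, lapply(split(seq_len(n), lab), function(idx)
      colMeans(xy[idx, , drop = FALSE])))
    # within-cluster mean distance to centroid (for Davies-Bouldin)
    scat <- vapply(seq_len(k), function(j) {
      idx <- which(lab == j)
      mean(sqrt(rowSums((xy[idx, , drop = FALSE] -
                         matrix(cent[j, ], length(idx), 2, byrow = TRUE))^2)))
    }, numeric(1))
    cd <- as.matrix(stats::dist(cent))
    db <- mean(vapply(seq_len(k), function(j)
      max(((scat[j] + scat[-j]) / cd[j, -j])), numeric(1)))
    # Dunn: min between-cluster separation / max cluster diameter
    diam <- vapply(seq_len(k), function(j) {
      idx <- which(lab == j)
      if (length(idx) < 2) 0 else max(dm[idx, idx])
    }, numeric(1))
    sep <- min(vapply(seq_len(k - 1), function(a) min(vapply((a + 1):k,
      function(b) min(dm[lab == a, lab == b]), numeric(1))), numeric(1)))
    nw <- length(within)
    dsort <- sort(dvec)
    cindex <- (sum(within) - sum(dsort[seq_len(nw)])) /
      (sum(rev(dsort)[seq_len(nw)]) - sum(dsort[seq_len(nw)]))
    list(
      silhouette = mean(cluster::silhouette(lab, d)[, "sil_width"]),
      ch = ((tot_ss - w[i]) / (k - 1)) / (w[i] / (n - k)),
      db = db,
      dunn = sep / max(diam),
      cindex = cindex,
      mcclain = mean(within) / mean(between),
      pb = stats::cor(dvec, as.numeric(!same)))
  })
  names(per_k) <- ks
  list(per_k = per_k, w = w)
}

gap_votes <- function(xy, ks, B = 25, gap_seed = 420L) {
  # private RNG stream: deterministic and side-effect free
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(gap_seed)
  n <- nrow(xy)
  rng <- apply(xy, 2, range)
  kfull <- c(1, ks)
  wk <- function(pts) {
    hc <- stats::hclust(stats::dist(pts), method = "ward.D2")
    log(wss_by_k(pts, lapply(kfull, function(k)
      if (k == 1) rep(1L, n) else stats::cutree(hc, k))))
  }
  obs <- wk(xy)
  ref <- replicate(B, wk(cbind(stats::runif(n, rng[1, 1], rng[2, 1]),
                               stats::runif(n, rng[1, 2], rng[2, 2]))))
  gap <- rowMeans(ref) - obs
  se <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B)
  # Tibshirani 1-SE rule over the candidate range
  for (i in seq_along(ks)) {
    j <- i + 1                      # position of ks[i] in kfull
    if (j == length(kfull)) return(ks[i])
    if (gap[j] >= gap[j + 1] - se[j + 1]) return(ks[i])
  }
  ks[length(ks)]
}

#' Majority-vote estimate of the number of landscape clusters
#'
#' Cuts a Ward-linkage hierarchical clustering of the (scaled) landscape
#' points at each candidate `k` and lets a panel of ten cluster-validity
#' indices - average silhouette width, Calinski-Harabasz, Davies-Bouldin,
#' Dunn, C-index, McClain-Rao, point-biserial, gap statistic (1-SE rule),
#' Hartigan and Krzanowski-Lai - each vote for its optimal `k`. The
#' modal `k` wins; ties are broken toward the smallest candidate and
#' recorded. The procedure is deterministic for a given point set.
#'
#' @param x a `"landscape"` object or n x 2 coordinate matrix.
#' @param k_range candidate cluster counts (default `2:8`; truncated with
#'   a warning when there are too few points).
#' @return object of class `"cluster_vote"`: `k` (majority), `votes`
#'   (named integer vector over candidates), `index_votes` (per-index
#'   choice), `tie` (logical), `labels` (Ward labels at the majority k).
#' @export
majority_cluster_count <- function(x, k_range = 2:8) {
  xy <- landscape_xy(x)
  n <- nrow(xy)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop_bad("candidate k must be >= 2")
  if (n < max(k_range) + 1) {
    k_range <- k_range[k_range <= n - 1]
    if (length(k_range) == 0) stop_bad("too few points for any candidate k")
    warning(sprintf("k range truncated to %d..%d (only %d points)",
                    min(k_range), max(k_range), n))
  }
  d <- stats::dist(xy)
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- k_range
  kext <- sort(unique(c(1, ks, max(ks) + 1)))   # for Hartigan / KL
  labels_ext <- lapply(kext, function(k)
    if (k == 1) rep(1L, n) else stats::cutree(hc, k))
  names(labels_ext) <- kext
  labels_by_k <- labels_ext[as.character(ks)]
  iv <- index_values(xy, d, labels_by_k, ks)
  w_ext <- wss_by_k(xy, labels_ext)
  names(w_ext) <- kext
  getw <- function(k) w_ext[as.character(k)]

  pull <- function(name) vapply(iv$per_k, function(z) z[[name]], numeric(1))
  hart <- vapply(ks, function(k) {
    h <- (getw(k) / getw(k + 1) - 1) * (n - k - 1)
    if (!is.finite(h)) Inf else h   # 0/0 or Inf*0: never a drop point
  }, numeric(1))
  hartigan_k <- if (any(hart <= 10)) ks[which(hart <= 10)[1]] else max(ks)
  p_dim <- 2
  diffk <- function(k) (k - 1)^(2 / p_dim) * getw(k - 1) -
    k^(2 / p_dim) * getw(k)
  kl <- vapply(ks, function(k) abs(diffk(k) / diffk(k + 1)), numeric(1))

  index_votes <- c(
    silhouette = vote_max(pull("silhouette"), ks),
    calinski_harabasz = vote_max(pull("ch"), ks),
    davies_bouldin = vote_min(pull("db"), ks),
    dunn = vote_max(pull("dunn"), ks),
    c_index = vote_min(pull("cindex"), ks),
    mcclain_rao = vote_min(pull("mcclain"), ks),
    point_biserial = vote_max(pull("pb"), ks),
    gap = gap_votes(xy, ks),
    hartigan = hartigan_k,
    krzanowski_lai = vote_max(kl, ks))

  votes <- table(factor(index_votes, levels = ks))
  top <- ks[votes == max(votes)]
  structure(list(k = min(top), votes = votes, index_votes = index_votes,
                 tie = length(top) > 1, k_range = ks,
                 labels = labels_by_k[[as.character(min(top))]]),
            class = "cluster_vote")
}

#' @export
print.cluster_vote <- function(x, ...) {
  cat(sprintf("Majority cluster count: k = %d%s\n", x$k,
              if (x$tie) " (tie, smallest k kept)" else ""))
  print(x$votes)
  invisible(x)
}

#' Correlation between quantity and quality components
#'
#' Pearson correlation of the raw (unscaled) QTC and QLC values across
#' functional groups, with the usual two-sided t-test. A positive
#' correlation indicates functional specialisation (the most frequent
#' visitors are also the best per visit).
#'
#' @param points an [effectiveness_points()] table or `"landscape"`.
#' @return list with `r`, `p`, `n`.
#' @export
qtc_qlc_correlation <- function(points) {
  qx <- points$qtc
  qy <- points$qlc
  if (length(qx) < 3) stop_bad("need at least 3 points")
  if (stats::sd(qx) == 0 || stats::sd(qy) == 0)
    stop_bad("zero variance in a component: correlation undefined")
  ct <- stats::cor.test(qx, qy, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(qx))
}
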