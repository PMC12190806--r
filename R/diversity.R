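#' Hurlbert's probability of interspecific encounter (PIE)
#'
#' The probability that two individuals drawn at random without replacement
#' from an assemblage belong to different functional groups:
#' \deqn{PIE = \frac{N}{N-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{N} the total count and \eqn{p_i = X_i/N} the relative
#' abundance of group \eqn{i}. An evenness-sensitive diversity index; it is
#' the measure of pollination generalisation used throughout this package.
#'
#' On integer counts the plug-in form above is algebraically identical to
#' the bias-corrected pair-count estimator
#' \eqn{1 - \sum_i X_i(X_i-1)/(N(N-1))} returned by [pie_unbiased()]; both
#' are exposed for transparency.
#'
#' @param counts non-negative integer counts per functional group.
#' @return PIE value in `[0, 1]`.
#' @examples
#' hurlbert_pie(c(10, 10))  # 100/190
#' @export
hurlbert_pie <- function(counts) {
  counts <- check_counts(counts, "counts")
  n <- sum(counts)
  if (n < 2) stop_bad("PIE undefined for N < 2 individuals")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' @rdname hurlbert_pie
#' @export
pie_unbiased <- function(counts) {
  counts <- check_counts(counts, "counts")
  n <- sum(counts)
  if (n < 2) stop_bad("PIE undefined for N < 2 individuals")
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Bootstrap estimate of PIE with percentile confidence interval
#'
#' Resamples `N` individuals multinomially from the observed relative
#' abundances `B` times, recomputes PIE on each resample, and summarises
#' the replicate distribution with its standard deviation (bootstrap SE)
#' and percentile interval. The resampling unit is the individual insect
#' (pooled counts), matching a census in which individuals are recorded
#' independently.
#'
#' @param counts non-negative integer counts per group (N = sum >= 2).
#' @param B number of bootstrap replicates (default 1000; fewer than 100
#'   triggers a warning about unstable intervals).
#' @param level confidence level for the percentile interval.
#' @param seed optional integer seed for reproducibility.
#' @param weighting label recording what the counts measure: `"visits"`
#'   (census counts) or `"seeds"` (effectiveness-attributed seed counts).
#' @return object of class `"diversity_estimate"`: list with `pie`, `se`,
#'   `ci_low`, `ci_high`, `n`, `B`, `level`, `weighting`, `seed`.
#' @export
pie_bootstrap <- function(counts, B = 1000, level = 0.95, seed = NULL,
                          weighting = c("visits", "seeds")) {
  weighting <- match.arg(weighting)
  counts <- check_counts(counts, "counts")
  n <- sum(counts)
  if (n < 2) stop_bad("PIE undefined for N < 2 individuals")
  if (B < 100) warning("fewer than 100 bootstrap replicates: interval is unstable")
  if (!is.null(seed)) set.seed(seed)
  p <- counts / n
  res <- stats::rmultinom(B, n, p)
  reps <- (n / (n - 1)) * (1 - colSums((res / n)^2))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(list(pie = hurlbert_pie(counts), se = stats::sd(reps),
                 ci_low = ci[1], ci_high = ci[2], n = n, B = B,
                 level = level, weighting = weighting, seed = seed),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("PIE (%s-weighted) = %.4f +/- %.4f SE, %g%% CI [%.4f, %.4f], N = %d\n",
              x$weighting, x$pie, x$se, 100 * x$level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Compare two bootstrap diversity estimates by interval overlap
#'
#' Two assemblages are declared to differ in diversity when their
#' percentile confidence intervals do not overlap (a deliberately
#' conservative criterion).
#'
#' @param a,b `"diversity_estimate"` objects from [pie_bootstrap()].
#' @return list with `overlap` (logical), `verdict` (`"different"` or
#'   `"not different"`) and the interval bounds compared.
#' @export
compare_estimates <- function(a, b) {
  stopifnot(inherits(a, "diversity_estimate"), inherits(b, "diversity_estimate"))
  overlap <- a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
  list(overlap = overlap,
       verdict = if (overlap) "not different" else "different",
       a = c(a$ci_low, a$ci_high), b = c(b$ci_low, b$ci_high))
}

assemblage_matrix <- function(x, scale = c("proportions", "counts"),
                              drop_empty = TRUE) {
  scale <- match.arg(scale)
  m <- if (inherits(x, "assemblage")) x$counts else as.matrix(x)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    if (!drop_empty && sum(empty) >= 2)
      stop_bad("dissimilarity undefined between two all-zero units")
    if (drop_empty) {
      message("dropping ", sum(empty), " all-zero unit(s): ",
              paste(rownames(m)[empty], collapse = ", "))
      m <- m[!empty, , drop = FALSE]
    }
  }
  if (nrow(m) < 2) stop_bad("need at least 2 non-empty units")
  if (scale == "proportions") m <- m / rowSums(m)
  m
}

#' Bray-Curtis dissimilarity between assemblage units
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' `[0, 1]`. All-zero units are dropped with a notice before computation
#' (the index is undefined on empty rows).
#'
#' @param x an [assemblage_table()] object or a numeric units x groups
#'   matrix.
#' @param scale `"proportions"` (default: rows rescaled to sum to 1, so
#'   units are compared by composition) or `"counts"` (raw counts, so
#'   units are also separated by sampling depth).
#' @return a `dist` object.
#' @export
bray_curtis <- function(x, scale = c("proportions", "counts")) {
  m <- assemblage_matrix(x, match.arg(scale))
  vegan::vegdist(m, method = "bray")
}

#' Permutational multivariate analysis of variance on a dissimilarity matrix
#'
#' Partitions a dissimilarity matrix among factors by the Gower-centred
#' inner-product decomposition with sequential (entry-order) sums of
#' squares, so a covariate listed first is controlled for before the term
#' of interest is assessed. Significance of each pseudo-F is obtained by
#' free permutation of units; `p = (1 + #(F* >= F)) / (1 + n_perm)`.
#' Computation is delegated to [vegan::adonis2()] with `by = "terms"`.
#'
#' @param d a `dist` object (e.g. from [bray_curtis()]).
#' @param data data.frame of unit-level factors, rows matching `d`.
#' @param terms character vector of factor names in the order they should
#'   enter the model (covariates first).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return object of class `"permanova_result"`: the per-term table
#'   (`df`, `ss`, `r2`, `f`, `p`), residual df/SS, `n_perm` and `seed`.
#' @export
permanova <- function(d, data, terms, n_perm = 999, seed = NULL) {
  stopifnot(inherits(d, "dist"))
  if (n_perm < 99) stop_bad("n_perm must be at least 99")
  miss <- setdiff(terms, names(data))
  if (length(miss) > 0) stop_bad("term(s) not in data: %s",
                                 paste(miss, collapse = ", "))
  n <- attr(d, "Size")
  if (nrow(data) != n) stop_bad("data has %d rows but dissimilarity has %d units",
                                nrow(data), n)
  for (tm in terms) {
    data[[tm]] <- factor(data[[tm]])
    if (nlevels(data[[tm]]) < 2)
      stop_bad("term '%s' has a single level", tm)
  }
  if (length(terms) > 1) {
    pairs <- utils::combn(terms, 2, simplify = FALSE)
    for (pr in pairs) {
      tab <- table(data[[pr[1]]], data[[pr[2]]]) > 0
      if (all(rowSums(tab) == 1) && all(colSums(tab) == 1))
        stop_bad("terms '%s' and '%s' are confounded (one-to-one levels)",
                 pr[1], pr[2])
    }
  }
  if (!is.null(seed)) set.seed(seed)
  fml <- stats::reformulate(terms, response = quote(d))
  fit <- vegan::adonis2(fml, data = data, permutations = n_perm, by = "terms")
  k <- length(terms)
  out <- list(terms = terms,
              table = data.frame(term = terms,
                                 df = fit$Df[seq_len(k)],
                                 ss = fit$SumOfSqs[seq_len(k)],
                                 r2 = fit$R2[seq_len(k)],
                                 f = fit$F[seq_len(k)],
                                 p = fit$`Pr(>F)`[seq_len(k)],
                                 stringsAsFactors = FALSE),
              residual_df = fit$Df[k + 1], residual_ss = fit$SumOfSqs[k + 1],
              total_ss = fit$SumOfSqs[k + 2], n_units = n,
              n_perm = n_perm, seed = seed)
  class(out) <- "permanova_result"
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d free permutations)\n", x$n_perm))
  print(x$table, row.names = FALSE)
  cat(sprintf("Residual: df = %d, SS = %.4f\n", x$residual_df, x$residual_ss))
  invisible(x)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' matrix \eqn{-\tfrac12 J D^2 J}; coordinates are eigenvectors scaled by
#' the square root of their eigenvalues. The proportion of variation per
#' axis is taken over the positive eigenvalues only; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported but neither corrected nor included in the denominator.
#'
#' @param d a `dist` object.
#' @param k number of axes to return (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return object of class `"pcoa_result"`: `points` (units x k), `eig`
#'   (all eigenvalues, decreasing), `prop` (variation proportions over
#'   positive eigenvalues), `k`.
#' @export
pcoa <- function(d, k = 2) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  # request all axes; the positive-eigenvalue count is handled below
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > npos) {
    warning(sprintf("only %d positive eigenvalues: k truncated from %d", npos, k))
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts, eig = eig,
                 prop = eig[seq_len(npos)] / sum(eig[seq_len(npos)]),
                 k = k), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d units, %d axes kept (%.1f%% of variation)\n",
              nrow(x$points), x$k, 100 * sum(x$prop[seq_len(x$k)])))
  invisible(x)
}

#' Project functional groups onto a principal-coordinates ordination
#'
#' Correlation-projection scores: the score of group `i` on axis `a` is
#' the Pearson correlation between the group's abundance across units and
#' the unit coordinates on that axis, scaled by the standard deviation of
#' the axis. Groups with zero variance across units get a score of 0 with
#' a warning.
#'
#' @param ord a `"pcoa_result"`.
#' @param x the assemblage (or matrix) the ordination was computed from;
#'   all-zero units are dropped to match the ordination.
#' @param scale `"proportions"` or `"counts"`, matching the distance input.
#' @return matrix of group scores, groups x axes.
#' @export
group_scores <- function(ord, x, scale = c("proportions", "counts")) {
  stopifnot(inherits(ord, "pcoa_result"))
  m <- assemblage_matrix(x, match.arg(scale))
  if (nrow(m) != nrow(ord$points))
    stop_bad("ordination and table do not share units (%d vs %d)",
             nrow(ord$points), nrow(m))
  sc <- matrix(0, ncol(m), ord$k,
               dimnames = list(colnames(m), colnames(ord$points)))
  zerovar <- apply(m, 2, stats::sd) == 0
  if (any(zerovar))
    warning("zero-variance group(s) scored 0: ",
            paste(colnames(m)[zerovar], collapse = ", "))
  for (a in seq_len(ord$k)) {
    ax <- ord$points[, a]
    sc[!zerovar, a] <- apply(m[, !zerovar, drop = FALSE], 2,
                             stats::cor, y = ax) * stats::sd(ax)
  }
  sc
}
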