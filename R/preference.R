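#' Jacobs' D electivity index
#'
#' Availability-corrected preference index
#' \deqn{D = \frac{r - p}{r + p - 2rp}}
#' where `r` is the proportion of a forager's visits that went to the
#' resource (here, the spring floral morph) and `p` the proportion of that
#' resource available in the environment (here, the spring share of open
#' flowers). `D = 0` under random use, `+1` for exclusive preference, `-1`
#' for total avoidance; unlike Ivlev's E it is robust to large changes in
#' resource availability. The degenerate inputs `r = p = 0` and
#' `r = p = 1` return 0 (random use by continuity) with a warning.
#'
#' @param r proportion of visits to the focal morph, in `[0, 1]`.
#' @param p proportion of available flowers of the focal morph, in `[0, 1]`.
#' @return D in `[-1, 1]`; vectorised over `r` and `p`.
#' @examples
#' jacobs_d(0.75, 0.5)  # 0.5
#' @export
jacobs_d <- function(r, p) {
  if (any(r < 0 | r > 1 | p < 0 | p > 1)) stop_bad("r and p must lie in [0, 1]")
  denom <- r + p - 2 * r * p
  out <- ifelse(denom == 0, 0, (r - p) / denom)
  if (any(denom == 0))
    warning("degenerate input (r = p = 0 or r = p = 1): D set to 0 by continuity")
  out
}

#' Ivlev's E electivity index
#'
#' \eqn{E = (r - p)/(r + p)}. Same sign convention as [jacobs_d()], but
#' sensitive to the absolute availability of the resource.
#'
#' @inheritParams jacobs_d
#' @return E in `[-1, 1]`.
#' @export
ivlev_e <- function(r, p) {
  if (any(r < 0 | r > 1 | p < 0 | p > 1)) stop_bad("r and p must lie in [0, 1]")
  if (any(r + p == 0)) stop_bad("Ivlev's E undefined at r = p = 0")
  (r - p) / (r + p)
}

#' Goodness-of-fit test for availability-proportional visitation
#'
#' Tests the null hypothesis that a functional group splits its visits
#' between the two floral morphs in direct proportion to the morphs'
#' relative flower availability. A 1-df chi-square goodness-of-fit test
#' (no continuity correction) is used when both expected counts are at
#' least 5; otherwise an exact binomial test is substituted automatically.
#'
#' @param visits integer vector of length 2: visits to (spring, summer)
#'   morphs.
#' @param availability numeric vector of length 2: open flowers of
#'   (spring, summer) morphs; both must be positive.
#' @return list with `statistic` (chi-square, or NA for the exact path),
#'   `p`, `method`, `expected`.
#' @examples
#' preference_gof(c(30, 10), c(50, 50))  # chi-square = 10
#' @export
preference_gof <- function(visits, availability) {
  visits <- check_counts(visits, "visits")
  if (length(visits) != 2 || length(availability) != 2)
    stop_bad("visits and availability must each have length 2")
  if (any(availability <= 0))
    stop_bad("both morphs must have positive flower availability")
  n <- sum(visits)
  if (n < 1) stop_bad("at least one visit is required")
  p0 <- availability[1] / sum(availability)
  expected <- n * c(p0, 1 - p0)
  if (any(expected < 5)) {
    p <- stats::binom.test(visits[1], n, p0)$p.value
    list(statistic = NA_real_, p = p, method = "exact binomial",
         expected = expected)
  } else {
    stat <- sum((visits - expected)^2 / expected)
    list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-square", expected = expected)
  }
}

#' Electivity analysis of pooled preference trials
#'
#' Pools visits and flower availability across trials (ratio of sums, the
#' stable estimator when per-trial counts are small) and computes, for
#' each functional group: the spring-morph visit proportion `r`, the
#' flower-weighted spring availability `p`, Jacobs' D, Ivlev's E, and the
#' availability-proportional goodness-of-fit test. Groups with fewer than
#' `min_visits` pooled visits are flagged `sufficient = FALSE` (their
#' indices are still reported).
#'
#' @param trials a [preference_trials()] table.
#' @param season optional filter: only trials from this season.
#' @param min_visits minimum pooled visits for a group to be considered
#'   adequately sampled (default 20).
#' @return data.frame of class `"preference_result"`, one row per group:
#'   `group`, `n_visits`, `r`, `p`, `D`, `E`, `gof_statistic`, `gof_p`,
#'   `gof_method`, `sufficient`.
#' @export
trial_aggregate <- function(trials, season = NULL, min_visits = 20) {
  stopifnot(inherits(trials, "preference_trials"))
  if (!is.null(season)) {
    season <- check_season(season)
    trials <- trials[trials$season %in% season, , drop = FALSE]
    if (nrow(trials) == 0) stop_bad("no trials in season '%s'", season)
  }
  # availability pooled over distinct trials (flower-weighted)
  fl <- unique(trials[c("trial", "flowers_spring", "flowers_summer")])
  avail <- c(sum(fl$flowers_spring), sum(fl$flowers_summer))
  p <- avail[1] / sum(avail)
  groups <- sort(unique(trials$group))
  rows <- lapply(groups, function(g) {
    sub <- trials[trials$group == g, , drop = FALSE]
    vs <- sum(sub$visits_spring)
    vu <- sum(sub$visits_summer)
    n <- vs + vu
    if (n == 0)
      return(data.frame(group = g, n_visits = 0L, r = NA_real_, p = p,
                        D = NA_real_, E = NA_real_, gof_statistic = NA_real_,
                        gof_p = NA_real_, gof_method = "none",
                        sufficient = FALSE, stringsAsFactors = FALSE))
    r <- vs / n
    gof <- preference_gof(c(vs, vu), avail)
    data.frame(group = g, n_visits = n, r = r, p = p,
               D = suppressWarnings(jacobs_d(r, p)), E = ivlev_e(r, p),
               gof_statistic = gof$statistic, gof_p = gof$p,
               gof_method = gof$method, sufficient = n >= min_visits,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("preference_result", "data.frame")
  out
}
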