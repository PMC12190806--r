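#' Quantity component of pollination effectiveness (QTC)
#'
#' Visits per plant per hour: the total visits a functional group made to
#' plants displaying a morph, divided by the total plant-observation hours
#' spent on that morph (every watch contributes to the denominator of
#' every group, whether or not the group appeared).
#'
#' @param surveys a [survey_table()].
#' @param group functional-group label (omit to get all groups).
#' @param morph floral morph.
#' @return visits/plant/hour; [qtc_table()] returns a data.frame over all
#'   group x morph combinations present.
#' @export
qtc <- function(surveys, group, morph) {
  stopifnot(inherits(surveys, "surveys"))
  morph <- check_season(morph, "morph")
  sub <- surveys[surveys$morph == morph, , drop = FALSE]
  effort <- sum(unique(sub[c("survey", "duration_min")])$duration_min) / 60
  if (effort <= 0) stop_bad("no survey effort on morph '%s'", morph)
  sum(sub$visits[sub$group == group]) / effort
}

#' @rdname qtc
#' @export
qtc_table <- function(surveys) {
  stopifnot(inherits(surveys, "surveys"))
  out <- expand.grid(group = sort(unique(surveys$group)),
                     morph = intersect(MORPHS, unique(surveys$morph)),
                     stringsAsFactors = FALSE)
  out$qtc <- mapply(function(g, m) qtc(surveys, g, m), out$group, out$morph)
  out
}

#' Quality component of pollination effectiveness (QLC)
#'
#' Viable seeds per visit: total viable seeds over all single-visit
#' flowers for the group x morph cell divided by the number of flowers
#' visited. Flowers that set no fruit contribute zero seeds but still
#' count one visit, so QLC reflects the full per-visit expectation, not
#' the per-fruit mean.
#'
#' @param records a [single_visits()] table.
#' @param group functional-group label.
#' @param morph floral morph.
#' @return seeds/visit; `NA` with a warning for an empty cell.
#'   [qlc_table()] covers all cells present.
#' @export
qlc <- function(records, group, morph) {
  stopifnot(inherits(records, "single_visits"))
  morph <- check_season(morph, "morph")
  sub <- records[records$group == group & records$morph == morph, ,
                 drop = FALSE]
  if (nrow(sub) == 0) {
    warning(sprintf("no single-visit records for %s on %s morph: QLC unknown",
                    group, morph))
    return(NA_real_)
  }
  sum(sub$viable_seeds) / nrow(sub)
}

#' @rdname qlc
#' @export
qlc_table <- function(records) {
  stopifnot(inherits(records, "single_visits"))
  out <- expand.grid(group = sort(unique(records$group)),
                     morph = intersect(MORPHS, unique(records$morph)),
                     stringsAsFactors = FALSE)
  out$qlc <- mapply(function(g, m) suppressWarnings(qlc(records, g, m)),
                    out$group, out$morph)
  out$n_flowers <- mapply(function(g, m)
    sum(records$group == g & records$morph == m), out$group, out$morph)
  out
}

#' Assemble the effectiveness points
#'
#' Joins the quantity and quality components and forms effectiveness as
#' their exact product (seeds per plant per hour). Group x morph cells
#' missing either component are omitted with a notice.
#'
#' @param qtc_tab data.frame from [qtc_table()] (columns group, morph,
#'   qtc).
#' @param qlc_tab data.frame from [qlc_table()] (columns group, morph,
#'   qlc).
#' @return data.frame of class `"effectiveness_points"`: `group`, `morph`,
#'   `qtc`, `qlc`, `effectiveness`.
#' @export
effectiveness_points <- function(qtc_tab, qlc_tab) {
  pts <- merge(qtc_tab[c("group", "morph", "qtc")],
               qlc_tab[c("group", "morph", "qlc")],
               by = c("group", "morph"))
  drop <- is.na(pts$qtc) | is.na(pts$qlc)
  if (any(drop)) {
    message("omitting ", sum(drop),
            " point(s) with a missing component: ",
            paste(pts$group[drop], pts$morph[drop], sep = "/", collapse = ", "))
    pts <- pts[!drop, , drop = FALSE]
  }
  pts$effectiveness <- pts$qtc * pts$qlc
  pts <- pts[order(pts$morph, pts$group), , drop = FALSE]
  rownames(pts) <- NULL
  class(pts) <- c("effectiveness_points", "data.frame")
  pts
}

#' Proportional seed contribution of each functional group
#'
#' Within a morph, attributes the morph's seed production to functional
#' groups in proportion to their effectiveness:
#' `share_i = E_i / sum_j E_j`.
#'
#' @param points an [effectiveness_points()] table.
#' @param morph floral morph to attribute.
#' @return data.frame `group`, `morph`, `share` (sums to 1).
#' @export
seed_shares <- function(points, morph) {
  stopifnot(inherits(points, "effectiveness_points"))
  morph <- check_season(morph, "morph")
  sub <- points[points$morph == morph, , drop = FALSE]
  if (nrow(sub) == 0 || sum(sub$effectiveness) <= 0)
    stop_bad("no positive effectiveness for morph '%s'", morph)
  data.frame(group = sub$group, morph = morph,
             share = sub$effectiveness / sum(sub$effectiveness),
             stringsAsFactors = FALSE)
}

#' Binomial GLM likelihood-ratio test
#'
#' Fits a logit-link binomial GLM of successes/totals on a single factor
#' and reports the likelihood-ratio (deviance) test of the factor against
#' the intercept-only null, with a chi-square p-value on
#' `levels - 1` degrees of freedom. Used for the "do functional groups
#' differ in per-visit seed production?" and "do morphs differ in the
#' proportion of ovules maturing to seed?" comparisons.
#'
#' @param successes integer successes per observation (e.g. viable seeds
#'   per flower).
#' @param totals integer trials per observation (e.g. ovules per flower).
#' @param labels factor coding the comparison (e.g. functional group or
#'   morph).
#' @return object of class `"glm_lrt"`: `deviance` (null - residual),
#'   `df`, `p`, `null_deviance`, `residual_deviance`, `coefficients`
#'   (logit scale), `fitted_props` (per level).
#' @export
binomial_glm_lrt <- function(successes, totals, labels) {
  successes <- check_counts(successes, "successes")
  totals <- check_counts(totals, "totals")
  if (any(totals < successes)) stop_bad("successes exceed totals")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_bad("need at least 2 factor levels")
  fit <- stats::glm(cbind(successes, totals - successes) ~ labels,
                    family = stats::binomial())
  if (!fit$converged) stop_bad("binomial GLM did not converge")
  dev <- fit$null.deviance - fit$deviance
  df <- nlevels(labels) - 1
  props <- stats::setNames(
    as.numeric(tapply(successes, labels, sum) / tapply(totals, labels, sum)),
    levels(labels))
  structure(list(deviance = dev, df = df,
                 p = stats::pchisq(dev, df, lower.tail = FALSE),
                 null_deviance = fit$null.deviance,
                 residual_deviance = fit$deviance,
                 coefficients = stats::coef(fit),
                 fitted_props = props), class = "glm_lrt")
}

#' @export
print.glm_lrt <- function(x, ...) {
  cat(sprintf("Binomial GLM LRT: deviance = %.2f on %d df, p = %.3g\n",
              x$deviance, x$df, x$p))
  invisible(x)
}

# Largest-remainder rounding of shares * total to integers summing to total.
largest_remainder <- function(shares, total) {
  raw <- shares * total
  base <- floor(raw)
  left <- round(total - sum(base))
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Visitation- vs effectiveness-weighted generalisation comparison
#'
#' Computes the bootstrap PIE estimate of the same assemblage under two
#' weightings - the number of visits per functional group, and the number
#' of seeds attributed to each group via its effectiveness - and declares
#' the generalisation levels "different" when the two 95 % percentile
#' intervals do not overlap. Seed counts are derived from the
#' effectiveness shares by largest-remainder rounding of
#' `share * total_seeds`, so the finite-sample PIE correction stays
#' defined.
#'
#' @param visit_counts integer visits per group.
#' @param seed_shares numeric effectiveness shares per group (same group
#'   order; rescaled to sum to 1).
#' @param total_seeds total seeds to distribute (>= 2).
#' @param B bootstrap replicates per weighting.
#' @param seed RNG seed.
#' @return list of class `"pie_comparison"`: `visits` and `seeds`
#'   ([pie_bootstrap()] estimates), `verdict`, `overlap`, `seed_counts`.
#' @export
weighted_pie_comparison <- function(visit_counts, seed_shares, total_seeds,
                                    B = 1000, seed = NULL) {
  if (length(visit_counts) != length(seed_shares))
    stop_bad("visit counts and seed shares must cover the same groups")
  if (total_seeds < 2) stop_bad("need at least 2 seeds")
  seed_counts <- largest_remainder(seed_shares / sum(seed_shares), total_seeds)
  ev <- pie_bootstrap(visit_counts, B = B, seed = seed, weighting = "visits")
  es <- pie_bootstrap(seed_counts, B = B,
                      seed = if (is.null(seed)) NULL else seed + 1,
                      weighting = "seeds")
  cmp <- compare_estimates(ev, es)
  structure(list(visits = ev, seeds = es, verdict = cmp$verdict,
                 overlap = cmp$overlap, seed_counts = seed_counts),
            class = "pie_comparison")
}

#' @export
print.pie_comparison <- function(x, ...) {
  print(x$visits); print(x$seeds)
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
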