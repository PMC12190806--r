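#' Invert Jacobs' D for the expected visit split
#'
#' Given a target electivity `D` and a spring-morph availability `p`,
#' returns the visit proportion `r` that produces exactly that electivity:
#' \deqn{r = \frac{p(1+D)}{1 + D(2p - 1)}}
#' This is the closed-form inverse of [jacobs_d()] in `r` and is what the
#' trial generator uses to translate ground-truth preferences into
#' binomial visit splits.
#'
#' @param D Jacobs' D target in `[-1, 1]` (the boundary values return
#'   `r = 1` or `r = 0`, i.e. exclusive use, with a warning).
#' @param p availability proportion of the spring morph in `(0, 1)`.
#' @return expected proportion of visits to the spring morph; vectorised.
#' @examples
#' solve_visit_split(0.5, 0.5)  # 0.75
#' @export
solve_visit_split <- function(D, p) {
  if (any(abs(D) > 1)) stop_bad("D must lie in [-1, 1]")
  if (any(p <= 0 | p >= 1)) stop_bad("p must lie in (0, 1)")
  if (any(abs(D) == 1))
    warning("|D| = 1: exclusive preference, boundary visit split returned")
  p * (1 + D) / (1 + D * (2 * p - 1))
}

#' Ground-truth scenario for the synthetic-data generator
#'
#' Bundles every parameter needed to simulate the four study tables
#' (census, preference trials, per-plant surveys, single-visit outcomes)
#' with known truth, so each downstream estimator can be checked for
#' parameter recovery.
#'
#' @param groups character vector of functional-group labels.
#' @param p_spring,p_summer multinomial abundance probabilities per group
#'   in each season (must sum to 1).
#' @param d_spring per-group Jacobs' D preference target for the spring
#'   morph, each in `[-1, 1]`.
#' @param qtc_spring,qtc_summer per-group Poisson visitation intensities
#'   (visits per plant per hour) on each morph.
#' @param f_spring,f_summer per-group fruit-set probability per single
#'   visit on each morph.
#' @param q_spring,q_summer per-group per-ovule fertilisation probability
#'   given fruit set.
#' @param ovules ovules per flower (same for both morphs by default; the
#'   expected seeds per visit is `f * ovules * q`).
#' @param trial_visit_rate expected total insect visits per 5-min trial,
#'   apportioned among groups by the season's abundance vector.
#' @param flowers_per_trial expected open flowers per morph per trial.
#' @param abort_frac fraction of unfertilised ovules recorded as aborted
#'   rather than unfertilised (the split is not identifiable from seed
#'   counts; 0.2 is an arbitrary bookkeeping default).
#' @param seed integer RNG seed stored with the scenario.
#' @return validated list of class `"effscape_scenario"`.
#' @export
scenario_config <- function(groups, p_spring, p_summer, d_spring,
                            qtc_spring, qtc_summer,
                            f_spring, f_summer, q_spring, q_summer,
                            ovules = 20, trial_visit_rate = 8,
                            flowers_per_trial = 50, abort_frac = 0.2,
                            seed = 1L) {
  k <- length(groups)
  vecs <- list(p_spring = p_spring, p_summer = p_summer, d_spring = d_spring,
               qtc_spring = qtc_spring, qtc_summer = qtc_summer,
               f_spring = f_spring, f_summer = f_summer,
               q_spring = q_spring, q_summer = q_summer)
  for (nm in names(vecs))
    if (length(vecs[[nm]]) != k)
      stop_bad("'%s' must have one value per group (%d)", nm, k)
  for (nm in c("p_spring", "p_summer"))
    if (abs(sum(vecs[[nm]]) - 1) > 1e-8 || any(vecs[[nm]] < 0))
      stop_bad("'%s' must be a probability vector summing to 1", nm)
  if (any(abs(d_spring) > 1)) stop_bad("d_spring values must lie in [-1, 1]")
  for (nm in c("f_spring", "f_summer", "q_spring", "q_summer"))
    if (any(vecs[[nm]] < 0 | vecs[[nm]] > 1))
      stop_bad("'%s' values must lie in [0, 1]", nm)
  if (ovules < 1) stop_bad("ovules must be >= 1")
  if (any(c(qtc_spring, qtc_summer) < 0)) stop_bad("QTC rates must be >= 0")
  structure(c(list(groups = as.character(groups)), vecs,
              list(ovules = ovules, trial_visit_rate = trial_visit_rate,
                   flowers_per_trial = flowers_per_trial,
                   abort_frac = abort_frac, seed = as.integer(seed))),
            class = "effscape_scenario")
}

#' Field-study-like default scenario
#'
#' A ten-group scenario whose marginal structure mimics the study system:
#' spring visitation dominated by one group of long-tongued large bees
#' (~62 % of visits) which also has the highest per-visit quality, so
#' seed production concentrates on it (~80 % of spring seeds, with
#' hovering beeflies a distant second); summer visitation much more even,
#' with per-visit quality weighted toward the rarer effective bees so
#' that seed production is spread more evenly than visitation. Under
#' these defaults the expected seed-weighted diversity is below the
#' visit-weighted diversity in spring and above it in summer.
#'
#' Preferences: bees and beeflies prefer the spring morph (positive D),
#' large flies and large butterflies the summer morph (negative D),
#' beetles and hoverflies are indifferent.
#'
#' @param seed RNG seed stored in the scenario.
#' @return an [scenario_config()] object.
#' @export
paper_like_scenario <- function(seed = 1L) {
  groups <- c("lt_large_bees", "st_large_bees", "st_small_bees",
              "st_xsmall_bees", "beeflies", "small_hoverflies",
              "large_flies", "large_butterflies", "large_beetles",
              "small_diving_beetles")
  p_spring <- c(61.8, 3.0, 6.0, 0.2, 8.5, 1.3, 0.9, 2.9, 2.0, 3.7)
  p_summer <- c(15.5, 6.6, 36.2, 3.1, 6.8, 5.0, 0.2, 7.6, 4.6, 1.7)
  scenario_config(
    groups = groups,
    p_spring = p_spring / sum(p_spring),
    p_summer = p_summer / sum(p_summer),
    d_spring = c(0.5, 0.3, 0.4, 0.3, 0.5, 0.0, -0.5, -0.4, 0.0, 0.0),
    qtc_spring = 6 * p_spring / sum(p_spring),
    qtc_summer = 3 * p_summer / sum(p_summer),
    # per-visit quality: expected seeds/visit = f * ovules * q
    f_spring = c(0.60, 0.50, 0.40, 0.40, 0.55, 0.05, 0.05, 0.50, 0.10, 0.10),
    q_spring = c(0.50, 0.40, 0.35, 0.30, 0.45, 0.10, 0.10, 0.40, 0.10, 0.10),
    f_summer = c(0.55, 0.50, 0.30, 0.80, 0.40, 0.05, 0.05, 0.50, 0.10, 0.10),
    q_summer = c(0.45, 0.50, 0.28, 0.70, 0.31, 0.10, 0.10, 0.50, 0.10, 0.10),
    seed = seed)
}

season_field <- function(config, prefix, season)
  config[[paste0(prefix, "_", season)]]

#' Simulate a visitation census
#'
#' Draws, for each site x season unit, a multinomial sample of
#' `n_insects` individuals from the season's ground-truth abundance
#' vector, emulating timed censuses of insects contacting anthers or
#' stigma.
#'
#' @param config an [scenario_config()].
#' @param sites character vector of site labels (each site is censused in
#'   both seasons).
#' @param n_insects insects recorded per unit (scalar or one per unit).
#' @param seed optional seed overriding `config$seed`.
#' @return an [assemblage_table()].
#' @export
gen_census <- function(config, sites = paste0("S", 1:6), n_insects = 500,
                       seed = NULL) {
  stopifnot(inherits(config, "effscape_scenario"))
  set.seed(if (is.null(seed)) config$seed else seed)
  units <- expand.grid(site = sites, season = SEASONS,
                       stringsAsFactors = FALSE)
  n_insects <- rep_len(n_insects, nrow(units))
  counts <- t(vapply(seq_len(nrow(units)), function(i) {
    p <- season_field(config, "p", units$season[i])
    as.numeric(stats::rmultinom(1, n_insects[i], p))
  }, numeric(length(config$groups))))
  colnames(counts) <- config$groups
  assemblage_table(counts, units$site, units$season)
}

#' Simulate two-morph preference trials
#'
#' For each 5-min trial, open-flower counts per morph are drawn around
#' `flowers_per_trial`; each group's total visits are Poisson with mean
#' `trial_visit_rate` times the group's seasonal abundance, and are split
#' between morphs binomially with probability
#' `solve_visit_split(D_group, availability)`, so the generated data obey
#' the ground-truth electivities exactly in expectation.
#'
#' @param config an [scenario_config()].
#' @param n_trials number of trials to simulate.
#' @param season season the trials are run in (sets group activity).
#' @param site site label recorded on the trials.
#' @param seed optional seed overriding `config$seed`.
#' @return a [preference_trials()] table.
#' @export
gen_trials <- function(config, n_trials, season = "spring",
                       site = "synthetic", seed = NULL) {
  stopifnot(inherits(config, "effscape_scenario"))
  season <- check_season(season)
  set.seed(if (is.null(seed)) config$seed else seed)
  k <- length(config$groups)
  if (n_trials == 0) {
    return(preference_trials(data.frame(
      trial = integer(), site = character(), season = character(),
      group = character(), flowers_spring = numeric(),
      flowers_summer = numeric(), visits_spring = integer(),
      visits_summer = integer(), stringsAsFactors = FALSE)))
  }
  abund <- season_field(config, "p", season)
  rows <- lapply(seq_len(n_trials), function(tr) {
    fs <- stats::rpois(1, config$flowers_per_trial) + 1
    fu <- stats::rpois(1, config$flowers_per_trial) + 1
    p <- fs / (fs + fu)
    total <- stats::rpois(k, config$trial_visit_rate * abund)
    r <- suppressWarnings(solve_visit_split(config$d_spring, p))
    vs <- stats::rbinom(k, total, r)
    data.frame(trial = tr, site = site, season = season,
               group = config$groups, flowers_spring = fs,
               flowers_summer = fu, visits_spring = vs,
               visits_summer = total - vs, stringsAsFactors = FALSE)
  })
  preference_trials(do.call(rbind, rows))
}

#' Simulate single-visit seed-set outcomes
#'
#' Two-stage seed model per visited virgin flower: fruit set is Bernoulli
#' with the group x morph fruit probability `f`; given fruit set, viable
#' seeds are Binomial(`ovules`, `q`). Ovules that do not become viable
#' seeds are split between unfertilised and aborted at a fixed
#' `abort_frac`. Expected seeds per visit is therefore `f * ovules * q`,
#' giving a closed-form oracle for the quality-component estimator.
#'
#' @param config an [scenario_config()].
#' @param n_flowers flowers exposed per group x morph cell.
#' @param morphs morphs to include (default both).
#' @param seed optional seed overriding `config$seed`.
#' @return a [single_visits()] table.
#' @export
gen_single_visits <- function(config, n_flowers = 100, morphs = MORPHS,
                              seed = NULL) {
  stopifnot(inherits(config, "effscape_scenario"))
  set.seed(if (is.null(seed)) config$seed else seed)
  m <- config$ovules
  rows <- list()
  fid <- 0L
  for (morph in check_season(morphs, "morph")) {
    f <- season_field(config, "f", morph)
    q <- season_field(config, "q", morph)
    for (g in seq_along(config$groups)) {
      fruit <- stats::rbinom(n_flowers, 1, f[g]) == 1
      viable <- ifelse(fruit, stats::rbinom(n_flowers, m, q[g]), 0L)
      rest <- m - viable
      aborted <- round(config$abort_frac * rest)
      rows[[length(rows) + 1]] <- data.frame(
        flower = fid + seq_len(n_flowers), morph = morph,
        group = config$groups[g], fruit_set = fruit,
        viable_seeds = viable, unfertilised_ovules = rest - aborted,
        aborted_seeds = aborted, stringsAsFactors = FALSE)
      fid <- fid + n_flowers
    }
  }
  single_visits(do.call(rbind, rows))
}

#' Simulate per-plant visitation surveys
#'
#' Timed watches of single plants displaying one morph; each group's
#' visit count in a watch is Poisson with mean equal to its ground-truth
#' visitation intensity (visits/plant/hour) times the watch duration.
#'
#' @param config an [scenario_config()].
#' @param n_surveys watches per morph.
#' @param duration_min watch length in minutes (default 5, the field
#'   protocol).
#' @param morphs morphs to include.
#' @param seed optional seed overriding `config$seed`.
#' @return a [survey_table()].
#' @export
gen_surveys <- function(config, n_surveys = 100, duration_min = 5,
                        morphs = MORPHS, seed = NULL) {
  stopifnot(inherits(config, "effscape_scenario"))
  set.seed(if (is.null(seed)) config$seed else seed)
  k <- length(config$groups)
  rows <- list()
  sid <- 0L
  for (morph in check_season(morphs, "morph")) {
    rate <- season_field(config, "qtc", morph)
    for (s in seq_len(n_surveys)) {
      sid <- sid + 1L
      rows[[length(rows) + 1]] <- data.frame(
        survey = sid, plant = paste0("P", 1 + (sid - 1) %% 100),
        morph = morph, duration_min = duration_min, group = config$groups,
        visits = stats::rpois(k, rate * duration_min / 60),
        stringsAsFactors = FALSE)
    }
  }
  survey_table(do.call(rbind, rows))
}
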