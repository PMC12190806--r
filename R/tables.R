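#' @keywords internal
"_PACKAGE"

SEASONS <- c("spring", "summer")
MORPHS <- c("spring", "summer")

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_season <- function(x, what = "season") {
  x <- as.character(x)
  bad <- setdiff(unique(x), SEASONS)
  if (length(bad) > 0)
    stop_bad("unknown %s label(s): %s (allowed: %s)", what,
             paste(bad, collapse = ", "), paste(SEASONS, collapse = ", "))
  x
}

check_counts <- function(x, what) {
  if (any(is.na(x))) stop_bad("%s contains NA", what)
  if (any(x < 0)) stop_bad("%s contains negative values", what)
  if (any(abs(x - round(x)) > 1e-8)) stop_bad("%s must be integral counts", what)
  round(x)
}

#' Assemblage table of functional-group counts
#'
#' A validated container for visitation censuses: one row per observation
#' unit (site x season), one column per pollinator functional group, cells
#' holding non-negative integer counts of individual insects. This is the
#' input to all alpha- and beta-diversity analyses.
#'
#' All-zero rows (units that were surveyed but recorded no insects, or that
#' could not be sampled) are kept but flagged in `$units$empty`; distance
#' based analyses drop them with a notice.
#'
#' @param counts matrix or data.frame of non-negative integer counts,
#'   units x groups. Column names identify the functional groups.
#' @param site character vector of site labels, one per row.
#' @param season character vector, `"spring"` or `"summer"`, one per row.
#' @param morph floral morph displayed by each unit; defaults to the morph
#'   matching the season (the study plant's seasonal polyphenism).
#' @return object of class `"assemblage"`: a list with `counts` (integer
#'   matrix) and `units` (data.frame with site, season, morph, total, empty).
#' @examples
#' a <- assemblage_table(rbind(c(3, 7), c(5, 5)),
#'                       site = c("A", "B"), season = c("spring", "spring"))
#' a$units$total
#' @export
assemblage_table <- function(counts, site, season, morph = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) stop_bad("no observation units")
  storage.mode(counts) <- "double"
  counts <- check_counts(counts, "assemblage counts")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  if (length(site) != nrow(counts) || length(season) != nrow(counts))
    stop_bad("site/season metadata must have one entry per unit")
  season <- check_season(season)
  if (is.null(morph)) morph <- season else morph <- check_season(morph, "morph")
  units <- data.frame(site = as.character(site), season = season,
                      morph = morph, total = rowSums(counts),
                      empty = rowSums(counts) == 0,
                      stringsAsFactors = FALSE)
  rownames(counts) <- paste(units$site, units$season, sep = "_")
  structure(list(counts = counts, units = units), class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("Assemblage table: %d units x %d functional groups, %d insects\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  if (any(x$units$empty))
    cat("  empty (all-zero) units:",
        paste(rownames(x$counts)[x$units$empty], collapse = ", "), "\n")
  print(cbind(x$units[c("site", "season", "total")]))
  invisible(x)
}

#' Read an assemblage table from CSV
#'
#' Expects columns `site`, `season`, optionally `morph` and `total`, and one
#' column per functional group. Percentage tables are auto-detected: if row
#' sums are approximately 100 and a `total` column is present, cells are
#' converted to counts as `round(total * pct / 100)`. A percentage-like
#' table without a `total` column is rejected (counts cannot be recovered).
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @return an [assemblage_table()] object.
#' @export
read_assemblage <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_bad("no observation units in %s", path)
  if (!all(c("site", "season") %in% names(df)))
    stop_bad("assemblage CSV needs 'site' and 'season' columns")
  meta_cols <- intersect(c("site", "season", "morph", "total"), names(df))
  gcols <- setdiff(names(df), meta_cols)
  if (length(gcols) == 0) stop_bad("no functional-group columns found")
  m <- as.matrix(df[gcols])
  m[is.na(m)] <- 0
  if (any(m < 0)) stop_bad("negative cell in assemblage table")
  nonzero <- rowSums(m) > 0
  pct_like <- any(nonzero) &&
    all(abs(rowSums(m[nonzero, , drop = FALSE]) - 100) < 2)
  fractional <- any(abs(m - round(m)) > 1e-8)
  if (fractional && !(pct_like && "total" %in% names(df))) {
    if (pct_like)
      stop_bad("percentage table without a 'total' column: counts cannot be recovered")
    stop_bad("assemblage cells must be integer counts or percentages with totals")
  }
  if (pct_like && "total" %in% names(df)) {
    m <- round(m * df$total / 100)
    mism <- abs(rowSums(m) - df$total) > pmax(1, 0.01 * df$total)
    if (any(mism))
      message("note: reconstructed counts differ from stated totals for unit(s): ",
              paste(df$site[mism], df$season[mism], sep = "-", collapse = ", "))
  }
  assemblage_table(m, df$site, df$season,
                   morph = if ("morph" %in% names(df)) df$morph else NULL)
}

#' Preference-trial table
#'
#' One row per trial x functional group from a two-morph simultaneous
#' offering experiment: counts of open flowers of each morph during the
#' trial and the group's visits to each morph.
#'
#' @param df data.frame with columns `trial`, `site`, `season`, `group`,
#'   `flowers_spring`, `flowers_summer`, `visits_spring`, `visits_summer`.
#' @return validated data.frame of class `"preference_trials"`.
#' @export
preference_trials <- function(df) {
  need <- c("trial", "site", "season", "group", "flowers_spring",
            "flowers_summer", "visits_spring", "visits_summer")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop_bad("trials table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  df$season <- check_season(df$season)
  if (any(df$flowers_spring <= 0) || any(df$flowers_summer <= 0))
    stop_bad("flower availability must be > 0 for both morphs")
  df$visits_spring <- check_counts(df$visits_spring, "visits_spring")
  df$visits_summer <- check_counts(df$visits_summer, "visits_summer")
  fl <- unique(df[c("trial", "flowers_spring", "flowers_summer")])
  if (anyDuplicated(fl$trial))
    stop_bad("inconsistent flower counts within a trial")
  class(df) <- c("preference_trials", "data.frame")
  df
}

#' Single-visit outcome records
#'
#' One row per virgin flower exposed to exactly one pollinator visit:
#' which morph, which functional group, whether a fruit was set, and the
#' fate of every ovule (viable seed, unfertilised, aborted).
#'
#' @param df data.frame with columns `flower`, `morph`, `group`,
#'   `fruit_set` (logical or 0/1), `viable_seeds`, `unfertilised_ovules`,
#'   `aborted_seeds`.
#' @return validated data.frame of class `"single_visits"`.
#' @export
single_visits <- function(df) {
  need <- c("flower", "morph", "group", "fruit_set", "viable_seeds",
            "unfertilised_ovules", "aborted_seeds")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop_bad("single-visit table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  df$morph <- check_season(df$morph, "morph")
  df$fruit_set <- as.logical(df$fruit_set)
  if (any(is.na(df$fruit_set))) stop_bad("fruit_set must be logical or 0/1")
  for (col in c("viable_seeds", "unfertilised_ovules", "aborted_seeds"))
    df[[col]] <- check_counts(df[[col]], col)
  if (any(!df$fruit_set & df$viable_seeds > 0))
    stop_bad("viable_seeds must be 0 when fruit_set is FALSE")
  class(df) <- c("single_visits", "data.frame")
  df
}

#' Per-plant visitation surveys
#'
#' One row per survey x functional group: a timed watch of one plant
#' displaying one floral morph. The quantity component of effectiveness
#' (visits per plant per hour) is computed from these records.
#'
#' @param df data.frame with columns `survey`, `plant`, `morph`,
#'   `duration_min`, `group`, `visits`.
#' @return validated data.frame of class `"surveys"`.
#' @export
survey_table <- function(df) {
  need <- c("survey", "plant", "morph", "duration_min", "group", "visits")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop_bad("survey table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  df$morph <- check_season(df$morph, "morph")
  if (any(df$duration_min <= 0)) stop_bad("survey duration must be > 0")
  df$visits <- check_counts(df$visits, "visits")
  dur <- unique(df[c("survey", "duration_min", "morph")])
  if (anyDuplicated(dur$survey))
    stop_bad("inconsistent duration or morph within a survey")
  class(df) <- c("surveys", "data.frame")
  df
}

#' Write a domain table to CSV
#'
#' Writes any of the validated domain tables as a plain CSV that
#' round-trips through its reader: `read(write(x))` reproduces `x`.
#'
#' @param x an `assemblage`, `preference_trials`, `single_visits` or
#'   `surveys` object.
#' @param path output file path.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.assemblage <- function(x, path) {
  df <- cbind(x$units[c("site", "season", "morph")],
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_plain <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.preference_trials <- function(x, path) write_plain(x, path)
#' @export
write_table.single_visits <- function(x, path) {
  x$fruit_set <- as.integer(x$fruit_set)
  write_plain(x, path)
}
#' @export
write_table.surveys <- function(x, path) write_plain(x, path)

#' @rdname preference_trials
#' @param path CSV file path.
#' @export
read_trials <- function(path)
  preference_trials(utils::read.csv(path, stringsAsFactors = FALSE))

#' @rdname single_visits
#' @param path CSV file path.
#' @export
read_single_visits <- function(path)
  single_visits(utils::read.csv(path, stringsAsFactors = FALSE))

#' @rdname survey_table
#' @param path CSV file path.
#' @export
read_surveys <- function(path)
  survey_table(utils::read.csv(path, stringsAsFactors = FALSE))

#' Packaged field census of the study system
#'
#' Loads the packaged site x season visitation census of the two seasonal
#' floral morphs (six sites in SE Spain, 29 pollinator functional groups,
#' published as percentages with per-unit totals). Percentages are
#' converted back to integer counts on read.
#'
#' Known quirk of the published table, preserved as printed: the
#' per-population spring totals sum to 4785 while the printed pooled spring
#' total is 4625 (and similarly in summer). The reader reports, but does
#' not resolve, such mismatches.
#'
#' @return an [assemblage_table()] object (one all-zero summer unit is
#'   flagged `empty`).
#' @export
moricandia_assemblage <- function() {
  read_assemblage(system.file("extdata", "moricandia_assemblage.csv",
                              package = "effscape", mustWork = TRUE))
}
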