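test_that("assemblage construction validates counts and metadata", {
  a <- assemblage_table(rbind(c(3, 7)), site = "A", season = "spring")
  expect_equal(a$units$total, 10)
  expect_false(a$units$empty)

  expect_error(assemblage_table(rbind(c(-1, 2)), "A", "spring"), "negative")
  expect_error(assemblage_table(rbind(c(1.5, 2)), "A", "spring"), "integral")
  expect_error(assemblage_table(rbind(c(1, 2)), "A", "autumn"), "unknown season")
  expect_error(assemblage_table(matrix(numeric(0), 0, 2), character(0),
                                character(0)), "no observation units")

  z <- assemblage_table(rbind(c(2, 2), c(0, 0)), c("A", "B"),
                        c("spring", "spring"))
  expect_equal(z$units$empty, c(FALSE, TRUE))
})

test_that("all four table types round-trip through CSV", {
  sc <- tiny_scenario()
  tmp <- withr::local_tempdir()

  a <- gen_census(sc, sites = c("A", "B"), n_insects = 50)
  fa <- file.path(tmp, "assemblage.csv")
  write_table(a, fa)
  a2 <- read_assemblage(fa)
  expect_equal(a2$counts, a$counts, ignore_attr = FALSE)
  expect_equal(a2$units, a$units)

  tr <- gen_trials(sc, 5, "spring")
  ft <- file.path(tmp, "trials.csv")
  write_table(tr, ft)
  expect_equal(as.data.frame(read_trials(ft)), as.data.frame(tr))

  sv <- gen_single_visits(sc, n_flowers = 10)
  fs <- file.path(tmp, "single.csv")
  write_table(sv, fs)
  expect_equal(as.data.frame(read_single_visits(fs)), as.data.frame(sv))

  su <- gen_surveys(sc, n_surveys = 4)
  fu <- file.path(tmp, "surveys.csv")
  write_table(su, fu)
  expect_equal(as.data.frame(read_surveys(fu)), as.data.frame(su))
})

test_that("percentage tables are detected and converted via totals", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,season,total,g1,g2",
               "A,spring,200,75,25",
               "B,spring,100,40,60"), tmp)
  a <- read_assemblage(tmp)
  expect_equal(unname(a$counts[1, ]), c(150, 50))
  expect_equal(unname(a$counts[2, ]), c(40, 60))

  # percentage-like but no total column: unrecoverable
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,season,g1,g2", "A,spring,75.5,24.5"), tmp2)
  expect_error(read_assemblage(tmp2), "total")

  # empty file
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,season,g1,g2", tmp3)
  expect_error(read_assemblage(tmp3), "no observation units")

  # negative cell is a hard error
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,season,g1,g2", "A,spring,-1,5"), tmp4)
  expect_error(read_assemblage(tmp4), "negative")
})

test_that("packaged census reconstructs printed percentages to 0.1", {
  asm <- moricandia_assemblage()
  expect_equal(dim(asm$counts), c(12, 29))
  expect_equal(sum(asm$units$empty), 1)

  raw <- utils::read.csv(system.file("extdata", "moricandia_assemblage.csv",
                                     package = "effscape"))
  pct <- as.matrix(raw[paste0("g", 1:29)])
  keep <- raw$total > 0
  renorm <- 100 * asm$counts[keep, ] / raw$total[keep]
  expect_lt(max(abs(renorm - pct[keep, ])), 0.1)
})

test_that("trial and single-visit validators enforce their invariants", {
  df <- data.frame(trial = 1, site = "A", season = "spring", group = "bees",
                   flowers_spring = 10, flowers_summer = 12,
                   visits_spring = 3, visits_summer = 1)
  expect_s3_class(preference_trials(df), "preference_trials")
  bad <- df; bad$flowers_summer <- 0
  expect_error(preference_trials(bad), "availability")

  sv <- data.frame(flower = 1, morph = "spring", group = "bees",
                   fruit_set = FALSE, viable_seeds = 2,
                   unfertilised_ovules = 10, aborted_seeds = 8)
  expect_error(single_visits(sv), "viable_seeds")
  sv$fruit_set <- TRUE
  expect_s3_class(single_visits(sv), "single_visits")

  su <- data.frame(survey = 1, plant = "P1", morph = "spring",
                   duration_min = 0, group = "bees", visits = 2)
  expect_error(survey_table(su), "duration")
})
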