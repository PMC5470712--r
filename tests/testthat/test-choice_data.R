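test_that("reader groups rows into choice sets and derives the used index", {
  tab <- make_choice_table(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  d <- read_choice_table(path)
  expect_s3_class(d, "choice_data")
  expect_equal(nrow(d) / 3, 3)
  expect_equal(attr(d, "excluded"), 0L)
  # used position is taken from the role column, not row order
  da <- choicesel:::design_all(d, model_spec())
  for (i in seq_len(3)) {
    rows <- d[d$set_id == unique(d$set_id)[i], ]
    expect_equal(which(rows$role == "used"), da$used[i])
  }
})

test_that("incomplete sets are excluded with a count; duplicate used is an error", {
  tab <- make_choice_table(3)
  short <- rbind(tab, loc_row("s999", "used"))        # 1-row set
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(short, path, row.names = FALSE)
  expect_message(d <- read_choice_table(path), "1 incomplete")
  expect_equal(nrow(d) / 3, 3)
  expect_equal(attr(d, "excluded"), 1L)

  dup <- tab
  dup$role[dup$set_id == "s001"] <- c("used", "used", "available")
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_choice_table(path), "duplicate used")
})

test_that("schema errors name the missing column; schema mapping renames", {
  tab <- make_choice_table(2)
  names(tab)[names(tab) == "litter_depth"] <- "litter_cm"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_choice_table(path), "litter_depth")
  d <- read_choice_table(path, schema = c(litter_depth = "litter_cm"))
  expect_equal(nrow(d) / 3, 2)
})

test_that("understory percent unit flag rescales to a proportion", {
  tab <- make_choice_table(2)
  tab$understory_density <- tab$understory_density * 100
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  d <- read_choice_table(path, understory_unit = "percent")
  expect_true(all(d$understory_density >= 0 & d$understory_density <= 1))
})

test_that("writing then reading a table is lossless", {
  d <- generate_dataset(sim_config(preset = "recovery",
                                   n_individuals_per_stage = c(3L, 3L),
                                   sets_per_individual = 4L, seed = 5))$data
  path <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(d, path)
  d2 <- read_choice_table(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("stage assignment follows the developmental cutoffs", {
  expect_equal(assign_stage(3, FALSE), "early_dependent")
  expect_equal(assign_stage(7, FALSE), "early_dependent")
  expect_equal(assign_stage(8, FALSE), "late_dependent")   # day 8 -> late
  expect_equal(assign_stage(15, FALSE), "late_dependent")
  expect_equal(assign_stage(25, TRUE), "independent")
  expect_equal(assign_stage(2, TRUE), "independent")       # flag dominates
  expect_error(assign_stage(-1, FALSE), "nonnegative")
  # monotone in day for fixed flag: never early after late
  days <- 0:40
  st <- assign_stage(days, FALSE)
  expect_false(any(st == "early_dependent" & days > 7))
  expect_false(is.unsorted(match(st, c("early_dependent", "late_dependent"))))
})

test_that("one-per-brood filter is seeded, deterministic, brood-preserving", {
  d <- generate_dataset(sim_config(preset = "recovery",
                                   n_individuals_per_stage = c(8L, 8L),
                                   sets_per_individual = 3L,
                                   siblings_per_brood = 2L, seed = 9))$data
  n_broods <- length(unique(d$brood_id[d$stage != "nest"]))
  f1 <- filter_one_per_brood(d, seed = 42)
  f2 <- filter_one_per_brood(d, seed = 42)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(length(unique(f1$brood_id[f1$stage != "nest"])), n_broods)
  expect_equal(length(unique(f1$individual_id[f1$stage != "nest"])), n_broods)
  expect_equal(attr(f1, "broods_collapsed"), 4L)
  # single-individual broods are untouched
  d1 <- generate_dataset(sim_config(preset = "recovery",
                                    n_individuals_per_stage = c(4L, 4L),
                                    sets_per_individual = 3L, seed = 9))$data
  expect_equal(nrow(filter_one_per_brood(d1, 1)), nrow(d1))
})

test_that("z-score standardization is pooled, invertible and guarded", {
  d <- generate_dataset(sim_config(preset = "recovery",
                                   n_individuals_per_stage = c(4L, 4L),
                                   sets_per_individual = 5L, seed = 3))$data
  dn <- standardize_covariates(d, "none")
  expect_equal(as.data.frame(dn), as.data.frame(d), ignore_attr = TRUE)
  dz <- standardize_covariates(d, "zscore")
  for (v in all_covariates()) {
    expect_equal(mean(dz[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(dz[[v]]), 1, tolerance = 1e-12)
  }
  back <- unstandardize_covariates(dz)
  expect_equal(back$canopy_cover, d$canopy_cover, tolerance = 1e-10)
  dd <- d
  dd$litter_depth <- 3
  expect_error(standardize_covariates(dd), "litter_depth")
})

test_that("validation enforces the field-protocol invariants", {
  tab <- make_choice_table(2)
  bad <- tab; bad$canopy_cover[1] <- 140
  expect_error(choice_data(bad), "canopy_cover")
  bad <- tab; bad$sapling_density[2] <- -5
  expect_error(choice_data(bad), "negative")
  bad <- tab; bad$stage <- "nest"; bad$day_postfledge <- 3L
  expect_error(choice_data(bad), "day_postfledge")
  bad <- tab; bad$role[1:3] <- "available"
  expect_error(choice_data(bad), "exactly one used")
})
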