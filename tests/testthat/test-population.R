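test_that("a minimal two-row file reads into one complete MZ pair", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("individual_id", "pair_id", "zygosity", "uc", paste0("c", 0:20)),
          collapse = "\t"),
    paste(c("a1", "p1", "MZ", 0, rep(0, 21)), collapse = "\t"),
    paste(c("a2", "p1", "MZ", 0, rep(0, 21)), collapse = "\t")
  ), path)
  pop <- read_population(path)
  expect_equal(nrow(pop), 2)
  pairs <- twin_pairs(pop)
  expect_equal(pairs$n_members, 2)
  expect_equal(pairs$zygosity, "MZ")
  expect_equal(pgg_dialect(pop), "study2")
})

test_that("validation rejects out-of-range, non-integer, missing and duplicate entries", {
  pop <- tiny_population(n = 4)

  bad <- pop; bad$c3[2] <- 21L
  expect_error(validate_population(bad), "\\[0, 20\\].*c3.*2", class = "twinpgg_error")

  bad <- pop; bad$uc <- as.numeric(bad$uc); bad$uc[3] <- 5.5
  expect_error(validate_population(bad), "Non-integer.*uc.*3", class = "twinpgg_error")

  bad <- pop; bad$c7[1] <- NA_integer_
  expect_error(validate_population(bad), "Missing.*c7.*1", class = "twinpgg_error")

  bad <- pop; bad$individual_id[2] <- bad$individual_id[1]
  expect_error(validate_population(bad), "Duplicate", class = "twinpgg_error")

  bad <- pop; bad$zygosity[4] <- "XX"
  expect_error(validate_population(bad), "zygosity.*4", class = "twinpgg_error")

  bad <- pop; bad$pair_id <- "p001"
  expect_error(validate_population(bad), "more than two members", class = "twinpgg_error")
})

test_that("validation accepts every integer inside [0, endowment] (property)", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:20, 1) * 2
    sched <- matrix(sample(0:20, n * 21, replace = TRUE), n, 21)
    pop <- tiny_population(n = n, uc = sample(0:20, n, replace = TRUE), sched = sched)
    expect_silent(out <- validate_population(pop))
    expect_equal(nrow(out), n)
  }
})

test_that("write/read round-trips byte-identically and value-identically", {
  g <- generate_twin_population(synthetic_config(n_mz = 15, n_dz = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population(g$profiles, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(g$profiles))
  # canonical formatting: a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_population(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degenerate population sizes write and read correctly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- tiny_population(n = 2)[0, ]
  write_population(empty, path)
  expect_length(readLines(path), 1)  # header only
  expect_equal(nrow(read_population(path)), 0)

  one <- tiny_population(n = 1)
  write_population(one, path)
  expect_length(readLines(path), 2)  # header + 1 data row
  expect_equal(nrow(read_population(path)), 1)
})

test_that("study1 dialect round-trips with an empty c0 column", {
  pop <- tiny_population(n = 4, dialect = "study1")
  expect_equal(pgg_dialect(pop), "study1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population(pop, path)
  back <- read_population(path, dialect = "study1")
  expect_true(all(is.na(back$c0)))
  expect_error(read_population(path, dialect = "study2"), "dialect",
               class = "twinpgg_error")
})

test_that("comma-delimited input is accepted", {
  pop <- tiny_population(n = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- pop
  tab$c0 <- as.character(tab$c0)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  back <- read_population(path)
  expect_equal(back$uc, pop$uc)
})

test_that("complete_pairs keeps exactly the two-member pairs, order preserved", {
  pop <- tiny_population(n = 9)  # p005 is a singleton
  kept <- complete_pairs(pop)
  expect_equal(nrow(kept), 8)
  expect_equal(kept$individual_id, pop$individual_id[1:8])

  pairs <- twin_pairs(pop)
  expect_equal(nrow(complete_pairs(pairs)), 4)

  singletons <- pop[c(1, 3, 5), ]
  expect_equal(nrow(complete_pairs(singletons)), 0)

  # mixed fixture: count equals the number of 2-member pairs
  mixed <- pop[c(1, 2, 3, 5, 6, 8), ]  # p001 complete, p003 complete, others partial
  expect_equal(nrow(complete_pairs(mixed)), 4)
})

test_that("game config enforces the social-dilemma condition and reads key/value files", {
  expect_error(game_config(multiplier = 4), "social dilemma", class = "twinpgg_error")
  expect_error(game_config(multiplier = 1), "social dilemma", class = "twinpgg_error")
  expect_error(game_config(group_size = 1), class = "twinpgg_error")
  expect_error(game_config(endowment = 0), class = "twinpgg_error")

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# web experiment", "group_size: 4", "multiplier: 2",
               "endowment: 20", "dialect: study2"), path)
  cfg <- read_game_config(path)
  expect_equal(cfg$multiplier, 2)
  expect_equal(attr(cfg, "dialect"), "study2")
  path2 <- withr::local_tempfile(fileext = ".cfg")
  writeLines("mystery: 1", path2)
  expect_error(read_game_config(path2), "Unknown", class = "twinpgg_error")
})
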