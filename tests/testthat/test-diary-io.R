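test_that("a well-formed file reads with all rows accepted", {
  path <- write_fixture(make_entries(3))
  d <- read_diaries(path)
  expect_s3_class(d, "chw_diaries")
  expect_equal(nrow(d), 3)
  expect_equal(nrow(rejected_rows(d)), 0)
  expect_equal(attr(d, "n_input"), 3)
})

test_that("rows with unknown codes are rejected with a categorised reason", {
  entries <- make_entries(3)
  entries$activity_code[2] <- "XYZ"
  d <- read_diaries(write_fixture(entries))
  expect_equal(nrow(d), 2)
  rej <- rejected_rows(d)
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "activity_code")
})

test_that("validation is total: accepted + rejected = input rows", {
  entries <- make_entries(8)
  entries$activity_code[2] <- "bogus"
  entries$travel_minutes[3] <- NA
  entries$activity_minutes[4] <- -5
  entries$day_index[5] <- 12
  entries$recipient_types[6] <- "adult;elderly;family;infant"
  entries$condition_codes[7] <- "hiv;notacondition"
  d <- diary_dataset(entries)
  rej <- rejected_rows(d)
  expect_equal(nrow(d) + nrow(rej), 8)
  expect_setequal(rej$row, 2:7)
  expect_true(all(nzchar(rej$reason)))
  # one categorised reason each
  expect_match(rej$reason[rej$row == 3], "travel")
  expect_match(rej$reason[rej$row == 5], "day_index")
  expect_match(rej$reason[rej$row == 6], "recipients")
})

test_that("a missing mandatory column is a hard error naming the column", {
  entries <- make_entries(3)
  entries$travel_minutes <- NULL
  path <- write_fixture(entries)
  expect_error(read_diaries(path), "travel_minutes")
  expect_error(diary_dataset(entries), "travel_minutes")
})

test_that("schema_config maps nonstandard headers", {
  entries <- make_entries(3)
  names(entries)[names(entries) == "chw_id"] <- "worker"
  path <- write_fixture(entries)
  expect_error(read_diaries(path), "chw_id")
  d <- read_diaries(path, schema_config = c(chw_id = "worker"))
  expect_equal(nrow(d), 3)
  expect_error(read_diaries(path, schema_config = c(chw_id = "nope")),
               "nope")
})

test_that("write/read round-trips datasets exactly", {
  small <- diary_dataset(make_entries(1))
  p1 <- tempfile(fileext = ".csv")
  write_diaries(small, p1)
  expect_length(readLines(p1), 2) # header + one episode

  empty <- diary_dataset(make_entries(0))
  p0 <- tempfile(fileext = ".csv")
  write_diaries(empty, p0)
  expect_length(readLines(p0), 1) # header only

  # 500 generated entries incl. multi-valued fields round-trip identically
  big <- generate_diaries(default_config("umzinyathi", "deep_rural",
                                         n_chws = 7, seed = 42))
  expect_gt(nrow(big), 400)
  p <- tempfile(fileext = ".csv")
  write_diaries(big, p)
  back <- read_diaries(p)
  expect_equal(as.data.frame(back), as.data.frame(big))
  # a second write is bit-identical
  p2 <- tempfile(fileext = ".csv")
  write_diaries(back, p2)
  expect_identical(readLines(p2), readLines(p))
  # tab-separated round-trip too
  pt <- tempfile(fileext = ".tsv")
  write_diaries(big, pt, sep = "\t")
  expect_equal(as.data.frame(read_diaries(pt)), as.data.frame(big))
})

test_that("unwritable paths are hard errors", {
  d <- diary_dataset(make_entries(2))
  expect_error(write_diaries(d, file.path(tempdir(), "no", "such", "dir",
                                          "f.csv")))
})

test_that("combined_minutes sums travel and activity time", {
  expect_equal(combined_minutes(make_entries(1, travel = 15,
                                             activity = 40)), 55)
  expect_equal(combined_minutes(make_entries(1, travel = 0,
                                             activity = 0)), 0)
  # published uMzinyathi peri-urban home-visit medians: 15 + 40 = 55
  expect_equal(combined_minutes(data.frame(travel_minutes = 15,
                                           activity_minutes = 40)), 55)
})
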