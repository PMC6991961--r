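test_that("generation is deterministic given the seed", {
  cfg <- default_config("sedibeng", "rural", n_chws = 5, seed = 7)
  d1 <- generate_diaries(cfg)
  d2 <- generate_diaries(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # byte-identical serialized output
  p1 <- tempfile(); p2 <- tempfile()
  write_diaries(d1, p1); write_diaries(d2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed changes the draw
  d3 <- generate_diaries(default_config("sedibeng", "rural", n_chws = 5,
                                        seed = 8))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("zero dispersion collapses durations onto the configured medians", {
  cfg <- default_config("umzinyathi", "peri_urban", n_chws = 4,
                        dispersion = 0, seed = 3)
  d <- generate_diaries(cfg)
  tu <- ref_time_use()
  tu <- tu[tu$district == "umzinyathi" & tu$site_class == "peri_urban", ]
  for (i in seq_len(nrow(tu))) {
    idx <- d$activity_code == tu$activity_code[i]
    if (!any(idx)) next
    expect_true(all(d$travel_minutes[idx] == tu$travel_median[i]))
    expect_true(all(d$activity_minutes[idx] == tu$activity_median[i]))
  }
})

test_that("configured medians are recovered from large samples", {
  # home-visit travel median configured at 20 recovered within +-1 minute
  cfg <- default_config("umzinyathi", "deep_rural", n_chws = 100, seed = 11)
  d <- generate_diaries(cfg)
  hv <- d$activity_code == "home_visit"
  expect_gt(sum(hv), 5000)
  expect_lt(abs(median(d$travel_minutes[hv]) - 20), 1)
  expect_lt(abs(median(d$activity_minutes[hv]) - 60), 60 * 0.1)

  # every activity with >= 500 episodes recovers both medians within 10%
  tu <- ref_time_use()
  tu <- tu[tu$district == "umzinyathi" & tu$site_class == "deep_rural", ]
  for (i in seq_len(nrow(tu))) {
    idx <- d$activity_code == tu$activity_code[i]
    if (sum(idx) < 500) next
    expect_lt(abs(median(d$travel_minutes[idx]) - tu$travel_median[i]),
              max(1, 0.1 * tu$travel_median[i]))
    expect_lt(abs(median(d$activity_minutes[idx]) - tu$activity_median[i]),
              max(1, 0.1 * tu$activity_median[i]))
  }
})

test_that("categorical frequencies are recovered within 3 points", {
  cfg <- default_config("sedibeng", "peri_urban", n_chws = 60, seed = 5)
  d <- generate_diaries(cfg)
  hv <- d[d$activity_code %in% home_visit_codes("sedibeng"), ]
  expect_gt(nrow(hv), 2000)
  comp <- ref_composition()
  # conditions: one code per visit drawn from the normalised frequencies
  cond <- comp[comp$district == "sedibeng" & comp$site_class == "peri_urban" &
                 comp$dimension == "condition", ]
  expected <- cond$pct / sum(cond$pct)
  observed <- table(factor(hv$condition_codes, levels = cond$code))
  observed <- as.numeric(observed) / sum(observed)
  expect_true(all(abs(observed - expected) < 0.03))
  # content: independent occurrence rates per visit
  cont <- comp[comp$district == "sedibeng" & comp$site_class == "peri_urban" &
                 comp$dimension == "content", ]
  toks <- strsplit(hv$content_codes, ";", fixed = TRUE)
  for (i in seq_len(nrow(cont))) {
    rate <- mean(vapply(toks, function(x) cont$code[i] %in% x, logical(1)))
    expect_lt(abs(rate - cont$pct[i] / 100), 0.03)
  }
})

test_that("default_config carries the published district parameters", {
  cfg <- default_config("umzinyathi", "deep_rural")
  hv <- Filter(function(p) p$activity_code == "home_visit",
               cfg$profiles)[[1]]
  expect_equal(hv$travel_median, 20)
  expect_equal(hv$activity_median, 60)

  sed <- default_config("sedibeng", "peri_urban")
  reg <- Filter(function(p) p$activity_code == "household_registration",
                sed$profiles)[[1]]
  expect_equal(unname(reg$content_probs["screening"]), 0.40)

  umz <- default_config("umzinyathi", "peri_urban")
  hv2 <- Filter(function(p) p$activity_code == "home_visit",
                umz$profiles)[[1]]
  expect_equal(unname(hv2$recipient_probs["adult"]), 0.49)

  # activity probabilities sum to one
  for (c in list(cfg, sed, umz)) {
    expect_equal(sum(vapply(c$profiles, `[[`, numeric(1), "probability")),
                 1, tolerance = 1e-12)
  }
})

test_that("invalid configurations are hard errors", {
  expect_error(default_config("sedibeng", "deep_rural"), "not sampled")
  expect_error(default_config("gauteng", "rural"), "unknown district")
  p1 <- activity_profile("other", 0.6, 10, 10)
  p2 <- activity_profile("meeting", 0.6, 10, 10)
  expect_error(generator_config("sedibeng", "rural", list(p1, p2), 5),
               "sum to 1")
  expect_error(activity_profile("other", 0.5, 0, 10), "median")
  expect_error(activity_profile("other", 0.5, 10, 10,
                                condition_probs = c(hiv = -0.2)),
               "condition_probs")
})
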