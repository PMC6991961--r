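test_that("annualize applies straight-line depreciation with allocation", {
  infra <- data.frame(unit_cost = 490000, quantity = 22, life_years = 15,
                      allocation_share = 0.35)
  expect_equal(annualize(infra), 251533, tolerance = 1e-5) # published 251,533
  kit <- data.frame(unit_cost = 510, quantity = 481, life_years = 2,
                    allocation_share = 1)
  expect_equal(annualize(kit), 122655)
  zero <- data.frame(unit_cost = 100, quantity = 0, life_years = 5,
                     allocation_share = 1)
  expect_equal(annualize(zero), 0)
  bad <- data.frame(unit_cost = 1, quantity = 1, life_years = 0,
                    allocation_share = 1)
  expect_error(annualize(bad), "life_years")
})

test_that("published line items reconstruct the district totals", {
  umz <- summarize_costs(ref_cost_model("umzinyathi"), "district")
  expect_equal(umz$subtotal, 14404985)
  expect_equal(umz$total, 14404985) # no overheads in uMzinyathi
  expect_equal(round_half_up(umz$per_chw), 29948)

  sed <- ref_cost_model("sedibeng")
  hp <- summarize_costs(sed, "health_posts")
  expect_equal(hp$subtotal, 20657492)
  expect_equal(round_half_up(hp$overhead_amount), 1652599)
  expect_lt(abs(hp$total - 22310091), 1)
  fac <- summarize_costs(sed, "facilities")
  expect_lt(abs(fac$total - 21779100), 1)

  dc <- district_costs(sed)
  expect_lt(abs(dc$total - 44089191), 1)
  expect_equal(round_half_up(dc$per_capita), 47)
})

test_that("unit-cost-derived lines agree with published lines to 2e-4", {
  for (d in districts()) {
    m <- ref_cost_model(d)
    derived <- annualize(m$ingredients)
    published <- m$ingredients$annual_cost
    expect_true(all(abs(derived - published) / published < 2e-4))
  }
})

test_that("totals are scale-equivariant and overhead-consistent", {
  m <- ref_cost_model("sedibeng")
  base <- summarize_costs(m, "health_posts", use_published = FALSE)
  k <- 2.5
  m2 <- m
  m2$ingredients$unit_cost <- m$ingredients$unit_cost * k
  m2$ingredients$annual_cost <- NA_real_
  scaled <- summarize_costs(m2, "health_posts", use_published = FALSE)
  expect_equal(scaled$total, k * base$total)
  expect_equal(scaled$per_chw, k * base$per_chw)
  d2 <- district_costs(m2, use_published = FALSE)
  d1 <- district_costs(m, use_published = FALSE)
  expect_equal(d2$per_capita, k * d1$per_capita)
  # total / subtotal = 1 + overhead rate, exactly
  expect_equal(base$total / base$subtotal, 1.08)
  expect_equal(scaled$total / scaled$subtotal, 1.08)
})

test_that("class_share reports expenditure shares against the total", {
  sed <- district_costs(ref_cost_model("sedibeng"))
  expect_equal(round(class_share(sed, "training"), 1), 2.3) # published 2.3%
  umz <- district_costs(ref_cost_model("umzinyathi"))
  # computed from the printed line items; the published text says 5.8%
  expect_equal(round(class_share(umz, "training"), 1), 4.0)
  hp <- summarize_costs(ref_cost_model("sedibeng"), "health_posts")
  all_classes <- unique(ref_cost_ingredients("sedibeng")$cost_class)
  expect_equal(class_share(hp, all_classes), 100 / 1.08)
  expect_equal(class_share(hp, character(0)), 0)
})

test_that("to_usd converts at the model's fixed rate", {
  expect_equal(to_usd(14.3), 1)
  expect_equal(round(to_usd(6000)), 420)   # published $420
  expect_equal(round(to_usd(3500)), 245)   # published $245
  expect_equal(to_usd(143, ref_cost_model("sedibeng")), 10)
  expect_error(to_usd(100, -1), "positive")
})

test_that("cost model construction validates its inputs", {
  ing <- ref_cost_ingredients("umzinyathi")
  expect_error(cost_model("x", ing[, -1], 100, 5), "name")
  expect_error(cost_model("x", ing, 0, 5), "population")
  bad <- ing
  bad$life_years[bad$category == "recurrent"][1] <- 3
  expect_error(cost_model("x", bad, 100, 5), "recurrent")
  m <- cost_model("x", ing, 100, 5)
  expect_error(summarize_costs(m, "nope"), "no such panel")
})
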