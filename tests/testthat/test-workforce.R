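test_that("visit needs and required hours invert each other", {
  inputs <- ref_workforce_inputs()
  for (cell in inputs) {
    profile <- service_time_profile(cell$district, cell$site_class,
                                    cell$minutes_per_visit)
    needs <- derive_visit_needs(profile, cell$hours_per_100k)
    back <- required_hours(needs, profile)
    expect_equal(unname(back$hours_by_service),
                 unname(cell$hours_per_100k), tolerance = 1e-12)
  }
  # published per-service hours: registration 1,295 h at 35 min/visit
  sp <- inputs$sedibeng_peri_urban
  profile <- service_time_profile("sedibeng", "peri_urban",
                                  sp$minutes_per_visit)
  needs <- derive_visit_needs(profile, sp$hours_per_100k)
  expect_equal(unname(needs$visits_per_100k["registration"]),
               1295 * 60 / 35)
  expect_equal(required_hours(needs, profile)$total_hours, 66623)
  # chronic in peri-urban uMzinyathi: 44,589 h at 72 min/visit
  up <- inputs$umzinyathi_peri_urban
  pu <- service_time_profile("umzinyathi", "peri_urban",
                             up$minutes_per_visit)
  nu <- derive_visit_needs(pu, up$hours_per_100k)
  expect_equal(unname(nu$visits_per_100k["chronic"]), 44589 * 60 / 72)
  # zero hours give zero visits; doubling visits doubles hours
  zero <- derive_visit_needs(profile,
                             0 * sp$hours_per_100k)
  expect_true(all(zero$visits_per_100k == 0))
  doubled <- visit_needs(2 * needs$visits_per_100k)
  expect_equal(required_hours(doubled, profile)$total_hours, 2 * 66623)
  expect_error(derive_visit_needs(profile, c(registration = 1)), "missing")
})

test_that("available hours multiply duty time by the home-visit share", {
  expect_equal(available_hours(workforce_params(200, 6, 0.66, 2)), 792)
  expect_equal(available_hours(workforce_params(200, 6, 0.57, 2)), 684)
  expect_equal(available_hours(workforce_params(200, 8, 0.55, 1)), 880)
  expect_equal(available_hours(workforce_params(200, 8, 0.49, 1)), 784)
  expect_equal(available_hours(workforce_params(200, 8, 1, 1)), 1600)
})

test_that("chws_required rounds half away from zero and scales with pairing", {
  expect_equal(chws_required(66623, 792, 2)$chws_required, 168)
  expect_equal(chws_required(173530, 784, 1)$chws_required, 221)
  expect_equal(chws_required(792, 792, 1)$chws_required, 1)
  expect_error(chws_required(100, 0, 1), "positive")
  # monotonicity in workload, team size and availability
  base <- chws_required(50000, 800, 1)$chws_required_unrounded
  expect_gte(chws_required(60000, 800, 1)$chws_required_unrounded, base)
  expect_gte(chws_required(50000, 800, 2)$chws_required_unrounded, base)
  expect_lte(chws_required(50000, 900, 1)$chws_required_unrounded, base)
})

test_that("relative requirements use the unrounded ratio", {
  wf <- ref_workforce_requirements()
  rel_sed <- relative_requirement(wf$by_site$sedibeng_peri_urban,
                                  wf$by_site$sedibeng_rural)
  expect_equal(rel_sed$percent, 33)
  rel_umz <- relative_requirement(wf$by_site$umzinyathi_peri_urban,
                                  wf$by_site$umzinyathi_deep_rural)
  expect_equal(rel_umz$percent, 62)
  # note: the rounded counts 221/137 would give 61%, not the published 62%
  expect_identical(
    relative_requirement(wf$by_site$sedibeng_rural,
                         wf$by_site$sedibeng_rural)$percent, 0)
})

test_that("households per CHW scale down with the requirement ratio", {
  expect_equal(households_per_chw(250, 1), 250)
  expect_equal(households_per_chw(250, 222.92398 / 168.23990), 169)
  expect_equal(households_per_chw(250, 221.33929 / 136.98750), 96)
  expect_error(households_per_chw(250, 0.9), "reference")
  # strictly decreasing in the ratio
  ratios <- seq(1, 1.8, by = 0.1)
  hh <- vapply(ratios, households_per_chw, numeric(1),
               base_households = 250)
  expect_true(all(diff(hh) < 0))
})

test_that("utilization rates are per-capita divisions with additive totals", {
  rec <- data.frame(site_class = "peri_urban", clinic_headcount = 3100,
                    home_visit_headcount = 400, population = 1000)
  u <- utilization_rates(rec)
  expect_equal(u$clinic_rate, 3.1)
  expect_equal(u$home_rate, 0.4)
  expect_equal(u$total_contacts, 3.5)
  zero <- utilization_rates(data.frame(site_class = "rural",
                                       clinic_headcount = 0,
                                       home_visit_headcount = 0,
                                       population = 50))
  expect_equal(zero$total_contacts, 0)
  set.seed(2)
  rand <- data.frame(site_class = "x",
                     clinic_headcount = sample(1e5, 20),
                     home_visit_headcount = sample(1e5, 20),
                     population = sample(1e4, 20))
  ur <- utilization_rates(rand)
  expect_equal(ur$total_contacts, ur$clinic_rate + ur$home_rate)
  expect_error(utilization_rates(data.frame(site_class = "x",
                                            clinic_headcount = 1,
                                            home_visit_headcount = 1,
                                            population = 0)),
               "population")
  # reference records reproduce the published per-capita rates
  pub <- utilization_rates(ref_utilization())
  expect_equal(pub$clinic_rate, c(2, 1.7, 3.2, 3.1))
  expect_equal(pub$home_rate, c(1, 0.4, 0.7, 0.4))
})
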