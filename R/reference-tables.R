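#' Published reference parameters for the two study districts
#'
#' These tables carry the published district-level inputs the toolkit ships
#' with: median travel/activity minutes and share-of-time percentages per
#' activity and site class, home-visit composition percentages (content,
#' conditions, recipients), cost-ingredient line items with annualization
#' rules, district financial parameters, per-service workforce inputs, and
#' facility/home-visit utilization rates. They parameterize the synthetic
#' diary generator ([default_config()]) and the worked cost/workforce
#' reconstructions.
#'
#' @return A data.frame (or list, for [ref_district_config()]); see each
#'   function's section below.
#' @name reference_tables
NULL

#' @describeIn reference_tables Median travel/activity minutes and percent
#'   share of combined time per activity, by district and site class. Share
#'   columns within each (district, site class) cell total 100; activities
#'   the published table showed as 0% carry small residual shares so the
#'   cell still totals 100.
#' @export
ref_time_use <- function() {
  tu <- function(district, site_class, code, travel, activity, share) {
    data.frame(district = district, site_class = site_class,
               activity_code = code, travel_median = travel,
               activity_median = activity, share_pct = share,
               stringsAsFactors = FALSE)
  }
  rbind(
    # Sedibeng, peri-urban. Home visits (registration + screening + other)
    # take 66% of combined time; the split across the three home-visit rows
    # is not published and is taken as equal thirds.
    tu("sedibeng", "peri_urban", "household_registration", 15, 19, 22),
    tu("sedibeng", "peri_urban", "household_screening",    15, 15, 22),
    tu("sedibeng", "peri_urban", "home_visit_other",       15, 20, 22),
    tu("sedibeng", "peri_urban", "facility_visit",         15, 25, 23),
    tu("sedibeng", "peri_urban", "support_group",          28, 10, 0.4),
    tu("sedibeng", "peri_urban", "creche_ecd",             20, 15, 0.4),
    tu("sedibeng", "peri_urban", "other_institution",      10, 10, 0.4),
    tu("sedibeng", "peri_urban", "health_day",             15, 20, 0.4),
    tu("sedibeng", "peri_urban", "school_health",          18, 53, 0.4),
    tu("sedibeng", "peri_urban", "meeting",                30, 330, 1),
    tu("sedibeng", "peri_urban", "other",                  17, 24, 8),
    # Sedibeng, rural (farm sites). Creche medians were not published for
    # rural sites; the peri-urban medians stand in.
    tu("sedibeng", "rural", "household_registration", 15, 24, 19),
    tu("sedibeng", "rural", "household_screening",    17, 23, 19),
    tu("sedibeng", "rural", "home_visit_other",       15, 20, 19),
    tu("sedibeng", "rural", "facility_visit",         30, 30, 29),
    tu("sedibeng", "rural", "support_group",          16, 34, 1),
    tu("sedibeng", "rural", "creche_ecd",             20, 15, 1),
    tu("sedibeng", "rural", "other_institution",      25, 10, 1 / 3),
    tu("sedibeng", "rural", "health_day",             20, 15, 1 / 3),
    tu("sedibeng", "rural", "school_health",          10, 21, 1 / 3),
    tu("sedibeng", "rural", "meeting",               165, 225, 3),
    tu("sedibeng", "rural", "other",                   9, 30, 8),
    # uMzinyathi, peri-urban.
    tu("umzinyathi", "peri_urban", "home_visit",     15, 40, 55),
    tu("umzinyathi", "peri_urban", "facility_visit", 25, 120, 18),
    tu("umzinyathi", "peri_urban", "phila_mtwana",   30, 360, 15),
    tu("umzinyathi", "peri_urban", "creche_ecd",     27, 50, 1),
    tu("umzinyathi", "peri_urban", "campaign",       20, 150, 2),
    tu("umzinyathi", "peri_urban", "meeting",        20, 40, 3),
    tu("umzinyathi", "peri_urban", "war_room",       30, 122, 2),
    tu("umzinyathi", "peri_urban", "training",       35, 51, 2),
    tu("umzinyathi", "peri_urban", "support_group",  30, 55, 1),
    tu("umzinyathi", "peri_urban", "other",          16, 43, 1),
    # uMzinyathi, deep-rural.
    tu("umzinyathi", "deep_rural", "home_visit",     20, 60, 49),
    tu("umzinyathi", "deep_rural", "facility_visit", 30, 115, 13),
    tu("umzinyathi", "deep_rural", "phila_mtwana",   30, 425, 16),
    tu("umzinyathi", "deep_rural", "creche_ecd",     23, 73, 2),
    tu("umzinyathi", "deep_rural", "campaign",       20, 235, 3),
    tu("umzinyathi", "deep_rural", "meeting",        30, 100, 4),
    tu("umzinyathi", "deep_rural", "war_room",       35, 188, 2),
    tu("umzinyathi", "deep_rural", "training",       30, 120, 5),
    tu("umzinyathi", "deep_rural", "support_group",  30, 95, 1),
    tu("umzinyathi", "deep_rural", "other",          15, 40, 5)
  )
}

#' @describeIn reference_tables Home-visit composition percentages by
#'   district, site class and dimension (`content`, `condition`,
#'   `recipient`). Content percentages are per-visit occurrence rates and do
#'   not total 100; condition and recipient percentages are relative code
#'   frequencies as published (columns total 99-118 before normalisation).
#' @export
ref_composition <- function() {
  block <- function(district, site_class, dimension, codes, pct) {
    data.frame(district = district, site_class = site_class,
               dimension = dimension, code = codes, pct = pct,
               stringsAsFactors = FALSE)
  }
  sed_content <- c("screening", "health_education", "bring_medicines",
                   "tracing_defaulters", "hbc", "referral", "dots", "other")
  umz_content <- c("screening", "health_education", "bring_medicines",
                   "referral", "child_health", "hbc", "tracing_defaulters",
                   "dots", "other")
  cond <- condition_codes()
  rec <- recipient_codes()
  rbind(
    block("sedibeng", "peri_urban", "content", sed_content,
          c(40, 30, 28, 4, 3, 4, 3, 4)),
    block("sedibeng", "rural", "content", sed_content,
          c(30, 19, 18, 26, 7, 3, 2, 7)),
    block("umzinyathi", "peri_urban", "content", umz_content,
          c(26, 34, 12, 2, 8, 9, 5, 5, 3)),
    block("umzinyathi", "deep_rural", "content", umz_content,
          c(23, 49, 7, 12, 12, 8, 6, 4, 5)),
    block("sedibeng", "peri_urban", "condition", cond,
          c(7, 20, 20, 45, 3, 12, 5, 4)),
    block("sedibeng", "rural", "condition", cond,
          c(4, 21, 38, 26, 5, 8, 5, 3)),
    block("umzinyathi", "peri_urban", "condition", cond,
          c(13, 11, 11, 28, 14, 20, 5, 2)),
    block("umzinyathi", "deep_rural", "condition", cond,
          c(14, 18, 14, 19, 19, 23, 10, 1)),
    block("sedibeng", "peri_urban", "recipient", rec,
          c(4, 2, 2, 5, 5, 48, 30, 12, 1, 1)),
    block("sedibeng", "rural", "recipient", rec,
          c(2, 1, 1, 4, 10, 59, 23, 14, 0, 3)),
    block("umzinyathi", "peri_urban", "recipient", rec,
          c(3, 3, 3, 9, 4, 49, 7, 12, 5, 4)),
    block("umzinyathi", "deep_rural", "recipient", rec,
          c(6, 6, 4, 19, 11, 47, 9, 14, 2, 0))
  )
}

#' @describeIn reference_tables Cost-ingredient line items for a district.
#'   One row per priced item: panel, category (`setup`/`recurrent`), cost
#'   class, unit cost (ZAR), quantity, life years, allocation share and the
#'   published annualized district cost. The published annualized values are
#'   authoritative for reconstructions (the published unit costs are rounded
#'   and can differ from `unit_cost x quantity x share / life_years` by up to
#'   about 0.02%).
#' @param district District name.
#' @export
ref_cost_ingredients <- function(district) {
  district <- match_district(district)
  ing <- function(name, panel, category, cost_class, unit_cost, quantity,
                  life_years, allocation_share, annual_cost, role = NA) {
    data.frame(name = name, panel = panel, category = category,
               cost_class = cost_class, unit_cost = unit_cost,
               quantity = quantity, life_years = life_years,
               allocation_share = allocation_share,
               annual_cost = annual_cost, role = role,
               stringsAsFactors = FALSE)
  }
  if (district == "sedibeng") {
    hp <- rbind(
      ing("Infrastructure", "health_posts", "setup", "infrastructure",
          490000, 22, 15, 0.35, 251533),
      ing("Equipment: Health Post", "health_posts", "setup", "equipment",
          39200, 22, 15, 0.35, 20123),
      ing("Equipment: kits", "health_posts", "setup", "equipment",
          2495, 424, 2, 1, 528940),
      ing("Training: CHWs", "health_posts", "setup", "training",
          6000, 424, 5, 1, 508800),
      ing("Asst Dr", "health_posts", "recurrent", "salary",
          426000, 1, 1, 0.5, 213000),
      ing("Professional Nurses", "health_posts", "recurrent", "salary",
          46423, 22, 1, 0.55, 561721),
      ing("Staff Nurses", "health_posts", "recurrent", "salary",
          251244, 22, 1, 1, 5527375),
      ing("CHW WBOTs", "health_posts", "recurrent", "salary",
          30000, 424, 1, 1, 12720000, role = "chw_stipend"),
      ing("Health Post Maintenance", "health_posts", "recurrent",
          "maintenance", 10000, 22, 1, 1, 220000),
      ing("Kit replenishment", "health_posts", "recurrent", "supplies",
          250, 424, 1, 1, 106000)
    )
    fac <- rbind(
      ing("Equipment: kits", "facilities", "setup", "equipment",
          2495, 424, 2, 1, 528940),
      ing("Training CHWs", "facilities", "setup", "training",
          6000, 424, 5, 1, 508800),
      ing("Asst Dr", "facilities", "recurrent", "salary",
          426000, 1, 1, 0.5, 213000),
      ing("Professional Nurses", "facilities", "recurrent", "salary",
          46423, 22, 1, 0.55, 561718),
      ing("Staff Nurses", "facilities", "recurrent", "salary",
          251244, 22, 1, 1, 5527375),
      ing("CHW WBOTs", "facilities", "recurrent", "salary",
          30000, 424, 1, 1, 12720000, role = "chw_stipend"),
      ing("Kit replenishment", "facilities", "recurrent", "supplies",
          250, 424, 1, 1, 106000)
    )
    return(rbind(hp, fac))
  }
  rbind(
    ing("Training/Supervision", "district", "setup", "training",
        2000, 6, 5, 1, 2400),
    ing("Training CHWs", "district", "setup", "training",
        6000, 481, 5, 1, 577200),
    ing("Car for community health facilitators", "district", "setup",
        "transport", 350000, 6, 5, 1, 420000),
    ing("Kit", "district", "setup", "equipment",
        510, 481, 2, 1, 122655),
    ing("Jacket, umbrella and coolerbox", "district", "setup", "equipment",
        477, 481, 1, 1, 229466),
    ing("District CHW co-ordinator", "district", "recurrent", "salary",
        426000, 1, 1, 1, 426000),
    ing("Community health facilitator", "district", "recurrent", "salary",
        177660, 6, 1, 1, 1065957),
    ing("CHW supervisor", "district", "recurrent", "salary",
        27600, 16, 1, 1, 441600, role = "supervisor_stipend"),
    ing("CHW", "district", "recurrent", "salary",
        21600, 481, 1, 1, 10389600, role = "chw_stipend"),
    ing("Kit replenishment", "district", "recurrent", "supplies",
        671, 481, 1, 1, 322751),
    ing("Transport supervisors", "district", "recurrent", "transport",
        101839, 4, 1, 1, 407356)
  )
}

#' @describeIn reference_tables District financial and organisational
#'   parameters: total population, overhead rate (8% in Sedibeng, none in
#'   uMzinyathi), CHWs per cost panel, PHC expenditure per capita (ZAR/year),
#'   the ZAR/USD exchange rate, and current monthly stipends.
#' @export
ref_district_config <- function(district) {
  district <- match_district(district)
  if (district == "sedibeng") {
    list(district = "sedibeng", population = 935831, overhead_rate = 0.08,
         n_chw = c(health_posts = 424, facilities = 424),
         phc_per_capita = 1200, exchange_rate = 14.3,
         chw_stipend_month = 2500, supervisor_stipend_month = NA_real_)
  } else {
    list(district = "umzinyathi", population = 513974, overhead_rate = 0,
         n_chw = c(district = 481),
         phc_per_capita = 1150, exchange_rate = 14.3,
         chw_stipend_month = 1800, supervisor_stipend_month = 2300)
  }
}

#' @describeIn reference_tables Workforce-model inputs per (district, site
#'   class): median combined minutes per home visit and required hours per
#'   service per 100,000 population (at 70% coverage), plus duty parameters
#'   (200 duty days/year; 6 h/day in Sedibeng vs 8 in uMzinyathi; share of
#'   CHW time on home visits; CHWs per visit -- pairs in Sedibeng).
#' @export
ref_workforce_inputs <- function() {
  svc <- c("registration", "screening", "mother_under5", "hiv_tb",
           "chronic", "other")
  cell <- function(district, site_class, minutes, hours, hours_per_day,
                   share, team) {
    list(district = district, site_class = site_class,
         services = svc,
         minutes_per_visit = stats::setNames(minutes, svc),
         hours_per_100k = stats::setNames(hours, svc),
         days_per_year = 200, hours_per_day = hours_per_day,
         share_home_visits = share, chws_per_visit = team,
         coverage = 0.70)
  }
  list(
    sedibeng_peri_urban = cell("sedibeng", "peri_urban",
      c(35, 35, 36, 35, 35, 39), c(1295, 1295, 21419, 18579, 24022, 13),
      6, 0.66, 2),
    sedibeng_rural = cell("sedibeng", "rural",
      c(40, 40, 40, 35, 45, 50), c(1480, 1480, 23799, 18579, 30885, 17),
      6, 0.57, 2),
    umzinyathi_peri_urban = cell("umzinyathi", "peri_urban",
      c(85, 35, 71, 61, 72, 110), c(5441, 7169, 23339, 39974, 44589, 38),
      8, 0.55, 1),
    umzinyathi_deep_rural = cell("umzinyathi", "deep_rural",
      c(75, 90, 110, 90, 89, 120), c(4801, 18434, 36159, 58978, 55117, 42),
      8, 0.49, 1)
  )
}

#' @describeIn reference_tables Synthetic utilization records back-derived
#'   from the published per-capita rates (clinic and home-visit headcounts on
#'   a 100,000-population base per site class). The original DHIS extract is
#'   not public; these records reproduce the published rates exactly.
#' @export
ref_utilization <- function() {
  data.frame(
    district = c("sedibeng", "sedibeng", "umzinyathi", "umzinyathi"),
    site_class = c("peri_urban", "rural", "peri_urban", "deep_rural"),
    clinic_headcount = c(200000, 170000, 320000, 310000),
    home_visit_headcount = c(100000, 40000, 70000, 40000),
    population = rep(100000, 4),
    stringsAsFactors = FALSE
  )
}
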