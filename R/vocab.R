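#' Controlled vocabularies for CHW diary records
#'
#' Diary records use fixed code lists for site classes, activities, home-visit
#' content, conditions addressed and visit recipients. Activity vocabularies
#' differ by district because the two service-delivery models expose CHWs to
#' different tasks (e.g. Phila Mtwana nutrition centres and war rooms exist
#' only in uMzinyathi; health posts only in Sedibeng).
#'
#' @param district Optional district name (`"sedibeng"` or `"umzinyathi"`).
#'   When given, only the codes valid for that district's diary are returned.
#' @return Character vector of valid codes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
site_classes <- function() {
  c("peri_urban", "rural", "deep_rural")
}

#' @rdname vocabularies
#' @export
districts <- function() {
  c("sedibeng", "umzinyathi")
}

.sedibeng_activities <- c(
  "household_registration", "household_screening", "home_visit_other",
  "facility_visit", "support_group", "creche_ecd", "other_institution",
  "health_day", "school_health", "meeting", "other"
)

.umzinyathi_activities <- c(
  "home_visit", "facility_visit", "phila_mtwana", "creche_ecd", "campaign",
  "meeting", "war_room", "training", "support_group", "other"
)

#' @rdname vocabularies
#' @export
activity_codes <- function(district = NULL) {
  if (is.null(district)) {
    return(union(.sedibeng_activities, .umzinyathi_activities))
  }
  district <- match_district(district)
  switch(district,
    sedibeng   = .sedibeng_activities,
    umzinyathi = .umzinyathi_activities
  )
}

#' @rdname vocabularies
#' @export
content_codes <- function() {
  c("screening", "health_education", "bring_medicines", "tracing_defaulters",
    "hbc", "referral", "dots", "child_health", "other")
}

#' @rdname vocabularies
#' @export
condition_codes <- function() {
  c("mother_child", "hiv", "tb", "chronic", "nutrition", "fp",
    "other", "unknown")
}

#' @rdname vocabularies
#' @export
recipient_codes <- function() {
  c("pregnant", "postnatal", "infant", "age1_5", "age5_18", "adult",
    "elderly", "family", "community", "unknown")
}

#' Activity codes that count as home visits
#'
#' Visit-composition tables (content, conditions, recipients) are defined over
#' home-visit episodes only. In Sedibeng the diary splits home visits into
#' registration, screening and other; in uMzinyathi a single home-visit row is
#' used.
#'
#' @param district District name.
#' @return Character vector of home-visit activity codes for the district.
#' @export
home_visit_codes <- function(district) {
  district <- match_district(district)
  switch(district,
    sedibeng   = c("household_registration", "household_screening",
                   "home_visit_other"),
    umzinyathi = "home_visit"
  )
}

#' Site classes sampled in a district
#'
#' Sedibeng diaries cover peri-urban and rural (farm) sites; uMzinyathi covers
#' peri-urban and deep-rural sites.
#'
#' @param district District name.
#' @return Character vector of site classes.
#' @export
district_site_classes <- function(district) {
  district <- match_district(district)
  switch(district,
    sedibeng   = c("peri_urban", "rural"),
    umzinyathi = c("peri_urban", "deep_rural")
  )
}

# Normalise district spelling; hard error on unknown districts.
match_district <- function(district) {
  d <- tolower(gsub("[ -]", "", as.character(district)))
  if (identical(d, "sedibeng")) return("sedibeng")
  if (d %in% c("umzinyathi", "umzinyathi")) return("umzinyathi")
  stop("unknown district: '", district,
       "' (expected one of: ", paste(districts(), collapse = ", "), ")",
       call. = FALSE)
}

#' Round half away from zero
#'
#' Display rounding convention for currency, headcounts and whole-percent
#' headlines (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
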