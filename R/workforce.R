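#' Per-service home-visit time profile
#'
#' Median combined (travel + activity) minutes per home visit, by service
#' type, for one geography.
#'
#' @param district District name.
#' @param site_class Site class.
#' @param minutes_per_visit Named numeric vector of minutes per visit, all
#'   positive; names are service types (registration, screening,
#'   mother_under5, hiv_tb, chronic, other).
#' @return Object of class `chw_service_profile`.
#' @export
service_time_profile <- function(district, site_class, minutes_per_visit) {
  if (is.null(names(minutes_per_visit)) || any(minutes_per_visit <= 0)) {
    stop("minutes_per_visit must be a named vector of positive minutes",
         call. = FALSE)
  }
  structure(list(district = district, site_class = site_class,
                 minutes_per_visit = minutes_per_visit),
            class = "chw_service_profile")
}

#' Modelled home-visit needs per 100,000 population
#'
#' Annual home visits required per service type per 100,000 total
#' population, at a given coverage of population need. The upstream
#' demographic/burden-of-disease model that produces these counts is not
#' re-implemented; counts are inputs, and [derive_visit_needs()] back-derives
#' them from per-service required hours so the packaged reconstructions are
#' self-contained.
#'
#' @param visits_per_100k Named non-negative numeric vector per service type.
#' @param coverage Fraction of modelled need assumed covered (default 0.70).
#' @return Object of class `chw_visit_needs`.
#' @export
visit_needs <- function(visits_per_100k, coverage = 0.70) {
  if (is.null(names(visits_per_100k)) || any(visits_per_100k < 0)) {
    stop("visits_per_100k must be a named vector of non-negative counts",
         call. = FALSE)
  }
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  structure(list(visits_per_100k = visits_per_100k, coverage = coverage),
            class = "chw_visit_needs")
}

#' Duty-time parameters for the workforce model
#'
#' @param days_per_year CHW duty days per year (200 in both districts).
#' @param hours_per_day Duty hours per day (6 in Sedibeng's 30-hour week, 8
#'   in uMzinyathi's 40-hour week).
#' @param share_home_visits Observed share of CHW time spent on home visits,
#'   in `[0, 1]`.
#' @param chws_per_visit CHWs per home visit (2 in Sedibeng, where CHWs work
#'   in pairs for security; 1 in uMzinyathi).
#' @return Object of class `chw_workforce_params`.
#' @export
workforce_params <- function(days_per_year = 200, hours_per_day,
                             share_home_visits, chws_per_visit = 1) {
  stopifnot(days_per_year > 0, hours_per_day > 0, chws_per_visit >= 1,
            share_home_visits > 0, share_home_visits <= 1)
  structure(list(days_per_year = days_per_year,
                 hours_per_day = hours_per_day,
                 share_home_visits = share_home_visits,
                 chws_per_visit = chws_per_visit),
            class = "chw_workforce_params")
}

#' Back-derive visit needs from per-service required hours
#'
#' `visits(s) = hours(s) * 60 / minutes_per_visit(s)`. Inverse of
#' [required_hours()].
#'
#' @param profile A [service_time_profile()].
#' @param hours_by_service Named vector of required hours per 100,000 per
#'   service; must cover the profile's services.
#' @param coverage Coverage fraction stored on the result.
#' @return A [visit_needs()] object.
#' @export
derive_visit_needs <- function(profile, hours_by_service, coverage = 0.70) {
  stopifnot(inherits(profile, "chw_service_profile"))
  svc <- names(profile$minutes_per_visit)
  missing <- setdiff(svc, names(hours_by_service))
  if (length(missing) > 0) {
    stop("hours_by_service is missing service(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  visits <- hours_by_service[svc] * 60 / profile$minutes_per_visit
  visit_needs(visits, coverage = coverage)
}

#' Annual home-visit hours required per 100,000 population
#'
#' `hours(s) = visits(s) * minutes_per_visit(s) / 60`, summed over services.
#'
#' @param needs A [visit_needs()] object.
#' @param profile A [service_time_profile()] with matching service names.
#' @return List with `hours_by_service` and `total_hours`.
#' @export
required_hours <- function(needs, profile) {
  stopifnot(inherits(needs, "chw_visit_needs"),
            inherits(profile, "chw_service_profile"))
  svc <- names(profile$minutes_per_visit)
  missing <- setdiff(svc, names(needs$visits_per_100k))
  if (length(missing) > 0) {
    stop("visit needs missing service(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hours <- needs$visits_per_100k[svc] * profile$minutes_per_visit / 60
  list(hours_by_service = hours, total_hours = sum(hours))
}

#' Annual CHW hours available for home visits
#'
#' `days_per_year * hours_per_day * share_home_visits`: of a CHW's duty
#' time, only the observed home-visit share is available for visits; the
#' remainder goes to facility time, meetings, campaigns and other duties.
#'
#' @param params A [workforce_params()] object.
#' @return Hours per CHW per year.
#' @export
available_hours <- function(params) {
  stopifnot(inherits(params, "chw_workforce_params"))
  params$days_per_year * params$hours_per_day * params$share_home_visits
}

#' CHWs required to cover the home-visit workload
#'
#' `total_hours / available * chws_per_visit`; working in pairs doubles the
#' requirement. The unrounded value is retained (it drives the
#' households-per-CHW norm); the headline count is rounded to the nearest
#' integer, half away from zero.
#'
#' @param total_hours Annual home-visit hours required (per 100,000
#'   population).
#' @param available Annual hours available per CHW ([available_hours()]).
#' @param chws_per_visit CHWs per home visit.
#' @return Object of class `chw_workforce`: list with `chws_required`
#'   (rounded), `chws_required_unrounded`, `total_hours`,
#'   `available_hours_per_chw`, `chws_per_visit`.
#' @export
chws_required <- function(total_hours, available, chws_per_visit = 1) {
  if (available <= 0) stop("available hours must be positive", call. = FALSE)
  unrounded <- total_hours / available * chws_per_visit
  structure(list(chws_required = round_half_up(unrounded),
                 chws_required_unrounded = unrounded,
                 total_hours = total_hours,
                 available_hours_per_chw = available,
                 chws_per_visit = chws_per_visit),
            class = "chw_workforce")
}

#' Run the workforce model for one geography
#'
#' Convenience wrapper: [required_hours()] then [chws_required()].
#'
#' @param needs A [visit_needs()] object.
#' @param profile A [service_time_profile()].
#' @param params A [workforce_params()] object.
#' @return A `chw_workforce` object with `hours_by_service` attached.
#' @export
workforce_requirement <- function(needs, profile, params) {
  rh <- required_hours(needs, profile)
  res <- chws_required(rh$total_hours, available_hours(params),
                       params$chws_per_visit)
  res$hours_by_service <- rh$hours_by_service
  res
}

#' Relative CHW requirement between two geographies
#'
#' Percent more CHWs required in one geography than a reference, from the
#' ratio of *unrounded* requirements (the published headline percentages
#' round this ratio: 222.92/168.24 gives 33%, 221.34/136.99 gives 62%).
#'
#' @param result_ref,result_other `chw_workforce` objects computed on the
#'   same population base.
#' @return List with `percent` (whole-percent headline), `ratio`
#'   (unrounded).
#' @export
relative_requirement <- function(result_ref, result_other) {
  stopifnot(inherits(result_ref, "chw_workforce"),
            inherits(result_other, "chw_workforce"))
  if (result_ref$chws_required_unrounded <= 0) {
    stop("reference requirement must be positive", call. = FALSE)
  }
  ratio <- result_other$chws_required_unrounded /
    result_ref$chws_required_unrounded
  list(percent = round_half_up(100 * (ratio - 1)), ratio = ratio)
}

#' Households-per-CHW coverage norm
#'
#' Scales the guideline norm of households one CHW covers (250 in peri-urban
#' areas) down by the extra staffing a geography needs: a site needing
#' `ratio` times the CHWs covers `base * (1 - (ratio - 1))` households per
#' CHW, using the unrounded requirement ratio.
#'
#' @param base_households Guideline households per CHW in the reference
#'   (peri-urban) geography; default 250.
#' @param unrounded_ratio Unrounded requirement ratio versus the reference
#'   (>= 1; see [relative_requirement()]).
#' @return Households per CHW, rounded to the nearest household.
#' @export
households_per_chw <- function(base_households = 250, unrounded_ratio) {
  if (base_households <= 0) stop("base must be positive", call. = FALSE)
  if (unrounded_ratio < 1) {
    stop("ratio must be >= 1: the reference must be the lower-need site",
         call. = FALSE)
  }
  round_half_up(base_households * (1 - (unrounded_ratio - 1)))
}

#' Per-capita service utilization rates
#'
#' Clinic and home-visit headcounts per capita per year from routine
#' facility records, plus their sum (total PHC contacts per capita).
#'
#' @param records data.frame with columns `site_class`, `clinic_headcount`,
#'   `home_visit_headcount`, `population` (and optionally `district`).
#' @return data.frame with `clinic_rate`, `home_rate`, `total_contacts`
#'   appended.
#' @export
utilization_rates <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("site_class", "clinic_headcount", "home_visit_headcount",
              "population")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("utilization records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$population <= 0)) {
    stop("population must be positive in every record", call. = FALSE)
  }
  records$clinic_rate <- records$clinic_headcount / records$population
  records$home_rate <- records$home_visit_headcount / records$population
  records$total_contacts <- records$clinic_rate + records$home_rate
  records
}

#' Workforce reconstruction for the four study geographies
#'
#' Runs the full workforce model on the published inputs
#' ([ref_workforce_inputs()]) and returns, per geography, the available
#' hours, total required hours, CHWs required (rounded and unrounded), and
#' the relative requirements and households-per-CHW norms.
#'
#' @return List with `by_site` (one `chw_workforce` per geography),
#'   `available_hours`, `chws_required`, `relative` (percent more CHWs in
#'   the rural/deep-rural site of each district) and `households` (norms for
#'   peri-urban, rural, deep-rural).
#' @export
ref_workforce_requirements <- function() {
  inputs <- ref_workforce_inputs()
  by_site <- lapply(inputs, function(cell) {
    profile <- service_time_profile(cell$district, cell$site_class,
                                    cell$minutes_per_visit)
    needs <- derive_visit_needs(profile, cell$hours_per_100k,
                                coverage = cell$coverage)
    params <- workforce_params(cell$days_per_year, cell$hours_per_day,
                               cell$share_home_visits, cell$chws_per_visit)
    workforce_requirement(needs, profile, params)
  })
  rel_sed <- relative_requirement(by_site$sedibeng_peri_urban,
                                  by_site$sedibeng_rural)
  rel_umz <- relative_requirement(by_site$umzinyathi_peri_urban,
                                  by_site$umzinyathi_deep_rural)
  list(
    by_site = by_site,
    available_hours = vapply(by_site, `[[`, numeric(1),
                             "available_hours_per_chw"),
    chws_required = vapply(by_site, `[[`, numeric(1), "chws_required"),
    relative = c(sedibeng_rural = rel_sed$percent,
                 umzinyathi_deep_rural = rel_umz$percent),
    households = c(peri_urban = households_per_chw(250, 1),
                   rural = households_per_chw(250, rel_sed$ratio),
                   deep_rural = households_per_chw(250, rel_umz$ratio))
  )
}

#' @export
print.chw_workforce <- function(x, ...) {
  cat("CHW workforce requirement (per 100,000 population)\n")
  cat(sprintf("  home-visit hours required: %s\n",
              format(round(x$total_hours), big.mark = ",")))
  cat(sprintf("  hours available per CHW:   %g\n",
              x$available_hours_per_chw))
  cat(sprintf("  CHWs per visit:            %g\n", x$chws_per_visit))
  cat(sprintf("  CHWs required:             %d (unrounded %.2f)\n",
              as.integer(x$chws_required), x$chws_required_unrounded))
  invisible(x)
}
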