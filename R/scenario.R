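#' Stipend scenario definition
#'
#' @param district District name.
#' @param current_stipend Current CHW stipend, ZAR per month (> 0).
#' @param new_stipend Modelled stipend, ZAR per month (default 3500, the
#'   national minimum wage).
#' @param raise_supervisors If `TRUE`, supervisor stipend lines below the
#'   new stipend are raised to it as well (default `FALSE`).
#' @param current_supervisor_stipend Supervisor stipend, ZAR per month; only
#'   used when `raise_supervisors = TRUE`.
#' @return Object of class `chw_stipend_scenario`.
#' @export
stipend_scenario <- function(district, current_stipend, new_stipend = 3500,
                             raise_supervisors = FALSE,
                             current_supervisor_stipend = NA_real_) {
  stopifnot(current_stipend > 0, new_stipend > 0)
  structure(list(district = district, current_stipend = current_stipend,
                 new_stipend = new_stipend,
                 raise_supervisors = raise_supervisors,
                 current_supervisor_stipend = current_supervisor_stipend),
            class = "chw_stipend_scenario")
}

#' Apply a stipend change to a cost model
#'
#' Rescales the CHW stipend line in every panel to `12 * new_stipend *
#' quantity`, reapplies the overhead rate to the new subtotal, and recomputes
#' all district cost metrics. Stipend lines are identified by the `role`
#' column (`"chw_stipend"`, and `"supervisor_stipend"` when supervisors are
#' raised); models without a `role` column fall back to matching line names
#' against `stipend_pattern`.
#'
#' @param model A `chw_cost_model`.
#' @param scenario A [stipend_scenario()].
#' @param stipend_pattern Regex fallback to find CHW stipend lines by name.
#' @return Object of class `chw_scenario`: list with
#'   `pct_stipend_increase`, `baseline_total`, `new_total`,
#'   `pct_district_increase`, `per_capita_before`, `per_capita_after`,
#'   `phc_share_before`, `phc_share_after`, and the modified model.
#' @export
apply_stipend <- function(model, scenario,
                          stipend_pattern = "^CHW( WBOTs)?$") {
  stopifnot(inherits(model, "chw_cost_model"),
            inherits(scenario, "chw_stipend_scenario"))
  before <- district_costs(model)
  ing <- model$ingredients
  is_chw <- !is.na(ing$role) & ing$role == "chw_stipend"
  if (!any(is_chw)) is_chw <- grepl(stipend_pattern, ing$name)
  if (!any(is_chw)) {
    stop("no CHW stipend line found in the model", call. = FALSE)
  }
  annual_new <- 12 * scenario$new_stipend
  ing$unit_cost[is_chw] <- annual_new
  ing$annual_cost[is_chw] <- annual_new * ing$quantity[is_chw] *
    ing$allocation_share[is_chw]
  if (isTRUE(scenario$raise_supervisors)) {
    sup <- !is.na(ing$role) & ing$role == "supervisor_stipend" &
      ing$unit_cost < annual_new
    ing$unit_cost[sup] <- annual_new
    ing$annual_cost[sup] <- annual_new * ing$quantity[sup] *
      ing$allocation_share[sup]
  }
  new_model <- model
  new_model$ingredients <- ing
  after <- district_costs(new_model)
  structure(list(
    district = model$district,
    current_stipend = scenario$current_stipend,
    new_stipend = scenario$new_stipend,
    pct_stipend_increase =
      100 * (scenario$new_stipend / scenario$current_stipend - 1),
    baseline_total = before$total,
    new_total = after$total,
    pct_district_increase = 100 * (after$total / before$total - 1),
    per_capita_before = before$per_capita,
    per_capita_after = after$per_capita,
    phc_share_before = before$phc_share,
    phc_share_after = after$phc_share,
    model = new_model
  ), class = "chw_scenario")
}

#' @export
print.chw_scenario <- function(x, ...) {
  cat(sprintf("Stipend scenario: %s, R%s -> R%s per month\n", x$district,
              format(x$current_stipend, big.mark = ","),
              format(x$new_stipend, big.mark = ",")))
  cat(sprintf("  stipend increase:        %.0f%%\n",
              round_half_up(x$pct_stipend_increase)))
  cat(sprintf("  district expenditure:    R%s -> R%s (+%.1f%%)\n",
              format(round_half_up(x$baseline_total), big.mark = ","),
              format(round_half_up(x$new_total), big.mark = ","),
              x$pct_district_increase))
  cat(sprintf("  per capita:              R%.0f -> R%.0f\n",
              round_half_up(x$per_capita_before),
              round_half_up(x$per_capita_after)))
  cat(sprintf("  share of PHC spend:      %.1f%% -> %.1f%%\n",
              x$phc_share_before, x$phc_share_after))
  invisible(x)
}
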