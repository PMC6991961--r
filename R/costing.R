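#' Build a district cost model
#'
#' An ingredient-based cost model: named panels of priced line items plus the
#' district parameters needed to turn annualized line costs into totals,
#' per-capita and per-CHW metrics and the share of primary-health-care (PHC)
#' expenditure.
#'
#' @param district District name (free text; the two study districts have
#'   ready-made models via [ref_cost_model()]).
#' @param ingredients data.frame of line items with columns `name`, `panel`,
#'   `category` (`"setup"` or `"recurrent"`), `cost_class`, `unit_cost`,
#'   `quantity`, `life_years`, `allocation_share`, and optionally
#'   `annual_cost` (a published annualized value that overrides the derived
#'   one) and `role` (e.g. `"chw_stipend"`).
#' @param population District population (> 0).
#' @param n_chw Named vector of CHWs per panel (or a scalar for a
#'   single-panel model).
#' @param overhead_rate Proportional overhead mark-up on each panel subtotal
#'   (e.g. 0.08).
#' @param phc_per_capita Annual PHC expenditure per capita (ZAR).
#' @param exchange_rate ZAR per USD (default 14.3).
#' @return An object of class `chw_cost_model`.
#' @export
cost_model <- function(district, ingredients, population, n_chw,
                       overhead_rate = 0, phc_per_capita = NA_real_,
                       exchange_rate = 14.3) {
  stopifnot(population > 0, overhead_rate >= 0, exchange_rate > 0)
  ingredients <- as.data.frame(ingredients, stringsAsFactors = FALSE)
  needed <- c("name", "panel", "category", "cost_class", "unit_cost",
              "quantity", "life_years", "allocation_share")
  missing <- setdiff(needed, names(ingredients))
  if (length(missing) > 0) {
    stop("ingredients table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"annual_cost" %in% names(ingredients)) {
    ingredients$annual_cost <- NA_real_
  }
  if (!"role" %in% names(ingredients)) ingredients$role <- NA_character_
  if (any(ingredients$unit_cost < 0)) {
    stop("unit costs must be non-negative", call. = FALSE)
  }
  if (any(ingredients$life_years <= 0)) {
    stop("life_years must be positive", call. = FALSE)
  }
  bad_rec <- ingredients$category == "recurrent" & ingredients$life_years != 1
  if (any(bad_rec)) {
    stop("recurrent ingredient(s) must have life_years = 1: ",
         paste(ingredients$name[bad_rec], collapse = ", "), call. = FALSE)
  }
  panels <- unique(ingredients$panel)
  if (length(n_chw) == 1 && is.null(names(n_chw))) {
    n_chw <- stats::setNames(rep(n_chw, length(panels)), panels)
  }
  if (!all(panels %in% names(n_chw)) || any(n_chw <= 0)) {
    stop("n_chw must be a positive count for every panel", call. = FALSE)
  }
  structure(list(district = district, ingredients = ingredients,
                 population = population, n_chw = n_chw,
                 overhead_rate = overhead_rate,
                 phc_per_capita = phc_per_capita,
                 exchange_rate = exchange_rate),
            class = "chw_cost_model")
}

#' Ready-made cost model for a study district
#'
#' Assembles [cost_model()] from the published ingredient and district
#' parameter tables ([ref_cost_ingredients()], [ref_district_config()]).
#'
#' @param district `"sedibeng"` or `"umzinyathi"`.
#' @return A `chw_cost_model`.
#' @export
ref_cost_model <- function(district) {
  cfg <- ref_district_config(district)
  cost_model(cfg$district, ref_cost_ingredients(district),
             population = cfg$population, n_chw = cfg$n_chw,
             overhead_rate = cfg$overhead_rate,
             phc_per_capita = cfg$phc_per_capita,
             exchange_rate = cfg$exchange_rate)
}

#' Annualize a capital line item by straight-line depreciation
#'
#' Annual cost of an ingredient: `unit_cost * quantity * allocation_share /
#' life_years`. Recurrent items have `life_years = 1`, so the same formula
#' covers both categories.
#'
#' @param ingredient A one-row data.frame (or list) with `unit_cost`,
#'   `quantity`, `life_years`, `allocation_share`; vectorised over rows of a
#'   multi-row data.frame.
#' @return Annualized cost(s), ZAR per year.
#' @export
annualize <- function(ingredient) {
  ly <- ingredient$life_years
  if (any(ly <= 0)) stop("life_years must be positive", call. = FALSE)
  ingredient$unit_cost * ingredient$quantity *
    ingredient$allocation_share / ly
}

# Line values for a set of ingredients: published annualized values where
# available (use_published = TRUE), otherwise derived from unit costs.
line_values <- function(ingredients, use_published = TRUE) {
  derived <- annualize(ingredients)
  if (use_published) {
    ifelse(is.na(ingredients$annual_cost), derived, ingredients$annual_cost)
  } else {
    derived
  }
}

#' Summarize costs for one panel of a cost model
#'
#' Annualizes every line in the panel, applies the overhead mark-up to the
#' subtotal, and derives the per-CHW cost. Per-capita and PHC-share metrics
#' are district-level quantities (all panels combined); use
#' [district_costs()] for those.
#'
#' @param model A `chw_cost_model`.
#' @param panel Panel name.
#' @param use_published Use published annualized line values where present
#'   (default); `FALSE` recomputes every line from unit costs.
#' @return An object of class `chw_cost_summary`: list with `lines` (named
#'   annualized costs), `subtotal`, `overhead_amount`, `total`, `per_chw`,
#'   `class_totals`, `class_shares` (percent of total by cost class),
#'   `overhead_rate`, `n_chw`.
#' @export
summarize_costs <- function(model, panel, use_published = TRUE) {
  stopifnot(inherits(model, "chw_cost_model"))
  ing <- model$ingredients[model$ingredients$panel == panel, , drop = FALSE]
  if (nrow(ing) == 0) {
    stop("no such panel: '", panel, "' (available: ",
         paste(unique(model$ingredients$panel), collapse = ", "), ")",
         call. = FALSE)
  }
  lines <- stats::setNames(line_values(ing, use_published), ing$name)
  subtotal <- sum(lines)
  overhead <- subtotal * model$overhead_rate
  total <- subtotal + overhead
  class_totals <- tapply(lines, ing$cost_class, sum)
  structure(list(district = model$district, panel = panel, lines = lines,
                 cost_class = stats::setNames(ing$cost_class, ing$name),
                 subtotal = subtotal, overhead_amount = overhead,
                 total = total, per_chw = total / model$n_chw[[panel]],
                 class_totals = class_totals,
                 class_shares = 100 * as.numeric(class_totals) / total,
                 overhead_rate = model$overhead_rate,
                 n_chw = model$n_chw[[panel]]),
            class = "chw_cost_summary")
}

#' District-level cost metrics across all panels
#'
#' Combines every panel of the model: district total (with overheads),
#' per-capita cost, overall per-CHW cost, and the district cost as a percent
#' of PHC expenditure per capita.
#'
#' @param model A `chw_cost_model`.
#' @param use_published Passed to [summarize_costs()].
#' @return List with `panel_summaries`, `total`, `per_capita`, `per_chw`,
#'   `phc_share`, `total_usd`.
#' @export
district_costs <- function(model, use_published = TRUE) {
  panels <- unique(model$ingredients$panel)
  sums <- lapply(panels, summarize_costs, model = model,
                 use_published = use_published)
  names(sums) <- panels
  total <- sum(vapply(sums, `[[`, numeric(1), "total"))
  per_capita <- total / model$population
  list(district = model$district, panel_summaries = sums, total = total,
       per_capita = per_capita,
       per_chw = total / sum(model$n_chw),
       phc_share = 100 * per_capita / model$phc_per_capita,
       total_usd = to_usd(total, model))
}

#' Share of panel expenditure in given cost classes
#'
#' Percent of a panel's total annualized cost (including overheads in the
#' denominator) falling in the given cost classes, e.g. `"training"`.
#'
#' @param summary A `chw_cost_summary` (or the result of
#'   [district_costs()], in which case lines are pooled across panels).
#' @param classes Character vector of cost classes.
#' @return Percent in `[0, 100]`; an empty class set gives 0.
#' @export
class_share <- function(summary, classes) {
  if (length(classes) == 0) return(0)
  if (inherits(summary, "chw_cost_summary")) {
    lines <- summary$lines
    cls <- summary$cost_class
    total <- summary$total
  } else {
    lines <- unlist(lapply(summary$panel_summaries, `[[`, "lines"))
    cls <- unlist(lapply(summary$panel_summaries, `[[`, "cost_class"))
    total <- summary$total
  }
  100 * sum(lines[cls %in% classes]) / total
}

#' Convert ZAR to USD at the model's fixed exchange rate
#'
#' @param amount Amount in ZAR.
#' @param model A `chw_cost_model` (or a number taken as the ZAR/USD rate).
#' @return Amount in USD.
#' @export
to_usd <- function(amount, model = 14.3) {
  rate <- if (inherits(model, "chw_cost_model")) model$exchange_rate else model
  if (!is.numeric(rate) || rate <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  amount / rate
}

#' @export
print.chw_cost_summary <- function(x, ...) {
  cat(sprintf("Cost summary: %s / %s (%d CHWs)\n", x$district, x$panel,
              x$n_chw))
  w <- max(nchar(names(x$lines)))
  for (nm in names(x$lines)) {
    cat(sprintf("  %-*s %14s\n", w, nm,
                format(round_half_up(x$lines[[nm]]), big.mark = ",")))
  }
  cat(sprintf("  %-*s %14s\n", w, "Subtotal",
              format(round_half_up(x$subtotal), big.mark = ",")))
  cat(sprintf("  %-*s %14s\n", w,
              sprintf("Overheads@%g%%", 100 * x$overhead_rate),
              format(round_half_up(x$overhead_amount), big.mark = ",")))
  cat(sprintf("  %-*s %14s\n", w, "Total",
              format(round_half_up(x$total), big.mark = ",")))
  cat(sprintf("  per CHW: R%s\n",
              format(round_half_up(x$per_chw), big.mark = ",")))
  invisible(x)
}
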