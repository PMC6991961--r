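#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving diary generation and bootstrap
#'   inference.
#' @param diaries Optional path to a diary CSV; when `NULL` (default) the
#'   four study geographies are simulated with [default_config()].
#' @param alpha Significance level used to flag table cells (default 0.05).
#' @param n_boot Bootstrap resamples for median-difference tests.
#' @param new_stipend Scenario stipend, ZAR/month.
#' @return Object of class `chw_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, diaries = NULL, alpha = 0.05,
                       n_boot = 500, new_stipend = 3500) {
  stopifnot(alpha > 0, alpha < 1, n_boot >= 99)
  if (!is.null(diaries) && !file.exists(diaries)) {
    stop("diary file not found: ", diaries, call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 diaries = diaries, alpha = alpha, n_boot = n_boot,
                 new_stipend = new_stipend),
            class = "chw_run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage from one configuration: diary acquisition
#' (read or simulate), time-use tables (medians, shares, composition) with
#' significance tests, cost summaries for both districts, utilization rates,
#' the workforce-requirement and households-per-CHW tables, and the
#' minimum-wage stipend scenario. Writes one CSV per report table plus a
#' JSON run manifest (package version, seed, input digests) and a structured
#' log, and is deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the report file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "chw_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_msg <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  out <- function(name) file.path(config$out_dir, name)
  write_report <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    name
  }
  files <- character(0)

  # -- diaries ---------------------------------------------------------
  if (is.null(config$diaries)) {
    sites <- list(c("sedibeng", "peri_urban"), c("sedibeng", "rural"),
                  c("umzinyathi", "peri_urban"),
                  c("umzinyathi", "deep_rural"))
    parts <- lapply(seq_along(sites), function(i) {
      cfg <- default_config(sites[[i]][1], sites[[i]][2],
                            seed = config$seed + i)
      as.data.frame(generate_diaries(cfg))
    })
    diaries <- diary_dataset(do.call(rbind, parts),
                             provenance = sprintf("simulated(seed=%d)",
                                                  config$seed))
    log_msg("diaries", sprintf("simulated %d episodes for %d geographies",
                               nrow(diaries), length(sites)))
  } else {
    diaries <- read_diaries(config$diaries)
    log_msg("diaries", sprintf("read %d episodes (%d rejected) from %s",
                               nrow(diaries), nrow(rejected_rows(diaries)),
                               config$diaries))
  }
  write_diaries(diaries, out("diaries.csv"))
  files <- c(files, "diaries.csv")

  # -- time use --------------------------------------------------------
  med <- summarize_times(diaries)
  files <- c(files, write_report(med, "table1_time_medians.csv"))
  shares <- share_of_time(diaries)
  shares$share <- round(shares$share, 4)
  files <- c(files, write_report(shares, "table1_time_shares.csv"))
  log_msg("time_use", sprintf("%d median cells, %d share rows",
                              nrow(med), nrow(shares)))

  comp_names <- c(content = "table2_visit_content.csv",
                  condition = "table3_visit_conditions.csv",
                  recipient = "table4_visit_recipients.csv")
  for (dim in names(comp_names)) {
    tab <- visit_composition(diaries, dim)
    tab$proportion <- round(tab$proportion, 4)
    files <- c(files, write_report(tab, comp_names[[dim]]))
  }

  # significance tests: site-class median contrasts per district/activity
  tests <- list()
  df <- as.data.frame(diaries)
  for (d in unique(tolower(df$district))) {
    sub <- df[tolower(df$district) == d, ]
    scs <- district_site_classes(d)
    if (!all(scs %in% sub$site_class)) next
    for (code in intersect(activity_codes(d), unique(sub$activity_code))) {
      for (what in c("travel_minutes", "activity_minutes")) {
        a <- sub[[what]][sub$activity_code == code &
                           sub$site_class == scs[1]]
        b <- sub[[what]][sub$activity_code == code &
                           sub$site_class == scs[2]]
        if (length(a) < 2 || length(b) < 2) next
        mt <- median_difference_test(a, b, n_boot = config$n_boot,
                                     seed = config$seed)
        tests[[length(tests) + 1]] <- data.frame(
          district = d, activity_code = code, measure = what,
          contrast = paste(scs[2], "vs", scs[1]),
          estimate = mt$estimate, ci_low = mt$ci_low,
          ci_high = mt$ci_high, p_value = signif(mt$p_value, 4),
          significant = mt$p_value < config$alpha,
          method = "median_qreg_bootstrap", stringsAsFactors = FALSE)
      }
    }
    for (what in c("travel_minutes", "activity_minutes")) {
      kw <- kruskal_wallis(split(sub[[what]], sub$activity_code))
      tests[[length(tests) + 1]] <- data.frame(
        district = d, activity_code = "all", measure = what,
        contrast = "across activities", estimate = kw$H, ci_low = NA,
        ci_high = NA, p_value = signif(kw$p_value, 4),
        significant = kw$p_value < config$alpha,
        method = "kruskal_wallis", stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  files <- c(files, write_report(tests, "significance_tests.csv"))
  log_msg("tests", sprintf("%d significance tests", nrow(tests)))

  # -- costing ---------------------------------------------------------
  for (d in districts()) {
    model <- ref_cost_model(d)
    dc <- district_costs(model)
    rows <- do.call(rbind, lapply(names(dc$panel_summaries), function(pn) {
      s <- dc$panel_summaries[[pn]]
      rbind(
        data.frame(panel = pn, line = names(s$lines),
                   annual_cost = round_half_up(unname(s$lines)),
                   per_chw = round_half_up(unname(s$lines) / s$n_chw),
                   stringsAsFactors = FALSE),
        data.frame(panel = pn,
                   line = c(sprintf("Overheads@%g%%",
                                    100 * s$overhead_rate), "Total"),
                   annual_cost = round_half_up(c(s$overhead_amount,
                                                 s$total)),
                   per_chw = round_half_up(c(s$overhead_amount,
                                             s$total) / s$n_chw),
                   stringsAsFactors = FALSE))
    }))
    metrics <- data.frame(panel = "district",
                          line = c("per_capita", "phc_share_pct",
                                   "total_usd"),
                          annual_cost = round(c(dc$per_capita,
                                                dc$phc_share,
                                                dc$total_usd), 2),
                          per_chw = NA, stringsAsFactors = FALSE)
    tabname <- if (d == "sedibeng") "table5_costs_sedibeng.csv" else
      "table6_costs_umzinyathi.csv"
    files <- c(files, write_report(rbind(rows, metrics), tabname))
    log_msg("costing", sprintf("%s total R%s (%.1f%% of PHC spend)", d,
                               format(round_half_up(dc$total),
                                      big.mark = ","), dc$phc_share))
  }

  # -- utilization -----------------------------------------------------
  util <- utilization_rates(ref_utilization())
  files <- c(files, write_report(util, "table7_utilization.csv"))

  # -- workforce -------------------------------------------------------
  wf <- ref_workforce_requirements()
  t8 <- do.call(rbind, lapply(names(wf$by_site), function(nm) {
    r <- wf$by_site[[nm]]
    data.frame(geography = nm,
               total_hours_per_100k = round(r$total_hours, 1),
               available_hours_per_chw = r$available_hours_per_chw,
               chws_per_visit = r$chws_per_visit,
               chws_required = r$chws_required,
               chws_required_unrounded = round(r$chws_required_unrounded,
                                               2),
               stringsAsFactors = FALSE)
  }))
  files <- c(files, write_report(t8, "table8_workforce.csv"))
  t9 <- data.frame(site_class = names(wf$households),
                   households_per_chw = unname(wf$households),
                   stringsAsFactors = FALSE)
  files <- c(files, write_report(t9, "table9_households.csv"))
  log_msg("workforce", paste("CHWs required:",
                             paste(wf$chws_required, collapse = "/")))

  # -- scenario --------------------------------------------------------
  t10 <- do.call(rbind, lapply(districts(), function(d) {
    cfg <- ref_district_config(d)
    sc <- apply_stipend(ref_cost_model(d),
                        stipend_scenario(d, cfg$chw_stipend_month,
                                         config$new_stipend))
    data.frame(district = d,
               current_stipend = sc$current_stipend,
               new_stipend = sc$new_stipend,
               pct_stipend_increase = round(sc$pct_stipend_increase, 1),
               pct_district_increase = round(sc$pct_district_increase, 1),
               per_capita_before = round(sc$per_capita_before, 2),
               per_capita_after = round(sc$per_capita_after, 2),
               phc_share_before = round(sc$phc_share_before, 2),
               phc_share_after = round(sc$phc_share_after, 2),
               stringsAsFactors = FALSE)
  }))
  files <- c(files, write_report(t10, "table10_stipend_scenario.csv"))
  log_msg("scenario", sprintf("stipend -> R%d/month", config$new_stipend))

  # -- manifest + log --------------------------------------------------
  digests <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package = "chwplan",
    version = as.character(utils::packageVersion("chwplan")),
    seed = config$seed,
    alpha = config$alpha,
    n_boot = config$n_boot,
    diaries = if (is.null(config$diaries)) "simulated" else config$diaries,
    report_digests = as.list(stats::setNames(unname(digests), files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, out("run_log.txt"))
  invisible(stats::setNames(as.list(file.path(config$out_dir,
                                              c(files, "manifest.json",
                                                "run_log.txt"))),
                            c(files, "manifest.json", "run_log.txt")))
}
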