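#' Median travel and activity time per activity and site class
#'
#' Episode-level medians of travel and activity minutes for every (district,
#' activity, site class) combination present in the data. Medians use the
#' usual midpoint convention for even counts.
#'
#' @param dataset A `chw_diaries` dataset.
#' @return data.frame with columns `district`, `activity_code`,
#'   `site_class`, `median_travel`, `median_activity`, `n_episodes`.
#' @export
summarize_times <- function(dataset) {
  stopifnot(inherits(dataset, "chw_diaries"))
  if (nrow(dataset) == 0) stop("empty diary dataset", call. = FALSE)
  df <- as.data.frame(dataset)
  key <- interaction(df$district, df$activity_code, df$site_class,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(district = g$district[1],
               activity_code = g$activity_code[1],
               site_class = g$site_class[1],
               median_travel = stats::median(g$travel_minutes),
               median_activity = stats::median(g$activity_minutes),
               n_episodes = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$district, out$site_class, out$activity_code), ]
}

#' Share of CHW time per activity group
#'
#' Fraction of total combined (travel + activity) minutes spent in each
#' activity group, within every (district, site class) cell. Shares within a
#' cell sum to 1.
#'
#' @param dataset A `chw_diaries` dataset.
#' @param grouping Named character vector mapping each activity code present
#'   in the data to a reporting group; by default every activity is its own
#'   group except that the district's home-visit codes are pooled into
#'   `"home_visits"`.
#' @return data.frame with columns `district`, `site_class`,
#'   `activity_group`, `minutes`, `share`.
#' @export
share_of_time <- function(dataset, grouping = NULL) {
  stopifnot(inherits(dataset, "chw_diaries"))
  df <- as.data.frame(dataset)
  if (nrow(df) == 0) stop("empty diary dataset", call. = FALSE)
  if (is.null(grouping)) {
    codes <- unique(df$activity_code)
    grouping <- stats::setNames(codes, codes)
    for (d in unique(tolower(df$district))) {
      hv <- intersect(home_visit_codes(d), codes)
      grouping[hv] <- "home_visits"
    }
  }
  absent <- setdiff(unique(df$activity_code), names(grouping))
  if (length(absent) > 0) {
    stop("grouping does not cover activity code(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df$minutes <- combined_minutes(df)
  df$group <- unname(grouping[df$activity_code])
  cellkey <- interaction(df$district, df$site_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, cellkey), function(cell) {
    total <- sum(cell$minutes)
    if (total <= 0) {
      stop("zero total time in cell ", cell$district[1], "/",
           cell$site_class[1], call. = FALSE)
    }
    mins <- tapply(cell$minutes, cell$group, sum)
    data.frame(district = cell$district[1], site_class = cell$site_class[1],
               activity_group = names(mins),
               minutes = as.numeric(mins),
               share = as.numeric(mins) / total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Home-visit composition frequency table
#'
#' Tabulates what home visits involved along one of three dimensions.
#' For `content`, the value per code is the fraction of home visits in which
#' that code occurs (a visit can carry several codes, so the column need not
#' sum to 1). For `condition` and `recipient`, each recorded code counts
#' once and proportions are taken over all recorded codes (columns sum to 1).
#'
#' @param dataset A `chw_diaries` dataset containing home-visit episodes.
#' @param dimension One of `"content"`, `"condition"`, `"recipient"`.
#' @return data.frame with columns `district`, `site_class`, `dimension`,
#'   `code`, `proportion`, `n_visits`, plus a `denominator` attribute
#'   (`"home_visits"` or `"recorded_codes"`) documenting the convention.
#' @export
visit_composition <- function(dataset,
                              dimension = c("content", "condition",
                                            "recipient")) {
  stopifnot(inherits(dataset, "chw_diaries"))
  dimension <- match.arg(dimension)
  df <- as.data.frame(dataset)
  df <- df[mapply(function(code, d) code %in% home_visit_codes(d),
                  df$activity_code, tolower(df$district)), , drop = FALSE]
  if (nrow(df) == 0) {
    stop("dataset contains no home-visit episodes", call. = FALSE)
  }
  col <- switch(dimension, content = "content_codes",
                condition = "condition_codes",
                recipient = "recipient_types")
  cellkey <- interaction(df$district, df$site_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, cellkey), function(cell) {
    toks <- strsplit(cell[[col]], ";", fixed = TRUE)
    toks <- lapply(toks, function(x) trimws(x[nzchar(trimws(x))]))
    if (dimension == "content") {
      # occurrence rate: fraction of visits containing the code
      counts <- table(unlist(lapply(toks, unique)))
      prop <- as.numeric(counts) / nrow(cell)
    } else {
      counts <- table(unlist(toks))
      prop <- as.numeric(counts) / sum(counts)
    }
    data.frame(district = cell$district[1], site_class = cell$site_class[1],
               dimension = dimension, code = names(counts),
               proportion = prop, n_visits = nrow(cell),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "denominator") <- if (dimension == "content") {
    "home_visits"
  } else {
    "recorded_codes"
  }
  out
}

#' Percent difference between two medians
#'
#' How much longer (in percent) one median is than a reference median, e.g.
#' home-visit activity medians of 40 minutes (peri-urban) vs 60 minutes
#' (deep-rural) give 50%.
#'
#' @param median_ref Reference median (> 0).
#' @param median_other Comparison median.
#' @return `100 * (median_other - median_ref) / median_ref`.
#' @export
percent_longer <- function(median_ref, median_other) {
  if (any(median_ref <= 0)) {
    stop("reference median must be positive", call. = FALSE)
  }
  100 * (median_other - median_ref) / median_ref
}
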