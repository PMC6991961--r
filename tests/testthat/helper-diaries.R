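# Build small in-code diary fixtures.

make_entries <- function(n = 3, district = "sedibeng",
                         site_class = "peri_urban",
                         activity_code = "household_registration",
                         travel = 15, activity = 40,
                         content = "", condition = "", recipients = "") {
  data.frame(
    chw_id = sprintf("CHW-%03d", seq_len(n)),
    district = rep_len(district, n),
    site_class = rep_len(site_class, n),
    day_index = ((seq_len(n) - 1) %% 10) + 1,
    activity_code = rep_len(activity_code, n),
    travel_minutes = rep_len(travel, n),
    activity_minutes = rep_len(activity, n),
    content_codes = rep_len(content, n),
    condition_codes = rep_len(condition, n),
    recipient_types = rep_len(recipients, n),
    stringsAsFactors = FALSE
  )
}

write_fixture <- function(entries, path = tempfile(fileext = ".csv")) {
  utils::write.table(entries, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  path
}

# Brute-force least-absolute-deviations fit for y ~ group indicator:
# minimises sum|y - b0 - b1*g| over a candidate grid built from the data.
# Independent check of the closed-form median-regression coefficient.
lad_brute_force <- function(a, b) {
  cand0 <- sort(unique(c(a, (rev(sort(a))[1] + sort(a)[1]) / 2,
                         outer(a, a, "+") / 2)))
  cand1 <- sort(unique(as.vector(outer(c(b, outer(b, b, "+") / 2),
                                       cand0, "-"))))
  obj <- function(b0, b1) sum(abs(a - b0)) + sum(abs(b - b0 - b1))
  best <- Inf
  best_b1 <- NA
  for (b0 in cand0) {
    o <- vapply(cand1, function(b1) obj(b0, b1), numeric(1))
    i <- which.min(o)
    if (o[i] < best - 1e-12) {
      best <- o[i]
      best_b1 <- cand1[i]
    }
  }
  list(objective = best, coef = best_b1)
}

# Hand-written Kruskal-Wallis rank statistic with tie correction; the
# independent oracle for kruskal_wallis().
kw_rank_formula <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) return(0)
  h / correction
}
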