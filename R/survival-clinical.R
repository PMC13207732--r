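#' Kaplan-Meier product-limit estimator
#'
#' At each distinct event time t with d events among n at risk,
#' S(t) = S(t-) * (1 - d/n). Subjects censored at an event time are counted
#' as at risk for that time's events (events first at ties) and leave the
#' risk set afterwards.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return A `KMCurve` list: `event_times` (ascending distinct event times),
#'   `survival_prob`, `n_at_risk`, `n_events`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0, na.rm = TRUE)) stop("negative survival time")
  ok <- !is.na(times) & !is.na(events)
  times <- times[ok]; events <- as.integer(events[ok])
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  ut <- sort(unique(times[events == 1L]))
  sorted_all <- sort(times)
  n_at_risk <- length(times) -
    findInterval(ut, sorted_all, left.open = TRUE)
  n_events <- as.integer(table(factor(times[events == 1L], levels = ut)))
  surv <- cumprod(1 - n_events / n_at_risk)
  structure(list(event_times = ut, survival_prob = surv,
                 n_at_risk = n_at_risk, n_events = n_events),
            class = "KMCurve")
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square using the hypergeometric variance of
#' the group-1 event count at each distinct event time.
#'
#' @param high,low Lists with elements `times` and `events` for the two
#'   groups.
#' @return A `SurvivalTestResult` list: `chi_square`, `p_value`, `n_high`,
#'   `n_low`, `events_high`, `events_low`. With zero total events the test
#'   is undefined: `chi_square`/`p_value` are `NA` and the result carries
#'   attribute `undefined = TRUE`.
#' @export
logrank_test <- function(high, low) {
  if (length(high$times) == 0L || length(low$times) == 0L)
    stop("both groups must be non-empty")
  gh <- data.frame(time = high$times, event = as.integer(high$events), g = 1L)
  gl <- data.frame(time = low$times, event = as.integer(low$events), g = 0L)
  d <- rbind(gh, gl)
  d <- d[!is.na(d$time) & !is.na(d$event), , drop = FALSE]
  if (any(d$time < 0)) stop("negative survival time")
  res <- structure(list(chi_square = NA_real_, p_value = NA_real_,
                        n_high = nrow(gh), n_low = nrow(gl),
                        events_high = sum(gh$event), events_low = sum(gl$event)),
                   class = "SurvivalTestResult")
  ut <- sort(unique(d$time[d$event == 1L]))
  if (length(ut) == 0L) {
    attr(res, "undefined") <- TRUE
    return(res)
  }
  sorted_all <- sort(d$time)
  sorted_g1 <- sort(d$time[d$g == 1L])
  n_at <- nrow(d) - findInterval(ut, sorted_all, left.open = TRUE)
  n1_at <- length(sorted_g1) - findInterval(ut, sorted_g1, left.open = TRUE)
  ev <- d$event == 1L
  dt <- as.integer(table(factor(d$time[ev], levels = ut)))
  d1 <- as.integer(table(factor(d$time[ev & d$g == 1L], levels = ut)))
  obs <- sum(d1)
  exp_ <- sum(dt * n1_at / n_at)
  ok <- n_at > 1L
  var_ <- sum((dt * (n1_at / n_at) * (1 - n1_at / n_at) *
                 (n_at - dt) / (n_at - 1L))[ok])
  if (var_ <= 0) {
    attr(res, "undefined") <- TRUE
    return(res)
  }
  chi <- (obs - exp_)^2 / var_
  res$chi_square <- chi
  res$p_value <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  res
}

#' Kaplan-Meier and log-rank comparison between high and low groups
#'
#' Pools the requested endpoint over the given cohorts, splits subjects by
#' the stratified groups, and returns both curves plus the log-rank test.
#' With `stratify_by_cohort = TRUE` the observed and expected event counts
#' are accumulated within cohort (stratified log-rank).
#'
#' @param cohorts List of `CohortDataset`s with clinical tables.
#' @param groups A `StratifiedGroups` whose ids cover the pooled samples.
#' @param endpoint `"os"` or `"pfs"`.
#' @param stratify_by_cohort Accumulate the log-rank within cohorts.
#' @return List with `curve_high`, `curve_low` (`KMCurve`s on the pooled
#'   data) and `test` (`SurvivalTestResult`).
#' @export
survival_comparison <- function(cohorts, groups, endpoint = c("pfs", "os"),
                                stratify_by_cohort = FALSE) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  grab <- function(co, ids) {
    cl <- co$clinical
    cl <- cl[cl$sample_id %in% ids & !is.na(cl[[tcol]]) & !is.na(cl[[ecol]]), ]
    list(times = cl[[tcol]], events = cl[[ecol]])
  }
  pool <- function(ids) {
    parts <- lapply(cohorts, grab, ids = ids)
    list(times = unlist(lapply(parts, `[[`, "times")),
         events = unlist(lapply(parts, `[[`, "events")))
  }
  hi <- pool(groups$high_ids); lo <- pool(groups$low_ids)
  test <- if (!stratify_by_cohort) logrank_test(hi, lo) else {
    # stratified: sum O - E and V over cohorts, one chi-square at the end
    oe <- vv <- 0; nh <- nl <- eh <- el <- 0L
    for (co in cohorts) {
      h <- grab(co, groups$high_ids); l <- grab(co, groups$low_ids)
      if (length(h$times) == 0L || length(l$times) == 0L) next
      nh <- nh + length(h$times); nl <- nl + length(l$times)
      eh <- eh + sum(h$events); el <- el + sum(l$events)
      d <- rbind(data.frame(time = h$times, event = h$events, g = 1L),
                 data.frame(time = l$times, event = l$events, g = 0L))
      for (t in sort(unique(d$time[d$event == 1L]))) {
        at <- d$time >= t
        n <- sum(at); n1 <- sum(at & d$g == 1L)
        dt <- sum(d$time == t & d$event == 1L)
        d1 <- sum(d$time == t & d$event == 1L & d$g == 1L)
        oe <- oe + d1 - dt * n1 / n
        if (n > 1L)
          vv <- vv + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1L)
      }
    }
    res <- structure(list(chi_square = NA_real_, p_value = NA_real_,
                          n_high = nh, n_low = nl,
                          events_high = eh, events_low = el),
                     class = "SurvivalTestResult")
    if (vv > 0) {
      res$chi_square <- oe^2 / vv
      res$p_value <- stats::pchisq(res$chi_square, 1L, lower.tail = FALSE)
    } else attr(res, "undefined") <- TRUE
    res
  }
  list(curve_high = km_estimate(hi$times, hi$events),
       curve_low = km_estimate(lo$times, lo$events),
       test = test)
}

#' Stage and grade contingency tables for high vs low groups
#'
#' Builds group x category count tables for AJCC T stage (T0-T4) and
#' histologic grade (low/mid/high) over the pooled cohorts, tests each with
#' the Pearson chi-square, and emits within-group percentage distributions
#' for bar-chart parity.
#'
#' @param cohorts List of `CohortDataset`s with clinical tables.
#' @param groups A `StratifiedGroups`.
#' @return Named list (per variable present) of lists with `table` (2 x
#'   categories counts, rows high/low), `percentages` (rows sum to 100) and
#'   `test` (`TestResult`).
#' @export
stage_grade_tables <- function(cohorts, groups) {
  levels_of <- list(t_stage = paste0("T", 0:4),
                    grade = c("low", "mid", "high"))
  clin <- do.call(rbind, lapply(cohorts, function(co) {
    cl <- co$clinical
    cols <- intersect(c("sample_id", "t_stage", "grade"), names(cl))
    cl[, cols, drop = FALSE]
  }))
  out <- list()
  for (v in names(levels_of)) {
    if (!v %in% names(clin)) next
    tab <- matrix(0L, nrow = 2L, ncol = length(levels_of[[v]]),
                  dimnames = list(c("high", "low"), levels_of[[v]]))
    for (grp in c("high", "low")) {
      ids <- if (grp == "high") groups$high_ids else groups$low_ids
      vals <- clin[[v]][clin$sample_id %in% ids]
      vals <- vals[!is.na(vals)]
      cnt <- table(factor(vals, levels = levels_of[[v]]))
      tab[grp, ] <- as.integer(cnt)
    }
    if (all(rowSums(tab) == 0)) next
    test <- tryCatch(compare_categorical(tab), error = function(e) NULL)
    pct <- 100 * tab / rowSums(tab)
    out[[v]] <- list(table = tab, percentages = pct, test = test)
  }
  out
}
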