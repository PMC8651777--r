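#' Aggregate daily monitor and weather records to state-week resolution
#'
#' Weekly bins are 7-day half-open intervals `[anchor + 7k, anchor + 7(k+1))`
#' extending backward through the training period; the forecast period is the
#' `horizon` bins starting at `week_anchor` (the study design anchors at
#' Jan 1 of the forecast year, so a Jan 1 - Apr 23 span of 114 days yields 16
#' full weeks with the final 2-day remainder dropped). The weekly value is
#' the arithmetic mean of the available daily values in the bin; bins with no
#' observations are flagged missing (`NA`) and must be filled with
#' [impute_short_gaps()]. More than `max_gap` consecutive missing weeks in
#' any variable is a hard error naming the state and weeks.
#'
#' @param monitors Data frame `date, state, pollutant, value` of daily
#'   state-level pollutant means.
#' @param weather Data frame `date, state, temperature, precipitation,
#'   humidity` of daily state-level weather.
#' @param week_anchor Date; start of forecast week 1.
#' @param horizon Number of forecast-period weeks.
#' @param max_gap Longest tolerated run of consecutive missing weeks.
#' @return Named list of [weekly_series()] (names `state.pollutant`), with
#'   missing bins as `NA` (`allow_na`).
#' @export
aggregate_daily_to_weekly <- function(monitors, weather,
                                      week_anchor = as.Date("2020-01-01"),
                                      horizon = 16L, max_gap = 2L) {
  stopifnot(all(c("date", "state", "pollutant", "value") %in% names(monitors)),
            all(c("date", "state", "temperature", "precipitation",
                  "humidity") %in% names(weather)))
  week_anchor <- as.Date(week_anchor)
  monitors$date <- as.Date(monitors$date)
  weather$date <- as.Date(weather$date)
  if (!all(is.finite(monitors$value))) stop("non-finite monitor values")

  bin_of <- function(d) floor(as.numeric(d - week_anchor) / 7)
  bin_mean <- function(values, bins, bin_range) {
    means <- tapply(values, factor(bins, levels = bin_range), mean)
    as.numeric(means)  # NA where a bin has no observations
  }

  out <- list()
  for (st in sort(unique(monitors$state))) {
    wsub <- weather[weather$state == st, ]
    if (!nrow(wsub)) stop("no weather records for state ", st)
    for (pol in sort(unique(monitors$pollutant[monitors$state == st]))) {
      msub <- monitors[monitors$state == st & monitors$pollutant == pol, ]
      mbin <- bin_of(msub$date)
      mbin <- mbin[mbin < horizon]         # drop records past the horizon
      msub <- msub[bin_of(msub$date) < horizon, ]
      bin_range <- seq(min(mbin), horizon - 1L)
      wbin <- bin_of(wsub$date)
      cols <- list(value = bin_mean(msub$value, mbin, bin_range),
                   temperature = bin_mean(wsub$temperature, wbin, bin_range),
                   precipitation = bin_mean(wsub$precipitation, wbin, bin_range),
                   humidity = bin_mean(wsub$humidity, wbin, bin_range))
      for (v in names(cols)) {
        runs <- rle(is.na(cols[[v]]))
        bad <- runs$lengths > max_gap & runs$values
        if (any(bad)) {
          ends <- cumsum(runs$lengths)
          i <- which(bad)[1]
          stop(sprintf("state %s %s: %d consecutive missing weeks (weeks %d-%d of the series)",
                       st, v, runs$lengths[i], ends[i] - runs$lengths[i] + 1L,
                       ends[i]))
        }
      }
      out[[paste(st, pol, sep = ".")]] <- weekly_series(
        week_start = week_anchor + 7 * bin_range, value = cols$value,
        temperature = cols$temperature, precipitation = cols$precipitation,
        humidity = cols$humidity, split_index = sum(bin_range < 0),
        state = st, pollutant = pol, allow_na = TRUE)
    }
  }
  out
}

#' Fill short gaps in a weekly series by linear interpolation
#'
#' Gaps of at most `max_gap` consecutive missing weeks are filled by linear
#' interpolation between the flanking observed weeks, separately for the
#' concentration and each weather covariate. Gaps at either series boundary
#' cannot be interpolated and raise an error; no extrapolation is ever done.
#'
#' @param series A [weekly_series()] possibly containing `NA`s.
#' @param max_gap Longest gap that may be filled.
#' @return The completed [weekly_series()]; the number of imputed values is
#'   recorded in attribute `n_imputed` and reported via `message()`.
#' @export
impute_short_gaps <- function(series, max_gap = 2L) {
  n_imputed <- 0L
  for (v in c("value", "temperature", "precipitation", "humidity")) {
    x <- series[[v]]
    if (!anyNA(x)) next
    if (is.na(x[1]) || is.na(x[length(x)]))
      stop("gap at series boundary in ", v, "; cannot extrapolate")
    runs <- rle(is.na(x))
    if (any(runs$lengths[runs$values] > max_gap))
      stop("gap longer than ", max_gap, " weeks in ", v)
    idx <- seq_along(x)
    filled <- approx(idx[!is.na(x)], x[!is.na(x)], xout = idx,
                     method = "linear")$y
    n_imputed <- n_imputed + sum(is.na(x))
    series[[v]] <- filled
  }
  if (n_imputed > 0)
    message(sprintf("imputed %d missing weekly values for %s %s",
                    n_imputed, attr(series, "state"), attr(series, "pollutant")))
  attr(series, "n_imputed") <- n_imputed
  series
}

#' Intervention calendar: state -> date of the emergency declaration
#'
#' @param df Data frame with columns `state` and `emergency_date`
#'   (ISO-8601); further policy-date columns are carried along.
#' @return An `intervention_calendar` data frame.
#' @export
intervention_calendar <- function(df) {
  stopifnot(all(c("state", "emergency_date") %in% names(df)))
  df$emergency_date <- as.Date(df$emergency_date)
  if (anyNA(df$emergency_date)) stop("unparseable emergency_date")
  if (anyDuplicated(df$state)) stop("duplicate state in calendar")
  structure(df, class = c("intervention_calendar", "data.frame"))
}

#' Forecast-period week index of a state's intervention date
#'
#' Returns the 1-based index `i` of the forecast week whose 7-day bin
#' contains the state's emergency-declaration date.
#'
#' @param calendar An [intervention_calendar()].
#' @param series The state's [weekly_series()] (supplies the forecast bins).
#' @param state State code to look up.
#' @return Integer week index in `1..horizon`.
#' @export
week_index_of <- function(calendar, series, state) {
  row <- which(calendar$state == state)
  if (!length(row)) stop("state ", state, " not in intervention calendar")
  t_int <- calendar$emergency_date[row[1]]
  start <- series$week_start[attr(series, "split_index") + 1L]
  i <- floor(as.numeric(t_int - start) / 7) + 1L
  h <- forecast_horizon(series)
  if (i < 1L || i > h)
    stop(sprintf("intervention date %s for %s falls outside the forecast period",
                 format(t_int), state))
  as.integer(i)
}

#' Before/after week windows around the intervention
#'
#' Partitions the forecast weeks `1..horizon` into the windows used by the
#' effect estimate. By default the week containing the intervention date is
#' assigned to the "after" window (the intervention acts within that week);
#' `t_int_in_after = FALSE` assigns it to "before". Either way the two
#' windows partition the horizon.
#'
#' @param t_int_week Intervention week index (from [week_index_of()]).
#' @param horizon Forecast-period length in weeks.
#' @param t_int_in_after Boundary rule flag.
#' @return List with integer vectors `before` and `after`.
#' @export
effect_windows <- function(t_int_week, horizon, t_int_in_after = TRUE) {
  t_int_week <- as.integer(t_int_week)
  cut <- if (t_int_in_after) t_int_week else t_int_week + 1L
  if (cut < 2L || cut > horizon)
    stop("t_int_week must leave both windows non-empty")
  list(before = seq_len(cut - 1L), after = seq.int(cut, horizon))
}
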