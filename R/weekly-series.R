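#' Weekly state-level pollutant series with aligned weather covariates
#'
#' A `weekly_series` is a data frame with one row per week and columns
#' `week_start` (Date, strictly increasing at exactly 7-day spacing),
#' `value` (weekly mean concentration), `temperature`, `precipitation`,
#' `humidity`, plus attributes `state`, `pollutant` and `split_index`, the
#' number of training weeks; the remaining rows are the forecast period
#' (16 weeks in the full-scale study design).
#'
#' @param week_start Date vector at 7-day spacing.
#' @param value Weekly mean concentrations (may contain `NA` before
#'   imputation; see [impute_short_gaps()]).
#' @param temperature,precipitation,humidity Weekly mean weather covariates.
#' @param split_index Number of training weeks; rows after it form the
#'   forecast period.
#' @param state Two-letter state code (or any label).
#' @param pollutant `"pm25"` or `"no2"` (or any label).
#' @param allow_na Permit missing values (pre-imputation stage).
#' @return An object of class `weekly_series`.
#' @export
weekly_series <- function(week_start, value, temperature, precipitation,
                          humidity, split_index, state = "XX",
                          pollutant = "pm25", allow_na = FALSE) {
  week_start <- as.Date(week_start)
  n <- length(week_start)
  stopifnot(n >= 2L, length(value) == n, length(temperature) == n,
            length(precipitation) == n, length(humidity) == n)
  d <- diff(as.numeric(week_start))
  if (any(d != 7))
    stop("week_start must be strictly increasing at exactly 7-day spacing")
  split_index <- as.integer(split_index)
  if (split_index < 1L || split_index >= n)
    stop("split_index must leave a non-empty training and forecast period")
  if (!allow_na && anyNA(c(value, temperature, precipitation, humidity)))
    stop("missing values present; impute or pass allow_na = TRUE")
  out <- data.frame(week_start = week_start, value = as.numeric(value),
                    temperature = as.numeric(temperature),
                    precipitation = as.numeric(precipitation),
                    humidity = as.numeric(humidity))
  structure(out, class = c("weekly_series", "data.frame"),
            state = state, pollutant = pollutant, split_index = split_index)
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("<weekly_series> %s %s: %d weeks (%d training + %d forecast), %s to %s\n",
              attr(x, "state"), attr(x, "pollutant"), nrow(x),
              attr(x, "split_index"), nrow(x) - attr(x, "split_index"),
              format(x$week_start[1]), format(x$week_start[nrow(x)])))
  invisible(x)
}

#' Number of forecast-period weeks of a weekly series
#' @param series A [weekly_series()].
#' @return Integer horizon length.
#' @export
forecast_horizon <- function(series) {
  nrow(series) - attr(series, "split_index")
}

# training / forecast pieces used throughout the pipeline
series_split <- function(series) {
  s <- attr(series, "split_index")
  xcols <- c("temperature", "precipitation", "humidity")
  list(y_train = series$value[seq_len(s)],
       xreg_train = as.matrix(series[seq_len(s), xcols]),
       y_future = series$value[-seq_len(s)],
       xreg_future = as.matrix(series[-seq_len(s), xcols]),
       week_start_future = series$week_start[-seq_len(s)],
       split_index = s)
}

#' Write / read a collection of weekly series as a weekly panel CSV
#'
#' The panel schema is
#' `state,pollutant,week_start,value,temperature,precipitation,humidity,is_forecast_period`
#' with ISO-8601 dates. Numeric columns are written with 17 significant
#' digits so a write/read round trip reproduces the series bit-exactly.
#'
#' @param series_list A `weekly_series` or list of them.
#' @param path Output CSV path.
#' @return `write_weekly_panel` returns `path` invisibly;
#'   `read_weekly_panel` returns a named list of `weekly_series`
#'   (names `state.pollutant`).
#' @export
write_weekly_panel <- function(series_list, path) {
  if (inherits(series_list, "weekly_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    n <- nrow(s)
    data.frame(state = attr(s, "state"), pollutant = attr(s, "pollutant"),
               week_start = format(s$week_start, "%Y-%m-%d"),
               value = sprintf("%.17g", s$value),
               temperature = sprintf("%.17g", s$temperature),
               precipitation = sprintf("%.17g", s$precipitation),
               humidity = sprintf("%.17g", s$humidity),
               is_forecast_period = seq_len(n) > attr(s, "split_index"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weekly_panel
#' @export
read_weekly_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "pollutant", "week_start", "value", "temperature",
            "precipitation", "humidity", "is_forecast_period")
  if (!all(need %in% names(df)))
    stop("weekly panel is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (key in unique(paste(df$state, df$pollutant, sep = "."))) {
    sub <- df[paste(df$state, df$pollutant, sep = ".") == key, ]
    sub <- sub[order(as.Date(sub$week_start)), ]
    out[[key]] <- weekly_series(
      week_start = as.Date(sub$week_start), value = as.numeric(sub$value),
      temperature = as.numeric(sub$temperature),
      precipitation = as.numeric(sub$precipitation),
      humidity = as.numeric(sub$humidity),
      split_index = sum(!sub$is_forecast_period),
      state = sub$state[1], pollutant = sub$pollutant[1])
  }
  out
}
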