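#' Categorization schemes for weekly climate covariates
#'
#' A `category_scheme` cuts a continuous covariate into ordered categories.
#' Intervals are left-closed/right-open at every interior break, the first
#' category is unbounded below and the last unbounded above, so every finite
#' value maps to exactly one category.
#'
#' The default schemes mirror the study design this package supports:
#' precipitation in three levels with breaks at 0.01 and 0.035 (low below
#' 0.01, mid from 0.01 to below 0.035, high at 0.035 and above), and
#' temperature in four levels with breaks at 15, 19 and 23 degrees C.
#'
#' @param breaks strictly increasing numeric cut points (interior breaks).
#' @param labels category names, one more than `breaks`.
#' @return a `category_scheme`.
#' @examples
#' categorize(0.005, precip_scheme())  # 1 = low
#' categorize(0.035, precip_scheme())  # 3 = high (breaks are left-closed)
#' categorize(24, temp_scheme())       # 4
#' @export
category_scheme <- function(breaks, labels = NULL) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1L || any(!is.finite(breaks)) || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be finite and strictly increasing")
  labels <- labels %||% paste0("cat", seq_len(length(breaks) + 1L))
  if (length(labels) != length(breaks) + 1L)
    stop("need exactly length(breaks) + 1 labels")
  structure(list(breaks = breaks, labels = labels), class = "category_scheme")
}

#' @rdname category_scheme
#' @export
precip_scheme <- function() {
  category_scheme(c(0.01, 0.035), c("low", "mid", "high"))
}

#' @rdname category_scheme
#' @export
temp_scheme <- function() {
  category_scheme(c(15, 19, 23), c("low", "mid", "average", "high"))
}

#' @rdname category_scheme
#' @param value numeric value(s) to categorize; must be finite.
#' @param scheme a `category_scheme`.
#' @return `categorize` returns integer category indices in
#'   `1..(length(breaks) + 1)`.
#' @export
categorize <- function(value, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (any(!is.finite(value)))
    stop("categorize: non-finite covariate value")
  findInterval(value, scheme$breaks, left.open = FALSE) + 1L
}

#' @rdname category_scheme
#' @export
n_categories <- function(scheme) length(scheme$labels)

#' Event windows around an extreme precipitation event
#'
#' Three contiguous, non-overlapping 28-day windows bracketing an extreme
#' event: before, during, after. The defaults are the flood windows of the
#' July 2021 central European flood: before 2021-05-25 to 2021-06-21, during
#' 2021-06-22 to 2021-07-19, after 2021-07-20 to 2021-08-16 (all endpoints
#' inclusive).
#'
#' @param before,during,after length-2 vectors of start/end dates.
#' @return an `event_windows` object.
#' @examples
#' assign_event_period(as.Date("2021-07-01"), event_windows())
#' @export
event_windows <- function(before = c("2021-05-25", "2021-06-21"),
                          during = c("2021-06-22", "2021-07-19"),
                          after = c("2021-07-20", "2021-08-16")) {
  w <- list(before = stopifnot_date(before), during = stopifnot_date(during),
            after = stopifnot_date(after))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || w[[nm]][2] < w[[nm]][1])
      stop("window '", nm, "' must be c(start, end) with start <= end")
    if (as.integer(w[[nm]][2] - w[[nm]][1]) != 27L)
      stop("window '", nm, "' must span exactly 28 days")
  }
  if (w$during[1] != w$before[2] + 1 || w$after[1] != w$during[2] + 1)
    stop("windows must be contiguous: before, during, after")
  structure(w, class = "event_windows")
}

#' @rdname event_windows
#' @param d a date (or vector of dates).
#' @param windows an `event_windows` object.
#' @return `assign_event_period` returns a character vector with values
#'   `"before"`, `"during"`, `"after"` or `"none"`; membership is inclusive
#'   on both endpoints.
#' @export
assign_event_period <- function(d, windows = event_windows()) {
  stopifnot(inherits(windows, "event_windows"))
  d <- stopifnot_date(d)
  out <- rep("none", length(d))
  for (nm in c("before", "during", "after"))
    out[d >= windows[[nm]][1] & d <= windows[[nm]][2]] <- nm
  out
}

#' Reduce daily regional series to weekly bins
#'
#' Collapses complete per-region daily climate series into one value per
#' region-week, using 7-day bins anchored at `week_origin` (the same binning
#' as the sentiment panel). The reducer is the mean by default for both
#' temperature and precipitation; a sum reducer is available for covariates
#' measured as accumulations.
#'
#' @param daily data.frame with columns `region`, `date`, and `value`.
#' @param reducer `"mean"` or `"sum"`.
#' @param week_origin first day of week 1.
#' @param n_weeks number of weekly bins; days outside the grid are an error.
#' @return a matrix with one row per region (sorted by first appearance) and
#'   one column per week, plus a `week_start` attribute.
#' @export
weekly_regional_covariate <- function(daily, reducer = c("mean", "sum"),
                                      week_origin = "2019-01-01", n_weeks) {
  reducer <- match.arg(reducer)
  stopifnot(all(c("region", "date", "value") %in% names(daily)))
  origin <- stopifnot_date(week_origin)
  dates <- stopifnot_date(daily$date)
  widx <- as.integer(floor(as.numeric(dates - origin) / 7)) + 1L
  if (any(widx < 1L) || any(widx > n_weeks))
    stop("daily series contains dates outside the weekly grid")
  regions <- unique(daily$region)
  out <- matrix(NA_real_, length(regions), n_weeks,
                dimnames = list(regions, NULL))
  cnt <- matrix(0L, length(regions), n_weeks, dimnames = list(regions, NULL))
  ridx <- match(daily$region, regions)
  for (k in seq_along(widx)) {
    i <- ridx[k]; t <- widx[k]
    out[i, t] <- if (cnt[i, t] == 0L) daily$value[k] else out[i, t] + daily$value[k]
    cnt[i, t] <- cnt[i, t] + 1L
  }
  if (any(cnt != 7L)) {
    bad <- which(cnt != 7L, arr.ind = TRUE)
    stop("incomplete daily series: region/week bins without 7 days: ",
         paste(sprintf("%s/week %d (%d days)", regions[bad[, 1]], bad[, 2],
                       cnt[cbind(bad[, 1], bad[, 2])])[seq_len(min(5, nrow(bad)))],
               collapse = "; "))
  }
  if (reducer == "mean") out <- out / 7
  attr(out, "week_start") <- origin + 7 * (seq_len(n_weeks) - 1L)
  out
}
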