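#' Weekly regional climate panel
#'
#' A `climate_panel` stores weekly temperature (degrees C) and precipitation
#' (native covariate unit, nonnegative) for every region and week: two
#' `n_regions x n_weeks` matrices plus the week start dates (consecutive
#' 7-day bins). No missing cells are allowed.
#'
#' @param temperature,precipitation numeric `n x T` matrices with region ids
#'   as row names.
#' @param week_start Date vector of length `T`, strictly increasing by 7 days.
#' @return a `climate_panel`.
#' @export
climate_panel <- function(temperature, precipitation, week_start) {
  week_start <- stopifnot_date(week_start)
  temperature <- as.matrix(temperature); precipitation <- as.matrix(precipitation)
  if (!identical(dim(temperature), dim(precipitation)))
    stop("temperature and precipitation must have identical dimensions")
  if (ncol(temperature) != length(week_start))
    stop("number of weeks must match length(week_start)")
  if (length(week_start) > 1 && any(diff(as.numeric(week_start)) != 7))
    stop("week_start must increase in steps of exactly 7 days")
  if (anyNA(temperature) || anyNA(precipitation))
    stop("climate panel must not contain missing cells")
  if (any(precipitation < 0)) stop("precipitation must be nonnegative")
  structure(list(temperature = temperature, precipitation = precipitation,
                 week_start = week_start,
                 region_ids = rownames(temperature) %||%
                   sprintf("R%02d", seq_len(nrow(temperature)))),
            class = "climate_panel")
}

#' @export
print.climate_panel <- function(x, ...) {
  cat(sprintf("climate_panel: %d regions x %d weeks (%s .. %s)\n",
              nrow(x$temperature), ncol(x$temperature),
              min(x$week_start), max(x$week_start)))
  cat(sprintf("  temperature   range %.2f .. %.2f\n", min(x$temperature), max(x$temperature)))
  cat(sprintf("  precipitation range %.4f .. %.4f\n", min(x$precipitation), max(x$precipitation)))
  invisible(x)
}

#' Simulate a weekly climate panel with a planted extreme event
#'
#' Generates seasonal weekly temperature and right-skewed weekly
#' precipitation for every region. Temperature follows a yearly sinusoid
#' (trough in mid-January, peak in mid-July) plus a fixed regional offset and
#' weekly noise, clipped to `[-1, 24]` degrees C. Precipitation is gamma
#' noise clipped to `[0, 0.07]` in the covariate's native unit. Cells inside
#' the event (given weeks x exposed regions) get `precip_boost` added before
#' clipping, pushing them toward the upper end of the range, which emulates a
#' multi-week extreme precipitation episode in a contiguous part of the map.
#'
#' Out-of-range draws are clipped rather than rejected so that the number of
#' random draws per cell is fixed and results are reproducible cell-by-cell.
#'
#' @param graph a [region_graph()].
#' @param n_weeks number of weeks, at least 8 (the event windows need room).
#' @param start_date first week start.
#' @param event list with `weeks` (integer week indices), `regions` (region
#'   ids or indices) and `precip_boost` (added precipitation). Use
#'   [default_flood_event()] for the default 4-week event.
#' @param seed integer seed.
#' @param temp_mean,temp_amplitude,temp_region_sd,temp_noise_sd,precip_shape,precip_scale
#'   generator parameters; the defaults produce occupancy in all four
#'   temperature and all three precipitation categories of the default
#'   schemes.
#' @return a [climate_panel()].
#' @examples
#' g <- german_region_graph()
#' cl <- simulate_climate(g, n_weeks = 20, event = list(weeks = 10:13,
#'   regions = c("NW", "RP"), precip_boost = 0.04), seed = 1)
#' @export
simulate_climate <- function(graph, n_weeks = 187L, start_date = "2019-01-01",
                             event = default_flood_event(graph), seed = 1L,
                             temp_mean = 12, temp_amplitude = 10,
                             temp_region_sd = 0.8, temp_noise_sd = 1.8,
                             precip_shape = 2, precip_scale = 0.008) {
  stopifnot(inherits(graph, "region_graph"))
  n_weeks <- as.integer(n_weeks)
  if (n_weeks < 8L)
    stop("need at least 8 weeks to host before/during/after event windows")
  start_date <- stopifnot_date(start_date)
  n <- n_regions(graph)
  ev_regions <- event$regions %||% integer(0)
  if (is.character(ev_regions)) {
    ev_regions <- match(ev_regions, graph$region_ids)
    if (anyNA(ev_regions)) stop("event region not in graph")
  }
  ev_weeks <- as.integer(event$weeks %||% integer(0))
  if (length(ev_weeks) && (min(ev_weeks) < 1L || max(ev_weeks) > n_weeks))
    stop("event weeks outside 1..n_weeks")
  boost <- event$precip_boost %||% 0
  with_seed(seed, {
    w <- seq_len(n_weeks)
    seasonal <- temp_mean - temp_amplitude * cos(2 * pi * (w - 2) / 52.18)
    offs <- stats::rnorm(n, 0, temp_region_sd)
    temp <- outer(offs, seasonal, `+`) +
      matrix(stats::rnorm(n * n_weeks, 0, temp_noise_sd), n, n_weeks)
    temp <- pmin(pmax(temp, -1), 24)
    prec <- matrix(stats::rgamma(n * n_weeks, shape = precip_shape,
                                 scale = precip_scale), n, n_weeks)
    if (length(ev_weeks) && length(ev_regions) && boost != 0)
      prec[ev_regions, ev_weeks] <- prec[ev_regions, ev_weeks] + boost
    prec <- pmin(pmax(prec, 0), 0.07)
    rownames(temp) <- rownames(prec) <- graph$region_ids
    climate_panel(temp, prec, start_date + 7 * (w - 1L))
  })
}

#' Default planted flood event
#'
#' Four event weeks matching the during-flood window of [event_windows()]
#' under a 2019-01-01 week origin (weeks 130 to 133), in four contiguous
#' western regions of the [german_region_graph()] (or the first four regions
#' of another graph), with a precipitation boost of 0.04 that pushes event
#' cells into the high precipitation category.
#'
#' @param graph a [region_graph()].
#' @param n_weeks panel length used to place the event; if shorter than 133
#'   weeks the event is centered in the panel.
#' @return a list with `weeks`, `regions`, `precip_boost`.
#' @export
default_flood_event <- function(graph, n_weeks = 187L) {
  regions <- intersect(c("NW", "RP", "SL", "HE"), graph$region_ids)
  if (length(regions) == 0)
    regions <- graph$region_ids[seq_len(min(4L, n_regions(graph)))]
  weeks <- if (n_weeks >= 133L) 130:133 else {
    mid <- max(5L, n_weeks %/% 2L); (mid - 3L):mid
  }
  list(weeks = weeks, regions = regions, precip_boost = 0.04)
}

#' Read / write a climate panel as tidy CSV
#'
#' Columns `region,week_start,temperature,precipitation`, one row per
#' region-week.
#'
#' @param panel a `climate_panel`.
#' @param path file path.
#' @export
write_climate_csv <- function(panel, path) {
  n <- nrow(panel$temperature); TT <- ncol(panel$temperature)
  df <- data.frame(
    region = rep(panel$region_ids, each = TT),
    week_start = rep(panel$week_start, n),
    temperature = as.vector(t(panel$temperature)),
    precipitation = as.vector(t(panel$precipitation)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "week_start", "temperature", "precipitation")
  if (!all(need %in% names(df))) stop("climate CSV needs columns ",
                                      paste(need, collapse = ", "))
  regions <- unique(df$region)
  weeks <- sort(unique(stopifnot_date(df$week_start)))
  key <- paste(match(df$region, regions),
               match(stopifnot_date(df$week_start), weeks))
  if (anyDuplicated(key)) stop("duplicate region/week rows in climate CSV")
  temp <- matrix(NA_real_, length(regions), length(weeks),
                 dimnames = list(regions, NULL))
  prec <- temp
  i <- match(df$region, regions)
  j <- match(stopifnot_date(df$week_start), weeks)
  temp[cbind(i, j)] <- df$temperature
  prec[cbind(i, j)] <- df$precipitation
  climate_panel(temp, prec, weeks)
}
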