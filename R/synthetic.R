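#' Ground-truth parameters for synthetic sentiment panels
#'
#' Collects the latent quantities of the generative model: the baseline
#' log-rate (`intercept`, the log of the dataset-wide negative proportion),
#' the categorized covariate effect vectors on the log-relative-risk scale,
#' the space-time field hyperparameters, and an additive extreme-event bump
#' applied to exposed regions during the event weeks.
#'
#' The covariate effect vectors are mean-centered at construction so that
#' they satisfy the same sum-to-zero identifiability convention under which
#' the model reports effects; the removed means are absorbed into the
#' baseline rate (both the raw input vectors and the centered versions are
#' stored). The default effect magnitudes are small log-relative-risk values
#' of the order of a fraction of a percent to two percent, i.e. the scale at
#' which weekly climate is expected to move sentiment.
#'
#' @param intercept baseline log-rate; `exp(intercept)` plays the role of the
#'   global negative proportion. Default `log(0.1)`.
#' @param f_temp,f_precip covariate effects (4 and 3 levels) on the log-RR
#'   scale, centered internally.
#' @param field_tau spatial precision scale of the intrinsic CAR factor.
#' @param ar_rho temporal AR1 correlation in (-1, 1).
#' @param event_effect additive log-RR bump in exposed regions during event
#'   weeks; default `log(1.10)`, a 10 percent relative-risk increase.
#' @param exposed_regions region ids or indices carrying the event bump.
#' @param event_weeks contiguous week indices of the event.
#' @return a `true_params` object.
#' @export
true_params <- function(intercept = log(0.1),
                        f_temp = c(0, -0.005, 0, 0.020),
                        f_precip = c(-0.0025, 0, 0.011),
                        field_tau = 24000, ar_rho = 0.98,
                        event_effect = log(1.10),
                        exposed_regions = c("NW", "RP", "SL", "HE"),
                        event_weeks = 130:133) {
  stopifnot(length(f_temp) == 4L, length(f_precip) == 3L,
            field_tau > 0, abs(ar_rho) < 1)
  event_weeks <- as.integer(event_weeks)
  if (length(event_weeks) && any(diff(sort(event_weeks)) != 1L))
    stop("event_weeks must be contiguous")
  structure(list(
    intercept = intercept,
    f_temp_raw = f_temp, f_precip_raw = f_precip,
    f_temp = f_temp - mean(f_temp),
    f_precip = f_precip - mean(f_precip),
    field_tau = field_tau, ar_rho = ar_rho,
    event_effect = event_effect,
    exposed_regions = exposed_regions,
    event_weeks = sort(event_weeks)), class = "true_params")
}

#' Simulate a weekly sentiment panel from the generative risk model
#'
#' The generative twin of the fitted model. Exposures `TTW(i,t)` are drawn
#' from an overdispersed (negative binomial) count distribution with mean
#' `mean_ttw` (floored at 1 unless `allow_zero_ttw`), emulating heavy-tailed
#' weekly document volumes. The latent space-time field is drawn from the
#' constrained intrinsic-CAR x AR1 Gaussian Markov random field with
#' precision scale `params$field_tau` and temporal correlation
#' `params$ar_rho` (so each weekly spatial slice sums to zero). The log
#' relative risk of cell `(i, t)` is
#' `field(i,t) + f_temp[cat_T(i,t)] + f_precip[cat_P(i,t)] +
#' event_effect * 1(exposed, event week)`, and counts are
#' `NTw(i,t) ~ Poisson(exp(intercept) * TTW(i,t) * relrisk(i,t))`.
#'
#' Cells where the unbounded Poisson draw exceeds `TTW` are redrawn (the
#' observed pipeline counts negatives among totals, so `NTw <= TTW` must
#' hold); at realistic baseline rates around 0.1 this touches at most a few
#' cells per million. A configuration whose expected count exceeds `1e7` in
#' any cell is rejected as an overflow guard.
#'
#' @param graph a [region_graph()].
#' @param climate a [climate_panel()] on the same regions.
#' @param params a [true_params()].
#' @param mean_ttw mean weekly document volume per region (>= 1).
#' @param seed integer seed; the bundle is bit-identical given the seed.
#' @param ttw_size negative binomial size (dispersion) of the exposure draws.
#' @param schemes list with `temperature` and `precipitation`
#'   [category_scheme()]s used to evaluate the covariate effects.
#' @param allow_zero_ttw keep zero exposures instead of flooring them at 1.
#' @return a `synthetic_bundle`: list with `graph`, `climate`, `panel`
#'   (a [sentiment_panel()]), `latents` (the field, `n x T`), `log_relrisk`
#'   (`n x T`), `params`, and `seed`.
#' @examples
#' g <- german_region_graph()
#' cl <- simulate_climate(g, n_weeks = 30, seed = 1,
#'   event = list(weeks = 10:13, regions = c("NW", "RP"), precip_boost = 0.04))
#' b <- simulate_panel(g, cl, true_params(event_weeks = 10:13), mean_ttw = 500, seed = 2)
#' b$panel
#' @export
simulate_panel <- function(graph, climate, params = true_params(),
                           mean_ttw = 6000, seed = 1L, ttw_size = 5,
                           schemes = list(temperature = temp_scheme(),
                                          precipitation = precip_scheme()),
                           allow_zero_ttw = FALSE) {
  stopifnot(inherits(graph, "region_graph"), inherits(climate, "climate_panel"),
            inherits(params, "true_params"), mean_ttw >= 1)
  n <- n_regions(graph); TT <- ncol(climate$temperature)
  if (nrow(climate$temperature) != n)
    stop("climate panel and graph disagree on the number of regions")
  exposed <- params$exposed_regions
  if (is.character(exposed)) {
    exposed <- match(exposed, graph$region_ids)
    exposed <- exposed[!is.na(exposed)]
  }
  ev_weeks <- params$event_weeks[params$event_weeks >= 1 &
                                   params$event_weeks <= TT]

  cat_t <- matrix(categorize(climate$temperature, schemes$temperature), n, TT)
  cat_p <- matrix(categorize(climate$precipitation, schemes$precipitation), n, TT)

  with_seed(seed, {
    ttw <- stats::rnbinom(n * TT, mu = mean_ttw, size = ttw_size)
    if (!allow_zero_ttw) ttw[ttw == 0L] <- 1L
    ttw <- matrix(ttw, n, TT)

    field <- if (is.finite(params$field_tau)) {
      sp <- icar_precision(graph, params$field_tau)
      te <- ar1_precision(TT, params$ar_rho, tau = 1)
      matrix(sample_gmrf(spacetime_precision(sp, te)), TT, n) |> t()
    } else matrix(0, n, TT)

    log_rr <- field + matrix(params$f_temp[cat_t], n, TT) +
      matrix(params$f_precip[cat_p], n, TT)
    if (length(exposed) && length(ev_weeks))
      log_rr[exposed, ev_weeks] <- log_rr[exposed, ev_weeks] + params$event_effect

    mu <- exp(params$intercept) * ttw * exp(log_rr)
    if (any(mu > 1e7))
      stop("expected counts exceed 1e7 in ", sum(mu > 1e7),
           " cell(s); refusing to simulate (overflow guard)")
    ntw <- matrix(stats::rpois(n * TT, mu), n, TT)
    bad <- which(ntw > ttw)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      ntw[bad] <- stats::rpois(length(bad), mu[bad])
      bad <- which(ntw > ttw)
      tries <- tries + 1L
    }
    if (length(bad)) {
      warning("clamping ", length(bad), " cell(s) with NTw > TTW after resampling")
      ntw[bad] <- ttw[bad]
    } else if (tries > 0L) {
      message("simulate_panel: resampled ", tries, " round(s) of NTw > TTW cells")
    }
    rownames(ntw) <- rownames(ttw) <- rownames(field) <- rownames(log_rr) <-
      graph$region_ids
    structure(list(
      graph = graph, climate = climate,
      panel = sentiment_panel(ntw, ttw, climate$week_start),
      latents = field, log_relrisk = log_rr,
      params = params, seed = seed), class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle (seed ", x$seed, ")\n", sep = "")
  print(x$panel)
  cat(sprintf("  field sd %.4f, event effect %+.4f in %d region(s) x %d week(s)\n",
              stats::sd(x$latents), x$params$event_effect,
              length(x$params$exposed_regions), length(x$params$event_weeks)))
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing graph, climate and sentiment panel in one
#' call under a single seed: the merged German federal-state graph, 187
#' weeks starting 2019-01-01 with the default planted flood event, and a
#' panel drawn from [simulate_panel()] under `params`.
#'
#' @param params a [true_params()].
#' @param n_weeks number of weeks.
#' @param mean_ttw mean weekly document volume per region.
#' @param seed integer seed.
#' @param graph optional [region_graph()] (default [german_region_graph()]).
#' @param start_date first week start.
#' @return a `synthetic_bundle`.
#' @export
simulate_bundle <- function(params = true_params(), n_weeks = 187L,
                            mean_ttw = 6000, seed = 1L,
                            graph = german_region_graph(),
                            start_date = "2019-01-01") {
  ev <- default_flood_event(graph, n_weeks)
  climate <- simulate_climate(graph, n_weeks, start_date, event = ev,
                              seed = derive_seed(seed, 1))
  if (n_weeks < max(c(0L, params$event_weeks)))
    params$event_weeks <- ev$weeks
  simulate_panel(graph, climate, params, mean_ttw,
                 seed = derive_seed(seed, 2))
}

#' Write a synthetic bundle to a directory
#'
#' Writes the graph edge list, climate and sentiment panels as tidy CSV and
#' the ground-truth parameters as JSON.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_region_graph(bundle$graph, file.path(dir, "graph_edges.csv"))
  write_climate_csv(bundle$climate, file.path(dir, "climate.csv"))
  write_panel_csv(bundle$panel, file.path(dir, "panel.csv"))
  p <- bundle$params
  jsonlite::write_json(
    list(intercept = p$intercept, f_temp = p$f_temp, f_precip = p$f_precip,
         field_tau = p$field_tau, ar_rho = p$ar_rho,
         event_effect = p$event_effect,
         exposed_regions = p$exposed_regions, event_weeks = p$event_weeks,
         seed = bundle$seed),
    file.path(dir, "true_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
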