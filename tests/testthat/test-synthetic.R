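test_that("simulate_climate respects the documented ranges and the event spec", {
  g <- german_region_graph()
  cl <- simulate_climate(g, n_weeks = 60, seed = 4,
                         event = list(weeks = 20:23,
                                      regions = c("NW", "RP"),
                                      precip_boost = 0.04))
  expect_true(all(cl$precipitation >= 0 & cl$precipitation <= 0.07))
  expect_true(all(cl$temperature >= -1 & cl$temperature <= 24))
  expect_equal(length(cl$week_start), 60L)
  expect_equal(diff(as.numeric(cl$week_start)), rep(7, 59))
  # boosted cells sit in the high precipitation category
  expect_true(all(cl$precipitation[c("NW", "RP"), 20:23] >= 0.035))
  # a zero boost leaves the generator path untouched
  cl0a <- simulate_climate(g, n_weeks = 30, seed = 9,
                           event = list(weeks = 10:13, regions = "NW",
                                        precip_boost = 0))
  cl0b <- simulate_climate(g, n_weeks = 30, seed = 9,
                           event = list(weeks = integer(0),
                                        regions = character(0),
                                        precip_boost = 0.04))
  expect_identical(cl0a$precipitation, cl0b$precipitation)
  expect_error(simulate_climate(g, n_weeks = 5, seed = 1), "at least 8 weeks")
})

test_that("true_params centers the effect vectors and keeps the raw input", {
  tp <- true_params()
  expect_equal(mean(tp$f_temp), 0)
  expect_equal(mean(tp$f_precip), 0)
  expect_equal(tp$f_temp_raw, c(0, -0.005, 0, 0.020))
  expect_equal(tp$f_temp, tp$f_temp_raw - mean(tp$f_temp_raw))
  expect_error(true_params(event_weeks = c(1, 3)), "contiguous")
  expect_error(true_params(ar_rho = 1.2))
})

test_that("simulate_panel obeys the generative contract", {
  b <- tiny_bundle(seed = 2)
  expect_s3_class(b$panel, "sentiment_panel")
  expect_true(all(b$panel$ntw <= b$panel$ttw))
  expect_true(all(b$panel$ttw >= 1L))
  expect_equal(dim(b$latents), dim(b$panel$ntw))
  # identical seed, identical bundle
  b2 <- tiny_bundle(seed = 2)
  expect_identical(b$panel$ntw, b2$panel$ntw)
  expect_identical(b$latents, b2$latents)
  # overflow guard
  g <- path_graph(2)
  cl <- simulate_climate(g, n_weeks = 10, seed = 1,
                         event = list(weeks = integer(0),
                                      regions = character(0), precip_boost = 0))
  expect_error(simulate_panel(g, cl, true_params(intercept = 15),
                              mean_ttw = 1e6, seed = 1), "overflow")
})

test_that("null generator hits the baseline rate", {
  g <- german_region_graph()
  cl <- simulate_climate(g, n_weeks = 40, seed = 5,
                         event = list(weeks = integer(0),
                                      regions = character(0), precip_boost = 0))
  tp <- true_params(f_temp = rep(0, 4), f_precip = rep(0, 3),
                    field_tau = Inf, event_effect = 0,
                    event_weeks = 10:13)
  b <- simulate_panel(g, cl, tp, mean_ttw = 2000, seed = 6)
  theta_hat <- sum(b$panel$ntw) / sum(b$panel$ttw)
  se <- sqrt(0.1 / sum(b$panel$ttw))
  expect_lt(abs(theta_hat - 0.1), 3 * se)
})

test_that("realized event relative risk matches the injected effect", {
  g <- german_region_graph()
  cl <- simulate_climate(g, n_weeks = 60, seed = 10,
                         event = list(weeks = 25:28,
                                      regions = c("NW", "RP", "SL", "HE"),
                                      precip_boost = 0.04))
  tp <- true_params(event_effect = log(1.10), event_weeks = 25:28)
  ratios <- vapply(seq_len(50), function(s) {
    b <- simulate_panel(g, cl, tp, mean_ttw = 2000, seed = 2000 + s)
    ev <- rownames(b$panel$ntw) %in% tp$exposed_regions
    # remove the known non-event structure, leaving exp(event_effect)
    base <- exp(tp$intercept) * b$panel$ttw *
      exp(b$log_relrisk - tp$event_effect *
            outer(ev, seq_len(60) %in% 25:28))
    sum(b$panel$ntw[ev, 25:28]) / sum(base[ev, 25:28])
  }, numeric(1))
  expect_gt(mean(ratios), 1.08)
  expect_lt(mean(ratios), 1.12)
})

test_that("bundles serialize to plain text", {
  b <- tiny_bundle(seed = 7, mean_ttw = 60)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("graph_edges.csv", "climate.csv", "panel.csv", "true_params.json")))))
  tp <- jsonlite::read_json(file.path(dir, "true_params.json"),
                            simplifyVector = TRUE)
  expect_equal(tp$event_effect, b$params$event_effect)
  cl2 <- read_climate_csv(file.path(dir, "climate.csv"))
  expect_equal(cl2$temperature, b$climate$temperature, ignore_attr = TRUE,
               tolerance = 1e-12)
})
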