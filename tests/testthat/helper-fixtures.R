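# Small shared fixtures, built in code at test time.

tiny_graph <- function() {
  region_graph(c("A", "B", "C", "D"),
               rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 3)))
}

path_graph <- function(n = 3) {
  region_graph(sprintf("P%d", seq_len(n)),
               cbind(seq_len(n - 1), seq_len(n - 1) + 1L))
}

# A small synthetic study: 4 regions x 16 weeks with an event in weeks 7-10.
tiny_bundle <- function(seed = 1, mean_ttw = 400, event_effect = log(1.1)) {
  g <- tiny_graph()
  cl <- simulate_climate(g, n_weeks = 16, start_date = "2019-01-01",
                         event = list(weeks = 7:10, regions = c("A", "B"),
                                      precip_boost = 0.04),
                         seed = seed)
  tp <- true_params(field_tau = 500, ar_rho = 0.8,
                    event_effect = event_effect,
                    exposed_regions = c("A", "B"), event_weeks = 7:10)
  simulate_panel(g, cl, tp, mean_ttw = mean_ttw, seed = seed + 1000)
}

# Windows aligned with the tiny bundle's week grid (weeks 3-6 / 7-10 / 11-14).
tiny_windows <- function() {
  event_windows(before = c("2019-01-15", "2019-02-11"),
                during = c("2019-02-12", "2019-03-11"),
                after = c("2019-03-12", "2019-04-08"))
}

# Dense constrained pseudo-inverse covariance of a gmrf_prec (independent
# oracle for the sampler).
pseudo_cov <- function(p, tol = 1e-9) {
  Q <- as.matrix(p$Q)
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}
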