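test_that("icar_precision is degree-minus-adjacency with a sum-to-zero null space", {
  p <- icar_precision(path_graph(3), tau = 1)
  expect_equal(unname(as.matrix(p$Q)),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(p$rank_deficiency, 1L)

  p2 <- icar_precision(path_graph(2), tau = 2)
  expect_equal(unname(as.matrix(p2$Q)), rbind(c(2, -2), c(-2, 2)))
  expect_equal(sort(eigen(as.matrix(p2$Q))$values), c(0, 4), tolerance = 1e-12)

  for (g in list(tiny_graph(), german_region_graph(),
                 make_region_graph(3, 3, seed = 2))) {
    q <- icar_precision(g, tau = 1.7)
    expect_equal(max(abs(Matrix::rowSums(q$Q))), 0, tolerance = 1e-12)
    ev <- eigen(as.matrix(q$Q), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev < 1e-8 * max(ev)), 1L)  # exactly span(1)
  }
  expect_error(icar_precision(region_graph(c("a", "b", "c"), cbind(1, 2))),
               "connected")
})

test_that("ar1_precision matches its closed form and is positive definite", {
  a <- ar1_precision(2, rho = 0.5, tau = 1)
  expect_equal(unname(as.matrix(a$Q)), rbind(c(1, -0.5), c(-0.5, 1)))
  # inverse = stationary covariance with variance 1/(tau (1 - rho^2))
  expect_equal(diag(solve(as.matrix(a$Q))), rep(1 / (1 - 0.25), 2),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(ar1_precision(5, 0, tau = 3)$Q)),
               diag(3, 5), tolerance = 1e-14)
  for (rho in c(-0.9, 0.3, 0.97)) {
    ev <- eigen(as.matrix(ar1_precision(12, rho, tau = 2)$Q),
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(ar1_precision(4, 1.0), "rho")
  expect_error(ar1_precision(4, -1.2), "rho")
})

test_that("chain_precision covers both prior kinds over category levels", {
  expect_equal(unname(as.matrix(chain_precision(3, "independent", tau = 1)$Q)),
               diag(3))
  q <- as.matrix(chain_precision(4, "ar", tau = 1, rho = 0.8)$Q)
  expect_equal(diag(q), c(1, 1.64, 1.64, 1), tolerance = 1e-12)
  expect_equal(q[1, 2], -0.8)
  expect_error(chain_precision(1, "independent"), "at least 2")
})

test_that("grid2d_icar_precision builds the lattice intrinsic CAR", {
  p22 <- grid2d_icar_precision(2, 2, tau = 1)
  expect_equal(Matrix::diag(p22$Q), rep(2, 4), ignore_attr = TRUE)
  expect_equal(max(abs(Matrix::rowSums(p22$Q))), 0)
  p34 <- grid2d_icar_precision(3, 4)
  ev <- eigen(as.matrix(p34$Q), only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8 * max(ev)), 11L)  # rank 11 on the 3x4 lattice
  # a 1 x n lattice degenerates to the chain/path intrinsic CAR
  p1n <- grid2d_icar_precision(1, 4)
  expect_equal(unname(as.matrix(p1n$Q)),
               unname(as.matrix(icar_precision(path_graph(4))$Q)))
})

test_that("spacetime_precision composes factors as a Kronecker product", {
  sp <- icar_precision(path_graph(2), tau = 1)
  te <- ar1_precision(2, rho = 0, tau = 1)
  st <- spacetime_precision(sp, te)
  expect_equal(as.matrix(st$Q),
               kronecker(as.matrix(sp$Q), as.matrix(te$Q)),
               ignore_attr = TRUE)
  # rank deficiency of ICAR x full-rank AR1 equals T, one constraint per slice
  sp3 <- icar_precision(path_graph(3))
  te5 <- ar1_precision(5, 0.6)
  st2 <- spacetime_precision(sp3, te5)
  expect_equal(st2$rank_deficiency, 5L)
  expect_equal(nrow(st2$constraints), 5L)
  ev <- eigen(as.matrix(st2$Q), only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 5L)
  # identity x identity composition
  id <- spacetime_precision(
    chain_precision(3, "independent", tau = 1),
    chain_precision(4, "independent", tau = 1), mode = "iid")
  expect_equal(as.matrix(id$Q), diag(12), ignore_attr = TRUE)
})

test_that("sample_gmrf matches constrained pseudo-inverse moments", {
  p <- icar_precision(path_graph(3))
  X <- sample_gmrf(p, seed = 42, n_samples = 50000)
  expect_equal(dim(X), c(3L, 50000L))
  # every draw satisfies the sum-to-zero constraint
  expect_lt(max(abs(colSums(X))), 1e-10)
  S <- stats::cov(t(X))
  Sp <- pseudo_cov(p)
  expect_lt(norm(S - Sp, "F") / norm(Sp, "F"), 0.05)

  # 2-node intrinsic CAR: antisymmetry is forced
  x2 <- sample_gmrf(icar_precision(path_graph(2)), seed = 1, n_samples = 100)
  expect_equal(x2[1, ], -x2[2, ], tolerance = 1e-12)

  # full-rank identity: unit variance
  pid <- chain_precision(4, "independent", tau = 1)
  Xi <- sample_gmrf(pid, seed = 7, n_samples = 50000)
  expect_true(all(abs(apply(Xi, 1, stats::var) - 1) < 0.03))

  # determinism
  expect_identical(sample_gmrf(p, seed = 11, n_samples = 5),
                   sample_gmrf(p, seed = 11, n_samples = 5))
})

test_that("factor-wise sampling of separable space-time fields matches the dense oracle", {
  st <- spacetime_precision(icar_precision(path_graph(3), tau = 2),
                            ar1_precision(4, 0.7, tau = 1))
  X <- sample_gmrf(st, seed = 5, n_samples = 40000)
  expect_lt(max(abs(st$constraints %*% X)), 1e-10)
  S <- stats::cov(t(X))
  Sp <- pseudo_cov(st)
  expect_lt(norm(S - Sp, "F") / norm(Sp, "F"), 0.06)
})

test_that("gmrf_logdensity matches the dense normal and is null-shift invariant", {
  a <- ar1_precision(4, 0.5, tau = 2)
  x <- c(0.3, -0.1, 0.2, 0.05)
  Q <- as.matrix(a$Q)
  dense <- -2 * log(2 * pi) + 0.5 * determinant(Q)$modulus -
    0.5 * as.numeric(x %*% Q %*% x)
  expect_equal(gmrf_logdensity(x, a), as.numeric(dense), tolerance = 1e-10)

  # identity: density gap between 0 and a unit vector is exactly 1/2
  pid <- chain_precision(3, "independent", tau = 1)
  expect_equal(gmrf_logdensity(c(0, 0, 0), pid) -
                 gmrf_logdensity(c(1, 0, 0), pid), 0.5)

  # intrinsic CAR: invariant to adding a constant (the null direction)
  p <- icar_precision(path_graph(3))
  x0 <- c(0.2, -0.5, 0.3)
  expect_equal(gmrf_logdensity(x0, p),
               gmrf_logdensity(x0 + 5, p, check = FALSE))
  expect_error(gmrf_logdensity(x0 + 5, p), "constraints")
})

test_that("precision structures serialize to text and back", {
  p <- icar_precision(tiny_graph(), tau = 3)
  path <- file.path(withr::local_tempdir(), "prec")
  write_precision(p, path)
  p2 <- read_precision(path)
  expect_equal(as.matrix(p2$Q), as.matrix(p$Q), ignore_attr = TRUE)
  expect_equal(p2$rank_deficiency, p$rank_deficiency)
  expect_equal(p2$constraints, p$constraints)
  expect_equal(p2$tau, p$tau)
})
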