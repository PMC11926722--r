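#' Gaussian Markov random field precision structures
#'
#' A `gmrf_prec` bundles a (possibly intrinsic) sparse precision matrix with
#' the bookkeeping the rest of the package needs: the scale multiplier, the
#' linear constraints that make intrinsic models identifiable, and the rank
#' deficiency. Intrinsic models (the Besag / intrinsic CAR family) have
#' `rank_deficiency > 0`; their null space is spanned by the stored
#' constraint vectors, and densities are defined through the generalized
#' (pseudo-) determinant over the non-null eigenvalues.
#'
#' @name gmrf_prec
#' @keywords internal
NULL

new_gmrf_prec <- function(Q, tau, rank_deficiency = 0L, constraints = NULL,
                          kron = NULL, kind = "generic") {
  Q <- methods::as(methods::as(Matrix::forceSymmetric(Q), "generalMatrix"),
                   "CsparseMatrix")
  structure(list(Q = Q, n = nrow(Q), tau = tau,
                 rank_deficiency = as.integer(rank_deficiency),
                 constraints = constraints, kron = kron, kind = kind),
            class = "gmrf_prec")
}

#' @export
print.gmrf_prec <- function(x, ...) {
  cat(sprintf("gmrf_prec [%s]: n = %d, tau = %g, rank deficiency = %d, %d constraint(s)\n",
              x$kind, x$n, x$tau, x$rank_deficiency,
              if (is.null(x$constraints)) 0L else nrow(x$constraints)))
  invisible(x)
}

#' Intrinsic CAR (Besag) precision on a region graph
#'
#' Builds the intrinsic conditional autoregressive precision
#' `Q = tau * (D - A)` where `D` is the diagonal degree matrix and `A` the
#' adjacency matrix of the neighbourhood graph. On a connected graph the
#' matrix has a one-dimensional null space spanned by the constant vector, so
#' the returned object carries `rank_deficiency = 1` and a sum-to-zero
#' constraint.
#'
#' @param graph a connected [region_graph()].
#' @param tau positive precision scale.
#' @return a `gmrf_prec`.
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
#' icar_precision(g, tau = 1)$Q
#' @export
icar_precision <- function(graph, tau = 1) {
  stopifnot(inherits(graph, "region_graph"), tau > 0)
  if (!is_connected_graph(graph))
    stop("icar_precision requires a connected graph (disconnected graphs ",
         "would need one sum-to-zero constraint per component)")
  A <- adjacency_matrix(graph)
  Q <- tau * (Matrix::Diagonal(x = Matrix::rowSums(A)) - A)
  new_gmrf_prec(Q, tau, rank_deficiency = 1L,
                constraints = matrix(1, 1L, n_regions(graph)), kind = "icar")
}

#' Stationary AR1 precision matrix
#'
#' Tridiagonal precision of a stationary first-order autoregression
#' `x_t = rho * x_(t-1) + eps_t`, `eps_t ~ N(0, 1/tau)`: diagonal
#' `tau * (1, 1 + rho^2, ..., 1 + rho^2, 1)`, off-diagonal `-tau * rho`.
#' `tau` is the innovation precision; the stationary marginal variance is
#' `1 / (tau * (1 - rho^2))`. Full rank, no constraint.
#'
#' @param n length of the chain, at least 2.
#' @param rho autocorrelation, strictly inside (-1, 1).
#' @param tau positive innovation precision.
#' @return a `gmrf_prec`.
#' @export
ar1_precision <- function(n, rho, tau = 1) {
  n <- as.integer(n)
  stopifnot(n >= 2L, tau > 0)
  if (!is.finite(rho) || abs(rho) >= 1) stop("ar1_precision needs |rho| < 1")
  d <- tau * c(1, rep(1 + rho^2, n - 2L), 1)
  Q <- Matrix::bandSparse(n, k = c(-1L, 0L, 1L),
                          diagonals = list(rep(-tau * rho, n - 1L), d,
                                           rep(-tau * rho, n - 1L)))
  p <- new_gmrf_prec(Q, tau, kind = "ar1")
  p$rho <- rho
  p
}

#' Chain prior over ordered covariate categories
#'
#' Random effects of a categorized covariate are given a Gaussian prior on
#' the chain graph linking consecutive category levels: either a stationary
#' AR1 process on the chain, or independent levels (`tau * I`). These are the
#' priors used for the temperature (4 levels) and precipitation (3 levels)
#' effect vectors.
#'
#' @param n_levels number of category levels, at least 2.
#' @param kind `"ar"` or `"independent"`.
#' @param tau positive precision.
#' @param rho AR parameter, used when `kind = "ar"`.
#' @return a `gmrf_prec`.
#' @export
chain_precision <- function(n_levels, kind = c("independent", "ar"),
                            tau = 1, rho = 0.5) {
  kind <- match.arg(kind)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("a chain prior needs at least 2 levels")
  if (kind == "ar") {
    p <- ar1_precision(n_levels, rho, tau)
    p$kind <- "chain_ar"
    p
  } else {
    new_gmrf_prec(tau * Matrix::Diagonal(n_levels), tau, kind = "chain_independent")
  }
}

#' Two-dimensional intrinsic CAR on a lattice of category pairs
#'
#' Intrinsic CAR precision on the `n1 x n2` 4-neighbour lattice, used as the
#' prior for the cross-product interaction of two categorized covariates
#' (cells ordered with the second index varying fastest). Rank deficiency 1
#' with a sum-to-zero constraint, as for any connected intrinsic CAR.
#'
#' @param n1,n2 lattice dimensions with `n1 * n2 >= 2`.
#' @param tau positive precision scale.
#' @return a `gmrf_prec`.
#' @export
grid2d_icar_precision <- function(n1, n2, tau = 1) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L || n1 * n2 < 2L) stop("need n1 * n2 >= 2 lattice cells")
  idx <- function(a, b) (a - 1L) * n2 + b
  edges <- NULL
  for (a in seq_len(n1)) for (b in seq_len(n2)) {
    if (b < n2) edges <- rbind(edges, c(idx(a, b), idx(a, b + 1L)))
    if (a < n1) edges <- rbind(edges, c(idx(a, b), idx(a + 1L, b)))
  }
  g <- region_graph(sprintf("C%02d", seq_len(n1 * n2)), edges)
  p <- icar_precision(g, tau)
  p$kind <- "grid2d_icar"
  p$dims <- c(n1, n2)
  p
}

#' Separable space-time precision
#'
#' Composes a spatial and a temporal `gmrf_prec` into a precision over the
#' `n_regions * n_weeks` space-time cells. Cells are ordered region-major
#' with the week index varying fastest, i.e. cell `(i, t)` sits at position
#' `(i - 1) * T + t`, matching `kronecker(Q_space, Q_time)`.
#'
#' Modes:
#' * `separable_kronecker` - `Q = Q_space %x% Q_time` (the Kronecker product).
#'   When the spatial part is intrinsic its null space crossed with time
#'   yields one sum-to-zero constraint per temporal slice; these are generated
#'   automatically (and symmetrically for an intrinsic temporal part).
#' * `space_only_iid_time` - spatial structure with independent weeks:
#'   `Q = Q_space %x% (tau_t * I)`.
#' * `iid` - fully independent cells, `Q = tau_s * tau_t * I`.
#'
#' @param spatial,temporal `gmrf_prec` objects for the spatial (n regions)
#'   and temporal (T weeks) factors.
#' @param mode composition mode, see Details.
#' @return a `gmrf_prec` over `n * T` cells; the factor structure is retained
#'   internally so sampling and log-determinants can work factor-wise.
#' @export
spacetime_precision <- function(spatial, temporal,
                                mode = c("separable_kronecker",
                                         "space_only_iid_time", "iid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spatial, "gmrf_prec"), inherits(temporal, "gmrf_prec"))
  n <- spatial$n; TT <- temporal$n
  if (mode != "separable_kronecker") {
    temporal <- new_gmrf_prec(temporal$tau * Matrix::Diagonal(TT),
                              temporal$tau, kind = "iid")
  }
  if (mode == "iid") {
    spatial <- new_gmrf_prec(spatial$tau * Matrix::Diagonal(n),
                             spatial$tau, kind = "iid")
  }
  Q <- spatial$Q %x% temporal$Q
  cons <- NULL
  rd_s <- spatial$rank_deficiency; rd_t <- temporal$rank_deficiency
  if (rd_s > 0) {
    # null(Q_s) x R^T: one constraint per temporal slice and spatial null vector
    for (k in seq_len(rd_s)) {
      u <- spatial$constraints[k, ]
      for (t in seq_len(TT)) {
        v <- numeric(n * TT); v[(seq_len(n) - 1L) * TT + t] <- u
        cons <- rbind(cons, v)
      }
    }
  }
  if (rd_t > 0) {
    for (k in seq_len(rd_t)) {
      u <- temporal$constraints[k, ]
      for (i in seq_len(n)) {
        v <- numeric(n * TT); v[(i - 1L) * TT + seq_len(TT)] <- u
        cons <- rbind(cons, v)
      }
    }
    if (rd_s > 0) cons <- cons[-nrow(cons), , drop = FALSE]  # drop one redundant row
  }
  rank_def <- n * TT - (n - rd_s) * (TT - rd_t)
  p <- new_gmrf_prec(Q, spatial$tau * temporal$tau, rank_deficiency = rank_def,
                     constraints = cons, kron = list(spatial = spatial,
                                                     temporal = temporal),
                     kind = paste0("spacetime_", mode))
  p
}

# Eigendecomposition helper: returns positive eigenvalues and the matching
# eigenvectors (dropping the null space of intrinsic models).
prec_pos_eigen <- function(p, tol = 1e-9) {
  e <- eigen(as.matrix(p$Q), symmetric = TRUE)
  thr <- tol * max(e$values, 1)
  keep <- e$values > thr
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}

# Generalized log-determinant (product of non-null eigenvalues), factor-wise
# for separable structures.
prec_gen_logdet <- function(p, tol = 1e-9) {
  if (!is.null(p$kron)) {
    es <- prec_pos_eigen(p$kron$spatial, tol)
    et <- prec_pos_eigen(p$kron$temporal, tol)
    return(length(et$values) * sum(log(es$values)) +
             length(es$values) * sum(log(et$values)))
  }
  sum(log(prec_pos_eigen(p, tol)$values))
}

#' Sample from a (possibly intrinsic) GMRF
#'
#' Draws from `N(0, Q^-)` restricted to the subspace satisfying the stored
#' linear constraints. Intrinsic models are sampled spectrally: standard
#' normals are scaled by the inverse square roots of the positive eigenvalues
#' and rotated back, which places every draw in the orthogonal complement of
#' the null space (so, e.g., intrinsic CAR draws sum to zero exactly).
#' Separable space-time structures are sampled factor-wise from the factor
#' eigendecompositions, which keeps large space-time fields cheap. Any stored
#' constraint not already implied by the null space is imposed by
#' conditioning by kriging.
#'
#' @param p a `gmrf_prec`.
#' @param seed integer seed (draws are deterministic given the seed).
#' @param n_samples number of draws.
#' @return a numeric vector (one draw) or an `n x n_samples` matrix.
#' @export
sample_gmrf <- function(p, seed = NULL, n_samples = 1L) {
  stopifnot(inherits(p, "gmrf_prec"))
  x <- with_seed(seed, {
    if (!is.null(p$kron)) {
      es <- prec_pos_eigen(p$kron$spatial)
      et <- prec_pos_eigen(p$kron$temporal)
      n <- p$kron$spatial$n; TT <- p$kron$temporal$n
      ks <- length(es$values); kt <- length(et$values)
      out <- matrix(0, n * TT, n_samples)
      for (s in seq_len(n_samples)) {
        z <- matrix(stats::rnorm(kt * ks), kt, ks)
        B <- z / sqrt(outer(et$values, es$values))
        X <- et$vectors %*% B %*% t(es$vectors)  # T x n, week fastest
        out[, s] <- as.vector(X)
      }
      out
    } else {
      e <- prec_pos_eigen(p)
      k <- length(e$values)
      z <- matrix(stats::rnorm(k * n_samples), k, n_samples)
      e$vectors %*% (z / sqrt(e$values))
    }
  })
  x <- impose_extra_constraints(p, x)
  if (n_samples == 1L) as.vector(x) else x
}

# Conditioning by kriging for constraints that are not already in the
# precision's null space (spectral sampling handles those exactly).
impose_extra_constraints <- function(p, x, tol = 1e-8) {
  C <- p$constraints
  if (is.null(C)) return(x)
  viol <- max(abs(C %*% x))
  if (viol <= tol * max(1, max(abs(x)))) return(x)
  e <- prec_pos_eigen(p)
  W <- t(e$vectors) %*% t(C)                     # k x m
  act <- colSums(W^2) > tol^2
  if (!any(act)) return(x)
  W <- W[, act, drop = FALSE]
  SigC <- e$vectors %*% (W / e$values)           # n x m_act
  S <- crossprod(W, W / e$values)                # m_act x m_act
  x - SigC %*% solve(S, C[act, , drop = FALSE] %*% x)
}

#' Log-density of a GMRF
#'
#' Evaluates the Gaussian log-density `0.5 * logdet+(Q) - 0.5 * x'Qx -
#' 0.5 * rank * log(2*pi)` where `logdet+` is the generalized
#' log-determinant over the non-null eigenvalues and `rank = n -
#' rank_deficiency`. For full-rank structures this is the ordinary
#' multivariate normal log-density; for intrinsic structures it is the
#' density on the constraint subspace, invariant to shifts along the null
#' space.
#'
#' @param x numeric vector of length `p$n`, satisfying the constraints.
#' @param p a `gmrf_prec`.
#' @param tol relative tolerance for the constraint check.
#' @param check verify that `x` satisfies the constraints; set `FALSE` to
#'   evaluate the generalized density of an intrinsic model at a point
#'   carrying a null-space component (the value is then the density of the
#'   point's projection, since the quadratic form is blind to the null
#'   space).
#' @return scalar log-density.
#' @export
gmrf_logdensity <- function(x, p, tol = 1e-6, check = TRUE) {
  stopifnot(inherits(p, "gmrf_prec"), length(x) == p$n)
  if (check && !is.null(p$constraints)) {
    viol <- max(abs(p$constraints %*% x))
    if (viol > tol * max(1, max(abs(x))))
      stop("x violates the GMRF constraints (max violation ", signif(viol, 3), ")")
  }
  rank <- p$n - p$rank_deficiency
  quad <- as.numeric(x %*% (p$Q %*% x))
  0.5 * prec_gen_logdet(p) - 0.5 * quad - 0.5 * rank * log(2 * pi)
}

#' Serialize a precision structure to plain text
#'
#' Writes the sparse matrix in coordinate format (`row,col,value`, upper
#' triangle plus diagonal) to `<path>.coo.csv` and a JSON header with `tau`,
#' `rank_deficiency` and the constraint vectors to `<path>.json`.
#'
#' @param p a `gmrf_prec`.
#' @param path path prefix (no extension).
#' @return `write_precision` returns `path` invisibly; `read_precision`
#'   rebuilds the `gmrf_prec` (without the factor structure).
#' @export
write_precision <- function(p, path) {
  Tm <- methods::as(Matrix::triu(p$Q), "TsparseMatrix")
  utils::write.csv(data.frame(row = Tm@i + 1L, col = Tm@j + 1L, value = Tm@x),
                   paste0(path, ".coo.csv"), row.names = FALSE)
  hdr <- list(n = p$n, tau = p$tau, rank_deficiency = p$rank_deficiency,
              kind = p$kind, constraints = p$constraints)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_precision
#' @export
read_precision <- function(path) {
  coo <- utils::read.csv(paste0(path, ".coo.csv"))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  Q <- Matrix::sparseMatrix(i = coo$row, j = coo$col, x = coo$value,
                            dims = c(hdr$n, hdr$n), symmetric = TRUE)
  cons <- hdr$constraints
  if (!is.null(cons)) cons <- matrix(as.numeric(cons), ncol = hdr$n)
  new_gmrf_prec(Q, hdr$tau, hdr$rank_deficiency, constraints = cons,
                kind = hdr$kind)
}
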