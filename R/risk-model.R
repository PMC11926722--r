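#' Global negative proportion
#'
#' The baseline rate of the model: the ratio of negative to total documents
#' over the whole panel, `sum(NTw) / sum(TTW)`.
#'
#' @param panel a [sentiment_panel()].
#' @return a proportion in `[0, 1]`.
#' @export
compute_theta_tot <- function(panel) {
  stopifnot(inherits(panel, "sentiment_panel"))
  tot <- sum(as.numeric(panel$ttw))
  if (tot == 0) stop("panel has zero total exposure")
  sum(as.numeric(panel$ntw)) / tot
}

#' Configuration of the relative-risk model and its fitter
#'
#' @param spatial spatial structure of the space-time field: `"icar"`
#'   (intrinsic CAR on the region graph) or `"iid"` (independent regions).
#' @param temporal temporal structure: `"ar1"` or `"iid"`.
#' @param rho AR1 correlation of the temporal factor.
#' @param field_tau precision scale of the spatial factor; `NULL` selects it
#'   by empirical Bayes over `field_tau_grid`.
#' @param field_tau_grid candidate precisions for the empirical-Bayes search.
#' @param tau_temp,tau_precip,tau_inter fixed prior precisions of the
#'   covariate effect blocks (weak by default: prior standard deviation 1 on
#'   the log-relative-risk scale, far wider than any plausible effect).
#' @param effect_prior chain prior over category levels: `"independent"` or
#'   `"ar"` (with `effect_rho`).
#' @param effect_rho AR parameter of the chain prior when `effect_prior="ar"`.
#' @param interaction include the temperature x precipitation interaction
#'   block with a two-dimensional intrinsic CAR prior.
#' @param field_constraint identifiability convention for an intrinsic
#'   spatial field. `"global"` (default) decomposes the field into a
#'   slice-centered part (every weekly spatial slice sums to zero) plus a
#'   free weekly region-average level with a flat prior and a single
#'   sum-to-zero constraint -- an exact reparameterization of the field with
#'   only one overall constraint. Week-specific shocks common to many
#'   regions (an extreme event, say) are then absorbed by the weekly level
#'   instead of being squeezed out of the model. `"per_slice"` drops the
#'   weekly level, forcing every weekly slice of the field to sum to zero,
#'   so the field carries pure within-week spatial contrasts only.
#' @param hyper_a,hyper_b gamma hyperprior parameters on the field precision
#'   (wide by default).
#' @param max_iter,tol Newton iteration cap and step-size convergence
#'   tolerance of the inner optimization.
#' @param sd_components `"all"` computes posterior standard deviations for
#'   every latent coordinate; `"effects"` restricts them to the intercept and
#'   covariate-effect blocks (cheaper in replicate studies).
#' @return a `risk_config` list.
#' @export
risk_config <- function(spatial = c("icar", "iid"), temporal = c("ar1", "iid"),
                        rho = 0.5, field_tau = NULL,
                        field_tau_grid = 10^seq(2, 5, length.out = 7),
                        tau_temp = 1, tau_precip = 1, tau_inter = 1,
                        effect_prior = c("independent", "ar"), effect_rho = 0.5,
                        interaction = FALSE,
                        field_constraint = c("global", "per_slice"),
                        hyper_a = 1, hyper_b = 5e-5,
                        max_iter = 50L, tol = 1e-10,
                        sd_components = c("all", "effects")) {
  structure(list(spatial = match.arg(spatial), temporal = match.arg(temporal),
                 rho = rho, field_tau = field_tau,
                 field_tau_grid = field_tau_grid,
                 tau_temp = tau_temp, tau_precip = tau_precip,
                 tau_inter = tau_inter,
                 effect_prior = match.arg(effect_prior),
                 effect_rho = effect_rho,
                 interaction = isTRUE(interaction),
                 field_constraint = match.arg(field_constraint),
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 max_iter = as.integer(max_iter), tol = tol,
                 sd_components = match.arg(sd_components)),
            class = "risk_config")
}

#' Assemble the relative-risk model
#'
#' Builds the latent structure of the Poisson relative-risk model
#' `NTw(i,t) ~ Poisson(theta_tot * TTW(i,t) * relrisk(i,t))` with
#' `log relrisk = intercept + field(i,t) + f_temp[cat_T(i,t)] +
#' f_precip[cat_P(i,t)] (+ f_int[cat_T, cat_P])`. Each cell gets its
#' covariate categories from the schemes, the latent blocks get their GMRF
#' priors from `config`, and the offset `log(theta_tot * TTW)` is computed
#' with zero-exposure cells dropped from the likelihood (the field still
#' smooths across them).
#'
#' Cells are ordered region-major with the week index fastest: cell `(i, t)`
#' is row `(i - 1) * T + t`.
#'
#' @param panel a [sentiment_panel()].
#' @param climate a [climate_panel()] on the same regions and weeks.
#' @param graph a [region_graph()].
#' @param schemes list with `temperature` and `precipitation`
#'   [category_scheme()]s.
#' @param config a [risk_config()].
#' @return a `risk_model_spec`.
#' @export
build_model <- function(panel, climate, graph,
                        schemes = list(temperature = temp_scheme(),
                                       precipitation = precip_scheme()),
                        config = risk_config()) {
  stopifnot(inherits(panel, "sentiment_panel"),
            inherits(climate, "climate_panel"),
            inherits(graph, "region_graph"))
  n <- n_regions(graph); TT <- ncol(panel$ntw)
  if (nrow(panel$ntw) != n) stop("panel and graph disagree on regions")
  if (!identical(dim(climate$temperature), dim(panel$ntw)))
    stop("climate and panel dimensions differ")
  if (any(panel$ttw > 0 & (is.na(climate$temperature) | is.na(climate$precipitation))))
    stop("cells with exposure but missing climate")

  K_t <- n_categories(schemes$temperature)
  K_p <- n_categories(schemes$precipitation)
  cat_t <- matrix(categorize(climate$temperature, schemes$temperature), n, TT)
  cat_p <- matrix(categorize(climate$precipitation, schemes$precipitation), n, TT)

  ncell <- n * TT
  # cell k = (i - 1) * TT + t  <=>  as.vector(t(M)) for an n x TT matrix M
  y <- as.vector(t(panel$ntw))
  ttw <- as.vector(t(panel$ttw))
  theta_tot <- compute_theta_tot(panel)
  mask <- ttw > 0
  offset <- ifelse(mask, log(theta_tot * pmax(ttw, 1)), 0)
  ct <- as.vector(t(cat_t)); cp <- as.vector(t(cat_p))

  has_week_level <- config$spatial == "icar" &&
    config$field_constraint == "global"
  idx <- list(intercept = 1L, field = 1L + seq_len(ncell),
              f_temp = 1L + ncell + seq_len(K_t),
              f_precip = 1L + ncell + K_t + seq_len(K_p))
  p <- 1L + ncell + K_t + K_p
  if (config$interaction) {
    idx$f_inter <- p + seq_len(K_t * K_p)
    p <- p + K_t * K_p
  }
  if (has_week_level) {
    idx$week_level <- p + seq_len(TT)
    p <- p + TT
  }

  cells <- seq_len(ncell)
  Ai <- c(cells, cells, cells, cells)
  Aj <- c(rep(1L, ncell), idx$field, idx$f_temp[ct], idx$f_precip[cp])
  if (config$interaction) {
    Ai <- c(Ai, cells)
    Aj <- c(Aj, idx$f_inter[(ct - 1L) * K_p + cp])
  }
  if (has_week_level) {
    Ai <- c(Ai, cells)
    Aj <- c(Aj, idx$week_level[(cells - 1L) %% TT + 1L])
  }
  A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = 1, dims = c(ncell, p))

  # linear constraints (rows orthonormal): sum-to-zero per weekly slice of
  # the slice-centered field when the spatial factor is intrinsic, one
  # sum-to-zero on the weekly level, and one per effect block
  cons <- list()
  if (config$spatial == "icar") {
    for (t in seq_len(TT)) {
      v <- numeric(p); v[idx$field[(seq_len(n) - 1L) * TT + t]] <- 1 / sqrt(n)
      cons[[length(cons) + 1L]] <- v
    }
  }
  blks <- c(if (has_week_level) "week_level", "f_temp", "f_precip",
            if (config$interaction) "f_inter")
  for (blk in blks) {
    v <- numeric(p); v[idx[[blk]]] <- 1 / sqrt(length(idx[[blk]]))
    cons[[length(cons) + 1L]] <- v
  }
  C <- do.call(rbind, cons)

  structure(list(
    n = n, TT = TT, p = p, idx = idx, A = A, C = C,
    has_week_level = has_week_level,
    y = y, ttw = ttw, mask = mask, offset = offset,
    theta_tot = theta_tot, cat_t = cat_t, cat_p = cat_p,
    K_t = K_t, K_p = K_p, schemes = schemes, graph = graph,
    week_start = panel$week_start, region_ids = graph$region_ids,
    config = config), class = "risk_model_spec")
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf("risk_model_spec: %d regions x %d weeks, %d latent coordinates, theta_tot = %.4f\n",
              x$n, x$TT, x$p, x$theta_tot))
  cat(sprintf("  field: %s space x %s time; interaction: %s; %d constraint(s)\n",
              x$config$spatial, x$config$temporal,
              if (x$config$interaction) "yes" else "no", nrow(x$C)))
  invisible(x)
}

# GMRF prior blocks of the model at given hyperparameters.
model_prior_blocks <- function(model, field_tau, rho = model$config$rho) {
  cfg <- model$config
  sp <- if (cfg$spatial == "icar") icar_precision(model$graph, field_tau)
        else new_gmrf_prec(field_tau * Matrix::Diagonal(model$n), field_tau,
                           kind = "iid")
  te <- if (cfg$temporal == "ar1") ar1_precision(model$TT, rho, tau = 1)
        else new_gmrf_prec(Matrix::Diagonal(model$TT), 1, kind = "iid")
  blocks <- list(field = spacetime_precision(sp, te))
  blocks$f_temp <- chain_precision(model$K_t, cfg$effect_prior, cfg$tau_temp,
                                   cfg$effect_rho)
  blocks$f_precip <- chain_precision(model$K_p, cfg$effect_prior,
                                     cfg$tau_precip, cfg$effect_rho)
  if (cfg$interaction)
    blocks$f_inter <- grid2d_icar_precision(model$K_t, model$K_p, cfg$tau_inter)
  blocks
}

# Joint prior precision over the full latent vector (flat on the intercept
# and on the weekly field level, which only the likelihood and the
# sum-to-zero constraint pin down).
assemble_prior_precision <- function(model, blocks) {
  parts <- c(list(Matrix::Matrix(0, 1, 1, sparse = TRUE)),
             lapply(blocks, function(b) b$Q))
  if (model$has_week_level)
    parts <- c(parts, list(Matrix::Matrix(0, model$TT, model$TT, sparse = TRUE)))
  Matrix::bdiag(parts)
}

#' Joint log-posterior of the latent field
#'
#' Evaluates `sum over observed cells of [NTw * eta - mu]` with
#' `eta = offset + intercept + field + covariate effects` and
#' `mu = exp(eta)`, plus the GMRF log-prior of every latent block (flat prior
#' on the intercept), exactly up to a constant not depending on the latents.
#' Used directly by the fitter's line search and exported so that the
#' Gaussian-approximation mode can be cross-checked against brute-force
#' maximization.
#'
#' @param model a `risk_model_spec`.
#' @param latents numeric vector of length `model$p` satisfying the model's
#'   constraints.
#' @param field_tau,rho hyperparameters of the space-time field prior.
#' @param include_prior include the GMRF prior terms (set `FALSE` for the
#'   pure Poisson log-likelihood part).
#' @return scalar log-density (up to an additive constant).
#' @export
log_posterior <- function(model, latents, field_tau, rho = model$config$rho,
                          include_prior = TRUE) {
  stopifnot(inherits(model, "risk_model_spec"), length(latents) == model$p)
  eta <- model$offset + as.vector(model$A %*% latents)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  m <- model$mask
  ll <- sum(model$y[m] * eta[m] - exp(eta[m]))
  if (!include_prior) return(ll)
  blocks <- model_prior_blocks(model, field_tau, rho)
  for (nm in names(blocks))
    ll <- ll + gmrf_logdensity(latents[model$idx[[nm]]], blocks[[nm]],
                               check = FALSE)
  ll
}

# Penalized Poisson log-likelihood used inside the Newton loop (prior
# log-determinants are constant in the latents and omitted).
penalized_ll <- function(model, Qp, x) {
  eta <- model$offset + as.vector(model$A %*% x)
  m <- model$mask
  if (any(!is.finite(exp(eta[m])))) return(-Inf)
  sum(model$y[m] * eta[m] - exp(eta[m])) -
    0.5 * as.numeric(x %*% (Qp %*% x))
}

# Constrained Newton maximization of the penalized likelihood. Each step
# solves the equality-constrained quadratic subproblem exactly: the
# unconstrained Newton point is corrected by conditioning by kriging with
# respect to the orthonormal constraint rows. A penalty kappa * C'C is folded
# into the Hessian before factorization; the constrained optimum and the
# constrained covariance are invariant to it, but it removes the structural
# flatness along the constrained directions (the intercept / field-level
# confounding) that would otherwise make the kriging system ill-conditioned.
newton_mode <- function(model, Qp, x0 = NULL, max_iter = 50L, tol = 1e-10,
                        ridge = 1e-8) {
  p <- model$p; A <- model$A; C <- model$C; m <- model$mask
  x <- x0 %||% numeric(p)
  if (!is.null(C)) x <- as.vector(x - t(C) %*% (C %*% x))
  Ct <- if (is.null(C)) NULL else t(C)
  CtC <- if (is.null(C)) NULL else Matrix::crossprod(Matrix::Matrix(C, sparse = TRUE))
  lp <- penalized_ll(model, Qp, x)
  Ch <- NULL; kap <- NULL
  for (it in seq_len(max_iter)) {
    eta <- model$offset + as.vector(A %*% x)
    mu <- exp(eta) * m
    g <- as.vector(Matrix::crossprod(A, (model$y * m - mu))) -
      as.vector(Qp %*% x)
    H <- Qp + Matrix::crossprod(A * sqrt(mu)) +
      ridge * Matrix::Diagonal(p)
    if (!is.null(CtC)) {
      if (is.null(kap)) kap <- mean(Matrix::diag(H))
      H <- H + kap * CtC
    }
    Ch <- Matrix::Cholesky(H, perm = TRUE)
    xu <- x + as.vector(Matrix::solve(Ch, g))
    if (!is.null(C)) {
      XC <- as.matrix(Matrix::solve(Ch, Ct))
      S <- as.matrix(C %*% XC)
      xn <- xu - as.vector(XC %*% solve(S, as.vector(C %*% xu)))
      xn <- as.vector(xn - Ct %*% (C %*% xn))
    } else xn <- xu
    # backtracking line search on the penalized likelihood
    step <- 1; lp_new <- penalized_ll(model, Qp, x + step * (xn - x))
    while (lp_new < lp && step > 1e-10) {
      step <- step / 2
      lp_new <- penalized_ll(model, Qp, x + step * (xn - x))
    }
    delta <- max(abs(step * (xn - x)))
    x <- x + step * (xn - x)
    lp <- lp_new
    if (delta < tol) {
      return(list(x = x, lp = lp, iterations = it, converged = TRUE,
                  grad_norm = max(abs(g)), H = H, Ch = Ch))
    }
  }
  list(x = x, lp = lp, iterations = max_iter, converged = FALSE,
       grad_norm = NA_real_, H = H, Ch = Ch)
}

# Laplace-approximate log marginal likelihood at the mode, for
# empirical-Bayes hyperparameter selection. With orthonormal constraint rows
# C, logdet of the Hessian restricted to the constraint subspace is
# logdet(H) + logdet(C H^-1 C').
laplace_lml <- function(model, res, blocks, field_tau) {
  cfg <- model$config
  x <- res$x
  eta <- model$offset + as.vector(model$A %*% x)
  m <- model$mask
  ll <- sum(model$y[m] * eta[m] - exp(eta[m]) - lgamma(model$y[m] + 1))
  lprior <- 0
  for (nm in names(blocks))
    lprior <- lprior + gmrf_logdensity(x[model$idx[[nm]]], blocks[[nm]],
                                       check = FALSE)
  ldH <- 2 * Matrix::determinant(res$Ch, sqrt = TRUE)$modulus
  mrow <- if (is.null(model$C)) 0L else nrow(model$C)
  ldC <- 0
  if (mrow > 0) {
    XC <- as.matrix(Matrix::solve(res$Ch, t(model$C)))
    ldC <- determinant(as.matrix(model$C %*% XC), logarithm = TRUE)$modulus
  }
  ldZHZ <- as.numeric(ldH + ldC)
  hyper <- (cfg$hyper_a - 1) * log(field_tau) - cfg$hyper_b * field_tau
  as.numeric(ll + lprior + hyper -
               (0.5 * ldZHZ - 0.5 * (model$p - mrow) * log(2 * pi)))
}

#' Fit the relative-risk model by a constrained Gaussian approximation
#'
#' Inner loop: Newton maximization of the joint log-posterior over the
#' latents at fixed hyperparameters, with the sum-to-zero constraints imposed
#' exactly at every step (each Newton step solves its equality-constrained
#' quadratic subproblem by conditioning by kriging). The posterior is then
#' approximated by a Gaussian centered at the mode with covariance the
#' inverse negative Hessian restricted to the constraint subspace.
#'
#' Outer loop: if `config$field_tau` is `NULL`, the field precision is chosen
#' by maximizing the Laplace-approximate log marginal likelihood over
#' `config$field_tau_grid` (empirical Bayes), warm-starting each Newton run
#' from the previous mode. No sampling is involved anywhere; the fit is
#' deterministic.
#'
#' @param model a `risk_model_spec` from [build_model()].
#' @return a `risk_fit`: posterior mean and sd per latent coordinate, block
#'   views (`intercept`, `field` as an `n x T` matrix, `f_temp`, `f_precip`),
#'   selected hyperparameters, the marginal-likelihood profile, and
#'   convergence diagnostics. Solver state is retained internally so that
#'   [effect_summary()] and [rr_difference()] can propagate full posterior
#'   covariance.
#' @export
fit_risk_model <- function(model) {
  stopifnot(inherits(model, "risk_model_spec"))
  cfg <- model$config
  taus <- if (!is.null(cfg$field_tau)) cfg$field_tau else cfg$field_tau_grid
  best <- NULL; prof <- data.frame(field_tau = taus, lml = NA_real_)
  x0 <- NULL
  for (k in seq_along(taus)) {
    blocks <- model_prior_blocks(model, taus[k])
    Qp <- assemble_prior_precision(model, blocks)
    res <- newton_mode(model, Qp, x0 = x0, max_iter = cfg$max_iter,
                       tol = cfg$tol)
    if (!res$converged)
      stop("Newton did not converge at field_tau = ", taus[k],
           " within ", cfg$max_iter, " iterations (last step ",
           signif(res$grad_norm, 3), ")")
    lml <- if (length(taus) > 1) laplace_lml(model, res, blocks, taus[k])
           else NA_real_
    prof$lml[k] <- lml
    x0 <- res$x
    if (is.null(best) || (!is.na(lml) && lml > best$lml)) {
      best <- list(res = res, blocks = blocks, Qp = Qp,
                   field_tau = taus[k], lml = lml)
    }
  }
  res <- best$res
  # re-run the winner if a later grid point overwrote the warm start
  if (!identical(res$x, x0)) {
    res <- newton_mode(model, best$Qp, x0 = res$x, max_iter = cfg$max_iter,
                       tol = cfg$tol)
  }
  x <- res$x
  Ch <- res$Ch
  C <- model$C
  XC <- as.matrix(Matrix::solve(Ch, t(C)))
  CHC <- as.matrix(C %*% XC)

  sd <- rep(NA_real_, model$p)
  want <- if (cfg$sd_components == "all") seq_len(model$p)
          else c(model$idx$intercept, model$idx$f_temp, model$idx$f_precip,
                 model$idx$f_inter)
  # diag of the constrained covariance: diag(H^-1) minus the kriging correction
  if (length(want) > model$p / 2) {
    Sig <- as.matrix(Matrix::solve(Ch, Matrix::Diagonal(model$p)))
    du <- diag(Sig)
  } else {
    E <- matrix(0, model$p, length(want)); E[cbind(want, seq_along(want))] <- 1
    du <- rep(NA_real_, model$p)
    du[want] <- colSums(E * as.matrix(Matrix::solve(Ch, E)))
  }
  corr <- rowSums((XC %*% solve(CHC)) * XC)
  sd[want] <- sqrt(pmax(du[want] - corr[want], 0))

  lml_final <- laplace_lml(model, res, best$blocks, best$field_tau)
  week_level <- if (model$has_week_level) x[model$idx$week_level]
                else rep(0, model$TT)
  structure(list(
    mean = x, sd = sd,
    intercept = x[model$idx$intercept],
    field = t(matrix(x[model$idx$field], model$TT, model$n)) +
      matrix(week_level, model$n, model$TT, byrow = TRUE),
    week_level = week_level,
    f_temp = x[model$idx$f_temp], f_precip = x[model$idx$f_precip],
    f_temp_sd = sd[model$idx$f_temp], f_precip_sd = sd[model$idx$f_precip],
    f_inter = if (cfg$interaction) x[model$idx$f_inter],
    field_tau = best$field_tau, rho = cfg$rho,
    lml = lml_final, lml_profile = prof,
    diagnostics = list(iterations = res$iterations,
                       converged = res$converged,
                       grad_norm = res$grad_norm),
    model = model,
    solver = list(Ch = Ch, XC = XC, CHC = CHC)), class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("risk_fit: intercept %.4f, field_tau %g (EB), lml %.1f, %d Newton iteration(s)\n",
              x$intercept, x$field_tau, x$lml, x$diagnostics$iterations))
  cat("  f_temp  :", sprintf("%+.4f", x$f_temp), "\n")
  cat("  f_precip:", sprintf("%+.4f", x$f_precip), "\n")
  invisible(x)
}

# Constrained-posterior covariance of linear functionals L (p x k):
# L' Sigma_c L with Sigma_c = H^-1 - H^-1 C' (C H^-1 C')^-1 C H^-1.
posterior_cov_of <- function(fit, L) {
  HiL <- as.matrix(Matrix::solve(fit$solver$Ch, L))
  W <- t(fit$solver$XC) %*% L
  as.matrix(t(L) %*% HiL) - t(W) %*% solve(fit$solver$CHC, W)
}

#' Per-category covariate effect summary
#'
#' Posterior mean and 95% interval (`mean +/- 1.96 sd` on the log-RR scale,
#' transformed monotonically to the percent relative-risk scale as
#' `exp(x) - 1`) for every level of a categorized covariate effect, together
#' with the occupancy count of observed cells per level (the category
#' histogram shown under the effect curves).
#'
#' @param fit a `risk_fit`.
#' @param effect `"temperature"`, `"precipitation"` or `"interaction"`.
#' @return a data.frame with one row per category level: `level`, `label`,
#'   `mean`, `sd`, `lower95`, `upper95`, `pct`, `pct_lower95`, `pct_upper95`,
#'   `n_cells`, `significant`.
#' @export
effect_summary <- function(fit, effect = c("temperature", "precipitation",
                                           "interaction")) {
  effect <- match.arg(effect)
  model <- fit$model
  blk <- switch(effect, temperature = "f_temp", precipitation = "f_precip",
                interaction = "f_inter")
  if (blk == "f_inter" && !model$config$interaction)
    stop("the model was built without an interaction block")
  mean_ <- fit$mean[model$idx[[blk]]]
  sd_ <- fit$sd[model$idx[[blk]]]
  occ_mask <- matrix(model$mask, model$TT, model$n) |> t()
  occ <- switch(effect,
    temperature = tabulate(model$cat_t[occ_mask], model$K_t),
    precipitation = tabulate(model$cat_p[occ_mask], model$K_p),
    interaction = tabulate((model$cat_t[occ_mask] - 1L) * model$K_p +
                             model$cat_p[occ_mask], model$K_t * model$K_p))
  labels <- switch(effect,
    temperature = model$schemes$temperature$labels,
    precipitation = model$schemes$precipitation$labels,
    interaction = as.vector(outer(model$schemes$precipitation$labels,
                                  model$schemes$temperature$labels,
                                  function(p, t) paste(t, p, sep = ":"))))
  lo <- mean_ - 1.96 * sd_; hi <- mean_ + 1.96 * sd_
  data.frame(level = seq_along(mean_), label = labels,
             mean = mean_, sd = sd_, lower95 = lo, upper95 = hi,
             pct = 100 * (exp(mean_) - 1),
             pct_lower95 = 100 * (exp(lo) - 1),
             pct_upper95 = 100 * (exp(hi) - 1),
             n_cells = occ,
             significant = lo > 0 | hi < 0)
}

#' Before-to-during relative-risk difference map
#'
#' For each region, the posterior difference between the mean log relative
#' risk over the `during` window weeks and over the `before` window weeks,
#' with a 95% interval propagated through the full Gaussian-approximation
#' covariance of all involved coordinates (field, covariate effects and, for
#' the interaction, the cross block; the intercept cancels). A region is
#' flagged significant when the interval excludes zero.
#'
#' @param fit a `risk_fit`.
#' @param windows an [event_windows()]; a window containing no model week is
#'   an error.
#' @param model the `risk_model_spec`; defaults to the one stored in `fit`.
#' @return a data.frame with one row per region: `region`, `delta` (log-RR
#'   difference), `sd`, `lower95`, `upper95`, `pct`, `pct_lower95`,
#'   `pct_upper95`, `significant`.
#' @export
rr_difference <- function(fit, windows = event_windows(), model = fit$model) {
  stopifnot(inherits(fit, "risk_fit"), inherits(windows, "event_windows"))
  wk <- model$week_start
  w_before <- which(wk >= windows$before[1] & wk <= windows$before[2])
  w_during <- which(wk >= windows$during[1] & wk <= windows$during[2])
  if (length(w_before) == 0 || length(w_during) == 0)
    stop("event window contains no model week")
  n <- model$n
  L <- matrix(0, model$p, n)
  for (i in seq_len(n)) {
    if (model$has_week_level) {
      L[model$idx$week_level[w_during], i] <- 1 / length(w_during)
      L[model$idx$week_level[w_before], i] <- -1 / length(w_before)
    }
    for (t in w_during) {
      cell <- (i - 1L) * model$TT + t
      L[model$idx$field[cell], i] <- L[model$idx$field[cell], i] + 1 / length(w_during)
      L[model$idx$f_temp[model$cat_t[i, t]], i] <-
        L[model$idx$f_temp[model$cat_t[i, t]], i] + 1 / length(w_during)
      L[model$idx$f_precip[model$cat_p[i, t]], i] <-
        L[model$idx$f_precip[model$cat_p[i, t]], i] + 1 / length(w_during)
      if (model$config$interaction) {
        j <- model$idx$f_inter[(model$cat_t[i, t] - 1L) * model$K_p + model$cat_p[i, t]]
        L[j, i] <- L[j, i] + 1 / length(w_during)
      }
    }
    for (t in w_before) {
      cell <- (i - 1L) * model$TT + t
      L[model$idx$field[cell], i] <- L[model$idx$field[cell], i] - 1 / length(w_before)
      L[model$idx$f_temp[model$cat_t[i, t]], i] <-
        L[model$idx$f_temp[model$cat_t[i, t]], i] - 1 / length(w_before)
      L[model$idx$f_precip[model$cat_p[i, t]], i] <-
        L[model$idx$f_precip[model$cat_p[i, t]], i] - 1 / length(w_before)
      if (model$config$interaction) {
        j <- model$idx$f_inter[(model$cat_t[i, t] - 1L) * model$K_p + model$cat_p[i, t]]
        L[j, i] <- L[j, i] - 1 / length(w_before)
      }
    }
  }
  delta <- as.vector(t(L) %*% fit$mean)
  V <- posterior_cov_of(fit, L)
  sd_ <- sqrt(pmax(diag(V), 0))
  lo <- delta - 1.96 * sd_; hi <- delta + 1.96 * sd_
  data.frame(region = model$region_ids, delta = delta, sd = sd_,
             lower95 = lo, upper95 = hi,
             pct = 100 * (exp(delta) - 1),
             pct_lower95 = 100 * (exp(lo) - 1),
             pct_upper95 = 100 * (exp(hi) - 1),
             significant = lo > 0 | hi < 0)
}
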