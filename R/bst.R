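#' Specify a Bayesian spatio-temporal effects model
#'
#' The model decomposes the log relative level of an indicator into additive
#' spatial, temporal and space-time interaction effects:
#' \deqn{\log(\theta_{it}) = \beta_0 + \sum_k \beta_k x_{kit} + \varphi_i
#'   + \Phi_t + \delta_{it} + \epsilon_{it}}
#' where \eqn{\theta_{it}} is the indicator value of region i in year t
#' divided by the national baseline (the unweighted cross-region mean) of
#' that year. \eqn{\varphi} carries a proper Leroux conditional
#' autoregressive prior on the adjacency graph with precision
#' \eqn{\tau_\varphi^{-2}\,(\rho (D - W) + (1-\rho) I)}; \eqn{\Phi} a
#' first-order random walk (or iid) prior; \eqn{\delta_{it}} iid normal.
#' The likelihood is Gaussian on the log scale -- the response is a smooth
#' positive ratio, not a count. Estimation is by Markov chain Monte Carlo:
#' conjugate Gibbs updates for all Gaussian blocks and variances, and a
#' Metropolis random-walk step for \eqn{\rho} on a uniform(0, 1) prior when
#' `rho_spatial = "estimated"`.
#'
#' @param response indicator modelled (`"epr"`, `"nhi"`, `"nbhi"`, `"nhtp"`)
#' @param covariates character vector of covariate indicator names (possibly
#'   empty); covariates are z-scored internally and the transform recorded
#'   so effects can be reported per raw unit
#' @param rho_spatial a fixed value in [0, 1) or `"estimated"`
#' @param temporal_structure `"random_walk_1"` or `"iid"`
#' @param interaction `"iid"` or `"none"`
#' @param prior_tau_shape,prior_tau_scale inverse-gamma hyperparameters for
#'   all variance components (default IG(1, 0.01))
#' @param prior_beta_var prior variance of the flat-normal regression
#'   coefficients (default 1e5)
#' @param n_iterations,n_burnin,thin MCMC run length controls
#' @param seed integer seed; the whole chain is reproducible from it
#' @return a `bst_model_spec` list
#' @export
bst_model_spec <- function(response,
                           covariates = character(0),
                           rho_spatial = "estimated",
                           temporal_structure = c("random_walk_1", "iid"),
                           interaction = c("iid", "none"),
                           prior_tau_shape = 1, prior_tau_scale = 0.01,
                           prior_beta_var = 1e5,
                           n_iterations = 20000L, n_burnin = 5000L,
                           thin = 2L, seed = 1L) {
  temporal_structure <- match.arg(temporal_structure)
  interaction <- match.arg(interaction)
  indicators <- c("epr", "nhi", "nbhi", "nhtp")
  stopifnot(response %in% indicators,
            all(covariates %in% indicators),
            n_burnin < n_iterations, thin >= 1L)
  if (!identical(rho_spatial, "estimated")) {
    stopifnot(is.numeric(rho_spatial), rho_spatial >= 0, rho_spatial < 1)
  }
  structure(list(response = response, covariates = covariates,
                 rho_spatial = rho_spatial,
                 temporal_structure = temporal_structure,
                 interaction = interaction,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_scale = prior_tau_scale,
                 prior_beta_var = prior_beta_var,
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "bst_model_spec")
}

#' Fit the Bayesian spatio-temporal effects model by MCMC
#'
#' Runs the Gibbs/Metropolis sampler described in [bst_model_spec()].
#' Identifiability of the additive decomposition is imposed by recentring
#' within every iteration: the spatial effects, the temporal effects and
#' each year-slice of the interaction are constrained to sum to zero, with
#' the removed means absorbed into the intercept (and, for the interaction,
#' into the temporal effects). Stored draws therefore satisfy
#' `sum(phi) = 0`, `sum(Phi) = 0` and `colSums(delta) = 0` exactly.
#'
#' @param panel a [region_panel()]
#' @param w a [spatial_weights()] covering the panel's regions
#' @param spec a [bst_model_spec()]
#' @return a `bst_posterior` object: matrices of retained draws (`beta0`,
#'   `beta`, `phi`, `Phi`, `delta`, `sigma2`, `tau2_*`, `rho`), the
#'   covariate standardisation, acceptance rate for rho, a Geweke-based
#'   [convergence_report()], and the model data (`y`, `X`) for
#'   likelihood checks
#' @export
fit_bst <- function(panel, w, spec) {
  stopifnot(inherits(panel, "region_panel"), inherits(w, "spatial_weights"),
            inherits(spec, "bst_model_spec"))
  regions <- panel_regions(panel)
  if (!identical(regions, w$region_ids)) {
    stop("weights regions do not match panel regions", call. = FALSE)
  }
  years <- panel_years(panel)
  n <- length(regions); t_len <- length(years)

  vals <- panel_matrix(panel, spec$response)
  if (any(vals <= 0)) stop("non-positive response values", call. = FALSE)
  baseline <- colMeans(vals)               # national baseline per year
  y <- log(sweep(vals, 2L, baseline, "/")) # n x T, log theta

  k <- length(spec$covariates)
  x_center <- x_scale <- stats::setNames(numeric(k), spec$covariates)
  X <- NULL
  if (k > 0L) {
    X <- matrix(0, n * t_len, k, dimnames = list(NULL, spec$covariates))
    for (j in seq_len(k)) {
      xm <- panel_matrix(panel, spec$covariates[[j]])
      x_center[j] <- mean(xm); x_scale[j] <- stats::sd(as.vector(xm))
      X[, j] <- (as.vector(xm) - x_center[j]) / x_scale[j]
    }
  }

  wm <- w$matrix
  d_minus_w <- diag(rowSums(wm)) - wm
  lambda <- eigen(d_minus_w, symmetric = TRUE, only.values = TRUE)$values
  estimate_rho <- identical(spec$rho_spatial, "estimated")
  rho <- if (estimate_rho) 0.5 else spec$rho_spatial
  if (!estimate_rho && rho >= 1) stop("rho must be < 1", call. = FALSE)

  # RW1 structure matrix (first differences), or identity for iid time
  if (spec$temporal_structure == "random_walk_1") {
    k_time <- diag(c(1, rep(2, t_len - 2L), 1))
    for (t in seq_len(t_len - 1L)) {
      k_time[t, t + 1L] <- k_time[t + 1L, t] <- -1
    }
    rank_time <- t_len - 1L
  } else {
    k_time <- diag(t_len)
    rank_time <- t_len
  }

  n_keep <- (spec$n_iterations - spec$n_burnin) %/% spec$thin
  draws <- list(
    beta0 = numeric(n_keep),
    beta = matrix(NA_real_, n_keep, k,
                  dimnames = list(NULL, spec$covariates)),
    phi = matrix(NA_real_, n_keep, n, dimnames = list(NULL, regions)),
    Phi = matrix(NA_real_, n_keep, t_len, dimnames = list(NULL, years)),
    delta = array(NA_real_, c(n_keep, n, t_len),
                  dimnames = list(NULL, regions, years)),
    sigma2 = numeric(n_keep), tau2_phi = numeric(n_keep),
    tau2_Phi = numeric(n_keep), tau2_delta = numeric(n_keep),
    rho = numeric(n_keep))

  a0 <- spec$prior_tau_shape; b0 <- spec$prior_tau_scale
  use_delta <- spec$interaction == "iid"
  rho_accept <- 0L; rho_tries <- 0L

  withr_seed(spec$seed, {
    beta0 <- mean(y); beta <- rep(0, k)
    phi <- rep(0, n); Phi <- rep(0, t_len); delta <- matrix(0, n, t_len)
    sigma2 <- stats::var(as.vector(y)) + 1e-6
    tau2_phi <- tau2_Phi <- tau2_delta <- 0.01
    xb <- matrix(0, n, t_len)
    kept <- 0L

    for (iter in seq_len(spec$n_iterations)) {
      ## --- regression block (intercept + covariates) ---
      r_vec <- as.vector(y - outer(phi, rep(1, t_len)) -
                           outer(rep(1, n), Phi) - delta)
      if (k > 0L) {
        Xfull <- cbind(1, X)
        prec <- crossprod(Xfull) / sigma2 + diag(k + 1L) / spec$prior_beta_var
        ch <- chol(prec)
        mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xfull, r_vec) / sigma2))
        bdraw <- mu + backsolve(ch, stats::rnorm(k + 1L))
        beta0 <- bdraw[1L]; beta <- bdraw[-1L]
        xb <- matrix(as.vector(X %*% beta), n, t_len)
      } else {
        prec <- n * t_len / sigma2 + 1 / spec$prior_beta_var
        mu <- sum(r_vec) / sigma2 / prec
        beta0 <- stats::rnorm(1L, mu, sqrt(1 / prec))
      }
      mean_part <- beta0 + xb

      ## --- spatial effects phi (joint Gaussian draw) ---
      q_rho <- rho * d_minus_w + (1 - rho) * diag(n)
      resid <- y - mean_part - outer(rep(1, n), Phi) - delta
      prec_phi <- (t_len / sigma2) * diag(n) + q_rho / tau2_phi
      b_phi <- rowSums(resid) / sigma2
      ch <- chol(prec_phi)
      phi <- backsolve(ch, forwardsolve(t(ch), b_phi) + stats::rnorm(n))

      ## --- temporal effects Phi ---
      resid <- y - mean_part - outer(phi, rep(1, t_len)) - delta
      prec_t <- (n / sigma2) * diag(t_len) + k_time / tau2_Phi
      b_t <- colSums(resid) / sigma2
      ch <- chol(prec_t)
      Phi <- backsolve(ch, forwardsolve(t(ch), b_t) + stats::rnorm(t_len))

      ## --- interaction delta ---
      if (use_delta) {
        resid <- y - mean_part - outer(phi, rep(1, t_len)) -
          outer(rep(1, n), Phi)
        v <- 1 / (1 / sigma2 + 1 / tau2_delta)
        delta <- matrix(stats::rnorm(n * t_len, v * as.vector(resid) / sigma2,
                                     sqrt(v)), n, t_len)
      }

      ## --- recentring for identifiability ---
      if (use_delta) {
        dc <- colMeans(delta)
        delta <- sweep(delta, 2L, dc)
        Phi <- Phi + dc
      }
      beta0 <- beta0 + mean(Phi) + mean(phi)
      Phi <- Phi - mean(Phi)
      phi <- phi - mean(phi)
      mean_part <- beta0 + xb

      ## --- variance components ---
      eps <- y - mean_part - outer(phi, rep(1, t_len)) -
        outer(rep(1, n), Phi) - delta
      sigma2 <- 1 / stats::rgamma(1L, a0 + n * t_len / 2,
                                  b0 + sum(eps^2) / 2)
      q_rho <- rho * d_minus_w + (1 - rho) * diag(n)
      tau2_phi <- 1 / stats::rgamma(1L, a0 + n / 2,
                                    b0 + sum(phi * (q_rho %*% phi)) / 2)
      tau2_Phi <- 1 / stats::rgamma(1L, a0 + rank_time / 2,
                                    b0 + sum(Phi * (k_time %*% Phi)) / 2)
      if (use_delta) {
        tau2_delta <- 1 / stats::rgamma(1L, a0 + n * t_len / 2,
                                        b0 + sum(delta^2) / 2)
      }

      ## --- rho (Metropolis, uniform(0,1) prior) ---
      if (estimate_rho) {
        rho_tries <- rho_tries + 1L
        prop <- stats::rnorm(1L, rho, 0.05)
        if (prop > 0 && prop < 1) {
          logdet_cur <- sum(log(rho * lambda + 1 - rho))
          logdet_prop <- sum(log(prop * lambda + 1 - prop))
          quad_cur <- sum(phi * ((rho * d_minus_w + (1 - rho) * diag(n)) %*% phi))
          quad_prop <- sum(phi * ((prop * d_minus_w + (1 - prop) * diag(n)) %*% phi))
          log_acc <- 0.5 * (logdet_prop - logdet_cur) -
            (quad_prop - quad_cur) / (2 * tau2_phi)
          if (log(stats::runif(1L)) < log_acc) {
            rho <- prop; rho_accept <- rho_accept + 1L
          }
        }
      }

      ## --- store ---
      if (iter > spec$n_burnin &&
          (iter - spec$n_burnin) %% spec$thin == 0L) {
        kept <- kept + 1L
        draws$beta0[kept] <- beta0
        if (k > 0L) draws$beta[kept, ] <- beta
        draws$phi[kept, ] <- phi
        draws$Phi[kept, ] <- Phi
        draws$delta[kept, , ] <- delta
        draws$sigma2[kept] <- sigma2
        draws$tau2_phi[kept] <- tau2_phi
        draws$tau2_Phi[kept] <- tau2_Phi
        draws$tau2_delta[kept] <- tau2_delta
        draws$rho[kept] <- rho
      }
    }
  })

  post <- structure(list(
    draws = draws, spec = spec, regions = regions, years = years,
    baseline = baseline, x_center = x_center, x_scale = x_scale,
    y = y, X = X,
    rho_acceptance = if (rho_tries > 0) rho_accept / rho_tries else NA_real_),
    class = "bst_posterior")
  post$convergence <- convergence_report(post)
  post
}

#' @export
print.bst_posterior <- function(x, ...) {
  cat(sprintf("bst_posterior: response %s, %d draws, %d regions x %d years\n",
              x$spec$response, length(x$draws$beta0), length(x$regions),
              length(x$years)))
  if (length(x$spec$covariates) > 0L) {
    bm <- colMeans(x$draws$beta) / x$x_scale
    cat("posterior mean effects (per raw unit): ",
        paste(sprintf("%s = %.4f", x$spec$covariates, bm), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("convergence: %s (max |Geweke z| = %.2f)\n",
              if (x$convergence$pass) "PASS" else "FAIL",
              max(abs(x$convergence$z))))
  invisible(x)
}

#' Geweke convergence diagnostic for one MCMC chain
#'
#' Compares the mean of an early segment of the chain with the mean of a
#' late segment: `z = (mean_first - mean_last) / sqrt(se1^2 + se2^2)` with
#' standard errors from the spectral density at frequency zero (estimated by
#' an AIC-selected autoregressive fit, so autocorrelation inflates the
#' errors appropriately). `|z| < 1.96` is the conventional convergence
#' criterion. A zero-variance chain has equal segment means and returns 0
#' with a `"degenerate"` attribute instead of NaN.
#'
#' @param chain numeric vector of draws (length >= 20)
#' @param first_frac fraction of the chain in the early window (default 0.1)
#' @param last_frac fraction in the late window (default 0.5)
#' @return the Geweke z statistic (numeric scalar)
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  m <- length(chain)
  if (m < 20L) stop("chain too short for Geweke diagnostic", call. = FALSE)
  first <- chain[seq_len(max(2L, floor(first_frac * m)))]
  last <- chain[seq.int(m - max(2L, floor(last_frac * m)) + 1L, m)]
  if (stats::var(first) == 0 && stats::var(last) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    warning("zero-variance chain segments; Geweke z set to 0")
    return(out)
  }
  se2 <- function(x) .spectrum0(x) / length(x)
  (mean(first) - mean(last)) / sqrt(se2(first) + se2(last))
}

# Spectral density of a chain at frequency zero via an AIC-selected AR fit
# (variance of the mean estimate accounting for autocorrelation).
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(25L, length(x) - 2L)),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0L) return(v)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  if (!is.finite(s0) || s0 <= 0) v else s0
}

#' Geweke convergence report for a fitted posterior
#'
#' Applies [geweke_z()] to every scalar parameter chain (intercept,
#' covariate effects, variance components and rho when estimated).
#'
#' @param posterior a `bst_posterior`
#' @return a `convergence_report` list: named vector `z` and logical `pass`
#'   (`TRUE` iff all `|z| < 1.96`)
#' @export
convergence_report <- function(posterior) {
  stopifnot(inherits(posterior, "bst_posterior"))
  d <- posterior$draws
  chains <- list(beta0 = d$beta0, sigma2 = d$sigma2,
                 tau2_phi = d$tau2_phi, tau2_Phi = d$tau2_Phi)
  if (posterior$spec$interaction == "iid") chains$tau2_delta <- d$tau2_delta
  if (identical(posterior$spec$rho_spatial, "estimated")) chains$rho <- d$rho
  for (cv in posterior$spec$covariates) {
    chains[[paste0("beta_", cv)]] <- d$beta[, cv]
  }
  z <- vapply(chains, function(ch) {
    suppressWarnings(as.numeric(geweke_z(ch)))
  }, numeric(1))
  structure(list(z = z, pass = all(abs(z) < 1.96)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Geweke diagnostics (|z| < 1.96 required):\n")
  print(round(x$z, 3))
  cat(if (x$pass) "PASS\n" else "FAIL\n")
  invisible(x)
}

#' Posterior relative risk for a covariate effect
#'
#' Exponentiates the covariate's posterior draws rescaled to the requested
#' unit of change on the raw covariate scale, e.g. the multiplicative change
#' in the response's relative level per one additional health technician
#' per 1000 population.
#'
#' @param posterior a `bst_posterior`
#' @param k covariate index or name
#' @param per unit of change on the raw covariate scale (default 1)
#' @return named numeric vector `point` (posterior median), `ci_low`,
#'   `ci_high` (95% equal-tailed)
#' @export
relative_risk <- function(posterior, k, per = 1) {
  stopifnot(inherits(posterior, "bst_posterior"))
  covs <- posterior$spec$covariates
  if (is.character(k)) k <- match(k, covs)
  if (is.na(k) || k < 1L || k > length(covs)) {
    stop("covariate index out of range", call. = FALSE)
  }
  beta_unit <- posterior$draws$beta[, k] / posterior$x_scale[k]
  rr <- exp(per * beta_unit)
  c(point = stats::median(rr),
    ci_low = unname(stats::quantile(rr, 0.025)),
    ci_high = unname(stats::quantile(rr, 0.975)))
}

#' Spatial relative level of each region
#'
#' The per-region multiplicative level relative to the national baseline:
#' `exp(S_i)` with `S_i` the posterior mean of `phi_i + delta_it` for the
#' requested year, or of `phi_i` alone when `year = "pooled"`. By the
#' sum-to-zero centring of the stored draws, the geometric mean of
#' `exp(S_i)` across regions is 1.
#'
#' @param posterior a `bst_posterior`
#' @param year calendar year within the fitted panel, or `"pooled"`
#' @return named numeric vector of `exp(S_i)` in canonical region order
#' @export
spatial_relative_level <- function(posterior, year = "pooled") {
  stopifnot(inherits(posterior, "bst_posterior"))
  phi_mean <- colMeans(posterior$draws$phi)
  if (identical(year, "pooled")) {
    s <- phi_mean
  } else {
    t_idx <- match(as.integer(year), posterior$years)
    if (is.na(t_idx)) {
      stop("year ", year, " outside the fitted panel range", call. = FALSE)
    }
    delta_mean <- apply(posterior$draws$delta[, , t_idx, drop = FALSE],
                        2L, mean)
    s <- phi_mean + delta_mean
  }
  stats::setNames(exp(s), posterior$regions)
}

#' Gaussian log-likelihood of the spatio-temporal model at given parameters
#'
#' Utility for likelihood diagnostics: evaluates the log-likelihood of the
#' fitted data at arbitrary parameter values (defaults to the posterior
#' means).
#'
#' @param posterior a `bst_posterior`
#' @param beta0,beta,phi,Phi,delta,sigma2 parameter values; `NULL` means the
#'   posterior mean
#' @return log-likelihood (numeric scalar)
#' @export
bst_log_likelihood <- function(posterior, beta0 = NULL, beta = NULL,
                               phi = NULL, Phi = NULL, delta = NULL,
                               sigma2 = NULL) {
  stopifnot(inherits(posterior, "bst_posterior"))
  d <- posterior$draws
  n <- length(posterior$regions); t_len <- length(posterior$years)
  if (is.null(beta0)) beta0 <- mean(d$beta0)
  if (is.null(beta)) beta <- if (ncol(d$beta) > 0L) colMeans(d$beta) else numeric(0)
  if (is.null(phi)) phi <- colMeans(d$phi)
  if (is.null(Phi)) Phi <- colMeans(d$Phi)
  if (is.null(delta)) delta <- apply(d$delta, c(2L, 3L), mean)
  if (is.null(sigma2)) sigma2 <- mean(d$sigma2)
  xb <- if (length(beta) > 0L) {
    matrix(as.vector(posterior$X %*% beta), n, t_len)
  } else matrix(0, n, t_len)
  mu <- beta0 + xb + outer(phi, rep(1, t_len)) + outer(rep(1, n), Phi) + delta
  sum(stats::dnorm(as.vector(posterior$y), as.vector(mu), sqrt(sigma2),
                   log = TRUE))
}
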