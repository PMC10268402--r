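#' Define a synthetic panel scenario
#'
#' Bundles every knob of the synthetic generative model. The generator mirrors
#' the analysis model: on the log scale, the elderly population ratio of
#' region i in year t is
#' \deqn{\log EPR_{it} = \log(base) + \beta_0 + \sum_k \beta_k x_{kit}
#'   + \varphi_i + \Phi_t + \delta_{it} + \epsilon_{it}}
#' with \eqn{\varphi} a proper (Leroux) conditional autoregressive field on
#' the adjacency graph, \eqn{\Phi_t} a linear drift plus random walk,
#' \eqn{\delta_{it}} independent space-time interaction noise and
#' \eqn{\epsilon} observation noise. The three medical-resource covariates
#' are generated first as positive log-normal processes with their own mild
#' spatial smoothing and annual trends; EPR is then generated conditional on
#' them, so a fitted spatio-temporal regression can be scored against the
#' known effects.
#'
#' @param n_regions number of areal units (>= 4); default 31, the number of
#'   provincial-level regions in a national mainland panel
#' @param n_years number of annual time points (>= 3); default 10, a decade
#' @param lattice adjacency topology: `"grid"` (rook), `"chain"` (path) or
#'   `"random_planar"` (relative-neighbourhood graph of random points)
#' @param beta0 baseline log-level offset
#' @param beta length-3 vector: log-linear effects of (NHI, NBHI, NHTP) on
#'   EPR per one unit of the covariate
#' @param tau_spatial marginal scale of the spatial field (>= 0)
#' @param rho spatial dependence of the Leroux field, in [0, 1)
#' @param tau_temporal scale of the temporal random-walk innovations (>= 0)
#' @param trend deterministic per-year drift of log EPR
#' @param tau_interaction scale of the iid space-time interaction (>= 0)
#' @param sigma_obs observation noise scale on the log scale (>= 0)
#' @param cov_tau_spatial scale of the covariates' own spatial smoothing
#'   (>= 0); 0 makes every region share the same covariate level
#' @param cov_sigma log-scale observation noise of the covariates (>= 0)
#' @param base_epr national baseline EPR level in percentage points
#' @param seed integer RNG seed; every draw in the generator flows from it
#' @return a `synthetic_scenario` list
#' @export
synthetic_scenario <- function(n_regions = 31L, n_years = 10L,
                               lattice = c("grid", "chain", "random_planar"),
                               beta0 = 0, beta = c(0, 0.01, 0.04),
                               tau_spatial = 0.15, rho = 0.8,
                               tau_temporal = 0.02, trend = 0.03,
                               tau_interaction = 0.02, sigma_obs = 0.02,
                               cov_tau_spatial = 0.15, cov_sigma = 0.02,
                               base_epr = 10, seed = 1L) {
  lattice <- match.arg(lattice)
  stopifnot(n_regions >= 4L, n_years >= 3L, length(beta) == 3L,
            tau_spatial >= 0, rho >= 0, rho < 1, tau_temporal >= 0,
            tau_interaction >= 0, sigma_obs >= 0, cov_tau_spatial >= 0,
            cov_sigma >= 0, base_epr > 0)
  structure(list(n_regions = as.integer(n_regions),
                 n_years = as.integer(n_years), lattice = lattice,
                 beta0 = beta0, beta = as.numeric(beta),
                 tau_spatial = tau_spatial, rho = rho,
                 tau_temporal = tau_temporal, trend = trend,
                 tau_interaction = tau_interaction, sigma_obs = sigma_obs,
                 cov_tau_spatial = cov_tau_spatial, cov_sigma = cov_sigma,
                 base_epr = base_epr, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a contiguity structure for synthetic regions
#'
#' `"grid"` builds a rook-contiguity rectangular lattice (`n_regions` is
#' factorised into the most square r x c layout); `"chain"` a path graph;
#' `"random_planar"` the relative-neighbourhood graph of uniform random
#' points, which is planar and connected (it contains the minimum spanning
#' tree). Region ids are zero-padded `R01, R02, ...`.
#'
#' @param n_regions number of regions (>= 4)
#' @param lattice `"grid"`, `"chain"` or `"random_planar"`
#' @param seed RNG seed (used by `random_planar` only)
#' @return a [spatial_weights()] object; for `random_planar` the point
#'   coordinates are attached as attribute `"coords"`
#' @export
generate_adjacency <- function(n_regions,
                               lattice = c("grid", "chain", "random_planar"),
                               seed = 1L) {
  lattice <- match.arg(lattice)
  n <- as.integer(n_regions)
  if (n < 4L) stop("need at least 4 regions", call. = FALSE)
  ids <- sprintf("R%0*d", nchar(as.character(n)), seq_len(n))
  w <- matrix(0, n, n)
  coords <- NULL
  if (lattice == "chain") {
    for (i in seq_len(n - 1L)) w[i, i + 1L] <- w[i + 1L, i] <- 1
    coords <- cbind(x = seq_len(n), y = rep(0, n))
  } else if (lattice == "grid") {
    nr <- floor(sqrt(n))
    while (n %% nr != 0L) nr <- nr - 1L
    nc <- n %/% nr
    row_of <- (seq_len(n) - 1L) %/% nc
    col_of <- (seq_len(n) - 1L) %% nc
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(row_of[i] - row_of[j]) + abs(col_of[i] - col_of[j]) == 1L) {
          w[i, j] <- 1
        }
      }
    }
    coords <- cbind(x = col_of + 1, y = row_of + 1)
  } else {
    pts <- withr_seed(seed, matrix(stats::runif(2L * n), ncol = 2L))
    d <- as.matrix(stats::dist(pts))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        # relative neighbourhood: no third point closer to both i and j
        blocked <- FALSE
        for (k in seq_len(n)) {
          if (k != i && k != j &&
              max(d[i, k], d[j, k]) < d[i, j]) { blocked <- TRUE; break }
        }
        if (!blocked) w[i, j] <- w[j, i] <- 1
      }
    }
    coords <- cbind(x = pts[, 1L], y = pts[, 2L])
  }
  out <- spatial_weights(w, ids)
  rownames(coords) <- ids
  attr(out, "coords") <- coords
  out
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Draw one realisation of a proper Leroux CAR field on W:
# precision (1/tau^2) * (rho * (D - W) + (1 - rho) * I), via Cholesky.
# tau = 0 returns exact zeros; rho = 0 degenerates to iid N(0, tau^2).
sample_car <- function(w_matrix, tau, rho, n_draws = 1L) {
  n <- nrow(w_matrix)
  if (tau == 0) return(matrix(0, n, n_draws))
  q <- rho * (diag(rowSums(w_matrix)) - w_matrix) + (1 - rho) * diag(n)
  r <- chol(q / tau^2)                     # t(r) %*% r = precision
  z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  backsolve(r, z)
}

#' Generate a synthetic region-by-year panel with known latent structure
#'
#' See [synthetic_scenario()] for the generative model. The true latent
#' effects are returned alongside the panel so that recovery by the analysis
#' stages can be scored.
#'
#' @param scenario a [synthetic_scenario()]
#' @param weights a [spatial_weights()] whose dimension matches
#'   `scenario$n_regions`; defaults to `generate_adjacency()` under the
#'   scenario's lattice and seed
#' @return a [region_panel()] with attribute `"truth"`, a list holding the
#'   true `beta0`, `beta`, spatial effects `phi`, temporal effects `Phi`,
#'   interaction `delta` (region x year) and the covariate matrices
#' @export
generate_panel <- function(scenario, weights = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(weights)) {
    weights <- generate_adjacency(scenario$n_regions, scenario$lattice,
                                  scenario$seed)
  }
  stopifnot(inherits(weights, "spatial_weights"))
  n <- scenario$n_regions
  if (length(weights$region_ids) != n) {
    stop("weights dimension ", length(weights$region_ids),
         " does not match n_regions ", n, call. = FALSE)
  }
  t_len <- scenario$n_years
  years <- seq(2011L, length.out = t_len)
  ids <- weights$region_ids
  wm <- weights$matrix

  withr_seed(scenario$seed, {
    # --- medical-resource covariates: log-normal around region baselines
    # with mild CAR spatial smoothing and a linear annual trend ---
    cov_means <- c(nhi = 0.55, nbhi = 5.5, nhtp = 7.0)  # per 1000 population
    cov_trend <- c(nhi = 0.010, nbhi = 0.025, nhtp = 0.030)  # log scale/yr
    covariates <- list()
    for (k in names(cov_means)) {
      reg_effect <- as.vector(sample_car(wm, tau = scenario$cov_tau_spatial,
                                         rho = 0.5))
      noise <- if (scenario$cov_sigma > 0) {
        matrix(stats::rnorm(n * t_len, 0, scenario$cov_sigma), n, t_len)
      } else matrix(0, n, t_len)
      logx <- log(cov_means[[k]]) + reg_effect +
        outer(rep(1, n), cov_trend[[k]] * (seq_len(t_len) - 1L)) + noise
      covariates[[k]] <- exp(logx)
    }

    # --- latent effects for EPR ---
    phi <- as.vector(sample_car(wm, scenario$tau_spatial, scenario$rho))
    rw <- if (scenario$tau_temporal > 0) {
      cumsum(stats::rnorm(t_len, 0, scenario$tau_temporal))
    } else rep(0, t_len)
    Phi <- scenario$trend * (seq_len(t_len) - 1L) + rw
    delta <- if (scenario$tau_interaction > 0) {
      matrix(stats::rnorm(n * t_len, 0, scenario$tau_interaction), n, t_len)
    } else matrix(0, n, t_len)
    eps <- if (scenario$sigma_obs > 0) {
      matrix(stats::rnorm(n * t_len, 0, scenario$sigma_obs), n, t_len)
    } else matrix(0, n, t_len)

    lin <- scenario$beta0 +
      scenario$beta[1L] * covariates$nhi +
      scenario$beta[2L] * covariates$nbhi +
      scenario$beta[3L] * covariates$nhtp
    epr <- scenario$base_epr *
      exp(lin + outer(phi, rep(1, t_len)) + outer(rep(1, n), Phi) +
            delta + eps)
  })

  df <- data.frame(
    region_id = rep(ids, times = t_len),
    year = rep(years, each = n),
    epr = as.vector(epr),
    nhi = as.vector(covariates$nhi),
    nbhi = as.vector(covariates$nbhi),
    nhtp = as.vector(covariates$nhtp),
    stringsAsFactors = FALSE)
  panel <- region_panel(df)
  dimnames(delta) <- list(ids, years)
  attr(panel, "truth") <- list(
    beta0 = scenario$beta0, beta = scenario$beta,
    phi = stats::setNames(phi, ids), Phi = stats::setNames(Phi, years),
    delta = delta,
    covariates = lapply(covariates, function(m) {
      dimnames(m) <- list(ids, years); m
    }))
  panel
}

#' Ground-truth latent effects attached to a synthetic panel
#' @param panel a panel produced by [generate_panel()]
#' @return list with elements `beta0`, `beta`, `phi`, `Phi`, `delta`,
#'   `covariates`
#' @export
panel_truth <- function(panel) attr(panel, "truth")
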