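#' Spatial matching odds ratio of a medical resource against ageing
#'
#' The elementwise ratio of a resource indicator's spatial relative level to
#' the elderly population ratio's spatial relative level,
#' `OR_i = exp(S_i^MR) / exp(S_i^EPR)`: values above 1 mean the region holds
#' more of that resource, relative to the national pattern, than its ageing
#' level alone would suggest.
#'
#' @param exp_s_mr per-region positive vector of the resource indicator's
#'   relative levels (see [spatial_relative_level()])
#' @param exp_s_epr per-region positive vector of the EPR relative levels,
#'   same region order (names, when present, are cross-checked)
#' @return per-region numeric vector of odds ratios
#' @export
compute_or <- function(exp_s_mr, exp_s_epr) {
  if (length(exp_s_mr) != length(exp_s_epr)) {
    stop("vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(exp_s_mr)) && !is.null(names(exp_s_epr)) &&
      !identical(names(exp_s_mr), names(exp_s_epr))) {
    stop("region order mismatch between the two relative-level vectors",
         call. = FALSE)
  }
  if (any(!is.finite(exp_s_mr)) || any(exp_s_mr <= 0) ||
      any(!is.finite(exp_s_epr)) || any(exp_s_epr <= 0)) {
    stop("relative levels must be strictly positive", call. = FALSE)
  }
  exp_s_mr / exp_s_epr
}

#' Combine the three resource odds ratios into the prior IAR
#'
#' Weighted combination
#' `IAR_prior = (1 - p - q) * OR_NHI + p * OR_NBHI + q * OR_NHTP`.
#' The defaults `p = 1/4`, `q = 1/2` give effective weights
#' (NHI, NBHI, NHTP) = (0.25, 0.25, 0.50): health technical personnel, the
#' resource most tightly coupled to ageing demand, counts double.
#'
#' @param or_nhi,or_nbhi,or_nhtp aligned per-region odds-ratio vectors
#' @param p weight on the beds indicator (default 1/4)
#' @param q weight on the technical-personnel indicator (default 1/2)
#' @return per-region numeric vector of prior IAR values
#' @export
compute_iar_prior <- function(or_nhi, or_nbhi, or_nhtp, p = 1 / 4, q = 1 / 2) {
  if (p < 0 || q < 0 || p + q > 1) {
    stop("need p >= 0, q >= 0 and p + q <= 1 (weights must be non-negative)",
         call. = FALSE)
  }
  if (length(or_nhi) != length(or_nbhi) || length(or_nhi) != length(or_nhtp)) {
    stop("odds-ratio vectors differ in length", call. = FALSE)
  }
  (1 - p - q) * or_nhi + p * or_nbhi + q * or_nhtp
}

#' Standardise the prior IAR to the cross-region mean
#'
#' Divides each region's prior IAR by the arithmetic mean over regions, so
#' the standardised indicator averages exactly 1 and reads as an odds ratio
#' against the national level.
#'
#' @param iar_prior per-region positive vector
#' @return per-region vector with mean exactly 1
#' @export
standardize_iar <- function(iar_prior) {
  if (length(iar_prior) == 0L) stop("empty IAR vector", call. = FALSE)
  if (any(!is.finite(iar_prior)) || any(iar_prior <= 0)) {
    stop("prior IAR values must be strictly positive", call. = FALSE)
  }
  iar_prior / mean(iar_prior)
}

#' Classify regional sufficiency of comprehensive medical allocation
#'
#' A region's allocation is sufficient when its standardised IAR is at least
#' 1 (boundary inclusive): its comprehensive medical resource level is no
#' less than its ageing level relative to the national pattern.
#'
#' @param iar_st per-region standardised IAR vector
#' @return logical vector, `TRUE` = sufficient
#' @export
classify_sufficiency <- function(iar_st) iar_st >= 1

#' Full IAR construction for one year of a panel
#'
#' Fits four spatio-temporal models with an identical specification -- one
#' for the elderly population ratio and one for each medical resource
#' indicator, each response-only -- extracts the year-specific spatial
#' relative levels `exp(S_i)`, and composes the odds ratios, the weighted
#' prior IAR and the mean-standardised IAR.
#'
#' @param panel a [region_panel()]
#' @param w a [spatial_weights()]
#' @param year calendar year for the relative levels, or `"pooled"`
#' @param spec a [bst_model_spec()] template; its response/covariates are
#'   overridden per indicator, everything else (priors, MCMC controls,
#'   seed) is reused. Seeds are offset per indicator so the four chains are
#'   independent but jointly reproducible.
#' @param p,q IAR weights, see [compute_iar_prior()]
#' @return an `iar_table` data.frame: `region_id`, `or_nhi`, `or_nbhi`,
#'   `or_nhtp`, `iar_prior`, `iar_st`, `sufficient`; attributes record
#'   `p`, `q`, `year`, the seeds used and any indicator whose chain failed
#'   the Geweke check (`geweke_warnings`)
#' @export
iar_pipeline <- function(panel, w, year, spec = NULL, p = 1 / 4, q = 1 / 2) {
  stopifnot(inherits(panel, "region_panel"), inherits(w, "spatial_weights"))
  if (is.null(spec)) spec <- bst_model_spec("epr")
  indicators <- c("epr", "nhi", "nbhi", "nhtp")
  fits <- list()
  warn <- character(0)
  for (i in seq_along(indicators)) {
    ind <- indicators[[i]]
    sp <- spec
    sp$response <- ind
    sp$covariates <- character(0)
    sp$seed <- spec$seed + (i - 1L)
    fit <- fit_bst(panel, w, sp)
    if (!fit$convergence$pass) warn <- c(warn, ind)
    fits[[ind]] <- fit
  }
  if (length(warn) > 0L) {
    warning("Geweke check failed for: ", paste(warn, collapse = ", "),
            "; IAR returned anyway (recorded in metadata)")
  }
  exp_s <- lapply(fits, spatial_relative_level, year = year)
  or_nhi <- compute_or(exp_s$nhi, exp_s$epr)
  or_nbhi <- compute_or(exp_s$nbhi, exp_s$epr)
  or_nhtp <- compute_or(exp_s$nhtp, exp_s$epr)
  iar_prior <- compute_iar_prior(or_nhi, or_nbhi, or_nhtp, p = p, q = q)
  iar_st <- standardize_iar(iar_prior)
  out <- data.frame(region_id = panel_regions(panel),
                    or_nhi = unname(or_nhi), or_nbhi = unname(or_nbhi),
                    or_nhtp = unname(or_nhtp),
                    iar_prior = unname(iar_prior), iar_st = unname(iar_st),
                    sufficient = unname(classify_sufficiency(iar_st)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("iar_table", "data.frame"),
            p = p, q = q, year = year,
            seeds = spec$seed + seq_along(indicators) - 1L,
            geweke_warnings = warn)
}

#' IAR time series for every year of a panel
#'
#' Fits the four response-only spatio-temporal models once (as in
#' [iar_pipeline()]) and composes the standardised IAR for every year from
#' the year-specific spatial relative levels, yielding the region-by-year
#' IAR matrix that the forecasting stage consumes.
#'
#' @inheritParams iar_pipeline
#' @return list with `iar_st` (region x year matrix, each column mean 1),
#'   `tables` (one `iar_table` per year) and `fits` (the four posteriors)
#' @export
iar_series <- function(panel, w, spec = NULL, p = 1 / 4, q = 1 / 2) {
  stopifnot(inherits(panel, "region_panel"), inherits(w, "spatial_weights"))
  if (is.null(spec)) spec <- bst_model_spec("epr")
  indicators <- c("epr", "nhi", "nbhi", "nhtp")
  fits <- list()
  warn <- character(0)
  for (i in seq_along(indicators)) {
    sp <- spec
    sp$response <- indicators[[i]]
    sp$covariates <- character(0)
    sp$seed <- spec$seed + (i - 1L)
    fits[[indicators[[i]]]] <- fit_bst(panel, w, sp)
    if (!fits[[indicators[[i]]]]$convergence$pass) {
      warn <- c(warn, indicators[[i]])
    }
  }
  if (length(warn) > 0L) {
    warning("Geweke check failed for: ", paste(warn, collapse = ", "))
  }
  years <- panel_years(panel)
  regions <- panel_regions(panel)
  iar_st <- matrix(NA_real_, length(regions), length(years),
                   dimnames = list(regions, years))
  tables <- list()
  for (yr in years) {
    exp_s <- lapply(fits, spatial_relative_level, year = yr)
    prior <- compute_iar_prior(compute_or(exp_s$nhi, exp_s$epr),
                               compute_or(exp_s$nbhi, exp_s$epr),
                               compute_or(exp_s$nhtp, exp_s$epr),
                               p = p, q = q)
    st <- standardize_iar(prior)
    iar_st[, as.character(yr)] <- st
    tab <- data.frame(region_id = regions, iar_prior = unname(prior),
                      iar_st = unname(st),
                      sufficient = unname(classify_sufficiency(st)),
                      stringsAsFactors = FALSE)
    tables[[as.character(yr)]] <- tab
  }
  list(iar_st = iar_st, tables = tables, fits = fits,
       geweke_warnings = warn)
}

#' Weighted Gaussian kernel density surface of the IAR over space
#'
#' Evaluates a weighted product-Gaussian kernel density on a regular grid
#' covering the region coordinates (projected centroids supplied by the
#' user), the surface used to map hotspot areas of resource-ageing
#' matching. `bandwidth = "auto"` applies Silverman's rule-of-thumb per
#' axis on the weighted points.
#'
#' @param coords two-column matrix (or data.frame) of planar coordinates,
#'   one row per region
#' @param weights per-region non-negative weights (e.g. standardised IAR)
#' @param bandwidth positive scalar, length-2 vector (per axis), or
#'   `"auto"`
#' @param grid_size number of grid points per axis (default 64)
#' @param margin grid margin beyond the coordinate range, in multiples of
#'   the bandwidth (default 4; large enough that the density mass is
#'   captured on the grid)
#' @return a `density_surface` list: vectors `x`, `y`, matrix `z`
#'   (density, rows indexing `x`), and `bandwidth`
#' @export
iar_kernel_density <- function(coords, weights, bandwidth = "auto",
                               grid_size = 64L, margin = 4) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 regions for a density surface",
                              call. = FALSE)
  stopifnot(ncol(coords) == 2L, all(is.finite(coords)),
            length(weights) == nrow(coords), all(weights >= 0),
            sum(weights) > 0)
  if (identical(bandwidth, "auto")) {
    wsum <- sum(weights)
    bandwidth <- vapply(1:2, function(j) {
      mu <- sum(weights * coords[, j]) / wsum
      sdw <- sqrt(sum(weights * (coords[, j] - mu)^2) / wsum)
      if (sdw == 0) sdw <- diff(range(coords[, j])) / 4 + 1e-8
      # Silverman's rule of thumb per axis
      1.06 * sdw * nrow(coords)^(-1 / 5)
    }, numeric(1))
  }
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive", call. = FALSE)
  gx <- seq(min(coords[, 1]) - margin * bandwidth[1],
            max(coords[, 1]) + margin * bandwidth[1], length.out = grid_size)
  gy <- seq(min(coords[, 2]) - margin * bandwidth[2],
            max(coords[, 2]) + margin * bandwidth[2], length.out = grid_size)
  kx <- stats::dnorm(outer(gx, coords[, 1], "-") / bandwidth[1]) / bandwidth[1]
  ky <- stats::dnorm(outer(gy, coords[, 2], "-") / bandwidth[2]) / bandwidth[2]
  # z[i, j] = sum_r w_r K(gx_i - x_r) K(gy_j - y_r)
  z <- kx %*% (weights * t(ky))
  structure(list(x = gx, y = gy, z = z, bandwidth = bandwidth),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("density_surface: %d x %d grid, bandwidth (%.4g, %.4g), total mass %.4g\n",
              length(x$x), length(x$y), x$bandwidth[1], x$bandwidth[2],
              sum(x$z) * diff(x$x[1:2]) * diff(x$y[1:2])))
  invisible(x)
}
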