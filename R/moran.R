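#' Global Moran's I with conditional permutation inference
#'
#' Computes the global spatial autocorrelation statistic
#' \deqn{I = \frac{n \sum_i \sum_j W_{ij} (x_i - \bar x)(x_j - \bar x)}
#'   {S_0 \sum_i (x_i - \bar x)^2}, \qquad S_0 = \sum_i \sum_j W_{ij}}
#' on binary (non-row-standardised) contiguity weights, exactly as the
#' formula is written; a row-standardisation flag is provided for
#' compatibility with GeoDa's default but is off by default. Inference is by
#' random permutation of the values across regions: the pseudo p-value is
#' `(#{|I_perm| >= |I_obs|} + 1) / (n_permutations + 1)` (two-sided; the
#' one-sided version is reported alongside) and the z-score uses the
#' permutation mean and standard deviation. The permutation-null expectation
#' is `-1/(n-1)`.
#'
#' @param x numeric vector of regional values (length n >= 3, nonzero
#'   variance)
#' @param w a [spatial_weights()] object with matching dimension
#' @param n_permutations number of random permutations (default 999)
#' @param seed RNG seed for the permutations
#' @param row_standardize if `TRUE`, rows of W are normalised to sum to 1
#' @return a `moran_result` list: `statistic`, `expected`, `p_value`
#'   (two-sided), `p_value_one_sided`, `z_score`, `n_permutations`, `n`,
#'   `perm_mean`, `perm_sd`
#' @export
global_morans_i <- function(x, w, n_permutations = 999L, seed = 1L,
                            row_standardize = FALSE) {
  wm <- .check_moran_inputs(x, w)
  if (row_standardize) wm <- .row_standardize(wm)
  n <- length(x)
  xd <- x - mean(x)
  s0 <- sum(wm)
  denom <- sum(xd^2)
  obs <- n * sum(xd * (wm %*% xd)) / (s0 * denom)

  perm <- withr_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      xp <- xd[sample.int(n)]
      n * sum(xp * (wm %*% xp)) / (s0 * denom)
    }, numeric(1))
  })
  expected <- -1 / (n - 1)
  p_two <- (sum(abs(perm) >= abs(obs)) + 1) / (n_permutations + 1)
  p_one <- if (obs >= expected) {
    (sum(perm >= obs) + 1) / (n_permutations + 1)
  } else {
    (sum(perm <= obs) + 1) / (n_permutations + 1)
  }
  z <- (obs - mean(perm)) / stats::sd(perm)
  structure(list(statistic = obs, expected = expected, p_value = p_two,
                 p_value_one_sided = p_one, z_score = z,
                 n_permutations = as.integer(n_permutations), n = n,
                 perm_mean = mean(perm), perm_sd = stats::sd(perm)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("global Moran's I = %.4f (E[I] = %.4f), z = %.2f, p = %.4f (%d permutations)\n",
              x$statistic, x$expected, x$z_score, x$p_value, x$n_permutations))
  invisible(x)
}

.check_moran_inputs <- function(x, w, name = "x") {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$region_ids)
  if (length(x) != n) {
    stop("length of ", name, " (", length(x),
         ") does not match weights dimension (", n, ")", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 regions", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate input: ", name, " has zero variance", call. = FALSE)
  }
  w$matrix
}

.row_standardize <- function(wm) {
  rs <- rowSums(wm)
  rs[rs == 0] <- 1
  wm / rs
}

#' Local Moran's I (LISA) with quadrant classification
#'
#' For each region, \eqn{I_i = \frac{x_i - \bar x}{S^2}
#'   \sum_j W_{ij} (x_j - \bar x)} with \eqn{S^2} the population variance
#' \eqn{\sum_i (x_i - \bar x)^2 / n}. Under this convention the local values
#' sum to \eqn{S_0 I_{global}}. Significance is assessed by conditional
#' permutation: region i's own value is held fixed while the remaining n-1
#' values are permuted, and the pseudo p compares `|I_i|` against the
#' permuted distribution. Cluster quadrants follow the usual LISA map
#' labels: HH/LL (value and spatial lag deviate the same way), LH/HL
#' (opposite), `NS` when the pseudo p exceeds `alpha` or value/lag deviation
#' is exactly zero, and `ISOLATE` for regions with no neighbours (their
#' local statistic is 0 and pseudo p is `NA`).
#'
#' @inheritParams global_morans_i
#' @param alpha significance threshold masking the quadrant labels
#'   (default 0.05)
#' @return a `lisa_result` data.frame with columns `region_id`, `local_i`,
#'   `deviation`, `lag`, `pseudo_p`, `quadrant`; attribute `"global"` holds
#'   the implied global statistic `sum(local_i)/S0`
#' @export
local_morans_i <- function(x, w, n_permutations = 999L, seed = 1L,
                           alpha = 0.05, row_standardize = FALSE) {
  wm <- .check_moran_inputs(x, w)
  if (row_standardize) wm <- .row_standardize(wm)
  n <- length(x)
  xd <- x - mean(x)
  s2 <- sum(xd^2) / n                      # population variance
  lag <- as.vector(wm %*% xd)
  local_i <- xd / s2 * lag
  isolate <- rowSums(wm != 0) == 0
  local_i[isolate] <- 0

  pseudo_p <- rep(NA_real_, n)
  withr_seed(seed, {
    for (i in which(!isolate)) {
      others <- xd[-i]
      nbr_count <- sum(wm[i, ] != 0)
      wts <- wm[i, wm[i, ] != 0]
      perm_stat <- vapply(seq_len(n_permutations), function(b) {
        picked <- others[sample.int(n - 1L, nbr_count)]
        xd[i] / s2 * sum(wts * picked)
      }, numeric(1))
      pseudo_p[i] <- (sum(abs(perm_stat) >= abs(local_i[i])) + 1) /
        (n_permutations + 1)
    }
  })

  quadrant <- .lisa_quadrant(xd, lag, pseudo_p, alpha, isolate)
  out <- data.frame(region_id = w$region_ids, local_i = local_i,
                    deviation = xd, lag = lag, pseudo_p = pseudo_p,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  structure(out, class = c("lisa_result", "data.frame"),
            global = sum(local_i) / sum(wm), alpha = alpha,
            n_permutations = as.integer(n_permutations))
}

.lisa_quadrant <- function(dev, lag, pseudo_p, alpha, isolate) {
  q <- ifelse(dev > 0 & lag > 0, "HH",
       ifelse(dev < 0 & lag < 0, "LL",
       ifelse(dev < 0 & lag > 0, "LH",
       ifelse(dev > 0 & lag < 0, "HL", "NS"))))
  q[!is.na(pseudo_p) & pseudo_p > alpha] <- "NS"
  q[is.na(pseudo_p) & !isolate] <- "NS"
  q[isolate] <- "ISOLATE"
  q
}

#' Bivariate local Moran's I
#'
#' Measures the association between variable `a` in a region and the spatial
#' lag of variable `b` in its neighbours (e.g. the elderly population ratio
#' against neighbouring levels of health technical personnel). Both
#' variables are standardised by their population mean and standard
#' deviation; the statistic is
#' \eqn{I^i_{ab} = P_a^i \sum_j W_{ij} P_b^j}. With `b` identical to `a` it
#' reduces elementwise to the (univariate) local Moran's I. Permutation
#' inference permutes `b` only, holding `a` fixed, conditional on region i.
#'
#' @param a numeric vector of the focal variable
#' @param b numeric vector of the lagged variable
#' @inheritParams local_morans_i
#' @return a `bilisa_result` data.frame with columns `region_id`,
#'   `bi_local_i`, `p_a` (standardised a), `lag_p_b` (spatial lag of
#'   standardised b), `pseudo_p`, `quadrant`
#' @export
bivariate_local_morans_i <- function(a, b, w, n_permutations = 999L,
                                     seed = 1L, alpha = 0.05,
                                     row_standardize = FALSE) {
  wm <- .check_moran_inputs(a, w, name = "a")
  .check_moran_inputs(b, w, name = "b")
  if (row_standardize) wm <- .row_standardize(wm)
  n <- length(a)
  pa <- (a - mean(a)) / sqrt(sum((a - mean(a))^2) / n)
  pb <- (b - mean(b)) / sqrt(sum((b - mean(b))^2) / n)
  lag_pb <- as.vector(wm %*% pb)
  bi <- pa * lag_pb
  isolate <- rowSums(wm != 0) == 0
  bi[isolate] <- 0

  pseudo_p <- rep(NA_real_, n)
  withr_seed(seed, {
    for (i in which(!isolate)) {
      others <- pb[-i]
      nbr <- which(wm[i, ] != 0)
      wts <- wm[i, nbr]
      perm_stat <- vapply(seq_len(n_permutations), function(k) {
        picked <- others[sample.int(n - 1L, length(nbr))]
        pa[i] * sum(wts * picked)
      }, numeric(1))
      pseudo_p[i] <- (sum(abs(perm_stat) >= abs(bi[i])) + 1) /
        (n_permutations + 1)
    }
  })

  quadrant <- .lisa_quadrant(pa, lag_pb, pseudo_p, alpha, isolate)
  out <- data.frame(region_id = w$region_ids, bi_local_i = bi, p_a = pa,
                    lag_p_b = lag_pb, pseudo_p = pseudo_p,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  structure(out, class = c("bilisa_result", "data.frame"),
            alpha = alpha, n_permutations = as.integer(n_permutations))
}

#' Per-year global Moran's I trace for a panel indicator
#'
#' Runs [global_morans_i()] on each year's cross-section of one indicator,
#' the statistic whose year-on-year rise signals strengthening spatial
#' agglomeration.
#'
#' @param panel a [region_panel()]
#' @param indicator indicator name (`"epr"`, `"nhi"`, `"nbhi"`, `"nhtp"`)
#' @inheritParams global_morans_i
#' @return data.frame with one row per year: `year`, `statistic`,
#'   `expected`, `z_score`, `p_value`, `p_value_one_sided`; the full
#'   `moran_result` objects are attached as attribute `"results"`
#' @export
moran_time_series <- function(panel, indicator, w, n_permutations = 999L,
                              seed = 1L, row_standardize = FALSE) {
  stopifnot(inherits(panel, "region_panel"))
  m <- panel_matrix(panel, indicator)
  years <- panel_years(panel)
  results <- lapply(seq_along(years), function(t) {
    global_morans_i(m[, t], w, n_permutations = n_permutations,
                    seed = seed + t - 1L, row_standardize = row_standardize)
  })
  out <- data.frame(
    year = years,
    statistic = vapply(results, `[[`, numeric(1), "statistic"),
    expected = vapply(results, `[[`, numeric(1), "expected"),
    z_score = vapply(results, `[[`, numeric(1), "z_score"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    p_value_one_sided = vapply(results, `[[`, numeric(1), "p_value_one_sided"))
  attr(out, "results") <- results
  attr(out, "indicator") <- indicator
  out
}
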