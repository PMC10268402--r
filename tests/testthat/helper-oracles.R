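# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles are deliberately naive double loops, kept separate
# from the package implementation.

oracle_global_moran <- function(x, wm) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0; s0 <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      num <- num + wm[i, j] * (x[i] - xbar) * (x[j] - xbar)
      s0 <- s0 + wm[i, j]
    }
  }
  n * num / (s0 * sum((x - xbar)^2))
}

oracle_local_moran <- function(x, wm) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- sum((x - xbar)^2) / n
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) acc <- acc + wm[i, j] * (x[j] - xbar)
    out[i] <- (x[i] - xbar) / s2 * acc
  }
  out
}

oracle_bivariate_moran <- function(a, b, wm) {
  n <- length(a)
  pa <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  pb <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) acc <- acc + wm[i, j] * pb[j]
    out[i] <- pa[i] * acc
  }
  out
}

# random symmetric binary zero-diagonal weights with at least one link
random_weights <- function(n, p_link = 0.4) {
  repeat {
    wm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_link) wm[i, j] <- wm[j, i] <- 1
      }
    }
    if (sum(wm) > 0) break
  }
  spatial_weights(wm, sprintf("R%02d", seq_len(n)))
}

# minimal valid panel from a region x year matrix of EPR values (resources
# filled with positive constants plus jitter so validation passes)
panel_from_epr <- function(epr_matrix, years = NULL) {
  n <- nrow(epr_matrix); t_len <- ncol(epr_matrix)
  if (is.null(years)) years <- seq(2011L, length.out = t_len)
  ids <- rownames(epr_matrix)
  if (is.null(ids)) ids <- sprintf("R%02d", seq_len(n))
  df <- expand.grid(region_id = ids, year = years, stringsAsFactors = FALSE)
  df$epr <- as.vector(epr_matrix)
  df$nhi <- 0.5; df$nbhi <- 5; df$nhtp <- 7
  region_panel(df)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# checkerboard values on the 2x2 rook grid (regions in row-major order)
checkerboard_grid <- function() {
  list(w = generate_adjacency(4, "grid"), x = c(1, -1, -1, 1))
}
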