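# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: plain double loops and grid refinement.

# Brute-force isolation: loop over every cell, classify by centre distance.
oracle_isolation <- function(raster, radius_km) {
  v <- raster$values
  n_disc <- 0L; n_land <- 0L
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      d <- raster$cell_size_km *
        sqrt((i - raster$center[1])^2 + (j - raster$center[2])^2)
      if (d <= radius_km) {
        n_disc <- n_disc + 1L
        if (v[i, j] == 1 && !raster$focal_mask[i, j]) n_land <- n_land + 1L
      }
    }
  }
  list(isolation = 1 - n_land / n_disc, n_disc = n_disc, n_land = n_land)
}

# Per-point roughness by explicit loops (no matrix shifting).
oracle_roughness <- function(values, neighbourhood = "queen") {
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighbourhood == "queen")
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  means <- c()
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (is.na(values[i, j])) next
      diffs <- c()
      for (o in offs) {
        r <- i + o[1]; cc <- j + o[2]
        if (r >= 1 && r <= nrow(values) && cc >= 1 && cc <= ncol(values) &&
            !is.na(values[r, cc]))
          diffs <- c(diffs, abs(values[i, j] - values[r, cc]))
      }
      if (length(diffs) > 0) means <- c(means, mean(diffs))
    }
  }
  mean(means)
}

# NB2 log-likelihood written out from the density, independent of MASS.
oracle_nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

oracle_beta_loglik <- function(y, mu, phi) {
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

# Dense grid maximisation with geometric box refinement: evaluates the
# objective on a full grid, re-centres the box on the argmax and shrinks it
# so successive stages zoom in on the optimum.
oracle_grid_maximise <- function(fn, lower, upper, n_pts = 9, n_stages = 40) {
  stopifnot(length(lower) == length(upper))
  lo <- lower; hi <- upper
  best <- NULL
  for (stage in seq_len(n_stages)) {
    axes <- mapply(function(l, h) seq(l, h, length.out = n_pts),
                   lo, hi, SIMPLIFY = FALSE)
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, fn)
    i <- which.max(vals)
    best <- grid[i, ]
    # keep a 2-step margin around the incumbent so a curved likelihood
    # ridge cannot escape the shrinking box
    step <- (hi - lo) / (n_pts - 1)
    lo <- pmax(lower, best - 2 * step)
    hi <- pmin(upper, best + 2 * step)
  }
  list(par = unname(best), value = max(vals))
}

# Grid-search ML for an NB2 model with one predictor: parameters
# (b0, b1, log theta).
oracle_nb_grid_fit <- function(y, x) {
  fn <- function(p) {
    mu <- exp(p[1] + p[2] * x)
    oracle_nb_loglik(y, mu, exp(p[3]))
  }
  res <- oracle_grid_maximise(fn, lower = c(-2, -5, log(0.05)),
                              upper = c(9, 5, log(5000)))
  list(b0 = res$par[1], b1 = res$par[2], theta = exp(res$par[3]),
       loglik = res$value)
}

# Grid-search ML for a one-predictor beta regression: (g0, g1, log phi).
oracle_beta_grid_fit <- function(y, x) {
  fn <- function(p) {
    mu <- plogis(p[1] + p[2] * x)
    oracle_beta_loglik(y, mu, exp(p[3]))
  }
  res <- oracle_grid_maximise(fn, lower = c(-6, -5, log(0.5)),
                              upper = c(6, 5, log(5000)))
  list(g0 = res$par[1], g1 = res$par[2], phi = exp(res$par[3]),
       loglik = res$value)
}

# Agreement to `sig` significant figures, as a relative comparison.
agrees_sig <- function(a, b, sig = 3) {
  scale <- pmax(abs(a), abs(b))
  ifelse(scale == 0, TRUE, abs(a - b) / scale < 10^(-sig) * 5)
}

# Assemble a minimal valid island table from raw predictor/response vectors.
make_island_table <- function(n, Area = NULL, Topography = NULL,
                              Isolation = NULL, Population = NULL,
                              Spp, Endemics = NULL) {
  df <- data.frame(
    Island = sprintf("Isl%03d", seq_len(n)),
    Area = Area %||% rep(1000, n),
    Topography = Topography %||% rep(200, n),
    Isolation = Isolation %||% rep(0.8, n),
    Population = Population %||% rep(100, n),
    Spp = Spp,
    Endemics = Endemics %||% pmin(pmax(round(Spp * 0.1), 0), Spp))
  island_table(df, provenance = "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
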