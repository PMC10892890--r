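#' Beta regression of the proportion of endemic taxa
#'
#' Fits a beta regression to a compositional response strictly inside (0, 1):
#' the mean follows a logit link, `logit(mu_i) = g0 + sum_j g_j x_ij`, with a
#' constant precision `phi`, and the response is Beta(mu*phi, (1-mu)*phi).
#' All parameters are estimated by maximum likelihood.
#'
#' Numerically, the optimiser works on internally standardised predictors
#' (so that area in km2 and isolation as a fraction are on comparable
#' scales) and on log(phi); coefficients, their covariance and Wald tests
#' are mapped back to the raw predictor scale. Initialisation is
#' deterministic: ordinary least squares of logit(y) for the mean
#' coefficients and a moment estimate for phi.
#'
#' @param table An [island_table()].
#' @param predictors Character vector of predictor columns (possibly empty).
#' @param response Response column, default `"Prop"` (exact endemic
#'   fraction).
#' @param boundary How to treat responses equal to 0 or 1: `"error"` (the
#'   default; the beta likelihood is undefined there) or `"shrink"`, the
#'   Smithson-Verkuilen compression `(y*(n-1) + 0.5)/n` applied to the whole
#'   response. Shrinkage is never applied silently.
#' @param control List of optimiser settings: `maxit` (default 1000) and
#'   `reltol` (default 1e-12) for [stats::optim()] BFGS.
#' @return An object of class `beta_fit`: raw-scale `coefficients`, `phi`,
#'   `loglik`, `pseudo_r2` (squared correlation of the fitted linear
#'   predictor with `logit(y)`), `aic`, `aicc` (k counts intercept, slopes
#'   and phi), Wald p-values, `n`, `k`.
#' @examples
#' tab <- load_island_fixture()
#' fit_beta_regression(tab, "Topography")
#' @export
fit_beta_regression <- function(table, predictors = character(),
                                response = "Prop",
                                boundary = c("error", "shrink"),
                                control = list()) {
  stopifnot(inherits(table, "island_table"))
  boundary <- match.arg(boundary)
  check_model_inputs(table, predictors, response)
  y <- table[[response]]
  if (anyNA(y))
    abort_validation("response contains missing values")
  n <- length(y)
  p <- length(predictors)
  k <- p + 2L
  if (n <= k)
    abort_validation(sprintf("n = %d observations cannot support k = %d parameters", n, k))
  if (any(y < 0 | y > 1))
    abort_domain("beta regression response must lie in [0, 1]")
  if (any(y == 0 | y == 1)) {
    if (boundary == "error")
      abort_domain(paste0("response contains boundary values 0 or 1; the beta ",
                          "likelihood is undefined there (use boundary = \"shrink\" ",
                          "for Smithson-Verkuilen compression)"))
    y <- (y * (n - 1) + 0.5) / n
  }
  maxit <- control$maxit %||% 1000
  reltol <- control$reltol %||% 1e-12

  Xraw <- as.matrix(as.data.frame(table)[, predictors, drop = FALSE])
  if (p > 0) {
    ctr <- colMeans(Xraw)
    scl <- apply(Xraw, 2, stats::sd)
    if (any(scl == 0))
      abort_degenerate("constant predictor: coefficient is unidentifiable")
    X <- cbind(1, sweep(sweep(Xraw, 2, ctr), 2, scl, `/`))
  } else {
    ctr <- scl <- numeric(0)
    X <- matrix(1, n, 1)
  }

  # deterministic start: logit-OLS mean, moment precision
  g0 <- qr.solve(X, stats::qlogis(y))
  e <- stats::qlogis(y) - X %*% g0
  mu0 <- stats::plogis(X %*% g0)
  s2 <- mean(e^2)
  phi0 <- max(mean(1 / (s2 * mu0 * (1 - mu0))) - 1, 2)
  start <- c(g0, log(phi0))

  nll <- function(par) {
    eta <- X %*% par[seq_len(p + 1)]
    mu <- stats::plogis(eta)
    phi <- exp(par[p + 2])
    if (!all(is.finite(mu)) || any(mu <= 0) || any(mu >= 1) ||
        !is.finite(phi) || phi <= 0)
      return(1e10)
    ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0)
    abort_convergence(
      sprintf("beta regression ML did not converge (optim code %d)",
              opt$convergence),
      trace = list(message = opt$message, counts = opt$counts,
                   par = opt$par))

  par_std <- opt$par
  gamma_std <- par_std[seq_len(p + 1)]
  phi_hat <- unname(exp(par_std[p + 2]))

  # linear map from (standardised coefs, log phi) to (raw coefs, phi)
  A <- diag(p + 2)
  if (p > 0) {
    A[1, 2:(p + 1)] <- -ctr / scl
    for (j in seq_len(p)) A[j + 1, j + 1] <- 1 / scl[j]
  }
  A[p + 2, p + 2] <- phi_hat  # d phi / d log phi
  par_raw <- c(A[seq_len(p + 1), seq_len(p + 1), drop = FALSE] %*% gamma_std,
               phi_hat)
  cov_std <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(cov_std)) {
    se_raw <- rep(NA_real_, p + 2)
    wald_p <- rep(NA_real_, p + 2)
  } else {
    cov_raw <- A %*% cov_std %*% t(A)
    se_raw <- sqrt(pmax(diag(cov_raw), 0))
    z <- par_raw / se_raw
    wald_p <- 2 * stats::pnorm(-abs(z))
  }
  coef_names <- c("(Intercept)", predictors)
  coefs <- stats::setNames(par_raw[seq_len(p + 1)], coef_names)

  eta_hat <- as.numeric(X %*% gamma_std)
  pseudo_r2 <- if (p == 0 || stats::sd(eta_hat) == 0) 0 else
    stats::cor(eta_hat, stats::qlogis(y))^2
  ll <- -opt$value
  structure(list(
    coefficients = coefs,
    se = stats::setNames(se_raw[seq_len(p + 1)], coef_names),
    wald_p = stats::setNames(wald_p[seq_len(p + 1)], coef_names),
    phi = phi_hat,
    phi_se = se_raw[p + 2],
    loglik = ll,
    pseudo_r2 = pseudo_r2,
    aic = aic(ll, k),
    aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
    fitted = as.numeric(stats::plogis(eta_hat)),
    linear_predictor = eta_hat,
    n = n, k = k,
    predictors = predictors,
    response = response,
    boundary = boundary,
    data = as.data.frame(table)),
    class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "Beta regression (logit link) fit of %s on {%s}\n", x$response,
    if (length(x$predictors)) paste(x$predictors, collapse = ", ") else "intercept"))
  cat(sprintf("  phi = %.2f, logLik = %.3f, AIC = %.2f, AICc = %.2f\n",
              x$phi, x$loglik, x$aic, x$aicc))
  cat(sprintf("  pseudo-R2 = %.3f\n", x$pseudo_r2))
  invisible(x)
}
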