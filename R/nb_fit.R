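#' Negative binomial regression of taxon counts
#'
#' Fits an NB2 generalised linear model (variance mu + mu^2/theta) with a
#' log link to a taxon count, on the untransformed predictors, with the
#' dispersion parameter theta estimated by maximum likelihood jointly with
#' the coefficients. This is the count model used throughout: taxon counts on
#' islands are strongly overdispersed relative to a Poisson model.
#'
#' The null deviance is evaluated by refitting the intercept-only mean while
#' holding theta at the fitted model's estimate, so it differs between
#' models with different theta-hat. The explained deviance is
#' `1 - residual/null`.
#'
#' @param table An [island_table()].
#' @param predictors Character vector of predictor column names (possibly
#'   empty for the intercept-only model); the standard set is `Area`,
#'   `Topography`, `Isolation`, `Population`.
#' @param response Response column, default `"Spp"` (total taxon count);
#'   `"Endemics"` is also meaningful.
#' @param theta Optional fixed dispersion. The default `NULL` estimates
#'   theta by ML (the standard analysis); a fixed value is useful for
#'   deviance comparisons at common dispersion.
#' @return An object of class `nb_fit`: coefficients on the log-link scale,
#'   `theta`, `loglik`, `null_deviance`, `residual_deviance`,
#'   `explained_deviance`, `aic`, `aicc` (k counts the intercept, slopes and
#'   theta), two-sided Wald p-values, `n`, `k`, and the underlying model
#'   object.
#' @examples
#' tab <- load_island_fixture()
#' fit <- fit_negative_binomial(tab, c("Area", "Topography"))
#' fit$explained_deviance
#' @export
fit_negative_binomial <- function(table, predictors = character(),
                                  response = "Spp", theta = NULL) {
  stopifnot(inherits(table, "island_table"))
  check_model_inputs(table, predictors, response)
  y <- table[[response]]
  if (any(y < 0) || any(y != round(y)))
    abort_domain("count response must contain non-negative integers")
  n <- nrow(table)
  p <- length(predictors)
  k <- p + 1L + if (is.null(theta)) 1L else 0L
  if (n <= k)
    abort_validation(sprintf("n = %d observations cannot support k = %d parameters", n, k))
  fml <- stats::reformulate(if (p == 0) "1" else predictors,
                            response = response)
  notes <- character()
  fit <- withCallingHandlers(
    tryCatch({
      if (is.null(theta)) {
        MASS::glm.nb(fml, data = as.data.frame(table),
                     control = stats::glm.control(maxit = 100))
      } else {
        stats::glm(fml, data = as.data.frame(table),
                   family = MASS::negative.binomial(theta = theta),
                   control = stats::glm.control(maxit = 100))
      }
    }, error = function(e) {
      abort_convergence(paste0("negative binomial fit failed: ",
                               conditionMessage(e)),
                        trace = conditionMessage(e))
    }),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!isTRUE(fit$converged))
    abort_convergence("negative binomial IRLS did not converge",
                      trace = notes)
  ll <- stats::logLik(fit)
  theta_hat <- if (is.null(theta)) fit$theta else theta
  null_dev <- fit$null.deviance
  res_dev <- stats::deviance(fit)
  expl <- if (null_dev > 0) 1 - res_dev / null_dev else 0
  structure(list(
    coefficients = stats::coef(fit),
    se = summary(fit)$coefficients[, "Std. Error"],
    wald_p = summary(fit)$coefficients[, 4],
    theta = theta_hat,
    theta_ml = is.null(theta),
    loglik = as.numeric(ll),
    null_deviance = null_dev,
    residual_deviance = res_dev,
    explained_deviance = min(max(expl, 0), 1),
    aic = aic(as.numeric(ll), k),
    aicc = if (n > k + 1) aicc(as.numeric(ll), k, n) else NA_real_,
    n = n, k = k,
    predictors = predictors,
    response = response,
    notes = notes,
    model = fit,
    data = as.data.frame(table)),
    class = "nb_fit")
}

check_model_inputs <- function(table, predictors, response) {
  bad <- setdiff(c(predictors, response), names(table))
  if (length(bad) > 0)
    abort_validation(paste0("column(s) not in table: ",
                            paste(bad, collapse = ", ")))
  if (anyDuplicated(predictors))
    abort_validation("duplicated predictor names")
  for (v in c(predictors, response))
    if (!is.numeric(table[[v]]))
      abort_validation(paste0("column ", v, " must be numeric"))
  invisible(TRUE)
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "Negative binomial (NB2, log link) fit of %s on {%s}\n",
    x$response,
    if (length(x$predictors)) paste(x$predictors, collapse = ", ") else "intercept"))
  cat(sprintf("  theta = %.2f%s, logLik = %.3f, AIC = %.2f, AICc = %.2f\n",
              x$theta, if (x$theta_ml) " (ML)" else " (fixed)",
              x$loglik, x$aic, x$aicc))
  cat(sprintf("  deviance: null %.2f, residual %.2f (%.1f%% explained)\n",
              x$null_deviance, x$residual_deviance,
              100 * x$explained_deviance))
  invisible(x)
}

#' Predicted-count surface over two predictors
#'
#' Evaluates the fitted mean count exp(linear predictor) on a rectangular
#' grid of two of the model's predictors, holding any remaining predictors
#' fixed (by default at their sample means). Used to draw richness contours
#' over, e.g., area and topography.
#'
#' @param fit An [fit_negative_binomial()] result with at least 2 predictors.
#' @param x_var,y_var Names of the two predictors to vary.
#' @param x_range,y_range Length-2 numeric ranges; default to the observed
#'   ranges in the fitting data.
#' @param n_grid Number of grid points per axis.
#' @param fixed Named list of values for the remaining predictors.
#' @return A data frame with columns `x_var`, `y_var` and `mu` (predicted
#'   count), `n_grid^2` rows in row-major order over `y` within `x`.
#' @export
predict_surface <- function(fit, x_var, y_var, x_range = NULL, y_range = NULL,
                            n_grid = 25, fixed = list()) {
  stopifnot(inherits(fit, "nb_fit"))
  if (length(fit$predictors) < 2)
    abort_validation("surface prediction needs a fit with at least 2 predictors")
  for (v in c(x_var, y_var))
    if (!(v %in% fit$predictors))
      abort_validation(paste0("predictor not in fit: ", v))
  rng <- function(v, r) if (is.null(r)) range(fit$data[[v]]) else r
  xr <- rng(x_var, x_range); yr <- rng(y_var, y_range)
  grid <- expand.grid(
    x = seq(xr[1], xr[2], length.out = n_grid),
    y = seq(yr[1], yr[2], length.out = n_grid))
  names(grid) <- c(x_var, y_var)
  for (v in setdiff(fit$predictors, c(x_var, y_var)))
    grid[[v]] <- fixed[[v]] %||% mean(fit$data[[v]])
  grid$mu <- as.numeric(stats::predict(fit$model, newdata = grid,
                                       type = "response"))
  grid[, c(x_var, y_var, "mu")]
}
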