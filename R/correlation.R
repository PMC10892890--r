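#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for the exploratory trend analysis (taxon
#' counts against area and topography, raw and log-log).
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    abort_validation("`x` and `y` must be numeric vectors of equal length")
  if (length(x) < 3)
    abort_validation("correlation needs at least 3 observations")
  if (anyNA(x) || anyNA(y))
    abort_validation("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_degenerate("correlation is undefined for a zero-variance argument")
  stats::cor(x, y)
}

#' Species-area power law
#'
#' Fits the classical island-biogeography relationship S = c * A^z by
#' ordinary least squares of log S on log A, where S is the taxon count and
#' A the island area.
#'
#' @param table An [island_table()]; `Spp` and `Area` must be positive.
#' @return An object of class `power_law_fit`: list with `c` (multiplier),
#'   `z` (exponent) and `r_loglog` (correlation of log S with log A).
#' @examples
#' fit_species_area_power_law(load_island_fixture())
#' @export
fit_species_area_power_law <- function(table) {
  stopifnot(inherits(table, "island_table"))
  S <- table$Spp; A <- table$Area
  if (any(S <= 0) || any(A <= 0))
    abort_domain("power law requires strictly positive Spp and Area")
  if (stats::sd(log(A)) == 0)
    abort_degenerate("slope is undefined when Area is constant")
  fit <- stats::lm(log(S) ~ log(A))
  structure(list(c = unname(exp(stats::coef(fit)[1])),
                 z = unname(stats::coef(fit)[2]),
                 r_loglog = pearson_r(log(S), log(A))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Species-area power law: S = %.4g * A^%.4g (log-log r = %.3f)\n",
              x$c, x$z, x$r_loglog))
  invisible(x)
}
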