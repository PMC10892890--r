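#' Standard labelled model suites
#'
#' The fixed predictor subsets used in the published eight-island analysis:
#' five negative binomial models A1-E1 for the taxon count and four beta
#' regression models A2-D2 for the endemic proportion, from the full
#' four-predictor model down to single-predictor models.
#'
#' @return A named list mapping model label to predictor vector, suitable for
#'   the `specs` argument of [best_subsets()].
#' @export
count_model_specs <- function() {
  list(A1 = c("Area", "Topography", "Isolation", "Population"),
       B1 = c("Area", "Topography", "Isolation"),
       C1 = c("Area", "Topography"),
       D1 = "Topography",
       E1 = "Area")
}

#' @rdname count_model_specs
#' @export
proportion_model_specs <- function() {
  list(A2 = c("Area", "Topography", "Isolation", "Population"),
       B2 = c("Area", "Topography", "Isolation"),
       C2 = c("Area", "Topography"),
       D2 = "Topography")
}

all_subsets <- function(candidates) {
  specs <- list()
  for (m in seq_along(candidates)) {
    combos <- utils::combn(candidates, m, simplify = FALSE)
    for (cm in combos) specs[[paste(cm, collapse = "+")]] <- cm
  }
  specs
}

#' Best-subsets regression with AICc ranking
#'
#' Fits the appropriate family (negative binomial for counts, beta
#' regression for proportions) over a collection of predictor subsets --
#' every non-empty subset of `candidates` by default, or an explicit
#' labelled list -- and ranks the fits by AICc (ascending). Exact ties are
#' broken by fewer parameters, then by label. A subset whose fit fails is
#' flagged and excluded from the ranking; the others are still ranked.
#'
#' @param table An [island_table()].
#' @param response `"count"` (models `Spp` via [fit_negative_binomial()]) or
#'   `"proportion"` (models `Prop` via [fit_beta_regression()]).
#' @param candidates Predictor pool; default the standard four.
#' @param specs Optional named list of label -> predictor vector (e.g.
#'   [count_model_specs()]); overrides `candidates`.
#' @param ... Passed on to the underlying fitter.
#' @return An object of class `model_table`: list with `summary` (ranked
#'   data frame), `fits` (named list), `failures` (named character vector of
#'   error messages) and `response`.
#' @examples
#' tab <- load_island_fixture()
#' mt <- best_subsets(tab, "count", specs = count_model_specs())
#' mt$summary$label[1]  # minimum-AICc model
#' @export
best_subsets <- function(table, response = c("count", "proportion"),
                         candidates = PREDICTOR_NAMES, specs = NULL, ...) {
  response <- match.arg(response)
  if (is.null(specs)) {
    if (length(candidates) == 0)
      abort_validation("`candidates` must be non-empty")
    specs <- all_subsets(candidates)
  }
  if (is.null(names(specs)) || anyDuplicated(names(specs)))
    abort_validation("`specs` must be a uniquely named list")
  fitter <- switch(response,
                   count = function(tab, pr, ...) fit_negative_binomial(tab, pr, ...),
                   proportion = function(tab, pr, ...) fit_beta_regression(tab, pr, ...))
  fits <- list()
  failures <- character()
  for (label in names(specs)) {
    res <- tryCatch(fitter(table, specs[[label]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[label]] <- conditionMessage(res)
    else fits[[label]] <- res
  }
  if (length(fits) == 0)
    abort_convergence("every candidate fit failed", trace = failures)
  summ <- do.call(rbind, lapply(names(fits), function(label) {
    f <- fits[[label]]
    data.frame(label = label,
               predictors = paste(f$predictors, collapse = "+"),
               k = f$k,
               loglik = f$loglik,
               aic = f$aic,
               aicc = f$aicc,
               fit_stat = if (response == "count") f$explained_deviance
                          else f$pseudo_r2,
               stringsAsFactors = FALSE)
  }))
  names(summ)[names(summ) == "fit_stat"] <-
    if (response == "count") "explained_deviance" else "pseudo_r2"
  summ <- summ[order(summ$aicc, summ$k, summ$label), , drop = FALSE]
  summ$rank <- seq_len(nrow(summ))
  rownames(summ) <- NULL
  structure(list(summary = summ, fits = fits, failures = failures,
                 response = response, specs = specs),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf("<model_table> %s response, %d model(s) ranked by AICc\n",
              x$response, nrow(x$summary)))
  print(x$summary, digits = 4)
  if (length(x$failures) > 0)
    cat("failed fits:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

format_p <- function(p, alpha) {
  txt <- ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  paste0(txt, ifelse(p <= alpha, "*", ""))
}

#' Render a ranked model table as a report
#'
#' One row per fitted model: label, each predictor with its two-sided Wald
#' p-value (marked `*` when significant at `alpha`; the intercept is never
#' rendered), deviances and explained percentage for count models or
#' pseudo-R2 for proportion models, and both information criteria.
#' Deviances and criteria are formatted to 2 decimals, explained deviance to
#' 1-decimal percent, pseudo-R2 to 3 decimals.
#'
#' @param mt A [best_subsets()] result.
#' @param path Optional CSV output path; the file re-parses to the same
#'   values.
#' @param alpha Significance level for marking predictors (default 0.05).
#' @return The report data frame (invisibly when `path` is given).
#' @export
model_report <- function(mt, path = NULL, alpha = 0.05) {
  stopifnot(inherits(mt, "model_table"))
  rows <- lapply(mt$summary$label, function(label) {
    f <- mt$fits[[label]]
    pv <- f$wald_p[names(f$wald_p) != "(Intercept)"]
    pred_txt <- if (length(pv) == 0) "(intercept only)" else
      paste(sprintf("%s, %s", names(pv), format_p(pv, alpha)),
            collapse = "; ")
    base <- data.frame(Model = label, Predictors = pred_txt,
                       stringsAsFactors = FALSE)
    if (mt$response == "count") {
      base$NullDeviance <- sprintf("%.2f", f$null_deviance)
      base$ResidualDeviance <- sprintf("%.2f", f$residual_deviance)
      base$ExplainedDeviance <- sprintf("%.1f%%", 100 * f$explained_deviance)
    } else {
      base$PseudoR2 <- sprintf("%.3f", f$pseudo_r2)
    }
    base$AIC <- sprintf("%.2f", f$aic)
    base$AICc <- sprintf("%.2f", f$aicc)
    base
  })
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(report, path, row.names = FALSE)
    return(invisible(report))
  }
  report
}
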