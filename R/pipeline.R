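# FNV-1a 32-bit hash of a character string; used to fingerprint settings in
# run manifests without an external digest dependency.
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor and multiply on 16-bit halves: R has no exact 32-bit integer ops
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_manifest <- function(outdir, command, settings, inputs, outputs,
                           seed = NULL, status = "ok", stage = NULL) {
  manifest <- list(
    command = command,
    package = "insulametrics",
    version = as.character(utils::packageVersion("insulametrics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    settings = settings,
    config_hash = fnv1a_hash(jsonlite::toJSON(settings, auto_unbox = TRUE,
                                              digits = NA)),
    inputs = inputs,
    outputs = outputs,
    status = status,
    failed_stage = stage)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("[stage %s] %s", stage, conditionMessage(e)),
      class = c("insula_stage_error", class(e)[class(e) != "condition"]),
      stage = stage))
  })
}

#' Reproduce the full eight-island analysis
#'
#' One-shot driver over the packaged dataset: exploratory correlations and
#' the species-area power law, the five-model negative binomial suite for
#' the taxon count, the four-model beta regression suite for the endemic
#' proportion, and the predicted-count surface of the best count model over
#' area and topography. Reports use presentation precision (3-dp
#' correlations, 2-dp deviances, 1-dp percentages); companion `*_full.csv`
#' files carry full precision. A `manifest.json` records the settings in
#' force. All steps are deterministic, so a rerun reproduces the report
#' files byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param table Input [island_table()]; defaults to the packaged fixture.
#' @param alpha Significance level for report marking.
#' @param surface_n Grid points per axis for the prediction surface.
#' @return Named list of output file paths, invisibly.
#' @export
reproduce_tables <- function(outdir, table = load_island_fixture(),
                             alpha = 0.05, surface_n = 25) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  settings <- list(alpha = alpha, surface_n = surface_n,
                   aicc_parameter_count = "includes dispersion/precision",
                   proportions = "exact Endemics/Spp ratios")
  outputs <- character()
  stage <- "correlations"
  result <- tryCatch({
    cors <- with_stage("correlations", {
      pl <- fit_species_area_power_law(table)
      data.frame(
        quantity = c("r(Spp, Area)", "r(log Spp, log Area)",
                     "r(Spp, Topography)", "r(Endemics, Topography)",
                     "power-law c", "power-law z"),
        value = c(pearson_r(table$Spp, table$Area),
                  pearson_r(log(table$Spp), log(table$Area)),
                  pearson_r(table$Spp, table$Topography),
                  pearson_r(table$Endemics, table$Topography),
                  pl$c, pl$z),
        stringsAsFactors = FALSE)
    })
    cors$formatted <- sprintf("%.3f", cors$value)
    f <- file.path(outdir, "correlations.csv")
    utils::write.csv(cors, f, row.names = FALSE)
    outputs <- c(outputs, f)

    stage <- "count_models"
    nb <- with_stage(stage,
                     best_subsets(table, "count", specs = count_model_specs()))
    f <- file.path(outdir, "nb_models.csv")
    model_report(nb, f, alpha = alpha)
    f2 <- file.path(outdir, "nb_models_full.csv")
    utils::write.csv(nb$summary, f2, row.names = FALSE)
    outputs <- c(outputs, f, f2)

    stage <- "proportion_models"
    bt <- with_stage(stage,
                     best_subsets(table, "proportion",
                                  specs = proportion_model_specs()))
    f <- file.path(outdir, "beta_models.csv")
    model_report(bt, f, alpha = alpha)
    f2 <- file.path(outdir, "beta_models_full.csv")
    utils::write.csv(bt$summary, f2, row.names = FALSE)
    outputs <- c(outputs, f, f2)

    stage <- "surface"
    best_label <- nb$summary$label[1]
    surf <- with_stage(stage, {
      fit <- nb$fits[[best_label]]
      predict_surface(fit, "Area", "Topography", n_grid = surface_n)
    })
    f <- file.path(outdir, "surface_best_count_model.csv")
    utils::write.csv(surf, f, row.names = FALSE)
    outputs <- c(outputs, f)
    list(correlations = cors, count_models = nb, proportion_models = bt,
         best_count_model = best_label)
  }, error = function(e) e)
  if (inherits(result, "error")) {
    write_manifest(outdir, "reproduce_tables", settings,
                   inputs = attr(table, "provenance") %||% "user table",
                   outputs = basename(outputs), status = "failed",
                   stage = stage)
    stop(result)
  }
  write_manifest(outdir, "reproduce_tables", settings,
                 inputs = attr(table, "provenance") %||% "user table",
                 outputs = basename(outputs))
  invisible(c(outputs, file.path(outdir, "manifest.json")))
}

#' Run the full pipeline: grids to metrics to models
#'
#' Ties the stages together for simulated (or supplied) inputs: elevation
#' grid -> roughness, land/sea raster -> isolation, island table -> ranked
#' count and proportion model suites, with stage-tagged errors and a run
#' manifest.
#'
#' @param config A [synthetic_config()]; its seed governs every stochastic
#'   step. Alternatively supply pre-built inputs via `dem`, `raster`,
#'   `table`.
#' @param outdir Output directory.
#' @param dem,raster,table Optional pre-built [elevation_grid()],
#'   [land_sea_raster()] and [island_table()]; generated from `config` when
#'   `NULL`.
#' @param neighbourhood Neighbourhood for [roughness_index()].
#' @param radius_km Survey radius for [isolation_index()].
#' @param alpha Significance level for reports.
#' @return List with elements `roughness`, `isolation`, `count_models`,
#'   `proportion_models` and `files`.
#' @export
run_pipeline <- function(config, outdir, dem = NULL, raster = NULL,
                         table = NULL, neighbourhood = "queen",
                         radius_km = NULL, alpha = 0.05) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  dem <- dem %||% with_stage("simulate_dem", generate_dem(config))
  raster <- raster %||% with_stage("simulate_raster",
                                   generate_land_sea(config))
  table <- table %||% with_stage("simulate_table",
                                 generate_island_table(config))
  if (!inherits(table, "island_table"))
    with_stage("validate_table", abort_validation("`table` is not an island_table"))

  rough <- with_stage("metrics", roughness_index(dem, neighbourhood))
  radius_km <- radius_km %||%
    min(max_covered_radius_km(raster),
        0.45 * raster$cell_size_km * min(dim(raster$values)))
  iso <- with_stage("metrics", isolation_index(raster, radius_km))
  metrics <- data.frame(metric = c("roughness_m", "isolation"),
                        value = c(rough$value, iso$isolation),
                        detail = c(rough$neighbourhood,
                                   sprintf("radius_km=%g", iso$radius_km)))
  f <- file.path(outdir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  outputs <- c(outputs, f)

  f <- file.path(outdir, "island_table.csv")
  write_island_csv(table, f)
  outputs <- c(outputs, f)

  nb <- with_stage("count_models", best_subsets(table, "count"))
  bt <- with_stage("proportion_models", best_subsets(table, "proportion"))
  f1 <- file.path(outdir, "count_models.csv")
  f2 <- file.path(outdir, "proportion_models.csv")
  model_report(nb, f1, alpha = alpha)
  model_report(bt, f2, alpha = alpha)
  outputs <- c(outputs, f1, f2)

  settings <- list(neighbourhood = neighbourhood, radius_km = radius_km,
                   alpha = alpha,
                   aicc_parameter_count = "includes dispersion/precision")
  write_manifest(outdir, "run_pipeline", settings,
                 inputs = attr(table, "provenance") %||% "user table",
                 outputs = basename(outputs), seed = config$seed)
  list(roughness = rough, isolation = iso, count_models = nb,
       proportion_models = bt,
       files = c(outputs, file.path(outdir, "manifest.json")))
}
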