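PREDICTOR_NAMES <- c("Area", "Topography", "Isolation", "Population")
CORE_COLUMNS <- c("Island", "Topography", "Isolation", "Area", "Population",
                  "Spp", "Endemics")

#' Build a validated island table
#'
#' One row per island or archipelago, carrying the geospatial predictors
#' (topographic roughness in m, isolation as a fraction of the survey disc,
#' surface area in km2, human population density in individuals per km2) and
#' the taxonomic responses (total taxon count `Spp`, narrow-endemic count
#' `Endemics`). The derived column `Prop` is always recomputed as the exact
#' ratio `Endemics / Spp`; rounded presentation values never enter models.
#'
#' @param df Data frame with columns `Island`, `Topography`, `Isolation`,
#'   `Area`, `Population`, `Spp`, `Endemics`. An `Archipelago` logical column
#'   is derived from a trailing `"(a)"` in the island name when absent.
#'   Additional columns are preserved untouched.
#' @param provenance Short tag recording where the rows came from
#'   (`"table3"` for the packaged fixture, `"synthetic"` for generated data).
#' @return A data frame of class `island_table` with attribute `provenance`.
#' @export
island_table <- function(df, provenance = "user") {
  missing_cols <- setdiff(CORE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    abort_validation(paste0("island table lacks required column(s): ",
                            paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$Island))
    abort_validation("island names must be unique")
  if (!("Archipelago" %in% names(df)))
    df$Archipelago <- grepl("\\(a\\)\\s*$", df$Island)
  num_cols <- c("Topography", "Isolation", "Area", "Population", "Spp",
                "Endemics")
  for (cc in num_cols)
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]]))
      abort_validation(paste0("column ", cc, " must be numeric and complete"))
  if (any(df$Endemics > df$Spp))
    abort_validation("Endemics exceeds Spp for at least one island")
  if (any(df$Spp < 0) || any(df$Endemics < 0) ||
      any(df$Spp != round(df$Spp)) || any(df$Endemics != round(df$Endemics)))
    abort_validation("Spp and Endemics must be non-negative integer counts")
  if (any(df$Isolation < 0 | df$Isolation > 1))
    abort_validation("Isolation must lie in [0, 1]")
  if (any(df$Area <= 0) || any(df$Topography <= 0) || any(df$Population <= 0))
    abort_validation("Area, Topography and Population must be positive")
  # derived column; NA (not an error) for zero-count rows, so tables can
  # carry such rows even though proportion models cannot use them
  df$Prop <- ifelse(df$Spp > 0, df$Endemics / pmax(df$Spp, 1), NA_real_)
  structure(df, class = c("island_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.island_table <- function(x, ...) {
  cat(sprintf("<island_table> %d islands (provenance: %s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Load the packaged eight-island dataset
#'
#' The geospatial, population and taxonomic data for the five largest
#' Mediterranean islands (Corsica, Crete, Sardinia, Sicily, Cyprus) and
#' three western-central archipelagos (Malta, Balearic, Tuscan), exactly as
#' published. On load, the printed percentage column is checked against the
#' exact `Endemics / Spp` ratio at one decimal place.
#'
#' @return An [island_table()] with 8 rows and provenance `"table3"`.
#' @examples
#' tab <- load_island_fixture()
#' tab[tab$Island == "Sicily", c("Area", "Spp", "Endemics")]
#' @export
load_island_fixture <- function() {
  path <- system.file("extdata", "table3.csv", package = "insulametrics",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  printed_pct <- as.numeric(sub("%$", "", raw$Prop))
  raw$Prop <- NULL
  tab <- island_table(raw, provenance = "table3")
  stopifnot(nrow(tab) == 8,
            all(abs(round(100 * tab$Prop, 1) - printed_pct) < 1e-9))
  tab
}

#' Proportion of endemic taxa
#'
#' @param endemics Endemic taxon count(s).
#' @param spp Total taxon count(s); must be positive.
#' @return `endemics / spp`, the exact compositional fraction.
#' @examples
#' derive_prop(26, 1100)   # Malta: 0.0236..., printed as 2.4%
#' @export
derive_prop <- function(endemics, spp) {
  if (any(spp <= 0))
    abort_domain("proportion of endemics is undefined when Spp is zero")
  if (any(endemics < 0) || any(endemics > spp))
    abort_validation("endemics must lie in [0, spp]")
  endemics / spp
}

#' Human population density
#'
#' @param population_count Number of inhabitants.
#' @param area_km2 Surface area in km2; must be positive.
#' @return Density in individuals per km2.
#' @export
derive_density <- function(population_count, area_km2) {
  if (any(area_km2 <= 0))
    abort_domain("population density is undefined for non-positive area")
  if (any(population_count < 0))
    abort_validation("population count must be non-negative")
  population_count / area_km2
}

#' Read / write island tables as CSV
#'
#' Header-bearing RFC-4180 CSV with the standard column names (`Island`,
#' `Topography`, `Isolation`, `Area`, `Population`, `Spp`, `Endemics`, plus
#' optional extras which round-trip untouched). `Prop` is written at full
#' float precision and recomputed on read, so a write/read cycle is
#' lossless.
#'
#' @param path File path.
#' @param provenance Provenance tag for the returned table.
#' @return `read_island_csv()` returns an [island_table()];
#'   `write_island_csv()` returns `path` invisibly.
#' @export
read_island_csv <- function(path, provenance = "file") {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$Prop <- NULL  # presentation column; recomputed from the counts
  island_table(raw, provenance = provenance)
}

#' @rdname read_island_csv
#' @param table An [island_table()] to write.
#' @export
write_island_csv <- function(table, path) {
  stopifnot(inherits(table, "island_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
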