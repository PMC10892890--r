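#' Construct an elevation grid
#'
#' A rectangular grid of ground elevations (metres above mean sea level)
#' sampled at regular intervals, as read off a digital elevation model at the
#' intersection points of a superimposed grid. This is the input to
#' [roughness_index()].
#'
#' @param values Numeric matrix of elevations in metres. Non-finite entries
#'   are treated as missing.
#' @param cell_size Ground distance between adjacent grid points, in metres.
#' @param nodata_mask Optional logical matrix, `TRUE` where the elevation is
#'   missing. Merged with non-finite entries of `values`.
#'
#' @return An object of class `elevation_grid`: a list with elements
#'   `values`, `cell_size` and `nodata_mask`. Masked cells hold `NA`.
#' @export
elevation_grid <- function(values, cell_size = 1, nodata_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_validation("`values` must be a numeric matrix")
  if (nrow(values) < 2 || ncol(values) < 2)
    abort_validation("elevation grid must have at least 2 x 2 cells")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    abort_validation("`cell_size` must be a single positive number")
  mask <- !is.finite(values)
  if (!is.null(nodata_mask)) {
    if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values)))
      abort_validation("`nodata_mask` must be a logical matrix matching `values`")
    mask <- mask | nodata_mask
  }
  if (all(mask))
    abort_degenerate("elevation grid contains no usable (non-masked) cells")
  values[mask] <- NA_real_
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 nodata_mask = mask),
            class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells, cell size %g m, %d masked\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              sum(x$nodata_mask)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  elevation range: %.1f to %.1f m\n", rng[1], rng[2]))
  invisible(x)
}

#' Read an elevation grid from disk
#'
#' Supports the ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by a row-major,
#' top-to-bottom body) and plain whitespace- or comma-delimited numeric
#' matrices.
#'
#' @param path Path to the file.
#' @param format `"auto"` (detect from content), `"esri_ascii"` or
#'   `"matrix"`.
#' @param cell_size Cell size in metres, used for `"matrix"` files which
#'   carry no header; ignored for ESRI ASCII input (the header's `cellsize`
#'   wins).
#' @return An [elevation_grid()].
#' @export
read_elevation_grid <- function(path, format = c("auto", "esri_ascii", "matrix"),
                                cell_size = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_degenerate("empty grid file")
  if (format == "auto") {
    format <- if (grepl("^\\s*ncols", lines[1], ignore.case = TRUE))
      "esri_ascii" else "matrix"
  }
  if (format == "esri_ascii") parse_esri_ascii(lines)
  else parse_matrix_grid(lines, cell_size)
}

parse_esri_ascii <- function(lines) {
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(header[[key]]))
      abort_format(paste0("ESRI ASCII header lacks ", key))
  body <- lines[i:length(lines)]
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
    if (anyNA(v)) abort_format("non-numeric value in grid body")
    v
  })
  # ESRI ASCII bodies are sometimes wrapped; re-flow against the header dims
  flat <- unlist(rows)
  if (length(flat) != header$ncols * header$nrows)
    abort_format(sprintf("grid body has %d values, header promises %d x %d",
                         length(flat), header$nrows, header$ncols))
  values <- matrix(flat, nrow = header$nrows, ncol = header$ncols,
                   byrow = TRUE)
  mask <- NULL
  if (!is.null(header$nodata_value))
    mask <- values == header$nodata_value
  elevation_grid(values, cell_size = header$cellsize, nodata_mask = mask)
}

parse_matrix_grid <- function(lines, cell_size) {
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
    v
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    abort_format("ragged rows: matrix grid rows have unequal lengths")
  values <- do.call(rbind, rows)
  elevation_grid(values, cell_size = cell_size)
}

#' Write an elevation grid to disk
#'
#' Inverse of [read_elevation_grid()]; round-trips the numeric content.
#'
#' @param grid An [elevation_grid()].
#' @param path Output path.
#' @param format `"esri_ascii"` or `"matrix"`.
#' @param nodata_value Sentinel written for masked cells in ESRI ASCII
#'   output.
#' @return `path`, invisibly.
#' @export
write_elevation_grid <- function(grid, path,
                                 format = c("esri_ascii", "matrix"),
                                 nodata_value = -9999) {
  stopifnot(inherits(grid, "elevation_grid"))
  format <- match.arg(format)
  v <- grid$values
  if (format == "esri_ascii") {
    v[grid$nodata_mask] <- nodata_value
    header <- c(
      sprintf("ncols %d", ncol(v)),
      sprintf("nrows %d", nrow(v)),
      "xllcorner 0",
      "yllcorner 0",
      sprintf("cellsize %.10g", grid$cell_size),
      sprintf("NODATA_value %.10g", nodata_value))
    body <- apply(v, 1, function(r) paste(format(r, scientific = FALSE,
                                                 trim = TRUE), collapse = " "))
    writeLines(c(header, body), path)
  } else {
    body <- apply(v, 1, function(r) paste(format(r, scientific = FALSE,
                                                 trim = TRUE), collapse = " "))
    writeLines(body, path)
  }
  invisible(path)
}

# Shift a matrix by (dr, dc), padding with NA.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

neighbour_offsets <- function(neighbourhood) {
  rook <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighbourhood == "rook") return(rook)
  c(rook, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
}

#' Index of topographic roughness
#'
#' Measures the topographic complexity of terrain as the arithmetic mean, over
#' all usable grid points, of each point's mean absolute elevation difference
#' to its immediate neighbours. Edge points use only the neighbours that
#' exist; masked points contribute neither as centres nor as neighbours. The
#' result is in metres and is scale-dependent: it describes relief at the
#' resolution of the sampling grid, so `cell_size` is carried in the input
#' type and the grid is never resampled implicitly.
#'
#' @param grid An [elevation_grid()].
#' @param neighbourhood `"queen"` (8 neighbours, the default) or `"rook"`
#'   (4 axial neighbours). "Immediate neighbours" on a square lattice is read
#'   as the queen neighbourhood, the common terrain-ruggedness convention;
#'   rook is provided for sensitivity checks.
#' @return An object of class `roughness_result`: list with `value` (metres),
#'   `neighbourhood`, and `n_points` (grid points entering the average).
#' @examples
#' g <- elevation_grid(matrix(c(0, 2, 1, 3), 2, 2), cell_size = 100)
#' roughness_index(g)$value          # queen: 5/3
#' roughness_index(g, "rook")$value  # 1.5
#' @export
roughness_index <- function(grid, neighbourhood = c("queen", "rook")) {
  stopifnot(inherits(grid, "elevation_grid"))
  neighbourhood <- match.arg(neighbourhood)
  v <- grid$values
  sum_abs <- matrix(0, nrow(v), ncol(v))
  n_nb <- matrix(0L, nrow(v), ncol(v))
  for (off in neighbour_offsets(neighbourhood)) {
    nb <- shift_matrix(v, off[1], off[2])
    ok <- !is.na(v) & !is.na(nb)
    sum_abs[ok] <- sum_abs[ok] + abs(v[ok] - nb[ok])
    n_nb[ok] <- n_nb[ok] + 1L
  }
  usable <- !is.na(v) & n_nb > 0L
  if (sum(usable) < 2)
    abort_degenerate("fewer than 2 grid points with at least one usable neighbour")
  per_point <- sum_abs[usable] / n_nb[usable]
  structure(list(value = mean(per_point),
                 neighbourhood = neighbourhood,
                 n_points = sum(usable)),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("Topographic roughness: %.3f m (%s neighbourhood, %d points)\n",
              x$value, x$neighbourhood, x$n_points))
  invisible(x)
}
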