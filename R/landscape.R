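#' Binary land-cover landscape
#'
#' A `binary_landscape` is a rectangular lattice in which every cell is
#' foreground (the land-cover class of interest, e.g. exurban development or
#' forest), background, or nodata. Row 1 is the northernmost row, matching
#' the on-disk raster convention; cell (r, c) has its centre at
#' `x = xll + (c - 0.5) * pixel_size`, `y = yll + (nrow - r + 0.5) * pixel_size`.
#'
#' @param grid logical matrix; `TRUE` = foreground.
#' @param pixel_size side length of a pixel in metres (> 0). Default 30,
#'   the Landsat TM pixel.
#' @param xll,yll coordinates of the lower-left raster corner (metres).
#' @param nodata optional logical matrix flagging nodata cells. Nodata cells
#'   are treated as background by all morphological operations but are
#'   propagated to outputs.
#' @return An object of class `binary_landscape`.
#' @export
binary_landscape <- function(grid, pixel_size = 30, xll = 0, yll = 0,
                             nodata = NULL) {
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1)))
      stop("grid must be binary (logical, or numeric 0/1)")
    grid <- grid == 1
  }
  if (!is.matrix(grid) || !is.logical(grid))
    stop("grid must be a logical matrix")
  if (anyNA(grid)) stop("grid must not contain NA; use the nodata mask")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  if (!is.null(nodata)) {
    if (!is.matrix(nodata) || !is.logical(nodata) ||
        !identical(dim(nodata), dim(grid)))
      stop("nodata must be a logical matrix with the same dimensions as grid")
    grid[nodata] <- FALSE
  }
  structure(
    list(grid = grid, pixel_size = pixel_size, xll = xll, yll = yll,
         nodata = nodata),
    class = "binary_landscape"
  )
}

#' @export
print.binary_landscape <- function(x, ...) {
  cat(sprintf(
    "<binary_landscape> %d x %d cells, %g m pixels, %.1f%% foreground\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size, 100 * mean(x$grid)))
  invisible(x)
}

#' @export
dim.binary_landscape <- function(x) dim(x$grid)

#' Read / write a binary landscape as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by one row of
#' space-separated cell values per line, northernmost row first. Values are
#' 0 (background), 1 (foreground), or the nodata value.
#'
#' @param path file path.
#' @return `read_ascii_grid()` returns a `binary_landscape`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!k %in% keys) stop("malformed ASCII grid header: missing ", k)
  nodata_val <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, what = numeric(), skip = 6, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- m == nodata_val
  if (!all(m[!nodata] %in% c(0, 1)))
    stop("ASCII grid is not binary: values other than 0/1/nodata found")
  binary_landscape(m == 1 & !nodata, pixel_size = vals[["cellsize"]],
                   xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                   nodata = if (any(nodata)) nodata else NULL)
}

#' @param x a `binary_landscape` (or an integer matrix for
#'   `write_ascii_grid.matrix`-style use via `values`).
#' @param values optional integer matrix to write instead of the 0/1 grid
#'   (used for class maps); must match the grid dimensions.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path, values = NULL) {
  stopifnot(inherits(x, "binary_landscape"))
  m <- if (is.null(values)) x$grid + 0L else values
  if (!identical(dim(m), dim(x$grid))) stop("values dimensions mismatch")
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (!is.null(x$nodata)) m[x$nodata] <- -9999
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(x$xll, scientific = FALSE)),
    paste("yllcorner", format(x$yll, scientific = FALSE)),
    paste("cellsize", format(x$pixel_size, scientific = FALSE)),
    "NODATA_value -9999")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Cell-centre coordinates of every cell in a landscape
#' @keywords internal
cell_centres <- function(landscape) {
  nr <- nrow(landscape$grid); nc <- ncol(landscape$grid)
  px <- landscape$pixel_size
  list(
    x = landscape$xll + (seq_len(nc) - 0.5) * px,
    y = landscape$yll + (nr - seq_len(nr) + 0.5) * px
  )
}
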