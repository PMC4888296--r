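#' MSPA class codes
#'
#' Integer codes used in class maps and on-disk rasters. Background is 0,
#' the seven foreground morphological classes are 1-7, nodata is 8.
#'
#' @export
mspa_classes <- function() {
  c(BACKGROUND = 0L, CORE = 1L, ISLET = 2L, EDGE = 3L, PERFORATION = 4L,
    BRIDGE = 5L, LOOP = 6L, BRANCH = 7L, NODATA = 8L)
}

#' MSPA configuration
#'
#' @param connectivity neighbourhood rule for the structuring element: 8
#'   (cardinal + diagonal, the default) or 4 (cardinal only).
#' @param edge_width number of erosion steps defining the core/edge
#'   transition, in pixels (>= 1).
#' @return An object of class `mspa_config`.
#' @export
mspa_config <- function(connectivity = 8, edge_width = 1) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!is.numeric(edge_width) || edge_width < 1 ||
      edge_width != round(edge_width))
    stop("edge_width must be a positive integer")
  structure(list(connectivity = as.integer(connectivity),
                 edge_width = as.integer(edge_width)),
            class = "mspa_config")
}

#' Morphological spatial pattern analysis of a binary landscape
#'
#' Partitions every foreground pixel into one of seven mutually exclusive
#' morphological classes:
#'
#' * **Core** - pixels surviving `edge_width` successive erosions (an erosion
#'   removes any foreground pixel with at least one background pixel among
#'   its connectivity-neighbours; cells outside the raster count as
#'   background).
#' * **Islet** - all pixels of a foreground connected component containing
#'   no core pixel.
#' * **Edge / Perforation** - non-core pixels of core-containing components
#'   reachable from core by at most `edge_width` geodesic dilation steps
#'   (the boundary zone). A boundary pixel adjacent to background connected
#'   to the raster border is Edge; one adjacent only to an enclosed
#'   background hole is Perforation; one adjacent to neither is Edge.
#'   Background connectivity is the complement of the foreground rule
#'   (4 when foreground is 8 and vice versa).
#' * **Bridge / Loop / Branch** - the remaining (connector) pixels, grouped
#'   into connected components. A connector's contacts are its maximal
#'   connected pixel subsets adjacent to the core-or-boundary zone. A
#'   connector touching two or more distinct core components is a Bridge;
#'   one with two or more contacts to a single core component is a Loop;
#'   one with a single contact is a Branch.
#'
#' Nodata cells are treated as background for all morphology and flagged
#' `NODATA` in the output. An all-background input yields an all-background
#' map. This implements the classification rules directly; it is not
#' guaranteed to be bit-compatible with the GUIDOS toolbox, which adds
#' sub-classes and option flags. The compactness index and the
#' {Islet, Bridge, Branch, Loop} grouping used downstream depend only on
#' distinctions these rules determine unambiguously at edge width 1.
#'
#' @param landscape a [binary_landscape()].
#' @param config an [mspa_config()].
#' @return An object of class `mspa_class_map`: list with `classes` (integer
#'   matrix of codes, see [mspa_classes()]), `landscape`, `config`.
#' @export
classify_mspa <- function(landscape, config = mspa_config()) {
  stopifnot(inherits(landscape, "binary_landscape"),
            inherits(config, "mspa_config"))
  fg <- landscape$grid
  nr <- nrow(fg); nc <- ncol(fg)
  conn <- config$connectivity
  bg_conn <- if (conn == 8) 4L else 8L
  ew <- config$edge_width
  codes <- mspa_classes()
  cls <- matrix(codes[["BACKGROUND"]], nr, nc)

  if (any(fg)) {
    # (1) core by iterated erosion
    core <- fg
    for (i in seq_len(ew)) core <- erode_mask(core, conn)

    # (2) islets: components without core
    comp <- label_components(fg, conn)
    core_comps <- unique(comp[core])
    islet <- fg & !(comp %in% core_comps)
    dim(islet) <- dim(fg)

    # (3) boundary zone: geodesic dilation of core within foreground
    bz <- core
    for (i in seq_len(ew)) bz <- dilate_in(bz, fg, conn)
    bz <- bz & !core

    # background topology: border-connected components are the "outside";
    # others are enclosed holes
    bglab <- label_components(!fg, bg_conn)
    border_labs <- unique(c(bglab[1, ], bglab[nr, ], bglab[, 1], bglab[, nc]))
    border_labs <- border_labs[border_labs > 0L]
    outside <- bglab > 0L & (bglab %in% border_labs)
    dim(outside) <- dim(fg)
    hole <- (!fg) & !outside

    near_outside <- adjacent_to(outside, conn)
    near_hole <- adjacent_to(hole, conn)
    perforation <- bz & near_hole & !near_outside
    edge <- bz & !perforation

    # (4) connectors
    connector <- fg & !core & !bz & !islet
    cls[core] <- codes[["CORE"]]
    cls[islet] <- codes[["ISLET"]]
    cls[edge] <- codes[["EDGE"]]
    cls[perforation] <- codes[["PERFORATION"]]

    if (any(connector)) {
      # distinct core components and their zone reach, via min/max label
      # propagation through edge_width geodesic steps
      clab <- label_components(core, conn)
      lmin <- clab; lmax <- clab
      for (i in seq_len(ew)) {
        lmin <- propagate_labels(lmin, fg, conn, "min")
        lmax <- propagate_labels(lmax, fg, conn, "max")
      }
      zone <- core | bz
      lmin[!zone] <- 0L; lmax[!zone] <- 0L
      conlab <- label_components(connector, conn)
      contact_px <- connector & adjacent_to(zone, conn)
      contact_lab <- label_components(contact_px, conn)

      off <- neighbour_offsets(conn)
      # per contact pixel: min/max core-component label among adjacent zone px
      pmin_m <- matrix(.Machine$integer.max, nr, nc)
      pmax_m <- matrix(0L, nr, nc)
      big <- max(clab) + 1L
      lmin0 <- lmin; lmin0[lmin0 == 0L] <- big
      for (i in seq_len(nrow(off))) {
        pmin_m <- pmin(pmin_m, shift_mask_int(lmin0, off[i, 1], off[i, 2],
                                              fill = big))
        pmax_m <- pmax(pmax_m, shift_mask_int(lmax, off[i, 1], off[i, 2],
                                              fill = 0L))
      }
      for (cc in unique(conlab[conlab > 0L])) {
        px <- conlab == cc
        cpx <- px & contact_px
        if (!any(cpx))
          stop("internal error: connector component with no contact")
        n_contacts <- length(unique(contact_lab[cpx]))
        lo <- min(pmin_m[cpx]); hi <- max(pmax_m[cpx])
        cls[px] <- if (lo != hi) codes[["BRIDGE"]]
          else if (n_contacts >= 2L) codes[["LOOP"]]
          else codes[["BRANCH"]]
      }
    }
  }

  if (!is.null(landscape$nodata)) cls[landscape$nodata] <- codes[["NODATA"]]
  structure(list(classes = cls, landscape = landscape, config = config),
            class = "mspa_class_map")
}

#' @export
print.mspa_class_map <- function(x, ...) {
  cat(sprintf("<mspa_class_map> %d x %d, connectivity %d, edge width %d\n",
              nrow(x$classes), ncol(x$classes),
              x$config$connectivity, x$config$edge_width))
  print(class_summary(x))
  invisible(x)
}

#' Per-class pixel counts and areas of an MSPA class map
#'
#' @param class_map an `mspa_class_map`.
#' @param mask optional logical matrix restricting the tally (e.g. a buffer).
#' @return data.frame with columns `class`, `count`, `area_ha`
#'   (count x pixel_size^2 / 1e4).
#' @export
class_summary <- function(class_map, mask = NULL) {
  stopifnot(inherits(class_map, "mspa_class_map"))
  codes <- mspa_classes()
  cls <- class_map$classes
  if (!is.null(mask)) cls <- cls[mask]
  counts <- vapply(codes, function(k) sum(cls == k), 0L)
  data.frame(class = names(codes), count = as.integer(counts),
             area_ha = counts * class_map$landscape$pixel_size^2 / 1e4,
             row.names = NULL)
}

#' Write an MSPA class map as an ASCII grid with a JSON code-table sidecar
#'
#' @param class_map an `mspa_class_map`.
#' @param path output `.asc` path; the code table is written to
#'   `paste0(path, ".json")`.
#' @export
write_class_map <- function(class_map, path) {
  stopifnot(inherits(class_map, "mspa_class_map"))
  write_ascii_grid(class_map$landscape, path, values = class_map$classes)
  sidecar <- list(codes = as.list(mspa_classes()),
                  connectivity = class_map$config$connectivity,
                  edge_width = class_map$config$edge_width)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read an MSPA class map written by [write_class_map()]
#' @param path the `.asc` path.
#' @return an `mspa_class_map` (grid foreground = any of the seven classes).
#' @export
read_class_map <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- tolower(vapply(kv, `[`, "", 1))
  body <- scan(path, what = numeric(), skip = 6, quiet = TRUE)
  m <- matrix(body, vals[["nrows"]], vals[["ncols"]], byrow = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  codes <- mspa_classes()
  nodata <- m == codes[["NODATA"]] | m == -9999
  fg <- m >= codes[["CORE"]] & m <= codes[["BRANCH"]]
  ls <- binary_landscape(fg, pixel_size = vals[["cellsize"]],
                         xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                         nodata = if (any(nodata)) nodata else NULL)
  m[m == -9999] <- codes[["NODATA"]]
  structure(list(classes = matrix(as.integer(m), nrow(m)), landscape = ls,
                 config = mspa_config(side$connectivity, side$edge_width)),
            class = "mspa_class_map")
}
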