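#' Survey stops table
#'
#' Validates a data frame of roadside survey stops. Coordinates are in the
#' projected CRS of the rasters, in metres.
#'
#' @param stops data.frame with columns `stop_id`, `x`, `y`, `route_id` and
#'   optionally `protected` (logical).
#' @return the validated data.frame.
#' @export
survey_stops <- function(stops) {
  need <- c("stop_id", "x", "y", "route_id")
  miss <- setdiff(need, names(stops))
  if (length(miss)) stop("stops table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(stops$stop_id)) stop("stop_id must be unique")
  if (!all(is.finite(stops$x)) || !all(is.finite(stops$y)))
    stop("stop coordinates must be finite")
  if (is.null(stops$protected)) stops$protected <- FALSE
  stops
}

#' Circular buffer mask around a survey stop
#'
#' A cell belongs to the buffer iff its centre lies within `radius` metres of
#' the stop (pixel-centre-in-circle rule).
#'
#' @param landscape a [binary_landscape()] supplying grid and georeference.
#' @param stop a single-row data.frame (or list) with `stop_id`, `x`, `y`.
#' @param radius buffer radius in metres (> 0).
#' @return logical matrix, `TRUE` inside the buffer.
#' @export
extract_buffer <- function(landscape, stop, radius) {
  stopifnot(inherits(landscape, "binary_landscape"), radius > 0)
  cc <- cell_centres(landscape)
  px <- landscape$pixel_size
  # the full circle must fit inside the raster
  if (stop$x - radius < landscape$xll ||
      stop$x + radius > landscape$xll + length(cc$x) * px ||
      stop$y - radius < landscape$yll ||
      stop$y + radius > landscape$yll + length(cc$y) * px)
    stop("buffer of radius ", radius, " m around stop '", stop$stop_id,
         "' extends beyond the raster extent")
  dx2 <- (cc$x - stop$x)^2
  dy2 <- (cc$y - stop$y)^2
  mask <- outer(dy2, dx2, `+`) <= radius^2
  if (!any(mask)) stop("empty buffer around stop '", stop$stop_id, "'")
  mask
}

#' Percent cover of a binary class inside a buffer
#'
#' 100 x foreground cells / valid buffer cells; nodata cells are excluded
#' from numerator and denominator.
#'
#' @param buffer logical buffer mask from [extract_buffer()].
#' @param landscape the class raster ([binary_landscape()]).
#' @return percent in \[0, 100\].
#' @export
proportion_cover <- function(buffer, landscape) {
  stopifnot(inherits(landscape, "binary_landscape"),
            identical(dim(buffer), dim(landscape$grid)))
  valid <- buffer
  if (!is.null(landscape$nodata)) valid <- valid & !landscape$nodata
  n <- sum(valid)
  if (n == 0) stop("buffer contains no valid cells")
  100 * sum(landscape$grid & valid) / n
}

#' Compactness index of exurban development within a buffer
#'
#' The proportion of exurban pixels falling in any MSPA class other than
#' Islet: `100 * (1 - islet pixels / all exurban pixels)`. 0% means fully
#' dispersed development (all Islets), 100% fully clumped (no Islets).
#' Buffers containing no exurban pixels have no defined compactness and
#' return `NA` (such stops are excluded downstream).
#'
#' @param class_map an `mspa_class_map` of the exurban foreground raster.
#' @param buffer logical buffer mask.
#' @return percent in \[0, 100\], or `NA_real_` when the buffer holds no
#'   exurban pixels.
#' @export
compactness_index <- function(class_map, buffer) {
  stopifnot(inherits(class_map, "mspa_class_map"),
            identical(dim(buffer), dim(class_map$classes)))
  codes <- mspa_classes()
  cls <- class_map$classes[buffer]
  e <- sum(cls >= codes[["CORE"]] & cls <= codes[["BRANCH"]])
  if (e == 0L) return(NA_real_)
  i <- sum(cls == codes[["ISLET"]])
  100 * (1 - i / e)
}

#' Number of forest patches above a minimum area within a buffer
#'
#' Connected foreground components are clipped to the buffer; a patch counts
#' when its clipped area strictly exceeds `min_area_ha`.
#'
#' @param forest forest [binary_landscape()].
#' @param buffer logical buffer mask.
#' @param min_area_ha minimum patch area in hectares (default 0.45, i.e.
#'   strictly more than 5 pixels at 30 m).
#' @param connectivity patch rule, default 8.
#' @return integer count.
#' @export
count_forest_patches <- function(forest, buffer, min_area_ha = 0.45,
                                 connectivity = 8) {
  stopifnot(inherits(forest, "binary_landscape"),
            identical(dim(buffer), dim(forest$grid)))
  clipped <- forest$grid & buffer
  if (!any(clipped)) return(0L)
  lab <- label_components(clipped, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  ha_per_px <- forest$pixel_size^2 / 1e4
  sum(sizes * ha_per_px > min_area_ha)
}

#' Forest edge length within a buffer
#'
#' Total length (metres) of boundaries between forest and non-forest cells,
#' counted over 4-adjacent cell pairs that both lie inside the buffer. The
#' buffer clip line itself contributes no edge, so the measure reflects
#' pattern, not buffer geometry.
#'
#' @inheritParams count_forest_patches
#' @return length in metres.
#' @export
forest_edge_length <- function(forest, buffer) {
  stopifnot(inherits(forest, "binary_landscape"),
            identical(dim(buffer), dim(forest$grid)))
  f <- forest$grid
  nr <- nrow(f); nc <- ncol(f)
  # vertical neighbours (r, c) ~ (r+1, c)
  v <- (f[-nr, , drop = FALSE] != f[-1, , drop = FALSE]) &
    buffer[-nr, , drop = FALSE] & buffer[-1, , drop = FALSE]
  # horizontal neighbours (r, c) ~ (r, c+1)
  h <- (f[, -nc, drop = FALSE] != f[, -1, drop = FALSE]) &
    buffer[, -nc, drop = FALSE] & buffer[, -1, drop = FALSE]
  forest$pixel_size * (sum(v) + sum(h))
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Classical Moran's I, `(n / S0) * (z' W z) / (z' z)` with `z` the centred
#' values, and a two-sided permutation p-value obtained by randomly permuting
#' values over locations (`+1` correction on both counts).
#'
#' @param values numeric vector, one value per stop; must not be constant.
#' @param x,y stop coordinates (metres).
#' @param weights either the string `"idw"` (row-standardised inverse
#'   distance, the default) or an n x n weight matrix with zero diagonal.
#' @param n_perm number of permutations for the p-value (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `I`, `p`, `expected` (-1/(n-1)), `n_perm`.
#' @export
morans_i <- function(values, x, y, weights = "idw", n_perm = 999, seed = 1) {
  n <- length(values)
  if (n < 3) stop("Moran's I needs at least 3 stops")
  if (length(x) != n || length(y) != n) stop("coordinate length mismatch")
  if (stats::sd(values) == 0)
    stop("Moran's I is undefined for constant values (0/0)")
  if (is.character(weights) && identical(weights, "idw")) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    if (any(d[upper.tri(d)] == 0))
      stop("duplicate stop locations: inverse-distance weights undefined")
    w <- 1 / d
    diag(w) <- 0
    w <- w / rowSums(w)
  } else {
    w <- weights
    stopifnot(is.matrix(w), identical(dim(w), c(n, n)), all(diag(w) == 0))
  }
  s0 <- sum(w)
  moran_stat <- function(v) {
    z <- v - mean(v)
    (n / s0) * as.numeric(crossprod(z, w %*% z)) / sum(z^2)
  }
  i_obs <- moran_stat(values)
  e_i <- -1 / (n - 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i_perm <- vapply(seq_len(n_perm),
                   function(k) moran_stat(sample(values)), 0)
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
  list(I = i_obs, p = p, expected = e_i, n_perm = n_perm)
}

#' Landscape metrics for every stop x year x radius combination
#'
#' Computes the full set of per-stop predictors from per-year exurban and
#' forest rasters: percent forest, percent exurban, compactness of exurban
#' development, forest patch count (> `min_area_ha`), and forest edge.
#'
#' @param stops a [survey_stops()] table.
#' @param rasters named list, one element per year, each a list with elements
#'   `exurban` and `forest` ([binary_landscape()] objects on one grid).
#' @param radii buffer radii in metres (default `c(400, 1000)`).
#' @param config [mspa_config()] used for the exurban classification.
#' @param min_area_ha forest patch threshold (default 0.45).
#' @return data.frame, one row per stop x year x radius, with the metric
#'   columns of a stop-landscape record (`compactness` is `NA` where the
#'   buffer holds no exurban development).
#' @export
stop_landscape_records <- function(stops, rasters, radii = c(400, 1000),
                                   config = mspa_config(),
                                   min_area_ha = 0.45) {
  stops <- survey_stops(stops)
  years <- names(rasters)
  if (is.null(years)) stop("rasters must be a named list (names = years)")
  out <- vector("list", length(years) * length(radii))
  k <- 0L
  for (yr in years) {
    ras <- rasters[[yr]]
    if (is.null(ras$exurban) || is.null(ras$forest))
      stop("rasters[['", yr, "']] must contain 'exurban' and 'forest'")
    cm <- classify_mspa(ras$exurban, config)
    codes <- mspa_classes()
    for (radius in radii) {
      rec <- lapply(seq_len(nrow(stops)), function(i) {
        stp <- stops[i, ]
        buf <- extract_buffer(ras$exurban, stp, radius)
        cls <- cm$classes[buf]
        n_ex <- sum(cls >= codes[["CORE"]] & cls <= codes[["BRANCH"]])
        data.frame(
          stop_id = stp$stop_id, route_id = stp$route_id,
          protected = stp$protected, year = yr, radius = radius,
          pct_forest = proportion_cover(buf, ras$forest),
          pct_exurban = proportion_cover(buf, ras$exurban),
          compactness = compactness_index(cm, buf),
          n_forest_patches = count_forest_patches(ras$forest, buf,
                                                  min_area_ha),
          forest_edge_m = forest_edge_length(ras$forest, buf),
          n_exurban_pixels = n_ex)
      })
      k <- k + 1L
      out[[k]] <- do.call(rbind, rec)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # year comes from the list names; restore numeric years where possible
  out$year <- utils::type.convert(out$year, as.is = TRUE)
  out
}

#' Landscape composition summary table (mean +/- s.d. per variable x year)
#'
#' Summarises [stop_landscape_records()] output in the layout of a
#' composition table: one row per variable x radius, columns per year,
#' formatted `mean +/- sd`, overall and for protected-area stops. Stops with
#' undefined compactness are excluded from the compactness rows and counted
#' in the `excluded` attribute.
#'
#' @param records output of [stop_landscape_records()].
#' @return data.frame with attribute `excluded` (named count of stop x radius
#'   combinations lacking exurban development in any year).
#' @export
composition_table <- function(records) {
  vars <- c(pct_forest = "Forest (%)", pct_exurban = "Exurban development (%)",
            compactness = "Compactness (%)")
  years <- sort(unique(records$year))
  fmt <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("-")
    sprintf("%.1f \u00b1 %.1f", mean(v), if (length(v) > 1) stats::sd(v) else 0)
  }
  build <- function(df, group) {
    rows <- list()
    for (radius in sort(unique(df$radius)))
      for (v in names(vars)) {
        cells <- vapply(years, function(yr)
          fmt(df[df$radius == radius & df$year == yr, v]), "")
        rows[[length(rows) + 1L]] <- data.frame(
          group = group, radius = radius, variable = vars[[v]],
          t(cells), check.names = FALSE)
      }
    out <- do.call(rbind, rows)
    names(out)[-(1:3)] <- years
    out
  }
  tab <- rbind(build(records, "all"),
               if (any(records$protected))
                 build(records[records$protected, ], "protected"))
  excl <- tapply(records$compactness, records$radius,
                 function(v) sum(is.na(v)))
  attr(tab, "excluded") <- excl
  rownames(tab) <- NULL
  tab
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
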