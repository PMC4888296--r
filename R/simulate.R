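#' Landscape scenario: exurban infill over survey-stop tiles
#'
#' Describes a synthetic study region: one square tile per survey stop,
#' arranged in a mosaic, with exurban development made of isolated
#' single-pixel units ("islets") and solid 3x3 blocks placed on an internal
#' lattice so that islets are never 8-adjacent to other development. Each
#' stop has a latent compactness propensity; over the study periods a
#' fraction of its islets is converted in place into 3x3 blocks (infill) and
#' total development grows, so mean compactness rises monotonically across
#' periods while stops span the whole 0-100% gradient. Forest is laid down
#' as rectangular patches that shrink over time and never overlap
#' development.
#'
#' All randomness is resolved when the scenario is built, so
#' [simulate_landscape()] renders any year deterministically and infill is
#' positionally consistent across years.
#'
#' @param n_stops number of survey stops (default 105).
#' @param tile_px tile side in pixels (default 70; 2.1 km at 30 m pixels, so
#'   a 1-km buffer around the tile centre stays inside the mosaic).
#' @param pixel_size metres per pixel (default 30).
#' @param years period labels (default `c(1986, 1993, 2000, 2009)`).
#' @param exurban_frac target exurban fraction of each tile per period.
#' @param compact_scale per-period multiplier on the stop's latent
#'   compactness propensity (monotone rise mirrors regional infill).
#' @param forest_scale per-period multiplier on the stop's latent forest
#'   fraction (mild decline = forest loss).
#' @param seed RNG seed.
#' @return object of class `landscape_scenario` with per-stop unit
#'   placements, stop table, and ground-truth compactness targets.
#' @export
landscape_scenario <- function(n_stops = 105, tile_px = 70, pixel_size = 30,
                               years = c(1986, 1993, 2000, 2009),
                               exurban_frac = c(0.025, 0.028, 0.033, 0.042),
                               compact_scale = c(0.22, 0.27, 0.46, 0.88),
                               forest_scale = c(1.00, 0.97, 0.93, 0.80),
                               seed = 1) {
  ny <- length(years)
  stopifnot(length(exurban_frac) == ny, length(compact_scale) == ny,
            length(forest_scale) == ny, tile_px >= 24)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ntx <- ceiling(sqrt(n_stops))
  nty <- ceiling(n_stops / ntx)
  # lattice of candidate unit centres, 4 px apart, >= 3 px inside the tile so
  # a 3x3 block never touches the tile boundary and no two units (islet or
  # block) are ever 8-adjacent
  lat <- seq(4L, tile_px - 4L, by = 4L)
  cells <- as.matrix(expand.grid(r = lat, c = lat))
  tile_area <- tile_px^2
  stops <- data.frame(
    stop_id = sprintf("S%03d", seq_len(n_stops)),
    tile_row = rep(seq_len(nty), each = ntx)[seq_len(n_stops)],
    tile_col = rep(seq_len(ntx), times = nty)[seq_len(n_stops)])
  stops$route_id <- sprintf("R%02d", (seq_len(n_stops) - 1) %/% 5 + 1)
  nr_px <- nty * tile_px; nc_px <- ntx * tile_px
  # stop coordinates at tile centres (row 1 of the raster = north)
  ctr_row <- (stops$tile_row - 1) * tile_px + tile_px / 2 + 0.5
  ctr_col <- (stops$tile_col - 1) * tile_px + tile_px / 2 + 0.5
  stops$x <- (ctr_col - 0.5) * pixel_size
  stops$y <- (nr_px - ctr_row + 0.5) * pixel_size
  stops$protected <- FALSE

  per_stop <- vector("list", n_stops)
  truth_c <- matrix(NA_real_, n_stops, ny,
                    dimnames = list(stops$stop_id, years))
  for (i in seq_len(n_stops)) {
    u <- stats::runif(1)           # compactness propensity
    v <- stats::runif(1, 0.1, 0.9) # forest propensity
    pool <- cells[sample.int(nrow(cells)), , drop = FALSE]
    next_free <- 1L
    take <- function(n) {
      if (next_free + n - 1L > nrow(pool))
        stop("unit placement pool exhausted for stop ", stops$stop_id[i],
             "; use a larger tile_px or lower exurban_frac")
      idx <- next_free:(next_free + n - 1L)
      next_free <<- next_free + n
      idx
    }
    blocks <- integer(0); islets <- integer(0)
    snap <- vector("list", ny)
    for (y in seq_len(ny)) {
      e_px <- round(exurban_frac[y] * tile_area)
      c_target <- min(100, 100 * u * compact_scale[y])
      b_t <- round(c_target / 100 * e_px / 9)
      s_t <- max(0L, e_px - 9L * b_t)
      nconv <- min(max(0L, b_t - length(blocks)), length(islets))
      if (nconv > 0) {
        conv <- sample(seq_along(islets), nconv)
        blocks <- c(blocks, islets[conv])
        islets <- islets[-conv]
      }
      if (length(blocks) < b_t) blocks <- c(blocks, take(b_t - length(blocks)))
      if (length(islets) < s_t) islets <- c(islets, take(s_t - length(islets)))
      else if (length(islets) > s_t)
        islets <- islets[seq_len(s_t)]
      snap[[y]] <- list(blocks = blocks, islets = islets)
      truth_c[i, y] <- if (e_px > 0)
        100 * 9 * length(blocks) / (9 * length(blocks) + length(islets))
        else NA_real_
    }
    # forest: rectangles laid at scenario start, thinned by clearing rects
    f_target <- v * 0.7
    rects <- list()
    area <- 0
    guard <- 0L
    while (area < f_target * tile_area && guard < 500L) {
      guard <- guard + 1L
      h <- sample(6:18, 1); w <- sample(6:18, 1)
      r0 <- sample.int(tile_px - h, 1); c0 <- sample.int(tile_px - w, 1)
      rects[[length(rects) + 1L]] <- c(r0, c0, h, w)
      area <- area + h * w
    }
    clear <- list()
    n_clear <- max(0L, round((1 - forest_scale[ny]) * length(rects)))
    if (n_clear > 0 && length(rects) > 1) {
      cut_years <- sort(sample(2:ny, n_clear, replace = TRUE))
      cut_rects <- sample(seq_along(rects), n_clear)
      clear <- Map(function(ri, yy) c(rects[[ri]], yy), cut_rects, cut_years)
    }
    per_stop[[i]] <- list(pool = pool, snapshots = snap,
                          forest_rects = rects, clear_rects = clear,
                          u = u, v = v)
  }
  structure(list(
    n_stops = n_stops, tile_px = tile_px, pixel_size = pixel_size,
    years = years, exurban_frac = exurban_frac,
    compact_scale = compact_scale, forest_scale = forest_scale,
    ntx = ntx, nty = nty, nrow_px = nr_px, ncol_px = nc_px,
    stops = stops, per_stop = per_stop, truth_compactness = truth_c,
    seed = seed), class = "landscape_scenario")
}

#' Render one study period of a landscape scenario
#'
#' @param scenario a [landscape_scenario()].
#' @param year one of `scenario$years`.
#' @return list of two [binary_landscape()] rasters on the mosaic grid:
#'   `exurban`, `forest`.
#' @export
simulate_landscape <- function(scenario, year) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  y <- match(year, scenario$years)
  if (is.na(y)) stop("year ", year, " not in scenario (",
                     paste(scenario$years, collapse = ", "), ")")
  tp <- scenario$tile_px
  ex <- matrix(FALSE, scenario$nrow_px, scenario$ncol_px)
  fo <- matrix(FALSE, scenario$nrow_px, scenario$ncol_px)
  for (i in seq_len(scenario$n_stops)) {
    ps <- scenario$per_stop[[i]]
    r_off <- (scenario$stops$tile_row[i] - 1L) * tp
    c_off <- (scenario$stops$tile_col[i] - 1L) * tp
    snap <- ps$snapshots[[y]]
    for (b in snap$blocks) {
      rr <- ps$pool[b, 1] + r_off; cc <- ps$pool[b, 2] + c_off
      ex[(rr - 1):(rr + 1), (cc - 1):(cc + 1)] <- TRUE
    }
    for (s in snap$islets)
      ex[ps$pool[s, 1] + r_off, ps$pool[s, 2] + c_off] <- TRUE
    for (rect in ps$forest_rects) {
      fo[rect[1]:(rect[1] + rect[3] - 1) + r_off,
         rect[2]:(rect[2] + rect[4] - 1) + c_off] <- TRUE
    }
    for (cl in ps$clear_rects) {
      if (y >= cl[5])
        fo[cl[1]:(cl[1] + cl[3] - 1) + r_off,
           cl[2]:(cl[2] + cl[4] - 1) + c_off] <- FALSE
    }
  }
  fo <- fo & !ex
  px <- scenario$pixel_size
  list(exurban = binary_landscape(ex, pixel_size = px),
       forest = binary_landscape(fo, pixel_size = px))
}

#' Community scenario: species with known responses to compactness
#'
#' Defines species whose expected counts follow the hierarchical count model
#' run forward, with a known response to the compactness gradient added to
#' the linear predictor: `"step"` species jump by `effect` (log scale) on the
#' high (`"z+"`) or low (`"z-"`) side of a known change point; `"none"`
#' species ignore compactness.
#'
#' The default community mirrors the study design: six forest species with
#' positive step responses at change points spread across the gradient, and
#' five forest-edge species with mixed responses.
#'
#' @param species data.frame with columns `species`, `guild`, `response`
#'   (`"step"`/`"none"`), `direction` (`"z+"`/`"z-"`/`NA`), `change_point`
#'   (% compactness), `effect` (log-scale step size), `base_log_abund`.
#'   Defaults to the 11-species community described above.
#' @param trend_sd s.d. of per-stop log-linear trends per decade
#'   (default 0.1).
#' @param stop_sd s.d. of per-stop intercept deviations (default 0.3).
#' @param route_sd,observer_sd,error_sd random-effect s.d.s (defaults 0.2,
#'   0.2, 0.3).
#' @param first_year_effect log-scale effect of an observer's first year
#'   (default -0.3; new observers miss birds).
#' @param seed RNG seed.
#' @return object of class `community_scenario`.
#' @export
community_scenario <- function(species = NULL, trend_sd = 0.1, stop_sd = 0.3,
                               route_sd = 0.2, observer_sd = 0.2,
                               error_sd = 0.3, first_year_effect = -0.3,
                               seed = 1) {
  if (is.null(species)) {
    species <- data.frame(
      species = c("AMRE", "EAWP", "OVEN", "REVI", "SCTA", "WOTH",
                  "EAPH", "EATO", "GRCA", "INBU", "NOCA"),
      guild = c(rep("forest", 6), rep("edge", 5)),
      response = c(rep("step", 6), "step", "step", "step", "step", "none"),
      direction = c(rep("z+", 6), "z+", "z-", "z+", "z-", NA),
      change_point = c(70, 25, 50, 40, 55, 30, 10, 65, 30, 45, NA),
      effect = c(rep(1.0, 6), 1.0, 1.0, 1.0, 1.0, 0),
      base_log_abund = log(c(3, 4, 3, 6, 2, 4, 3, 4, 5, 6, 7)))
  }
  stopifnot(all(c("species", "response", "direction", "change_point",
                  "effect", "base_log_abund") %in% names(species)))
  if (any(stats::na.omit(species$change_point) <= 0) ||
      any(stats::na.omit(species$change_point) >= 100))
    stop("change points must lie in (0, 100)")
  structure(list(species = species, trend_sd = trend_sd, stop_sd = stop_sd,
                 route_sd = route_sd, observer_sd = observer_sd,
                 error_sd = error_sd, first_year_effect = first_year_effect,
                 seed = seed),
            class = "community_scenario")
}

#' Simulate stop-level counts from the hierarchical model run forward
#'
#' For every stop x year x species, draws
#' `C ~ Pois(exp(b0_stop + b1_stop * Year + b2 * FirstYear + Route +
#' Observer + Error + f(compactness)))` with all effects drawn from the
#' community scenario. Observers are assigned per route: one observer covers
#' the first half of the study, a second the rest, with `first_year = 1` in
#' each observer's first year. `Year` is centred on the mid-study year and
#' scaled to decades, matching the analysis model.
#'
#' @param stops stop table (needs `stop_id`, `route_id`).
#' @param years vector of calendar years.
#' @param metrics data.frame with `stop_id`, `year`, `compactness` (the
#'   gradient driving responses; `NA` compactness contributes no response
#'   term). Typically [stop_landscape_records()] output at one radius.
#' @param community a [community_scenario()].
#' @return list: `counts` (long data.frame: stop_id, year, species, count,
#'   observer_id, route_id, first_year) and `truth` (all generating
#'   parameters, suitable for JSON serialisation).
#' @export
simulate_counts <- function(stops, years, metrics, community) {
  stopifnot(inherits(community, "community_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(community$seed)
  ny <- length(years)
  mid_year <- mean(range(years))
  routes <- sort(unique(stops$route_id))
  # observer rota: two observers per route, handing over in a year that
  # varies by route (staggered turnover keeps the first-year effect
  # distinguishable from year-specific route conditions)
  switch_at <- sample(2:ny, length(routes), replace = TRUE)
  names(switch_at) <- routes
  obs_tab <- expand.grid(route_id = routes, yi = seq_len(ny),
                         stringsAsFactors = FALSE)
  obs_tab$observer_id <- paste0(
    obs_tab$route_id, "-O",
    ifelse(obs_tab$yi < switch_at[obs_tab$route_id], 1L, 2L))
  obs_tab$first_year <- as.integer(
    obs_tab$yi == 1L | obs_tab$yi == switch_at[obs_tab$route_id])
  observers <- sort(unique(obs_tab$observer_id))
  obs_eff <- stats::rnorm(length(observers), 0, community$observer_sd)
  names(obs_eff) <- observers
  route_eff <- matrix(stats::rnorm(length(routes) * ny, 0,
                                   community$route_sd),
                      length(routes), ny, dimnames = list(routes, years))
  spp <- community$species
  n_stop <- nrow(stops)
  b0 <- outer(stats::rnorm(n_stop, 0, community$stop_sd),
              spp$base_log_abund, `+`)
  dimnames(b0) <- list(stops$stop_id, spp$species)
  b1 <- stats::rnorm(n_stop, 0, community$trend_sd)
  names(b1) <- stops$stop_id

  key <- paste(metrics$stop_id, metrics$year)
  recs <- list()
  for (yi in seq_len(ny)) {
    yr <- years[yi]
    yr_sc <- (yr - mid_year) / 10
    comp <- metrics$compactness[match(paste(stops$stop_id, yr), key)]
    ot <- obs_tab[obs_tab$yi == yi, ]
    oid <- ot$observer_id[match(stops$route_id, ot$route_id)]
    fy <- ot$first_year[match(stops$route_id, ot$route_id)]
    for (sp_i in seq_len(nrow(spp))) {
      f_resp <- rep(0, n_stop)
      if (spp$response[sp_i] == "step") {
        above <- !is.na(comp) & comp >= spp$change_point[sp_i]
        below <- !is.na(comp) & comp < spp$change_point[sp_i]
        f_resp[if (spp$direction[sp_i] == "z+") above else below] <-
          spp$effect[sp_i]
      }
      lp <- b0[, sp_i] + b1 * yr_sc +
        community$first_year_effect * fy +
        route_eff[stops$route_id, yi] +
        obs_eff[oid] +
        stats::rnorm(n_stop, 0, community$error_sd) +
        f_resp
      recs[[length(recs) + 1L]] <- data.frame(
        stop_id = stops$stop_id, year = yr, species = spp$species[sp_i],
        count = stats::rpois(n_stop, exp(lp)), observer_id = oid,
        route_id = stops$route_id, first_year = fy)
    }
  }
  counts <- do.call(rbind, recs)
  rownames(counts) <- NULL
  truth <- list(
    species = spp, trend_sd = community$trend_sd,
    stop_sd = community$stop_sd, route_sd = community$route_sd,
    observer_sd = community$observer_sd, error_sd = community$error_sd,
    first_year_effect = community$first_year_effect,
    mid_year = mid_year, years = years, seed = community$seed)
  list(counts = counts, truth = truth)
}

#' Full synthetic input bundle at the study's scale
#'
#' Builds a complete, ready-to-analyse dataset mirroring the study design:
#' 105 stops, four periods, two buffer radii, and an 11-species community
#' (six forest species with positive step responses, five forest-edge species
#' with mixed responses). Optionally writes rasters (ASCII grid), stops and
#' counts CSVs, and a machine-readable `ground_truth.json` to `dir`.
#'
#' @param seed global seed; landscape and community streams are derived from
#'   it.
#' @param dir optional output directory.
#' @param n_stops number of stops (default 105).
#' @return list: `scenario`, `community`, `stops`, `rasters` (per year),
#'   `metrics` (both radii), `counts`, `truth`.
#' @export
study_scale_scenario <- function(seed = 1, dir = NULL, n_stops = 105) {
  scen <- landscape_scenario(n_stops = n_stops, seed = seed)
  rasters <- lapply(scen$years, function(yr) simulate_landscape(scen, yr))
  names(rasters) <- scen$years
  metrics <- stop_landscape_records(scen$stops, rasters,
                                    radii = c(400, 1000))
  comm <- community_scenario(seed = seed + 1)
  m1k <- metrics[metrics$radius == 1000, ]
  sim <- simulate_counts(scen$stops, scen$years, m1k, comm)
  truth <- c(sim$truth,
             list(landscape_seed = seed,
                  compactness_targets = scen$truth_compactness,
                  response_radius = 1000))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (yr in names(rasters)) {
      write_ascii_grid(rasters[[yr]]$exurban,
                       file.path(dir, paste0("exurban_", yr, ".asc")))
      write_ascii_grid(rasters[[yr]]$forest,
                       file.path(dir, paste0("forest_", yr, ".asc")))
    }
    utils::write.csv(scen$stops, file.path(dir, "stops.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$counts, file.path(dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(dir, "stop_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(scenario = scen, community = comm, stops = scen$stops,
       rasters = rasters, metrics = metrics, counts = sim$counts,
       truth = truth)
}
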