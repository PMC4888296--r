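# Independent brute-force MSPA reference. Deliberately naive: per-pixel
# loops, per-component set arithmetic, no shared code with the package
# implementation. Codes follow mspa_classes().

oracle_neighbours <- function(r, c, nr, nc, connectivity) {
  if (connectivity == 4) {
    d <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    d <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  out <- list()
  for (dd in d) {
    rr <- r + dd[1]; cc <- c + dd[2]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
      out[[length(out) + 1]] <- c(rr, cc)
  }
  out
}

# how many of the pixel's connectivity-neighbours are outside the raster
oracle_n_outside <- function(r, c, nr, nc, connectivity) {
  total <- if (connectivity == 4) 4 else 8
  total - length(oracle_neighbours(r, c, nr, nc, connectivity))
}

# flood-fill component labels of a logical matrix, queue-based
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue)) {
      px <- queue[[1]]; queue <- queue[-1]
      for (nb in oracle_neighbours(px[1], px[2], nr, nc, connectivity)) {
        if (mask[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
          lab[nb[1], nb[2]] <- k
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  lab
}

oracle_mspa <- function(grid, connectivity = 8, edge_width = 1) {
  nr <- nrow(grid); nc <- ncol(grid)
  CODES <- c(BACKGROUND = 0L, CORE = 1L, ISLET = 2L, EDGE = 3L,
             PERFORATION = 4L, BRIDGE = 5L, LOOP = 6L, BRANCH = 7L)
  out <- matrix(CODES["BACKGROUND"], nr, nc)
  if (!any(grid)) return(out)

  # (1) core: edge_width successive erosions; outside the raster counts as
  # background
  core <- grid
  for (step in seq_len(edge_width)) {
    nxt <- core
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!core[r, c]) next
      n_bg <- oracle_n_outside(r, c, nr, nc, connectivity)
      for (nb in oracle_neighbours(r, c, nr, nc, connectivity))
        if (!core[nb[1], nb[2]]) n_bg <- n_bg + 1
      if (n_bg >= 1) nxt[r, c] <- FALSE
    }
    core <- nxt
  }

  # (2) islets: foreground components containing no core pixel
  fg_lab <- oracle_label(grid, connectivity)
  core_comps <- unique(fg_lab[core])
  islet <- grid & !matrix(fg_lab %in% core_comps, nr, nc)

  # (3) boundary zone: geodesic dilation of core within foreground
  bz <- core
  for (step in seq_len(edge_width)) {
    nxt <- bz
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (bz[r, c] || !grid[r, c]) next
      for (nb in oracle_neighbours(r, c, nr, nc, connectivity))
        if (bz[nb[1], nb[2]]) { nxt[r, c] <- TRUE; break }
    }
    bz <- nxt
  }
  bz <- bz & !core

  # background components under the complementary connectivity; those
  # touching the raster border are the outside, the rest are holes
  bg_conn <- if (connectivity == 8) 4 else 8
  bg_lab <- oracle_label(!grid, bg_conn)
  outside_labs <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!grid[r, c] && (r == 1 || r == nr || c == 1 || c == nc))
      outside_labs <- union(outside_labs, bg_lab[r, c])
  }
  adj_outside <- function(r, c) {
    for (nb in oracle_neighbours(r, c, nr, nc, connectivity))
      if (!grid[nb[1], nb[2]] && bg_lab[nb[1], nb[2]] %in% outside_labs)
        return(TRUE)
    FALSE
  }
  adj_hole <- function(r, c) {
    for (nb in oracle_neighbours(r, c, nr, nc, connectivity))
      if (!grid[nb[1], nb[2]] && !(bg_lab[nb[1], nb[2]] %in% outside_labs))
        return(TRUE)
    FALSE
  }
  edge <- perf <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!bz[r, c]) next
    if (adj_hole(r, c) && !adj_outside(r, c)) perf[r, c] <- TRUE
    else edge[r, c] <- TRUE
  }

  # (4) connectors: per core component, the geodesic reach of its core
  # within edge_width steps defines its zone (core + boundary)
  core_lab <- oracle_label(core, connectivity)
  n_core_comp <- max(core_lab)
  zones <- list()
  if (n_core_comp > 0) for (k in seq_len(n_core_comp)) {
    z <- core_lab == k
    for (step in seq_len(edge_width)) {
      nxt <- z
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (z[r, c] || !grid[r, c]) next
        for (nb in oracle_neighbours(r, c, nr, nc, connectivity))
          if (z[nb[1], nb[2]]) { nxt[r, c] <- TRUE; break }
      }
      z <- nxt
    }
    zones[[k]] <- z
  }
  connector <- grid & !core & !bz & !islet
  con_lab <- oracle_label(connector, connectivity)
  zone_all <- core | bz
  bridge <- loop <- branch <- matrix(FALSE, nr, nc)
  if (max(con_lab) > 0) for (k in seq_len(max(con_lab))) {
    px <- which(con_lab == k, arr.ind = TRUE)
    # contact pixels: adjacent to the core-or-boundary zone
    is_contact <- logical(nrow(px))
    comps_touched <- integer(0)
    for (i in seq_len(nrow(px))) {
      for (nb in oracle_neighbours(px[i, 1], px[i, 2], nr, nc, connectivity)) {
        if (zone_all[nb[1], nb[2]]) {
          is_contact[i] <- TRUE
          for (z in seq_along(zones))
            if (zones[[z]][nb[1], nb[2]])
              comps_touched <- union(comps_touched, z)
        }
      }
    }
    cmask <- matrix(FALSE, nr, nc)
    cmask[px[is_contact, , drop = FALSE]] <- TRUE
    n_contacts <- max(oracle_label(cmask, connectivity))
    stopifnot(n_contacts >= 1)
    code <- if (length(comps_touched) >= 2) "BRIDGE"
      else if (n_contacts >= 2) "LOOP" else "BRANCH"
    for (i in seq_len(nrow(px))) out[px[i, 1], px[i, 2]] <- CODES[code]
  }
  out[core] <- CODES["CORE"]
  out[islet] <- CODES["ISLET"]
  out[edge] <- CODES["EDGE"]
  out[perf] <- CODES["PERFORATION"]
  out
}
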