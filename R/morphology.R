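# Low-level binary morphology on logical matrices. Cells outside the raster
# are always treated as background, so foreground touching the map border
# erodes there.

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
shift_mask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# One erosion step: a foreground pixel survives iff all its
# connectivity-neighbours (outside cells = background) are foreground.
erode_mask <- function(m, connectivity = 8) {
  off <- neighbour_offsets(connectivity)
  keep <- m
  for (i in seq_len(nrow(off)))
    keep <- keep & shift_mask(m, off[i, 1], off[i, 2], fill = FALSE)
  keep
}

# One dilation step restricted to `within` (geodesic dilation).
dilate_in <- function(m, within, connectivity = 8) {
  off <- neighbour_offsets(connectivity)
  grown <- m
  for (i in seq_len(nrow(off)))
    grown <- grown | shift_mask(m, off[i, 1], off[i, 2], fill = FALSE)
  grown & within
}

# TRUE where a cell has >= 1 connectivity-neighbour inside `m`.
adjacent_to <- function(m, connectivity = 8) {
  off <- neighbour_offsets(connectivity)
  adj <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    adj <- adj | shift_mask(m, off[i, 1], off[i, 2], fill = FALSE)
  adj
}

#' Label connected components of a logical matrix
#'
#' Breadth-first flood fill; labels are assigned in raster order of each
#' component's first pixel, starting at 1. Background cells get 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (rook) or 8 (queen).
#' @return integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a background frame so neighbour index arithmetic never wraps
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[seq_len(nr) + 1L, seq_len(nc) + 1L] <- mask
  npr <- nr + 2L
  off <- neighbour_offsets(connectivity)
  offs <- off[, 1] + off[, 2] * npr
  lab <- integer(length(p))
  todo <- p
  seeds <- which(p)
  k <- 0L
  for (seed in seeds) {
    if (!todo[seed]) next
    k <- k + 1L
    lab[seed] <- k
    todo[seed] <- FALSE
    frontier <- seed
    while (length(frontier)) {
      nb <- rep(frontier, each = length(offs)) + offs
      nb <- nb[todo[nb]]
      if (length(nb)) {
        nb <- unique(nb)
        lab[nb] <- k
        todo[nb] <- FALSE
      }
      frontier <- nb
    }
  }
  matrix(lab, npr)[seq_len(nr) + 1L, seq_len(nc) + 1L, drop = FALSE]
}

# Propagate integer labels one geodesic step (min or max over self and
# neighbours, restricted to `within`; 0 = unlabelled).
propagate_labels <- function(lab, within, connectivity, op = c("min", "max")) {
  op <- match.arg(op)
  off <- neighbour_offsets(connectivity)
  big <- max(lab) + 1L
  cur <- lab
  if (op == "min") cur[cur == 0L] <- big
  acc <- cur
  for (i in seq_len(nrow(off))) {
    sh <- shift_mask_int(cur, off[i, 1], off[i, 2],
                         fill = if (op == "min") big else 0L)
    acc <- if (op == "min") pmin(acc, sh) else pmax(acc, sh)
  }
  acc[!within] <- if (op == "min") big else 0L
  if (op == "min") acc[acc == big] <- 0L
  acc
}

shift_mask_int <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
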