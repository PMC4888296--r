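# Small grid constructors shared across tests.

empty_grid <- function(nr, nc = nr) matrix(FALSE, nr, nc)

# solid block of given side with top-left corner at (r0, c0)
with_block <- function(grid, r0, c0, side_r, side_c = side_r) {
  grid[r0:(r0 + side_r - 1), c0:(c0 + side_c - 1)] <- TRUE
  grid
}

# n isolated pixels on a coarse sub-lattice (never 8-adjacent)
with_islets <- function(grid, n, spacing = 3, r0 = 2, c0 = 2) {
  rows <- seq(r0, nrow(grid) - 1, by = spacing)
  cols <- seq(c0, ncol(grid) - 1, by = spacing)
  pos <- as.matrix(expand.grid(rows, cols))
  stopifnot(nrow(pos) >= n)
  grid[pos[seq_len(n), , drop = FALSE]] <- TRUE
  grid
}

full_buffer <- function(grid) matrix(TRUE, nrow(grid), ncol(grid))

class_count <- function(cm, name) sum(cm$classes == mspa_classes()[[name]])
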