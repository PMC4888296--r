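# a 100x100, 30 m landscape with the stop at a pixel centre in the middle
centre_stop_landscape <- function(grid = empty_grid(100)) {
  ls <- binary_landscape(grid, pixel_size = 30)
  stop <- list(stop_id = "S1", x = (50 - 0.5) * 30, y = (100 - 50 + 0.5) * 30)
  list(ls = ls, stop = stop)
}

test_that("buffer membership follows the pixel-centre-in-circle rule", {
  cs <- centre_stop_landscape()
  buf <- extract_buffer(cs$ls, cs$stop, 400)
  # exact enumeration: cells at offsets (30i, 30j) with (30i)^2+(30j)^2<=400^2
  expected <- sum(outer((-14:14)^2, (-14:14)^2, `+`) <= (400 / 30)^2)
  expect_equal(sum(buf), expected)
  expect_lt(abs(sum(buf) - pi * 400^2 / 900) / (pi * 400^2 / 900), 0.02)
  # tiny radius captures exactly the stop's own cell
  expect_equal(sum(extract_buffer(cs$ls, cs$stop, 10)), 1L)
  # symmetry about the stop (transpose + mirrors generate the 90-degree rotation)
  expect_identical(buf, t(buf))
  expect_identical(buf[1:99, ], buf[99:1, ])
  expect_identical(buf[, 1:99], buf[, 99:1])
})

test_that("buffers that leave the raster are rejected by stop name", {
  cs <- centre_stop_landscape()
  edge_stop <- list(stop_id = "S9", x = 45, y = 45)
  expect_error(extract_buffer(cs$ls, edge_stop, 400), "S9")
})

test_that("percent cover is the foreground share of valid buffer cells", {
  cs <- centre_stop_landscape(matrix(TRUE, 100, 100))
  buf <- extract_buffer(cs$ls, cs$stop, 400)
  expect_equal(proportion_cover(buf, cs$ls), 100)
  none <- binary_landscape(empty_grid(100), pixel_size = 30)
  expect_equal(proportion_cover(buf, none), 0)
  # exactly half the buffer cells forested -> 50%
  g <- empty_grid(100)
  idx <- which(buf)
  g[idx[seq_len(sum(buf) %/% 2)]] <- TRUE
  half <- binary_landscape(g, pixel_size = 30)
  expect_equal(proportion_cover(buf, half),
               100 * (sum(buf) %/% 2) / sum(buf))
  # nodata excluded from numerator and denominator
  nd <- matrix(FALSE, 100, 100); nd[idx[1:10]] <- TRUE
  masked <- binary_landscape(matrix(TRUE, 100, 100), pixel_size = 30,
                             nodata = nd)
  expect_equal(proportion_cover(buf, masked), 100)
  expect_error(proportion_cover(matrix(FALSE, 100, 100), cs$ls), "no valid")
})

test_that("compactness spans 0% (all islets) to 100% (no islets)", {
  g <- with_islets(empty_grid(30), 20)
  cm <- classify_mspa(binary_landscape(g, pixel_size = 30))
  expect_equal(compactness_index(cm, full_buffer(g)), 0)
  g2 <- with_block(empty_grid(30), 10, 10, 9)
  cm2 <- classify_mspa(binary_landscape(g2, pixel_size = 30))
  expect_equal(compactness_index(cm2, full_buffer(g2)), 100)
  # one 3x3 block (9 px, non-islet) + 9 islets -> 50%
  g3 <- with_block(empty_grid(30), 2, 2, 3)
  g3 <- with_islets(g3, 9, spacing = 3, r0 = 10, c0 = 10)
  cm3 <- classify_mspa(binary_landscape(g3, pixel_size = 30))
  expect_equal(compactness_index(cm3, full_buffer(g3)), 50)
  # no exurban development -> undefined
  cm4 <- classify_mspa(binary_landscape(empty_grid(10), pixel_size = 30))
  expect_true(is.na(compactness_index(cm4, full_buffer(empty_grid(10)))))
})

test_that("converting islets to core blocks never decreases compactness", {
  set.seed(41)
  g <- with_islets(empty_grid(40), 12, spacing = 5)
  g <- with_block(g, 30, 30, 3)
  base <- compactness_index(classify_mspa(binary_landscape(g)),
                            full_buffer(g))
  g2 <- with_block(g, 30, 34, 3)  # one more block, islets unchanged
  more <- compactness_index(classify_mspa(binary_landscape(g2)),
                            full_buffer(g2))
  expect_gte(more, base)
})

test_that("forest patch counting uses a strict area threshold", {
  ls <- binary_landscape(
    with_block(with_block(empty_grid(20), 2, 2, 3), 10, 10, 3),
    pixel_size = 30)
  buf <- full_buffer(ls$grid)
  expect_equal(count_forest_patches(ls, buf), 2L)
  tiny <- binary_landscape(with_islets(empty_grid(20), 5), pixel_size = 30)
  expect_equal(count_forest_patches(tiny, buf), 0L)
  # exactly 5 pixels = 0.45 ha is NOT greater than 0.45 ha
  g5 <- empty_grid(20); g5[3, 3:7] <- TRUE
  expect_equal(count_forest_patches(binary_landscape(g5, pixel_size = 30),
                                    buf), 0L)
  g6 <- empty_grid(20); g6[3, 3:8] <- TRUE
  expect_equal(count_forest_patches(binary_landscape(g6, pixel_size = 30),
                                    buf), 1L)
})

test_that("forest edge counts interior forest/non-forest adjacencies", {
  g <- with_block(empty_grid(20), 5, 5, 3)
  ls <- binary_landscape(g, pixel_size = 30)
  expect_equal(forest_edge_length(ls, full_buffer(g)), 12 * 30)
  allf <- binary_landscape(matrix(TRUE, 20, 20), pixel_size = 30)
  expect_equal(forest_edge_length(allf, full_buffer(g)), 0)
  one <- empty_grid(20); one[10, 10] <- TRUE
  expect_equal(forest_edge_length(binary_landscape(one, pixel_size = 30),
                                  full_buffer(g)), 120)
  # the buffer clip line contributes nothing: clipping to columns 1-5 leaves
  # a 3x1 forest strip whose interior boundary is 3 pairs facing col 4 plus
  # the two end caps; the cut side (col 5 | col 6) is not counted
  half_buf <- full_buffer(g); half_buf[, 6:20] <- FALSE
  expect_equal(forest_edge_length(ls, half_buf), 5 * 30)
})

test_that("Moran's I on a rook checkerboard is exactly -1", {
  pts <- expand.grid(x = 1:4, y = 1:4)
  vals <- ifelse((pts$x + pts$y) %% 2 == 0, 1, -1)
  d <- as.matrix(dist(pts))
  w <- (abs(d - 1) < 1e-9) * 1
  w <- w / rowSums(w)
  res <- morans_i(vals, pts$x, pts$y, weights = w, n_perm = 99, seed = 2)
  expect_equal(res$I, -1, tolerance = 1e-12)
  # brute-force double-loop evaluation of the formula
  n <- length(vals); z <- vals - mean(vals)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  i_brute <- (n / sum(w)) * num / sum(z^2)
  expect_equal(res$I, i_brute, tolerance = 1e-12)
})

test_that("Moran's I agrees with ape and rejects constant input", {
  skip_if_not_installed("ape")
  set.seed(42)
  x <- runif(25, 0, 1000); y <- runif(25, 0, 1000)
  v <- rnorm(25)
  res <- morans_i(v, x, y, n_perm = 199, seed = 3)
  w <- 1 / as.matrix(dist(cbind(x, y))); diag(w) <- 0
  ref <- ape::Moran.I(v, w)  # ape row-normalises by default
  expect_equal(res$I, ref$observed, tolerance = 1e-10)
  expect_error(morans_i(rep(1, 10), runif(10), runif(10)), "constant")
  expect_error(morans_i(1:2, 1:2, 1:2), "at least 3")
})

test_that("permutation p for Moran's I is roughly uniform under the null", {
  set.seed(43)
  x <- runif(20, 0, 100); y <- runif(20, 0, 100)
  ps <- replicate(200, morans_i(rnorm(20), x, y, n_perm = 99,
                                seed = sample.int(1e6, 1))$p)
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("stop metrics are invariant to translating scene and stop together", {
  set.seed(44)
  g <- matrix(runif(3600) < 0.15, 60, 60)
  ls1 <- binary_landscape(g, pixel_size = 30, xll = 0, yll = 0)
  ls2 <- binary_landscape(g, pixel_size = 30, xll = 5000, yll = -2000)
  s1 <- list(stop_id = "A", x = 30 * 30, y = 30 * 30)
  s2 <- list(stop_id = "A", x = 5000 + 30 * 30, y = -2000 + 30 * 30)
  b1 <- extract_buffer(ls1, s1, 500); b2 <- extract_buffer(ls2, s2, 500)
  expect_identical(b1, b2)
  expect_equal(proportion_cover(b1, ls1), proportion_cover(b2, ls2))
  expect_equal(forest_edge_length(ls1, b1), forest_edge_length(ls2, b2))
})

test_that("composition table summarises records and reports exclusions", {
  set.seed(45)
  recs <- expand.grid(stop_id = sprintf("S%d", 1:6),
                      year = c(1986, 1993), radius = c(400, 1000))
  recs$route_id <- "R1"; recs$protected <- recs$stop_id == "S1"
  recs$pct_forest <- runif(nrow(recs), 20, 60)
  recs$pct_exurban <- runif(nrow(recs), 5, 20)
  recs$compactness <- runif(nrow(recs), 0, 100)
  recs$compactness[recs$stop_id == "S2"] <- NA  # no development there
  tab <- composition_table(recs)
  expect_true(all(c("group", "radius", "variable", "1986", "1993")
                  %in% names(tab)))
  expect_equal(unname(attr(tab, "excluded")["400"]), 2)
  # means match a direct aggregation oracle
  m <- mean(recs$pct_forest[recs$year == 1986 & recs$radius == 400])
  cell <- tab[tab$group == "all" & tab$radius == 400 &
                tab$variable == "Forest (%)", "1986"]
  expect_equal(as.numeric(sub(" .*", "", cell)), round(m, 1))
})
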