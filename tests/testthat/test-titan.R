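# Independent naive scan for small n: explicit loops over candidate
# partitions, hand-computed indicator values, and the same permutation
# stream (seeded sample.int calls) standardising them.
oracle_scan <- function(y, env, min_split, n_perm, seed) {
  n <- length(y)
  ord <- order(env)
  ys <- y[ord]; es <- env[ord]
  iv_one <- function(yy, k, side) {
    lo <- yy[1:k]; hi <- yy[(k + 1):n]
    a_lo <- mean(lo) / (mean(lo) + mean(hi))
    if (side == "low") 100 * a_lo * mean(lo > 0)
    else 100 * (1 - a_lo) * mean(hi > 0)
  }
  cands <- integer(0)
  for (k in 1:(n - 1))
    if (es[k] != es[k + 1] && k >= min_split && (n - k) >= min_split)
      cands <- c(cands, k)
  set.seed(seed)
  perm_iv <- array(NA_real_, c(n_perm, length(cands), 2))
  for (b in 1:n_perm) {
    yp <- ys[sample.int(n)]
    for (ci in seq_along(cands)) {
      perm_iv[b, ci, 1] <- iv_one(yp, cands[ci], "low")
      perm_iv[b, ci, 2] <- iv_one(yp, cands[ci], "high")
    }
  }
  best_z <- -Inf; best <- NULL
  for (ci in seq_along(cands)) for (side in 1:2) {
    obs <- iv_one(ys, cands[ci], c("low", "high")[side])
    mu <- mean(perm_iv[, ci, side]); sdv <- sd(perm_iv[, ci, side])
    z <- if (sdv == 0) 0 else (obs - mu) / sdv
    if (z > best_z) {
      best_z <- z
      best <- list(cp = (es[cands[ci]] + es[cands[ci] + 1]) / 2,
                   direction = c("z-", "z+")[side], z = z)
    }
  }
  best
}

test_that("indicator values follow the specificity x fidelity definition", {
  # perfect low-side indicator
  expect_equal(indval(c(3, 3, 3, 0, 0, 0), c(T, T, T, F, F, F)),
               c(low = 100, high = 0))
  # identical abundance everywhere: both sides 50
  expect_equal(indval(rep(2, 6), c(T, T, T, F, F, F)),
               c(low = 50, high = 50))
  # hand computation: low = {2, 0}, high = {4, 4}
  expect_equal(indval(c(2, 0, 4, 4), c(T, T, F, F)),
               c(low = 10, high = 80))
  expect_error(indval(c(0, 0, 0), c(T, F, F)), "absent")
  expect_error(indval(c(1, 2, 3), c(T, T, T)), "non-empty")
})

test_that("a step species is located at its step with direction z+", {
  env <- seq(0, 100, length.out = 30)
  y <- ifelse(env >= 50, 10, 0)
  res <- change_point_scan(y, env, titan_config(seed = 5))
  gap <- max(diff(sort(unique(env))))
  expect_equal(res$direction, "z+")
  expect_lt(abs(res$change_point - 50), gap + 1e-9)
  expect_lte(res$p, 0.01)
  # mirrored gradient flips the direction, same |z|
  res2 <- change_point_scan(y, -env, titan_config(seed = 5))
  expect_equal(res2$direction, "z-")
  expect_equal(abs(res2$z), abs(res$z), tolerance = 1e-9)
})

test_that("z is invariant to positive rescaling of abundance", {
  set.seed(51)
  env <- runif(40, 0, 100)
  y <- rpois(40, 2) + ifelse(env > 60, 5, 0)
  a <- change_point_scan(y, env, titan_config(seed = 6))
  b <- change_point_scan(y * 17.3, env, titan_config(seed = 6))
  expect_equal(a$z, b$z, tolerance = 1e-9)
  expect_equal(a$change_point, b$change_point)
  expect_equal(a$p, b$p)
})

test_that("scan respects min_split and degenerate inputs error clearly", {
  expect_error(change_point_scan(1:8, 1:8, titan_config(min_split = 5)),
               "2 \\* min_split")
  expect_error(change_point_scan(rep(1, 12), rep(3, 12), titan_config()),
               "candidate")
  # constant abundance: permutation sd is 0 at every candidate
  expect_warning(
    res <- change_point_scan(rep(2, 12), 1:12, titan_config(min_split = 3,
                                                            n_perm = 20)),
    "zero permutation")
  expect_equal(res$z, 0)
})

test_that("the scan matches the naive oracle on small gradients", {
  set.seed(52)
  for (rep in 1:8) {
    n <- 12
    env <- sample(1:20, n)
    y <- rpois(n, 3) + ifelse(env > sample(5:15, 1), rpois(n, 4), 0)
    if (all(y == 0)) next
    cfg <- titan_config(min_split = 3, n_perm = 60, seed = 100 + rep)
    got <- suppressWarnings(change_point_scan(y, env, cfg))
    want <- suppressWarnings(oracle_scan(y, env, 3, 60, 100 + rep))
    expect_equal(got$change_point, want$cp)
    expect_equal(got$direction, want$direction)
    expect_equal(got$z, want$z, tolerance = 1e-9)
  }
})

test_that("change points stay strictly inside the gradient range", {
  set.seed(53)
  for (rep in 1:20) {
    env <- runif(30, 0, 100)
    y <- rpois(30, 3)
    if (all(y == 0)) next
    res <- suppressWarnings(
      change_point_scan(y, env, titan_config(seed = rep)))
    expect_gt(res$change_point, min(env))
    expect_lt(res$change_point, max(env))
    expect_gte(sum(env < res$change_point), 5)
    expect_gte(sum(env > res$change_point), 5)
  }
})

test_that("bootstrap diagnostics are clean for a noiseless step", {
  env <- seq(0, 100, length.out = 40)
  y <- ifelse(env >= 42, 8, 0)
  cfg <- titan_config(n_boot = 100, seed = 9)
  obs <- change_point_scan(y, env, cfg)
  boot <- bootstrap_diagnostics(y, env, cfg, obs)
  expect_equal(boot$purity, 1.0)
  expect_equal(boot$reliability, 1.0)
  expect_lt(boot$cp_quantiles[2] - boot$cp_quantiles[1], 15)
  expect_true(obs$change_point >= boot$cp_quantiles[1] - 5 &&
                obs$change_point <= boot$cp_quantiles[2] + 5)
  # single bootstrap replicate: quantiles collapse onto its change point
  one <- bootstrap_diagnostics(y, env, titan_config(n_boot = 1, seed = 9),
                               obs)
  expect_equal(unname(one$cp_quantiles[1]), unname(one$cp_quantiles[2]))
})

test_that("pure-noise species earn weak diagnostics", {
  set.seed(54)
  env <- runif(60, 0, 100)
  y <- rpois(60, 5)
  cfg <- titan_config(n_boot = 60, seed = 11)
  obs <- change_point_scan(y, env, cfg)
  boot <- bootstrap_diagnostics(y, env, cfg, obs)
  expect_lt(boot$reliability, 0.9)
})

test_that("run_titan returns one row per species, order-invariant", {
  set.seed(55)
  env <- c(runif(50, 0, 100), NA, NA)
  abund <- cbind(up = rpois(52, 1) + ifelse(!is.na(env) & env > 55, 6, 0),
                 down = rpois(52, 1) + ifelse(!is.na(env) & env < 35, 6, 0),
                 flat = rpois(52, 4),
                 gone = rep(0, 52))
  cfg <- titan_config(n_perm = 100, n_boot = 30, seed = 12)
  res <- run_titan(abund, env, cfg)
  expect_equal(res$species, c("up", "down", "flat"))
  expect_equal(attr(res, "dropped_species"), "gone")
  expect_equal(attr(res, "n_sites"), 50)
  expect_equal(res$direction[res$species == "up"], "z+")
  expect_equal(res$direction[res$species == "down"], "z-")
  expect_true(all(res$status == "ok"))
  expect_true(all(res$purity >= 0 & res$purity <= 1))
  expect_true(all(res$p > 0 & res$p <= 1))
  # permuting columns permutes rows only
  res2 <- run_titan(abund[, c(3, 1, 2, 4)], env, cfg)
  re_ordered <- res2[match(res$species, res2$species), ]
  rownames(re_ordered) <- NULL
  expect_equal(re_ordered, res)
  # empty community
  empty <- run_titan(matrix(0, 52, 0), env, cfg)
  expect_equal(nrow(empty), 0)
})

test_that("per-species errors become row status, not batch failures", {
  env <- runif(12, 0, 100)
  abund <- cbind(ok = rpois(12, 3) + 1, tiny = c(1, rep(0, 11)))
  cfg <- titan_config(min_split = 5, n_perm = 50, n_boot = 10, seed = 13)
  res <- suppressWarnings(run_titan(abund, env, cfg))
  expect_equal(nrow(res), 2)
  expect_true(all(c("ok") %in% res$species[res$status == "ok"]))
})
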