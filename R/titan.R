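#' TITAN configuration
#'
#' @param min_split minimum number of sites required on each side of a
#'   candidate change point (default 5).
#' @param n_perm permutations used to standardise indicator values into
#'   z-scores and for the p-value (default 250).
#' @param n_boot bootstrap resamples for purity/reliability and change-point
#'   quantiles (default 250).
#' @param boot_quantiles change-point uncertainty quantiles
#'   (default `c(0.05, 0.95)`).
#' @param maximize statistic maximised over candidates: `"z"`
#'   (permutation-standardised, default) or `"indval"`.
#' @param seed RNG seed.
#' @return object of class `titan_config`.
#' @export
titan_config <- function(min_split = 5, n_perm = 250, n_boot = 250,
                         boot_quantiles = c(0.05, 0.95),
                         maximize = c("z", "indval"), seed = 1) {
  if (min_split < 3) stop("min_split must be >= 3")
  if (n_perm < 1 || n_boot < 1) stop("n_perm and n_boot must be >= 1")
  structure(list(min_split = as.integer(min_split),
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 boot_quantiles = boot_quantiles,
                 maximize = match.arg(maximize), seed = seed),
            class = "titan_config")
}

#' Dufrene-Legendre indicator value of a two-group partition
#'
#' For group g: specificity `A_g` = mean abundance in g / (sum of the two
#' group mean abundances); fidelity `B_g` = fraction of g's sites where the
#' species occurs; `IndVal_g = 100 * A_g * B_g`.
#'
#' @param abundance non-negative numeric vector over sites.
#' @param low logical vector, `TRUE` for sites in the low group.
#' @return named vector `c(low = , high = )`, each in \[0, 100\].
#' @export
indval <- function(abundance, low) {
  if (all(abundance == 0)) stop("species absent from every site")
  if (!any(low) || all(low)) stop("both groups must be non-empty")
  m_lo <- mean(abundance[low]); m_hi <- mean(abundance[!low])
  a_lo <- m_lo / (m_lo + m_hi)
  c(low = 100 * a_lo * mean(abundance[low] > 0),
    high = 100 * (1 - a_lo) * mean(abundance[!low] > 0))
}

# IndVal for every candidate split of env-sorted abundance, via cumulative
# sums. y must already be ordered by env. Returns a (n-1) x 2 matrix
# (rows = split after position k; cols = low, high); non-candidate rows NA.
indval_profile <- function(y_sorted, cand) {
  n <- length(y_sorted)
  cs <- cumsum(y_sorted)
  co <- cumsum(y_sorted > 0)
  k <- seq_len(n - 1L)
  m_lo <- cs[k] / k
  m_hi <- (cs[n] - cs[k]) / (n - k)
  tot <- m_lo + m_hi
  a_lo <- ifelse(tot > 0, m_lo / tot, NA_real_)
  iv <- cbind(low = 100 * a_lo * co[k] / k,
              high = 100 * (1 - a_lo) * (co[n] - co[k]) / (n - k))
  iv[!cand, ] <- NA_real_
  iv
}

# Candidate splits: positions k (split between sorted positions k and k+1)
# with distinct env on either side and >= min_split sites each side.
candidate_splits <- function(env_sorted, min_split) {
  n <- length(env_sorted)
  k <- seq_len(n - 1L)
  env_sorted[k] != env_sorted[k + 1L] & k >= min_split & (n - k) >= min_split
}

#' Change-point scan of one species along an environmental gradient
#'
#' Candidate change points are midpoints between consecutive distinct sorted
#' environment values leaving at least `min_split` sites on each side. At
#' each candidate the two-group [indval()] is computed for both sides and
#' standardised against a permutation null (environment values permuted over
#' sites, identical candidate set): `z = (IndVal - mean_perm) / sd_perm`.
#' The species' change point is the candidate/side pair maximising z (or
#' IndVal when `maximize = "indval"`); the direction is `z-` when the winning
#' side is the low group, `z+` when it is the high group. The p-value
#' compares the observed maximum IndVal over all candidates and sides against
#' the permutation distribution of the same maximum (+1 correction), so the
#' scan's selection step is accounted for.
#'
#' @param abundance non-negative numeric vector (adjusted counts) over sites.
#' @param env finite numeric gradient values (e.g. compactness %), one per
#'   site.
#' @param config a [titan_config()].
#' @return list: `direction` (`"z-"`/`"z+"`), `z`, `change_point`,
#'   `indval_at_cp`, `p`, plus the per-candidate profile in `profile`.
#' @export
change_point_scan <- function(abundance, env, config = titan_config()) {
  n <- length(env)
  if (length(abundance) != n) stop("abundance/env length mismatch")
  if (!all(is.finite(env))) stop("env must be finite")
  if (n < 2 * config$min_split)
    stop("need at least 2 * min_split = ", 2 * config$min_split, " sites")
  ord <- order(env)
  env_s <- env[ord]
  y_s <- abundance[ord]
  cand <- candidate_splits(env_s, config$min_split)
  if (!any(cand))
    stop("no candidate change point leaves min_split sites on each side")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  scan <- .scan_core(y_s, env_s, cand, config$n_perm, config$maximize)
  scan
}

# Core scan on env-sorted data; assumes RNG already seeded.
.scan_core <- function(y_s, env_s, cand, n_perm, maximize = "z") {
  n <- length(y_s)
  iv_obs <- indval_profile(y_s, cand)
  # permutation null: permuting env over sites == permuting y over positions
  s1 <- matrix(0, n - 1L, 2L); s2 <- matrix(0, n - 1L, 2L)
  max_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ivp <- indval_profile(y_s[sample.int(n)], cand)
    s1 <- s1 + ivp; s2 <- s2 + ivp^2
    max_perm[b] <- max(ivp, na.rm = TRUE)
  }
  mu <- s1 / n_perm
  sdv <- sqrt(pmax(s2 / n_perm - mu^2, 0) * n_perm / max(n_perm - 1, 1))
  z <- (iv_obs - mu) / sdv
  degenerate <- is.finite(iv_obs) & (sdv == 0 | !is.finite(sdv))
  if (any(degenerate)) {
    warning("zero permutation s.d. at some candidates; z set to 0 there")
    z[degenerate] <- 0
  }
  crit <- if (maximize == "z") z else iv_obs
  best <- which(crit == max(crit, na.rm = TRUE), arr.ind = TRUE)[1, ]
  k <- best[["row"]]; side <- best[["col"]]
  p <- (1 + sum(max_perm >= max(iv_obs, na.rm = TRUE))) / (n_perm + 1)
  list(direction = if (side == 1L) "z-" else "z+",
       z = unname(z[k, side]),
       change_point = unname((env_s[k] + env_s[k + 1L]) / 2),
       indval_at_cp = unname(iv_obs[k, side]),
       p = p,
       profile = data.frame(split = seq_len(n - 1L),
                            midpoint = (env_s[-n] + env_s[-1L]) / 2,
                            candidate = cand, indval_low = iv_obs[, 1],
                            indval_high = iv_obs[, 2], z_low = z[, 1],
                            z_high = z[, 2]))
}

#' Bootstrap purity, reliability and change-point quantiles
#'
#' Resamples sites with replacement `n_boot` times and reruns the
#' change-point scan on each resample. Purity is the fraction of replicates
#' whose direction matches the observed one; reliability the fraction with
#' permutation p <= 0.05; the change-point quantiles summarise the bootstrap
#' change-point distribution. Resamples on which no valid candidate split
#' exists (e.g. all sites identical) are redrawn, up to 20 * n_boot draws.
#'
#' @inheritParams change_point_scan
#' @param observed result of [change_point_scan()] on the original data.
#' @return list: `purity`, `reliability`, `cp_quantiles`, `cp_boot`
#'   (the bootstrap change points), `n_redrawn`.
#' @export
bootstrap_diagnostics <- function(abundance, env, config = titan_config(),
                                  observed = NULL) {
  if (is.null(observed)) observed <- change_point_scan(abundance, env, config)
  n <- length(env)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  dirs <- character(config$n_boot)
  ps <- cps <- numeric(config$n_boot)
  n_redrawn <- 0L
  for (b in seq_len(config$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      env_b <- env[idx]; y_b <- abundance[idx]
      ord <- order(env_b)
      env_s <- env_b[ord]; y_s <- y_b[ord]
      cand <- candidate_splits(env_s, config$min_split)
      if (any(cand) && any(y_s > 0)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 20L * config$n_boot)
        stop("bootstrap resampling failed: too many degenerate resamples")
    }
    res <- suppressWarnings(
      .scan_core(y_s, env_s, cand, config$n_perm, config$maximize))
    dirs[b] <- res$direction
    ps[b] <- res$p
    cps[b] <- res$change_point
  }
  list(purity = mean(dirs == observed$direction),
       reliability = mean(ps <= 0.05),
       cp_quantiles = stats::quantile(cps, config$boot_quantiles, names = TRUE),
       cp_boot = cps, n_redrawn = n_redrawn)
}

#' Threshold Indicator Taxa Analysis over a community matrix
#'
#' Runs [change_point_scan()] and [bootstrap_diagnostics()] for every species
#' column along one environmental gradient. Sites with non-finite `env` and
#' species with zero total abundance are dropped (reported in attributes).
#' Each species draws its own RNG stream from `config$seed` and a hash of the
#' species name, so results do not depend on column order.
#'
#' @param abundance numeric matrix or data.frame, sites x species; column
#'   names identify species.
#' @param env numeric gradient, one value per site; `NA` sites are excluded.
#' @param config a [titan_config()].
#' @return data.frame, one row per species: `species`, `direction`, `z`,
#'   `change_point`, `cp_5`, `cp_95` (bootstrap quantiles), `purity`,
#'   `reliability`, `p`, `significant_090`, `significant_095` (p < 0.05 and
#'   purity/reliability at or above 0.90 / 0.95), `status`.
#' @export
run_titan <- function(abundance, env, config = titan_config()) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) == 0) {
    out <- data.frame(species = character(), direction = character(),
                      z = numeric(), change_point = numeric(),
                      cp_5 = numeric(), cp_95 = numeric(),
                      purity = numeric(), reliability = numeric(),
                      p = numeric(), significant_090 = logical(),
                      significant_095 = logical(), status = character())
    attr(out, "dropped_species") <- character()
    attr(out, "n_sites") <- sum(is.finite(env))
    return(out)
  }
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sp", seq_len(ncol(abundance)))
  keep_site <- is.finite(env)
  env <- env[keep_site]
  abundance <- abundance[keep_site, , drop = FALSE]
  dropped <- colnames(abundance)[colSums(abundance) == 0]
  abundance <- abundance[, colSums(abundance) > 0, drop = FALSE]
  species <- colnames(abundance)
  rows <- lapply(species, function(sp) {
    cfg <- config
    cfg$seed <- species_seed(config$seed, sp)
    res <- tryCatch({
      obs <- change_point_scan(abundance[, sp], env, cfg)
      boot <- bootstrap_diagnostics(abundance[, sp], env, cfg, obs)
      data.frame(species = sp, direction = obs$direction, z = obs$z,
                 change_point = obs$change_point,
                 cp_5 = unname(boot$cp_quantiles[1]),
                 cp_95 = unname(boot$cp_quantiles[2]),
                 purity = boot$purity, reliability = boot$reliability,
                 p = obs$p,
                 significant_090 = obs$p < 0.05 & boot$purity >= 0.90 &
                   boot$reliability >= 0.90,
                 significant_095 = obs$p < 0.05 & boot$purity >= 0.95 &
                   boot$reliability >= 0.95,
                 status = "ok")
    }, error = function(e)
      data.frame(species = sp, direction = NA_character_, z = NA_real_,
                 change_point = NA_real_, cp_5 = NA_real_, cp_95 = NA_real_,
                 purity = NA_real_, reliability = NA_real_, p = NA_real_,
                 significant_090 = FALSE, significant_095 = FALSE,
                 status = paste("error:", conditionMessage(e))))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped_species") <- dropped
  attr(out, "n_sites") <- length(env)
  out
}

# Deterministic per-species seed independent of column order: combine the
# global seed with a small polynomial hash of the species name (mod 2^28 so
# sums with offsets stay well inside 32-bit integer range).
species_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 268435456
  as.integer((seed + h) %% 268435456)
}
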