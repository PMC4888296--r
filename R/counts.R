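#' Build the hierarchical over-dispersed Poisson count model
#'
#' Roadside counts `C_it` for one species at stop i in year t are modelled as
#' `C_it ~ Pois(mu_it)` with
#' `log(mu_it) = beta0_stop + beta1_stop * Year_t + beta2 * FirstYear_it
#'  + Route_it + Observer_it + Error_it`:
#' a separate intercept and time trend per stop, a first-year-observer
#' effect, and zero-mean random effects for route conditions (year-varying by
#' default, since route conditions change among years), observer identity,
#' and record-level over-dispersion. `Year_t` is centred on the mid-study
#' year and scaled to decades so trends are O(1) per decade. Priors are
#' weakly informative: Normal(0, 10^2) on the betas, half-Normal(0, 2) on the
#' random-effect scales.
#'
#' @param counts data.frame with columns `stop_id`, `year` (numeric calendar
#'   year), `count`, `observer_id`, `route_id`, `first_year` (0/1 or
#'   logical). One species at a time; (stop, year) must be unique.
#' @param route_varying if `TRUE` (default) the route effect is indexed by
#'   route x year; if `FALSE` it is a static per-route effect.
#' @return object of class `count_model_spec`: JAGS model string, data list,
#'   index maps, and year-coding metadata.
#' @export
build_model <- function(counts, route_varying = TRUE) {
  need <- c("stop_id", "year", "count", "observer_id", "route_id",
            "first_year")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(counts[, c("stop_id", "year")]))
    stop("(stop_id, year) must be unique within a species")
  stops <- sort(unique(counts$stop_id))
  years <- sort(unique(counts$year))
  observers <- sort(unique(counts$observer_id))
  if (length(stops) < 2) stop("need at least 2 stops")
  if (length(years) < 2)
    stop("need at least 2 years: a single year makes the stop trend and ",
         "year-varying effects unidentifiable")
  if (length(observers) < 2)
    stop("need at least 2 observers: the observer effect is ",
         "unidentifiable from a single observer")
  mid_year <- mean(range(years))
  yr_scaled <- (counts$year - mid_year) / 10
  route_key <- if (route_varying)
    paste(counts$route_id, counts$year, sep = "|") else
      as.character(counts$route_id)
  obs_key <- as.character(counts$observer_id)
  routes <- sort(unique(route_key))
  data <- list(
    C = as.integer(counts$count),
    stop = match(counts$stop_id, stops),
    yr = yr_scaled,
    fy = as.numeric(counts$first_year),
    route = match(route_key, routes),
    obs = match(obs_key, observers),
    nobs = nrow(counts),
    nstop = length(stops),
    nroute = length(routes),
    nobserver = length(observers))
  model_string <- "
model {
  for (k in 1:nobs) {
    C[k] ~ dpois(mu[k])
    log(mu[k]) <- beta0[stop[k]] + beta1[stop[k]] * yr[k] + beta2 * fy[k] +
                  route_eff[route[k]] + obs_eff[obs[k]] + sd_eps * z_eps[k]
    # non-centered over-dispersion: scale mixing is far better than with
    # eps[k] ~ dnorm(0, tau_eps) when the per-record information is weak
    z_eps[k] ~ dnorm(0, 1)
  }
  for (s in 1:nstop) {
    beta0[s] ~ dnorm(0, 0.01)
    beta1[s] ~ dnorm(0, 0.01)
  }
  beta2 ~ dnorm(0, 0.01)
  for (r in 1:nroute) { route_eff[r] ~ dnorm(0, tau_route) }
  for (o in 1:nobserver) { obs_eff[o] ~ dnorm(0, tau_obs) }
  sd_route ~ dnorm(0, 0.25) T(0,)
  sd_obs ~ dnorm(0, 0.25) T(0,)
  sd_eps ~ dnorm(0, 0.25) T(0,)
  tau_route <- pow(sd_route, -2)
  tau_obs <- pow(sd_obs, -2)
}"
  structure(list(model_string = model_string, data = data,
                 stops = stops, years = years, observers = observers,
                 routes = routes, mid_year = mid_year,
                 route_varying = route_varying, counts = counts),
            class = "count_model_spec")
}

#' Fit the count model by MCMC
#'
#' Runs JAGS with `chains` parallel chains and returns post-warm-up draws of
#' all model parameters. Fully reproducible under a fixed seed (per-chain
#' RNG seeds are derived from it).
#'
#' @param spec a [build_model()] spec.
#' @param chains number of Markov chains (default 2; at least 2 are needed
#'   for convergence diagnostics).
#' @param draws post-warm-up iterations per chain (default 2000).
#' @param warmup adaptation + burn-in iterations (default 1000).
#' @param seed integer seed.
#' @param quiet suppress JAGS progress output (default TRUE).
#' @return object of class `posterior_draws`: list of per-chain matrices
#'   (iterations x parameters), plus `spec`, `seed`.
#' @export
fit_mcmc <- function(spec, chains = 2, draws = 2000, warmup = 1000, seed = 1,
                     quiet = TRUE) {
  stopifnot(inherits(spec, "count_model_spec"), chains >= 1)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.double(seed) * 1009 + ch) %% 2147483629)))
  monitors <- c("beta0", "beta1", "beta2", "route_eff", "obs_eff",
                "sd_route", "sd_obs", "sd_eps")
  run <- function() {
    jm <- rjags::jags.model(textConnection(spec$model_string),
                            data = spec$data, inits = inits,
                            n.chains = chains,
                            n.adapt = max(100, warmup %/% 2),
                            quiet = quiet)
    burn <- warmup - max(100, warmup %/% 2)
    if (burn > 0) update(jm, n.iter = burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = draws, progress.bar = "none")
  }
  samples <- tryCatch(
    if (quiet) suppressWarnings(run()) else run(),
    error = function(e) stop("MCMC failed: ", conditionMessage(e)))
  chains_list <- lapply(samples, function(m) {
    m <- as.matrix(m)
    attr(m, "mcpar") <- NULL
    m
  })
  structure(list(chains = chains_list, spec = spec, seed = seed,
                 draws = draws, warmup = warmup),
            class = "posterior_draws")
}

#' Gelman-Rubin potential scale reduction factor (split R-hat)
#'
#' Classical split R-hat: each chain is split in half, and
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean
#' within-half-chain variance and `B/n` the between-half-chain variance of
#' the half-chain means. Values near 1 indicate the chains have mixed; >= 1
#' up to floating-point error by construction.
#'
#' @param draws a `posterior_draws` object, or a list of iteration x
#'   parameter matrices (one per chain).
#' @return named numeric vector of R-hat per parameter (NA for parameters
#'   with zero within-chain variance).
#' @export
gelman_rubin <- function(draws) {
  chains <- if (inherits(draws, "posterior_draws")) draws$chains else draws
  if (!is.list(chains) || length(chains) < 2)
    stop("split R-hat needs at least 2 chains")
  len <- unique(vapply(chains, nrow, 0L))
  if (length(len) != 1) stop("chains must have equal length")
  if (len < 10) stop("need at least 10 draws per chain")
  half <- len %/% 2
  halves <- unlist(lapply(chains, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[(len - half + 1):len, , drop = FALSE])), recursive = FALSE)
  m <- length(halves); n <- half
  means <- vapply(halves, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(halves, function(h) apply(h, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {  # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  w <- rowMeans(vars)
  b_over_n <- apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * w + b_over_n) / w)
  rhat[w == 0] <- NA_real_
  names(rhat) <- colnames(chains[[1]])
  rhat
}

#' Observer-standardised adjusted counts
#'
#' For each stop x year cell present in the data, summarises the posterior of
#' the expected count with observer-related nuisance terms removed:
#' `exp(beta0_stop + beta1_stop * Year_t + Route_it)`. The observer,
#' first-year and over-dispersion effects are set to zero; the route effect
#' is retained by default as part of the stop's habitat context
#' (`zero_route = TRUE` removes it too). Refuses to summarise a
#' non-converged fit (max split R-hat above `rhat_threshold`) unless
#' `force = TRUE`.
#'
#' @param draws a `posterior_draws` from [fit_mcmc()].
#' @param summary `"mean"` (default) or `"median"` as the point estimate
#'   passed downstream.
#' @param zero_route also remove the route effect.
#' @param rhat_threshold convergence gate (default 1.1).
#' @param force summarise even if not converged.
#' @return data.frame per stop x year: `stop_id`, `year`, `adjusted`
#'   (the chosen point summary), `mean`, `median`, `lower95`, `upper95`,
#'   with attribute `max_rhat`.
#' @export
adjusted_counts <- function(draws, summary = c("mean", "median"),
                            zero_route = FALSE, rhat_threshold = 1.1,
                            force = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  summary <- match.arg(summary)
  spec <- draws$spec
  rhat <- gelman_rubin(draws)
  max_rhat <- max(rhat, na.rm = TRUE)
  if (!force && max_rhat >= rhat_threshold)
    stop(sprintf(
      "fit not converged (max split R-hat %.3f >= %.2f); use force = TRUE",
      max_rhat, rhat_threshold))
  all_draws <- do.call(rbind, draws$chains)
  cells <- unique(spec$counts[, c("stop_id", "year", "route_id")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    s <- match(cell$stop_id, spec$stops)
    yr <- (cell$year - spec$mid_year) / 10
    lp <- all_draws[, sprintf("beta0[%d]", s)] +
      all_draws[, sprintf("beta1[%d]", s)] * yr
    if (!zero_route) {
      key <- if (spec$route_varying)
        paste(cell$route_id, cell$year, sep = "|") else
          as.character(cell$route_id)
      r <- match(key, spec$routes)
      lp <- lp + all_draws[, sprintf("route_eff[%d]", r)]
    }
    mu <- exp(lp)
    q <- stats::quantile(mu, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(stop_id = cell$stop_id, year = cell$year,
               adjusted = if (summary == "mean") mean(mu) else q[2],
               mean = mean(mu), median = q[2],
               lower95 = q[1], upper95 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "max_rhat") <- max_rhat
  attr(out, "rhat") <- rhat
  out
}
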