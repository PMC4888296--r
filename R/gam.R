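#' Loess screen for nonlinearity
#'
#' Fits a locally weighted polynomial regression (tricube weights) and
#' compares its residual sum of squares against an ordinary linear fit with
#' an approximate F statistic:
#' `F = ((RSS_lin - RSS_loess) / (enp - 2)) / (RSS_loess / (n - enp))`,
#' where `enp` is the loess fit's equivalent number of parameters. Large F
#' flags curvature that a straight line misses; the statistic is a screen,
#' not a gate - downstream change-point analysis is run for all species.
#'
#' @param x,y numeric vectors (>= 10 points).
#' @param span loess span in (0, 1\] (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return list: `fitted` (at the observed x), `rss_loess`, `rss_linear`,
#'   `enp`, `f_statistic`, `p_value`, `loess` (the fit object).
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2) {
  n <- length(x)
  if (n < 10) stop("need at least 10 points")
  if (length(y) != n) stop("x/y length mismatch")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  fit <- tryCatch(
    suppressWarnings(stats::loess(y ~ x, span = span, degree = degree,
                                  surface = "direct")),
    error = function(e) stop("loess failed (span too small?): ",
                             conditionMessage(e)))
  lin <- stats::lm(y ~ x)
  rss_lo <- sum(stats::residuals(fit)^2)
  rss_li <- sum(stats::residuals(lin)^2)
  enp <- fit$enp
  df1 <- max(enp - 2, 0.5)
  df2 <- max(n - enp, 1)
  f <- if (rss_lo == 0 && rss_li == 0) 0 else
    max(0, (rss_li - rss_lo) / df1 / (rss_lo / df2))
  list(fitted = stats::fitted(fit), rss_loess = rss_lo, rss_linear = rss_li,
       enp = enp, f_statistic = f,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE), loess = fit)
}

#' Fit a Gaussian additive model of adjusted counts on landscape predictors
#'
#' Each continuous term enters as a penalized thin-plate regression spline
#' (basis dimension 10) with the smoothing parameter chosen by generalized
#' cross validation; `year` enters as a factor (no smooth). Gaussian errors,
#' identity link. The summary reports, per smooth, the effective degrees of
#' freedom and approximate Wald-type p-value, plus percent deviance
#' explained, the GCV score and AIC (computed with the penalized fit's
#' effective degrees of freedom).
#'
#' @param data data.frame with a `response` column, the continuous predictor
#'   columns named in `terms`, and optionally `year`.
#' @param terms character vector of continuous predictor names to smooth.
#' @param year_factor include `year` as a factor term (default TRUE when a
#'   `year` column is present).
#' @param k basis dimension per smooth (default 10).
#' @return object of class `gam_fit_summary`: `terms` data.frame (term, edf,
#'   p), `deviance_explained` (%), `gcv`, `aic`, `converged`, and the mgcv
#'   fit in `$fit`.
#' @export
fit_gam <- function(data, terms, year_factor = "year" %in% names(data),
                    k = 10) {
  if (!"response" %in% names(data)) stop("data needs a 'response' column")
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop("unknown predictor(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(terms)) stop("duplicate predictor in terms")
  use <- c("response", terms, if (year_factor) "year")
  cc <- stats::complete.cases(data[, use, drop = FALSE])
  d <- data[cc, use, drop = FALSE]
  if (year_factor) d$year <- factor(d$year)
  n_terms <- length(terms) + as.integer(year_factor)
  if (nrow(d) < 10 * max(1, n_terms))
    stop("too few rows: need >= 10 per fitted term")
  for (tm in terms)
    for (other in setdiff(terms, tm))
      if (isTRUE(all.equal(d[[tm]], d[[other]])))
        stop("collinear (identical) predictors: ", tm, " and ", other)
  smooth_k <- vapply(terms, function(tm)
    min(k, length(unique(d[[tm]]))), 0)
  rhs <- paste(c(sprintf("s(%s, k = %d)", terms, smooth_k),
                 if (year_factor) "year"), collapse = " + ")
  form <- stats::as.formula(paste("response ~", rhs))
  fit <- tryCatch(
    mgcv::gam(form, data = d, family = stats::gaussian(), method = "GCV.Cp"),
    error = function(e) stop("GAM fit failed: ", conditionMessage(e)))
  sm <- summary(fit)
  term_tab <- data.frame(
    term = terms,
    edf = as.numeric(sm$edf),
    p = as.numeric(sm$s.pv))
  if (year_factor && !is.null(sm$pTerms.pv))
    term_tab <- rbind(term_tab,
                      data.frame(term = "year", edf = NA_real_,
                                 p = as.numeric(sm$pTerms.pv[["year"]])))
  structure(list(terms = term_tab,
                 deviance_explained = 100 * sm$dev.expl,
                 gcv = as.numeric(fit$gcv.ubre),
                 aic = stats::AIC(fit),
                 converged = isTRUE(fit$converged),
                 n = nrow(d), formula = form, fit = fit),
            class = "gam_fit_summary")
}

#' @export
print.gam_fit_summary <- function(x, ...) {
  cat(sprintf("GAM (Gaussian/identity, GCV): n = %d, %s\n", x$n,
              deparse(x$formula)))
  print(x$terms, digits = 3)
  cat(sprintf("deviance explained %.1f%%, GCV %.4g, AIC %.2f, converged %s\n",
              x$deviance_explained, x$gcv, x$aic, x$converged))
  invisible(x)
}

#' Backward stepwise GAM selection by AIC
#'
#' Starting from the full additive model, repeatedly drops the single term
#' whose removal lowers AIC the most, until no removal lowers it. Returns the
#' full and best-fitted models with delta-AIC relative to the best (the best
#' model's delta-AIC is 0) and flags terms significant at p < 0.01 as key
#' factors.
#'
#' @param data as in [fit_gam()].
#' @param full_terms character vector: the full model's continuous terms.
#' @param keep_year keep the year factor in every candidate model
#'   (default TRUE; set FALSE to let it be dropped too).
#' @inheritParams fit_gam
#' @return list: `full`, `best` (both `gam_fit_summary`), `table`
#'   (model, terms, aic, delta_aic, deviance_explained, gcv), `path`
#'   (terms dropped, in order), `key_factors` (best-model terms with
#'   p < 0.01).
#' @export
backward_select <- function(data, full_terms,
                            year_factor = "year" %in% names(data),
                            keep_year = TRUE, k = 10) {
  fit_one <- function(terms, with_year)
    fit_gam(data, terms, year_factor = with_year, k = k)
  full <- fit_one(full_terms, year_factor)
  cur_terms <- full_terms
  cur_year <- year_factor
  cur <- full
  path <- character()
  repeat {
    cands <- list()
    for (tm in cur_terms)
      if (length(cur_terms) > 1 || cur_year)
        cands[[tm]] <- list(terms = setdiff(cur_terms, tm), year = cur_year)
    if (cur_year && !keep_year && length(cur_terms))
      cands[["year"]] <- list(terms = cur_terms, year = FALSE)
    if (!length(cands)) break
    fits <- lapply(cands, function(cd)
      tryCatch(fit_one(cd$terms, cd$year), error = function(e) NULL))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
    if (min(aics) >= cur$aic) break
    drop <- names(which.min(aics))
    path <- c(path, drop)
    cur <- fits[[drop]]
    cur_terms <- cands[[drop]]$terms
    cur_year <- cands[[drop]]$year
  }
  best <- cur
  tab <- data.frame(
    model = c("full", "best"),
    terms = c(paste(c(full_terms, if (year_factor) "year"), collapse = "+"),
              paste(c(cur_terms, if (cur_year) "year"), collapse = "+")),
    aic = c(full$aic, best$aic),
    delta_aic = c(full$aic - best$aic, 0),
    deviance_explained = c(full$deviance_explained, best$deviance_explained),
    gcv = c(full$gcv, best$gcv))
  key <- best$terms$term[!is.na(best$terms$p) & best$terms$p < 0.01]
  list(full = full, best = best, table = tab, path = path, key_factors = key)
}
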