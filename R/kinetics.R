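#' Fit the longitudinal mixed-effects model for one endpoint
#'
#' Linear mixed model of an optical endpoint against time from excision:
#' fixed effects for time and histology subtype (and optionally a
#' diagnosis-by-time interaction), with correlated random intercept and slope
#' per site. Per-site lines are BLUPs (fixed plus random effects), which is
#' what "sample-specific slopes estimated from the mixed model" means here.
#' Oxy-/deoxy-hemoglobin and HbSat are deliberately excluded from this linear
#' treatment by the surrounding pipeline: their post-excision kinetics are
#' not linear over the measurement window.
#'
#' @param data Tidy endpoint observations: one row per (site, timepoint)
#'   with columns `site_id`, `specimen_type`, `histology`, `diagnosis`,
#'   `time_min`, and one column per endpoint.
#' @param endpoint Name of the endpoint column to fit.
#' @param include_interaction Add a `diagnosis:time` fixed effect (used by
#'   the tissue-type rate comparison).
#' @param REML Use REML (default) or ML (required for likelihood-ratio
#'   tests).
#' @return A `kinetics_fit`: the `lme4` model, a per-site data frame with
#'   BLUP `intercept` and `slope` (endpoint units and units/min), fixed
#'   effects, the singular-fit flag, and the log-likelihood.
#' @export
fit_longitudinal <- function(data, endpoint, include_interaction = FALSE,
                             REML = TRUE) {
  need <- c("site_id", "histology", "time_min", endpoint)
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  y <- data[[endpoint]]
  if (any(!is.finite(y))) stop("endpoint contains non-finite values")
  nsite <- length(unique(data$site_id))
  if (nsite < 1) stop("empty cohort")
  cnt <- table(data$site_id)
  if (any(cnt < 2)) stop("every site needs >= 2 observations")
  df <- data.frame(y = y, time = data$time_min,
                   site = factor(data$site_id),
                   histology = factor(data$histology))
  if (include_interaction) {
    if (!"diagnosis" %in% names(data) ||
        length(unique(data$diagnosis)) < 2)
      stop("interaction model needs both diagnosis classes")
    df$diagnosis <- factor(data$diagnosis)
  }
  single_hist <- length(unique(df$histology)) < 2
  if (nsite == 1) {
    # degenerate case: ordinary least squares on the single site
    fit <- stats::lm(y ~ time, data = df)
    co <- stats::coef(fit)
    sites <- data.frame(site_id = levels(df$site),
                        intercept = unname(co[1]), slope = unname(co[2]))
    return(structure(list(model = fit, sites = sites,
                          fixed = co, singular = FALSE,
                          logLik = as.numeric(stats::logLik(fit)),
                          endpoint = endpoint), class = "kinetics_fit"))
  }
  fixed <- if (single_hist) "y ~ time" else "y ~ time + histology"
  if (include_interaction) fixed <- paste(fixed, "+ time:diagnosis")
  form <- stats::as.formula(paste(fixed, "+ (1 + time | site)"))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = REML,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 calc.derivs = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. noiseless series with no slope heterogeneity)
    # can defeat the mixed fit; fall back to per-site ordinary least squares
    # and flag the fit as singular
    sp <- split(df, df$site)
    co <- t(vapply(sp, function(s)
      stats::lm.fit(cbind(1, s$time), s$y)$coefficients, numeric(2)))
    pooled <- stats::lm(y ~ time, data = df)
    return(structure(list(model = pooled,
                          sites = data.frame(site_id = names(sp),
                                             intercept = co[, 1],
                                             slope = co[, 2],
                                             row.names = NULL),
                          fixed = stats::coef(pooled), singular = TRUE,
                          logLik = as.numeric(stats::logLik(pooled)),
                          endpoint = endpoint), class = "kinetics_fit"))
  }
  # per-site BLUP line: predict at time 0 and 1 with each site's covariates
  site_rows <- df[!duplicated(df$site), , drop = FALSE]
  nd0 <- site_rows; nd0$time <- 0
  nd1 <- site_rows; nd1$time <- 1
  p0 <- stats::predict(fit, newdata = nd0)
  p1 <- stats::predict(fit, newdata = nd1)
  sites <- data.frame(site_id = as.character(site_rows$site),
                      intercept = as.numeric(p0),
                      slope = as.numeric(p1 - p0))
  structure(list(model = fit, sites = sites,
                 fixed = lme4::fixef(fit),
                 singular = lme4::isSingular(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 endpoint = endpoint), class = "kinetics_fit")
}

#' Percent change at a time horizon
#'
#' The percent-change statistic: `100 * slope / |intercept| * horizon` per
#' site, linear in the horizon by construction, with the cohort median. Sites
#' with a zero fitted intercept are flagged and excluded from the median with
#' a warning.
#'
#' @param fit A `kinetics_fit`.
#' @param horizon Minutes post-excision.
#' @return List with `per_site` (data frame `site_id`, `percent_change`,
#'   `flagged`), `median`, `horizon`, `endpoint`.
#' @export
percent_change <- function(fit, horizon = 30) {
  stopifnot(inherits(fit, "kinetics_fit"))
  s <- fit$sites
  flagged <- s$intercept == 0
  pct <- ifelse(flagged, NA_real_,
                100 * s$slope / abs(s$intercept) * horizon)
  if (any(flagged))
    warning(sum(flagged), " site(s) with zero intercept excluded from the median")
  list(per_site = data.frame(site_id = s$site_id, percent_change = pct,
                             flagged = flagged),
       median = stats::median(pct, na.rm = TRUE),
       horizon = horizon, endpoint = fit$endpoint)
}

#' Time for the percent change to consume a benign-malignant difference
#'
#' Given the percent change of an endpoint at a reference horizon and the
#' percent difference between two tissue classes, returns the time at which
#' the (linear-in-time) percent change would exceed the class difference:
#' `t* = horizon * |difference| / |change at horizon|`.
#'
#' @param change_at_horizon Percent change at `horizon` (e.g. -44.2).
#' @param difference Percent difference between tissue classes (e.g. -92.3).
#' @param horizon Reference horizon in minutes (30 by default).
#' @return List with `minutes` (rounded to the nearest minute for reporting)
#'   and `minutes_exact`; infinite and flagged when the rate is zero.
#' @export
time_to_contrast_loss <- function(change_at_horizon, difference,
                                  horizon = 30) {
  if (!is.finite(change_at_horizon) || !is.finite(difference))
    stop("inputs must be finite")
  if (change_at_horizon == 0)
    return(list(minutes = Inf, minutes_exact = Inf, zero_rate = TRUE))
  exact <- horizon * abs(difference) / abs(change_at_horizon)
  list(minutes = round(exact), minutes_exact = exact, zero_rate = FALSE)
}

#' Compare cauterized and non-cauterized benign tissue
#'
#' Wilcoxon rank-sum tests between benign lumpectomy sites (cauterized
#' surface) and benign mastectomy sites (freshly incised, no cautery) on (a)
#' the first-measurement value of the endpoint per site and (b) per-site
#' fitted rates from mixed models refit on each group's observations
#' constrained to the first `window` minutes of its own series. Exact p-values
#' for small samples without ties, normal approximation with tie correction
#' otherwise.
#'
#' @param lump_data,mast_data Tidy observation data frames (see
#'   [fit_longitudinal()]) for the two groups.
#' @param endpoint Endpoint column name.
#' @param window Minutes from each site's first measurement used for the
#'   rate comparison.
#' @return List with `first_value` and `rate` test reports (statistic, p,
#'   group medians) and the per-site values used.
#' @export
compare_cautery <- function(lump_data, mast_data, endpoint, window = 10) {
  if (nrow(lump_data) == 0 || nrow(mast_data) == 0)
    stop("both groups must be non-empty")
  first_vals <- function(d) {
    sp <- split(d, d$site_id)
    vapply(sp, function(s) s[[endpoint]][which.min(s$time_min)], numeric(1))
  }
  windowed <- function(d) {
    sp <- split(d, d$site_id)
    do.call(rbind, lapply(sp, function(s)
      s[s$time_min <= min(s$time_min) + window, , drop = FALSE]))
  }
  v1 <- first_vals(lump_data); v2 <- first_vals(mast_data)
  all_tied <- length(unique(c(v1, v2))) == 1
  wt <- function(x, y) {
    if (length(unique(c(x, y))) == 1)
      return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                  all_tied = TRUE, exact = FALSE))
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) < 50 && length(y) < 50
    # with ties the normal approximation (tie-corrected) is used instead of
    # the exact distribution
    h <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    list(statistic = unname(h$statistic), p.value = h$p.value,
         all_tied = FALSE, exact = exact)
  }
  r1 <- fit_longitudinal(windowed(lump_data), endpoint)$sites$slope
  r2 <- fit_longitudinal(windowed(mast_data), endpoint)$sites$slope
  list(endpoint = endpoint, window = window,
       first_value = c(wt(v1, v2),
                       list(median_lump = stats::median(v1),
                            median_mast = stats::median(v2))),
       rate = c(wt(r1, r2),
                list(median_lump = stats::median(r1),
                     median_mast = stats::median(r2))),
       per_site = list(first_lump = v1, first_mast = v2,
                       rate_lump = r1, rate_mast = r2))
}

#' Likelihood-ratio test for tissue-type dependence of the kinetic rate
#'
#' Fits the longitudinal model with and without the diagnosis-by-time
#' interaction by maximum likelihood and compares them with a likelihood
#' ratio test: does the rate of change differ between benign and malignant
#' tissue?
#'
#' @param data Tidy observations containing both diagnosis classes.
#' @param endpoint Endpoint column name.
#' @return List with `statistic`, `df`, `p.value`, both fits, and flags for
#'   singular fits.
#' @export
interaction_lrt <- function(data, endpoint) {
  if (length(unique(data$diagnosis)) < 2)
    stop("both diagnosis classes must be present")
  f0 <- fit_longitudinal(data, endpoint, include_interaction = FALSE,
                         REML = FALSE)
  f1 <- fit_longitudinal(data, endpoint, include_interaction = TRUE,
                         REML = FALSE)
  stat <- 2 * (f1$logLik - f0$logLik)
  df <- length(f1$fixed) - length(f0$fixed)
  if (df <= 0) stop("models are not nested")
  list(statistic = max(0, stat), df = df,
       p.value = stats::pchisq(max(0, stat), df = df, lower.tail = FALSE),
       singular = f0$singular || f1$singular,
       null_fit = f0, alt_fit = f1)
}

#' Spearman correlation of first measurements with time from excision
#'
#' Per site, takes the first measured value of the endpoint and the minutes
#' post-excision at which it was taken, and computes the Spearman rank
#' correlation between them. A drift here means the endpoint is already
#' changing before the first measurement (as patent blue dye does while it
#' drains from the tissue).
#'
#' @param data Tidy observations.
#' @param endpoint Endpoint column name.
#' @return List with `rho`, `p.value`, `n`, `constant` flag.
#' @export
first_measurement_correlation <- function(data, endpoint) {
  sp <- split(data, data$site_id)
  if (length(sp) < 3) stop("need >= 3 sites")
  v <- vapply(sp, function(s) s[[endpoint]][which.min(s$time_min)],
              numeric(1))
  t1 <- vapply(sp, function(s) min(s$time_min), numeric(1))
  if (length(unique(v)) == 1 || length(unique(t1)) == 1)
    return(list(rho = NA_real_, p.value = NA_real_, n = length(v),
                constant = TRUE))
  h <- suppressWarnings(stats::cor.test(v, t1, method = "spearman"))
  list(rho = unname(h$estimate), p.value = h$p.value, n = length(v),
       constant = FALSE)
}

#' Apply a median percent change to a margin parameter map
#'
#' Multiplies every pixel of a 2-D endpoint map by `1 + pct/100`, emulating
#' how an image measured `horizon` minutes later would look; optionally
#' upsamples the result with separable cubic-spline interpolation for
#' rendering. Percent changes at or below -100% are clipped at zero with a
#' warning.
#'
#' @param map Numeric matrix of endpoint values.
#' @param pct Percent change to apply (e.g. the cohort median at the
#'   horizon).
#' @param upsample Integer upsampling factor (1 = none).
#' @return The decayed (and optionally upsampled) matrix.
#' @export
contrast_decay_map <- function(map, pct, upsample = 1) {
  if (any(!is.finite(map))) stop("map values must be finite")
  f <- 1 + pct / 100
  if (f < 0) {
    warning("percent change below -100%: map clipped at 0")
    f <- 0
  }
  out <- map * f
  if (upsample > 1) {
    ix <- seq_len(nrow(out)); iy <- seq_len(ncol(out))
    ox <- seq(1, nrow(out), length.out = nrow(out) * upsample)
    oy <- seq(1, ncol(out), length.out = ncol(out) * upsample)
    tmp <- apply(out, 2, function(col) stats::spline(ix, col, xout = ox)$y)
    out <- t(apply(tmp, 1, function(row) stats::spline(iy, row, xout = oy)$y))
  }
  out
}
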