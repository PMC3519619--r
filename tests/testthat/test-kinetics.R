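test_that("a single noiseless site reduces to exact least squares", {
  d <- make_series("s1", intercept = 3, slope = -0.5, times = seq(5, 20, 1))
  fit <- fit_longitudinal(d, "THb")
  expect_equal(fit$sites$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$sites$slope, -0.5, tolerance = 1e-10)
})

test_that("with no slope heterogeneity the fixed slope equals pooled least squares", {
  set.seed(31)
  d <- do.call(rbind, lapply(1:8, function(i)
    make_series(sprintf("s%d", i), intercept = 20, slope = -0.4,
                times = seq(4 + i / 7, 18, 0.9), noise_sd = 1e-4)))
  fit <- fit_longitudinal(d, "THb")
  pooled <- unname(coef(lm(THb ~ time_min, data = d))[2])
  expect_lt(abs(unname(fit$fixed["time"]) - pooled), 1e-6)
})

test_that("fit preconditions are enforced", {
  d <- make_series("s1", 3, -0.5, c(4, 9))
  expect_error(fit_longitudinal(d[1, ], "THb"), ">= 2 observations")
  d2 <- d; d2$THb[1] <- Inf
  expect_error(fit_longitudinal(d2, "THb"), "non-finite")
  expect_error(fit_longitudinal(d[0, ], "THb"))
})

test_that("percent change is linear in horizon with the documented sign convention", {
  fake <- structure(list(sites = data.frame(site_id = "s1", intercept = 1,
                                            slope = -0.442 / 30 * 10 / 10),
                         endpoint = "THb"), class = "kinetics_fit")
  fake$sites$slope <- -44.2 / 100 / 30      # -44.2% at 30 minutes
  p30 <- percent_change(fake, 30)
  p10 <- percent_change(fake, 10)
  expect_equal(p30$median, -44.2, tolerance = 1e-10)
  expect_equal(p10$median, -44.2 / 3, tolerance = 1e-10)
  expect_equal(round(p10$median, 2), -14.73)

  zero <- structure(list(sites = data.frame(site_id = "s1", intercept = 5,
                                            slope = 0), endpoint = "x"),
                    class = "kinetics_fit")
  expect_equal(percent_change(zero, 30)$median, 0)

  conv <- structure(list(sites = data.frame(site_id = "s1", intercept = -2,
                                            slope = 1), endpoint = "x"),
                    class = "kinetics_fit")
  expect_equal(percent_change(conv, 10)$median, 500)

  flagged <- structure(list(sites = data.frame(site_id = c("a", "b"),
                                               intercept = c(0, 1),
                                               slope = c(1, 0.1)),
                            endpoint = "x"), class = "kinetics_fit")
  expect_warning(pc <- percent_change(flagged, 10), "zero intercept")
  expect_true(pc$per_site$flagged[1])
  expect_equal(pc$median, 100)
})

test_that("contrast-crossing times match hand arithmetic", {
  thb <- time_to_contrast_loss(-44.2, -92.3, 30)
  expect_equal(thb$minutes, 63)
  expect_equal(thb$minutes_exact, 30 * 92.3 / 44.2, tolerance = 1e-12)
  bc <- time_to_contrast_loss(-8.2, 29.8, 30)
  expect_equal(bc$minutes, 109)
  same <- time_to_contrast_loss(-20, -20, 30)
  expect_equal(same$minutes, 30)
  z <- time_to_contrast_loss(0, 50, 30)
  expect_true(is.infinite(z$minutes) && z$zero_rate)
})

test_that("cautery comparison: null case, enumerated example, and windowing", {
  tt <- seq(4, 16, 1)
  mk <- function(vals, prefix, specimen)
    do.call(rbind, lapply(seq_along(vals), function(i)
      make_series(sprintf("%s%d", prefix, i), vals[i], -0.01, tt,
                  specimen = specimen)))
  identical_groups <- compare_cautery(mk(c(5, 6, 7), "l", "lumpectomy"),
                                      mk(c(5, 6, 7), "m", "mastectomy"),
                                      "THb")
  expect_equal(identical_groups$first_value$p.value, 1)
  constant_groups <- compare_cautery(mk(c(5, 5, 5), "l", "lumpectomy"),
                                     mk(c(5, 5, 5), "m", "mastectomy"),
                                     "THb")
  expect_equal(constant_groups$first_value$p.value, 1)
  expect_true(constant_groups$first_value$all_tied)

  sep <- compare_cautery(mk(c(1, 2, 3), "l", "lumpectomy"),
                         mk(c(10, 11, 12), "m", "mastectomy"), "THb")
  expect_equal(sep$first_value$p.value, 0.1, tolerance = 1e-12)
  # matches the enumeration oracle
  bf <- bf_wilcox(c(1, 2, 3) - 0.01 * 4, c(10, 11, 12) - 0.01 * 4)
  expect_equal(sep$first_value$p.value, bf$p.value, tolerance = 1e-12)
  expect_error(compare_cautery(mk(1, "l", "lumpectomy")[0, ],
                               mk(1, "m", "mastectomy"), "THb"))
})

test_that("generated cautery contrast is detected in most seeds", {
  cfg <- fixture_config()
  rej <- vapply(1:25, function(s) {
    co <- generate_cohort(cfg, seed = s)
    d <- co$data
    cc <- compare_cautery(d[d$specimen_type == "lumpectomy", ],
                          d[d$specimen_type == "mastectomy" &
                              d$diagnosis == "benign", ], "THb")
    cc$first_value$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("the interaction test separates classes with extreme rate differences", {
  tt <- seq(4, 16, 1)
  set.seed(5)
  ben <- do.call(rbind, lapply(1:10, function(i)
    make_series(sprintf("b%d", i), 20 + i / 5, 0, tt, noise_sd = 0.05,
                diagnosis = "benign", specimen = "mastectomy")))
  mal <- do.call(rbind, lapply(1:10, function(i)
    make_series(sprintf("m%d", i), 20 + i / 5, -1, tt, noise_sd = 0.05,
                diagnosis = "malignant", histology = "IDC",
                specimen = "mastectomy")))
  lrt <- interaction_lrt(rbind(ben, mal), "THb")
  expect_lt(lrt$p.value, 1e-3)
  expect_equal(lrt$df, 1)
  expect_error(interaction_lrt(ben, "THb"), "diagnosis")
})

test_that("at generator defaults the tissue-type interaction is mostly non-significant", {
  cfg <- fixture_config()
  ps <- vapply(1:15, function(s) {
    co <- generate_cohort(cfg, seed = s, classes = mastectomy_classes)
    interaction_lrt(co$data, "THb")$p.value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("first-measurement correlation has exact rank properties", {
  tt <- seq(2, 14, 1)
  d <- do.call(rbind, lapply(1:8, function(i)
    make_series(sprintf("s%d", i), intercept = i, slope = 0,
                times = tt + i)))
  r <- first_measurement_correlation(d, "THb")
  expect_equal(r$rho, 1)
  # invariant under strictly monotone transforms of either variable
  d2 <- d; d2$THb <- exp(d2$THb)
  expect_equal(first_measurement_correlation(d2, "THb")$rho, r$rho)
  dc <- d; dc$THb <- 5
  expect_true(first_measurement_correlation(dc, "THb")$constant)
  expect_error(first_measurement_correlation(d[d$site_id %in%
                                                 c("s1", "s2"), ], "THb"))
})

test_that("dye washout alone drives the first-measurement drift", {
  cfg <- fixture_config()
  static <- cfg
  for (e in setdiff(names(static$classes$lumpectomy_benign$endpoints), "dye")) {
    static$classes$lumpectomy_benign$endpoints[[e]]$rate_mean <- 0
    static$classes$lumpectomy_benign$endpoints[[e]]$rate_sd <- 0
  }
  res <- vapply(1:30, function(s) {
    co <- generate_cohort(static, seed = s, classes = "lumpectomy_benign")
    dye <- first_measurement_correlation(co$data, "dye")
    c(dye_p = dye$p.value, dye_rho = dye$rho,
      THb = first_measurement_correlation(co$data, "THb")$p.value,
      bc = first_measurement_correlation(co$data, "beta_carotene")$p.value)
  }, numeric(4))
  # washout drains dye before the first measurement: the correlation is
  # negative in essentially every cohort and significant in most
  expect_gte(mean(res["dye_rho", ] < 0), 0.95)
  expect_gt(mean(res["dye_p", ] < 0.05), 0.6)
  expect_gte(mean(res["THb", ] > 0.05), 0.8)
  expect_gte(mean(res["bc", ] > 0.05), 0.8)
})

test_that("per-site BLUP slopes track the generating truth", {
  cfg <- fixture_config()
  co <- generate_cohort(cfg, seed = 2, classes = "lumpectomy_benign")
  fit <- fit_longitudinal(co$data, "THb")
  tr <- co$truth[co$truth$endpoint == "THb", ]
  m <- merge(fit$sites, tr, by = "site_id")
  expect_gt(cor(m$slope.x, m$slope.y), 0.9)
})

test_that("contrast decay maps scale pixels and upsample smoothly", {
  m <- matrix(1:12, 3, 4)
  expect_equal(contrast_decay_map(m, 0), m)
  expect_equal(contrast_decay_map(m, -50), m / 2)
  expect_warning(z <- contrast_decay_map(m, -150), "clipped")
  expect_true(all(z == 0))
  up <- contrast_decay_map(m, -10, upsample = 5)
  expect_equal(dim(up), c(15, 20))
  expect_equal(mean(up), mean(m * 0.9), tolerance = 0.05)
  expect_error(contrast_decay_map(matrix(c(1, NA), 1), 0))
})
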