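test_that("cohort generation is seed-deterministic with the published counts", {
  cfg <- fixture_config()
  c1 <- generate_cohort(cfg, seed = 4)
  c2 <- generate_cohort(cfg, seed = 4)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cfg, seed = 5)
  expect_false(identical(c1$data, c3$data))

  d <- c1$data
  n_by <- table(unique(d[, c("site_id", "specimen_type", "diagnosis")])[, 2:3])
  expect_equal(unname(n_by["lumpectomy", "benign"]), 59)
  expect_equal(unname(n_by["mastectomy", "benign"]), 13)
  expect_equal(unname(n_by["mastectomy", "malignant"]), 7)
  lump_hist <- table(unique(d[d$specimen_type == "lumpectomy",
                              c("site_id", "histology")])$histology)
  expect_equal(as.vector(lump_hist[c("FG", "FA", "adipose",
                                     "mixed_other")]),
               c(1, 2, 29, 27))
})

test_that("measurement cadence honors the class timing models", {
  cfg <- fixture_config()
  d <- generate_cohort(cfg, seed = 8)$data
  for (sp in split(d, d$site_id)) {
    expect_true(all(diff(sp$time_min) > 0))
    expect_gte(nrow(sp), 2)
    dur <- max(sp$time_min) - min(sp$time_min)
    if (sp$specimen_type[1] == "lumpectomy") {
      expect_gte(min(sp$time_min), 2); expect_lte(min(sp$time_min), 12)
      expect_true(all(diff(sp$time_min) <= 1 + 1e-9))
      expect_gte(dur, 10); expect_lte(dur, 22)
    } else {
      expect_gte(min(sp$time_min), 10); expect_lte(min(sp$time_min), 27)
      expect_true(all(diff(sp$time_min) <= 0.5 + 1e-9))
      expect_gte(dur, 10); expect_lte(dur, 32.5)
    }
  }
  # lumpectomy intervals average near 0.93 min, mastectomy near 0.42 min
  iv <- function(x) unlist(lapply(split(x, x$site_id),
                                  function(s) diff(s$time_min)))
  expect_equal(mean(iv(d[d$specimen_type == "lumpectomy", ])), 0.93,
               tolerance = 0.02)
  expect_equal(mean(iv(d[d$specimen_type == "mastectomy", ])), 0.42,
               tolerance = 0.02)
})

test_that("zeroed rates and noise produce constant series", {
  cfg <- fixture_config()
  for (cl in names(cfg$classes)) {
    for (e in names(cfg$classes[[cl]]$endpoints)) {
      cfg$classes[[cl]]$endpoints[[e]]$rate_mean <- 0
      cfg$classes[[cl]]$endpoints[[e]]$rate_sd <- 0
    }
  }
  cfg$noise_sd <- 0
  cfg$dye_washout <- FALSE
  d <- generate_cohort(cfg, seed = 2)$data
  for (sp in split(d, d$site_id))
    for (e in c("THb", "beta_carotene", "mean_musp", "dye"))
      expect_equal(sd(sp[[e]]), 0)
})

test_that("default calibration encodes the published rates and targets", {
  cfg <- fixture_config()
  lump <- cfg$classes$lumpectomy_benign$endpoints
  expect_equal(lump$THb$rate_mean, -0.537)
  expect_equal(lump$THb$rate_sd, 0.750)
  expect_equal(lump$beta_carotene$rate_mean, -0.027)
  expect_equal(cfg$classes$mastectomy_benign$endpoints$THb$rate_mean, -0.036)
  expect_equal(cfg$classes$mastectomy_malignant$endpoints$THb$rate_mean,
               -0.123)
  expect_equal(unname(cfg$targets),
               c(-8.2, -13.8, 8.0, -44.2, -40.8))
  expect_equal(cfg$washout_rate, -228.7 / 100 / 30)
})

test_that("implied median percent changes equal the calibration targets", {
  cfg <- fixture_config()
  # independent oracle: draw many 59-site cohorts directly from the
  # generating distributions and average their sample medians
  set.seed(77)
  for (e in c("beta_carotene", "mean_musp", "THb")) {
    ep <- cfg$classes$lumpectomy_benign$endpoints[[e]]
    meds <- replicate(1500, {
      u <- runif(59)
      median(3000 * qnorm(1 - u, ep$rate_mean, ep$rate_sd) /
               qlnorm(u, ep$meanlog, ep$sdlog))
    })
    target <- unname(cfg$targets[e])
    expect_lt(abs(mean(meds) - target) / abs(target), 0.05)
  }
  # dye washout: the implied change is the target exactly, site by site
  co <- generate_cohort(cfg, seed = 3, classes = "lumpectomy_benign")
  tr <- co$truth[co$truth$endpoint == "dye", ]
  expect_equal(3000 * tr$slope / tr$intercept, rep(-228.7, nrow(tr)),
               tolerance = 1e-9)
})

test_that("truth medians converge to the calibrated targets in large cohorts", {
  cfg <- fixture_config()
  cfg$classes$lumpectomy_benign$n <- 501
  co <- generate_cohort(cfg, seed = 9, classes = "lumpectomy_benign")
  for (e in c("mean_musp", "THb")) {
    tr <- co$truth[co$truth$endpoint == e, ]
    med <- median(3000 * tr$slope / tr$intercept)
    expect_lt(abs(med - cfg$targets[[e]]) / abs(cfg$targets[[e]]), 0.10)
  }
})

test_that("margin maps are seeded, polarized, and respect zero field variance", {
  cfg <- fixture_config()
  m1 <- generate_margin_maps(cfg, "negative", size = 16, seed = 3)
  m2 <- generate_margin_maps(cfg, "negative", size = 16, seed = 3)
  expect_identical(m1, m2)
  expect_false(identical(
    m1, generate_margin_maps(cfg, "negative", size = 16, seed = 4)))

  flat <- generate_margin_maps(cfg, "negative", size = 8, seed = 1,
                               field_sdlog = 0)
  med <- exp(cfg$classes$lumpectomy_benign$endpoints$THb$meanlog)
  expect_equal(flat$THb, matrix(med, 8, 8))

  neg <- generate_margin_maps(cfg, "negative", size = 24, seed = 5)
  pos <- generate_margin_maps(cfg, "positive", size = 24, seed = 6)
  # positive margins: more hemoglobin, less beta-carotene
  expect_gt(median(pos$THb), median(neg$THb))
  expect_lt(median(pos$beta_carotene), median(neg$beta_carotene))
})

test_that("applying the 30-minute decay preserves benign-malignant contrast", {
  cfg <- fixture_config()
  neg <- generate_margin_maps(cfg, "negative", size = 24, seed = 5)
  pos <- generate_margin_maps(cfg, "positive", size = 24, seed = 6)
  # beta-carotene is higher on negative margins and decays -8.2% in 30 min
  dec_bc <- contrast_decay_map(neg$beta_carotene, -8.2)
  expect_gt(median(dec_bc), median(pos$beta_carotene))
  # THb is higher on positive margins; decaying the brighter image by -44.2%
  # narrows but does not erase the contrast
  dec_thb <- contrast_decay_map(pos$THb, -44.2)
  expect_gt(median(dec_thb), median(neg$THb))
})

test_that("endpoint tables round-trip through the csv writer", {
  co <- generate_cohort(fixture_config(), seed = 1,
                        classes = "mastectomy_benign")
  f <- tempfile(fileext = ".csv")
  write_endpoints(co$data, f)
  back <- read_endpoints(f)
  expect_equal(nrow(back), nrow(co$data))
  expect_equal(back$THb, co$data$THb, tolerance = 1e-12)
  expect_identical(back$site_id, co$data$site_id)
  unlink(f)
})
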