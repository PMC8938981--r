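# PSTH construction, zone segmentation, signatures and resampling.

test_that("PSTH counting matches hand oracles", {
  # one synthetic spike per trial exactly at onset
  n_trials <- 8
  onsets <- seq(700, 840, length.out = n_trials)
  pops <- data.frame(name = "SNr", size = 4L, offset = 0L, model = "adex")
  rasters <- lapply(onsets, function(o)
    structure(list(id = 1L, t = o + 0.5, duration = 1200, dt = 0.1,
                   populations = pops),
              class = "bg_raster"))
  ps <- compute_psth(rasters, onsets, pop = "SNr")
  expect_equal(length(ps$rate), 350L)
  expect_equal(ps$rate[101], 1000 / 4)  # bin at t = 0, neuron-normalized
  expect_equal(sum(ps$rate), 1000 / 4)
  expect_equal(ps$baseline$mean, 0)

  # homogeneous Poisson raster with no stimulus: all bins near the rate
  set.seed(7)
  n_neu <- 50L
  popsP <- data.frame(name = "SNr", size = n_neu, offset = 0L, model = "adex")
  rate_hz <- 30
  rasters <- lapply(1:20, function(i) {
    n <- stats::rpois(1, rate_hz * n_neu * 1.2)
    structure(list(id = sample.int(n_neu, n, replace = TRUE),
                   t = stats::runif(n, 0, 1200), duration = 1200, dt = 0.1,
                   populations = popsP),
              class = "bg_raster")
  })
  ps <- compute_psth(rasters, rep(800, 20), pop = "SNr")
  expect_equal(ps$baseline$mean, rate_hz, tolerance = 0.1)
  expect_equal(mean(ps$rate), rate_hz, tolerance = 0.1)
})

test_that("zone segmentation reproduces the counting oracle on synthetic PSTHs", {
  ps <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 10, z = 5), list(from = 11, to = 16, z = -5),
    list(from = 17, to = 26, z = 5), list(from = 27, to = 36, z = -5))))
  z <- detect_zones(ps)
  expect_true(all(z$detected))
  expect_equal(z$L[z$zone == "EE"], 7)
  expect_equal(z$D[z$zone == "EE"], 4)
  expect_equal(z$L[z$zone == "EI"], 11)
  expect_equal(z$D[z$zone == "EI"], 6)
  expect_equal(z$L[z$zone == "LE"], 17)
  expect_equal(z$D[z$zone == "LE"], 10)
  expect_equal(z$L[z$zone == "LI"], 27)
  expect_equal(z$D[z$zone == "LI"], 10)
  # zones are ordered and non-overlapping
  det <- z[z$detected, ]
  expect_true(all(diff(det$L) > 0))
  expect_true(all((det$L + det$D)[-nrow(det)] <= det$L[-1]))
})

test_that("a missing inhibitory episode merges the two excitations", {
  ps <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 26, z = 5), list(from = 27, to = 36, z = -5))))
  z <- detect_zones(ps)
  expect_true(z$detected[z$zone == "EE"])
  expect_false(z$detected[z$zone == "EI"])
  expect_false(z$detected[z$zone == "LE"])
  expect_equal(z$L[z$zone == "EE"], 7)
  expect_equal(z$D[z$zone == "EE"], 20)
  expect_equal(z$L[z$zone == "LI"], 27)
  # a separated-but-unbridged pair of excitations is also merged under EE
  ps2 <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 12, z = 5), list(from = 17, to = 26, z = 5),
    list(from = 29, to = 38, z = -5))))
  z2 <- detect_zones(ps2)
  expect_true(z2$merged[z2$zone == "EE"])
  expect_equal(z2$L[z2$zone == "EE"], 7)
  expect_equal(z2$D[z2$zone == "EE"], 20)
})

test_that("flat PSTHs yield no zones and baseline shifts cancel", {
  ps <- synthetic_psth(zone_profile(spans = list()))
  z <- detect_zones(ps)
  expect_false(any(z$detected))
  # adding a constant to every bin leaves the segmentation unchanged
  ps1 <- synthetic_psth(zone_profile(spans = list(
    list(from = 5, to = 9, z = 6), list(from = 12, to = 17, z = -6))))
  ps2 <- ps1
  ps2$rate <- ps2$rate + 100
  ps2$baseline$mean <- ps2$baseline$mean + 100
  z1 <- detect_zones(ps1)
  z2 <- detect_zones(ps2)
  expect_equal(z1$L, z2$L)
  expect_equal(z1$D, z2$D)
  expect_equal(z1$detected, z2$detected)
})

test_that("zone features follow the summation oracle", {
  base <- 30
  ps <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 10, z = 50), list(from = 13, to = 18, z = -50),
    list(from = 21, to = 30, z = 50))),
    base = base)
  z <- detect_zones(ps)
  sd_ <- ps$baseline$sd
  ee <- z[z$zone == "EE", ]
  expect_equal(ee$A, 4 * 50 * sd_, tolerance = 1e-6)
  expect_equal(ee$H_mu, base + 50 * sd_, tolerance = 1e-6)
  expect_equal(ee$H_sigma, 0)  # constant-height zone
  expect_equal(ee$H_p, base + 50 * sd_, tolerance = 1e-6)
  expect_equal(ee$H_dev, 50 * sd_ - (base - ps$baseline$mean), tolerance = 1e-4)
  ei <- z[z$zone == "EI", ]
  expect_equal(ei$H_p, base - 50 * sd_, tolerance = 1e-6)
  expect_lt(ei$H_dev, 0)
})

test_that("signatures pack 24 components and distances match brute force", {
  ps <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 10, z = 5), list(from = 11, to = 16, z = -5),
    list(from = 17, to = 26, z = 5), list(from = 27, to = 36, z = -5))))
  f <- extract_signature(detect_zones(ps))
  expect_length(f, 24L)
  expect_false(any(attr(f, "missing")))
  expect_equal(signature_distance(f, f), 0)

  # one-component difference of delta gives distance delta
  g <- f
  g[5] <- g[5] + 3.5
  expect_equal(signature_distance(f, g), 3.5)

  # random vectors against an elementwise brute-force computation
  set.seed(11)
  for (i in 1:5) {
    a <- f; b <- f
    a[] <- stats::rnorm(24); b[] <- stats::rnorm(24)
    brute <- sqrt(sum(vapply(1:24, function(k)
      (as.numeric(a)[k] - as.numeric(b)[k])^2, 0)))
    expect_equal(signature_distance(a, b), brute)
  }

  # mismatched missing-zone markers refuse to compare (unless forced)
  ps2 <- synthetic_psth(zone_profile(spans = list(
    list(from = 7, to = 26, z = 5), list(from = 27, to = 36, z = -5))))
  f2 <- extract_signature(detect_zones(ps2))
  expect_true(any(attr(f2, "missing")))
  expect_error(signature_distance(f, f2), "missing-zone")
  expect_gt(signature_distance(f, f2, strict = FALSE), 0)
  # an all-undetected signature is zero with all markers set
  fe <- extract_signature(detect_zones(synthetic_psth(zone_profile())))
  expect_true(all(attr(fe, "missing")))
  expect_equal(as.numeric(fe), rep(0, 24))
})

test_that("subpopulation resampling behaves like the resampling oracle", {
  # build rasters whose SNr response is a deterministic step: every neuron
  # fires once at onset+5 ms on every trial, plus baseline Poisson spikes
  set.seed(3)
  n_neu <- 40L
  pops <- data.frame(name = "SNr", size = n_neu, offset = 0L, model = "adex")
  onsets <- rep(800, 30)
  rasters <- lapply(onsets, function(o) {
    nb <- stats::rpois(1, 20 * n_neu * 1.2)
    structure(list(id = c(sample.int(n_neu, nb, replace = TRUE),
                          rep(1:n_neu, 2)),
                   t = c(stats::runif(nb, 0, 1200),
                         rep(c(o + 5.5, o + 6.5), each = n_neu)),
                   duration = 1200, dt = 0.1, populations = pops),
              class = "bg_raster")
  })
  full <- detect_zones(compute_psth(rasters, onsets, pop = "SNr"))
  ee_full <- full[full$zone == "EE", ]
  expect_true(ee_full$detected)

  sub50 <- subsample_features(rasters, onsets, N_S = 0.5, O_S = 30, seed = 1)
  sub100 <- subsample_features(rasters, onsets, N_S = 1.0, O_S = 5, seed = 1)
  m50 <- sub50[sub50$zone == "EE" & sub50$feature == "H_p", ]
  m100 <- sub100[sub100$zone == "EE" & sub100$feature == "H_p", ]
  # full-population observation has zero variance across observations
  expect_equal(m100$sd, 0)
  expect_equal(m100$mean, ee_full$H_p)
  # subsampled mean stays close to the full-population value
  expect_equal(m50$mean, ee_full$H_p, tolerance = 0.05)
  # smaller subsets cannot reduce the amplitude variability
  sub20 <- subsample_features(rasters, onsets, N_S = 0.2, O_S = 30, seed = 2)
  m20 <- sub20[sub20$zone == "EE" & sub20$feature == "H_p", ]
  expect_gte(m20$sd, m50$sd)
  expect_error(subsample_features(rasters, onsets, N_S = 0.01, O_S = 2),
               "one neuron")
})
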