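test_that("optical density conversion has the log10 fixed points", {
  const <- matrix(5, 10, 1)
  expect_equal(max(abs(intensity_to_od(const))), 0)
  # I / reference = 0.1 at one sample -> OD = 1 there
  x <- matrix(1, 10, 1); x[4] <- 0.1
  od <- intensity_to_od(x * 50)
  ref <- mean(x * 50)
  expect_equal(od[4], -log10(50 * 0.1 / ref))
  # halving every intensity leaves the referenced OD unchanged
  set.seed(1); y <- matrix(runif(30, 0.5, 2), 30, 1)
  expect_equal(intensity_to_od(y), intensity_to_od(y / 2), tolerance = 1e-12)
  bad <- y; bad[7] <- -1; colnames(bad) <- "ch9"
  expect_error(intensity_to_od(bad), "ch9.*sample 7")
})

test_that("modified Beer-Lambert inverts the forward model exactly", {
  set.seed(2)
  hbo <- matrix(rnorm(200, sd = 1e-3), 100, 2)
  hbr <- matrix(rnorm(200, sd = 1e-3), 100, 2)
  od <- beer_lambert_forward(hbo, hbr)
  h <- mbll(od)
  expect_equal(h$dHbO, hbo, tolerance = 1e-12)
  expect_equal(h$dHbR, hbr, tolerance = 1e-12)
  # zero OD maps to zero concentrations
  z <- mbll(list("695" = matrix(0, 5, 1), "830" = matrix(0, 5, 1)))
  expect_equal(max(abs(z$dHbO)), 0)
  # doubling the DPF halves recovered concentrations
  h2 <- mbll(od, dpf = c(12, 12))
  expect_equal(h2$dHbO, hbo / 2, tolerance = 1e-12)
  sing <- matrix(c(1, 2, 1, 2), 2, dimnames = list(c("695", "830"), c("HbO", "HbR")))
  expect_error(mbll(od, extinction = sing), "singular")
})

test_that("band-pass keeps the 0.01-0.2 Hz band and removes cardiac and drift", {
  t <- seq(0, 149.9, by = 0.1)
  mid <- 300:1200
  y1 <- bandpass_filter(sin(2 * pi * 1 * t), 10)    # cardiac
  expect_lt(max(abs(y1[mid])), 10^(-20 / 20))       # >= 20 dB attenuation
  y2 <- bandpass_filter(sin(2 * pi * 0.05 * t), 10) # in band
  expect_lt(abs(max(abs(y2[mid])) - 1), 0.05)
  y3 <- bandpass_filter(rep(2.5, 1500), 10)         # DC
  expect_lt(max(abs(y3)), 1e-6)
  expect_error(bandpass_filter(t, 10, low = 0, high = 0.2), "corner")
  expect_error(bandpass_filter(t, 10, low = 0.01, high = 6), "corner")
})

test_that("hemodynamic separation projects out the systemic direction", {
  set.seed(3)
  f <- matrix(rnorm(300), 100, 3)
  mk <- function(hbo, hbr) structure(list(dHbO = hbo, dHbR = hbr),
                                     class = "hemo_series")
  # fixed point: already purely functional input passes through
  h <- hemodynamic_separation(mk(f, -0.6 * f), k = -0.6)
  expect_equal(h$dHbO, f, tolerance = 1e-12)
  # purely systemic input (dHbR = +1 dHbO) vanishes
  s <- hemodynamic_separation(mk(f, f), k = -0.6, k_systemic = 1)
  expect_lt(max(abs(s$dHbO)), 1e-12)
  # linearity
  mix <- mk(f + 0.5 * f^0 * 2, -0.6 * f + 2)
  a1 <- hemodynamic_separation(mk(2 * f, 2 * (-0.6 * f)), k = -0.6)
  expect_equal(a1$dHbO, 2 * f, tolerance = 1e-12)
  expect_error(hemodynamic_separation(mk(f, f), k = 0.2), "negative")
})

test_that("ROI aggregation sums channel signals in the fixed ROI order", {
  m <- build_montage()
  one_per_roi <- vapply(roi_names(), function(r)
    as.integer(names(m$roi_map)[m$roi_map == r][1]), integer(1))
  ms <- subset_montage(m, one_per_roi)
  set.seed(4)
  x <- matrix(rnorm(600), 100, 6)
  colnames(x) <- as.character(one_per_roi)
  h <- structure(list(dHbO = x, dHbR = -0.6 * x), class = "hemo_series")
  rt <- aggregate_rois(h, ms)
  expect_equal(rownames(rt$traces), roi_names())
  expect_equal(unname(rt$traces[1, ]), unname(x[, 1]))
  # duplicated channel doubles the trace, correlations unchanged
  two <- as.integer(names(m$roi_map)[m$roi_map == "DLPFC(R)"][1:2])
  ms2 <- subset_montage(m, c(two, one_per_roi[-1]))
  x2 <- cbind(x, x[, 1, drop = FALSE])
  colnames(x2) <- c(as.character(one_per_roi), as.character(two[2]))
  colnames(x2)[1] <- as.character(two[1])
  h2 <- structure(list(dHbO = x2, dHbR = -0.6 * x2), class = "hemo_series")
  rt2 <- aggregate_rois(h2, ms2)
  expect_equal(unname(rt2$traces[1, ]), unname(2 * x[, 1]))
  expect_equal(cor(rt2$traces[1, ], rt2$traces[2, ]),
               cor(rt$traces[1, ], rt$traces[2, ]))
  # missing ROI errors
  h3 <- structure(list(dHbO = x[, -1], dHbR = -0.6 * x[, -1]),
                  class = "hemo_series")
  expect_error(aggregate_rois(h3, ms), "ROI without channels")
})

test_that("preprocessing a default recording yields 6 x 1500 ROI traces", {
  co <- small_cohort()
  qc <- qc_cohort(co$recordings)
  m <- suppressMessages(apply_channel_filter(qc, co$montage))
  rt <- preprocess_recording(co$recordings[[1]], m)
  expect_s3_class(rt, "roi_timeseries")
  expect_equal(dim(rt$traces), c(6L, 1500L))
  expect_true(all(is.finite(rt$traces)))
  # recovered ROI traces track the planted latents
  lat <- co$latents[[1]]
  cc <- vapply(1:6, function(i) cor(rt$traces[i, ], lat[i, ]), numeric(1))
  expect_gt(min(cc), 0.6)
})
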