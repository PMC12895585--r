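test_that("identical config and seed reproduce latents and recordings bit for bit", {
  cfg <- small_config(seed = 9L)
  a <- generate_roi_latents(cfg, 2)
  b <- generate_roi_latents(cfg, 2)
  expect_identical(a$traces, b$traces)
  ra <- project_to_channels(a, cfg, 2)
  rb <- project_to_channels(b, cfg, 2)
  expect_identical(ra$intensity, rb$intensity)
  expect_identical(ra$artifact_log, rb$artifact_log)
  # different participant index gives different data
  expect_false(identical(a$traces, generate_roi_latents(cfg, 3)$traces))
})

test_that("coupling modulation drives genuine window-to-window variation", {
  # stationary case: window estimates scatter around the static value with
  # (large, band-limited) sampling error only, identically at every onset
  cfg0 <- small_config(seed = 5L,
                       dynamic_modulation = list(amplitude = 0, period_s = 60))
  cfg1 <- small_config(seed = 5L,
                       dynamic_modulation = list(amplitude = 0.8, period_s = 60))
  win_var <- function(cfg) {
    v <- vapply(1:4, function(i) {
      lat <- generate_roi_latents(cfg, i)
      mean(apply(dynamic_fc(as_roi_ts(lat$traces))$X, 1, var))
    }, numeric(1))
    mean(v)
  }
  v0 <- win_var(cfg0)
  v1 <- win_var(cfg1)
  # modulation adds window-to-window variance on top of the stationary
  # sampling floor
  expect_gt(v1, v0 + 0.02)
  # and the window-wise estimates track the planted sinusoidal coupling
  lat1 <- generate_roi_latents(cfg1, 1)
  X <- dynamic_fc(as_roi_ts(lat1$traces))$X
  tm <- (seq_len(ncol(X)) - 1) + 10  # window mid-times (s)
  tracking <- vapply(seq_len(nrow(X)), function(k) {
    zexp <- lat1$truth$z[k] +
      lat1$truth$mod_amp[k] * sin(2 * pi * tm / 60 + lat1$truth$mod_phase[k])
    cor(X[k, ], zexp)
  }, numeric(1))
  expect_gt(mean(tracking), 0.4)
  # stationary window deviations show no temporal drift: the mean deviation
  # in the first and last third of the windows agree within the scatter
  lat <- generate_roi_latents(cfg0, 1)
  rt <- as_roi_ts(lat$traces)
  dev <- sweep(dynamic_fc(rt)$X, 1, static_fc(rt)$pair_vector)
  third <- ncol(dev) %/% 3
  drift <- abs(rowMeans(dev[, 1:third]) - rowMeans(dev[, (2 * third + 1):ncol(dev)]))
  expect_lt(median(drift), 2 * median(apply(dev, 1, sd)))
})

test_that("simulated control latents hit the target mean pairwise Fisher-z", {
  # Monte-Carlo check of the generator against its own target (0.39 +/- 0.05)
  cfg <- simulation_config(n_per_group = c(MDD = 0L, HC = 40L), seed = 31L)
  zbar <- vapply(seq_len(40), function(i) {
    lat <- generate_roi_latents(cfg, i)
    mean(static_fc(as_roi_ts(lat$traces))$pair_vector)
  }, numeric(1))
  expect_lt(abs(mean(zbar) - 0.39), 0.05)
})

test_that("requested mean Fisher-z implying |r| >= 1 is rejected", {
  expect_error(small_config(group_mean_z = c(HC = 25, MDD = 0.32)),
               "implies \\|r\\| >= 1")
  expect_error(small_config(noise = list(cardiac = -1, respiratory = 0,
                                         mayer = 0, white_od = 0,
                                         cardiac_hz = 1, respiratory_hz = 0.3,
                                         mayer_hz = 0.1)),
               "amplitudes")
})

test_that("channel projection carries physiology, artifacts and a clean baseline", {
  co <- small_cohort()
  rec <- co$recordings[[1]]
  expect_equal(nrow(rec$intensity[[1]]), 1600L)
  expect_equal(ncol(rec$intensity[[1]]), 52L)
  # cardiac component: periodogram of a task-segment channel peaks near 1 Hz
  od <- -log10(rec$intensity[["830"]][101:1600, 5] /
                 mean(rec$intensity[["830"]][101:1600, 5]))
  sp <- stats::spec.pgram(stats::ts(od, frequency = 10), plot = FALSE,
                          taper = 0, detrend = TRUE)
  hi <- sp$freq > 0.5
  expect_lt(abs(sp$freq[hi][which.max(sp$spec[hi])] - 1), 0.15)
  # artifact bookkeeping
  expect_true(all(c("channel", "sample", "type") %in% colnames(rec$artifact_log)))
  cfg0 <- small_config(seed = 8L,
                       artifact_rate = list(spikes_per_min = 0, shifts_per_min = 0))
  rec0 <- project_to_channels(generate_roi_latents(cfg0, 1), cfg0, 1)
  expect_equal(nrow(rec0$artifact_log), 0L)
})

test_that("zero noise and zero artifacts make within-ROI channels proportional", {
  cfg0 <- small_config(
    seed = 3L,
    noise = list(cardiac = 0, respiratory = 0, mayer = 0, white_od = 0,
                 cardiac_hz = 1, respiratory_hz = 0.3, mayer_hz = 0.1),
    artifact_rate = list(spikes_per_min = 0, shifts_per_min = 0))
  rec <- project_to_channels(generate_roi_latents(cfg0, 1), cfg0, 1)
  m <- cfg0$montage
  ch_dlpfc <- names(m$roi_map)[m$roi_map == "DLPFC(R)"][1:2]
  od <- intensity_to_od(rec$intensity[["830"]][101:1600, ch_dlpfc])
  # same ROI latent, no channel noise: task optical densities correlate ~1
  expect_gt(cor(od[, 1], od[, 2]), 0.999999)
})

test_that("clinical table respects instrument ranges and planted copula links", {
  set.seed(100)
  cfg <- simulation_config(n_per_group = c(MDD = 83L, HC = 78L), seed = 17L)
  feat <- matrix(rnorm(161 * 2), 161, 2,
                 dimnames = list(c(sprintf("MDD%03d", 1:83), sprintf("HC%03d", 84:161)),
                                 c("static|DLPFC(R)~mPFC(R)", "PC3|DLPFC(L)~TL(L)")))
  cl <- generate_clinical(cfg, feat)
  expect_equal(nrow(cl), 161L)
  expect_true(all(cl$dass_d >= 0 & cl$dass_d <= 21))
  expect_true(all(cl$shaps >= 0 & cl$shaps <= 42))
  expect_true(all(cl$age >= 12 & cl$age <= 18))
  expect_true(all(is.na(cl$medication[cl$group == "HC"])))
  expect_true(all(cl$medication[cl$group == "MDD"] %in%
                    names(fluoxetine_equivalence_table())))
  # planted Spearman -0.48 at n = 83 recovered within +/- 0.15
  mdd <- cl$group == "MDD"
  r_hat <- cor(cl$dass_d[mdd], feat[mdd, 1], method = "spearman")
  expect_lt(abs(r_hat - (-0.48)), 0.15)
  # SHAPS marginal moments near the configured 33.07 +/- 7.37
  expect_lt(abs(mean(cl$shaps[mdd]) - 33.07), 3 * 7.37 / sqrt(83))
  expect_lt(abs(sd(cl$shaps[mdd]) - 7.37), 2.5)
})

test_that("unlinked scores stay inside the null correlation band", {
  cfg <- simulation_config(
    n_per_group = c(MDD = 83L, HC = 0L), seed = 23L,
    clinical_link = data.frame(feature_id = character(0),
                               score = character(0), r = numeric(0)))
  feat <- matrix(rnorm(83), 83, 1,
                 dimnames = list(sprintf("MDD%03d", 1:83), "static|TL(R)~TL(L)"))
  cl <- generate_clinical(cfg, feat)
  r0 <- cor(cl$dass_d, feat[, 1], method = "spearman")
  expect_lt(abs(r0), 3 / sqrt(83))  # ~3 null standard errors
})

test_that("invalid clinical links are rejected", {
  cfg <- small_config()
  feat <- matrix(rnorm(8), 8, 1,
                 dimnames = list(c(sprintf("MDD%03d", 1:4), sprintf("HC%03d", 5:8)),
                                 "static|TL(R)~TL(L)"))
  expect_error(generate_clinical(cfg, feat), "not among the feature labels")
  expect_error(
    small_config(clinical_link = data.frame(
      feature_id = "static|DLPFC(R)~mPFC(R)", score = "dass_d", r = 1.2)),
    "target_spearman_r")
})

test_that("whole-cohort simulation is seed-deterministic", {
  a <- simulate_cohort(small_config(n_mdd = 2L, n_hc = 2L, seed = 77L))
  b <- simulate_cohort(small_config(n_mdd = 2L, n_hc = 2L, seed = 77L))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$recordings[[3]]$intensity, b$recordings[[3]]$intensity)
  expect_identical(a$anchor_features, b$anchor_features)
})
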