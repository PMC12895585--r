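# Shared small fixtures, generated in code and cached per session.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(n_mdd = 4L, n_hc = 4L, seed = 42L, ...) {
  simulation_config(n_per_group = c(MDD = n_mdd, HC = n_hc), seed = seed, ...)
}

small_cohort <- function(n_mdd = 4L, n_hc = 4L, seed = 42L) {
  key <- sprintf("cohort_%d_%d_%d", n_mdd, n_hc, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cohort(small_config(n_mdd, n_hc, seed),
                                             keep_latents = TRUE)
  }
  .fixture_cache[[key]]
}

# roi_timeseries wrapper around a 6 x T trace matrix
as_roi_ts <- function(traces, rate = 10, id = "P1", group = "HC") {
  rownames(traces) <- roi_names()
  structure(list(traces = traces, roi_order = roi_names(),
                 sampling_rate = rate, id = id, group = group),
            class = "roi_timeseries")
}

# correlated 6-ROI Gaussian traces with common correlation rho
correlated_traces <- function(T_n, rho, seed = 1) {
  set.seed(seed)
  C <- matrix(rho, 6, 6); diag(C) <- 1
  t(chol(C)) %*% matrix(rnorm(6 * T_n), 6, T_n)
}

# minimal fnirs_recording built from explicit intensity matrices
fake_recording <- function(intensity, baseline_n, id = "X1", group = "HC",
                           rate = 10) {
  structure(list(id = id, group = group, intensity = intensity,
                 sampling_rate = rate, baseline_n = baseline_n,
                 wavelengths = as.numeric(names(intensity)),
                 artifact_log = data.frame(), truth = NULL),
            class = "fnirs_recording")
}
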