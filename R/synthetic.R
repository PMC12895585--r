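#' Configuration for the synthetic task-fNIRS cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults encode the study
#' conditions the downstream analysis assumes: a 52-channel frontotemporal
#' montage sampled at 10 Hz during a 150-s block task (30 s pre / 60 s task /
#' 60 s post) preceded by a 10-s quiet baseline; six ROIs whose band-limited
#' (0.01-0.2 Hz) hemodynamic latents carry a group-dependent pairwise
#' correlation structure (mean pairwise Fisher-z 0.39 for controls, 0.32 for
#' the clinical group, between-subject SD 0.07 / 0.11); slow sinusoidal
#' modulation of the coupling so that sliding-window connectivity is genuinely
#' time-varying; channel-level physiological nuisance (cardiac ~1 Hz,
#' respiratory ~0.3 Hz, Mayer ~0.1 Hz) entering as systemic hemodynamics;
#' white measurement noise; sparse spike and baseline-shift motion artifacts;
#' and clinical scores tied to chosen connectivity features through a
#' Gaussian copula with stated Spearman targets.
#'
#' @param n_per_group named integer vector `c(MDD = ..., HC = ...)`.
#' @param sampling_rate Hz.
#' @param timeline list with `pre_s`, `task_s`, `post_s`, `baseline_s`.
#' @param group_mean_z named vector of target mean pairwise Fisher-z per group.
#' @param subject_z_sd named vector, between-subject SD of the participant
#'   mean Fisher-z per group.
#' @param pathway_effects data frame with columns `pair`, `group`, `z_offset`:
#'   additive Fisher-z offsets planted on specific ROI pairs. The per-group
#'   base level is renormalised so the group mean stays at `group_mean_z`.
#' @param dynamic_modulation list `amplitude` (Fisher-z units; per-participant
#'   pair amplitudes are drawn uniformly in +/-50% of this) and `period_s`.
#' @param noise list of amplitudes (concentration units for the sinusoids,
#'   optical density for `white_od`) and nuisance frequencies.
#' @param artifact_rate list `spikes_per_min`, `shifts_per_min`.
#' @param clinical_link data frame `feature_id`, `score`, `r`: planted
#'   Spearman correlations, clinical group only. Feature ids use the feature
#'   table labels (`"static|<pair>"` or `"PC<k>|<pair>"`); scores are
#'   anchored by Gaussian copula on the corresponding feature computed from
#'   the noise-free latent ROI traces.
#' @param clinical_means list of `c(mean, sd)` per score and group;
#'   see defaults in the function body.
#' @param low_snr_channels channels whose baseline is generated noisy enough
#'   to fail a 40-dB SNR screen (default the six peripheral channels).
#' @param latent_amp SD of the functional hemoglobin latent (mM).
#' @param hemo_ratios list `functional` (HbR/HbO ratio of the functional
#'   component, negative) and `systemic` (positive).
#' @param baseline_snr_db target baseline SNR for good channels (dB);
#'   `low_snr_db` for the channels listed in `low_snr_channels`.
#' @param montage a `montage` object (default [build_montage()]).
#' @param seed integer master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_per_group = c(MDD = 80L, HC = 80L),
                              sampling_rate = 10,
                              timeline = list(pre_s = 30, task_s = 60,
                                              post_s = 60, baseline_s = 10),
                              group_mean_z = c(HC = 0.39, MDD = 0.32),
                              subject_z_sd = c(HC = 0.07, MDD = 0.11),
                              pathway_effects = default_pathway_effects(),
                              dynamic_modulation = list(amplitude = 0.15,
                                                        period_s = 60),
                              noise = list(cardiac = 5e-4, respiratory = 3e-4,
                                           mayer = 3e-4, white_od = 2e-3,
                                           cardiac_hz = 1.0,
                                           respiratory_hz = 0.3,
                                           mayer_hz = 0.1),
                              artifact_rate = list(spikes_per_min = 0.5,
                                                   shifts_per_min = 0.2),
                              clinical_link = default_clinical_links(),
                              clinical_means = default_clinical_means(),
                              low_snr_channels = c(1L, 10L, 12L, 20L, 22L, 31L),
                              latent_amp = 1e-3,
                              hemo_ratios = list(functional = -0.6, systemic = 1),
                              baseline_snr_db = 50,
                              low_snr_db = 34,
                              montage = build_montage(),
                              seed = 1L) {
  rois <- roi_names()
  stopifnot(length(rois) == 6L)
  amps <- unlist(noise[c("cardiac", "respiratory", "mayer", "white_od")])
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  if (dynamic_modulation$amplitude < 0) stop("dynamic modulation amplitude must be >= 0")
  total_s <- timeline$pre_s + timeline$task_s + timeline$post_s
  if (total_s != 150) {
    warning("analysis period is ", total_s, " s, not the standard 150 s")
  }
  if (!all(c("MDD", "HC") %in% names(n_per_group))) {
    stop("n_per_group must be named with groups MDD and HC")
  }
  for (g in names(group_mean_z)) {
    off <- pathway_effects$z_offset[pathway_effects$group == g]
    base <- group_mean_z[[g]] - sum(off) / length(roi_pair_names())
    if (abs(tanh(base + max(c(0, off)) + 3 * subject_z_sd[[g]])) >= 1) {
      stop("group ", g, ": requested mean Fisher-z implies |r| >= 1")
    }
  }
  if (nrow(clinical_link) > 0 && any(abs(clinical_link$r) >= 1)) {
    stop("|target_spearman_r| must be < 1")
  }
  bad <- setdiff(pathway_effects$pair, roi_pair_names())
  if (length(bad) > 0) stop("unknown ROI pair(s) in pathway_effects: ",
                            paste(bad, collapse = ", "))
  if (nrow(clinical_link) > 0) {
    lp <- sub("^[^|]+\\|", "", clinical_link$feature_id)
    bad <- setdiff(lp, roi_pair_names())
    if (length(bad) > 0) stop("unknown ROI pair(s) in clinical_link: ",
                              paste(bad, collapse = ", "))
  }
  structure(
    list(
      n_per_group = n_per_group, sampling_rate = sampling_rate,
      timeline = timeline, roi_names = rois,
      group_mean_z = group_mean_z, subject_z_sd = subject_z_sd,
      pathway_effects = pathway_effects,
      dynamic_modulation = dynamic_modulation, noise = noise,
      artifact_rate = artifact_rate, clinical_link = clinical_link,
      clinical_means = clinical_means,
      low_snr_channels = as.integer(low_snr_channels),
      latent_amp = latent_amp, hemo_ratios = hemo_ratios,
      baseline_snr_db = baseline_snr_db, low_snr_db = low_snr_db,
      montage = montage, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default planted pathway offsets
#'
#' Additive Fisher-z offsets for the clinical group on the four pathways the
#' analysis is designed to detect: reduced coupling in DLPFC(R)~mPFC(R),
#' DLPFC(R)~TL(L) and DLPFC(L)~TL(L), increased coupling in DLPFC(L)~TL(R).
#'
#' @return data frame with columns `pair`, `group`, `z_offset`.
#' @export
default_pathway_effects <- function() {
  data.frame(
    pair = c("DLPFC(R)~mPFC(R)", "DLPFC(R)~TL(L)",
             "DLPFC(L)~TL(L)", "DLPFC(L)~TL(R)"),
    group = "MDD",
    z_offset = c(-0.10, -0.08, -0.08, 0.18),
    stringsAsFactors = FALSE
  )
}

#' Default planted clinical links
#'
#' Spearman targets tying clinical-group symptom scores to connectivity
#' features: depression and anxiety scores to the static DLPFC(R)~mPFC(R)
#' coupling (negative), the anhedonia score to the third principal component
#' of the window-wise DLPFC(L)~TL(L) coupling (negative).
#'
#' @return data frame with columns `feature_id`, `score`, `r`.
#' @export
default_clinical_links <- function() {
  data.frame(
    feature_id = c("static|DLPFC(R)~mPFC(R)", "static|DLPFC(R)~mPFC(R)",
                   "PC3|DLPFC(L)~TL(L)"),
    score = c("dass_d", "dass_a", "shaps"),
    r = c(-0.48, -0.51, -0.52),
    stringsAsFactors = FALSE
  )
}

#' Default clinical score marginals
#'
#' Mean/SD per score and group. Clinical-group values follow the instrument
#' summaries the generator is asked to emulate (DASS-D 16.12 +/- 1.93, DASS-A
#' 11.43 +/- 4.16, DASS-S 11.22 +/- 5.77, SHAPS 33.07 +/- 7.37); control
#' values sit in the healthy range (SHAPS 21.5 +/- 5.17 from published
#' healthy-student norms).
#'
#' @return nested list `[[group]][[score]] = c(mean, sd)`.
#' @export
default_clinical_means <- function() {
  list(
    MDD = list(dass_d = c(16.12, 1.93), dass_a = c(11.43, 4.16),
               dass_s = c(11.22, 5.77), shaps = c(33.07, 7.37)),
    HC = list(dass_d = c(3, 2), dass_a = c(2.5, 2),
              dass_s = c(4, 2.5), shaps = c(21.5, 5.17))
  )
}

# deterministic per-participant stream seed (kept below 2^31)
participant_seed <- function(master, index, stream = 0L) {
  (as.numeric(master) * 48271 + index * 16807 + stream * 69621) %% 2147483562 + 1
}

# group of global participant index: clinical group first, then controls
participant_group <- function(config, index) {
  if (index <= config$n_per_group[["MDD"]]) "MDD" else "HC"
}

# per-group base Fisher-z level, renormalised so the group mean over the 15
# pairs (including pathway offsets) equals the configured target
group_base_z <- function(config, group) {
  off <- config$pathway_effects$z_offset[config$pathway_effects$group == group]
  config$group_mean_z[[group]] - sum(off) / length(roi_pair_names())
}

# participant-level truth: pairwise Fisher-z targets, modulation amplitudes
# and phases. Deterministic in (config$seed, index).
participant_truth <- function(config, index) {
  group <- participant_group(config, index)
  pairs <- roi_pair_names(config$roi_names)
  set.seed(participant_seed(config$seed, index, 0L))
  u <- stats::rnorm(1, 0, config$subject_z_sd[[group]])
  z <- stats::setNames(rep(group_base_z(config, group) + u, length(pairs)), pairs)
  pe <- config$pathway_effects[config$pathway_effects$group == group, , drop = FALSE]
  if (nrow(pe) > 0) z[pe$pair] <- z[pe$pair] + pe$z_offset
  amp <- config$dynamic_modulation$amplitude
  mod_amp <- stats::setNames(stats::runif(length(pairs), 0.5, 1.5) * amp, pairs)
  mod_phase <- stats::setNames(stats::runif(length(pairs), 0, 2 * pi), pairs)
  list(index = index, group = group, subject_shift = u, z = z,
       mod_amp = mod_amp, mod_phase = mod_phase)
}

# unit-variance Gaussian series with a flat spectrum on [low, high] Hz,
# synthesized in the frequency domain (exactly stationary, no edge effects)
band_limited_gauss <- function(n, rate, low, high, ncol) {
  half <- (n - 1L) %/% 2L
  f <- (1:half) * rate / n
  sel <- which(f >= low & f <= high)
  m <- matrix(0+0i, n, ncol)
  z <- matrix(stats::rnorm(length(sel) * ncol), length(sel), ncol) +
    1i * matrix(stats::rnorm(length(sel) * ncol), length(sel), ncol)
  m[1L + sel, ] <- z
  m[n + 1L - sel, ] <- Conj(z)
  x <- Re(stats::mvfft(m, inverse = TRUE))
  sweep(x, 2, apply(x, 2, stats::sd), `/`)
}

# symmetric correlation matrix from a named pair vector of Fisher-z values;
# ridged to positive definiteness if needed
pair_z_to_cor <- function(z, rois) {
  n <- length(rois)
  C <- diag(n)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      k <- k + 1L
      C[i, j] <- C[j, i] <- tanh(z[k])
    }
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    C <- C + diag(n) * (1e-6 - min(ev))
    C <- stats::cov2cor(C)
  }
  C
}

#' Generate the six latent ROI hemodynamic traces for one participant
#'
#' Band-limited (0.01-0.2 Hz) unit-variance Gaussian innovations are mixed
#' through a slowly time-varying correlation matrix built from the
#' participant's pairwise Fisher-z targets plus sinusoidal coupling
#' modulation, then scaled to the configured functional amplitude.
#'
#' @param config a `sim_config`.
#' @param participant_index global participant index (clinical group first).
#' @return list with `traces` (6 x T matrix, mM), `truth` (planted
#'   parameters), `group`.
#' @export
generate_roi_latents <- function(config, participant_index) {
  stopifnot(inherits(config, "sim_config"))
  truth <- participant_truth(config, participant_index)
  rate <- config$sampling_rate
  T_n <- round((config$timeline$pre_s + config$timeline$task_s +
                  config$timeline$post_s) * rate)
  pairs <- roi_pair_names(config$roi_names)

  set.seed(participant_seed(config$seed, participant_index, 1L))
  # stationary band-limited Gaussian innovations by spectral synthesis
  E <- t(band_limited_gauss(T_n, rate, 0.01, 0.2, 6L))

  tt <- (seq_len(T_n) - 1) / rate
  period <- config$dynamic_modulation$period_s
  block <- 10L  # samples per correlation update (1 s at 10 Hz)
  Y <- matrix(0, 6L, T_n)
  starts <- seq(1L, T_n, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, T_n)
    tm <- mean(tt[idx])
    z_t <- truth$z + truth$mod_amp * sin(2 * pi * tm / period + truth$mod_phase)
    L <- t(chol(pair_z_to_cor(z_t, config$roi_names)))
    Y[, idx] <- L %*% E[, idx, drop = FALSE]
  }
  rownames(Y) <- config$roi_names
  list(traces = Y * config$latent_amp, truth = truth, group = truth$group)
}

#' Project ROI latents onto montage channels and synthesize a raw recording
#'
#' Each channel carries its ROI's functional hemoglobin latent plus a
#' channel-specific systemic component (cardiac, respiratory and Mayer-wave
#' sinusoids with jittered frequency and random phase). Oxy/deoxy traces
#' follow the two-compartment ratios (`functional`, `systemic`), are pushed
#' through the forward Beer-Lambert model to dual-wavelength optical density,
#' and corrupted with white measurement noise plus spike and baseline-shift
#' motion artifacts; an artifact-free 10-s baseline intensity segment is
#' prepended for quality control.
#'
#' @param latents output of [generate_roi_latents()].
#' @param config a `sim_config`.
#' @param participant_index global participant index.
#' @return An object of class `fnirs_recording`: list with `id`, `group`,
#'   `intensity` (list of time x channel matrices named by wavelength),
#'   `sampling_rate`, `baseline_n`, `wavelengths`, `artifact_log`, `truth`.
#' @export
project_to_channels <- function(latents, config, participant_index) {
  stopifnot(inherits(config, "sim_config"))
  montage <- config$montage
  ch <- montage$channels$channel
  n_ch <- length(ch)
  roi_of <- montage$roi_map[as.character(ch)]
  if (any(is.na(roi_of)) || !all(roi_of %in% config$roi_names)) {
    stop("montage channel without a valid ROI assignment")
  }
  rate <- config$sampling_rate
  T_n <- ncol(latents$traces)
  tt <- (seq_len(T_n) - 1) / rate
  set.seed(participant_seed(config$seed, participant_index, 2L))

  nz <- config$noise
  freqs <- c(nz$cardiac_hz, nz$respiratory_hz, nz$mayer_hz) *
    stats::runif(3, 0.95, 1.05)
  amps <- c(nz$cardiac, nz$respiratory, nz$mayer)
  # systemic fluctuations are global physiology: one waveform per component
  # and participant, scaled by a channel-specific gain
  s_common <- numeric(T_n)
  for (k in 1:3) {
    if (amps[k] <= 0) next
    s_common <- s_common + amps[k] * sin(2 * pi * freqs[k] * tt +
                                           stats::runif(1, 0, 2 * pi))
  }
  gain <- stats::runif(n_ch, 0.5, 1.5)
  S <- outer(s_common, gain)
  Ff <- t(latents$traces[roi_of, , drop = FALSE])  # T x n_ch functional HbO
  kf <- config$hemo_ratios$functional
  ks <- config$hemo_ratios$systemic
  hbo <- Ff + S
  hbr <- kf * Ff + ks * S

  ext <- extinction_coefficients()
  dpf <- c(6, 6)
  d_cm <- montage$distance_cm
  wl <- rownames(ext)
  od <- list()
  artifact_log <- data.frame(channel = integer(0), sample = integer(0),
                             type = character(0), stringsAsFactors = FALSE)
  # artifact event schedule shared across wavelengths (motion moves the probe)
  minutes <- T_n / rate / 60
  n_spike <- stats::rpois(1, config$artifact_rate$spikes_per_min * minutes)
  n_shift <- stats::rpois(1, config$artifact_rate$shifts_per_min * minutes)
  spike_ch <- sample(n_ch, n_spike, replace = TRUE)
  spike_t <- sample(T_n, n_spike, replace = TRUE)
  spike_sgn <- sample(c(-1, 1), n_spike, replace = TRUE)
  shift_ch <- sample(n_ch, n_shift, replace = TRUE)
  shift_t <- sample(T_n, n_shift, replace = TRUE)
  shift_sgn <- sample(c(-1, 1), n_shift, replace = TRUE)

  for (w in wl) {
    e <- ext[w, ]
    m <- d_cm * dpf[match(w, wl)] * (e[["HbO"]] * hbo + e[["HbR"]] * hbr)
    m <- m + matrix(stats::rnorm(T_n * n_ch, 0, nz$white_od), T_n, n_ch)
    sds <- apply(m, 2, stats::sd)
    if (n_spike > 0) {
      for (a in seq_len(n_spike)) {
        m[spike_t[a], spike_ch[a]] <- m[spike_t[a], spike_ch[a]] +
          spike_sgn[a] * 8 * sds[spike_ch[a]]
      }
    }
    if (n_shift > 0) {
      for (a in seq_len(n_shift)) {
        idx <- shift_t[a]:T_n
        m[idx, shift_ch[a]] <- m[idx, shift_ch[a]] +
          shift_sgn[a] * 4 * sds[shift_ch[a]]
      }
    }
    od[[w]] <- m
  }
  if (n_spike > 0) {
    artifact_log <- rbind(artifact_log,
                          data.frame(channel = ch[spike_ch], sample = spike_t,
                                     type = "spike", stringsAsFactors = FALSE))
  }
  if (n_shift > 0) {
    artifact_log <- rbind(artifact_log,
                          data.frame(channel = ch[shift_ch], sample = shift_t,
                                     type = "shift", stringsAsFactors = FALSE))
  }

  base_n <- round(config$timeline$baseline_s * rate)
  i0 <- 1000 * stats::runif(n_ch, 0.8, 1.2)
  snr <- rep(config$baseline_snr_db, n_ch)
  snr[ch %in% config$low_snr_channels] <- config$low_snr_db
  base_sd <- i0 * 10^(-snr / 20)
  intensity <- list()
  for (w in wl) {
    base <- matrix(stats::rnorm(base_n * n_ch), base_n, n_ch)
    base <- sweep(sweep(base, 2, base_sd, `*`), 2, i0, `+`)
    task <- sweep(10^(-od[[w]]), 2, i0, `*`)
    intensity[[w]] <- rbind(base, task)
    colnames(intensity[[w]]) <- as.character(ch)
  }

  structure(
    list(
      id = sprintf("%s%03d", latents$group, participant_index),
      group = latents$group,
      intensity = intensity,
      sampling_rate = rate,
      baseline_n = base_n,
      wavelengths = as.numeric(wl),
      artifact_log = artifact_log,
      truth = latents$truth
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "fNIRS recording %s (%s): %d channels x %d samples at %g Hz (%d baseline), %d artifact(s)\n",
    x$id, x$group, ncol(x$intensity[[1]]), nrow(x$intensity[[1]]),
    x$sampling_rate, x$baseline_n, nrow(x$artifact_log)
  ))
  invisible(x)
}

# Spearman target -> Pearson correlation of the Gaussian copula
spearman_to_pearson <- function(r) 2 * sin(pi * r / 6)

score_range <- function(score) {
  switch(score, dass_d = , dass_a = , dass_s = c(0, 21), shaps = c(0, 42),
         stop("unknown score: ", score))
}

#' Generate the per-participant clinical table
#'
#' Demographics follow the configured cohort structure (ages 12-18, balanced
#' sex, school years); symptom scores are drawn from per-group marginals
#' and, for the clinical group, tied to the named connectivity feature
#' through a Gaussian copula on the feature ranks, so a stated Spearman
#' correlation is achieved in expectation. Antidepressant exposure (clinical
#' group only) is sampled from the five drugs of the fluoxetine-equivalence
#' table with plausible doses.
#'
#' @param config a `sim_config`.
#' @param planted_features participants x features numeric matrix whose
#'   column names include every `clinical_link$feature_id` and whose row
#'   names are participant ids; may be `NULL` when the config plants no
#'   links (ids are then derived from the configured group sizes).
#' @param groups group label per row; default parsed from the row names.
#' @return data frame of class `clinical_table`.
#' @export
generate_clinical <- function(config, planted_features = NULL, groups = NULL) {
  stopifnot(inherits(config, "sim_config"))
  links <- config$clinical_link
  if (nrow(links) > 0) {
    if (any(abs(links$r) >= 1)) stop("|target_spearman_r| must be < 1")
    if (is.null(planted_features)) {
      stop("planted_features required when clinical links are configured")
    }
    missing_f <- setdiff(links$feature_id, colnames(planted_features))
    if (length(missing_f) > 0) {
      stop("clinical_link feature id(s) not among the feature labels: ",
           paste(missing_f, collapse = ", "))
    }
  }
  if (is.null(planted_features)) {
    ids <- c(sprintf("MDD%03d", seq_len(config$n_per_group[["MDD"]])),
             sprintf("HC%03d", config$n_per_group[["MDD"]] +
                       seq_len(config$n_per_group[["HC"]])))
    n <- length(ids)
  } else {
    n <- nrow(planted_features)
    ids <- rownames(planted_features)
  }
  if (is.null(groups)) groups <- sub("[0-9]+$", "", ids)
  stopifnot(all(groups %in% c("MDD", "HC")))
  set.seed(participant_seed(config$seed, 0L, 3L))
  age <- pmin(18, pmax(12, stats::rnorm(n, 15.5, 1.7)))
  sex <- ifelse(stats::runif(n) < 0.45, "male", "female")
  education <- round(pmin(12, pmax(5, stats::rnorm(n, 8.6, 1.7))))
  duration <- ifelse(groups == "MDD",
                     round(pmax(1, stats::rlnorm(n, log(10), 0.6))), 0)
  drugs <- names(fluoxetine_equivalence_table())
  dose_range <- list(fluoxetine = c(20, 60), sertraline = c(50, 150),
                     paroxetine = c(20, 40), clomipramine = c(75, 150),
                     venlafaxine = c(75, 225))
  medication <- rep(NA_character_, n)
  dose <- rep(0, n)
  mdd_idx <- which(groups == "MDD")
  medication[mdd_idx] <- sample(drugs, length(mdd_idx), replace = TRUE)
  for (i in mdd_idx) {
    rng <- dose_range[[medication[i]]]
    dose[i] <- round(stats::runif(1, rng[1], rng[2]) / 25) * 25
    if (dose[i] < rng[1]) dose[i] <- rng[1]
  }

  scores <- c("dass_d", "dass_a", "dass_s", "shaps")
  out <- data.frame(
    id = ids, group = groups, age = round(age, 1), sex = sex,
    education = education, duration_months = duration,
    medication = medication, dose_mg_day = dose, stringsAsFactors = FALSE
  )
  for (sc in scores) out[[sc]] <- NA_real_

  for (g in c("MDD", "HC")) {
    gi <- which(groups == g)
    if (length(gi) == 0) next
    for (sc in scores) {
      ms <- config$clinical_means[[g]][[sc]]
      lk <- if (g == "MDD") links[links$score == sc, , drop = FALSE] else
        links[0, , drop = FALSE]
      if (nrow(lk) >= 1) {
        # Gaussian copula on the feature ranks: exact Spearman control
        f <- planted_features[gi, lk$feature_id[1]]
        fz <- stats::qnorm(rank(f, ties.method = "average") / (length(f) + 1))
        fz <- fz / stats::sd(fz)
        rg <- spearman_to_pearson(lk$r[1])
        lat <- rg * fz + sqrt(1 - rg^2) * stats::rnorm(length(gi))
      } else {
        lat <- stats::rnorm(length(gi))
      }
      rng <- score_range(sc)
      out[[sc]][gi] <- pmin(rng[2], pmax(rng[1], round(ms[1] + ms[2] * lat)))
    }
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_roi_latents()] and [project_to_channels()] for every
#' participant (clinical group first, then controls) and attaches the
#' clinical table and the planted truth. Identical `config` (including seed)
#' reproduces the cohort bit for bit.
#'
#' Planted clinical links emulate the observed phenotype-symptom
#' correlations of the study design, which are correlations between
#' *measured* connectivity features and scores; by default the copula is
#' therefore anchored on the features the standard extraction computes from
#' the generated recordings (`anchor = "measured"`). `anchor = "latent"`
#' anchors on features of the noise-free latent ROI traces instead, in which
#' case downstream recovery is attenuated by the measurement chain.
#'
#' @param config a `sim_config`.
#' @param keep_latents keep the noise-free ROI latents in the output (used by
#'   diagnostics; default `FALSE` to save memory).
#' @param anchor `"measured"` (default) or `"latent"`; ignored when no
#'   clinical links are configured.
#' @return Object of class `synthetic_cohort`: list with `recordings`,
#'   `clinical`, `truth` (per-participant planted parameters),
#'   `anchor_features` (the copula anchor matrix, `NULL` without links),
#'   `montage`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), keep_latents = FALSE,
                            anchor = c("measured", "latent")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$n_per_group)
  recordings <- vector("list", n)
  truths <- vector("list", n)
  roi_list <- vector("list", n)
  for (i in seq_len(n)) {
    lat <- generate_roi_latents(config, i)
    recordings[[i]] <- project_to_channels(lat, config, i)
    truths[[i]] <- lat$truth
    roi_list[[i]] <- structure(
      list(traces = lat$traces, roi_order = config$roi_names,
           sampling_rate = config$sampling_rate,
           id = recordings[[i]]$id, group = lat$group),
      class = "roi_timeseries")
  }
  anchor_feat <- NULL
  if (nrow(config$clinical_link) > 0) {
    anchor_feat <- if (anchor == "measured") {
      extract_cohort_features(recordings, config$montage,
                              n_components = 6L)$features
    } else {
      build_features(roi_list, n_components = 6L)$features
    }
  }
  clinical <- generate_clinical(config, anchor_feat)
  structure(
    list(recordings = recordings, clinical = clinical, truth = truths,
         anchor_features = anchor_feat,
         latents = if (keep_latents) lapply(roi_list, `[[`, "traces"),
         montage = config$montage, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(vapply(x$recordings, function(r) r$group, character(1)))
  cat("Synthetic task-fNIRS cohort:",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  %d channels, %d samples at %g Hz (incl. %d baseline), seed %d\n",
              ncol(x$recordings[[1]]$intensity[[1]]),
              nrow(x$recordings[[1]]$intensity[[1]]),
              x$config$sampling_rate, x$recordings[[1]]$baseline_n,
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One intensity CSV per participant and wavelength (first column `time_s`,
#' remaining columns channels), plus `clinical.csv`, `truth.json` and
#' `montage.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    for (w in names(rec$intensity)) {
      m <- rec$intensity[[w]]
      tt <- (seq_len(nrow(m)) - 1) / rec$sampling_rate
      df <- data.frame(time_s = tt, m, check.names = FALSE)
      utils::write.csv(df, file.path(dir, sprintf("%s_%snm.csv", rec$id, w)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(cohort$truth, function(t) list(
      index = t$index, group = t$group, subject_shift = t$subject_shift,
      z = as.list(t$z), mod_amp = as.list(t$mod_amp),
      mod_phase = as.list(t$mod_phase))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_montage(cohort$montage, file.path(dir, "montage.json"))
  invisible(dir)
}
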