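#' Beat morphology description
#'
#' Parameterises one cardiac cycle as a sum of five Gaussian bumps — the P
#' wave, the Q, R and S deflections of the QRS complex, and the T wave —
#' plus a flat baseline shift over the ST segment (the interval between the
#' end of the QRS and the onset of the T wave). Defaults approximate a
#' normal adult beat at a heart rate of 75 bpm.
#'
#' @param wave_centers Named numeric, time offsets (s) of the five wave
#'   centres within the beat, strictly increasing in the order P, Q, R, S, T.
#' @param wave_amplitudes Named numeric, peak amplitudes (mV); Q and S are
#'   conventionally negative.
#' @param wave_widths Named numeric, Gaussian standard deviations (s), all
#'   positive.
#' @param pr_interval PR interval (s), kept for reference; must be positive.
#' @param st_offset Baseline shift (mV) applied over the ST window.
#' @param st_window Length-2 numeric, start and end (s) of the ST segment
#'   within the beat.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(wave_centers = c(P = 0.10, Q = 0.225, R = 0.25, S = 0.275, T = 0.45),
                            wave_amplitudes = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.20, T = 0.30),
                            wave_widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.045),
                            pr_interval = 0.15,
                            st_offset = 0,
                            st_window = c(0.30, 0.39)) {
  waves <- c("P", "Q", "R", "S", "T")
  wave_centers <- wave_centers[waves]
  wave_amplitudes <- wave_amplitudes[waves]
  wave_widths <- wave_widths[waves]
  if (anyNA(wave_centers) || anyNA(wave_amplitudes) || anyNA(wave_widths)) {
    stopf("wave parameters must be named with P, Q, R, S, T")
  }
  if (any(wave_widths <= 0)) stopf("wave_widths must be positive")
  if (any(diff(wave_centers) <= 0)) {
    stopf("wave_centers must be strictly increasing in the order P < Q < R < S < T")
  }
  if (pr_interval <= 0) stopf("pr_interval must be positive")
  structure(
    list(wave_centers = wave_centers, wave_amplitudes = wave_amplitudes,
         wave_widths = wave_widths, pr_interval = pr_interval,
         st_offset = st_offset, st_window = st_window),
    class = "beat_morphology"
  )
}

#' Standard 12-lead names
#' @return Character vector of the 12 standard clinical leads.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Per-lead wave projection
#'
#' A `[n_leads x 5]` matrix scaling each wave's amplitude per lead,
#' emulating how each lead views the heart's electrical axis from a
#' different direction. The default reproduces coarse textbook morphology:
#' dominant R in II and the lateral precordials, deep S in V1/V2, an
#' inverted complex in aVR.
#'
#' @param lead_names Ordered subset of [standard_leads()], at least 2.
#' @param weights Optional numeric matrix `[length(lead_names) x 5]` with
#'   columns P, Q, R, S, T; defaults to the built-in projection.
#' @return An object of class `lead_projection`.
#' @export
lead_projection <- function(lead_names = standard_leads(), weights = NULL) {
  if (length(lead_names) < 2) stopf("at least 2 leads are required")
  if (anyDuplicated(lead_names)) stopf("lead_names must be unique")
  unknown <- setdiff(lead_names, standard_leads())
  if (length(unknown) > 0) {
    stopf("unknown lead(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(weights)) {
    weights <- .default_projection[lead_names, , drop = FALSE]
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != length(lead_names) || ncol(weights) != 5) {
    stopf("weights must be [%d x 5]", length(lead_names))
  }
  rownames(weights) <- lead_names
  colnames(weights) <- c("P", "Q", "R", "S", "T")
  structure(list(weights = weights, lead_names = lead_names),
            class = "lead_projection")
}

# rows: 12 standard leads; columns: P Q R S T amplitude scalings
.default_projection <- local({
  m <- rbind(
    I   = c(0.5, 0.5, 0.6, 0.4, 0.5),
    II  = c(1.0, 1.0, 1.0, 1.0, 1.0),
    III = c(0.5, 0.6, 0.5, 0.6, 0.4),
    aVR = c(-0.8, -0.6, -0.8, -0.6, -0.7),
    aVL = c(0.3, 0.3, 0.3, 0.3, 0.3),
    aVF = c(0.7, 0.8, 0.7, 0.8, 0.7),
    V1  = c(0.3, 0.1, 0.2, 1.6, 0.3),
    V2  = c(0.3, 0.1, 0.4, 1.5, 0.5),
    V3  = c(0.5, 0.3, 0.7, 1.0, 0.6),
    V4  = c(0.7, 0.5, 1.1, 0.6, 0.6),
    V5  = c(0.6, 0.6, 1.2, 0.3, 0.5),
    V6  = c(0.5, 0.6, 1.0, 0.2, 0.4)
  )
  colnames(m) <- c("P", "Q", "R", "S", "T")
  m
})

#' Class-conditional morphology effect
#'
#' Describes how one fine-grained diagnostic class deforms the normal beat:
#' rhythm statistics (mean and SD of the RR interval), which leads carry the
#' deformation, multiplicative amplitude/width scalings per wave, an
#' additive ST-segment shift, and per-beat probabilities of ectopic (wide,
#' P-less, early) and dropped (P-only) beats.
#'
#' @param label2 Fine-grained class label (see [task2_classes()]).
#' @param rr_mean,rr_sd Mean and SD of the RR interval (s).
#' @param affected_leads Leads carrying the morphology deformation.
#' @param amp_scale,width_scale Named multiplicative factors over waves
#'   P, Q, R, S, T (unnamed waves default to 1).
#' @param st_delta Additive ST baseline shift (mV) on affected leads.
#' @param ectopic_rate,dropped_beat_rate Per-beat probabilities in `[0, 1]`.
#' @return An object of class `class_effect`.
#' @export
class_effect <- function(label2, rr_mean = 0.8, rr_sd = 0.02,
                         affected_leads = character(0),
                         amp_scale = numeric(0), width_scale = numeric(0),
                         st_delta = 0, ectopic_rate = 0,
                         dropped_beat_rate = 0) {
  if (!label2 %in% task2_classes()) stopf("unknown fine-grained label: %s", label2)
  if (rr_mean <= 0) stopf("rr_mean must be positive")
  if (rr_sd < 0) stopf("rr_sd must be nonnegative")
  for (r in c(ectopic_rate, dropped_beat_rate)) {
    if (r < 0 || r > 1) stopf("beat-event rates must lie in [0, 1]")
  }
  full <- function(x) {
    out <- c(P = 1, Q = 1, R = 1, S = 1, T = 1)
    out[names(x)] <- x
    out
  }
  structure(
    list(label2 = label2, rr_mean = rr_mean, rr_sd = rr_sd,
         affected_leads = affected_leads,
         amp_scale = full(amp_scale), width_scale = full(width_scale),
         st_delta = st_delta, ectopic_rate = ectopic_rate,
         dropped_beat_rate = dropped_beat_rate),
    class = "class_effect"
  )
}

#' Built-in class effects for all 15 fine-grained classes
#'
#' Textbook lead conventions: anterior infarction shifts the ST segment in
#' V1-V4, inferior in II/III/aVF, lateral in I/aVL/V5/V6; left ventricular
#' hypertrophy scales R in the lateral leads, right in V1/V2; atrial
#' hypertrophy widens (left), peaks (right) or does both to (biatrial) the
#' P wave. Rhythm classes act mainly through RR variability, ectopic or
#' dropped beats.
#'
#' @return Named list of [class_effect()] objects, one per fine class.
#' @export
default_class_effects <- function() {
  lat <- c("I", "aVL", "V5", "V6")
  inf <- c("II", "III", "aVF")
  list(
    N   = class_effect("N"),
    SA  = class_effect("SA", rr_mean = 0.8, rr_sd = 0.14),
    AA  = class_effect("AA", rr_sd = 0.06, ectopic_rate = 0.30,
                       affected_leads = standard_leads(),
                       amp_scale = c(P = 0.5)),
    JA  = class_effect("JA", rr_mean = 0.95,
                       affected_leads = standard_leads(),
                       amp_scale = c(P = -0.4)),
    VA  = class_effect("VA", ectopic_rate = 0.30),
    HB  = class_effect("HB", rr_mean = 1.05, dropped_beat_rate = 0.25),
    AMI = class_effect("AMI", affected_leads = c("V1", "V2", "V3", "V4"),
                       amp_scale = c(Q = 2.0), st_delta = 0.20),
    IMI = class_effect("IMI", affected_leads = inf,
                       amp_scale = c(Q = 2.0), st_delta = 0.20),
    LMI = class_effect("LMI", affected_leads = lat,
                       amp_scale = c(Q = 2.0), st_delta = 0.20),
    LVH = class_effect("LVH", affected_leads = c("V5", "V6", "I"),
                       amp_scale = c(R = 1.7, S = 1.3)),
    RVH = class_effect("RVH", affected_leads = c("V1", "V2"),
                       amp_scale = c(R = 2.2, T = -0.8)),
    BVH = class_effect("BVH", affected_leads = c("V1", "V2", "V5", "V6", "I"),
                       amp_scale = c(R = 1.5)),
    LAH = class_effect("LAH", affected_leads = c("I", "II", "V1"),
                       amp_scale = c(P = 1.3), width_scale = c(P = 1.9)),
    RAH = class_effect("RAH", affected_leads = inf,
                       amp_scale = c(P = 2.2)),
    BAH = class_effect("BAH", affected_leads = c(inf, "V1"),
                       amp_scale = c(P = 1.7), width_scale = c(P = 1.5))
  )
}

#' Render one single-lead beat
#'
#' The beat is the sum of five Gaussian bumps at the morphology's wave
#' centres plus the ST baseline shift over the ST window.
#'
#' @param morph A [beat_morphology()].
#' @param fs Sampling rate (Hz), positive.
#' @param rr Beat duration (s), positive; the waveform has
#'   `round(rr * fs)` samples.
#' @return Numeric vector of length `round(rr * fs)` (mV).
#' @examples
#' beat <- generate_beat(beat_morphology(), fs = 500, rr = 0.8)
#' length(beat) # 400
#' @export
generate_beat <- function(morph, fs, rr) {
  stopifnot(inherits(morph, "beat_morphology"))
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(rr, "rr")
  n <- round(rr * fs)
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (w in seq_along(morph$wave_centers)) {
    a <- morph$wave_amplitudes[[w]]
    if (a != 0) {
      y <- y + a * exp(-(t - morph$wave_centers[[w]])^2 /
                         (2 * morph$wave_widths[[w]]^2))
    }
  }
  if (morph$st_offset != 0) {
    win <- t >= morph$st_window[1] & t <= morph$st_window[2]
    y[win] <- y[win] + morph$st_offset
  }
  y
}

# Apply a class effect to the base morphology for one lead. Ectopic beats
# are wide, P-less and early; dropped beats keep only the P wave.
.lead_morphology <- function(base, projection_row, effect, lead,
                             ectopic = FALSE, dropped = FALSE) {
  amps <- base$wave_amplitudes * projection_row
  widths <- base$wave_widths
  st <- base$st_offset
  if (lead %in% effect$affected_leads) {
    amps <- amps * effect$amp_scale
    widths <- widths * effect$width_scale
    st <- st + effect$st_delta
  }
  if (ectopic) {
    amps[["P"]] <- 0
    amps[["R"]] <- amps[["R"]] * 1.3
    widths[["R"]] <- widths[["R"]] * 2.5
    widths[["S"]] <- widths[["S"]] * 2.0
  }
  if (dropped) {
    amps[c("Q", "R", "S", "T")] <- 0
    st <- 0
  }
  beat_morphology(wave_centers = base$wave_centers, wave_amplitudes = amps,
                  wave_widths = widths, pr_interval = base$pr_interval,
                  st_offset = st, st_window = base$st_window)
}

#' Generate one labelled multi-lead ECG record
#'
#' Simulates a beat train with class-conditional rhythm (RR mean/SD,
#' ectopic and dropped beats) and per-lead morphology (wave scalings and ST
#' shifts on the affected leads), projects it onto the requested leads, and
#' adds measurement noise: white Gaussian noise plus low-frequency
#' sinusoidal baseline wander (random phase per lead), with an optional
#' powerline component (off by default).
#'
#' @param label2 Fine-grained class label.
#' @param duration Record length (s); must be at least two mean RR
#'   intervals.
#' @param fs Sampling rate (Hz).
#' @param projection A [lead_projection()]; defaults to all 12 leads.
#' @param effect A [class_effect()] for `label2`; defaults to the built-in
#'   effect table.
#' @param morphology Base [beat_morphology()].
#' @param noise List with elements `white_sd` (mV, default 0.02),
#'   `wander_amp` (mV, default 0.05), `wander_freq` (Hz, default 0.25),
#'   `powerline_amp` (mV, default 0).
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical records.
#' @param record_id Identifier string.
#' @return An [ecg_record()].
#' @export
generate_record <- function(label2, duration = 10, fs = 500,
                            projection = lead_projection(),
                            effect = NULL,
                            morphology = beat_morphology(),
                            noise = list(), seed,
                            record_id = "rec00001") {
  if (!label2 %in% task2_classes()) stopf("unknown fine-grained label: %s", label2)
  assert_scalar_pos(duration, "duration")
  assert_scalar_pos(fs, "fs")
  if (missing(seed)) stopf("seed is required")
  effect <- effect %||% default_class_effects()[[label2]]
  stopifnot(inherits(effect, "class_effect"), effect$label2 == label2)
  if (duration < 2 * effect$rr_mean) {
    stopf("duration must be at least two mean RR intervals (%.2f s)",
          2 * effect$rr_mean)
  }
  noise <- utils::modifyList(
    list(white_sd = 0.02, wander_amp = 0.05, wander_freq = 0.25,
         powerline_amp = 0, powerline_freq = 50),
    noise
  )
  n_leads <- length(projection$lead_names)
  n_samples <- round(duration * fs)

  with_seed(seed, {
    # rhythm: draw beats until the train covers the record
    rr <- numeric(0)
    ectopic <- logical(0)
    dropped <- logical(0)
    total <- 0
    while (total < duration + effect$rr_mean) {
      e <- stats::runif(1) < effect$ectopic_rate
      d <- !e && stats::runif(1) < effect$dropped_beat_rate
      r <- max(0.3, stats::rnorm(1, effect$rr_mean, effect$rr_sd))
      if (e) r <- r * 0.75
      rr <- c(rr, r)
      ectopic <- c(ectopic, e)
      dropped <- c(dropped, d)
      total <- total + r
    }
    signal <- matrix(0, nrow = n_leads, ncol = n_samples,
                     dimnames = list(projection$lead_names, NULL))
    for (li in seq_len(n_leads)) {
      lead <- projection$lead_names[li]
      pos <- 0L
      trace <- numeric(n_samples)
      for (b in seq_along(rr)) {
        m <- .lead_morphology(morphology, projection$weights[li, ],
                              effect, lead, ectopic[b], dropped[b])
        beat <- generate_beat(m, fs, rr[b])
        idx <- pos + seq_along(beat)
        keep <- idx <= n_samples
        trace[idx[keep]] <- trace[idx[keep]] + beat[keep]
        pos <- pos + length(beat)
        if (pos >= n_samples) break
      }
      signal[li, ] <- trace
    }
    # noise, per lead
    t <- (seq_len(n_samples) - 1) / fs
    for (li in seq_len(n_leads)) {
      w <- if (noise$white_sd > 0) stats::rnorm(n_samples, 0, noise$white_sd) else 0
      bw <- if (noise$wander_amp > 0) {
        noise$wander_amp * sin(2 * pi * noise$wander_freq * t +
                                 stats::runif(1, 0, 2 * pi))
      } else 0
      pl <- if (noise$powerline_amp > 0) {
        noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t)
      } else 0
      signal[li, ] <- signal[li, ] + w + bw + pl
    }
    ecg_record(signal, fs = fs, lead_names = projection$lead_names,
               task1 = map_task2_to_task1(label2), task2 = label2,
               record_id = record_id)
  })
}

#' Prior class proportions of a large clinical 12-lead corpus
#'
#' Normal rhythm dominates at 61.10%, sinus arrhythmia and atrial
#' arrhythmia account for 18.14% and 7.72%, and the remaining 12 classes
#' share the residual 13.04% equally.
#'
#' @return Named 15-vector of priors summing to 1.
#' @export
clinical_priors <- function() {
  p <- stats::setNames(rep(0.1304 / 12, 15), task2_classes())
  p["N"] <- 0.6110
  p["SA"] <- 0.1814
  p["AA"] <- 0.0772
  p
}

#' Generate a labelled synthetic dataset
#'
#' Draws fine-grained labels from `class_priors` and one record per label.
#' Each record's seed is derived deterministically from the master seed and
#' the record index (documented linear congruential mix), so a dataset is
#' reproducible record-by-record and independent of generation order.
#'
#' @param n_records Number of records.
#' @param class_priors Named 15-vector of class probabilities summing to 1;
#'   defaults to [clinical_priors()].
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param lead_names Leads to synthesise; default all 12.
#' @param noise Noise parameters, see [generate_record()].
#' @param effects Named list of [class_effect()] overrides.
#' @param seed Master integer seed.
#' @return An [ecg_dataset()] whose manifest is a tibble with columns
#'   `record_id`, `task1`, `task2`, `seed`.
#' @export
generate_dataset <- function(n_records, class_priors = clinical_priors(),
                             duration = 10, fs = 500,
                             lead_names = standard_leads(),
                             noise = list(), effects = list(), seed) {
  if (missing(seed)) stopf("seed is required")
  if (n_records < 1) stopf("n_records must be at least 1")
  if (any(class_priors < 0)) stopf("class priors must be nonnegative")
  if (abs(sum(class_priors) - 1) > 1e-6) stopf("class priors must sum to 1")
  cls <- task2_classes()
  if (is.null(names(class_priors)) || !setequal(names(class_priors), cls)) {
    stopf("class_priors must be named with the 15 fine-grained classes")
  }
  class_priors <- class_priors[cls]
  projection <- lead_projection(lead_names)
  all_effects <- utils::modifyList(default_class_effects(), effects)

  labels <- with_seed(seed, sample(cls, n_records, replace = TRUE,
                                   prob = class_priors))
  seeds <- vapply(seq_len(n_records), function(i) derive_seed(seed, i),
                  numeric(1))
  ids <- sprintf("rec%05d", seq_len(n_records))
  records <- purrr::map(seq_len(n_records), function(i) {
    generate_record(labels[i], duration = duration, fs = fs,
                    projection = projection,
                    effect = all_effects[[labels[i]]],
                    noise = noise, seed = seeds[i], record_id = ids[i])
  })
  ecg_dataset(records, manifest = tibble::tibble(
    record_id = ids, task1 = map_task2_to_task1(labels), task2 = labels,
    seed = seeds
  ))
}
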