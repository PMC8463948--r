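# Synthetic slot-asynchronous 12-lead ECG generator.
#
# Signals are built from a 10 s beat train of P-QRS-T component time
# courses attached to a 3-component cardiac dipole, projected onto fixed
# per-lead direction vectors.  The limb-lead vectors satisfy Einthoven's
# law and the Goldberger relations by construction, so every projected
# record satisfies the identities to machine precision before noise.
# Positives receive an ST-segment deviation: a frontal-plane ST dipole
# (which keeps the limb-lead algebra exact and produces reciprocal
# depression in the leads opposing the territory) plus direct ST elevation
# on the territory's precordial leads.  This is textbook-style synthetic
# morphology for exercising the pipeline, not validated clinical realism.

lead_vectors <- function() {
  uI <- c(1, 0, 0)
  uII <- c(cos(pi / 3), sin(pi / 3), 0)
  rbind(
    I = uI, II = uII, III = uII - uI,
    aVR = -(uI + uII) / 2, aVL = uI - uII / 2, aVF = uII - uI / 2,
    V1 = c(-0.35, 0.05, 0.95), V2 = c(-0.10, 0.10, 1.00),
    V3 = c(0.30, 0.15, 0.85), V4 = c(0.65, 0.25, 0.60),
    V5 = c(0.90, 0.20, 0.30), V6 = c(1.00, 0.15, 0.05)
  )
}

TERRITORIES <- c("anterior", "inferior", "lateral")

territory_leads <- function(territory) {
  switch(territory,
         anterior = c("V1", "V2", "V3", "V4"),
         inferior = c("II", "III", "aVF"),
         lateral = c("I", "aVL", "V5", "V6"),
         stop("unknown territory: ", territory))
}

# Frontal-plane ST dipole per territory (scaled by st_shift at projection
# time) and the precordial leads receiving direct ST elevation.  The
# magnitudes are chosen so the territory's limb leads see exactly +st and
# the opposing limb leads the textbook half-magnitude reciprocal
# depression: (0, 2/sqrt(3)) projects to +1 on II, III and aVF and -1/2 on
# aVR and aVL; (1, -1/sqrt(3)) projects to +1 on I and aVL, 0 on II and
# -1/2 on aVF.
territory_st <- function(territory) {
  switch(territory,
         inferior = list(frontal = c(0, 2 / sqrt(3), 0),
                         precordial = character(0)),
         anterior = list(frontal = c(0, -1 / sqrt(3), 0),
                         precordial = c("V1", "V2", "V3", "V4")),
         lateral = list(frontal = c(1, -1 / sqrt(3), 0),
                        precordial = c("V5", "V6")),
         stop("unknown territory: ", territory))
}

#' Synthetic-data configuration
#'
#' Study conditions for the generator: record count, class prevalence
#' (default the 1.78% prevalence of the emulated training regime), heart
#' rate range, ST deviation magnitude for positives, territory mix, noise
#' level, and the 500 Hz pre-downsampling acquisition rate.
#'
#' @param n_records Number of records.
#' @param prevalence Fraction of positive (AMI) records; the positive
#'   count is exactly `round(prevalence * n_records)`.
#' @param heart_rate_range Heart rate range in bpm.
#' @param st_shift ST-segment deviation magnitude (mV) for positives.
#' @param territory_probs Named probabilities over anterior/inferior/
#'   lateral territories for positives.
#' @param noise_sd SD (mV) of additive Gaussian noise (applied after
#'   downsampling).
#' @param sampling_rate Acquisition rate in Hz before 2x decimation.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_records = 100L,
                         prevalence = 0.0178,
                         heart_rate_range = c(60, 100),
                         st_shift = 0.2,
                         territory_probs = c(anterior = 0.4,
                                             inferior = 0.35,
                                             lateral = 0.25),
                         noise_sd = 0.05,
                         sampling_rate = 500,
                         seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1, st_shift >= 0, noise_sd >= 0,
            sampling_rate > 0, length(heart_rate_range) == 2L)
  territory_probs <- territory_probs / sum(territory_probs)
  stopifnot(setequal(names(territory_probs), TERRITORIES))
  structure(list(
    n_records = as.integer(n_records), prevalence = prevalence,
    heart_rate_range = heart_rate_range, st_shift = st_shift,
    territory_probs = territory_probs[TERRITORIES], noise_sd = noise_sd,
    sampling_rate = sampling_rate, seed = as.integer(seed)
  ), class = "synth_config")
}

gauss_train <- function(t, onsets, center, sd, amp) {
  out <- numeric(length(t))
  for (o in onsets) {
    out <- out + amp * exp(-0.5 * ((t - o - center) / sd)^2)
  }
  out
}

# Waveform timing (seconds from beat onset); ST window sits between the
# end of the QRS complex and the onset of the T wave.
BEAT <- list(
  p = list(center = 0.10, sd = 0.020, amp = 0.12),
  q = list(center = 0.200, sd = 0.009, amp = -0.10),
  r = list(center = 0.220, sd = 0.012, amp = 1.10),
  s = list(center = 0.245, sd = 0.009, amp = -0.25),
  t = list(center = 0.400, sd = 0.050, amp = 0.35),
  st_window = c(0.255, 0.385),   # extent of the ST pulse
  st_measure = c(0.285, 0.355),  # interior plateau, clear of filter edges
  dirs = list(p = c(0.45, 0.60, 0.35), qrs = c(0.60, 0.70, 0.45),
              t = c(0.55, 0.60, 0.50))
)

#' Generate one synthetic 12-lead record
#'
#' Simulates 10 s at `sampling_rate` Hz, downsamples by 2 with
#' [signal::decimate()] (anti-aliased decimation) and assembles either a
#' report-style record (each lead trimmed to its 2.5 s slot, offsets
#' 0/2.5/5/7.5 s) or the full simultaneous record.  Base morphology (heart
#' rate, phase, amplitude) is drawn before any label-dependent quantity,
#' so the same RNG state yields the same underlying beats for a positive
#' and its negative counterpart.
#'
#' @param config A [synth_config()].
#' @param label 0 or 1.
#' @param territory Infarct territory for positives (`"anterior"`,
#'   `"inferior"` or `"lateral"`).
#' @param subject_id,record_id Identifiers.
#' @param layout `"report"` (asynchronous 2.5 s per lead) or
#'   `"simultaneous"` (full 10 s per lead).
#' @return An [ecg_record()] with attributes `territory`, `heart_rate` and
#'   `st_mask` (logical ST-window mask on the downsampled 10 s time base).
#' @export
generate_record <- function(config, label = 0L, territory = "anterior",
                            subject_id = "S1", record_id = "R1",
                            layout = c("report", "simultaneous")) {
  layout <- match.arg(layout)
  fs <- config$sampling_rate
  dur <- slot_layout()$total_duration
  n <- as.integer(round(fs * dur))
  t <- (seq_len(n) - 1) / fs

  hr <- stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
  period <- 60 / hr
  phase <- stats::runif(1, 0, period)
  amp_scale <- stats::runif(1, 0.9, 1.1)
  onsets <- seq(phase - period, dur + period, by = period)

  p_tc <- gauss_train(t, onsets, BEAT$p$center, BEAT$p$sd, BEAT$p$amp)
  qrs_tc <- gauss_train(t, onsets, BEAT$q$center, BEAT$q$sd, BEAT$q$amp) +
    gauss_train(t, onsets, BEAT$r$center, BEAT$r$sd, BEAT$r$amp) +
    gauss_train(t, onsets, BEAT$s$center, BEAT$s$sd, BEAT$s$amp)
  t_tc <- gauss_train(t, onsets, BEAT$t$center, BEAT$t$sd, BEAT$t$amp)
  st_tc <- numeric(n)
  for (o in onsets) {
    st_tc[t >= o + BEAT$st_window[1] & t <= o + BEAT$st_window[2]] <- 1
  }

  U <- lead_vectors()
  M <- cbind(
    p = amp_scale * (U %*% BEAT$dirs$p),
    qrs = amp_scale * (U %*% BEAT$dirs$qrs),
    t = amp_scale * (U %*% BEAT$dirs$t),
    st = numeric(12)
  )
  if (label == 1L && config$st_shift > 0) {
    ts <- territory_st(territory)
    M[, "st"] <- config$st_shift * (U %*% ts$frontal)
    M[rownames(U) %in% ts$precordial, "st"] <-
      M[rownames(U) %in% ts$precordial, "st"] + config$st_shift
  }

  # 2x anti-aliased decimation of the component time courses; projection
  # is linear, so decimating components and projecting afterwards equals
  # decimating every lead (and keeps the limb-lead identities exact)
  comp <- rbind(
    p = signal::decimate(p_tc, 2),
    qrs = signal::decimate(qrs_tc, 2),
    t = signal::decimate(t_tc, 2),
    st = signal::decimate(st_tc, 2)
  )
  signals <- M %*% comp                       # 12 x n250
  fs_out <- fs / 2
  n_out <- ncol(signals)
  if (config$noise_sd > 0) {
    signals <- signals + matrix(stats::rnorm(length(signals),
                                             sd = config$noise_sd),
                                nrow(signals))
  }
  st_mask <- numeric(n_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  for (o in onsets) {
    st_mask[t_out >= o + BEAT$st_measure[1] &
              t_out <= o + BEAT$st_measure[2]] <- 1
  }

  layout_def <- slot_layout()
  seg_len <- as.integer(round(2.5 * fs_out))
  sig_list <- list()
  offsets <- numeric(0)
  for (lead in lead_order()) {
    slot <- layout_def$slot_of[lead]
    if (layout == "report") {
      start <- as.integer(round(layout_def$offsets[slot] * fs_out))
      sig_list[[lead]] <- signals[lead, (start + 1L):(start + seg_len)]
      offsets[lead] <- layout_def$offsets[slot]
    } else {
      sig_list[[lead]] <- signals[lead, ]
      offsets[lead] <- 0
    }
  }
  rec <- ecg_record(sig_list, sampling_rate = fs_out, lead_offsets = offsets,
                    label = label, subject_id = subject_id,
                    record_id = record_id)
  attr(rec, "territory") <- if (label == 1L) territory else NA_character_
  attr(rec, "heart_rate") <- hr
  attr(rec, "st_mask") <- as.logical(st_mask)
  rec
}

#' Generate a synthetic dataset
#'
#' Exactly `round(prevalence * n_records)` positives; positive territories
#' are drawn from `territory_probs`; one subject per record.  All
#' randomness flows from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param layout Passed to [generate_record()].
#' @return List of [ecg_record()]s.
#' @export
generate_dataset <- function(config, layout = "report") {
  set.seed(config$seed)
  n <- config$n_records
  n_pos <- round(config$prevalence * n)
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L
  territories <- sample(TERRITORIES, n, replace = TRUE,
                        prob = config$territory_probs)
  lapply(seq_len(n), function(i) {
    generate_record(config, label = labels[i], territory = territories[i],
                    subject_id = sprintf("S%05d", i),
                    record_id = sprintf("R%05d", i), layout = layout)
  })
}

#' Generate a synthetic visit/diagnosis/ECG table set
#'
#' Emits tidy tables exercising every cohort rule: a controllable number
#' of I21/I22-coded visits, of which some have a null code-registration
#' time and some a registration beyond 24 h of the ECG; a controllable
#' number of under-20 patients; all other ECGs within 24 h of the visit.
#' Times are numeric hours.
#'
#' @param n_visits Number of visits (one patient each).
#' @param n_ami Number of visits coded I21/I22.
#' @param n_null_registration Of the AMI visits, how many have a null
#'   registration time (excluded by rule).
#' @param n_out_of_window Of the AMI visits, how many have the code
#'   registered more than 24 h from the ECG (excluded by rule).
#' @param n_under20 Number of visits from patients aged under 20.
#' @param ecgs_per_visit ECGs recorded per visit.
#' @param seed Integer seed.
#' @return List with data frames `visits`, `diagnoses`, `ecgs` (the input
#'   contract of [label_and_filter()]).
#' @export
generate_visit_table <- function(n_visits = 100L, n_ami = 10L,
                                 n_null_registration = 0L,
                                 n_out_of_window = 0L,
                                 n_under20 = 0L,
                                 ecgs_per_visit = 1L, seed = 1L) {
  stopifnot(n_ami <= n_visits,
            n_null_registration + n_out_of_window <= n_ami,
            n_under20 <= n_visits - n_ami)
  set.seed(seed)
  visit_id <- sprintf("V%04d", seq_len(n_visits))
  ami <- seq_len(n_ami)
  null_reg <- ami[seq_len(n_null_registration)]
  oow <- ami[n_null_registration + seq_len(n_out_of_window)]
  under20 <- if (n_under20 > 0) n_ami + seq_len(n_under20) else integer(0)
  age <- sample(20:90, n_visits, replace = TRUE)
  age[under20] <- sample(1:19, n_under20, replace = TRUE)
  visits <- data.frame(
    visit_id = visit_id,
    subject_id = sprintf("P%04d", seq_len(n_visits)),
    visit_time = round(stats::runif(n_visits, 0, 1000), 2),
    age = age
  )
  ecgs <- data.frame(
    ecg_id = sprintf("E%05d", seq_len(n_visits * ecgs_per_visit)),
    visit_id = rep(visit_id, each = ecgs_per_visit),
    ecg_time = rep(visits$visit_time, each = ecgs_per_visit) +
      round(stats::runif(n_visits * ecgs_per_visit, 0, 20), 2)
  )
  first_ecg <- ecgs$ecg_time[match(visit_id, ecgs$visit_id)]
  codes <- list()
  for (i in seq_len(n_visits)) {
    if (i %in% ami) {
      code <- sample(c("I21.0", "I21.4", "I22", "I22.1"), 1L)
      reg <- if (i %in% null_reg) NA_real_
             else if (i %in% oow) first_ecg[i] + 30
             else first_ecg[i] + round(stats::runif(1, -10, 10), 2)
      codes[[length(codes) + 1L]] <- data.frame(
        visit_id = visit_id[i], code = code, registration_time = reg)
    }
    # background non-AMI diagnoses on some visits
    if (stats::runif(1) < 0.3) {
      codes[[length(codes) + 1L]] <- data.frame(
        visit_id = visit_id[i],
        code = sample(c("I50", "R07.4", "J18.9", "I20.0"), 1L),
        registration_time = visits$visit_time[i] + 1)
    }
  }
  list(visits = visits, diagnoses = do.call(rbind, codes), ecgs = ecgs)
}
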