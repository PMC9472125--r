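# Synthetic simultaneous EEG + fNIRS n-back sessions.
#
# The generator reproduces the protocol structure of the working-memory
# paradigm (per series: instruction, a task block of discrete stimuli, rest)
# and plants class-dependent signal signatures so that the workload labels
# are recoverable by the downstream pipeline: frontal theta power rises and
# parietal alpha power falls with n-back level in the EEG, and the fNIRS
# hemodynamic response amplitude grows with level. These signatures are
# modeling choices from the n-back literature, not measurements.

#' Experimental protocol specification
#'
#' Defaults describe one run of the n-back paradigm: 3 sessions, 3 series
#' per condition per session, each series being 2 s instruction + 40 s task
#' (20 stimuli of 2 s) + 20 s rest, for conditions 0-back, 2-back, 3-back.
#'
#' @slot nSessions,seriesPerCondition,stimuliPerSeries counts (>= 1).
#' @slot stimulusDuration,instructionDuration,restDuration seconds (> 0).
#' @slot conditions ordered character vector of task conditions.
#' @export
setClass("ProtocolSpec", representation(
  nSessions = "integer", seriesPerCondition = "integer",
  stimuliPerSeries = "integer", stimulusDuration = "numeric",
  instructionDuration = "numeric", restDuration = "numeric",
  conditions = "character"
))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (any(c(object@nSessions, object@seriesPerCondition,
            object@stimuliPerSeries) < 1L))
    msg <- c(msg, "all counts must be >= 1")
  if (any(c(object@stimulusDuration, object@instructionDuration,
            object@restDuration) <= 0))
    msg <- c(msg, "all durations must be > 0")
  if (!all(object@conditions %in% setdiff(.CLASS_LABELS, "rest")))
    msg <- c(msg, "conditions must be drawn from 0-back, 2-back, 3-back")
  if (length(msg)) msg else TRUE
})

#' @param nSessions,seriesPerCondition,stimuliPerSeries protocol counts.
#' @param stimulusDuration,instructionDuration,restDuration durations (s).
#' @param conditions task conditions.
#' @return a [ProtocolSpec-class].
#' @rdname ProtocolSpec-class
#' @export
ProtocolSpec <- function(nSessions = 3, seriesPerCondition = 3,
                         stimuliPerSeries = 20, stimulusDuration = 2,
                         instructionDuration = 2, restDuration = 20,
                         conditions = c("0-back", "2-back", "3-back")) {
  new("ProtocolSpec", nSessions = as.integer(nSessions),
      seriesPerCondition = as.integer(seriesPerCondition),
      stimuliPerSeries = as.integer(stimuliPerSeries),
      stimulusDuration = stimulusDuration,
      instructionDuration = instructionDuration,
      restDuration = restDuration, conditions = conditions)
}

#' Task-block duration of one series (s)
#' @param spec a [ProtocolSpec-class]
#' @export
taskDuration <- function(spec) spec@stimuliPerSeries * spec@stimulusDuration

#' Total duration of one series (s)
#' @param spec a [ProtocolSpec-class]
#' @export
seriesDuration <- function(spec)
  spec@instructionDuration + taskDuration(spec) + spec@restDuration

#' Number of stimulus trials per condition over the whole run
#' @param spec a [ProtocolSpec-class]
#' @export
trialsPerCondition <- function(spec)
  spec@nSessions * spec@seriesPerCondition * spec@stimuliPerSeries

#' Synthetic subject profile
#'
#' @slot seed integer; fully determines the generated signals.
#' @slot eegChannels,fnirsSites channel counts.
#' @slot eegRate,fnirsRate sampling rates (Hz).
#' @slot effectSize dimensionless scaling of the class-dependent signal
#'   components; 0 removes all class information.
#' @slot noiseLevels named amplitudes: `pink` (uV), `line` (uV, 50 Hz),
#'   `cardiac` (~1.1 Hz), `respiration` (~0.25 Hz), `mayer` (~0.1 Hz, fNIRS,
#'   umol/L), `drift` (linear, per recording), `od_white` (OD units).
#' @slot wavelengths two fNIRS wavelengths (nm).
#' @slot dpf differential pathlength factor (per wavelength, recycled).
#' @slot distance source-detector separation (cm).
#' @export
setClass("SubjectProfile", representation(
  seed = "integer", eegChannels = "integer", fnirsSites = "integer",
  eegRate = "numeric", fnirsRate = "numeric", effectSize = "numeric",
  noiseLevels = "numeric", wavelengths = "numeric", dpf = "numeric",
  distance = "numeric"
))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (object@eegRate <= 0 || object@fnirsRate <= 0)
    msg <- c(msg, "rates must be positive")
  if (object@effectSize < 0)
    msg <- c(msg, "effectSize must be >= 0")
  if (length(object@wavelengths) != 2L)
    msg <- c(msg, "exactly two wavelengths are required")
  if (length(msg)) msg else TRUE
})

.DEFAULT_NOISE <- c(pink = 5, line = 1, cardiac = 0.5, respiration = 0.5,
                    mayer = 0.1, drift = 1, od_white = 2e-4)

#' @param seed RNG seed (integer).
#' @param eegChannels,fnirsSites,eegRate,fnirsRate acquisition geometry.
#' @param effectSize class-effect scaling.
#' @param noiseLevels named amplitude overrides (see slots).
#' @param wavelengths,dpf,distance fNIRS optics.
#' @return a [SubjectProfile-class].
#' @rdname SubjectProfile-class
#' @export
SubjectProfile <- function(seed = 1L, eegChannels = 30, fnirsSites = 16,
                           eegRate = 1000, fnirsRate = 10.4, effectSize = 1,
                           noiseLevels = NULL, wavelengths = c(760, 850),
                           dpf = 6, distance = 3) {
  nl <- .DEFAULT_NOISE
  if (!is.null(noiseLevels)) nl[names(noiseLevels)] <- noiseLevels
  new("SubjectProfile", seed = as.integer(seed),
      eegChannels = as.integer(eegChannels),
      fnirsSites = as.integer(fnirsSites), eegRate = eegRate,
      fnirsRate = fnirsRate, effectSize = effectSize, noiseLevels = nl,
      wavelengths = wavelengths, dpf = rep_len(dpf, 2L), distance = distance)
}

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build the event schedules for a synthetic run
#'
#' Produces one [EventSchedule-class] per series, with onsets continuous
#' across the whole run (sessions back to back). Within each session the
#' order of the `conditions x seriesPerCondition` series is a seeded
#' permutation. Each series carries exactly three events: instruction, the
#' task block (labeled with its condition) and rest.
#'
#' @param spec a [ProtocolSpec-class].
#' @param seed integer seed for the series-order permutation.
#' @return list of [EventSchedule-class], one per series.
#' @examples
#' sch <- buildSchedule(ProtocolSpec(), seed = 1)
#' length(sch)                                  # 27 series
#' sum(events(sch[[1]])$duration)               # 62 s
#' @export
buildSchedule <- function(spec, seed = 1L) {
  validObject(spec)
  .with_seed(seed, {
    out <- list()
    t0 <- 0
    sid <- 0L
    for (s in seq_len(spec@nSessions)) {
      conds <- rep(spec@conditions, each = spec@seriesPerCondition)
      conds <- conds[sample.int(length(conds))]
      for (cond in conds) {
        sid <- sid + 1L
        on <- c(t0,
                t0 + spec@instructionDuration,
                t0 + spec@instructionDuration + taskDuration(spec))
        du <- c(spec@instructionDuration, taskDuration(spec),
                spec@restDuration)
        out[[sid]] <- EventSchedule(on, du, c("instruction", cond, "rest"),
                                    sessionId = s, seriesId = sid)
        t0 <- t0 + seriesDuration(spec)
      }
    }
    out
  })
}

.nback_level <- function(label)
  c("0-back" = 1, "2-back" = 2, "3-back" = 3, rest = 0)[label]

# boxcar over [on, off) seconds with 1 s raised-cosine ramps
.envelope <- function(t, on, off, ramp = 1) {
  e <- numeric(length(t))
  inside <- t >= on & t < off
  e[inside] <- 1
  r1 <- t >= on & t < on + ramp
  e[r1] <- 0.5 * (1 - cos(pi * (t[r1] - on) / ramp))
  r2 <- t >= off - ramp & t < off
  e[r2] <- 0.5 * (1 - cos(pi * (off - t[r2]) / ramp))
  e
}

# pink (1/f amplitude) noise via spectral shaping
.pink_noise <- function(n) {
  nf <- n %/% 2L + 1L
  amp <- c(0, 1 / sqrt(seq_len(nf - 1L)))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(nf - 1L + n %% 2L)])))[1:n]
  x <- Re(stats::fft(full, inverse = TRUE)) / sqrt(n)
  x / stats::sd(x)
}

.run_duration <- function(schedules) {
  max(vapply(schedules, function(s) {
    ev <- events(s); max(ev$onset + ev$duration)
  }, numeric(1)))
}

#' Simulate the EEG stream of a synthetic run
#'
#' Generates a 30-channel (by default) EEG recording covering all series of
#' `schedules`. During task blocks, theta (6 Hz) amplitude on the frontal
#' third of the channels scales up and alpha (10 Hz) amplitude on the
#' parietal third scales down monotonically with n-back level times
#' `effectSize`; pink noise, 50 Hz line noise, cardiac and respiratory
#' components and a linear drift are added on every channel. Identical
#' `(schedules, profile)` give bit-identical output.
#'
#' @param schedules list of [EventSchedule-class] from [buildSchedule()].
#' @param profile a [SubjectProfile-class].
#' @return list with `recording` (modality `"eeg"`) and `truth`
#'   (`data.frame` of labeled task/rest intervals).
#' @export
simulateEEG <- function(schedules, profile) {
  validObject(profile)
  fmax <- max(50 * (profile@noiseLevels["line"] > 0), 11)
  if (profile@eegRate < 2 * fmax)
    stop("eegRate ", profile@eegRate, " Hz is below the Nyquist rate ",
         "for the configured components (need >= ", 2 * fmax, " Hz)")
  dur <- .run_duration(schedules)
  n <- floor(dur * profile@eegRate)
  t <- (0:(n - 1)) / profile@eegRate
  C <- profile@eegChannels
  nl <- profile@noiseLevels
  frontal <- seq_len(max(1L, C %/% 3L))
  parietal <- (C - max(1L, C %/% 3L) + 1L):C

  ev <- do.call(rbind, lapply(schedules, events))
  task <- ev[ev$label %in% setdiff(.CLASS_LABELS, "rest"), , drop = FALSE]

  .with_seed(profile@seed, {
    theta_mod <- numeric(n)
    alpha_mod <- numeric(n)
    for (i in seq_len(nrow(task))) {
      lev <- .nback_level(task$label[i])
      e <- .envelope(t, task$onset[i], task$onset[i] + task$duration[i])
      theta_mod <- theta_mod + lev * e
      alpha_mod <- alpha_mod + lev * e
    }
    # class information is carried by the theta:alpha power ratio within
    # each channel (both rhythms are present everywhere): recurrence plots
    # of z-scored windows are scale-invariant, so a pure amplitude change
    # would be invisible — only the mixture ratio (waveform shape) survives.
    # Rhythms and physiological artifacts are shared source time courses
    # mixed into every channel (scalp channels are strongly correlated),
    # with independent pink noise per channel.
    # frontal-midline theta also speeds up slightly with workload: a
    # frequency code that survives normalization and thresholding
    th_gain <- 1 + 0.5 * profile@effectSize * theta_mod
    al_gain <- exp(-0.3 * profile@effectSize * alpha_mod)
    th_freq <- pmin(5.5 + 0.15 * profile@effectSize * theta_mod, 7.5)
    th_phase <- 2 * pi * cumsum(th_freq) / profile@eegRate
    theta_src <- sin(th_phase + stats::runif(1, 0, 2 * pi))
    alpha_src <- sin(2 * pi * 9 * t + stats::runif(1, 0, 2 * pi))
    line_src <- sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    cardiac_src <- sin(2 * pi * 1.1 * t + stats::runif(1, 0, 2 * pi))
    resp_src <- sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
    pink_src1 <- .pink_noise(n)            # shared broadband background
    pink_src2 <- .pink_noise(n)

    x <- matrix(0, C, n)
    for (ch in seq_len(C)) {
      base_th <- if (ch %in% frontal) 2 else if (ch %in% parietal) 0.5 else 1
      base_al <- if (ch %in% frontal) 0.5 else if (ch %in% parietal) 2 else 1
      mix <- stats::runif(5, 0.5, 1.5)     # per-channel source gains
      x[ch, ] <- nl["pink"] * (0.6 * mix[4] * pink_src1 +
                               0.6 * mix[5] * pink_src2 +
                               0.5 * .pink_noise(n)) +
        nl["line"] * mix[1] * line_src +
        nl["cardiac"] * mix[2] * cardiac_src +
        nl["respiration"] * mix[3] * resp_src +
        nl["drift"] * seq(-1, 1, length.out = n) +
        base_th * th_gain * theta_src +
        base_al * al_gain * alpha_src
    }
    rec <- Recording(x, rate = profile@eegRate,
                     channels = sprintf("EEG%02d", seq_len(C)),
                     modality = "eeg")
    list(recording = rec, truth = .truth_table(schedules))
  })
}

.truth_table <- function(schedules) {
  ev <- do.call(rbind, lapply(schedules, function(s) {
    e <- events(s)
    e$session <- s@sessionId; e$series <- s@seriesId
    e
  }))
  ev <- ev[ev$label != "instruction", , drop = FALSE]
  data.frame(start = ev$onset, end = ev$onset + ev$duration,
             class = ev$label, session = ev$session, series = ev$series,
             stringsAsFactors = FALSE)
}

# tabulated molar extinction coefficients, L / (mol cm)
.EXTINCTION <- rbind(
  "690" = c(hbo = 276,    hbr = 2051.96),
  "760" = c(hbo = 586,    hbr = 1548.52),
  "780" = c(hbo = 710,    hbr = 1075.44),
  "808" = c(hbo = 866,    hbr = 723.52),
  "830" = c(hbo = 974,    hbr = 693.04),
  "850" = c(hbo = 1058,   hbr = 691.32)
)

#' Molar extinction coefficients for HbO/HbR
#'
#' Returns the 2 x 2 extinction matrix (rows: wavelengths, columns:
#' HbO, HbR) in L/(umol cm) for a pair of wavelengths from the bundled table.
#'
#' @param wavelengths numeric length-2 (nm).
#' @return 2 x 2 matrix in umol^-1 L cm^-1.
#' @export
extinctionMatrix <- function(wavelengths = c(760, 850)) {
  key <- as.character(round(wavelengths))
  miss <- setdiff(key, rownames(.EXTINCTION))
  if (length(miss))
    stop("no extinction entry for wavelength(s) ", paste(miss, collapse = ", "),
         " nm; available: ", paste(rownames(.EXTINCTION), collapse = ", "))
  .EXTINCTION[key, , drop = FALSE] * 1e-6
}

# canonical double-gamma hemodynamic response, undershoot ~16 s; the
# time-to-peak is a parameter (response latency grows with workload)
.hrf <- function(t, peak = 6) {
  h <- stats::dgamma(t, shape = peak, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Simulate the fNIRS stream of a synthetic run
#'
#' Per site, a latent HbO concentration change is built as a class-amplitude
#' boxcar over each task block convolved with a double-gamma hemodynamic
#' response (peak ~6 s, undershoot ~16 s); HbR is -1/3 of HbO. Mayer waves,
#' respiration, cardiac pulsation and drift are added, and two-wavelength
#' optical densities are produced by the forward modified Beer-Lambert law.
#'
#' @param schedules list of [EventSchedule-class].
#' @param profile a [SubjectProfile-class].
#' @return list with `recording` (modality `"fnirs_od"`, channels ordered
#'   site-major with both wavelengths adjacent), `truth` (labeled intervals)
#'   and `hbo`, `hbr` (sites x samples ground-truth concentration changes,
#'   umol/L).
#' @export
simulateFNIRS <- function(schedules, profile) {
  validObject(profile)
  ext <- extinctionMatrix(profile@wavelengths)   # errors on unknown wavelength
  dur <- .run_duration(schedules)
  n <- floor(dur * profile@fnirsRate)
  t <- (0:(n - 1)) / profile@fnirsRate
  S <- profile@fnirsSites
  nl <- profile@noiseLevels

  ev <- do.call(rbind, lapply(schedules, events))
  task <- ev[ev$label %in% setdiff(.CLASS_LABELS, "rest"), , drop = FALSE]

  # Class signatures are waveform-coded so they survive the scale-invariant
  # recurrence-plot transform (a pure amplitude change would not): the
  # neural drive of a task block carries a slow effort-fluctuation
  # oscillation whose frequency grows with workload (0.05 Hz per n-back
  # level, inside the 0.2 Hz hemodynamic band), the response latency
  # (time-to-peak) grows with workload, and autonomic arousal scales the
  # Mayer-wave amplitude during task blocks. The response amplitude also
  # grows with level.
  tk <- seq(0, 30, by = 1 / profile@fnirsRate)
  S <- profile@fnirsSites

  .with_seed(profile@seed + 1L, {
    mayer_mod <- numeric(n)
    act <- numeric(n)
    for (i in seq_len(nrow(task))) {
      lev <- .nback_level(task$label[i])
      box <- as.numeric(t >= task$onset[i] &
                        t < task$onset[i] + task$duration[i])
      f_eff <- 0.05 * lev * stats::runif(1, 0.8, 1.2)
      drive <- box * (1 + 0.25 * sin(2 * pi * f_eff * (t - task$onset[i]) +
                                     stats::runif(1, 0, 2 * pi)))
      hk <- .hrf(tk, peak = 4 + lev)
      act <- act + 0.3 * lev * profile@effectSize *
        stats::convolve(drive, rev(hk), type = "open")[seq_len(n)] /
        profile@fnirsRate
      mayer_mod <- mayer_mod + 0.15 * profile@effectSize * lev^2 * box
    }
    gain <- stats::runif(S, 0.3, 1.2)       # site-specific responsiveness
    hbo <- matrix(0, S, n)
    hbr <- matrix(0, S, n)
    for (s in seq_len(S)) {
      osc <- nl["mayer"] * (1 + mayer_mod) *
        sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi)) +
        0.5 * nl["mayer"] * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
        0.25 * nl["mayer"] * sin(2 * pi * 1.1 * t + stats::runif(1, 0, 2 * pi)) +
        0.1 * nl["mayer"] * seq(-1, 1, length.out = n)
      hbo[s, ] <- gain[s] * act + osc
      hbr[s, ] <- -gain[s] * act / 3 - osc / 3
    }

    dpf <- profile@dpf
    d <- profile@distance
    x <- matrix(0, 2L * S, n)
    labs <- character(2L * S)
    wl <- numeric(2L * S)
    for (s in seq_len(S)) {
      for (w in 1:2) {
        i <- 2L * (s - 1L) + w
        x[i, ] <- d * dpf[w] * (ext[w, "hbo"] * hbo[s, ] +
                                ext[w, "hbr"] * hbr[s, ]) +
          nl["od_white"] * stats::rnorm(n)
        labs[i] <- sprintf("S%d-D%d:%g", s, s, profile@wavelengths[w])
        wl[i] <- profile@wavelengths[w]
      }
    }
    chinfo <- channelInfo(labs, role = "source-detector pair",
                          wavelength = wl, sourceDetectorDistance = d)
    rec <- Recording(x, rate = profile@fnirsRate, channels = chinfo,
                     modality = "fnirs_od")
    list(recording = rec, truth = .truth_table(schedules), hbo = hbo, hbr = hbr)
  })
}

#' Simulate one complete synthetic subject
#'
#' Convenience wrapper: builds the schedules and both modality streams.
#'
#' @param spec a [ProtocolSpec-class].
#' @param profile a [SubjectProfile-class].
#' @return list with `schedules`, `eeg`, `fnirs` (each as returned by the
#'   stream simulators) and `truth`.
#' @export
simulateSubject <- function(spec = ProtocolSpec(), profile = SubjectProfile()) {
  schedules <- buildSchedule(spec, seed = profile@seed)
  eeg <- simulateEEG(schedules, profile)
  fnirs <- simulateFNIRS(schedules, profile)
  list(schedules = schedules, eeg = eeg, fnirs = fnirs, truth = eeg$truth)
}
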