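#' Configuration for a synthetic extracellular recording
#'
#' Describes a multichannel recording with known ground truth: a set of
#' single units with gamma-distributed interspike intervals, band-limited
#' (300-3000 Hz) Gaussian/pink noise, and two artifact classes mirroring
#' what chronic in vivo recordings contain: coincident motion artifacts
#' (near-simultaneous deflections on >= 15 channels) and over-range
#' artifacts (single-channel deflections beyond +/-500 uV).
#'
#' @param n_channels number of channels (default 16, one probe).
#' @param fs sampling rate in Hz (default 24414, the acquisition rate).
#' @param duration_s recording length in seconds.
#' @param units data frame with one row per ground-truth unit and columns
#'   `channel`, `rate_hz` (mean firing rate), `amp_uV` (absolute negative
#'   peak amplitude) and `shape` (template shape id 1-3). `NULL` for none.
#' @param noise_sigma per-channel noise standard deviation in uV, before
#'   band-passing.
#' @param pink_fraction fraction of noise variance carried by a 1/f
#'   component, in `[0, 1]`.
#' @param artifact_rate_coincident events/s of motion artifacts.
#' @param artifact_rate_overrange events/s of over-range artifacts.
#' @param refractory_ms hard refractory period in ms (default 1.5).
#' @param seed integer seed; the same config and seed give bit-identical
#'   output.
#'
#' @return A list of class `recording_config`.
#' @seealso [gen_recording()], [default_recording_units()]
#' @export
recording_config <- function(n_channels = 16L,
                             fs = 24414,
                             duration_s = 10,
                             units = default_recording_units(),
                             noise_sigma = 12,
                             pink_fraction = 0.3,
                             artifact_rate_coincident = 0.2,
                             artifact_rate_overrange = 0.05,
                             refractory_ms = 1.5,
                             seed = 1L) {
  stop_if_not_scalar_num(n_channels, "n_channels", lower = 1)
  stop_if_not_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  stop_if_not_scalar_num(pink_fraction, "pink_fraction", lower = 0, upper = 1)
  stop_if_not_scalar_num(artifact_rate_coincident, "artifact_rate_coincident", lower = 0)
  stop_if_not_scalar_num(artifact_rate_overrange, "artifact_rate_overrange", lower = 0)
  stop_if_not_scalar_num(refractory_ms, "refractory_ms", lower = 0, strict_lower = TRUE)
  if (!is.null(units)) {
    units <- as.data.frame(units)
    need <- c("channel", "rate_hz", "amp_uV", "shape")
    if (!all(need %in% names(units)))
      stop("'units' needs columns: ", paste(need, collapse = ", "))
    if (any(units$amp_uV <= 0)) stop("unit amplitudes must be > 0")
    if (any(units$channel < 1 | units$channel > n_channels))
      stop("unit channels out of range")
    if (any(units$rate_hz >= 1000 / refractory_ms))
      stop("unit rate incompatible with the refractory period")
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration_s = duration_s,
    units = units, noise_sigma = noise_sigma, pink_fraction = pink_fraction,
    artifact_rate_coincident = artifact_rate_coincident,
    artifact_rate_overrange = artifact_rate_overrange,
    refractory_ms = refractory_ms, seed = as.integer(seed)),
    class = "recording_config")
}

#' Default ground-truth unit set
#'
#' Six units spread over a 16-channel probe with firing rates and
#' amplitudes in the range typically isolated from rat motor cortex
#' (4-12 Hz, 80-140 uV negative peaks).
#'
#' @return data frame usable as the `units` argument of
#'   [recording_config()].
#' @export
default_recording_units <- function() {
  data.frame(
    channel = c(1L, 3L, 5L, 8L, 11L, 14L),
    rate_hz = c(6, 9, 4, 12, 7, 5),
    amp_uV  = c(120, 90, 140, 80, 110, 100),
    shape   = c(1L, 2L, 3L, 1L, 2L, 3L)
  )
}

#' Canonical biphasic spike template
#'
#' Negative-leading biphasic waveform of 1.6 ms total duration, scaled so
#' the negative peak equals `-amp_uV`. Three shape ids vary the relative
#' size and width of the repolarisation lobe.
#'
#' @param fs sampling rate in Hz.
#' @param amp_uV absolute negative-peak amplitude in uV.
#' @param shape shape id in 1..3.
#' @return numeric vector of samples (uV).
#' @export
spike_template <- function(fs, amp_uV, shape = 1L) {
  stop_if_not_scalar_num(amp_uV, "amp_uV", lower = 0, strict_lower = TRUE)
  shape <- as.integer(shape)
  if (!shape %in% 1:3) stop("'shape' must be 1, 2 or 3")
  len <- max(3L, round(0.0016 * fs))
  t <- seq(0, 1, length.out = len)
  par <- switch(shape,
    `1` = c(t0 = 0.35, s1 = 0.11, t1 = 0.72, s2 = 0.22, a2 = 0.35),
    `2` = c(t0 = 0.30, s1 = 0.09, t1 = 0.65, s2 = 0.25, a2 = 0.45),
    `3` = c(t0 = 0.38, s1 = 0.13, t1 = 0.78, s2 = 0.20, a2 = 0.25))
  w <- -exp(-((t - par["t0"]) / par["s1"])^2) +
    par["a2"] * exp(-((t - par["t1"]) / par["s2"])^2)
  w * (amp_uV / abs(min(w)))
}

# 1/f ("pink") noise with unit variance, via spectral shaping.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  w <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # two-sided frequency index
  s <- 1 / sqrt(f)
  s[1] <- 0                          # no DC
  x <- Re(stats::fft(w * s, inverse = TRUE)) / n
  as.numeric(x / stats::sd(x))
}

# gamma(shape 2) interspike intervals with a hard refractory floor whose
# mean equals 1/rate; returns event times (s) within [0, duration).
gamma_spike_times <- function(rate_hz, duration_s, refractory_s) {
  mu <- 1 / rate_hz
  if (mu <= refractory_s)
    stop("firing rate incompatible with the refractory period")
  n_guess <- ceiling(duration_s * rate_hz * 2 + 20)
  times <- numeric(0)
  t_last <- stats::runif(1, 0, mu)   # random phase start
  repeat {
    isi <- refractory_s +
      stats::rgamma(n_guess, shape = 2, scale = (mu - refractory_s) / 2)
    times <- c(times, t_last + cumsum(isi))
    if (times[length(times)] >= duration_s) break
    t_last <- times[length(times)]
  }
  times[times < duration_s]
}

#' Generate a synthetic multichannel recording with ground truth
#'
#' Builds band-limited noise (Gaussian plus an optional 1/f component,
#' band-passed 300-3000 Hz with a zero-phase 4th-order Butterworth),
#' inserts spike templates at gamma-process times honouring the
#' refractory period, and adds the two artifact classes. Every inserted
#' event is listed exactly once in the returned ground truth.
#'
#' Coincident motion artifacts hit 15 or 16 of the channels within
#' +/-0.1 ms of a common centre with sub-over-range amplitudes
#' (250-400 uV), so they are removable only by the coincidence rule;
#' over-range artifacts are single-channel deflections of 550-900 uV.
#'
#' @param config a [recording_config()].
#' @return list with elements
#'   \describe{
#'     \item{block}{a [recording_block()] (channels x samples, uV).}
#'     \item{truth}{data frame of inserted events: `class`
#'       (`"spike"`, `"coincident"`, `"overrange"`), `unit` (id or `NA`),
#'       `channel`, `t_index` (sample of the negative peak, 1-based),
#'       `amp_uV` (signed peak).}
#'   }
#' @examples
#' r <- gen_recording(recording_config(duration_s = 1, seed = 7))
#' r$block
#' table(r$truth$class)
#' @export
gen_recording <- function(config) {
  stopifnot(inherits(config, "recording_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  tmpl_len <- max(3L, round(0.0016 * fs))
  if (n < tmpl_len)
    stop("duration too short to hold one spike template")
  nch <- config$n_channels
  refr_s <- config$refractory_ms / 1000

  with_seed(config$seed, {
    x <- matrix(0, nch, n)

    ## --- noise ---
    if (config$noise_sigma > 0) {
      pf <- config$pink_fraction
      for (ch in seq_len(nch)) {
        w <- stats::rnorm(n)
        z <- if (pf > 0) sqrt(1 - pf) * w + sqrt(pf) * pink_noise(n) else w
        x[ch, ] <- config$noise_sigma * z
      }
      bf <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
      for (ch in seq_len(nch))
        x[ch, ] <- signal::filtfilt(bf, x[ch, ])
    }

    truth <- list()

    ## --- units ---
    if (!is.null(config$units) && nrow(config$units) > 0) {
      for (u in seq_len(nrow(config$units))) {
        ui <- config$units[u, ]
        if (ui$rate_hz <= 0) next
        tmpl <- spike_template(fs, ui$amp_uV, ui$shape)
        peak_off <- which.min(tmpl)
        times <- gamma_spike_times(ui$rate_hz, config$duration_s, refr_s)
        idx <- round(times * fs) + 1L
        start <- idx - peak_off + 1L
        keep <- start >= 1L & (start + length(tmpl) - 1L) <= n
        idx <- idx[keep]; start <- start[keep]
        for (s in start) {
          sp <- s:(s + length(tmpl) - 1L)
          x[ui$channel, sp] <- x[ui$channel, sp] + tmpl
        }
        if (length(idx))
          truth[[length(truth) + 1L]] <- data.frame(
            class = "spike", unit = u, channel = ui$channel,
            t_index = idx, amp_uV = -ui$amp_uV)
      }
    }

    ## --- coincident motion artifacts ---
    ## One cycle of a 2.5 kHz wave packet (in-band), hitting 15 or 16
    ## channels with random but balanced polarity: the across-channel
    ## median stays near zero, so common-median referencing does not
    ## cancel the artifact and the >14-channel coincidence rule is what
    ## removes it. Each channel's negative trough falls within 0.2 ms of
    ## the others (opposite polarities are half a cycle apart).
    n_co <- stats::rpois(1, config$artifact_rate_coincident * config$duration_s)
    if (n_co > 0) {
      f_art <- 2500
      t_art <- seq(0, 1 / f_art, by = 1 / fs)
      taper <- sin(pi * t_art * f_art)^2          # smooth on/off
      m_art <- sin(2 * pi * f_art * t_art) * taper
      m_art <- m_art / max(abs(m_art))
      centers <- sort(stats::runif(n_co, 0.01, config$duration_s - 0.01))
      for (ci in seq_len(n_co)) {
        nhit <- min(sample(c(15L, 16L), 1), nch)
        chans <- sample(seq_len(nch), nhit)
        signs <- sample(rep(c(-1, 1), length.out = nhit))
        amps <- stats::runif(nhit, 250, 400)
        jit <- stats::runif(nhit, -2e-5, 2e-5)
        start <- round((centers[ci] + jit) * fs) + 1L
        keep <- start >= 1L & (start + length(m_art) - 1L) <= n
        chans <- chans[keep]; signs <- signs[keep]
        amps <- amps[keep]; start <- start[keep]
        peak_idx <- integer(length(chans))
        for (k in seq_along(chans)) {
          w <- signs[k] * amps[k] * m_art
          sp <- start[k]:(start[k] + length(w) - 1L)
          x[chans[k], sp] <- x[chans[k], sp] + w
          peak_idx[k] <- sp[which.min(w)]
        }
        if (length(chans))
          truth[[length(truth) + 1L]] <- data.frame(
            class = "coincident", unit = NA_integer_, channel = chans,
            t_index = peak_idx, amp_uV = -amps)
      }
    }

    ## --- over-range artifacts ---
    n_ov <- stats::rpois(1, config$artifact_rate_overrange * config$duration_s)
    if (n_ov > 0) {
      for (ci in seq_len(n_ov)) {
        ch <- sample(seq_len(nch), 1)
        amp <- stats::runif(1, 550, 900)
        tmpl <- spike_template(fs, amp, 1L)
        peak_off <- which.min(tmpl)
        idx <- round(stats::runif(1, 0.005, config$duration_s - 0.005) * fs) + 1L
        start <- idx - peak_off + 1L
        if (start >= 1L && (start + length(tmpl) - 1L) <= n) {
          sp <- start:(start + length(tmpl) - 1L)
          x[ch, sp] <- x[ch, sp] + tmpl
          truth[[length(truth) + 1L]] <- data.frame(
            class = "overrange", unit = NA_integer_, channel = ch,
            t_index = idx, amp_uV = -amp)
        }
      }
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(class = character(), unit = integer(), channel = integer(),
                 t_index = integer(), amp_uV = numeric())
    truth <- truth[order(truth$t_index, truth$channel), , drop = FALSE]
    rownames(truth) <- NULL

    list(block = recording_block(x, fs, filtered = TRUE), truth = truth)
  })
}
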