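#' Common median referencing
#'
#' Subtracts, at every sample, the across-channel median from every
#' channel. This cancels common-mode components (movement, mains pickup)
#' that appear simultaneously on all channels of a probe.
#'
#' @param block a [recording_block()] with at least 2 channels.
#' @return the referenced [recording_block()].
#' @export
common_median_reference <- function(block) {
  stopifnot(inherits(block, "recording_block"))
  if (nrow(block$samples) < 2L)
    stop("common median reference undefined for a single channel")
  med <- .col_median(block$samples)
  block$samples <- sweep(block$samples, 2L, med)
  block
}

#' Robust noise standard deviation of a voltage trace
#'
#' The median-absolute-deviation estimator `median(|x|) / 0.6745`,
#' consistent for the standard deviation of Gaussian noise and nearly
#' unaffected by the spikes riding on it. The trace is expected to be
#' zero-centred (referenced / mean-subtracted).
#'
#' @param trace numeric vector of voltages (uV).
#' @return estimated sigma in uV.
#' @export
estimate_sigma <- function(trace) {
  if (length(trace) == 0L) stop("empty trace")
  stats::median(abs(trace)) / 0.6745
}

#' Threshold spike detection
#'
#' Finds negative-going threshold crossings at `-k * sigma`: every
#' maximal run of consecutive samples at or below the threshold yields
#' one event at its most negative sample. Events closer than the lockout
#' are suppressed (earliest kept).
#'
#' @param trace numeric voltage vector (uV), zero-centred.
#' @param sigma noise sigma in uV (> 0), e.g. from [estimate_sigma()].
#' @param fs sampling rate in Hz.
#' @param k threshold multiplier (default 4).
#' @param lockout_ms minimum separation between events in ms (default 1).
#' @return data frame with columns `t_index` (1-based sample of the
#'   negative peak) and `peak_amp` (trace value there, uV).
#' @export
detect_spikes <- function(trace, sigma, fs, k = 4, lockout_ms = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be > 0")
  thr <- -k * sigma
  below <- which(trace <= thr)
  empty <- data.frame(t_index = integer(), peak_amp = numeric())
  if (length(below) == 0L) return(empty)
  seg <- cumsum(c(1L, diff(below) > 1L))
  peaks <- vapply(split(below, seg), function(ix) ix[which.min(trace[ix])], 1L)
  peaks <- unname(sort(peaks))
  lock <- max(1L, round(lockout_ms / 1000 * fs))
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= lock) { keep[i] <- TRUE; last <- peaks[i] }
  }
  data.frame(t_index = peaks[keep], peak_amp = trace[peaks[keep]])
}

#' Reject over-range events
#'
#' Removes events whose absolute peak amplitude exceeds the limit
#' (strictly greater than 500 uV by default); such deflections are
#' outside the physiological range of extracellular spikes.
#'
#' @param events data frame with a `peak_amp` column (uV).
#' @param limit_uV amplitude limit (default 500).
#' @return the surviving events.
#' @export
reject_overrange <- function(events, limit_uV = 500) {
  events[abs(events$peak_amp) <= limit_uV, , drop = FALSE]
}

#' Reject coincident (motion) artifacts
#'
#' Deflections detected near-simultaneously on many channels of a probe
#' are movement artifacts, not propagating spikes. Any event that falls
#' in a time window of total width `window_ms` containing events on more
#' than `max_channels` distinct channels is removed.
#'
#' @param events data frame with `channel` and `t_index` columns
#'   (pooled over channels).
#' @param fs sampling rate in Hz.
#' @param window_ms total coincidence window width in ms (default 0.5).
#' @param max_channels largest channel spread still accepted as neural
#'   (default 14; groups spanning more than this are removed).
#' @return the surviving events.
#' @export
reject_coincident <- function(events, fs, window_ms = 0.5, max_channels = 14) {
  if (nrow(events) == 0L) return(events)
  ord <- order(events$t_index)
  t <- events$t_index[ord]
  ch <- events$channel[ord]
  w <- round(window_ms / 1000 * fs)
  bad <- logical(length(t))
  j <- 1L
  for (i in seq_along(t)) {
    if (j < i) j <- i
    while (j < length(t) && t[j + 1L] - t[i] <= w) j <- j + 1L
    if (length(unique(ch[i:j])) > max_channels) bad[i:j] <- TRUE
  }
  keep <- ord[!bad]
  events[sort(keep), , drop = FALSE]
}

#' Extract peak-aligned waveform snippets
#'
#' Cuts a fixed window around every event, aligned so the detection peak
#' sits at the `pre_ms` mark. Events whose window does not fit inside
#' the trace are dropped.
#'
#' @param trace numeric voltage vector (uV).
#' @param events data frame with `t_index`.
#' @param fs sampling rate in Hz.
#' @param pre_ms window before the peak in ms (default 0.6).
#' @param post_ms window after the peak in ms (default 1.8).
#' @return list with `waveforms` (events x samples matrix) and `t_index`
#'   (events actually kept).
#' @export
extract_waveforms <- function(trace, events, fs, pre_ms = 0.6, post_ms = 1.8) {
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  idx <- events$t_index
  ok <- idx - pre >= 1L & idx + post <= length(trace)
  idx <- idx[ok]
  wf <- if (length(idx))
    t(vapply(idx, function(i) trace[(i - pre):(i + post)],
             numeric(pre + post + 1L)))
  else matrix(numeric(0), 0L, pre + post + 1L)
  list(waveforms = wf, t_index = idx, peak_sample = pre + 1L)
}

#' Cluster waveform snippets into single units
#'
#' Projects the snippets of one channel onto their first two principal
#' components and runs k-means for k = 1..`max_k`, choosing k by the
#' largest mean silhouette width. k = 1 is forced when fewer than
#' `min_snippets` snippets are available or when no k >= 2 reaches a
#' mean silhouette of `min_silhouette`. The clustering seed is fixed so
#' results are reproducible.
#'
#' @param waveforms snippets x samples matrix (uV) for one channel.
#' @param t_index event sample indices matching the rows.
#' @param channel channel id carried through to the units.
#' @param max_k maximum number of clusters scanned (default 5).
#' @param min_snippets below this, k is forced to 1 (default 8).
#' @param min_silhouette acceptance level for k >= 2 (default 0.5).
#' @param seed internal clustering seed (default 4242).
#' @return list of `sorted_unit` objects: each has `channel`,
#'   `spike_indices`, `mean_waveform`, `vpp` (max - min of the mean
#'   waveform, uV), `n_spikes`, `cluster_id`.
#' @export
cluster_units <- function(waveforms, t_index, channel = NA_integer_,
                          max_k = 5, min_snippets = 8, min_silhouette = 0.5,
                          seed = 4242L) {
  n <- nrow(waveforms)
  if (n == 0L) return(list())
  assign_k1 <- rep(1L, n)
  assignment <- assign_k1
  if (n >= min_snippets) {
    pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
    d <- min(2L, ncol(pc$x))
    proj <- pc$x[, seq_len(d), drop = FALSE]
    best_sil <- -Inf
    best_assign <- NULL
    dmat <- stats::dist(proj)
    for (k in 2:min(max_k, n - 1L)) {
      km <- with_seed(seed, stats::kmeans(proj, centers = k, nstart = 10,
                                          iter.max = 100))
      sil <- cluster::silhouette(km$cluster, dmat)
      msil <- mean(sil[, "sil_width"])
      if (msil > best_sil) { best_sil <- msil; best_assign <- km$cluster }
    }
    if (is.finite(best_sil) && best_sil >= min_silhouette)
      assignment <- best_assign
  }
  lapply(sort(unique(assignment)), function(cl) {
    rows <- assignment == cl
    mw <- colMeans(waveforms[rows, , drop = FALSE])
    structure(list(
      channel = channel,
      spike_indices = sort(t_index[rows]),
      mean_waveform = mw,
      vpp = max(mw) - min(mw),
      n_spikes = sum(rows),
      cluster_id = cl), class = "sorted_unit")
  })
}

#' Keep only putative single units
#'
#' Units whose mean-waveform peak-to-peak amplitude is below 40 uV are
#' considered non-putative and removed (the rule is strict "less than":
#' exactly 40 uV is kept).
#'
#' @param units list of `sorted_unit`s.
#' @param min_vpp_uV cutoff (default 40).
#' @return the surviving units.
#' @export
validate_units <- function(units, min_vpp_uV = 40) {
  Filter(function(u) u$vpp >= min_vpp_uV, units)
}

#' RMS noise after spike excision
#'
#' Root mean square of the trace with samples within
#' `+/- excision_ms / 2` of every detected spike removed, so large
#' transients do not inflate the noise floor.
#'
#' @param trace numeric voltage vector (uV), zero-centred.
#' @param spike_indices sample indices of all detected events.
#' @param fs sampling rate in Hz.
#' @param excision_ms total excision width per spike in ms (default 2.4).
#' @return noise RMS in uV.
#' @export
noise_rms <- function(trace, spike_indices, fs, excision_ms = 2.4) {
  if (length(trace) == 0L) stop("empty trace")
  keep <- rep(TRUE, length(trace))
  if (length(spike_indices)) {
    half <- round(excision_ms / 2 / 1000 * fs)
    for (i in spike_indices) {
      lo <- max(1L, i - half); hi <- min(length(trace), i + half)
      keep[lo:hi] <- FALSE
    }
  }
  if (!any(keep)) stop("all samples excised; no noise estimate possible")
  sqrt(mean(trace[keep]^2))
}

#' Spike rate from the median interspike interval
#'
#' `1 / median(ISI)`; robust to pauses and bursts compared with a plain
#' count rate. Undefined (NA) for fewer than two spikes.
#'
#' @param spike_indices sorted sample indices of one unit's spikes.
#' @param fs sampling rate in Hz.
#' @return rate in Hz, or `NA_real_` when fewer than 2 spikes.
#' @export
spike_rate <- function(spike_indices, fs) {
  if (length(spike_indices) < 2L) return(NA_real_)
  1 / stats::median(diff(sort(spike_indices)) / fs)
}

#' ROUT-style robust outlier removal
#'
#' Flags outliers in a sample by the Robust regression and OUTlier
#' removal recipe applied to a location fit: robust centre = median,
#' robust scale = the 68.27th percentile of the absolute residuals times
#' `N / (N - 1)` (the RSDR), residual p-values from the t distribution
#' with `N - 1` degrees of freedom, and a Benjamini-Hochberg-style pass
#' at false-discovery rate `Q` flagging the largest residuals first.
#' Fewer than 3 values are returned unfiltered.
#'
#' @param values numeric vector (e.g. unit SNRs).
#' @param Q false discovery rate in percent (default 5).
#' @return list with `kept`, `flagged` and the logical `is_outlier`.
#' @examples
#' rout_filter(c(4.9, 5, 5, 5.1, 25))$flagged
#' @export
rout_filter <- function(values, Q = 5) {
  n <- length(values)
  if (n < 3L)
    return(list(kept = values, flagged = values[0],
                is_outlier = rep(FALSE, n)))
  res <- values - stats::median(values)
  absr <- abs(res)
  rsdr <- stats::quantile(absr, 0.6827, names = FALSE) * n / (n - 1)
  p <- if (rsdr > 0) 2 * stats::pt(-absr / rsdr, df = n - 1)
       else ifelse(absr > 0, 0, 1)
  ord <- order(p)
  thresh <- (Q / 100) * seq_len(n) / n
  pass <- p[ord] <= thresh
  k <- if (any(pass)) max(which(pass)) else 0L
  is_out <- rep(FALSE, n)
  if (k > 0L) is_out[ord[seq_len(k)]] <- TRUE
  list(kept = values[!is_out], flagged = values[is_out], is_outlier = is_out)
}

#' Per-channel summary metrics
#'
#' Averages validated-unit properties at the channel level: mean Vpp,
#' spike-excised noise RMS, SNR (= mean Vpp / noise RMS) and the mean
#' spike rate over units with a defined rate. A channel is active when
#' it carries at least one validated unit.
#'
#' @param units list of validated `sorted_unit`s on this channel (possibly
#'   empty).
#' @param trace the channel's referenced voltage trace (uV).
#' @param fs sampling rate in Hz.
#' @param all_spike_indices every detected event on the channel (used
#'   for noise excision), not just unit spikes.
#' @param channel channel id for the output row.
#' @return one-row data frame: `channel`, `n_units`, `vpp_mean`,
#'   `noise_rms`, `snr`, `spike_rate`, `active`.
#' @export
channel_metrics <- function(units, trace, fs, all_spike_indices = NULL,
                            channel = NA_integer_) {
  all_spike_indices <- all_spike_indices %||%
    sort(unique(unlist(lapply(units, `[[`, "spike_indices"))))
  if (length(units) == 0L)
    return(data.frame(channel = channel, n_units = 0L, vpp_mean = NA_real_,
                      noise_rms = NA_real_, snr = NA_real_,
                      spike_rate = NA_real_, active = FALSE))
  nr <- noise_rms(trace, all_spike_indices, fs)
  vpps <- vapply(units, `[[`, 0, "vpp")
  rates <- vapply(units, function(u) spike_rate(u$spike_indices, fs), 0)
  data.frame(channel = channel, n_units = length(units),
             vpp_mean = mean(vpps), noise_rms = nr,
             snr = if (nr > 0) mean(vpps) / nr else NA_real_,
             spike_rate = if (any(!is.na(rates))) mean(rates, na.rm = TRUE)
                          else NA_real_,
             active = TRUE)
}

#' Full single-recording spike pipeline
#'
#' Runs the stage-1 chain in its fixed order: optional acquisition-style
#' band-pass (only when the block is flagged unfiltered), common median
#' reference, per-channel mean subtraction, robust-sigma threshold
#' detection, over-range rejection, cross-channel coincidence rejection,
#' waveform extraction, PCA/k-means unit isolation, Vpp validation, and
#' per-channel metrics. Optionally applies [rout_filter()] to the pooled
#' unit SNRs of this recording; leave it off when pooling units across
#' recordings first (then call [rout_filter()] on the pool).
#'
#' @param block a [recording_block()].
#' @param k detection threshold multiplier (default 4).
#' @param lockout_ms detection lockout (default 1).
#' @param overrange_uV over-range limit (default 500).
#' @param coincidence_window_ms coincidence window width (default 0.5).
#' @param coincidence_max_channels largest accepted channel spread
#'   (default 14).
#' @param min_vpp_uV unit validation cutoff (default 40).
#' @param q_rout ROUT false discovery rate in percent, or `NA` to skip
#'   the recording-level ROUT pass (default 5).
#' @return list with
#'   \describe{
#'     \item{spikes}{detected events surviving both artifact filters
#'       (`channel`, `t_index`, `peak_amp`).}
#'     \item{units}{data frame of validated units (`channel`,
#'       `cluster_id`, `n_spikes`, `vpp`, `snr`, `spike_rate`,
#'       `rout_outlier`).}
#'     \item{metrics}{per-channel [channel_metrics()] rows.}
#'     \item{unit_objects}{the `sorted_unit` list (with waveforms).}
#'   }
#' @export
ephys_pipeline <- function(block, k = 4, lockout_ms = 1, overrange_uV = 500,
                           coincidence_window_ms = 0.5,
                           coincidence_max_channels = 14,
                           min_vpp_uV = 40, q_rout = 5) {
  stopifnot(inherits(block, "recording_block"))
  fs <- block$fs
  if (!isTRUE(block$filtered)) {
    bf <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
    for (ch in seq_len(nrow(block$samples)))
      block$samples[ch, ] <- signal::filtfilt(bf, block$samples[ch, ])
    block$filtered <- TRUE
  }
  block <- common_median_reference(block)
  nch <- nrow(block$samples)
  centred <- block$samples - rowMeans(block$samples)

  ## detection per channel
  det <- lapply(seq_len(nch), function(ch) {
    tr <- centred[ch, ]
    sg <- estimate_sigma(tr)
    if (sg <= 0) return(data.frame(channel = integer(), t_index = integer(),
                                   peak_amp = numeric()))
    ev <- detect_spikes(tr, sg, fs, k = k, lockout_ms = lockout_ms)
    if (nrow(ev)) cbind(channel = ch, ev) else
      data.frame(channel = integer(), t_index = integer(),
                 peak_amp = numeric())
  })
  events_all <- do.call(rbind, det)
  events <- reject_overrange(events_all, overrange_uV)
  events <- reject_coincident(events, fs, coincidence_window_ms,
                              coincidence_max_channels)

  ## sorting + metrics per channel
  unit_objects <- list()
  metrics <- list()
  for (ch in seq_len(nch)) {
    tr <- centred[ch, ]
    ev_ch <- events[events$channel == ch, , drop = FALSE]
    all_idx <- events_all$t_index[events_all$channel == ch]
    units <- list()
    if (nrow(ev_ch)) {
      wf <- extract_waveforms(tr, ev_ch, fs)
      if (nrow(wf$waveforms)) {
        units <- cluster_units(wf$waveforms, wf$t_index, channel = ch)
        units <- validate_units(units, min_vpp_uV)
      }
    }
    metrics[[ch]] <- channel_metrics(units, tr, fs,
                                     all_spike_indices = all_idx,
                                     channel = ch)
    unit_objects <- c(unit_objects, units)
  }
  metrics <- do.call(rbind, metrics)

  units_df <- if (length(unit_objects)) {
    noise_by_ch <- metrics$noise_rms[match(
      vapply(unit_objects, `[[`, 0L, "channel"), metrics$channel)]
    data.frame(
      channel = vapply(unit_objects, `[[`, 0L, "channel"),
      cluster_id = vapply(unit_objects, `[[`, 0L, "cluster_id"),
      n_spikes = vapply(unit_objects, `[[`, 0L, "n_spikes"),
      vpp = vapply(unit_objects, `[[`, 0, "vpp"),
      snr = vapply(unit_objects, `[[`, 0, "vpp") / noise_by_ch,
      spike_rate = vapply(unit_objects,
                          function(u) spike_rate(u$spike_indices, fs), 0))
  } else {
    data.frame(channel = integer(), cluster_id = integer(),
               n_spikes = integer(), vpp = numeric(), snr = numeric(),
               spike_rate = numeric())
  }

  if (!is.na(q_rout) && nrow(units_df) >= 3L) {
    ro <- rout_filter(units_df$snr, Q = q_rout)
    units_df$rout_outlier <- ro$is_outlier
    keep <- !ro$is_outlier
    unit_objects <- unit_objects[keep]
    ## recompute channel-level summaries from surviving units
    for (ch in unique(units_df$channel)) {
      rows <- units_df$channel == ch & keep
      i <- which(metrics$channel == ch)
      if (!any(rows)) {
        metrics$n_units[i] <- 0L
        metrics$vpp_mean[i] <- metrics$snr[i] <- metrics$spike_rate[i] <- NA_real_
        metrics$active[i] <- FALSE
      } else {
        metrics$n_units[i] <- sum(rows)
        metrics$vpp_mean[i] <- mean(units_df$vpp[rows])
        metrics$snr[i] <- metrics$vpp_mean[i] / metrics$noise_rms[i]
        rts <- units_df$spike_rate[rows]
        metrics$spike_rate[i] <- if (any(!is.na(rts))) mean(rts, na.rm = TRUE)
                                 else NA_real_
      }
    }
    units_df <- units_df[keep, , drop = FALSE]
  } else {
    units_df$rout_outlier <- rep(FALSE, nrow(units_df))
  }
  rownames(units_df) <- NULL
  rownames(metrics) <- NULL

  list(spikes = events, units = units_df, metrics = metrics,
       unit_objects = unit_objects)
}
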