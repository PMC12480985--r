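# Small fixtures shared across test files; everything is generated in
# code so the suite carries no binary data.

# circular hole mask centred in an n x n image
disk_mask <- function(n, radius_px, center = (n + 1) / 2) {
  rw <- matrix(seq_len(n), n, n)
  (rw - center)^2 + (t(rw) - center)^2 <= radius_px^2
}

# a quiet recording with one known unit and no artifacts
quiet_recording <- function(rate_hz = 10, amp_uV = 120, duration_s = 5,
                            noise_sigma = 5, seed = 11) {
  recording_config(
    duration_s = duration_s,
    units = data.frame(channel = 3L, rate_hz = rate_hz, amp_uV = amp_uV,
                       shape = 1L),
    noise_sigma = noise_sigma,
    artifact_rate_coincident = 0, artifact_rate_overrange = 0,
    seed = seed)
}

# brute-force ring labelling: per-pixel minimum distance to any hole pixel
ring_labels_bruteforce <- function(hole_mask, mpp, bin_width = 50,
                                   max_dist = 650) {
  hp <- which(hole_mask, arr.ind = TRUE)
  n <- nrow(hole_mask); m <- ncol(hole_mask)
  out <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (hole_mask[i, j]) next
      d <- sqrt(min((hp[, 1] - i)^2 + (hp[, 2] - j)^2)) * mpp
      if (d < max_dist) out[i, j] <- as.integer(floor(d / bin_width))
    }
  }
  out
}
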