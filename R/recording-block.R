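#' Multichannel extracellular recording block
#'
#' Container for a block of multichannel voltage samples. Voltages are in
#' microvolts, stored as a channels x samples matrix. The `filtered`
#' attribute records whether the data have already passed the acquisition
#' band-pass (300-3000 Hz); the analysis pipeline only applies its own
#' band-pass when this is `FALSE`.
#'
#' @param samples numeric matrix, channels x samples, in uV.
#' @param fs sampling rate in Hz.
#' @param channel_ids optional channel labels; defaults to `1:nrow(samples)`.
#' @param filtered logical; `TRUE` if the block is already band-limited.
#'
#' @return An object of class `recording_block`: a list with elements
#'   `samples`, `fs`, `channel_ids`, `filtered`.
#' @examples
#' blk <- recording_block(matrix(rnorm(32), 2), fs = 1000)
#' blk
#' @export
recording_block <- function(samples, fs, channel_ids = NULL, filtered = TRUE) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (channels x samples)")
  if (any(!is.finite(samples)))
    stop("'samples' must be finite")
  stop_if_not_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  if (nrow(samples) < 1L) stop("need at least one channel")
  channel_ids <- channel_ids %||% seq_len(nrow(samples))
  if (length(channel_ids) != nrow(samples))
    stop("'channel_ids' length must match the number of channels")
  structure(
    list(samples = samples, fs = fs, channel_ids = channel_ids,
         filtered = isTRUE(filtered)),
    class = "recording_block"
  )
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf(
    "<recording_block> %d channels x %d samples @ %.3f kHz (%.2f s, %s)\n",
    nrow(x$samples), ncol(x$samples), x$fs / 1000,
    ncol(x$samples) / x$fs,
    if (x$filtered) "band-limited" else "unfiltered"))
  invisible(x)
}

n_samples <- function(block) ncol(block$samples)
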