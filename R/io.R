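#' Write and read a recording block
#'
#' Recordings are stored as little-endian float32 binary, sample-major
#' (all channels of sample 1, then all channels of sample 2, ...), with
#' a JSON sidecar holding `fs_hz`, `n_channels`, `units` ("uV"),
#' `duration_s` and `filtered`.
#'
#' @param block a [recording_block()].
#' @param bin_path path of the binary payload.
#' @param sidecar_path path of the JSON sidecar; defaults to
#'   `bin_path` with a `.json` extension.
#' @return `write_recording()` returns the paths invisibly;
#'   `read_recording()` returns a [recording_block()].
#' @export
write_recording <- function(block, bin_path,
                            sidecar_path = paste0(bin_path, ".json")) {
  stopifnot(inherits(block, "recording_block"))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(block$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(fs_hz = block$fs, n_channels = nrow(block$samples), units = "uV",
         duration_s = ncol(block$samples) / block$fs,
         filtered = isTRUE(block$filtered)),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin_path, sidecar = sidecar_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(bin_path,
                           sidecar_path = paste0(bin_path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("fs_hz", "n_channels"))
    if (is.null(meta[[field]]))
      stop(sprintf("sidecar %s is missing required field '%s'",
                   sidecar_path, field))
  n_bytes <- file.size(bin_path)
  n_vals <- n_bytes / 4L
  nch <- as.integer(meta$n_channels)
  if (n_vals %% nch != 0)
    stop(sprintf("binary size (%d floats) is not a multiple of n_channels (%d)",
                 n_vals, nch))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
  recording_block(matrix(x, nrow = nch), fs = meta$fs_hz,
                  filtered = isTRUE(meta$filtered %||% TRUE))
}

#' Write and read study tables (CSV)
#'
#' Plain CSV with the study-table columns (`arm`, `animal`, `channel`,
#' `week`, `active`, `n_units`, `dead_from_outset`). Reading tolerates
#' extra columns with a warning and preserves them; missing required
#' columns are an error naming the column.
#'
#' @param table a study table data frame.
#' @param path CSV path.
#' @return `read_study()` returns the study table.
#' @export
write_study <- function(table, path) {
  utils::write.csv(check_study_table(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("arm", "animal", "channel", "week", "active", "n_units",
            "dead_from_outset")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("study CSV missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tab), need)
  if (length(extra))
    warning("study CSV has extra column(s), preserved: ",
            paste(extra, collapse = ", "))
  tab$active <- as.logical(tab$active)
  tab$dead_from_outset <- as.logical(tab$dead_from_outset)
  tab
}

#' Write and read 16-bit grayscale images and 8-bit masks (TIFF)
#'
#' Images are written as 16-bit grayscale TIFF (intensities 0-65535);
#' masks as 8-bit TIFF holding 0/255.
#'
#' @param image numeric matrix with values in `[0, 65535]`.
#' @param mask logical matrix.
#' @param path TIFF path.
#' @return readers return the matrix; writers the path, invisibly.
#' @export
write_image16 <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 65535))
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image16
#' @export
read_image16 <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * 65535)
}

#' @rdname write_image16
#' @export
write_mask8 <- function(mask, path) {
  stopifnot(is.matrix(mask))
  tiff::writeTIFF((mask > 0) * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image16
#' @export
read_mask8 <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' Write and read centroid tables (CSV)
#'
#' Column format `x_px`, `y_px` (1-based pixel coordinates,
#' column/row), the exchange format for externally computed centroids
#' (e.g. from a trained segmentation model).
#'
#' @param centroids data frame with `x_px`, `y_px`.
#' @param path CSV path.
#' @return `read_centroids()` returns the data frame.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(all(c("x_px", "y_px") %in% names(centroids)))
  utils::write.csv(centroids, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  tab <- utils::read.csv(path)
  miss <- setdiff(c("x_px", "y_px"), names(tab))
  if (length(miss))
    stop("centroid CSV missing column(s): ", paste(miss, collapse = ", "))
  tab
}
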