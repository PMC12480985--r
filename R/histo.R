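#' Concentric-ring labels around an implant hole
#'
#' Assigns every pixel outside the hole to a 50 um-wide annulus by its
#' Euclidean distance to the nearest hole pixel (i.e. to the outer edge
#' of the implant hole), computed with an exact distance transform.
#' Bins are half-open: `[0,50), [50,100), ..., [600,650)`; pixels at or
#' beyond `max_dist_um` and pixels inside the hole are unlabeled (`NA`).
#' Bin indices are 0-based (bin 0 is the ring touching the hole).
#'
#' @param hole_mask logical matrix, `TRUE` inside the hole.
#' @param microns_per_pixel spatial scale in um/px.
#' @param bin_width_um ring width (default 50).
#' @param max_dist_um outer limit of the last ring (default 650).
#' @return integer matrix of bin indices (`NA` where unlabeled) with
#'   attributes `bin_width_um`, `max_dist_um`, `n_bins`,
#'   `microns_per_pixel`.
#' @export
ring_labels <- function(hole_mask, microns_per_pixel, bin_width_um = 50,
                        max_dist_um = 650) {
  stopifnot(is.matrix(hole_mask))
  hole_mask <- hole_mask > 0
  if (!any(hole_mask)) stop("empty hole mask")
  stop_if_not_scalar_num(microns_per_pixel, "microns_per_pixel", 0,
                         strict_lower = TRUE)
  nr <- nrow(hole_mask); nc <- ncol(hole_mask)
  if (any(hole_mask[1, ]) || any(hole_mask[nr, ]) ||
      any(hole_mask[, 1]) || any(hole_mask[, nc]))
    stop("implant hole touches the image border; rings would be truncated")
  m <- matrix(1, nr, nc)
  m[hole_mask] <- 0
  d_um <- as.matrix(EBImage::distmap(m)) * microns_per_pixel
  bins <- floor(d_um / bin_width_um)
  n_bins <- as.integer(max_dist_um / bin_width_um)
  bins[d_um >= max_dist_um | hole_mask] <- NA
  bins <- matrix(as.integer(bins), nr, nc)
  attr(bins, "bin_width_um") <- bin_width_um
  attr(bins, "max_dist_um") <- max_dist_um
  attr(bins, "n_bins") <- n_bins
  attr(bins, "microns_per_pixel") <- microns_per_pixel
  bins
}

ring_bin_edges <- function(labels) {
  w <- attr(labels, "bin_width_um")
  n <- attr(labels, "n_bins")
  data.frame(bin = 0:(n - 1), lo_um = w * (0:(n - 1)), hi_um = w * (1:n))
}

#' Mean marker intensity per ring
#'
#' Per-bin mean pixel intensity over labeled pixels, excluding pixels
#' under the artifact mask (tears, folds, debris). Bins with no usable
#' pixel are reported with `NA` mean and zero pixels.
#'
#' @param image numeric intensity matrix.
#' @param labels ring labels from [ring_labels()].
#' @param artifact_mask optional logical matrix, `TRUE` where excluded.
#' @return data frame (`ring_profile`): `bin`, `lo_um`, `hi_um`,
#'   `mean_raw`, `n_pixels`.
#' @export
bin_intensity <- function(image, labels, artifact_mask = NULL) {
  stopifnot(is.matrix(image), all(dim(image) == dim(labels)))
  use <- !is.na(labels)
  if (!is.null(artifact_mask)) {
    stopifnot(all(dim(artifact_mask) == dim(image)))
    use <- use & !(artifact_mask > 0)
  }
  prof <- ring_bin_edges(labels)
  lv <- factor(labels[use], levels = prof$bin)
  sums <- tapply(image[use], lv, sum)
  cnts <- tapply(rep(1L, sum(use)), lv, sum)
  prof$n_pixels <- ifelse(is.na(cnts), 0L, as.integer(cnts))
  prof$mean_raw <- ifelse(prof$n_pixels > 0, as.numeric(sums) / prof$n_pixels,
                          NA_real_)
  prof
}

#' Normalize a ring profile to the background bin
#'
#' Divides each bin mean by the background-bin mean (600-650 um by
#' default, tissue far enough from the implant to be healthy) and shifts
#' by the marker factor: `normalized = mean / mean_bg - (1 - f)`. With
#' `f = 1` (astrocyte marker, present in healthy tissue) the background
#' bin maps to 1; with `f = 0` (markers absent from healthy tissue:
#' activated microglia, serum IgG) it maps to 0.
#'
#' @param profile a `ring_profile` data frame from [bin_intensity()].
#' @param marker_factor 0 or 1.
#' @param background_bin bin index used as background (default: the
#'   last bin of the profile).
#' @return the profile with a `normalized` column.
#' @export
normalize_profile <- function(profile, marker_factor,
                              background_bin = max(profile$bin)) {
  stopifnot(marker_factor %in% c(0, 1))
  i <- match(background_bin, profile$bin)
  if (is.na(i)) stop("background bin not present in profile")
  bg <- profile$mean_raw[i]
  if (!is.finite(bg) || bg <= 0)
    stop("background-bin mean must be > 0")
  profile$normalized <- profile$mean_raw / bg - (1 - marker_factor)
  profile$marker_factor <- marker_factor
  profile
}

#' Detect cell centroids by Laplacian-of-Gaussian blob detection
#'
#' Deterministic stand-in for learned nuclei segmentation at the scale
#' of round, bright somata: the image is Gaussian-smoothed at the soma
#' scale, the negative discrete Laplacian of the smoothed image is the
#' blob response, and response local maxima above a robust threshold
#' (`median + threshold_k * MAD`) are reported as centroids. Centroids
#' inside the hole or artifact masks are suppressed. Externally
#' generated centroid tables (e.g. from a trained segmentation model)
#' can be used anywhere this function's output is accepted; see
#' [read_centroids()].
#'
#' @param image numeric intensity matrix.
#' @param microns_per_pixel spatial scale in um/px.
#' @param soma_radius_um typical soma radius (default 4).
#' @param hole_mask,artifact_mask optional logical exclusion masks.
#' @param threshold_k robust threshold multiplier (default 6).
#' @return data frame with `x_px` (column) and `y_px` (row), 1-based.
#' @export
detect_centroids <- function(image, microns_per_pixel, soma_radius_um = 4,
                             hole_mask = NULL, artifact_mask = NULL,
                             threshold_k = 6) {
  stopifnot(is.matrix(image))
  sigma_px <- max(1, (soma_radius_um / 2) / microns_per_pixel)
  ## fill masked regions (hole, artifacts) with the background median so
  ## their sharp edges do not ring through the blob filter
  excl <- NULL
  if (!is.null(hole_mask) || !is.null(artifact_mask)) {
    excl <- matrix(FALSE, nrow(image), ncol(image))
    if (!is.null(hole_mask)) excl <- excl | (hole_mask > 0)
    if (!is.null(artifact_mask)) excl <- excl | (artifact_mask > 0)
    if (any(excl)) image[excl] <- stats::median(image[!excl])
  }
  h <- ceiling(3 * sigma_px)
  g <- stats::dnorm(-h:h, sd = sigma_px)
  g <- g / sum(g)
  s <- .sep_conv2(image, g, g)
  n <- nrow(s); m <- ncol(s)
  ## negative discrete Laplacian of the smoothed image (LoG response,
  ## positive on bright blobs)
  lap <- matrix(0, n, m)
  lap[2:(n - 1), 2:(m - 1)] <-
    4 * s[2:(n - 1), 2:(m - 1)] -
    s[1:(n - 2), 2:(m - 1)] - s[3:n, 2:(m - 1)] -
    s[2:(n - 1), 1:(m - 2)] - s[2:(n - 1), 3:m]
  thr <- stats::median(lap) + threshold_k * stats::mad(lap)
  r <- max(1L, round(1.2 * sigma_px))
  pk <- .local_maxima(lap, r, thr)
  if (nrow(pk) && !is.null(excl))
    pk <- pk[!excl[pk], , drop = FALSE]
  data.frame(x_px = pk[, 2], y_px = pk[, 1])
}

#' Neuron density per ring
#'
#' Counts centroids per ring, divides by the usable ring area (labeled,
#' non-artifact pixels, converted to mm^2) and normalizes by the
#' background-bin density, which must contain at least one centroid.
#'
#' @param centroids data frame with `x_px`, `y_px` (1-based pixel
#'   coordinates, column/row).
#' @param labels ring labels from [ring_labels()].
#' @param artifact_mask optional logical matrix; its pixels are removed
#'   from the area denominator (and such centroids are not counted).
#' @param background_bin bin index used for normalization (default: the
#'   last ring).
#' @return data frame (`density_profile`): `bin`, `lo_um`, `hi_um`,
#'   `count`, `area_mm2`, `density` (per mm^2), `normalized`.
#' @export
density_profile <- function(centroids, labels, artifact_mask = NULL,
                            background_bin = NULL) {
  mpp <- attr(labels, "microns_per_pixel")
  prof <- ring_bin_edges(labels)
  background_bin <- background_bin %||% max(prof$bin)
  usable <- !is.na(labels)
  if (!is.null(artifact_mask)) usable <- usable & !(artifact_mask > 0)
  cnts <- tapply(rep(1L, sum(usable)), factor(labels[usable],
                                              levels = prof$bin), sum)
  prof$area_mm2 <- ifelse(is.na(cnts), 0, as.numeric(cnts)) * mpp^2 / 1e6
  prof$count <- 0L
  if (nrow(centroids)) {
    ij <- cbind(centroids$y_px, centroids$x_px)
    ok <- ij[, 1] >= 1 & ij[, 1] <= nrow(labels) &
      ij[, 2] >= 1 & ij[, 2] <= ncol(labels)
    ij <- ij[ok, , drop = FALSE]
    inside <- usable[ij]
    b <- labels[ij[inside, , drop = FALSE]]
    tb <- table(factor(b, levels = prof$bin))
    prof$count <- as.integer(tb)
  }
  prof$density <- ifelse(prof$area_mm2 > 0, prof$count / prof$area_mm2,
                         NA_real_)
  i <- match(background_bin, prof$bin)
  if (is.na(i) || prof$count[i] < 1)
    stop("background bin contains no centroids; cannot normalize")
  prof$normalized <- prof$density / prof$density[i]
  prof
}

#' Detect the implant hole
#'
#' Finds the dark implant hole by thresholding at a configured intensity
#' quantile, morphologically closing, and keeping the largest connected
#' component. A user-supplied mask always takes precedence.
#'
#' @param image numeric intensity matrix (hole darker than tissue).
#' @param microns_per_pixel spatial scale in um/px.
#' @param dark_quantile intensity quantile for the dark threshold
#'   (default 0.05).
#' @param close_radius_um radius of the morphological closing brush
#'   (default 5).
#' @param min_area_um2 smallest acceptable hole area (default 2000).
#' @param mask optional user-provided hole mask, returned unchanged.
#' @return logical hole mask.
#' @export
detect_hole <- function(image, microns_per_pixel, dark_quantile = 0.05,
                        close_radius_um = 5, min_area_um2 = 2000,
                        mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(image)))
    return(mask > 0)
  }
  if (diff(range(image)) == 0)
    stop("image has no contrast; supply the hole mask manually")
  thr <- stats::quantile(image, dark_quantile, names = FALSE)
  bw <- (image <= thr) * 1
  r_px <- max(1L, round(close_radius_um / microns_per_pixel))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  bw <- EBImage::closing(bw, brush)
  lab <- EBImage::bwlabel(bw)
  if (max(lab) < 1)
    stop("no dark component found; supply the hole mask manually")
  sizes <- tabulate(as.integer(lab[lab > 0]))
  biggest <- which.max(sizes)
  if (sizes[biggest] * microns_per_pixel^2 < min_area_um2)
    stop("largest dark component below the minimum hole area; ",
         "supply the hole mask manually")
  as.matrix(lab) == biggest
}
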