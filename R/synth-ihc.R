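#' Stepwise radial truth profile
#'
#' A per-ring step function of distance from the implant-hole edge: the
#' value over `[50*(i-1), 50*i)` um is `values[i]`, and the last value
#' extends beyond the final edge (distal tissue is taken as uniform
#' background). Defined this way, the per-ring area-weighted mean equals
#' the stated value exactly, so calibration targets expressed per bin
#' are reproduced without discretization bias.
#'
#' @param values numeric vector of per-bin values (first bin adjacent to
#'   the hole).
#' @param bin_width_um ring width (default 50).
#' @return function mapping distance (um, vectorised) to the value.
#' @export
step_profile <- function(values, bin_width_um = 50) {
  force(values); force(bin_width_um)
  function(d_um) {
    i <- pmin(floor(d_um / bin_width_um) + 1L, length(values))
    i[i < 1L] <- 1L
    values[i]
  }
}

#' Linear retention profile from the near-hole bin to background
#'
#' Per-bin retention fractions rising linearly from `bin0` in the first
#' 50 um ring to 1.0 in the last (background) ring.
#'
#' @param bin0 retained fraction in the 0-50 um ring.
#' @param n_bins number of rings (default 13, i.e. out to 650 um).
#' @return numeric vector of length `n_bins`.
#' @export
retention_values <- function(bin0, n_bins = 13) {
  stop_if_not_scalar_num(bin0, "bin0", 0, 1)
  bin0 + (1 - bin0) * (seq_len(n_bins) - 1) / (n_bins - 1)
}

#' Configuration for a synthetic implant-site image
#'
#' Describes a 16-bit fluorescence image around a circular implant hole.
#' For intensity markers (CD68, GFAP, IgG) pixel intensity is
#' `profile(distance) + Gaussian noise`; for the neuronal marker (NeuN)
#' the image is rendered from a Poisson point process whose density
#' (per mm^2) follows `profile`, with each soma drawn as a Gaussian
#' blob on a noisy background. Artifact patches (saturated discs) are
#' recorded in the artifact mask.
#'
#' @param marker one of `"NeuN"`, `"CD68"`, `"GFAP"`, `"IgG"`.
#' @param profile function of distance (um) from the hole edge giving
#'   the true mean intensity (intensity markers) or the true neuron
#'   density in cells/mm^2 (NeuN). Must be defined at every distance
#'   occurring in the image.
#' @param hole_radius_um implant-hole radius (default 200).
#' @param microns_per_pixel spatial scale (default 0.65, a 20x slide
#'   scan).
#' @param image_size image side in pixels; the default is the smallest
#'   square holding the hole plus a 650 um ring margin plus 10 um.
#' @param artifact_patches number of saturated artifact discs
#'   (default 2).
#' @param noise_sigma Gaussian intensity noise sd (default 100).
#' @param background_intensity NeuN background level (default 500).
#' @param soma_amp_intensity NeuN soma peak above background
#'   (default 3000).
#' @param soma_sigma_um Gaussian soma radius parameter (default 2).
#' @param hole_intensity mean intensity inside the hole (default 100).
#' @param seed integer seed.
#' @return list of class `ihc_image_config`.
#' @seealso [gen_ihc_image()], [default_neun_config()]
#' @export
ihc_image_config <- function(marker, profile, hole_radius_um = 200,
                             microns_per_pixel = 0.65, image_size = NULL,
                             artifact_patches = 2L, noise_sigma = 100,
                             background_intensity = 500,
                             soma_amp_intensity = 3000, soma_sigma_um = 2,
                             hole_intensity = 100, seed = 1L) {
  marker <- match.arg(marker, c("NeuN", "CD68", "GFAP", "IgG"))
  stopifnot(is.function(profile))
  stop_if_not_scalar_num(hole_radius_um, "hole_radius_um", 0,
                         strict_lower = TRUE)
  stop_if_not_scalar_num(microns_per_pixel, "microns_per_pixel", 0,
                         strict_lower = TRUE)
  stop_if_not_scalar_num(noise_sigma, "noise_sigma", 0)
  image_size <- image_size %||%
    ceiling(2 * (hole_radius_um + 650 + 10) / microns_per_pixel)
  if (image_size * microns_per_pixel < 2 * (hole_radius_um + 650))
    stop("image too small: the hole needs a 650 um ring margin")
  structure(list(
    marker = marker, profile = profile, hole_radius_um = hole_radius_um,
    microns_per_pixel = microns_per_pixel, image_size = as.integer(image_size),
    artifact_patches = as.integer(artifact_patches),
    noise_sigma = noise_sigma, background_intensity = background_intensity,
    soma_amp_intensity = soma_amp_intensity, soma_sigma_um = soma_sigma_um,
    hole_intensity = hole_intensity, seed = as.integer(seed)),
    class = "ihc_image_config")
}

#' Default NeuN image configurations per treatment arm
#'
#' Neuron-density truth profiles for the two arms with stated near-hole
#' retention: the treated arm retains 59 percent of the background
#' density in the 0-50 um ring, the vehicle arm 21 percent, both rising
#' linearly to the background density at 600 um. The baseline density
#' (800 neurons/mm^2) is typical of NeuN counts in 20 um rat cortical
#' sections.
#'
#' @param arm `"DEXSPPIN"` or `"DILUENT"`.
#' @param baseline_density background neuron density in cells/mm^2
#'   (default 800).
#' @param seed integer seed.
#' @param ... passed on to [ihc_image_config()].
#' @return an [ihc_image_config()].
#' @export
default_neun_config <- function(arm = c("DEXSPPIN", "DILUENT"),
                                baseline_density = 800, seed = 1L, ...) {
  arm <- match.arg(arm)
  bin0 <- switch(arm, DEXSPPIN = 0.59, DILUENT = 0.21)
  prof <- step_profile(baseline_density * retention_values(bin0))
  ihc_image_config("NeuN", prof, seed = seed, ...)
}

disc_mask <- function(n, center_row, center_col, radius_px) {
  rw <- matrix(seq_len(n), n, n)
  (rw - center_row)^2 + (t(rw) - center_col)^2 <= radius_px^2
}

#' Generate a synthetic implant-site image with ground truth
#'
#' Renders the image described by an [ihc_image_config()] plus its hole
#' mask, artifact mask and truth tables. Every generated soma appears
#' exactly once in the centroid truth (with a flag when it falls under
#' an artifact patch). Identical config and seed give identical output.
#'
#' @param config an [ihc_image_config()].
#' @return list with `image` (numeric matrix, 16-bit range), `hole_mask`,
#'   `artifact_mask` (logical matrices), `truth_profile` (data frame
#'   `bin`, `lo_um`, `hi_um`, `value`), and for NeuN `centroids`
#'   (data frame `x_px`, `y_px`, `in_artifact`).
#' @export
gen_ihc_image <- function(config) {
  stopifnot(inherits(config, "ihc_image_config"))
  n <- config$image_size
  mpp <- config$microns_per_pixel
  c0 <- (n + 1) / 2
  hole <- disc_mask(n, c0, c0, config$hole_radius_um / mpp)

  m <- matrix(1, n, n); m[hole] <- 0
  d_um <- as.matrix(EBImage::distmap(m)) * mpp
  vals <- config$profile(d_um[!hole])
  if (any(!is.finite(vals)))
    stop("truth profile undefined at a distance required by the image")

  with_seed(config$seed, {
    img <- matrix(stats::rnorm(n * n, sd = config$noise_sigma), n, n)
    centroids <- NULL
    if (config$marker == "NeuN") {
      img <- img + config$background_intensity
      lambda <- matrix(0, n, n)
      lambda[!hole] <- vals * mpp^2 / 1e6     # cells per pixel
      counts <- stats::rpois(n * n, lambda)
      where <- which(counts > 0L)
      where <- rep(where, counts[where])
      rows <- ((where - 1L) %% n) + 1L
      cols <- ((where - 1L) %/% n) + 1L
      sig <- config$soma_sigma_um / mpp
      hpatch <- ceiling(4 * sig)
      px <- -hpatch:hpatch
      patch <- config$soma_amp_intensity *
        exp(-outer(px^2, px^2, "+") / (2 * sig^2))
      for (k in seq_along(rows)) {
        r0 <- rows[k]; c0k <- cols[k]
        rr <- max(1L, r0 - hpatch):min(n, r0 + hpatch)
        cc <- max(1L, c0k - hpatch):min(n, c0k + hpatch)
        img[rr, cc] <- img[rr, cc] +
          patch[rr - r0 + hpatch + 1L, cc - c0k + hpatch + 1L]
      }
      centroids <- data.frame(x_px = cols, y_px = rows)
    } else {
      vmap <- matrix(0, n, n)
      vmap[!hole] <- vals
      img <- img + vmap
    }
    img[hole] <- config$hole_intensity +
      stats::rnorm(sum(hole), sd = config$noise_sigma)

    artifact <- matrix(FALSE, n, n)
    if (config$artifact_patches > 0L) {
      placed <- 0L
      while (placed < config$artifact_patches) {
        rad_um <- stats::runif(1, 30, 60)
        ang <- stats::runif(1, 0, 2 * pi)
        rmin <- config$hole_radius_um + rad_um + 10
        rmax <- n / 2 * mpp - rad_um - 10
        dist <- stats::runif(1, rmin, min(rmax, rmin + 600))
        cr <- c0 + dist * sin(ang) / mpp
        cc <- c0 + dist * cos(ang) / mpp
        if (cr < 1 || cr > n || cc < 1 || cc > n) next
        artifact <- artifact | disc_mask(n, cr, cc, rad_um / mpp)
        placed <- placed + 1L
      }
      img[artifact] <- 65535
    }
    img <- pmin(pmax(round(img), 0), 65535)

    if (!is.null(centroids))
      centroids$in_artifact <- artifact[cbind(centroids$y_px, centroids$x_px)]

    edges <- seq(0, 650, by = 50)
    truth_profile <- data.frame(
      bin = 0:12, lo_um = edges[-14], hi_um = edges[-1],
      value = config$profile(edges[-14] + 25))

    out <- list(image = img, hole_mask = hole, artifact_mask = artifact,
                truth_profile = truth_profile)
    if (!is.null(centroids)) out$centroids <- centroids
    out
  })
}
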