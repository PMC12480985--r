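#' Ground truth for a simulated dialysis release experiment
#'
#' Defines the true biexponential kinetics and the sampling protocol of
#' a dialysis-membrane release assay: the device sits in a
#' `bath_volume_ml` sink; at each sample time an aliquot is withdrawn
#' for quantification (its drug leaves the system) and replaced with
#' blank buffer.
#'
#' @param f_burst,k_burst,k_sustained true kinetics (see
#'   [biexp_params()]); defaults are the package release defaults.
#' @param loaded_ug drug mass in the dialysis device (ug).
#' @param bath_volume_ml sink volume (default 14).
#' @param aliquot_volume_ml withdrawn volume (default 1).
#' @param sample_times_days strictly increasing sampling times.
#' @param measurement_cv coefficient of variation of the concentration
#'   measurement (lognormal, mean-preserving; 0 = noise-free).
#' @param seed integer seed.
#' @return list of class `release_truth`.
#' @export
release_truth <- function(f_burst = 0.62, k_burst = 3.78,
                          k_sustained = 0.1227, loaded_ug = 2000,
                          bath_volume_ml = 14, aliquot_volume_ml = 1,
                          sample_times_days = c(0.25, 0.5, 1, 2, 3, 5, 7,
                                                10, 14, 18, 21, 24),
                          measurement_cv = 0.03, seed = 1L) {
  params <- biexp_params(f_burst, k_burst, k_sustained)
  stop_if_not_scalar_num(loaded_ug, "loaded_ug", 0, strict_lower = TRUE)
  if (aliquot_volume_ml >= bath_volume_ml)
    stop("'aliquot_volume_ml' must be smaller than 'bath_volume_ml'")
  if (any(diff(sample_times_days) <= 0) || any(sample_times_days <= 0))
    stop("'sample_times_days' must be positive and strictly increasing")
  stop_if_not_scalar_num(measurement_cv, "measurement_cv", 0)
  structure(list(params = params, loaded_ug = loaded_ug,
                 bath_volume_ml = bath_volume_ml,
                 aliquot_volume_ml = aliquot_volume_ml,
                 sample_times_days = sample_times_days,
                 measurement_cv = measurement_cv, seed = as.integer(seed)),
            class = "release_truth")
}

#' Simulate aliquot concentrations from a dialysis release experiment
#'
#' Between samples the released mass follows the biexponential law in
#' continuous time; at each sample time the bath concentration is
#' (noisily) measured, the aliquot's drug mass leaves the system, and
#' blank buffer restores the volume. Mass is conserved exactly:
#' unreleased + bath + withdrawn = loaded at every step.
#'
#' @param truth a [release_truth()].
#' @return data frame of class `release_curve` (see
#'   [cumulative_release()]) with the measured `conc_ug_per_ml` and, as
#'   attributes, the noise-free truth: `true_conc`, `true_fraction`.
#' @export
gen_release <- function(truth) {
  stopifnot(inherits(truth, "release_truth"))
  tt <- truth$sample_times_days
  Fv <- eval_release_model(truth$params, tt)
  bath <- 0
  conc_true <- numeric(length(tt))
  F_prev <- 0
  for (i in seq_along(tt)) {
    bath <- bath + (Fv[i] - F_prev) * truth$loaded_ug
    F_prev <- Fv[i]
    conc_true[i] <- bath / truth$bath_volume_ml
    bath <- bath - conc_true[i] * truth$aliquot_volume_ml
  }
  conc_obs <- with_seed(truth$seed, {
    if (truth$measurement_cv > 0) {
      sdlog <- sqrt(log(1 + truth$measurement_cv^2))
      conc_true * stats::rlnorm(length(tt), meanlog = -sdlog^2 / 2,
                                sdlog = sdlog)
    } else conc_true
  })
  out <- cumulative_release(tt, conc_obs, truth$loaded_ug,
                            truth$bath_volume_ml, truth$aliquot_volume_ml)
  attr(out, "true_conc") <- conc_true
  attr(out, "true_fraction") <- Fv
  out
}

#' Configuration for simulated HPLC encapsulation-efficiency batches
#'
#' Each manufactured batch contributes: a true encapsulation efficiency
#' drawn from a normal distribution truncated to `[0, 100]`, the implied
#' unencapsulated drug mass dissolved in `sample_volume_ml` of
#' supernatant, a set of calibration standards whose analyte/IS peak
#' area ratios are linear in the concentration ratio with multiplicative
#' noise, and the unknown's measured area ratio.
#'
#' @param n_batches number of batches (default 7).
#' @param total_drug_mg drug loaded per batch (default 4).
#' @param true_ee_mean,true_ee_sd batch-to-batch EE distribution in
#'   percent (defaults 78.7 and 5.5).
#' @param standards concentration-ratio grid for the calibration line;
#'   must span the unknowns.
#' @param area_noise_cv multiplicative noise on measured area ratios
#'   (default 0.02).
#' @param is_conc_ug_per_ml internal-standard concentration
#'   (default 100).
#' @param sample_volume_ml supernatant volume holding the
#'   unencapsulated drug (default 10).
#' @param true_slope,true_intercept true detector response line
#'   (defaults 1.05 and 0.01).
#' @param seed integer seed.
#' @return list of class `hplc_batch_config`.
#' @export
hplc_batch_config <- function(n_batches = 7L, total_drug_mg = 4,
                              true_ee_mean = 78.7, true_ee_sd = 5.5,
                              standards = c(0.1, 0.25, 0.5, 1, 1.5, 2),
                              area_noise_cv = 0.02,
                              is_conc_ug_per_ml = 100,
                              sample_volume_ml = 10,
                              true_slope = 1.05, true_intercept = 0.01,
                              seed = 1L) {
  stop_if_not_scalar_num(n_batches, "n_batches", 1)
  stop_if_not_scalar_num(total_drug_mg, "total_drug_mg", 0, strict_lower = TRUE)
  stop_if_not_scalar_num(true_ee_mean, "true_ee_mean", 0, 100)
  stop_if_not_scalar_num(true_ee_sd, "true_ee_sd", 0)
  stop_if_not_scalar_num(area_noise_cv, "area_noise_cv", 0)
  if (length(standards) < 3L) stop("need at least 3 standards")
  structure(list(n_batches = as.integer(n_batches),
                 total_drug_mg = total_drug_mg, true_ee_mean = true_ee_mean,
                 true_ee_sd = true_ee_sd, standards = standards,
                 area_noise_cv = area_noise_cv,
                 is_conc_ug_per_ml = is_conc_ug_per_ml,
                 sample_volume_ml = sample_volume_ml,
                 true_slope = true_slope, true_intercept = true_intercept,
                 seed = as.integer(seed)),
            class = "hplc_batch_config")
}

#' Simulate HPLC batches for encapsulation-efficiency recovery
#'
#' @param config an [hplc_batch_config()].
#' @return list of batches; each batch is a list with `standards`
#'   (data frame `conc_ratio`, `area_ratio`), `unknown_area_ratio`,
#'   `is_conc_ug_per_ml`, `sample_volume_ml`, `total_drug_mg` and the
#'   ground truth `true_ee`.
#' @seealso [estimate_ee()]
#' @export
gen_hplc_batches <- function(config) {
  stopifnot(inherits(config, "hplc_batch_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_batches), function(b) {
      repeat {
        ee <- stats::rnorm(1, config$true_ee_mean, config$true_ee_sd)
        if (ee >= 0 && ee <= 100) break
      }
      unencap_mg <- config$total_drug_mg * (1 - ee / 100)
      conc <- unencap_mg * 1000 / config$sample_volume_ml      # ug/mL
      ratio <- conc / config$is_conc_ug_per_ml
      noisy <- function(x) {
        if (config$area_noise_cv > 0) {
          sdlog <- sqrt(log(1 + config$area_noise_cv^2))
          x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
        } else x
      }
      line <- function(cr) config$true_intercept + config$true_slope * cr
      list(standards = data.frame(conc_ratio = config$standards,
                                  area_ratio = noisy(line(config$standards))),
           unknown_area_ratio = noisy(line(ratio)),
           is_conc_ug_per_ml = config$is_conc_ug_per_ml,
           sample_volume_ml = config$sample_volume_ml,
           total_drug_mg = config$total_drug_mg,
           true_ee = ee)
    })
  })
}
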