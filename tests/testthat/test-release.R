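test_that("standard curves fit and report R^2", {
  c1 <- fit_standard_curve(0:2, 0:2)
  expect_equal(c1$slope, 1)
  expect_equal(c1$intercept, 0)
  expect_equal(c1$r_squared, 1)

  c2 <- fit_standard_curve(0:2, c(1, 1, 1))
  expect_equal(c2$slope, 0)
  expect_equal(c2$intercept, 1)

  withr::with_seed(3, {
    x <- seq(0, 2, length.out = 10)
    y <- 2 * x + rnorm(10, sd = 0.01)
    expect_equal(fit_standard_curve(x, y)$slope, 2, tolerance = 0.02)
  })
  expect_error(fit_standard_curve(0:1, 0:1), "3 standards")
  expect_error(fit_standard_curve(rep(1, 4), 1:4), "spread")
})

test_that("unknowns are quantified by inverting the line", {
  cv <- fit_standard_curve(0:2, 0:2)
  expect_equal(quantify_unknown(0.5, cv, 10), 5)
  expect_equal(quantify_unknown(cv$intercept, cv, 10), 0)
  expect_warning(out <- quantify_unknown(-0.2, cv, 10), "clipped")
  expect_equal(out, 0)
})

test_that("encapsulation efficiency follows the mass-balance formula", {
  expect_equal(encapsulation_efficiency(4, 0), 100)
  expect_equal(encapsulation_efficiency(4, 4), 0)
  expect_equal(encapsulation_efficiency(4, 0.852), 78.7)
  # scale invariance: mg vs ug
  expect_equal(encapsulation_efficiency(4000, 852),
               encapsulation_efficiency(4, 0.852))
  expect_error(encapsulation_efficiency(4, 5), "exceeds")
})

test_that("cumulative release applies the withdrawal correction", {
  z <- cumulative_release(c(1, 2, 3), c(0, 0, 0), loaded_ug = 100)
  expect_equal(z$cumulative_fraction, c(0, 0, 0))
  one <- cumulative_release(1, 2, loaded_ug = 100)
  expect_equal(one$cumulative_fraction, 0.28)            # 2 x 14 / 100
  two <- cumulative_release(c(1, 2), c(2, 3), loaded_ug = 100)
  expect_equal(two$cumulative_fraction[2], 0.44)         # 3 x 14 + 2 x 1
  expect_error(cumulative_release(c(1, 2), c(1, -1), 100), "negative")
})

test_that("the biexponential model reproduces its anchor points", {
  p <- default_release_params()
  expect_equal(eval_release_model(p, 0), 0)
  expect_equal(eval_release_model(p, 1), 0.650, tolerance = 1e-3)
  expect_equal(eval_release_model(p, 24), 0.980, tolerance = 1e-3)
  expect_gt(eval_release_model(p, 1000), 0.9999)
  expect_error(eval_release_model(p, -1), ">= 0")
  expect_error(biexp_params(0.5, 0.1, 3), "exceed")
})

test_that("biexponential fitting recovers known parameters", {
  p <- biexp_params(0.55, 2.5, 0.08)
  tt <- c(0.25, 0.5, 1, 2, 4, 7, 10, 14, 21, 28)
  fit <- fit_biexponential(tt, eval_release_model(p, tt))
  expect_equal(fit$f_burst, p$f_burst, tolerance = 0.01)
  expect_equal(fit$k_burst, p$k_burst, tolerance = 0.025)
  expect_equal(fit$k_sustained, p$k_sustained, tolerance = 0.001)

  # single-exponential input drives the burst fraction to ~1
  single <- 1 - exp(-0.5 * tt)
  fs <- fit_biexponential(tt, single)
  expect_gt(fs$f_burst, 0.95)

  expect_error(fit_biexponential(c(1, 2), c(0.2, 0.4)), "3 points")
  expect_error(fit_biexponential(c(1, 2, 3), c(0.5, 0.2, 0.6)),
               "decrease")
})

test_that("simulated sink and analytic model are mutually consistent", {
  truth <- release_truth(measurement_cv = 0, seed = 8)
  rel <- gen_release(truth)
  expect_lt(max(abs(rel$cumulative_fraction - attr(rel, "true_fraction"))),
            1e-6)
  # mass conservation at every sampling step, to 1e-9 relative:
  # unreleased + bath content + everything withdrawn = loaded
  loaded <- attr(rel, "loaded_ug")
  cf <- attr(rel, "true_conc")
  unreleased <- (1 - attr(rel, "true_fraction")) * loaded
  withdrawn <- cumsum(cf * 1)
  bath_before <- cf * 14
  total <- unreleased + bath_before + c(0, withdrawn[-length(withdrawn)])
  expect_lt(max(abs(total - loaded)) / loaded, 1e-9)
})

test_that("release at a half-way point maps to the expected concentration", {
  # pick t* with F(t*) = 0.5; a single noise-free sample there reads
  # 50 ug of 100 ug load in 14 mL
  p <- default_release_params()
  t_half <- stats::uniroot(function(t) eval_release_model(p, t) - 0.5,
                           c(0.01, 5), tol = 1e-12)$root
  truth <- release_truth(loaded_ug = 100, sample_times_days = t_half,
                         measurement_cv = 0, seed = 1)
  rel <- gen_release(truth)
  expect_equal(rel$conc_ug_per_ml, 50 / 14, tolerance = 1e-6)
})

test_that("noise-free HPLC batches recover EE exactly", {
  cfg <- hplc_batch_config(n_batches = 1, true_ee_mean = 50, true_ee_sd = 0,
                           area_noise_cv = 0, seed = 1)
  b <- gen_hplc_batches(cfg)[[1]]
  est <- estimate_ee(b)
  expect_equal(est$unencapsulated_mg, 2, tolerance = 1e-9)
  expect_equal(est$ee_percent, 50, tolerance = 1e-9)
  expect_equal(est$curve$slope, cfg$true_slope)
  expect_equal(est$curve$intercept, cfg$true_intercept, tolerance = 1e-12)
})

test_that("batch EE recovery is unbiased around the configured mean", {
  means <- vapply(1:20, function(s) {
    b <- gen_hplc_batches(hplc_batch_config(seed = s))
    mean(vapply(b, function(x) estimate_ee(x)$ee_percent, 0))
  }, 0)
  expect_lt(abs(mean(means) - 78.7), 2)
})
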