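sw <- frequency_sweep()
geo3 <- make_circular_scan(120, 3)

test_that("sweep defaults and fractional bandwidth match the design band", {
  expect_equal(sw$n_samples, 284L)
  expect_equal(sw$frequencies[1], 0.75e9)
  expect_equal(sw$frequencies[284], 2.55e9)
  expect_equal(fractional_bandwidth(sw), 200 * 1.8 / 3.3)
  expect_error(frequency_sweep(2e9, 1e9), "f_min")
})

test_that("all-pass spectrum peaks at zero range and echoes at their delay", {
  s <- matrix(1 + 0i, 3, 284)
  ds <- reflection_dataset(s, sw, geo3)
  ts <- to_time_domain(ds)
  expect_equal(which.max(Mod(ts$samples[1, ])), 1L)
  expect_equal(ts$range_axis[1], 0)
  # on-grid echo: peak at the sample nearest the delay, unit amplitude
  k <- 4L * 284L
  dt <- 1 / (k * sw$df)
  tau0 <- 150 * dt
  ds2 <- echo_dataset(rep(tau0, 3), sw, geo3)
  ts2 <- to_time_domain(ds2)
  expect_equal(which.max(Mod(ts2$samples[2, ])), 151L)
  expect_equal(ts2$samples[2, 151], 1 + 0i, tolerance = 1e-12)
})

test_that("time-domain conversion is exactly invertible on the band bins", {
  set.seed(5)
  s <- matrix(complex(real = rnorm(3 * 284), imaginary = rnorm(3 * 284)),
              3, 284)
  ds <- reflection_dataset(s, sw, geo3)
  for (k in c(284L, 1136L)) {
    ts <- to_time_domain(ds, k_samples = k)
    back <- from_time_domain(ts)
    expect_lt(max(Mod(back - s)) / max(Mod(s)), 1e-10)
  }
  expect_error(to_time_domain(ds, k_samples = 100L), "at least")
})

test_that("adjacent average subtraction cancels identical baselines", {
  base <- exp(-2i * pi * sw$frequencies * 1e-9)
  s <- matrix(rep(base, 5), 5, 284, byrow = TRUE)
  geo5 <- make_circular_scan(120, 5)
  ts <- to_time_domain(reflection_dataset(s, sw, geo5))
  sc <- adjacent_average_subtract(ts)
  expect_lt(max(Mod(sc$samples)), 1e-12)
})

test_that("a position-unique echo survives subtraction of the baseline", {
  base <- exp(-2i * pi * sw$frequencies * 0.8e-9)
  echo <- 0.3 * exp(-2i * pi * sw$frequencies * 2.5e-9)
  s <- matrix(rep(base, 3), 3, 284, byrow = TRUE)
  s[1, ] <- s[1, ] + echo
  ts <- to_time_domain(reflection_dataset(s, sw, geo3))
  sc <- adjacent_average_subtract(ts)
  # 3-position reference: s1_hat = s1 - (s2 + s3)/2 keeps the echo intact
  # while the common baseline cancels identically
  echo_only <- to_time_domain(reflection_dataset(
    rbind(echo, echo, echo), sw, geo3))
  expect_equal(sc$samples[1, ], echo_only$samples[1, ], tolerance = 1e-12)
  expect_equal(sc$samples[2, ], -echo_only$samples[1, ] / 2,
               tolerance = 1e-12)
  dt <- ts$time_axis[2] - ts$time_axis[1]
  idx <- round(2.5e-9 / dt) + 1
  expect_gte(Mod(sc$samples[1, idx]), 0.9 * 0.3)
})

test_that("Woody alignment reduces the residual of shifted baselines", {
  k <- 4L * 284L
  dt <- 1 / (k * sw$df)
  taus <- 1e-9 + c(-2, 0, 2, 0, -2) * dt # +/- 2 samples between neighbors
  ds <- echo_dataset(taus, sw, make_circular_scan(120, 5))
  ts <- to_time_domain(ds, k_samples = k)
  e_plain <- sum(Mod(adjacent_average_subtract(ts, align = FALSE)$samples)^2)
  e_woody <- sum(Mod(adjacent_average_subtract(ts, align = TRUE)$samples)^2)
  expect_lt(e_woody, e_plain)
  expect_lt(e_woody, 0.01 * e_plain)
})

test_that("subtraction is linear and its output energy is ring-bounded", {
  set.seed(6)
  mk <- function() {
    s <- matrix(complex(real = rnorm(4 * 284), imaginary = rnorm(4 * 284)),
                4, 284)
    to_time_domain(reflection_dataset(s, sw, make_circular_scan(100, 4)))
  }
  x <- mk(); y <- mk()
  lin <- x
  lin$samples <- 2 * x$samples - 3 * y$samples
  lhs <- adjacent_average_subtract(lin)$samples
  rhs <- 2 * adjacent_average_subtract(x)$samples -
    3 * adjacent_average_subtract(y)$samples
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_lte(sum(Mod(adjacent_average_subtract(x)$samples)^2),
             4 * sum(Mod(x$samples)^2))
  ts2 <- mk()
  ts2$samples <- ts2$samples[1:2, ]
  expect_error(adjacent_average_subtract(ts2), "at least 3")
})

test_that("gain normalization scales to unit peak and preserves shape", {
  s <- matrix(0i, 3, 284)
  s[1, ] <- 0.2 * exp(-2i * pi * sw$frequencies * 1e-9)
  s[2, ] <- 5 * exp(-2i * pi * sw$frequencies * 2e-9)
  ts <- to_time_domain(reflection_dataset(s, sw, geo3))
  nm <- normalize_gain(ts)
  expect_equal(max(Mod(nm$samples[1, ])), 1, tolerance = 1e-12)
  expect_equal(max(Mod(nm$samples[2, ])), 1, tolerance = 1e-12)
  # all-zero position flagged, unchanged
  expect_true(nm$zero_flags[3])
  expect_equal(nm$samples[3, ], ts$samples[3, ])
  # inverse check
  peaks <- attr(nm, "peaks")
  expect_equal(nm$samples[1, ] * peaks[1], ts$samples[1, ],
               tolerance = 1e-12)
})

test_that("the excitation pulse is centered and covers the band", {
  t <- seq(-6e-9, 6e-9, by = 1e-12)
  p <- gaussian_pulse(pulse_spec(), t)
  env_peak <- which.max(abs(p))
  expect_lt(abs(t[env_peak]), 0.2e-9) # envelope maximum at grid center
  spec <- Mod(stats::fft(p))
  fax <- (seq_along(p) - 1) / (length(p) * 1e-12)
  half <- seq_len(length(p) %/% 2)
  pk <- fax[half][which.max(spec[half])]
  expect_lt(abs(pk - 1.6e9), 1 / (length(p) * 1e-12) + 1) # within one bin
  at <- function(f) {
    20 * log10(spec[which.min(abs(fax[half] - f))] / max(spec[half]))
  }
  expect_gt(at(0.75e9), -10)
  expect_gt(at(2.55e9), -10)
  expect_error(gaussian_pulse(pulse_spec(), seq(0, 5e-9, by = 1e-12)),
               "6 pulse widths")
})

test_that("noise injection hits the requested SNR and is reproducible", {
  s <- matrix(1 + 0i, 32, 284)
  ds <- reflection_dataset(s, sw, make_circular_scan(120, 32))
  expect_identical(add_noise(ds, noise_config(Inf))$s11, s)
  n1 <- add_noise(ds, noise_config(20, seed = 9))
  n2 <- add_noise(ds, noise_config(20, seed = 9))
  expect_identical(n1$s11, n2$s11)
  emp <- 10 * log10(mean(Mod(s)^2) / mean(Mod(n1$s11 - s)^2))
  expect_lt(abs(emp - 20), 0.5)
  expect_equal(n1$snr_db, 20)
})

test_that("time signals export to long-format CSV", {
  s <- matrix(1 + 0i, 3, 284)
  ts <- to_time_domain(reflection_dataset(s, sw, geo3), k_samples = 284L)
  path <- tempfile(fileext = ".csv")
  write_time_signals(ts, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 3L * 284L)
  expect_equal(df$amplitude[df$position == 1 & df$k == 0], 1)
})
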