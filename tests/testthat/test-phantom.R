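test_that("tissue permittivities interpolate the band-edge values", {
  tab <- tissue_table()
  expect_equal(tissue_permittivity("skin", 0.75e9, tab), 50)
  expect_equal(tissue_permittivity("skin", 2.55e9, tab), 44)
  expect_equal(tissue_permittivity("csf", 2.55e9, tab), 66.2)
  expect_equal(tissue_permittivity("dura", 0.75e9, tab), 44)
  expect_equal(tissue_permittivity("muscle", 0.75e9, tab), 55)
  mid <- (0.75e9 + 2.55e9) / 2
  for (tis in rownames(tab)) {
    expect_equal(tissue_permittivity(tis, mid, tab),
                 (tab[tis, "eps_lo"] + tab[tis, "eps_hi"]) / 2)
  }
  expect_error(tissue_permittivity("bone marrow", 1e9, tab), "unknown")
  expect_error(tissue_permittivity("skin", 3e9, tab), "band")
  tab2 <- tissue_table(overrides = list(fat = c(6, 5.5, 0.1)))
  expect_equal(tissue_permittivity("fat", 0.75e9, tab2), 6)
})

test_that("wave impedance has the vacuum limit and matches complex math", {
  expect_equal(wave_impedance(1, 0, 1e9), 376.73, tolerance = 1e-4)
  expect_equal(wave_impedance(4, 0, 1e9), 376.73 / 2, tolerance = 1e-4)
  # lossy case against a direct complex evaluation
  w <- 2 * pi * 1.6e9
  mu0 <- 4e-7 * pi; eps0 <- 8.8541878128e-12
  direct <- Mod(sqrt(1i * w * mu0 / (1.2 + 1i * w * eps0 * 52)))
  expect_equal(wave_impedance(52, 1.2, 1.6e9), direct, tolerance = 1e-12)
  expect_error(wave_impedance(0.5, 0, 1e9), "eps_r")
})

test_that("impedance contrast reproduces the blood/gray band-edge figures", {
  expect_equal(round(impedance_contrast(44.8, 48.9), 1), 9.2)
  expect_equal(round(impedance_contrast(49.9, 52.5), 1), 5.2)
  expect_equal(impedance_contrast(50, 50), 0)
  expect_error(impedance_contrast(0, 50), "positive")
})

test_that("phantom construction validates layers and target placement", {
  ph <- make_head_phantom()
  expect_equal(ph$shell_thickness, 10)
  expect_s3_class(ph$boundary, "head_boundary")
  ph2 <- insert_target(ph, c(45, 55))
  expect_equal(ph2$target$center, c(45, 55))
  # re-inserting replaces
  ph3 <- insert_target(ph2, c(-20, 10), 15, 20)
  expect_equal(ph3$target$center, c(-20, 10))
  expect_equal(ph3$target$width, 15)
  expect_error(insert_target(ph, c(85, 0)), "inside")
  expect_error(make_head_phantom(layers = c(skin = 2, fat = 1, skull = 4,
                                            csf = 90)), "semi-minor")
})

test_that("every interior point maps to exactly one tissue, in layer order", {
  ph <- insert_target(make_head_phantom(), c(40, 40))
  known <- c("skin", "fat", "skull", "csf", "gray", "white", "blood", "air")
  set.seed(12)
  pts <- cbind(runif(300, -95, 95), runif(300, -115, 115))
  for (i in seq_len(nrow(pts))) {
    expect_true(tissue_at(ph, pts[i, ]) %in% known)
  }
  # along +x axis the sequence is air, skin, fat, skull, csf, gray, white
  xs <- c(91, 89.5, 87.5, 85, 82, 70, 50)
  expect_equal(vapply(xs, function(x) tissue_at(ph, c(x, 0)), ""),
               c("air", "skin", "fat", "skull", "csf", "gray", "white"))
  expect_equal(tissue_at(ph, c(40, 40)), "blood")
  expect_equal(tissue_at(ph, c(40, 40), ignore_target = TRUE), "white")
})

test_that("straight-ray delay matches closed forms and a line integral", {
  ph <- make_head_phantom()
  c0 <- 299792458
  # point on the skin surface: free-space time only
  tau <- straight_ray_delay(c(120, 0), c(90, 0), ph)
  expect_equal(tau, 30e-3 / c0, tolerance = 1e-15)
  # layered case vs a fine-step numerical line integral
  ant <- c(120, 15); pt <- c(-10, 20)
  tau2 <- straight_ray_delay(ant, pt, ph)
  u <- (pt - ant); len <- sqrt(sum(u^2)); u <- u / len
  step <- 0.02
  mids <- seq(step / 2, len - step / 2, by = step)
  f <- 1.6e9; w <- 2 * pi * f; eps0 <- 8.8541878128e-12
  num <- sum(vapply(mids, function(s) {
    tis <- tissue_at(ph, ant + s * u)
    eps <- tissue_permittivity(tis, f, ph$tissues)
    sig <- ph$tissues[tis, "sigma"]
    Re(sqrt(complex(real = eps, imaginary = -sig / (w * eps0))))
  }, numeric(1))) * step * 1e-3 / c0
  expect_lt(abs(tau2 - num) / num, 0.001)
  expect_error(straight_ray_delay(c(120, 0), c(95, 0), ph), "inside")
})

test_that("the physical first arrival never exceeds the straight-ray time", {
  ph <- insert_target(make_head_phantom(), c(45, 55))
  geo <- make_parabolic_scan(105, 125, 8)
  for (i in 1:8) {
    fl <- fermat_layered_delay(geo$positions[i, ], c(45, 55), ph)
    st <- straight_ray_delay(geo$positions[i, ], c(45, 55), ph)
    expect_lte(fl$delay, st + 1e-15)
    expect_gte(fl$attenuation_np, 0)
  }
  # for the aligned (nearest) antenna the two nearly coincide
  d <- sqrt(rowSums((geo$positions -
                       matrix(c(45, 55), 8, 2, byrow = TRUE))^2))
  i0 <- which.min(d)
  fl <- fermat_layered_delay(geo$positions[i0, ], c(45, 55), ph)
  st <- straight_ray_delay(geo$positions[i0, ], c(45, 55), ph)
  expect_lt(abs(fl$delay - st), 5e-12)
})

test_that("identical baselines cancel exactly for a symmetric scan", {
  ph <- make_head_phantom(semi_axes = c(80, 80))
  geo <- make_circular_scan(95, 12)
  dat <- simulate_reflection(ph, geo, frequency_sweep(),
                             forward_config(seed = 3))
  ts <- to_time_domain(dat)
  sc <- adjacent_average_subtract(ts)
  expect_lt(sum(Mod(sc$samples)^2), 1e-10 * sum(Mod(ts$samples)^2))
})

test_that("simulated datasets are bit-reproducible and superpose exactly", {
  ph0 <- make_head_phantom(skin_jitter_sd = 0.3)
  geo <- make_parabolic_scan(105, 125, 8)
  sw <- frequency_sweep()
  d1 <- simulate_reflection(ph0, geo, sw, forward_config(seed = 7))
  d2 <- simulate_reflection(ph0, geo, sw, forward_config(seed = 7))
  expect_identical(d1$s11, d2$s11)
  d3 <- simulate_reflection(ph0, geo, sw, forward_config(seed = 8))
  expect_false(identical(d1$s11, d3$s11))
  # superposition: no-target + target-only = with-target, exactly
  ph_t <- insert_target(ph0, c(45, 55))
  d_with <- simulate_reflection(ph_t, geo, sw, forward_config(seed = 7))
  d_only <- simulate_reflection(ph_t, geo, sw,
                                forward_config(seed = 7,
                                               include_skin_echo = FALSE))
  expect_equal(d1$s11 + d_only$s11, d_with$s11, tolerance = 1e-15)
})

test_that("post-subtraction echoes land at the forward-model delays", {
  ph <- insert_target(make_head_phantom(), c(45, 55))
  geo <- make_parabolic_scan(105, 125, 32)
  sw <- frequency_sweep()
  dat <- simulate_reflection(ph, geo, sw, forward_config(seed = 1))
  ts <- to_time_domain(dat)
  sc <- adjacent_average_subtract(ts, align = TRUE)
  dt <- ts$time_axis[2] - ts$time_axis[1]
  d <- sqrt(rowSums((geo$positions -
                       matrix(c(45, 55), 32, 2, byrow = TRUE))^2))
  near <- order(d)[1:12]
  errs <- vapply(near, function(i) {
    pk <- ts$time_axis[which.max(Mod(sc$samples[i, ]))]
    tau <- 2 * fermat_layered_delay(geo$positions[i, ], c(45, 55), ph)$delay
    abs(pk - tau) / dt
  }, numeric(1))
  # target echo dominates the closest channels; distant channels may be
  # dominated by residual skin scattering instead
  expect_gte(sum(errs <= 1), 9)
})

test_that("target amplitude grows with the blood-background contrast", {
  # same target location, background switched from white to gray by
  # thickening the cortical shell; blood/white contrast > blood/gray
  sw <- frequency_sweep()
  geo <- make_parabolic_scan(105, 125, 8)
  ph_w <- make_head_phantom(gray_thickness = 15)
  ph_g <- make_head_phantom(gray_thickness = 40)
  expect_equal(tissue_at(ph_w, c(0, 70)), "white")
  expect_equal(tissue_at(ph_g, c(0, 70)), "gray")
  amp <- function(ph) {
    d <- simulate_reflection(insert_target(ph, c(0, 70)), geo, sw,
                             forward_config(seed = 4,
                                            include_skin_echo = FALSE))
    max(Mod(d$s11))
  }
  expect_gt(amp(ph_w), amp(ph_g))
})

test_that("healthy phantom with jitter scatters only near the skin", {
  ph <- make_head_phantom(skin_jitter_sd = 0.3)
  geo <- make_parabolic_scan(105, 125, 16)
  dat <- simulate_reflection(ph, geo, frequency_sweep(),
                             forward_config(seed = 5))
  grid <- imaging_grid(300, 300, 2)
  fit <- fit_permittivity_model(phantom_permittivity_curves(
    make_head_phantom()))
  img <- reconstruct_pipeline(dat, ph$boundary, grid, fit)
  am <- which(img$intensity == max(img$intensity), arr.ind = TRUE)[1, ]
  pt <- c(grid$xs[am[1]], grid$ys[am[2]])
  expect_lte(hemoscan:::distance_to_boundary(pt, ph$boundary), 10)
})
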