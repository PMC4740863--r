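# hand-built image on a tiny grid with a known head mask
mk_scene <- function(vals) {
  grid <- imaging_grid(20, 20, 1)
  mask <- matrix(TRUE, 20, 20)
  img <- structure(
    list(intensity = vals, grid = grid, mask = mask,
         normalized = max(vals) == 1, raw_max = max(vals)),
    class = "reconstructed_image"
  )
  list(img = img, grid = grid)
}

test_that("signal-to-max-clutter compares region maxima and classifies", {
  vals <- matrix(0.1, 20, 20)
  vals[5, 5] <- 1.0   # inside target
  vals[15, 15] <- 0.5 # clutter
  sc <- mk_scene(vals)
  tgt <- target_region_rect(sc$grid, c(sc$grid$xs[5], sc$grid$ys[5]), 4, 4)
  expect_equal(signal_to_max_clutter(sc$img, tgt), 2.0)
  m <- image_metrics(sc$img, tgt)
  expect_true(m$localized_correctly)
  # reversed intensities: incorrect localization
  vals2 <- matrix(0.1, 20, 20)
  vals2[5, 5] <- 0.5
  vals2[15, 15] <- 1.0
  sc2 <- mk_scene(vals2)
  m2 <- image_metrics(sc2$img, tgt)
  expect_equal(m2$gamma, 0.5)
  expect_false(m2$localized_correctly)
})

test_that("average signal-to-clutter handles uniform and scaled images", {
  vals <- matrix(1, 20, 20)
  sc <- mk_scene(vals)
  tgt <- target_region_rect(sc$grid, c(0, 0), 6, 6)
  expect_equal(avg_signal_to_clutter(sc$img, tgt), 1)
  vals2 <- matrix(3, 20, 20)
  vals2[tgt$mask] <- 6
  sc2 <- mk_scene(vals2)
  expect_equal(avg_signal_to_clutter(sc2$img, tgt), 2)
})

test_that("metrics equal exhaustive brute-force computation on random images", {
  set.seed(8)
  for (rep in 1:3) {
    vals <- matrix(runif(400), 20, 20)
    sc <- mk_scene(vals)
    tgt <- target_region_rect(sc$grid, c(2.5, -3.5), 5, 7)
    tm <- tgt$mask; cm <- !tgt$mask
    expect_equal(signal_to_max_clutter(sc$img, tgt),
                 max(vals[tm]) / max(vals[cm]))
    expect_equal(avg_signal_to_clutter(sc$img, tgt),
                 mean(vals[tm]) / mean(vals[cm]))
    am <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    loc <- c(sc$grid$xs[am[1]], sc$grid$ys[am[2]])
    expect_equal(localization_error(sc$img, tgt),
                 sqrt(sum((loc - tgt$true_center)^2)))
  }
})

test_that("localization error uses cell centers with 3-4-5 geometry", {
  vals <- matrix(0, 20, 20)
  vals[10, 10] <- 1
  sc <- mk_scene(vals)
  truec <- c(sc$grid$xs[10] + 3, sc$grid$ys[10] + 4) # offset (3, 4) mm
  tgt <- target_region(matrix(TRUE, 20, 20) & row(vals) > 5, truec, sc$grid)
  expect_equal(localization_error(sc$img, tgt), 5)
  # argmax in the true cell: error bounded by half the cell diagonal
  tgt2 <- target_region_rect(sc$grid, c(sc$grid$xs[10], sc$grid$ys[10]), 3, 3)
  expect_lte(localization_error(sc$img, tgt2), sqrt(2) / 2)
})

test_that("metric ratios are scale invariant and normalization cancels", {
  set.seed(9)
  vals <- matrix(runif(400), 20, 20)
  sc_raw <- mk_scene(vals * 7.3)
  sc_norm <- mk_scene(vals * 7.3 / max(vals * 7.3))
  tgt <- target_region_rect(sc_raw$grid, c(0, 0), 6, 6)
  expect_equal(signal_to_max_clutter(sc_raw$img, tgt),
               signal_to_max_clutter(sc_norm$img, tgt), tolerance = 1e-12)
  expect_equal(avg_signal_to_clutter(sc_raw$img, tgt),
               avg_signal_to_clutter(sc_norm$img, tgt), tolerance = 1e-12)
})

test_that("sole nonzero cell inside the target yields an infinite ratio", {
  vals <- matrix(0, 20, 20)
  vals[5, 5] <- 1
  sc <- mk_scene(vals)
  tgt <- target_region_rect(sc$grid, c(sc$grid$xs[5], sc$grid$ys[5]), 2, 2)
  expect_identical(signal_to_max_clutter(sc$img, tgt), Inf)
})

test_that("argmax ties break deterministically by lowest p then q", {
  vals <- matrix(0, 20, 20)
  vals[c(12, 3), c(8, 15)] <- 1 # four tied maxima
  sc <- mk_scene(vals)
  tgt <- target_region_rect(sc$grid, c(0, 0), 4, 4)
  m <- image_metrics(sc$img, tgt)
  expect_equal(m$argmax_location, c(sc$grid$xs[3], sc$grid$ys[8]))
})

test_that("accuracy map runs per position and self-difference is zero", {
  ph0 <- make_head_phantom()
  fit <- fit_permittivity_model(phantom_permittivity_curves(ph0))
  geo <- make_parabolic_scan(105, 125, 16)
  grid <- imaging_grid(300, 300, 2)
  tab <- build_travel_time_table(geo, ph0$boundary, grid, fit)
  pos <- rbind(c(0, 72), c(0, 12))
  am <- accuracy_map(pos, ph0, geo, frequency_sweep(), grid, fit,
                     noise = noise_config(30, seed = 21), table = tab)
  expect_equal(nrow(am$metrics), 2L)
  expect_true(all(is.finite(am$metrics$gamma)))
  d0 <- differential_map(am, am)
  expect_true(all(d0$d_gamma == 0 & d0$d_q == 0 & d0$d_delta_mm == 0))
  # penetration loss: the deep position does not beat the shallow one on Q
  expect_lte(am$metrics$q[2], am$metrics$q[1])
  expect_error(differential_map(am, structure(
    list(metrics = am$metrics[1, ]), class = "accuracy_map")), "identical")
})

test_that("metrics tables serialize to CSV and JSON", {
  vals <- matrix(runif(400), 20, 20)
  sc <- mk_scene(vals)
  tgt <- target_region_rect(sc$grid, c(0, 0), 6, 6)
  m <- image_metrics(sc$img, tgt)
  csv <- tempfile(fileext = ".csv")
  write_metrics(list(proposed = m, `snr20` = m), csv)
  df <- utils::read.csv(csv)
  expect_equal(df$gamma, rep(m$gamma, 2))
  js <- tempfile(fileext = ".json")
  write_metrics(list(proposed = m), js)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$gamma[1],
               m$gamma)
})
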