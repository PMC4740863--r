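#' Target region on the imaging grid
#'
#' The region Omega_target of the true scatterer, as a boolean field on the
#' grid together with the true central location.
#'
#' @param mask P x Q logical matrix; must be nonempty.
#' @param true_center length-2 true target center (mm).
#' @param grid the [imaging_grid()] the mask lives on.
#' @return An object of class `target_region`.
#' @export
target_region <- function(mask, true_center, grid) {
  if (!any(mask)) stop("target mask is empty")
  structure(
    list(mask = mask, true_center = as.numeric(true_center), grid = grid),
    class = "target_region"
  )
}

#' Axis-aligned rectangular target region
#'
#' Convenience constructor matching how synthetic targets are inserted:
#' cells whose centers fall inside the rectangle `center +/- (width, height)/2`.
#'
#' @param grid an [imaging_grid()].
#' @param center rectangle center (mm).
#' @param width,height rectangle extent (mm).
#' @return A [target_region()].
#' @export
target_region_rect <- function(grid, center, width, height) {
  inx <- abs(grid$xs - center[1L]) <= width / 2
  iny <- abs(grid$ys - center[2L]) <= height / 2
  target_region(outer(inx, iny, `&`), center, grid)
}

#' Argmax cell of an image with deterministic tie-breaking
#'
#' Ties are broken by lowest row index p, then lowest column index q.
#' @noRd
argmax_cell <- function(intensity) {
  mx <- max(intensity)
  hits <- which(intensity == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  hits[1L, ]
}

#' Signal-to-maximum-clutter ratio (gamma)
#'
#' Compares the maximum intensity over the target region with the maximum
#' over the rest of the head area. `gamma > 1` means the image's highest peak
#' lies inside the actual target region (correct localization); `gamma < 1`
#' means the maximum falls outside it. If no clutter cell has nonzero
#' intensity the ratio is `+Inf`.
#'
#' @param image a `reconstructed_image`.
#' @param target a [target_region()]; must be strictly smaller than the head
#'   region.
#' @return dimensionless ratio.
#' @export
signal_to_max_clutter <- function(image, target) {
  tm <- target$mask & image$mask
  cm <- image$mask & !tm
  if (!any(tm) || !any(cm)) stop("target and clutter regions must be nonempty")
  max(image$intensity[tm]) / max(image$intensity[cm])
}

#' Average signal-to-clutter ratio (Q)
#'
#' Relative magnitude of the mean intensity inside the target region to the
#' mean over the rest of the head area; higher values mean the target stands
#' out more clearly.
#'
#' @inheritParams signal_to_max_clutter
#' @return dimensionless ratio.
#' @export
avg_signal_to_clutter <- function(image, target) {
  tm <- target$mask & image$mask
  cm <- image$mask & !tm
  if (!any(tm) || !any(cm)) stop("target and clutter regions must be nonempty")
  mean(image$intensity[tm]) / mean(image$intensity[cm])
}

#' Localization error (delta, mm)
#'
#' Euclidean distance between the true target center and the center of the
#' maximum-intensity cell.
#'
#' @inheritParams signal_to_max_clutter
#' @return distance in mm.
#' @export
localization_error <- function(image, target) {
  if (image$raw_max == 0) stop("localization undefined for an all-zero image")
  pq <- argmax_cell(image$intensity)
  loc <- c(image$grid$xs[pq[1L]], image$grid$ys[pq[2L]])
  sqrt(sum((loc - target$true_center)^2))
}

#' All image-quality metrics for one image/target pair
#'
#' @inheritParams signal_to_max_clutter
#' @return An object of class `image_metrics` with `gamma`, `q_ratio`,
#'   `delta_mm`, `argmax_location` and `localized_correctly` (`gamma > 1`).
#' @export
image_metrics <- function(image, target) {
  pq <- argmax_cell(image$intensity)
  gamma <- signal_to_max_clutter(image, target)
  structure(
    list(
      gamma = gamma,
      q_ratio = avg_signal_to_clutter(image, target),
      delta_mm = localization_error(image, target),
      argmax_location = c(image$grid$xs[pq[1L]], image$grid$ys[pq[2L]]),
      localized_correctly = gamma > 1
    ),
    class = "image_metrics"
  )
}

#' @export
print.image_metrics <- function(x, ...) {
  cat(sprintf(
    "<image_metrics> gamma = %.3f, Q = %.3f, delta = %.2f mm, argmax (%.1f, %.1f) mm [%s]\n",
    x$gamma, x$q_ratio, x$delta_mm, x$argmax_location[1L],
    x$argmax_location[2L],
    if (x$localized_correctly) "correct localization" else "incorrect localization"
  ))
  invisible(x)
}

#' Reconstruction-accuracy map over systematic target positions
#'
#' For each requested target center a synthetic acquisition is simulated, the
#' image reconstructed and the quality metrics computed, building the
#' per-position accuracy map. When both a proposed (variable) and a fixed
#' model image are requested, the differential map (proposed minus fixed) can
#' be formed with [differential_map()].
#'
#' @param positions list (or n x 2 matrix) of target centers (mm), all inside
#'   the head.
#' @param phantom a target-free [make_head_phantom()]; the target is inserted
#'   at each position in turn.
#' @param geometry,sweep,grid,model acquisition and reconstruction settings.
#' @param cfg a [forward_config()].
#' @param target_size target extent c(width, height) mm.
#' @param noise optional [noise_config()] applied to each simulated dataset.
#' @param table optional precomputed travel-time table for `model`.
#' @param align Woody alignment flag passed to the pipeline.
#' @return An object of class `accuracy_map`: data frame `metrics` with one
#'   row (x, y, gamma, q, delta_mm) per position.
#' @export
accuracy_map <- function(positions, phantom, geometry, sweep, grid, model,
                         cfg = forward_config(), target_size = c(20, 20),
                         noise = NULL, table = NULL, align = TRUE) {
  if (is.matrix(positions)) {
    positions <- lapply(seq_len(nrow(positions)), function(i) positions[i, ])
  }
  if (is.null(table)) {
    table <- build_travel_time_table(geometry, phantom$boundary, grid, model)
  }
  rows <- lapply(positions, function(ctr) {
    ph <- insert_target(phantom, ctr, target_size[1L], target_size[2L])
    dat <- simulate_reflection(ph, geometry, sweep, cfg)
    if (!is.null(noise)) dat <- add_noise(dat, noise)
    img <- reconstruct_pipeline(dat, phantom$boundary, grid, model,
                                align = align, table = table)
    tgt <- target_region_rect(grid, ctr, target_size[1L], target_size[2L])
    met <- image_metrics(img, tgt)
    data.frame(x = ctr[1L], y = ctr[2L], gamma = met$gamma, q = met$q_ratio,
               delta_mm = met$delta_mm)
  })
  structure(
    list(metrics = do.call(rbind, rows), model = model),
    class = "accuracy_map"
  )
}

#' Differential accuracy map (proposed minus fixed)
#'
#' @param map_a,map_b two [accuracy_map()] results over identical positions.
#' @return data frame with per-position differences of gamma, Q and delta.
#' @export
differential_map <- function(map_a, map_b) {
  a <- map_a$metrics; b <- map_b$metrics
  if (nrow(a) != nrow(b) || any(a$x != b$x) || any(a$y != b$y)) {
    stop("maps must cover identical positions")
  }
  data.frame(
    x = a$x, y = a$y,
    d_gamma = a$gamma - b$gamma,
    d_q = a$q - b$q,
    d_delta_mm = a$delta_mm - b$delta_mm
  )
}

#' Write metrics to JSON or a Table-1-style CSV
#'
#' @param metrics_list named list of `image_metrics` (names label the
#'   model/SNR condition).
#' @param path output path; `.json` or `.csv` decides the format.
#' @export
write_metrics <- function(metrics_list, path) {
  rows <- data.frame(
    condition = names(metrics_list),
    gamma = vapply(metrics_list, function(m) m$gamma, 1),
    q = vapply(metrics_list, function(m) m$q_ratio, 1),
    delta_mm = vapply(metrics_list, function(m) m$delta_mm, 1)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
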