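#' Delay-and-sum back-projection image formation
#'
#' For every in-head grid cell the normalized scattered signals are assumed to
#' originate from that cell: each channel is sampled (linear interpolation) at
#' its hypothesized round-trip delay to the cell and the samples are summed
#' coherently. A correct hypothesis adds the channels in phase and produces a
#' large value; a wrong one produces near-cancellation. The intensity is the
#' absolute value of the coherent sum (taken after summation, preserving the
#' cancellation behavior); delays beyond the signal support contribute zero.
#' The image is max-normalized to 1 over the head region, with the
#' pre-normalization maximum kept in `raw_max` (un-normalized magnitudes
#' carry diagnostic information: strong targets reach magnitudes an order
#' above the skin residual of a healthy head).
#'
#' @param signals a `time_signals` object of scattered signals.
#' @param table a [build_travel_time_table()] sharing the scan geometry.
#' @param mask optional override of the table's head mask.
#' @return An object of class `reconstructed_image`: `intensity` (P x Q,
#'   zeros outside the head), `normalized`, `raw_max`, plus grid/mask
#'   references.
#' @export
das_reconstruct <- function(signals, table, mask = NULL) {
  if (is.null(mask)) mask <- table$mask
  n <- nrow(signals$samples)
  if (dim(table$times)[1L] != n) {
    stop("signals and travel-time table have different antenna counts")
  }
  k <- ncol(signals$samples)
  dt <- signals$time_axis[2L] - signals$time_axis[1L]
  p <- table$grid$dims[1L]; q <- table$grid$dims[2L]
  flat <- which(as.vector(mask))
  acc <- rep(0i, length(flat))
  for (i in seq_len(n)) {
    tt <- table$times[i, , ][flat]
    idx <- tt / dt # zero-based fractional sample index
    lo <- floor(idx)
    frac <- idx - lo
    valid <- lo >= 0 & lo < (k - 1L)
    contrib <- rep(0i, length(flat))
    if (any(valid)) {
      row <- signals$samples[i, ]
      l1 <- lo[valid] + 1L
      contrib[valid] <- row[l1] * (1 - frac[valid]) + row[l1 + 1L] * frac[valid]
    }
    acc <- acc + contrib
  }
  img <- matrix(0, p, q)
  img[flat] <- Mod(acc)
  raw_max <- max(img)
  normalized <- raw_max > 0
  if (normalized) img <- img / raw_max
  structure(
    list(
      intensity = img, grid = table$grid, mask = mask,
      normalized = normalized, raw_max = raw_max
    ),
    class = "reconstructed_image"
  )
}

#' @export
print.reconstructed_image <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_image> %d x %d cells (%.2f mm), raw max %.3g%s\n",
    x$grid$dims[1L], x$grid$dims[2L], x$grid$cell_size, x$raw_max,
    if (x$normalized) ", normalized" else ", all-zero (not normalized)"
  ))
  invisible(x)
}

#' Full reconstruction pipeline: sweep data to image
#'
#' Chains the processing stages end to end: inverse DFT to time domain,
#' adjacent average subtraction (Woody-aligned by default), gain
#' normalization, travel-time table construction, and delay-and-sum
#' back-projection.
#'
#' @param data a [reflection_dataset()].
#' @param boundary a [head_boundary()].
#' @param grid an [imaging_grid()].
#' @param model a [permittivity_model()].
#' @param align Woody alignment in the clutter-removal stage.
#' @param window spectral window for the time-domain conversion.
#' @param k_samples zero-padded record length.
#' @param antenna_delay seconds.
#' @param table optional precomputed travel-time table (reused across runs
#'   that share geometry, boundary, grid and model).
#' @param keep_intermediate retain the intermediate signal stages.
#' @return A `reconstructed_image`; if `keep_intermediate`, a list with
#'   elements `image`, `time_signals`, `scattered`, `normalized_signals`,
#'   `table`.
#' @export
reconstruct_pipeline <- function(data, boundary, grid, model,
                                 align = TRUE, window = "none",
                                 k_samples = 4L * data$sweep$n_samples,
                                 antenna_delay = 0, table = NULL,
                                 keep_intermediate = FALSE) {
  ts <- to_time_domain(data, k_samples = k_samples, window = window)
  sc <- adjacent_average_subtract(ts, align = align)
  nm <- normalize_gain(sc)
  if (is.null(table)) {
    table <- build_travel_time_table(data$geometry, boundary, grid, model,
                                     antenna_delay = antenna_delay)
  }
  img <- das_reconstruct(nm, table)
  if (keep_intermediate) {
    list(image = img, time_signals = ts, scattered = sc,
         normalized_signals = nm, table = table)
  } else {
    img
  }
}
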