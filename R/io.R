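#' Write a one-port Touchstone (.s1p) file
#'
#' Version 1.1 dialect: option line `# Hz S <FMT> R 50`, one frequency per
#' row. Formats: `RI` (real/imaginary, default and lossless), `MA`
#' (magnitude/angle-degrees), `DB` (dB-magnitude/angle-degrees).
#'
#' @param frequencies numeric frequencies (Hz).
#' @param s complex reflection coefficients, same length.
#' @param path output file.
#' @param format `"RI"`, `"MA"` or `"DB"`.
#' @export
write_touchstone <- function(frequencies, s, path, format = c("RI", "MA", "DB")) {
  format <- match.arg(format)
  stopifnot(length(frequencies) == length(s))
  cols <- switch(format,
    RI = cbind(Re(s), Im(s)),
    MA = cbind(Mod(s), Arg(s) * 180 / pi),
    DB = cbind(20 * log10(Mod(s)), Arg(s) * 180 / pi)
  )
  lines <- c(
    "! hemoscan one-port reflection data",
    sprintf("# Hz S %s R 50", format),
    sprintf("%.10e %.17e %.17e", frequencies, cols[, 1L], cols[, 2L])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-port Touchstone (.s1p) file
#'
#' @param path file path.
#' @return list with `frequencies` (Hz) and complex `s`.
#' @export
read_touchstone <- function(path) {
  raw <- readLines(path)
  raw <- trimws(raw)
  opt_i <- grep("^#", raw)
  if (length(opt_i) == 0L) stop("missing Touchstone option line in ", path)
  opt <- toupper(strsplit(raw[opt_i[1L]], "\\s+")[[1L]][-1L])
  funit <- 1
  fmt <- "MA" # Touchstone default
  i <- 1L
  while (i <= length(opt)) {
    tok <- opt[i]
    if (tok %in% c("HZ", "KHZ", "MHZ", "GHZ")) {
      funit <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[[tok]]
    } else if (tok == "S") {
      # parameter type; nothing to do for one-port reflection
    } else if (tok %in% c("RI", "MA", "DB")) {
      fmt <- tok
    } else if (tok == "R") {
      i <- i + 1L # reference resistance value follows
    } else {
      stop(sprintf("unknown Touchstone option '%s' at line %d of %s",
                   tok, opt_i[1L], path))
    }
    i <- i + 1L
  }
  body <- raw[-seq_len(opt_i[1L])]
  body <- body[nzchar(body) & !startsWith(body, "!")]
  num <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  if (ncol(num) < 3L) stop("malformed Touchstone data rows in ", path)
  s <- switch(fmt,
    RI = complex(real = num[, 2L], imaginary = num[, 3L]),
    MA = num[, 2L] * exp(1i * num[, 3L] * pi / 180),
    DB = 10^(num[, 2L] / 20) * exp(1i * num[, 3L] * pi / 180)
  )
  list(frequencies = num[, 1L] * funit, s = s)
}

#' Write a reflection dataset as Touchstone files plus a JSON manifest
#'
#' One `pos_###.s1p` per antenna position (RI format, lossless at the printed
#' precision) and a `manifest.json` carrying the scan geometry, sweep and
#' declared SNR.
#'
#' @param data a [reflection_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(data$s11)
  files <- sprintf("pos_%03d.s1p", seq_len(n))
  for (i in seq_len(n)) {
    write_touchstone(data$sweep$frequencies, data$s11[i, ],
                     file.path(dir, files[i]), format = "RI")
  }
  manifest <- list(
    n_positions = n,
    files = files,
    positions = apply(data$geometry$positions, 1L, as.numeric,
                      simplify = FALSE),
    center = data$geometry$center,
    sweep = list(f_min = data$sweep$f_min, f_max = data$sweep$f_max,
                 n_samples = data$sweep$n_samples),
    snr_db = if (is.na(data$snr_db)) NULL else data$snr_db
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reflection dataset from a Touchstone directory with manifest
#'
#' @param dir dataset directory.
#' @return A [reflection_dataset()].
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  n <- mf$n_positions
  missing <- !file.exists(file.path(dir, mf$files))
  if (any(missing)) {
    stop("manifest lists ", n, " positions but file(s) missing: ",
         paste(mf$files[missing], collapse = ", "))
  }
  sw <- frequency_sweep(mf$sweep$f_min, mf$sweep$f_max, mf$sweep$n_samples)
  s11 <- matrix(0i, n, sw$n_samples)
  for (i in seq_len(n)) {
    ts <- read_touchstone(file.path(dir, mf$files[i]))
    if (length(ts$s) != sw$n_samples) {
      stop("file ", mf$files[i], " has ", length(ts$s),
           " rows, manifest says ", sw$n_samples)
    }
    s11[i, ] <- ts$s
  }
  pos <- if (is.matrix(mf$positions)) mf$positions else
    do.call(rbind, mf$positions)
  geom <- scan_geometry(pos, unlist(mf$center))
  snr <- if (is.null(mf$snr_db)) NA_real_ else mf$snr_db
  reflection_dataset(s11, sw, geom, snr_db = snr)
}

#' Write a reconstructed image as PNG + CSV matrix + JSON sidecar
#'
#' PNG uses a perceptual sequential colormap on the normalized intensity;
#' the CSV holds the raw P x Q matrix and the sidecar the grid metadata.
#'
#' @param image a `reconstructed_image`.
#' @param stem output path stem (writes `<stem>.png`, `<stem>.csv`,
#'   `<stem>.json`).
#' @export
write_image <- function(image, stem) {
  pal <- grDevices::hcl.colors(256L, "viridis")
  idx <- pmin(255L, pmax(0L, floor(image$intensity * 255))) + 1L
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  p <- image$grid$dims[1L]; q <- image$grid$dims[2L]
  # PNG rows run top to bottom: row 1 = max y
  arr <- array(0, c(q, p, 3L))
  for (ch in 1:3) {
    arr[, , ch] <- t(matrix(rgb[ch, ], p, q))[q:1, , drop = FALSE]
  }
  png::writePNG(arr, paste0(stem, ".png"))
  utils::write.table(image$intensity, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(dims = image$grid$dims, cell_size = image$grid$cell_size,
         extent = image$grid$extent, center = image$grid$center,
         normalized = image$normalized, raw_max = image$raw_max),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Build domain objects from an experiment configuration list
#' @noRd
config_objects <- function(cfg) {
  gspec <- cfg$geometry
  geometry <- switch(gspec$type,
    circle = make_circular_scan(gspec$radius, gspec$n,
                                center = unlist(gspec$center %||% c(0, 0))),
    parabola = make_parabolic_scan(gspec$r1, gspec$r2, gspec$n,
                                   center = unlist(gspec$center %||% c(0, 0))),
    explicit = scan_geometry(do.call(rbind, gspec$positions),
                             unlist(gspec$center %||% c(0, 0))),
    stop("unknown geometry type: ", gspec$type)
  )
  pspec <- cfg$phantom
  phantom <- make_head_phantom(
    semi_axes = unlist(pspec$semi_axes %||% c(90, 110)),
    layers = unlist(pspec$layers %||%
                      c(skin = 2, fat = 1, skull = 4, csf = 3)),
    gray_thickness = pspec$gray_thickness %||% 15,
    skin_jitter_sd = pspec$skin_jitter_sd %||% 0
  )
  if (!is.null(pspec$target)) {
    phantom <- insert_target(phantom, unlist(pspec$target$center),
                             pspec$target$width %||% 20,
                             pspec$target$height %||% 20)
  }
  sspec <- cfg$sweep
  sw <- frequency_sweep(sspec$f_min %||% 0.75e9, sspec$f_max %||% 2.55e9,
                        sspec$n_samples %||% 284L)
  mspec <- cfg$model
  model <- if (identical(mspec$kind, "fixed")) {
    permittivity_model("fixed", eps_fixed = mspec$eps %||% 45)
  } else {
    permittivity_model("variable")
  }
  grspec <- cfg$grid
  grid <- imaging_grid(grspec$extent %||% 300, grspec$extent %||% 300,
                       grspec$cell %||% 0.5)
  list(geometry = geometry, phantom = phantom, sweep = sw, model = model,
       grid = grid, seed = cfg$seed %||% 1L,
       snr_db = cfg$noise$snr_db %||% Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an experiment configuration (YAML)
#'
#' The configuration is a plain nested list (phantom, geometry, sweep, model,
#' noise, grid, seed) that round-trips losslessly through YAML.
#'
#' @param path YAML file.
#' @return `read_experiment_config` returns the configuration list.
#' @export
read_experiment_config <- function(path) yaml::read_yaml(path)

#' @rdname read_experiment_config
#' @param cfg configuration list.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`simulate <config.yaml> <out_dir>` - synthesize a scan
#'     dataset (Touchstone + manifest) from a config.}
#'   \item{reconstruct}{`reconstruct <config.yaml> <dataset_dir> <out_stem>
#'     [model] [eps]` - back-project a dataset into an image (PNG/CSV/JSON);
#'     `model` is `proposed` (default) or `fixed`, `eps` the fixed value.}
#'   \item{evaluate}{`evaluate <config.yaml> <dataset_dir> <out.json>` -
#'     reconstruct and report gamma/Q/delta against the configured target.}
#'   \item{safety}{`safety <out.csv>` - thermal rise curves over the band.}
#' }
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1L) stop("usage: hemoscan <simulate|reconstruct|evaluate|safety> ...")
    cmd <- argv[1L]
    args <- argv[-1L]
    if (cmd == "simulate") {
      cfg <- read_experiment_config(args[1L])
      ob <- config_objects(cfg)
      dat <- simulate_reflection(ob$phantom, ob$geometry, ob$sweep,
                                 forward_config(seed = ob$seed))
      if (is.finite(ob$snr_db)) {
        dat <- add_noise(dat, noise_config(ob$snr_db, seed = ob$seed))
      }
      write_dataset(dat, args[2L])
      message("wrote dataset (seed ", ob$seed, ") to ", args[2L])
    } else if (cmd == "reconstruct") {
      cfg <- read_experiment_config(args[1L])
      ob <- config_objects(cfg)
      dat <- read_dataset(args[2L])
      model <- ob$model
      if (length(args) >= 4L && args[4L] == "fixed") {
        model <- permittivity_model("fixed", eps_fixed =
                                      if (length(args) >= 5L) as.numeric(args[5L]) else 45)
      }
      img <- reconstruct_pipeline(dat, ob$phantom$boundary, ob$grid, model)
      write_image(img, args[3L])
      message("wrote image to ", args[3L], ".png (raw max ",
              signif(img$raw_max, 3), ")")
    } else if (cmd == "evaluate") {
      cfg <- read_experiment_config(args[1L])
      ob <- config_objects(cfg)
      if (is.null(ob$phantom$target)) stop("config has no target to evaluate")
      dat <- read_dataset(args[2L])
      img <- reconstruct_pipeline(dat, ob$phantom$boundary, ob$grid, ob$model)
      tgt <- target_region_rect(ob$grid, ob$phantom$target$center,
                                ob$phantom$target$width,
                                ob$phantom$target$height)
      met <- image_metrics(img, tgt)
      jsonlite::write_json(
        list(gamma = met$gamma, q = met$q_ratio, delta_mm = met$delta_mm,
             localized_correctly = met$localized_correctly),
        args[3L], auto_unbox = TRUE, digits = NA
      )
      message(sprintf("gamma = %.3f, Q = %.3f, delta = %.2f mm",
                      met$gamma, met$q_ratio, met$delta_mm))
    } else if (cmd == "safety") {
      freqs <- seq(0.75e9, 2.55e9, length.out = 7L)
      df <- band_sweep_temperature(freqs, rep(1 / 7, 7L))
      utils::write.csv(df, args[1L], row.names = FALSE)
      message("wrote thermal curves to ", args[1L])
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
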