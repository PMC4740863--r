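#' Effective head permittivity model
#'
#' The propagation model at the core of the imager: a single effective
#' dielectric constant that reproduces the true propagation delay through the
#' heterogeneous head, expressed as a function of penetration depth `d` from
#' the signal's point of entry. The variable model rises from a small value at
#' the entry (thin high-permittivity skin followed by low-permittivity fat and
#' skull), then saturates near `eps_max` as the signal reaches the CSF and
#' brain tissues:
#'
#' \deqn{\varepsilon_{eff}(d) = \varepsilon_{max}\,(1 - c_1 e^{-c_2 d / a})}
#'
#' where `a` is the normal distance from the entry point to the head center.
#' Band-wide defaults extracted from realistic head simulations are
#' `eps_max = 46.8`, `c1 = 0.75`, `c2 = 6.4`. The fixed model (`kind =
#' "fixed"`) is the legacy constant-permittivity assumption used by earlier
#' back-projection imagers.
#'
#' @param kind `"variable"` (the depth-dependent model) or `"fixed"`.
#' @param eps_max maximum (plateau) permittivity; >= 1.
#' @param c1 dimensionless shape constant in (0, 1]: relative depth of the
#'   entry dip.
#' @param c2 dimensionless shape constant > 0: saturation rate per normalized
#'   depth `d/a`.
#' @param eps_fixed constant permittivity, used only when `kind = "fixed"`.
#' @return An object of class `permittivity_model`.
#' @export
permittivity_model <- function(kind = c("variable", "fixed"), eps_max = 46.8,
                               c1 = 0.75, c2 = 6.4, eps_fixed = 45) {
  kind <- match.arg(kind)
  if (eps_max < 1) stop("eps_max must be >= 1")
  if (kind == "variable" && (c1 < 0 || c1 > 1 || c2 < 0)) {
    stop("shape constants must satisfy 0 <= c1 <= 1, c2 >= 0")
  }
  if (kind == "fixed" && (!is.numeric(eps_fixed) || eps_fixed < 1)) {
    stop("eps_fixed must be >= 1")
  }
  structure(
    list(kind = kind, eps_max = eps_max, c1 = c1, c2 = c2,
         eps_fixed = eps_fixed),
    class = "permittivity_model"
  )
}

#' @export
print.permittivity_model <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("<permittivity_model> fixed, eps = %.2f\n", x$eps_fixed))
  } else {
    cat(sprintf(
      "<permittivity_model> variable, eps_max = %.2f, c1 = %.3f, c2 = %.2f\n",
      x$eps_max, x$c1, x$c2
    ))
  }
  invisible(x)
}

#' Evaluate the effective permittivity at penetration depth d
#'
#' For the variable model the depth is clamped at `2a` (a ray cannot penetrate
#' farther than the far boundary), keeping the function constant beyond it.
#'
#' @param d penetration depth(s) from the point of entry (mm), >= 0.
#' @param a normal distance from the entry point to the head center (mm), > 0.
#' @param model a [permittivity_model()].
#' @return numeric vector of effective permittivities (>= 1 for physical
#'   parameter choices).
#' @export
effective_permittivity <- function(d, a, model) {
  if (any(d < 0)) stop("penetration depth must be >= 0")
  if (!is.numeric(a) || a <= 0) stop("normal depth a must be > 0")
  if (model$kind == "fixed") {
    return(rep(model$eps_fixed, length(d)))
  }
  dd <- pmin(d, 2 * a)
  model$eps_max * (1 - model$c1 * exp(-model$c2 * dd / a))
}

#' Extract effective permittivity from a differential arrival time
#'
#' Given the differential time of signal arrival `delta_t` between the entry
#' point and a probe at depth `d`, the effective permittivity of the traversed
#' path is `(c * delta_t / d)^2` with `c` the free-space speed of light.
#'
#' @param delta_t differential arrival time (seconds), > 0.
#' @param d distance from the entry point to the investigation point (mm), > 0.
#' @return dimensionless effective permittivity.
#' @export
extract_effective_permittivity <- function(delta_t, d) {
  if (any(delta_t <= 0) || any(d <= 0)) {
    stop("delta_t and d must be positive")
  }
  (C0 * delta_t / (d * 1e-3))^2
}

#' Per-entry-angle effective permittivity curve
#'
#' One curve of extracted effective permittivities versus penetration depth,
#' for a given point of entry (identified by its angle about the head center).
#'
#' @param entry_angle entry angle (degrees).
#' @param distances strictly increasing penetration depths (mm), all > 0.
#' @param eps_values effective permittivities (>= 1), same length.
#' @param normal_depth_a distance from the entry point to the head center (mm).
#' @return An object of class `permittivity_curve`.
#' @export
permittivity_curve <- function(entry_angle, distances, eps_values,
                               normal_depth_a) {
  if (length(distances) != length(eps_values)) {
    stop("distances and eps_values must have equal length")
  }
  if (any(distances <= 0) || any(diff(distances) <= 0)) {
    stop("distances must be strictly increasing and positive")
  }
  if (any(eps_values < 1)) stop("eps_values must be >= 1")
  if (normal_depth_a <= 0) stop("normal_depth_a must be positive")
  structure(
    list(entry_angle = entry_angle, distances = as.numeric(distances),
         eps_values = as.numeric(eps_values),
         normal_depth_a = normal_depth_a),
    class = "permittivity_curve"
  )
}

#' Fit the unified effective permittivity model to per-angle curves
#'
#' Averages the per-entry-angle curves onto a common normalized-depth axis
#' (`u = d / a`, linear interpolation) and least-squares fits the three model
#' parameters `(eps_max, c1, c2)`. The fit is deterministic: unweighted
#' nonlinear least squares started from three fixed initial guesses, keeping
#' the solution with the lowest residual sum of squares.
#'
#' @param curves list of [permittivity_curve()] objects (>= 1, each with >= 3
#'   points).
#' @param n_grid number of normalized-depth samples used for averaging.
#' @return A [permittivity_model()] with attributes `residual_rms` (RMS of fit
#'   residuals) and `n_points`.
#' @export
fit_permittivity_model <- function(curves, n_grid = 100L) {
  if (length(curves) < 1L) stop("need at least one curve")
  if (any(vapply(curves, function(cv) length(cv$distances), 1L) < 3L)) {
    stop("each curve needs at least 3 points")
  }
  u_lists <- lapply(curves, function(cv) cv$distances / cv$normal_depth_a)
  u_min <- max(vapply(u_lists, min, 1))
  u_max <- min(vapply(u_lists, max, 1))
  if (u_max <= u_min) stop("curves do not overlap in normalized depth")
  u <- seq(u_min, u_max, length.out = n_grid)
  eps_mat <- vapply(
    seq_along(curves),
    function(i) stats::approx(u_lists[[i]], curves[[i]]$eps_values, u)$y,
    numeric(n_grid)
  )
  eps_avg <- rowMeans(eps_mat)

  df <- data.frame(u = u, eps = eps_avg)
  starts <- list(
    c(eps_max = 46.8, c1 = 0.75, c2 = 6.4),
    c(eps_max = max(eps_avg), c1 = 0.5, c2 = 3),
    c(eps_max = 1.05 * max(eps_avg), c1 = 0.9, c2 = 10)
  )
  best <- NULL
  best_ss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        eps ~ eps_max * (1 - c1 * exp(-c2 * u)),
        data = df, start = as.list(s),
        lower = c(eps_max = 1, c1 = 0, c2 = 0),
        upper = c(eps_max = Inf, c1 = 1, c2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
  }
  if (is.null(best)) {
    # degenerate (e.g. constant) averaged curve: flat model at its mean
    out <- permittivity_model("variable", eps_max = mean(eps_avg), c1 = 0,
                              c2 = 1)
    attr(out, "residual_rms") <- stats::sd(eps_avg)
    attr(out, "n_points") <- n_grid
    return(out)
  }
  cf <- stats::coef(best)
  out <- permittivity_model("variable", eps_max = cf[["eps_max"]],
                            c1 = cf[["c1"]], c2 = cf[["c2"]])
  attr(out, "residual_rms") <- sqrt(best_ss / n_grid)
  attr(out, "n_points") <- n_grid
  out
}

#' Write / read permittivity curves as CSV
#'
#' Columns: `entry_angle_deg`, `a_mm`, `d_mm`, `eps_eff`; one row per sample,
#' curves identified by their entry angle.
#'
#' @param curves list of [permittivity_curve()].
#' @param path CSV file path.
#' @return `read_permittivity_curves` returns a list of curves.
#' @export
write_permittivity_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(
      entry_angle_deg = cv$entry_angle, a_mm = cv$normal_depth_a,
      d_mm = cv$distances, eps_eff = cv$eps_values
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_permittivity_curves
#' @export
read_permittivity_curves <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$entry_angle_deg), function(g) {
    g <- g[order(g$d_mm), ]
    permittivity_curve(g$entry_angle_deg[1L], g$d_mm, g$eps_eff, g$a_mm[1L])
  })
}

#' Serialize / restore a permittivity model as YAML
#' @param model a [permittivity_model()].
#' @param path YAML file path.
#' @export
write_permittivity_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_permittivity_model
#' @export
read_permittivity_model <- function(path) {
  x <- yaml::read_yaml(path)
  permittivity_model(x$kind, eps_max = x$eps_max, c1 = x$c1, c2 = x$c2,
                     eps_fixed = x$eps_fixed)
}
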