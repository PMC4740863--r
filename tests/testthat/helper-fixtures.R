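# Shared small fixtures, built in code.

C0 <- 299792458

circle_boundary <- function(r = 80, n = 360L, center = c(0, 0)) {
  ellipse_boundary(r, r, n = n, center = center)
}

# proper (interior) intersection test for two segments, used by the
# visibility oracle
segments_properly_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1)
  d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1)
  d4 <- orient(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# brute-force visibility: vertex i is visible from the antenna if the open
# segment antenna->vertex crosses no polygon edge properly
visible_vertices_oracle <- function(antenna, poly) {
  n <- nrow(poly)
  vapply(seq_len(n), function(i) {
    v <- poly[i, ]
    for (j in seq_len(n)) {
      jn <- if (j == n) 1L else j + 1L
      if (j == i || jn == i) next
      if (segments_properly_intersect(antenna, v, poly[j, ], poly[jn, ])) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

# minimal time_signals object built from a raw complex matrix
make_time_signals <- function(samples, sweep, geometry, k = ncol(samples)) {
  dt <- 1 / (k * sweep$df)
  tax <- (seq_len(k) - 1L) * dt
  structure(
    list(samples = samples, time_axis = tax,
         range_axis = C0 * tax / 2 * 1e3, sweep = sweep,
         geometry = geometry, window = "none", k_samples = k,
         zero_flags = rep(FALSE, nrow(samples)), normalized = FALSE),
    class = "time_signals"
  )
}

# dataset whose channels contain a single unit echo at given round-trip delays
echo_dataset <- function(taus, sweep, geometry) {
  s11 <- t(vapply(taus, function(tau) exp(-2i * pi * sweep$frequencies * tau),
                  complex(sweep$n_samples)))
  reflection_dataset(s11, sweep, geometry)
}
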