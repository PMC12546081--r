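# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored binary fixtures.

# segment -> centerline -> tortuosity on a tube phantom, one call
extract_from_phantom <- function(ph, step_mm = 0.5, ...) {
  seg <- threshold_segment(ph$volume, ph$foreground_intensity / 2)
  src <- round(physical_to_index(ph$volume, ph$truth_centerline$points[1, ]))
  extract_centerline(select_component(seg, src), src, step_mm = step_mm, ...)
}

# straight-segment centerline along a unit direction
line_centerline <- function(length_mm, dir = c(0, 0, 1), n = 101L,
                            start = c(0, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(0, length_mm, length.out = n)
  centerline(cbind(start[1] + s * dir[1], start[2] + s * dir[2],
                   start[3] + s * dir[3]))
}

# planar arc centerline of given radius and angular span (radians)
arc_centerline <- function(radius_mm, span_rad, n = 400L) {
  th <- seq(0, span_rad, length.out = n)
  centerline(cbind(radius_mm * cos(th), radius_mm * sin(th), 0))
}

# independent 26-neighbour Dijkstra oracle for geodesic time on a lattice;
# slow but simple: edge traversal time = physical length x trapezoidal
# mean of the endpoint slownesses (the 1D travel-time quadrature)
dijkstra26 <- function(speed, spacing, source) {
  d <- dim(speed)
  n <- prod(d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  elen <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
               (offs[, 3] * spacing[3])^2)
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  lin <- function(v) v[1] + d[1] * (v[2] - 1L + d[2] * (v[3] - 1L))
  dist[lin(source)] <- 0
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    uv <- arrayInd(u, d)[1, ]
    su <- speed[u]
    for (m in seq_len(nrow(offs))) {
      vv <- uv + offs[m, ]
      if (any(vv < 1L) || any(vv > d)) next
      v <- lin(vv)
      if (done[v]) next
      sv <- speed[v]
      if (!is.finite(sv) || sv <= 0) next
      w <- elen[m] * (1 / su + 1 / sv) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  array(dist, d)
}

# numeric arc-length oracle for an analytic curve between parameters,
# independent of gen_curve's trapezoid (uses stats::integrate)
sinusoid_arc_length <- function(length_mm, amplitude_mm, periods) {
  w <- 2 * pi * periods
  stats::integrate(function(t)
    sqrt((amplitude_mm * w * cos(w * t))^2 + length_mm^2),
    0, 1, rel.tol = 1e-10)$value
}
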