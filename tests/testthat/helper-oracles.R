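# Independent oracles and fixture builders. These deliberately avoid the
# package's internal code paths: rasterization and counting are done with
# plain double loops / direct arithmetic so they can arbitrate.

# Render a filled ellipse mask (pixel-centre membership test), independent
# of the generator's paint_ellipse.
render_ellipse_mask <- function(a, b, phi_deg, pad = 6) {
  side <- ceiling(2 * a) + 2 * pad
  cx <- cy <- (side + 1) / 2
  th <- phi_deg * pi / 180
  m <- matrix(FALSE, side, side)
  for (r in seq_len(side)) {
    for (cc in seq_len(side)) {
      dx <- cc - cx
      dy <- -(r - cy)
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      if (u * u + v * v <= 1) m[r, cc] <- TRUE
    }
  }
  m
}

render_disk_mask <- function(radius, pad = 4) {
  render_ellipse_mask(radius, radius, 0, pad = pad)
}

# Brute-force box counting: explicit double loop over grid cells anchored
# at the image origin.
brute_force_box_count <- function(mask, eps) {
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  for (br in seq_len(ceiling(h / eps))) {
    for (bc in seq_len(ceiling(w / eps))) {
      rows <- ((br - 1L) * eps + 1L):min(br * eps, h)
      cols <- ((bc - 1L) * eps + 1L):min(bc * eps, w)
      if (any(mask[rows, cols])) n <- n + 1L
    }
  }
  n
}

# Brute-force inner-boundary pixel count: foreground pixels with at least
# one of the 8 neighbours outside the foreground (or on the image border).
brute_force_edge_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      if (!mask[r, cc]) next
      boundary <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; ccc <- cc + dc
          if (rr < 1 || rr > h || ccc < 1 || ccc > w || !mask[rr, ccc])
            boundary <- TRUE
        }
      }
      if (boundary) n <- n + 1L
    }
  }
  n
}

# von Mises class mass by direct numerical integration of the angular
# density on 2*phi: P(cos(2 phi) <= -0.5) = P(|2 phi - 180| <= 60) under
# vonMises(180, kappa) on (-180, 180].
vm_perpendicular_mass <- function(kappa) {
  dens <- function(psi) exp(kappa * cos((psi - 180) * pi / 180))
  num <- integrate(dens, 120, 240, rel.tol = 1e-10)$value
  den <- integrate(dens, -180, 180, rel.tol = 1e-10)$value
  num / den
}

# Two-sided pooled-variance t-test p-value via numerical integration of the
# t density (independent of pt()).
pooled_t_p_numeric <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail_mass <- integrate(dens, abs(tstat), Inf, rel.tol = 1e-13,
                         abs.tol = 1e-14)$value
  list(t = tstat, df = df, p = 2 * tail_mass)
}
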