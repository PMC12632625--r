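# Shared fixtures: a typical titration design and small independent
# oracles used to cross-check the geometric and regression code.

default_protocol <- function(n_inj = 20) {
  titration_protocol(cell_volume_ul = 200, cell_conc = 1e-3,
                     syringe_conc = 1e-2,
                     injection_volumes_ul = rep(2, n_inj))
}

# Brute-force plane-fit oracle: scan plane normals over a spherical grid,
# refining around the best direction. Returns the minimal rms
# perpendicular residual of a plane through the centroid.
plane_rms_grid_oracle <- function(coords, levels = 4) {
  ctr <- colMeans(coords)
  centered <- sweep(coords, 2, ctr)
  rss <- function(theta, phi) {
    n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    sum((centered %*% n)^2)
  }
  th_range <- c(0, pi); ph_range <- c(0, 2 * pi)
  best <- c(pi / 2, pi)
  step <- pi / 60
  for (lvl in seq_len(levels)) {
    th <- seq(max(th_range[1], best[1] - 30 * step),
              min(th_range[2], best[1] + 30 * step), by = step)
    ph <- seq(best[2] - 30 * step, best[2] + 30 * step, by = step)
    vals <- outer(th, ph, Vectorize(rss))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(th[idx[1]], ph[idx[2]])
    step <- step / 10
  }
  sqrt(rss(best[1], best[2]) / nrow(coords))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
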