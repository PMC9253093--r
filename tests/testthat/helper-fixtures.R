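# shared helpers: random rigid transforms, cached conch models, oracles

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# cache the (deterministic) demo conch models across test files
.conch_cache <- new.env(parent = emptyenv())
cached_demo_model <- function(name, step_deg = 4, n_section = 32) {
  key <- paste(name, step_deg, n_section)
  if (is.null(.conch_cache[[key]]))
    .conch_cache[[key]] <- conch_model(
      demo_conch_specs(step_deg = step_deg, n_section = n_section)[[name]])
  .conch_cache[[key]]
}

# brute-force volume/centroid oracle for unions of axis-aligned boxes;
# `cell` should divide the box edge coordinates for an edge-aligned grid
box_union_oracle <- function(boxes, cell = 0.025) {
  lo <- apply(sapply(boxes, `[[`, "lower"), 1, min)
  hi <- apply(sapply(boxes, `[[`, "upper"), 1, max)
  gx <- lo[1] + (seq_len(round((hi[1] - lo[1]) / cell)) - 0.5) * cell
  gy <- lo[2] + (seq_len(round((hi[2] - lo[2]) / cell)) - 0.5) * cell
  gz <- lo[3] + (seq_len(round((hi[3] - lo[3]) / cell)) - 0.5) * cell
  g <- expand.grid(x = gx, y = gy, z = gz)
  inside <- rep(FALSE, nrow(g))
  for (b in boxes)
    inside <- inside | (g$x >= b$lower[1] & g$x <= b$upper[1] &
                          g$y >= b$lower[2] & g$y <= b$upper[2] &
                          g$z >= b$lower[3] & g$z <= b$upper[3])
  list(volume = sum(inside) * cell^3,
       centroid = c(mean(g$x[inside]), mean(g$y[inside]), mean(g$z[inside])))
}

# parity ray-casting volume oracle: casts x-parallel rays through a
# (ny x nz) grid of columns and sums the inside interval lengths
raycast_volume <- function(mesh, n = 96L) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ry <- range(v[, 2]); rz <- range(v[, 3])
  eps_y <- diff(ry) * 1e-4; eps_z <- diff(rz) * 1e-4
  ys <- seq(ry[1] + eps_y, ry[2] - eps_y, length.out = n) + eps_y * 0.37
  zs <- seq(rz[1] + eps_z, rz[2] - eps_z, length.out = n) + eps_z * 0.41
  # precompute 2D (y,z) edge data for projected triangles
  total <- 0
  cell <- (ys[2] - ys[1]) * (zs[2] - zs[1])
  for (yq in ys) {
    # triangles whose y-range covers yq
    sel <- pmin(a[, 2], b[, 2], c_[, 2]) <= yq &
      pmax(a[, 2], b[, 2], c_[, 2]) >= yq
    if (!any(sel)) next
    aa <- a[sel, , drop = FALSE]
    bb <- b[sel, , drop = FALSE]
    cc <- c_[sel, , drop = FALSE]
    for (zq in zs) {
      # ray (t, yq, zq), direction +x: solve barycentric in (y, z)
      d00 <- bb[, 2] - aa[, 2]; d01 <- cc[, 2] - aa[, 2]
      d10 <- bb[, 3] - aa[, 3]; d11 <- cc[, 3] - aa[, 3]
      det <- d00 * d11 - d01 * d10
      ok <- abs(det) > 1e-14
      if (!any(ok)) next
      py <- yq - aa[, 2]; pz <- zq - aa[, 3]
      u <- (py * d11 - pz * d01) / det
      w <- (pz * d00 - py * d10) / det
      hit <- ok & u >= 0 & w >= 0 & (u + w) <= 1
      if (!any(hit)) next
      xs <- aa[hit, 1] + u[hit] * (bb[hit, 1] - aa[hit, 1]) +
        w[hit] * (cc[hit, 1] - aa[hit, 1])
      xs <- sort(xs)
      if (length(xs) %% 2L == 0L)
        total <- total + sum(xs[seq(2, length(xs), 2)] -
                               xs[seq(1, length(xs), 2)]) * cell
    }
  }
  total
}

# analytic kinematic trial builders (not ODE-based)
synthetic_rotation_trial <- function(total_deg, n_frames = 240,
                                     fps = 23.975, noise_sd = 0,
                                     baseline = 0.12, seed = 1) {
  t <- (seq_len(n_frames) - 1) / fps
  s <- (1 - cos(pi * t / max(t))) / 2 # smooth 0 -> 1
  psi <- total_deg * pi / 180 * s
  p1 <- cbind(baseline / 2 * cos(psi), baseline / 2 * sin(psi),
              rep(0.1, n_frames))
  p2 <- cbind(-baseline / 2 * cos(psi), -baseline / 2 * sin(psi),
              rep(0.1, n_frames))
  if (noise_sd > 0) {
    set.seed(seed)
    p1 <- p1 + matrix(rnorm(length(p1), 0, noise_sd), ncol = 3)
    p2 <- p2 + matrix(rnorm(length(p2), 0, noise_sd), ncol = 3)
  }
  df <- data.frame(frame = seq_len(n_frames) - 1L, t_s = t,
                   p1x = p1[, 1], p1y = p1[, 2], p1z = p1[, 3],
                   p2x = p2[, 1], p2y = p2[, 2], p2z = p2[, 3],
                   motor_on = as.integer(t < 1))
  attr(df, "fps") <- fps
  class(df) <- c("tracked_trial", "data.frame")
  df
}

synthetic_path_trial <- function(mid, t, motor_on = rep(0L, length(t)),
                                 offset = c(0, 0, 0.05)) {
  p1 <- sweep(mid, 2, offset, "+")
  p2 <- sweep(mid, 2, -offset, "+")
  df <- data.frame(frame = seq_along(t) - 1L, t_s = t,
                   p1x = p1[, 1], p1y = p1[, 2], p1z = p1[, 3],
                   p2x = p2[, 1], p2y = p2[, 2], p2z = p2[, 3],
                   motor_on = as.integer(motor_on))
  attr(df, "fps") <- 1 / median(diff(t))
  class(df) <- c("tracked_trial", "data.frame")
  df
}
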