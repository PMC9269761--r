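# Independent brute-force oracles used across the suite.  These are written
# as plain nested loops (or numerical differentiation), deliberately sharing
# no code with the package internals they check.

# Central differences interior, one-sided at borders, by explicit loops.
loop_gradient <- function(f) {
  h <- nrow(f); w <- ncol(f)
  gx <- gy <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gx[i, j] <- if (j == 1) f[i, 2] - f[i, 1]
        else if (j == w) f[i, w] - f[i, w - 1]
        else (f[i, j + 1] - f[i, j - 1]) / 2
      gy[i, j] <- if (i == 1) f[2, j] - f[1, j]
        else if (i == h) f[h, j] - f[h - 1, j]
        else (f[i + 1, j] - f[i - 1, j]) / 2
    }
  }
  list(gx = gx, gy = gy)
}

# 5-point Laplacian with replicated borders, by explicit loops.
loop_laplacian <- function(f) {
  h <- nrow(f); w <- ncol(f)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      up <- f[max(i - 1, 1), j]; dn <- f[min(i + 1, h), j]
      lf <- f[i, max(j - 1, 1)]; rt <- f[i, min(j + 1, w)]
      out[i, j] <- up + dn + lf + rt - 4 * f[i, j]
    }
  }
  out
}

# Direct windowed inverse-square-law sum (charge model), by explicit loops.
loop_vef <- function(f, t) {
  h <- nrow(f); w <- ncol(f)
  u <- v <- matrix(0, h, w)
  for (i0 in seq_len(h)) {
    for (j0 in seq_len(w)) {
      for (di in -t:t) {
        for (dj in -t:t) {
          if (di == 0 && dj == 0) next
          i <- i0 + di; j <- j0 + dj
          if (i < 1 || i > h || j < 1 || j > w) next
          r3 <- (di^2 + dj^2)^1.5
          u[i0, j0] <- u[i0, j0] + dj / r3 * f[i, j]
          v[i0, j0] <- v[i0, j0] + di / r3 * f[i, j]
        }
      }
    }
  }
  list(u = u, v = v)
}

# One explicit GVF step from (u, v), by explicit loops.
loop_gvf_step <- function(u, v, em, mu, dt) {
  lap_u <- loop_laplacian(u); lap_v <- loop_laplacian(v)
  list(u = u + dt * (mu * lap_u - em$gmag2 * (u - em$fx)),
       v = v + dt * (mu * lap_v - em$gmag2 * (v - em$fy)))
}

# Discrete anisotropic smoothness energy by loops: forward differences,
# tensor at the pixel.  Used to check div(D grad u) by numerical
# differentiation (a route fully independent of the stencil algebra).
loop_smooth_energy <- function(u, a, b, cc) {
  h <- nrow(u); w <- ncol(u)
  e <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ux <- if (j < w) u[i, j + 1] - u[i, j] else 0
      uy <- if (i < h) u[i + 1, j] - u[i, j] else 0
      e <- e + a[i, j] * ux^2 + 2 * b[i, j] * ux * uy + cc[i, j] * uy^2
    }
  }
  e
}

# div(D grad u) = -(1/2) dE/du by central-difference perturbation.
numdiff_div_tensor <- function(u, a, b, cc, h_step = 1e-6) {
  out <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(u))) {
    for (j in seq_len(ncol(u))) {
      up <- u; up[i, j] <- up[i, j] + h_step
      um <- u; um[i, j] <- um[i, j] - h_step
      de <- (loop_smooth_energy(up, a, b, cc) -
               loop_smooth_energy(um, a, b, cc)) / (2 * h_step)
      out[i, j] <- -de / 2
    }
  }
  out
}

# Bilinear interpolation at one point, by direct formula.
loop_bilinear <- function(m, x, y) {
  w <- ncol(m); h <- nrow(m)
  x <- min(max(x, 0), w - 1); y <- min(max(y, 0), h - 1)
  x0 <- min(floor(x), w - 2); y0 <- min(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  m[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
    m[y0 + 1, x0 + 2] * fx * (1 - fy) +
    m[y0 + 2, x0 + 1] * (1 - fx) * fy +
    m[y0 + 2, x0 + 2] * fx * fy
}

# Shoelace area of a polygon.
shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Do two segments (p1,p2) and (p3,p4) properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# Is a closed polygon simple (no proper self-intersections)?
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (segments_intersect(poly[i, ], poly[nxt[i], ],
                             poly[j, ], poly[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# A small random edge map built through the public constructor.
rand_edge_map <- function(h, w, seed, sigma = 0) {
  set.seed(seed)
  img <- matrix(stats::runif(h * w), h, w)
  edge_map(hbgvf::normalize_intensity(img), sigma = sigma)
}
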