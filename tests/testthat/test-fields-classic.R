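test_that("GVF of a blank edge map is the zero fixed point", {
  em <- edge_map(matrix(0.5, 8, 8), sigma = 1)
  fld <- gvf(em, n_iter = 25)
  expect_equal(fld$u, matrix(0, 8, 8))
  expect_equal(fld$v, matrix(0, 8, 8))
})

test_that("one GVF step matches the explicit-loop update oracle", {
  em <- rand_edge_map(5, 5, seed = 11)
  fld <- gvf(em, mu = 0.2, dt = 1, n_iter = 1)
  o <- loop_gvf_step(em$fx, em$fy, em, mu = 0.2, dt = 1)
  expect_equal(fld$u, o$u, tolerance = 1e-14)
  expect_equal(fld$v, o$v, tolerance = 1e-14)
})

test_that("GVF rejects unstable time steps", {
  em <- rand_edge_map(5, 5, seed = 1)
  expect_error(gvf(em, mu = 0.3, dt = 1), "unstable")
  expect_error(ngvf(em, mu = 0.6, dt = 1), "unstable")
  expect_error(ggvf(em, dt = 0.3), "unstable")
  expect_error(cn_ggvf(em, dt = 0.3), "unstable")
})

test_that("converged GVF across a vertical step edge is symmetric with v ~ 0", {
  img <- matrix(0, 16, 16); img[, 9:16] <- 1
  em <- edge_map(img, sigma = 1)
  fld <- gvf(em, n_iter = 256)
  mid <- 8  # edge ridge sits between columns 8 and 9 (1-based)
  # u antisymmetric about the edge (pointing toward it from both sides)
  expect_equal(fld$u[, mid - 2], -fld$u[, mid + 3], tolerance = 1e-8)
  expect_equal(fld$u[, mid - 4], -fld$u[, mid + 5], tolerance = 1e-8)
  expect_lt(max(abs(fld$v)), 1e-8)
  # magnitude decays with distance from the edge
  expect_gt(abs(fld$u[8, mid - 1]), abs(fld$u[8, mid - 5]))
})

test_that("GGVF weights follow the stated exponential form", {
  em <- rand_edge_map(6, 6, seed = 3)
  # at |grad f| = k the diffusion weight is exp(-1)
  k <- sqrt(max(em$gmag2))  # pick k so the max-gradient pixel sits at k
  g <- exp(-em$gmag2 / k^2)
  i <- which.max(em$gmag2)
  expect_equal(g[i], exp(-1))
  # blank edge map: g == 1 everywhere, pure Laplacian smoothing
  em0 <- edge_map(matrix(0.5, 6, 6), sigma = 0)
  fld <- ggvf(em0, k = 0.5, dt = 0.2, n_iter = 5)
  expect_equal(fld$u, matrix(0, 6, 6))  # zero init stays zero under smoothing
})

test_that("one GGVF step matches the weighted-update loop oracle", {
  em <- rand_edge_map(5, 5, seed = 23)
  k <- 0.5; dt <- 0.2
  fld <- ggvf(em, k = k, dt = dt, n_iter = 1)
  g <- exp(-em$gmag2 / k^2); h <- 1 - g
  lap_u <- loop_laplacian(em$fx); lap_v <- loop_laplacian(em$fy)
  expect_equal(fld$u, em$fx + dt * (g * lap_u - h * (em$fx - em$fx)),
               tolerance = 1e-14)
  expect_equal(fld$v, em$fy + dt * (g * lap_v - h * (em$fy - em$fy)),
               tolerance = 1e-14)
  # the magnitude exponent form is exposed and differs
  fld2 <- ggvf(em, k = k, dt = dt, n_iter = 1, form = "magnitude")
  expect_false(isTRUE(all.equal(fld$u, fld2$u)))
})

test_that("GVF equals GGVF-style update with constant weights", {
  # structural check: the GVF update is the g = mu, h = |grad f|^2 special
  # case of the weighted update
  em <- rand_edge_map(6, 6, seed = 5)
  mu <- 0.2; dt <- 1
  fld <- gvf(em, mu = mu, dt = dt, n_iter = 3)
  u <- em$fx; v <- em$fy
  for (i in 1:3) {
    u <- u + dt * (mu * loop_laplacian(u) - em$gmag2 * (u - em$fx))
    v <- v + dt * (mu * loop_laplacian(v) - em$gmag2 * (v - em$fy))
  }
  expect_equal(fld$u, u, tolerance = 1e-13)
  expect_equal(fld$v, v, tolerance = 1e-13)
})

test_that("VEF of a single charge follows the inverse-square law", {
  img <- matrix(0, 11, 11)
  em <- edge_map(img, sigma = 0)
  em$f[6, 6] <- 1  # single unit charge at (x, y) = (5, 5)
  fld <- vef_direct(em, t = 5)
  # at (2, 5): offset (+3, 0), r = 3: force (1/9, 0) toward the charge
  expect_equal(fld$u[6, 3], 3 / 27)
  expect_equal(fld$v[6, 3], 0)
  # at (5, 9): offset (0, -4): force (0, -1/16)
  expect_equal(fld$v[10, 6], -4 / 64)
  # direction: always along the ray toward the charge
  expect_gt(fld$u[6, 4], 0)   # left of charge, points right
  expect_lt(fld$u[6, 8], 0)   # right of charge, points left
})

test_that("VEF vanishes for a blank map and at symmetry midpoints", {
  em <- edge_map(matrix(0.5, 9, 9), sigma = 0)
  fld <- vef_direct(em, t = 3)
  expect_equal(fld$u, matrix(0, 9, 9))
  # two equal charges symmetric about the midpoint cancel there
  em$f[5, 3] <- 1; em$f[5, 7] <- 1
  fld <- vef_direct(em, t = 4)
  expect_equal(fld$u[5, 5], 0)
  expect_equal(fld$v[5, 5], 0)
})

test_that("FFT and direct VEF agree to floating-point tolerance", {
  for (seed in c(2, 9)) {
    em <- rand_edge_map(16, 16, seed = seed)
    fd <- vef_direct(em, t = 5)
    ff <- vef_fft(em, t = 5)
    scale <- max(abs(fd$u), abs(fd$v))
    expect_lt(max(abs(ff$u - fd$u)) / scale, 1e-9)
    expect_lt(max(abs(ff$v - fd$v)) / scale, 1e-9)
  }
  # and the direct evaluation itself matches the nested-loop charge sum
  em <- rand_edge_map(8, 8, seed = 4)
  fd <- vef_direct(em, t = 3)
  o <- loop_vef(em$f, t = 3)
  expect_equal(fd$u, o$u, tolerance = 1e-12)
  expect_equal(fd$v, o$v, tolerance = 1e-12)
})

test_that("an impulse recovers the VEF kernel through the FFT path", {
  em <- edge_map(matrix(0, 9, 9), sigma = 0)
  em$f[5, 5] <- 1
  t <- 3
  ff <- vef_fft(em, t = t)
  for (di in -t:t) {
    for (dj in -t:t) {
      expected <- if (di == 0 && dj == 0) 0 else -dj / (di^2 + dj^2)^1.5
      # at probe (5 - dj, 5 - di) the charge offset is (dj, dk): u = dj/r^3
      expect_equal(ff$u[5 - di, 5 - dj], dj / max((di^2 + dj^2)^1.5, 1),
                   tolerance = 1e-10)
    }
  }
})

test_that("tangent/normal decomposition has the right closed forms", {
  w <- 9; h <- 9
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  # u = x^2: gradient along x, so uNN = 2, uTT = 0 at interior pixels
  d <- tangent_normal(xs^2)
  inner <- 2:(h - 1)
  expect_equal(d$uNN[inner, 3:(w - 2)], matrix(2, length(inner), w - 4))
  expect_equal(d$uTT[inner, 3:(w - 2)], matrix(0, length(inner), w - 4))
  # u = x^2 + y^2 away from the origin: both directional curvatures are 2
  u <- (xs - 0.3)^2 + (ys - 0.4)^2  # offset so no grid point has zero gradient
  d <- tangent_normal(u)
  expect_equal(d$uNN[3:(h - 2), 3:(w - 2)], matrix(2, h - 4, w - 4),
               tolerance = 1e-10)
  expect_equal(d$uTT[3:(h - 2), 3:(w - 2)], matrix(2, h - 4, w - 4),
               tolerance = 1e-10)
})

test_that("uTT + uNN reproduces the 5-point Laplacian everywhere", {
  for (seed in c(1, 6)) {
    set.seed(seed)
    u <- gaussian_smooth(matrix(rnorm(15 * 13), 15, 13), 1)
    d <- tangent_normal(u)
    expect_equal(d$uTT + d$uNN, loop_laplacian(u), tolerance = 1e-6)
  }
  # degenerate (constant) field: split evenly, still summing to the Laplacian
  d <- tangent_normal(matrix(1, 5, 5))
  expect_equal(d$uNN, matrix(0, 5, 5))
  expect_equal(d$uTT, matrix(0, 5, 5))
})

test_that("one NGVF step matches the decomposition-based loop oracle", {
  em <- rand_edge_map(5, 5, seed = 31)
  mu <- 0.2; dt <- 1
  fld <- ngvf(em, mu = mu, dt = dt, n_iter = 1)
  # oracle: second directional derivative along the gradient via the
  # pointwise formula, then the explicit update
  dir_second <- function(u) {
    g <- loop_gradient(u)
    uxx <- uyy <- uxy <- matrix(0, nrow(u), ncol(u))
    h <- nrow(u); w <- ncol(u)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        uxx[i, j] <- u[i, max(j - 1, 1)] + u[i, min(j + 1, w)] - 2 * u[i, j]
        uyy[i, j] <- u[max(i - 1, 1), j] + u[min(i + 1, h), j] - 2 * u[i, j]
      }
    }
    uxy <- loop_gradient(g$gx)$gy
    m2 <- g$gx^2 + g$gy^2
    out <- (g$gx^2 * uxx + 2 * g$gx * g$gy * uxy + g$gy^2 * uyy) /
      ifelse(m2 < 1e-12, 1, m2)
    out[m2 < 1e-12] <- ((uxx + uyy) / 2)[m2 < 1e-12]
    out
  }
  expect_equal(fld$u,
               em$fx + dt * (mu * dir_second(em$fx) -
                               em$gmag2 * (em$fx - em$fx)),
               tolerance = 1e-13)
  expect_equal(fld$v,
               em$fy + dt * (mu * dir_second(em$fy) -
                               em$gmag2 * (em$fy - em$fy)),
               tolerance = 1e-13)
})

test_that("NGVF of a blank edge map stays at the zero fixed point", {
  em <- edge_map(matrix(0.5, 8, 8), sigma = 1)
  fld <- ngvf(em, n_iter = 10)
  expect_equal(fld$u, matrix(0, 8, 8))
})

test_that("component sign maps components to {-1, 0, 1} and is idempotent", {
  em <- rand_edge_map(6, 6, seed = 8)
  fld <- gvf(em, n_iter = 5)
  s1 <- component_sign(fld)
  expect_true(all(s1$u %in% c(-1, 0, 1)))
  expect_true(all(s1$v %in% c(-1, 0, 1)))
  s2 <- component_sign(s1)
  expect_equal(s2$u, s1$u)
  expect_equal(s2$v, s1$v)
  # the sign definition itself
  f2 <- fld; f2$u[1, 1] <- 0.3; f2$v[1, 1] <- -2.1
  s <- component_sign(f2)
  expect_equal(unname(c(s$u[1, 1], s$v[1, 1])), c(1, -1))
  f2$u[2, 2] <- 0; f2$v[2, 2] <- 0
  s <- component_sign(f2)
  expect_equal(unname(c(s$u[2, 2], s$v[2, 2])), c(0, 0))
})

test_that("CN-GGVF output is sign-normalized and blank input maps to zero", {
  em <- rand_edge_map(6, 6, seed = 13)
  fld <- cn_ggvf(em, n_iter = 10)
  expect_true(all(fld$u %in% c(-1, 0, 1)))
  expect_true(all(fld$v %in% c(-1, 0, 1)))
  em0 <- edge_map(matrix(0.5, 6, 6), sigma = 1)
  f0 <- cn_ggvf(em0, n_iter = 5)
  expect_equal(f0$u, matrix(0, 6, 6))
})

test_that("one pre-normalization CN-GGVF step matches the mixed-weight oracle", {
  em <- rand_edge_map(5, 5, seed = 17)
  k <- 0.5; dt <- 0.2
  fld <- cn_ggvf(em, k = k, dt = dt, n_iter = 1)
  g <- exp(-em$gmag2 / k^2); h <- 1 - g
  step_one <- function(u0, fx) {
    d <- tangent_normal(u0)
    u0 + dt * (g * (g * d$uNN + h * d$uTT) - h * (u0 - fx))
  }
  expect_equal(fld$u, sign(step_one(em$fx, em$fx)))
  expect_equal(fld$v, sign(step_one(em$fy, em$fy)))
})

test_that("strong data term pins converged fields to the edge gradient", {
  # where |grad f|^2 is large and mu small, (u, v) -> (fx, fy)
  img <- matrix(0, 12, 12); img[, 7:12] <- 1
  em <- edge_map(img, sigma = 1)
  fld <- gvf(em, mu = 0.002, dt = 5, n_iter = 3000)
  strong <- em$gmag2 > 0.5 * max(em$gmag2)
  expect_lt(max(abs(fld$u[strong] - em$fx[strong])), 0.01)
})

test_that("field computations are bit-reproducible", {
  em <- rand_edge_map(8, 8, seed = 19, sigma = 1)
  expect_identical(gvf(em, n_iter = 30), gvf(em, n_iter = 30))
  expect_identical(ggvf(em, n_iter = 30), ggvf(em, n_iter = 30))
  expect_identical(vef_fft(em, t = 3), vef_fft(em, t = 3))
  expect_identical(cn_ggvf(em, n_iter = 15), cn_ggvf(em, n_iter = 15))
})

test_that("discrete GVF energy is non-increasing at a stable step", {
  em <- rand_edge_map(10, 10, seed = 21, sigma = 1)
  fld <- gvf(em, mu = 0.2, dt = 1, n_iter = 60, energy_every = 1)
  expect_true(all(diff(fld$energy) <= 1e-12 * abs(fld$energy[1])))
})
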