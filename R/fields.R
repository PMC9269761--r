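#' @title External force vector fields
#' @description Constructors for the GVF-family external force fields.  Each
#'   returns a `vector_field` object: matrices `u` (x component) and `v`
#'   (y component) plus the method name and parameters that produced it
#'   (provenance), so a field can be serialized and reproduced exactly.
#' @name vector_field
NULL

new_vector_field <- function(u, v, method, params, energy = NULL) {
  stopifnot(all(is.finite(u)), all(is.finite(v)), all(dim(u) == dim(v)))
  structure(list(u = u, v = v, method = method, params = params,
                 energy = energy),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("Vector field (%s): %d x %d  [%s]\n",
              x$method, nrow(x$u), ncol(x$u), p))
  invisible(x)
}

#' @export
plot.vector_field <- function(x, every = 4, scale = 3, ...) {
  h <- nrow(x$u); w <- ncol(x$u)
  ys <- seq(1L, h, by = every); xs <- seq(1L, w, by = every)
  g <- expand.grid(row = ys, col = xs)
  u <- x$u[cbind(g$row, g$col)]; v <- x$v[cbind(g$row, g$col)]
  mg <- sqrt(u^2 + v^2); mg[mg == 0] <- 1
  graphics::plot(NA, xlim = c(-1, w), ylim = c(h, -1), asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("%s field", x$method), ...)
  graphics::arrows(g$col - 1, g$row - 1,
                   g$col - 1 + scale * u / mg, g$row - 1 + scale * v / mg,
                   length = 0.03, col = "steelblue")
  invisible(x)
}

# Default iteration count: the full M*N schedule, capped for large images.
default_iters <- function(edge, n_iter, cap = 10000L) {
  if (!is.null(n_iter)) {
    stopifnot(n_iter >= 1)
    return(as.integer(n_iter))
  }
  full <- nrow(edge$f) * ncol(edge$f)
  if (full > cap) {
    message(sprintf("field iterations capped at %d (full M*N schedule = %d)",
                    cap, full))
    return(as.integer(cap))
  }
  as.integer(full)
}

#' Gradient vector flow (GVF) field
#'
#' Isotropic diffusion of the edge-map gradient: starting from
#' `(u, v) = (fx, fy)`, iterate the explicit scheme
#' `u <- u + dt * (mu * lap(u) - |grad f|^2 * (u - fx))` (likewise `v`)
#' for `n_iter` steps.  The result extends the attraction range of the edge
#' gradient across the whole image while keeping `(u, v) ~ (fx, fy)` where
#' edges are strong.
#'
#' @param edge An [edge_map()] object.
#' @param mu Positive diffusion weight (regularization); default 0.2.
#' @param dt Explicit time step; must satisfy `dt < 1/(4*mu)`.
#' @param n_iter Iterations; default is the M*N schedule (capped at 10000
#'   with a message).
#' @param energy_every If > 0, record the discrete field energy every that
#'   many iterations in the `energy` element of the result.
#' @return A `vector_field` object.
#' @export
gvf <- function(edge, mu = 0.2, dt = 1, n_iter = NULL, energy_every = 0) {
  check_edge_map(edge)
  stopifnot(mu > 0, dt > 0)
  if (dt >= 1 / (4 * mu)) {
    stop(sprintf("unstable time step: need dt < 1/(4*mu) = %g, got %g",
                 1 / (4 * mu), dt), call. = FALSE)
  }
  n_iter <- default_iters(edge, n_iter)
  u <- edge$fx; v <- edge$fy
  b <- edge$gmag2
  etrace <- numeric(0)
  for (it in seq_len(n_iter)) {
    u <- u + dt * (mu * laplacian5(u) - b * (u - edge$fx))
    v <- v + dt * (mu * laplacian5(v) - b * (v - edge$fy))
    if (energy_every > 0 && it %% energy_every == 0) {
      etrace <- c(etrace, gvf_energy_uv(u, v, edge, mu))
    }
  }
  new_vector_field(u, v, "gvf", list(mu = mu, dt = dt, n_iter = n_iter),
                   energy = if (length(etrace)) etrace else NULL)
}

#' Generalized gradient vector flow (GGVF) field
#'
#' GVF with spatially varying diffusion and data weights
#' `g = exp(-|grad f|^2 / k^2)` and `h = 1 - g` (so `g + h == 1`): diffusion
#' dominates in homogeneous regions, the data term near edges, which improves
#' convergence into thin concavities.  `form = "magnitude"` selects the
#' alternative weighting `g = exp(-|grad f| / k)` found in the original GGVF
#' literature.
#'
#' @inheritParams gvf
#' @param k Positive threshold controlling the diffusion/data trade-off.
#' @param dt Explicit time step; the diffusion weight reaches 1, so stability
#'   requires `dt < 1/4`; default 0.2.
#' @param form Exponent form of the weighting function, `"squared"` (default)
#'   or `"magnitude"`.
#' @return A `vector_field` object.
#' @export
ggvf <- function(edge, k = 0.5, dt = 0.2, n_iter = NULL,
                 form = c("squared", "magnitude")) {
  check_edge_map(edge)
  form <- match.arg(form)
  stopifnot(k > 0, dt > 0)
  if (dt >= 0.25) {
    stop("unstable time step for GGVF: need dt < 1/4 (diffusion weight g <= 1)",
         call. = FALSE)
  }
  n_iter <- default_iters(edge, n_iter)
  g <- ggvf_weight(edge, k, form)
  h <- 1 - g
  u <- edge$fx; v <- edge$fy
  for (it in seq_len(n_iter)) {
    u <- u + dt * (g * laplacian5(u) - h * (u - edge$fx))
    v <- v + dt * (g * laplacian5(v) - h * (v - edge$fy))
  }
  new_vector_field(u, v, "ggvf",
                   list(k = k, dt = dt, n_iter = n_iter, form = form))
}

ggvf_weight <- function(edge, k, form) {
  if (form == "squared") exp(-edge$gmag2 / k^2) else exp(-sqrt(edge$gmag2) / k)
}

#' Virtual electric field (VEF) by direct summation
#'
#' Treats every pixel as a point charge of magnitude `f(x, y)`; the force at
#' `(x0, y0)` is the inverse-square-law sum over all other pixels in the
#' `(2t+1) x (2t+1)` window `D` centered there, each contribution pointing
#' from `(x0, y0)` toward the charge with magnitude `f / r^2`.  The
#' singular center pixel (self-force) is excluded.
#'
#' @param edge An [edge_map()] object.
#' @param t Window half-width in pixels (>= 1).
#' @return A `vector_field` object.
#' @seealso [vef_fft()] for the equivalent FFT-convolution evaluation.
#' @export
vef_direct <- function(edge, t = 5L) {
  check_edge_map(edge)
  stopifnot(t >= 1)
  f <- edge$f
  h <- nrow(f); w <- ncol(f)
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (dy in -t:t) {
    for (dx in -t:t) {
      if (dx == 0L && dy == 0L) next
      r3 <- (dx^2 + dy^2)^1.5
      fs <- shift_zero(f, dy, dx)
      u <- u + (dx / r3) * fs
      v <- v + (dy / r3) * fs
    }
  }
  new_vector_field(u, v, "vef", list(t = t, impl = "direct"))
}

# Shift a matrix so element [i, j] picks up m[i + dy, j + dx], zero outside.
shift_zero <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  out[ys, xs] <- m[ys + dy, xs + dx, drop = FALSE]
  out
}

#' Virtual electric field (VEF) by FFT convolution
#'
#' Evaluates the same windowed inverse-square-law field as [vef_direct()] by
#' zero-padded linear convolution with the kernel `(-x/r^3, -y/r^3)`
#' (support restricted to the `(2t+1)` window, center set to 0), computed via
#' the FFT.  Agrees with the direct sum to floating-point tolerance.
#'
#' @inheritParams vef_direct
#' @return A `vector_field` object.
#' @export
vef_fft <- function(edge, t = 5L) {
  check_edge_map(edge)
  stopifnot(t >= 1)
  f <- edge$f
  off <- -t:t
  dx <- matrix(off, 2 * t + 1, 2 * t + 1, byrow = TRUE)
  dy <- matrix(off, 2 * t + 1, 2 * t + 1)
  r3 <- (dx^2 + dy^2)^1.5
  r3[t + 1L, t + 1L] <- 1  # center excluded below
  kx <- dx / r3; ky <- dy / r3
  kx[t + 1L, t + 1L] <- 0; ky[t + 1L, t + 1L] <- 0
  u <- fft_correlate(f, kx, t)
  v <- fft_correlate(f, ky, t)
  new_vector_field(u, v, "vef", list(t = t, impl = "fft"))
}

# Cross-correlation out(p) = sum_d k(d) * f(p + d) via zero-padded FFT
# convolution with the flipped kernel.
fft_correlate <- function(f, kern, t) {
  h <- nrow(f); w <- ncol(f)
  kh <- nrow(kern)
  ph <- h + kh - 1L; pw <- w + kh - 1L
  fp <- matrix(0, ph, pw); fp[1:h, 1:w] <- f
  gp <- matrix(0, ph, pw); gp[1:kh, 1:kh] <- kern[kh:1, kh:1]  # flip
  conv <- Re(stats::fft(stats::fft(fp) * stats::fft(gp), inverse = TRUE)) /
    (ph * pw)
  conv[(t + 1L):(t + h), (t + 1L):(t + w), drop = FALSE]
}

#' Second derivatives along and across the isophotes of a field
#'
#' Decomposes the Laplacian as `lap(u) = uTT + uNN`, where `uNN` is the
#' second derivative along the local gradient direction of `u` (across its
#' level lines) and `uTT` along the isophote tangent.  Where the local
#' gradient vanishes the direction is undefined and the Laplacian is split
#' evenly (`uNN = uTT = lap(u)/2`), which preserves the sum identity
#' everywhere.
#'
#' @param field Numeric matrix of finite values.
#' @param eps Gradient-magnitude-squared threshold below which the direction
#'   is treated as degenerate.
#' @return List with matrices `uTT` and `uNN`.
#' @export
tangent_normal <- function(field, eps = 1e-12) {
  stopifnot(is.matrix(field), all(is.finite(field)))
  g <- gradient_xy(field)
  ux <- g$gx; uy <- g$gy
  uxx <- shift_left(field) + shift_right(field) - 2 * field
  uyy <- shift_up(field) + shift_down(field) - 2 * field
  uxy <- gradient_xy(ux)$gy
  m2 <- ux^2 + uy^2
  lap <- uxx + uyy
  deg <- m2 < eps
  m2s <- ifelse(deg, 1, m2)
  uNN <- (ux^2 * uxx + 2 * ux * uy * uxy + uy^2 * uyy) / m2s
  uTT <- (uy^2 * uxx - 2 * ux * uy * uxy + ux^2 * uyy) / m2s
  uNN[deg] <- lap[deg] / 2
  uTT[deg] <- lap[deg] / 2
  list(uTT = uTT, uNN = uNN)
}

#' Gradient vector flow in the normal direction (NGVF)
#'
#' Replaces the Laplacian in the GVF diffusion by `uNN`, the second
#' derivative across the evolving field's own level lines (the best
#' -performing interpolation operator of the three), giving
#' `u <- u + dt * (mu * uNN - |grad f|^2 * (u - fx))`.
#'
#' @inheritParams gvf
#' @param dt Explicit time step; must satisfy `dt < 1/(2*mu)`.
#' @return A `vector_field` object.
#' @export
ngvf <- function(edge, mu = 0.2, dt = 1, n_iter = NULL) {
  check_edge_map(edge)
  stopifnot(mu > 0, dt > 0)
  if (dt >= 1 / (2 * mu)) {
    stop(sprintf("unstable time step: need dt < 1/(2*mu) = %g for NGVF",
                 1 / (2 * mu)), call. = FALSE)
  }
  n_iter <- default_iters(edge, n_iter)
  u <- edge$fx; v <- edge$fy
  b <- edge$gmag2
  for (it in seq_len(n_iter)) {
    u <- u + dt * (mu * tangent_normal(u)$uNN - b * (u - edge$fx))
    v <- v + dt * (mu * tangent_normal(v)$uNN - b * (v - edge$fy))
  }
  new_vector_field(u, v, "ngvf", list(mu = mu, dt = dt, n_iter = n_iter))
}

#' Component-wise sign normalization of a vector field
#'
#' Replaces each component independently by its sign (`-1`, `0`, or `1`),
#' the component normalization that turns a GGVF-style field into CN-GGVF.
#'
#' @param field A `vector_field` object.
#' @return A `vector_field` with all components in `{-1, 0, 1}`.
#' @export
component_sign <- function(field) {
  stopifnot(inherits(field, "vector_field"))
  new_vector_field(sign(field$u), sign(field$v),
                   paste0(field$method, "+sign"), field$params)
}

#' Component-normalized generalized GVF (CN-GGVF) field
#'
#' Diffuses with the mixed tangent/normal weighting
#' `u <- u + dt * (g * (g * uNN + h * uTT) - h * (u - fx))` using the GGVF
#' weights `g`, `h`, then applies [component_sign()] once to the final field,
#' yielding unit-strength components that help the snake descend deep thin
#' notches (at the cost of direction quantization).
#'
#' @inheritParams ggvf
#' @return A `vector_field` with components in `{-1, 0, 1}`.
#' @export
cn_ggvf <- function(edge, k = 0.5, dt = 0.2, n_iter = NULL,
                    form = c("squared", "magnitude")) {
  check_edge_map(edge)
  form <- match.arg(form)
  stopifnot(k > 0, dt > 0)
  if (dt >= 0.25) {
    stop("unstable time step for CN-GGVF: need dt < 1/4", call. = FALSE)
  }
  n_iter <- default_iters(edge, n_iter)
  g <- ggvf_weight(edge, k, form)
  h <- 1 - g
  u <- edge$fx; v <- edge$fy
  for (it in seq_len(n_iter)) {
    du <- tangent_normal(u); dv <- tangent_normal(v)
    u <- u + dt * (g * (g * du$uNN + h * du$uTT) - h * (u - edge$fx))
    v <- v + dt * (g * (g * dv$uNN + h * dv$uTT) - h * (v - edge$fy))
  }
  new_vector_field(sign(u), sign(v), "cn_ggvf",
                   list(k = k, dt = dt, n_iter = n_iter, form = form))
}

# Discrete GVF energy with forward differences (the Lyapunov function of the
# explicit scheme at a stable step).
gvf_energy_uv <- function(u, v, edge, mu) {
  sm <- function(m) {
    ux <- shift_right(m) - m
    uy <- shift_down(m) - m
    sum(ux^2 + uy^2)
  }
  mu * (sm(u) + sm(v)) +
    sum(edge$gmag2 * ((u - edge$fx)^2 + (v - edge$fy)^2))
}

#' Discrete field energy (GVF / HBGVF form)
#'
#' Evaluates the quadratic energy the diffusion schemes descend: the
#' smoothness term `mu * (grad u)' D (grad u)` (forward differences, tensor
#' `D` = identity when `tensor` is `NULL`, i.e. the plain GVF energy) plus
#' the data term `|grad f|^2 * |(u,v) - grad f|^2`, summed over pixels.
#' Non-negative because `D` is positive semi-definite.
#'
#' @param field A `vector_field`.
#' @param edge The [edge_map()] the field was computed from.
#' @param mu Diffusion weight used.
#' @param tensor Optional [diffusion_tensor()]; identity if `NULL`.
#' @return Scalar energy.
#' @export
field_energy <- function(field, edge, mu = 0.2, tensor = NULL) {
  stopifnot(inherits(field, "vector_field"))
  check_edge_map(edge)
  if (is.null(tensor)) {
    return(gvf_energy_uv(field$u, field$v, edge, mu))
  }
  stopifnot(inherits(tensor, "tensor_field"))
  sm <- function(m) {
    ux <- shift_right(m) - m
    uy <- shift_down(m) - m
    sum(tensor$a * ux^2 + 2 * tensor$b * ux * uy + tensor$c * uy^2)
  }
  mu * (sm(field$u) + sm(field$v)) +
    sum(edge$gmag2 * ((field$u - edge$fx)^2 + (field$v - edge$fy)^2))
}
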