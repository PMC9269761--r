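#' Image Hessian field
#'
#' Second partial derivatives `Ixx`, `Ixy`, `Iyy` of the Gaussian-smoothed
#' image, computed by repeated application of the central-difference gradient
#' ([gradient_xy()]).  The Hessian at a pixel is the symmetric matrix
#' `H = [[Ixx, Ixy], [Ixy, Iyy]]`; its leading eigenvector points across the
#' local image feature, the other along it.
#'
#' @param image Numeric matrix with intensities in \[0,1\], at least 3x3.
#' @param sigma Gaussian derivative scale in pixels (>= 0).
#' @return An object of class `hessian_field`: list with `Ixx`, `Ixy`, `Iyy`
#'   and `sigma`.
#' @export
hessian_field <- function(image, sigma = 1) {
  check_image(image)
  stopifnot(sigma >= 0)
  sm <- gaussian_smooth(image, sigma)
  g1 <- gradient_xy(sm)
  Ixx <- gradient_xy(g1$gx)$gx
  Ixy <- gradient_xy(g1$gx)$gy
  Iyy <- gradient_xy(g1$gy)$gy
  structure(list(Ixx = Ixx, Ixy = Ixy, Iyy = Iyy, sigma = sigma),
            class = "hessian_field")
}

#' Eigen-decomposition of a 2x2 symmetric Hessian field
#'
#' Closed-form per-pixel eigenpairs:
#' `lambda1 = (Ixx + Iyy + s) / 2`, `lambda2 = (Ixx + Iyy - s) / 2` with
#' `s = sqrt((Ixx - Iyy)^2 + 4 Ixy^2)`, so `lambda1 >= lambda2` everywhere.
#' The eigenvectors `e1 = (2 Ixy, Iyy - Ixx + s)` and
#' `e2 = (2 Ixy, Iyy - Ixx - s)` are normalized to unit length.  Those
#' formulas are literally degenerate (zero vector) when `Ixy = 0`; there the
#' axis-aligned limit is used: `e1` on the axis of the larger of `Ixx`,
#' `Iyy` (x axis on ties), `e2` orthogonal.
#'
#' @param h A [hessian_field()] object.
#' @param eps Degeneracy threshold on `|Ixy|` (normalized-intensity units).
#' @return List of matrices `lambda1`, `lambda2`, `e1x`, `e1y`, `e2x`, `e2y`;
#'   `(e1, e2)` form an orthonormal basis at every pixel.
#' @export
hessian_eigen <- function(h, eps = 1e-12) {
  stopifnot(inherits(h, "hessian_field"))
  with(h, {
    s <- sqrt((Ixx - Iyy)^2 + 4 * Ixy^2)
    lambda1 <- (Ixx + Iyy + s) / 2
    lambda2 <- (Ixx + Iyy - s) / 2
    e1x <- 2 * Ixy; e1y <- Iyy - Ixx + s
    e2x <- 2 * Ixy; e2y <- Iyy - Ixx - s
    deg <- abs(Ixy) < eps
    xx_major <- deg & (Ixx >= Iyy)
    yy_major <- deg & (Ixx < Iyy)
    # larger diagonal entry owns e1 (it is the larger eigenvalue there)
    e1x[xx_major] <- 1; e1y[xx_major] <- 0
    e2x[xx_major] <- 0; e2y[xx_major] <- 1
    e1x[yy_major] <- 0; e1y[yy_major] <- 1
    e2x[yy_major] <- 1; e2y[yy_major] <- 0
    n1 <- sqrt(e1x^2 + e1y^2); n2 <- sqrt(e2x^2 + e2y^2)
    # guard: fully degenerate pixels already overwritten above, norms > 0
    list(lambda1 = lambda1, lambda2 = lambda2,
         e1x = e1x / n1, e1y = e1y / n1,
         e2x = e2x / n2, e2y = e2y / n2)
  })
}

#' Hessian-steered diffusion tensor
#'
#' Builds the per-pixel symmetric positive semi-definite tensor
#' `D = [e1 e2] diag(eta1, eta2) [e1 e2]'` that steers the HBGVF diffusion:
#' the eigenvectors come from the image Hessian ([hessian_eigen()]), and the
#' eigenvalues are `eta1 = 1 / (1 + (|grad I| / K)^2)` across the feature
#' and `eta2 = 1` along it.  Consequences: where `|grad I| = 0` the tensor is
#' exactly the identity (isotropic diffusion in homogeneous regions), and as
#' `|grad I|` grows, `eta1 -> 0`, shutting off diffusion across edges so
#' edges — including weak ones — are preserved.
#'
#' @param image Numeric matrix with intensities in \[0,1\], at least 3x3.
#' @param K Positive gradient threshold: `eta1 = 1/2` exactly at
#'   `|grad I| = K`.
#' @param sigma Gaussian scale for both the Hessian and `|grad I|`
#'   (computed from the same smoothed image).
#' @return An object of class `tensor_field`: matrices `a`, `b`, `c`
#'   (`D = [[a, b], [b, c]]`), `eta1`, `eta2`, the Hessian eigenpairs, `K`
#'   and `sigma`.
#' @export
diffusion_tensor <- function(image, K = 0.1, sigma = 1) {
  check_image(image)
  if (!is.numeric(K) || length(K) != 1L || K <= 0) {
    stop("K must be a positive scalar threshold", call. = FALSE)
  }
  sm <- gaussian_smooth(image, sigma)
  g <- gradient_xy(sm)
  gmag2 <- g$gx^2 + g$gy^2
  eta1 <- 1 / (1 + gmag2 / K^2)
  eta2 <- matrix(1, nrow(image), ncol(image))
  h <- hessian_field(image, sigma)
  e <- hessian_eigen(h)
  # The feature-crossing direction is the principal-curvature axis, i.e. the
  # eigenvector of the larger-MAGNITUDE eigenvalue.  The signed ordering
  # lambda1 >= lambda2 flips e1 onto the along-edge axis on the flank of an
  # edge where the dominant second derivative is negative; attaching the
  # suppressed eigenvalue eta1 there would open the diffusion barrier across
  # that flank and defeat weak-edge preservation.  So eta1 rides on the
  # dominant-|lambda| eigenvector, eta2 = 1 on the other.
  swap <- abs(e$lambda2) > abs(e$lambda1)
  cx <- ifelse(swap, e$e2x, e$e1x); cy2 <- ifelse(swap, e$e2y, e$e1y)
  tx <- ifelse(swap, e$e1x, e$e2x); ty <- ifelse(swap, e$e1y, e$e2y)
  a <- eta1 * cx^2 + eta2 * tx^2
  b <- eta1 * cx * cy2 + eta2 * tx * ty
  cc <- eta1 * cy2^2 + eta2 * ty^2
  structure(list(a = a, b = b, c = cc, eta1 = eta1, eta2 = eta2,
                 lambda1 = e$lambda1, lambda2 = e$lambda2,
                 e1x = e$e1x, e1y = e$e1y, e2x = e$e2x, e2y = e$e2y,
                 K = K, sigma = sigma),
            class = "tensor_field")
}

#' Identity diffusion tensor
#'
#' Convenience constructor of a `tensor_field` equal to the identity at every
#' pixel; [hbgvf()] with this tensor reduces exactly to [gvf()].
#'
#' @param h,w Image dimensions.
#' @return A `tensor_field` with `a = c = 1`, `b = 0` everywhere.
#' @export
identity_tensor <- function(h, w) {
  one <- matrix(1, h, w); zero <- matrix(0, h, w)
  structure(list(a = one, b = zero, c = one, eta1 = one, eta2 = one,
                 lambda1 = zero, lambda2 = zero,
                 e1x = one, e1y = zero, e2x = zero, e2y = one,
                 K = Inf, sigma = 0),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf(
    "Diffusion tensor: %d x %d, K = %g, sigma = %g, min eta1 = %.4g\n",
    nrow(x$a), ncol(x$a), x$K, x$sigma, min(x$eta1)))
  invisible(x)
}

# Conservative divergence div(D grad u): forward-difference gradient, tensor
# sampled at the pixel, and the adjoint (backward-difference) divergence.
# Sampling the whole tensor at one point keeps every per-cell quadratic form
# equal to the (positive semi-definite) local tensor, so the scheme is the
# exact negative gradient of a PSD discrete energy and descends it at stable
# steps; half-point averaging of the axial entries would break per-cell
# definiteness where the cross entry is large.  With D = identity the
# operator reduces to the replicate-boundary 5-point Laplacian.
div_tensor <- function(u, a, b, cc) {
  h <- nrow(u); w <- ncol(u)
  ux <- shift_right(u) - u   # forward difference; last column = 0
  uy <- shift_down(u) - u    # forward difference; last row = 0
  p <- a * ux + b * uy
  q <- b * ux + cc * uy
  dx <- p
  dx[, 2:w] <- p[, 2:w, drop = FALSE] - p[, 1:(w - 1L), drop = FALSE]
  dx[, w] <- -p[, w - 1L]
  dy <- q
  dy[2:h, ] <- q[2:h, , drop = FALSE] - q[1:(h - 1L), , drop = FALSE]
  dy[h, ] <- -q[h - 1L, ]
  dx + dy
}

#' Hessian-based gradient vector flow (HBGVF) field
#'
#' Anisotropic diffusion of the edge-map gradient: the explicit scheme
#' `u <- u + dt * (mu * div(D grad u) - |grad f|^2 * (u - fx))` (likewise
#' `v`), where `D` is the Hessian-steered [diffusion_tensor()].  Diffusion
#' across strong image gradients is suppressed (`eta1` small), so the field
#' preserves weak edges and converges into concavities, while homogeneous
#' regions diffuse isotropically exactly as in [gvf()].
#'
#' @inheritParams gvf
#' @param tensor A [diffusion_tensor()] (or [identity_tensor()]) matching the
#'   edge map's shape.
#' @return A `vector_field` object.
#' @export
hbgvf <- function(edge, tensor, mu = 0.2, dt = 1, n_iter = NULL,
                  energy_every = 0) {
  check_edge_map(edge)
  stopifnot(inherits(tensor, "tensor_field"), mu > 0, dt > 0)
  if (!all(dim(tensor$a) == dim(edge$f))) {
    stop("tensor and edge map shapes differ", call. = FALSE)
  }
  # tensor eigenvalues are <= 1, so the isotropic bound applies
  if (dt >= 1 / (4 * mu)) {
    stop(sprintf("unstable time step: need dt < 1/(4*mu) = %g, got %g",
                 1 / (4 * mu), dt), call. = FALSE)
  }
  n_iter <- default_iters(edge, n_iter)
  u <- edge$fx; v <- edge$fy
  bdat <- edge$gmag2
  etrace <- numeric(0)
  for (it in seq_len(n_iter)) {
    u <- u + dt * (mu * div_tensor(u, tensor$a, tensor$b, tensor$c) -
                     bdat * (u - edge$fx))
    v <- v + dt * (mu * div_tensor(v, tensor$a, tensor$b, tensor$c) -
                     bdat * (v - edge$fy))
    if (energy_every > 0 && it %% energy_every == 0) {
      etrace <- c(etrace,
                  field_energy(new_vector_field(u, v, "hbgvf", list()),
                               edge, mu, tensor))
    }
  }
  new_vector_field(u, v, "hbgvf",
                   list(mu = mu, dt = dt, n_iter = n_iter, K = tensor$K),
                   energy = if (length(etrace)) etrace else NULL)
}
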