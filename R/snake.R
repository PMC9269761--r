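#' Closed contours
#'
#' Contours are N x 2 matrices of (x, y) coordinates, 0-based and
#' pixel-centered (pixel `[i, j]` of an image matrix sits at
#' `x = j - 1, y = i - 1`), implicitly closed, N >= 4.
#'
#' @param cx,cy Circle center.
#' @param r Radius in pixels.
#' @param n Number of points.
#' @return N x 2 coordinate matrix.
#' @export
circle_contour <- function(cx, cy, r, n = 100L) {
  stopifnot(r > 0, n >= 4L)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

check_contour <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) < 4L ||
      !all(is.finite(points))) {
    stop("contour must be a finite N x 2 matrix with N >= 4", call. = FALSE)
  }
  invisible(points)
}

#' Arc-length uniform resampling of a closed contour
#'
#' Resamples the closed polyline to (approximately) uniform spacing by linear
#' interpolation along arc length; the perimeter is preserved to within the
#' polygonal approximation.  The number of output points is
#' `max(4, round(perimeter / spacing))`.
#'
#' @param points N x 2 contour matrix.
#' @param spacing Target point spacing in pixels.
#' @return Resampled contour matrix.
#' @export
resample_contour <- function(points, spacing = 1) {
  check_contour(points)
  stopifnot(spacing > 0)
  closed <- rbind(points, points[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  perim <- sum(seg)
  if (perim <= .Machine$double.eps * 100) {
    stop("contour has (near) zero perimeter; cannot resample", call. = FALSE)
  }
  s <- c(0, cumsum(seg))
  n_new <- max(4L, as.integer(round(perim / spacing)))
  targets <- seq(0, perim, length.out = n_new + 1L)[1:n_new]
  x <- stats::approx(s, closed[, 1L], xout = targets)$y
  y <- stats::approx(s, closed[, 2L], xout = targets)$y
  cbind(x = x, y = y)
}

#' Semi-implicit internal-force system for a closed snake
#'
#' The internal force `alpha * c'' - beta * c''''` discretized with cyclic
#' (closed-contour) differences gives a circulant pentadiagonal operator `A`.
#' One implicit step solves `(I + tau * (-alpha * D2 + beta * D4)) c_new =
#' rhs`; this factors the dense system once so solving is a matrix-vector
#' product per iteration, unconditionally stable in the internal term.
#'
#' @param n Number of contour points (>= 4).
#' @param alpha Tension weight (>= 0).
#' @param beta Rigidity weight (>= 0).
#' @param tau Time step (> 0).
#' @return List with the solver matrix `Minv` (n x n) and the parameters.
#' @export
internal_system <- function(n, alpha, beta, tau) {
  if (n < 4L) stop("contour too small: need at least 4 points", call. = FALSE)
  stopifnot(alpha >= 0, beta >= 0, tau > 0)
  idx <- function(j) ((j - 1L) %% n) + 1L
  M <- diag(n)
  for (i in seq_len(n)) {
    # -alpha * D2: 2 on the diagonal, -1 on neighbors
    M[i, idx(i)]      <- M[i, idx(i)] + tau * (2 * alpha + 6 * beta)
    M[i, idx(i - 1L)] <- M[i, idx(i - 1L)] - tau * (alpha + 4 * beta)
    M[i, idx(i + 1L)] <- M[i, idx(i + 1L)] - tau * (alpha + 4 * beta)
    M[i, idx(i - 2L)] <- M[i, idx(i - 2L)] + tau * beta
    M[i, idx(i + 2L)] <- M[i, idx(i + 2L)] + tau * beta
  }
  list(Minv = solve(M), n = n, alpha = alpha, beta = beta, tau = tau)
}

#' Bilinear sampling of a vector field at contour points
#'
#' Interpolates `(u, v)` bilinearly at each (x, y) point; points outside the
#' image domain are clamped to the boundary before sampling.
#'
#' @param field A `vector_field`.
#' @param points N x 2 contour matrix (0-based pixel-centered coordinates).
#' @return N x 2 matrix of force vectors (columns `u`, `v`).
#' @export
sample_field <- function(field, points) {
  stopifnot(inherits(field, "vector_field"))
  check_contour(points)
  h <- nrow(field$u); w <- ncol(field$u)
  x <- pmin(pmax(points[, 1L], 0), w - 1)
  y <- pmin(pmax(points[, 2L], 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  bi <- function(m) {
    m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
      m[cbind(i0 + 1, j0)] * (1 - fx) * fy +
      m[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  cbind(u = bi(field$u), v = bi(field$v))
}

#' Fit an active contour (snake) to an external force field
#'
#' Evolves a closed parametric contour under internal tension/rigidity forces
#' and the external force sampled from `field`, by the classic semi-implicit
#' scheme: internal forces implicit (unconditionally stable), external force
#' explicit, `c_new = (I + tau * A)^{-1} (c + tau * F_ext(c))`.  The contour
#' is resampled to uniform spacing every `resample_every` iterations so the
#' finite differences behind the internal forces stay meaningful, and
#' evolution stops when the maximum per-point displacement in one iteration
#' falls below `tol` (or at `max_iter`).
#'
#' @param field A `vector_field` external force.
#' @param init Initial contour: an N x 2 matrix (see [circle_contour()]).
#' @param alpha Tension weight; default 0.1.
#' @param beta Rigidity weight; default 0.1.
#' @param tau Time step; default 0.5.
#' @param max_iter Iteration cap; default 2000.
#' @param tol Convergence threshold on the per-iteration maximum point
#'   displacement, in pixels; default 0.01.
#' @param force_mode `"raw"` uses the field as sampled; `"unit"` normalizes
#'   each sampled force vector to unit length (useful when field magnitudes
#'   decay far from edges).
#' @param resample_every Resampling interval in iterations; default 10.
#' @param spacing Target point spacing in pixels; default 1.
#' @param keep_every If > 0, keep an intermediate contour snapshot every that
#'   many iterations in the `trajectory` element.
#' @return An object of class `snake`: list with `points` (final contour),
#'   `init`, `iterations`, `converged`, `trajectory`, the parameters and the
#'   field provenance.  Methods: `print`, `summary`, `plot`, `coef`
#'   (final coordinates), `residuals` (final sampled external force).
#' @examples
#' sc <- make_ushape(size = 48)
#' em <- edge_map(sc$image, sigma = 1)
#' fld <- gvf(em, n_iter = 500)
#' fit <- snake(fld, circle_contour(23.5, 23.5, 20), max_iter = 200)
#' fit
#' @export
snake <- function(field, init, alpha = 0.1, beta = 0.1, tau = 0.5,
                  max_iter = 2000L, tol = 0.01,
                  force_mode = c("raw", "unit"),
                  resample_every = 10L, spacing = 1, keep_every = 0L) {
  stopifnot(inherits(field, "vector_field"))
  check_contour(init)
  force_mode <- match.arg(force_mode)
  stopifnot(alpha >= 0, beta >= 0, tau > 0, max_iter >= 1, tol >= 0)
  pts <- resample_contour(init, spacing)
  sys <- internal_system(nrow(pts), alpha, beta, tau)
  trajectory <- list()
  converged <- FALSE
  failed <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    F <- sample_field(field, pts)
    if (force_mode == "unit") {
      nrm <- sqrt(rowSums(F^2))
      F <- F / pmax(nrm, 1e-10)
      F[nrm < 1e-12, ] <- 0
    }
    new_pts <- sys$Minv %*% (pts + tau * F)
    if (!all(is.finite(new_pts))) {
      warning("contour left the numeric domain; reporting failed convergence",
              call. = FALSE)
      failed <- TRUE
      break
    }
    disp <- max(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    if (keep_every > 0L && it %% keep_every == 0L) {
      trajectory[[length(trajectory) + 1L]] <- pts
    }
    if (resample_every > 0L && it %% resample_every == 0L) {
      res <- tryCatch(resample_contour(pts, spacing), error = function(e) NULL)
      if (is.null(res) || nrow(unique(round(res, 8))) < 4L) {
        warning("contour collapsed to fewer than 4 distinct points; ",
                "reporting failed convergence", call. = FALSE)
        failed <- TRUE
        break
      }
      if (nrow(res) != sys$n) {
        sys <- internal_system(nrow(res), alpha, beta, tau)
      }
      pts <- res
    }
    if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  colnames(pts) <- c("x", "y")
  structure(
    list(points = pts, init = init, iterations = it,
         converged = converged, failed = failed, trajectory = trajectory,
         params = list(alpha = alpha, beta = beta, tau = tau,
                       max_iter = max_iter, tol = tol,
                       force_mode = force_mode,
                       resample_every = resample_every, spacing = spacing),
         field_method = field$method, field_params = field$params),
    class = "snake"
  )
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf(
    "Snake fit (%s field): %d points, %d iteration%s, %s\n",
    x$field_method, nrow(x$points), x$iterations,
    if (x$iterations == 1L) "" else "s",
    if (x$failed) "FAILED (contour collapse)"
    else if (x$converged) "converged" else "stopped at max_iter"))
  invisible(x)
}

#' @export
summary.snake <- function(object, ...) {
  p <- object$points
  closed <- rbind(p, p[1L, ])
  perim <- sum(sqrt(rowSums(diff(closed)^2)))
  area <- polygon_area(p)
  out <- list(n_points = nrow(p), iterations = object$iterations,
              converged = object$converged, failed = object$failed,
              perimeter = perim, area = abs(area),
              orientation = if (area >= 0) "counter-clockwise" else "clockwise",
              params = object$params, field_method = object$field_method)
  class(out) <- "summary.snake"
  out
}

#' @export
print.summary.snake <- function(x, ...) {
  cat(sprintf("Snake fit (%s field)\n", x$field_method))
  cat(sprintf("  points:      %d\n", x$n_points))
  cat(sprintf("  iterations:  %d (%s)\n", x$iterations,
              if (x$failed) "failed" else if (x$converged) "converged"
              else "max_iter reached"))
  cat(sprintf("  perimeter:   %.2f px\n", x$perimeter))
  cat(sprintf("  area:        %.2f px^2 (%s)\n", x$area, x$orientation))
  cat(sprintf("  alpha=%g beta=%g tau=%g tol=%g force_mode=%s\n",
              x$params$alpha, x$params$beta, x$params$tau, x$params$tol,
              x$params$force_mode))
  invisible(x)
}

#' @export
coef.snake <- function(object, ...) object$points

#' @export
residuals.snake <- function(object, field = NULL, ...) {
  # Residual force imbalance at the final contour: the external force that
  # the internal forces must cancel at equilibrium.  Needs the field the
  # snake was fitted with (not stored, to keep fits light).
  if (is.null(field)) {
    stop("supply the vector_field the snake was fitted with: ",
         "residuals(fit, field = fld)", call. = FALSE)
  }
  sample_field(field, object$points)
}

#' @export
plot.snake <- function(x, image = NULL, boundary = NULL, ...) {
  if (!is.null(image)) {
    plot_raster(image, main = sprintf("snake (%s)", x$field_method), ...)
  } else {
    rng <- apply(rbind(x$points, x$init), 2L, range)
    graphics::plot(NA, xlim = rng[, 1L], ylim = rev(rng[, 2L]), asp = 1,
                   xlab = "x", ylab = "y",
                   main = sprintf("snake (%s)", x$field_method), ...)
  }
  closed <- function(p) rbind(p, p[1L, , drop = FALSE])
  if (!is.null(boundary)) {
    graphics::lines(closed(boundary), col = "forestgreen", lwd = 1)
  }
  graphics::lines(closed(x$init), col = "gray50", lty = 2)
  graphics::lines(closed(x$points), col = "red", lwd = 2)
  invisible(x)
}

# Signed polygon area (shoelace); positive = counter-clockwise in (x, y).
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Distances from points of one contour to another contour's polyline
#'
#' For each point of `from`, the Euclidean distance to the nearest point on
#' the closed polyline `to` (segments, not just vertices).  Used for
#' boundary-accuracy metrics against analytic ground truth.
#'
#' @param from N x 2 matrix of query points.
#' @param to M x 2 closed polyline.
#' @return Numeric vector of length N.
#' @export
contour_distance <- function(from, to) {
  check_contour(to)
  stopifnot(is.matrix(from), ncol(from) == 2L)
  a <- to
  b <- to[c(2:nrow(to), 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1
  d <- matrix(NA_real_, nrow(from), nrow(to))
  for (s in seq_len(nrow(to))) {
    ap_x <- from[, 1L] - a[s, 1L]
    ap_y <- from[, 2L] - a[s, 2L]
    t_par <- pmin(1, pmax(0, (ap_x * ab[s, 1L] + ap_y * ab[s, 2L]) / len2[s]))
    d[, s] <- sqrt((ap_x - t_par * ab[s, 1L])^2 + (ap_y - t_par * ab[s, 2L])^2)
  }
  apply(d, 1L, min)
}
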