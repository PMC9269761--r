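#' @title Synthetic benchmark scenes
#' @description Generators for the binary/grayscale test images used to
#'   exercise the snake and its external forces: a U-shaped object (concavity
#'   convergence), heart/hook/semi-closed concavity shapes, and a double ring
#'   whose outer edge is blurred along an arc (weak-edge preservation).
#'   Every scene carries its analytic boundary polyline, so boundary-distance
#'   metrics never rely on hand-drawn truth.  All generators are pure
#'   functions of their parameters; [add_noise()] is explicitly seeded.
#' @name synthetic_scenes
NULL

new_scene <- function(image, boundary, name, params) {
  structure(list(image = image, boundary = boundary, name = name,
                 params = params,
                 size = c(h = nrow(image), w = ncol(image))),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("Synthetic scene '%s': %d x %d, boundary %d points\n",
              x$name, x$size["h"], x$size["w"],
              if (is.matrix(x$boundary)) nrow(x$boundary)
              else sum(vapply(x$boundary, nrow, 1L))))
  invisible(x)
}

#' @export
plot.scene <- function(x, ...) {
  plot_raster(x$image, main = x$name, ...)
  b <- if (is.matrix(x$boundary)) list(x$boundary) else x$boundary
  for (p in b) graphics::lines(rbind(p, p[1L, ]), col = "red")
  invisible(x)
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon with supersampled anti-aliasing
#'
#' Fills the polygon (foreground 1 on background 0) on a `size x size` pixel
#' grid, 0-based pixel-centered coordinates.  Each pixel is sampled on a
#' `ss x ss` subgrid and box-averaged, so boundary pixels take fractional
#' coverage values and edges span about one pixel — avoiding degenerate
#' single-pixel gradients in the edge map.
#'
#' @param poly N x 2 polygon vertex matrix (x, y).
#' @param size Image side length in pixels.
#' @param ss Supersampling factor per axis; default 4.
#' @return `size x size` numeric matrix in \[0,1\].
#' @export
rasterize_polygon <- function(poly, size, ss = 4L) {
  sub <- ((seq_len(ss) - 0.5) / ss) - 0.5
  centers <- seq_len(size) - 1
  coords <- as.vector(outer(sub, centers, `+`))  # ss*size ordered by pixel
  px <- rep(coords, times = size * ss)
  py <- rep(coords, each = size * ss)
  inside <- points_in_polygon(px, py, poly)
  m <- matrix(as.numeric(inside), nrow = size * ss, ncol = size * ss)
  # box-average ss x ss blocks; rows of m index x, columns index y here
  block <- function(mm) {
    out <- matrix(0, size, size)
    for (a in seq_len(ss)) {
      for (b in seq_len(ss)) {
        out <- out + mm[seq(a, by = ss, length.out = size),
                        seq(b, by = ss, length.out = size)]
      }
    }
    out / (ss * ss)
  }
  sub_img <- block(m)
  # sub_img[ix, iy]: transpose to image layout [row = y, col = x]
  t(sub_img)
}

#' U-shaped object scene
#'
#' A bright U (foreground 1) on dark background: a rectangle with a
#' rectangular notch cut into its top edge, the classic concavity-convergence
#' benchmark.  `depth = 0` degenerates to a plain rectangle.
#'
#' @param size Image side (>= 32); default 64.
#' @param opening_width Notch width in pixels.
#' @param depth Notch depth in pixels.
#' @param opening_center x coordinate of the notch center; default the image
#'   center (use an off-center value for asymmetric/mirrored variants).
#' @param margin Object margin from the image frame; default `size / 8`.
#' @return A `scene` with the analytic boundary polygon; `params$concavity`
#'   holds the notch rectangle (for region-restricted metrics).
#' @export
make_ushape <- function(size = 64L, opening_width = 16, depth = 24,
                        opening_center = NULL, margin = NULL) {
  stopifnot(size >= 32L)
  if (is.null(margin)) margin <- size / 8
  if (is.null(opening_center)) opening_center <- (size - 1) / 2
  left <- margin; right <- size - 1 - margin
  top <- margin; bottom <- size - 1 - margin
  xl <- opening_center - opening_width / 2
  xr <- opening_center + opening_width / 2
  if (xl <= left || xr >= right) {
    stop("opening does not fit inside the object", call. = FALSE)
  }
  if (depth < 0 || depth >= bottom - top) {
    stop("notch depth must be in [0, object height)", call. = FALSE)
  }
  poly <- if (depth == 0) {
    cbind(x = c(left, right, right, left),
          y = c(top, top, bottom, bottom))
  } else {
    cbind(x = c(left, xl, xl, xr, xr, right, right, left),
          y = c(top, top, top + depth, top + depth, top, top, bottom, bottom))
  }
  img <- rasterize_polygon(poly, size)
  new_scene(img, poly, "ushape",
            list(size = size, opening_width = opening_width, depth = depth,
                 opening_center = opening_center, margin = margin,
                 concavity = c(x0 = xl, x1 = xr, y0 = top, y1 = top + depth)))
}

#' Concavity test shapes
#'
#' Three shapes probing different concavity geometries:
#' * `"heart"` — two circular lobes over a tip, with a single reflex dimple
#'   between the lobes (exactly one concave boundary region);
#' * `"hook"` — a rectangle with an L-shaped (bent) cavity;
#' * `"semiclosed"` — a rectangle with a chamber whose entrance is narrower
#'   than its interior.
#'
#' @param kind One of `"heart"`, `"hook"`, `"semiclosed"`.
#' @param size Image side (>= 32); default 64.
#' @param entrance_width For `"semiclosed"`, the entrance width in pixels
#'   (default 4); the chamber interior is substantially wider.
#' @return A `scene` with the analytic boundary polygon.
#' @export
make_concavity_shape <- function(kind = c("heart", "hook", "semiclosed"),
                                 size = 64L, entrance_width = 4) {
  kind <- match.arg(kind)
  stopifnot(size >= 32L)
  u <- size / 64  # scale unit: shapes are drafted on a 64-grid
  poly <- switch(kind,
    heart = heart_polygon(size),
    hook = u * cbind(
      x = c(10, 34, 34, 20, 20, 44, 44, 54, 54, 10),
      y = c(10, 10, 28, 28, 40, 40, 10, 10, 54, 54)),
    semiclosed = {
      ew <- entrance_width
      cxm <- 32 * u
      stopifnot(ew >= 1, ew < 20 * u)  # entrance narrower than the chamber
      cbind(
        x = c(10 * u, cxm - ew / 2, cxm - ew / 2, 20 * u, 20 * u, 44 * u,
              44 * u, cxm + ew / 2, cxm + ew / 2, 54 * u, 54 * u, 10 * u),
        y = u * c(10, 10, 24, 24, 44, 44, 24, 24, 10, 10, 54, 54))
    }
  )
  img <- rasterize_polygon(poly, size)
  new_scene(img, poly, paste0("concavity_", kind),
            list(kind = kind, size = size,
                 entrance_width = if (kind == "semiclosed") entrance_width
                                  else NA_real_))
}

# Heart outline: two lobes (circles) meeting at a reflex dimple, tangent
# lines down to a tip.  Drafted in y-up coordinates, flipped to image rows.
heart_polygon <- function(size) {
  s <- size / 64
  r <- 12 * s; d <- 8 * s
  lobe_y <- 38 * s        # y-up height of lobe centers
  tip <- c(32 * s, 8 * s) # y-up tip
  h <- sqrt(r^2 - d^2)
  cx <- 32 * s
  dimple <- c(cx, lobe_y + h)
  cR <- c(cx + d, lobe_y)
  # tangent point from tip to right circle (lower-right touch point)
  tangent_touch <- function(C, P, r) {
    v <- P - C
    L2 <- sum(v^2)
    dd <- sqrt(L2 - r^2)
    # touch points of tangent lines from P
    base <- C + r^2 / L2 * v
    off <- r * dd / L2 * c(-v[2L], v[1L])
    list(base + off, base - off)
  }
  tt <- tangent_touch(cR, tip, r)
  # pick the touch point on the outer (right/lower) side
  touch <- if (tt[[1L]][1L] > tt[[2L]][1L]) tt[[1L]] else tt[[2L]]
  a0 <- atan2(dimple[2L] - cR[2L], dimple[1L] - cR[1L])
  a1 <- atan2(touch[2L] - cR[2L], touch[1L] - cR[1L])
  if (a1 > a0) a1 <- a1 - 2 * pi  # go clockwise (over the top of the lobe)
  th <- seq(a0, a1, length.out = 40L)
  arc_r <- cbind(cR[1L] + r * cos(th), cR[2L] + r * sin(th))
  right_side <- rbind(dimple, arc_r[-1L, ], tip)
  left_side <- right_side[rev(seq_len(nrow(right_side) - 1L)[-1L]), , drop = FALSE]
  left_side[, 1L] <- 2 * cx - left_side[, 1L]
  poly_up <- rbind(right_side, left_side)
  cbind(x = poly_up[, 1L], y = (size - 1) - poly_up[, 2L])
}

#' Double-ring scene with a locally blurred (weak) outer edge
#'
#' Two concentric intensity steps: background 0, annulus between the inner
#' and outer circles at 0.5, inner disk at 1.0 — so the inner circle is a
#' strong edge and the outer circle an equally strong edge, except that the
#' outer transition is Gaussian-blurred within the given angular arc,
#' creating a locally weak edge toward which a snake is prone to leak.
#' Outside the arc the image is bit-identical to the `blur_sigma = 0` scene.
#' Ground truth is the outer circle.
#'
#' @param size Image side; default 64.
#' @param r_outer,r_inner Circle radii (pixels), `r_inner < r_outer <
#'   size/2`; defaults scale with `size` (24 and 12 at 64).
#' @param blur_arc Length-2 numeric, angular interval \[rad\] of the blurred
#'   arc; angles measured counter-clockwise from the +x axis in standard
#'   orientation (y up), so `c(0, pi/2)` is the upper-right quadrant.
#' @param blur_sigma Gaussian blur scale for the outer transition inside the
#'   arc; 0 = no blur.  The default 1.5 weakens the arc's edge-map ridge to
#'   roughly a third of the strong-edge peak while keeping it a distinct
#'   ridge: the blurred transition band must stay well inside the
#'   `r_outer - r_inner` gap, or the "weak edge" ceases to exist as an edge
#'   and every gradient-based force field collapses to the inner ring.
#' @return A `scene`; the boundary is the outer circle (128-gon), and
#'   `params` records the arc for arc-restricted metrics.
#' @export
make_weak_edge_ring <- function(size = 64L, r_outer = 0.375 * size,
                                r_inner = r_outer / 2,
                                blur_arc = c(0, pi / 2), blur_sigma = 1.5) {
  stopifnot(r_inner >= 2, r_inner < r_outer, r_outer < size / 2,
            blur_sigma >= 0, length(blur_arc) == 2L)
  cc <- (size - 1) / 2
  disk <- function(r) {
    ss <- 4L
    sub <- ((seq_len(ss) - 0.5) / ss) - 0.5
    centers <- seq_len(size) - 1
    coords <- as.vector(outer(sub, centers, `+`))
    px <- rep(coords, times = size * ss)
    py <- rep(coords, each = size * ss)
    inside <- (px - cc)^2 + (py - cc)^2 <= r^2
    m <- matrix(as.numeric(inside), size * ss, size * ss)
    out <- matrix(0, size, size)
    for (a in seq_len(ss)) for (b in seq_len(ss)) {
      out <- out + m[seq(a, by = ss, length.out = size),
                     seq(b, by = ss, length.out = size)]
    }
    t(out / (ss * ss))
  }
  outer_comp <- 0.5 * disk(r_outer)
  inner_comp <- 0.5 * disk(r_inner)
  if (blur_sigma > 0) {
    blurred <- gaussian_smooth(outer_comp, blur_sigma)
    xs <- matrix(rep(0:(size - 1), each = size), size, size) - cc
    ys <- matrix(rep(0:(size - 1), times = size), size, size) - cc
    ang <- atan2(-ys, xs)  # y axis points down in image rows; flip for math
    in_arc <- angle_in_arc(ang, blur_arc[1L], blur_arc[2L])
    outer_comp[in_arc] <- blurred[in_arc]
  }
  img <- pmin(outer_comp + inner_comp, 1)
  th <- seq(0, 2 * pi, length.out = 129L)[-129L]
  boundary <- cbind(x = cc + r_outer * cos(th), y = cc - r_outer * sin(th))
  new_scene(img, boundary, "weak_edge_ring",
            list(size = size, r_outer = r_outer, r_inner = r_inner,
                 blur_arc = blur_arc, blur_sigma = blur_sigma, center = cc))
}

angle_in_arc <- function(ang, a0, a1) {
  two_pi <- 2 * pi
  rel <- (ang - a0) %% two_pi
  span <- (a1 - a0) %% two_pi
  if (span == 0) span <- two_pi
  rel <= span
}

#' Add clipped Gaussian noise to a scene
#'
#' Adds i.i.d. Gaussian noise of standard deviation `level` to the image and
#' clips back to \[0,1\].  Seeded and reproducible: the same `(scene, level,
#' seed)` always yields the same output, and the caller's random stream is
#' left untouched.
#'
#' @param scene A `scene`.
#' @param level Noise standard deviation in intensity units (>= 0).
#' @param seed Integer RNG seed.
#' @return The scene with a noisy image and an updated descriptor.
#' @export
add_noise <- function(scene, level, seed = 1L) {
  stopifnot(inherits(scene, "scene"), level >= 0)
  if (level == 0) return(scene)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(scene$image), sd = level),
                  nrow(scene$image), ncol(scene$image))
  scene$image <- pmin(pmax(scene$image + noise, 0), 1)
  scene$params$noise <- c(level = level, seed = seed)
  scene
}
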