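#' Edge map of a grayscale image
#'
#' The edge-strength field driving every external force in this package:
#' `f = |grad(G_sigma * I)|^2`, the squared gradient magnitude of the
#' Gaussian-smoothed image, rescaled so its maximum is 1 (for a non-constant
#' image).  The rescaling puts the diffusion thresholds `k` (GGVF) and `K`
#' (HBGVF) on a consistent scale across images.  `fx`, `fy` are the central
#' -difference gradient of `f` itself; `gmag2 = fx^2 + fy^2` is the data-term
#' weight of the GVF family.
#'
#' @param image Numeric matrix with intensities in \[0,1\]
#'   (see [normalize_intensity()]); at least 3x3.
#' @param sigma Gaussian smoothing scale in pixels (>= 0; 0 = no smoothing).
#' @return An object of class `edge_map`: list with `f`, `fx`, `fy`, `gmag2`,
#'   and the `sigma` used.
#' @examples
#' img <- matrix(0, 16, 16); img[, 9:16] <- 1
#' em <- edge_map(img, sigma = 1)
#' max(em$f)  # 1
#' @export
edge_map <- function(image, sigma = 1) {
  check_image(image)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  sm <- gaussian_smooth(image, sigma)
  g <- gradient_xy(sm)
  f <- g$gx^2 + g$gy^2
  mx <- max(f)
  if (mx > 0) f <- f / mx
  gf <- gradient_xy(f)
  structure(
    list(f = f, fx = gf$gx, fy = gf$gy, gmag2 = gf$gx^2 + gf$gy^2,
         sigma = sigma),
    class = "edge_map"
  )
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("Edge map: %d x %d, sigma = %g, max |grad f|^2 = %.4g\n",
              nrow(x$f), ncol(x$f), x$sigma, max(x$gmag2)))
  invisible(x)
}

#' @export
plot.edge_map <- function(x, ...) {
  plot_raster(x$f, main = "edge map f", ...)
  invisible(x)
}

# Shared raster display: row 1 at the top, grayscale.
plot_raster <- function(mat, main = "", ...) {
  h <- nrow(mat); w <- ncol(mat)
  graphics::image(x = 0:(w) - 0.5, y = 0:(h) - 0.5,
                  z = t(mat[h:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  asp = 1, xlab = "x", ylab = "y", main = main,
                  useRaster = TRUE, ...)
}

check_edge_map <- function(edge) {
  if (!inherits(edge, "edge_map")) {
    stop("expected an edge_map object (see edge_map())", call. = FALSE)
  }
  invisible(edge)
}
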