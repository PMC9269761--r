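#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM rasters as a numeric matrix.  Color images are
#' reduced to grayscale by the unweighted channel average before any further
#' processing.  The returned matrix is row = y (top to bottom), column = x,
#' the usual raster layout.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @return Numeric matrix of intensities (not yet normalized; PNG/TIFF decode
#'   to \[0,1\], PGM to its stated maxval scale).
#' @seealso [normalize_intensity()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = read_pgm(path),
    stop("unsupported image format: .", ext, " (use PNG, TIFF or PGM)",
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    # drop an alpha channel, average the color channels
    if (nc == 4L) img <- img[, , 1:3, drop = FALSE]
    img <- apply(img, c(1L, 2L), mean)
  }
  storage.mode(img) <- "double"
  img
}

# Minimal PGM reader: ASCII (P2) and 8/16-bit binary (P5).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  }
  # header tokens: width height maxval, '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header", call. = FALSE)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  }
  if (length(vals) != n) stop("truncated PGM pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Min-max normalize image intensities to \[0,1\]
#'
#' All processing in this package assumes intensities in \[0,1\]; raw rasters
#' are affinely rescaled so that the darkest pixel maps to 0 and the brightest
#' to 1.  A constant image has no contrast and maps to all zeros.
#'
#' @param image Numeric matrix of finite intensities.
#' @return Numeric matrix with values in \[0,1\].
#' @examples
#' normalize_intensity(matrix(c(10, 20, 30, 10, 20, 30, 10, 20, 30), 3))
#' @export
normalize_intensity <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (length(image) < 1L) stop("image must have at least one pixel", call. = FALSE)
  if (!all(is.finite(image))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  r <- range(image)
  if (r[2L] == r[1L]) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - r[1L]) / (r[2L] - r[1L])
}

check_image <- function(image, min_side = 3L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < min_side || ncol(image) < min_side) {
    stop("image must be at least ", min_side, "x", min_side, call. = FALSE)
  }
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("image intensities must lie in [0,1]; call normalize_intensity() first",
         call. = FALSE)
  }
  invisible(image)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable Gaussian convolution, kernel truncated at 4 standard deviations,
#' boundaries handled by mirror (half-sample symmetric) reflection so that no
#' artificial edge appears at the image frame.  `sigma = 0` returns the input
#' unchanged.
#'
#' @param field Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(field, sigma) {
  stopifnot(is.matrix(field), is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(field)
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  out <- conv1_reflect(field, kern)        # along rows (y direction)
  out <- t(conv1_reflect(t(out), kern))    # along columns (x direction)
  out
}

# 1-D convolution down the rows of a matrix with mirror padding.
conv1_reflect <- function(mat, kern) {
  if (length(kern) == 0L) return(mat)
  r <- (length(kern) - 1L) %/% 2L
  n <- nrow(mat)
  idx <- c(pmin(n, pmax(1L, r:1)), 1:n, pmin(n, pmax(1L, n:(n - r + 1L))))
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (k in seq_along(kern)) {
    out <- out + kern[k] * padded[(k - 1L) + 1:n, , drop = FALSE]
  }
  out
}

#' Discrete gradient of a scalar field
#'
#' Central differences at interior pixels, one-sided first differences at the
#' borders, so the outputs keep the input's shape.  `gx` is the derivative
#' along x (columns), `gy` along y (rows); grid spacing is 1 pixel.
#'
#' @param field Numeric matrix of finite values.
#' @return List with matrices `gx` and `gy`.
#' @export
gradient_xy <- function(field) {
  stopifnot(is.matrix(field), all(is.finite(field)))
  h <- nrow(field); w <- ncol(field)
  if (w >= 3L) {
    gx <- cbind(field[, 2L] - field[, 1L],
                (field[, 3:w, drop = FALSE] - field[, 1:(w - 2L), drop = FALSE]) / 2,
                field[, w] - field[, w - 1L])
  } else {
    gx <- cbind(field[, w] - field[, 1L], field[, w] - field[, 1L])[, 1:w, drop = FALSE]
  }
  if (h >= 3L) {
    gy <- rbind(field[2L, ] - field[1L, ],
                (field[3:h, , drop = FALSE] - field[1:(h - 2L), , drop = FALSE]) / 2,
                field[h, ] - field[h - 1L, ])
  } else {
    gy <- rbind(field[h, ] - field[1L, ], field[h, ] - field[1L, ])[1:h, , drop = FALSE]
  }
  list(gx = gx, gy = gy)
}

# Neighbor shifts with replicated (Neumann) borders; used by the 5-point
# Laplacian and the second-difference stencils.
shift_up    <- function(m) m[c(1L, 1:(nrow(m) - 1L)), , drop = FALSE]
shift_down  <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1L, 1:(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]

#' Five-point Laplacian with replicated borders
#'
#' @param field Numeric matrix.
#' @return Matrix of the same size holding the discrete Laplacian.
#' @keywords internal
laplacian5 <- function(field) {
  shift_up(field) + shift_down(field) + shift_left(field) + shift_right(field) -
    4 * field
}
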