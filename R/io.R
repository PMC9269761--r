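#' Run configuration
#'
#' Bundles every parameter of a field/segmentation run with defaults from the
#' reference experimental settings: `alpha = beta = 0.1`, `tau = 0.5`,
#' `mu = 0.2` (GVF/NGVF/HBGVF), `k = 0.5` (GGVF/CN-GGVF), `K = 0.1` (HBGVF),
#' field `dt = 1` (0.2 for the GGVF-type schemes, whose stability bound is
#' tighter).  Configs serialize losslessly to flat `key = value` text.
#'
#' @param method Field method: one of `"gvf"`, `"ggvf"`, `"vef"`, `"ngvf"`,
#'   `"cnggvf"`, `"hbgvf"`.
#' @param input,output Optional input image path / output path.
#' @param sigma Edge-map (and Hessian) Gaussian scale.
#' @param mu,k,K,dt,n_iter,t Field parameters (see the field constructors).
#' @param alpha,beta,tau,max_iter,tol,force_mode Snake parameters.
#' @param init Initial contour spec: `"circle:cx,cy,r"` or a contour file
#'   path.
#' @param seed RNG seed recorded for provenance.
#' @param verbose Logical; log progress and energy checkpoints.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(method = "hbgvf", input = NULL, output = NULL,
                       sigma = 1, mu = 0.2, k = 0.5, K = 0.1,
                       dt = NULL, n_iter = NULL, t = 5,
                       alpha = 0.1, beta = 0.1, tau = 0.5,
                       max_iter = 2000, tol = 0.01, force_mode = "raw",
                       init = NULL, seed = 1, verbose = FALSE) {
  method <- match.arg(method, c("gvf", "ggvf", "vef", "ngvf", "cnggvf",
                                "hbgvf"))
  if (is.null(dt)) dt <- if (method %in% c("ggvf", "cnggvf")) 0.2 else 1
  structure(list(method = method, input = input, output = output,
                 sigma = sigma, mu = mu, k = k, K = K, dt = dt,
                 n_iter = n_iter, t = t, alpha = alpha, beta = beta,
                 tau = tau, max_iter = max_iter, tol = tol,
                 force_mode = force_mode, init = init, seed = seed,
                 verbose = verbose),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run config:\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Write / read a run configuration as flat key = value text
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config` (round-trips losslessly).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- !vapply(config, is.null, TRUE)
  lines <- vapply(names(config)[keep], function(nm) {
    val <- config[[nm]]
    sprintf("%s = %s", nm,
            if (is.character(val)) val
            else if (is.logical(val)) tolower(as.character(val))
            else paste(format(val, digits = 17), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(
    lines,
    regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
            lines))
  cfg <- run_config()
  numeric_keys <- c("sigma", "mu", "k", "K", "dt", "n_iter", "t", "alpha",
                    "beta", "tau", "max_iter", "tol", "seed")
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[2L]; val <- trimws(m[3L])
    cfg[[key]] <- if (key %in% numeric_keys) as.numeric(val)
      else if (key == "verbose") identical(val, "true")
      else val
  }
  cfg
}

#' Serialize a vector field to plain text
#'
#' Header lines (`# key: value`) record the method and parameters, followed
#' by `x y u v` rows (0-based pixel coordinates), one per pixel.
#'
#' @param field A `vector_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  h <- nrow(field$u); w <- ncol(field$u)
  hdr <- c(sprintf("# method: %s", field$method),
           sprintf("# shape: %d %d", h, w),
           vapply(names(field$params), function(nm)
             sprintf("# %s: %s", nm, format(field$params[[nm]], digits = 17)),
             ""),
           "# columns: x y u v")
  g <- expand.grid(row = seq_len(h), col = seq_len(w))
  body <- sprintf("%d %d %.17g %.17g", g$col - 1L, g$row - 1L,
                  field$u[cbind(g$row, g$col)], field$v[cbind(g$row, g$col)])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a vector field written by [write_field()]
#'
#' @param path Path to a field text file.
#' @return A `vector_field`.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(m) == 0L) return(NULL)
    trimws(sub(paste0("# ", key, ":"), "", m[1L], fixed = TRUE))
  }
  shape <- as.integer(strsplit(get_hdr("shape"), " ")[[1L]])
  h <- shape[1L]; w <- shape[2L]
  dat <- utils::read.table(text = body, col.names = c("x", "y", "u", "v"))
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  u[cbind(dat$y + 1L, dat$x + 1L)] <- dat$u
  v[cbind(dat$y + 1L, dat$x + 1L)] <- dat$v
  method <- get_hdr("method")
  known <- setdiff(vapply(strsplit(sub("^# ", "", hdr), ":"), `[`, "", 1L),
                   c("method", "shape", "columns"))
  params <- lapply(known, function(k) {
    val <- get_hdr(k)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) val else num
  })
  names(params) <- known
  new_vector_field(u, v, method, params)
}

#' Write / read a contour
#'
#' Plain-text contours are `x,y` rows (closure implied); JSON contours
#' (`.json` extension) carry the coordinates plus arbitrary metadata.
#'
#' @param points N x 2 contour matrix.
#' @param path Output path (`.json` triggers JSON, anything else text).
#' @param metadata Named list stored alongside JSON contours.
#' @return `path` invisibly (write); an N x 2 matrix (read).
#' @export
write_contour <- function(points, path, metadata = list()) {
  check_contour(points)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(x = points[, 1L], y = points[, 2L], metadata = metadata),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("%.17g,%.17g", points[, 1L], points[, 2L]), path)
  }
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(cbind(x = obj$x, y = obj$y))
  }
  dat <- utils::read.csv(path, header = FALSE, col.names = c("x", "y"))
  cbind(x = dat$x, y = dat$y)
}

# Build the requested external force field from an image matrix.
compute_field <- function(image, config) {
  em <- edge_map(image, sigma = config$sigma)
  n_iter <- if (is.null(config$n_iter) || is.na(config$n_iter)) NULL
            else config$n_iter
  switch(config$method,
    gvf = gvf(em, mu = config$mu, dt = config$dt, n_iter = n_iter,
              energy_every = if (isTRUE(config$verbose)) 50 else 0),
    ggvf = ggvf(em, k = config$k, dt = config$dt, n_iter = n_iter),
    vef = vef_fft(em, t = config$t),
    ngvf = ngvf(em, mu = config$mu, dt = config$dt, n_iter = n_iter),
    cnggvf = cn_ggvf(em, k = config$k, dt = config$dt, n_iter = n_iter),
    hbgvf = {
      tens <- diffusion_tensor(image, K = config$K, sigma = config$sigma)
      hbgvf(em, tens, mu = config$mu, dt = config$dt, n_iter = n_iter,
            energy_every = if (isTRUE(config$verbose)) 50 else 0)
    }
  )
}

#' Compute and write an external force field from a config
#'
#' Reads and normalizes the input image, computes the configured field, and
#' writes it with a provenance header via [write_field()].  With
#' `verbose = TRUE`, parameter values and (for the energy-bearing GVF/HBGVF
#' schemes) the discrete energy every 50 iterations are reported.
#'
#' @param config A [run_config()] with `input` and `output` set (or `image`
#'   supplied directly).
#' @param image Optional image matrix overriding `config$input`.
#' @return The `vector_field`, invisibly.
#' @export
run_field <- function(config, image = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(image)) {
    if (is.null(config$input)) stop("config$input is not set", call. = FALSE)
    image <- read_gray_image(config$input)
  }
  image <- normalize_intensity(image)
  if (isTRUE(config$verbose)) {
    message(sprintf("field: method=%s sigma=%g mu=%g k=%g K=%g dt=%g",
                    config$method, config$sigma, config$mu, config$k,
                    config$K, config$dt))
  }
  fld <- compute_field(image, config)
  if (isTRUE(config$verbose) && !is.null(fld$energy)) {
    message("energy checkpoints (every 50 iters): ",
            paste(sprintf("%.4g", fld$energy), collapse = " "))
  }
  if (!is.null(config$output)) write_field(fld, config$output)
  invisible(fld)
}

parse_init <- function(init) {
  if (is.matrix(init)) return(init)
  if (is.character(init) && startsWith(init, "circle:")) {
    vals <- as.numeric(strsplit(sub("circle:", "", init), ",")[[1L]])
    if (length(vals) != 3L || anyNA(vals)) {
      stop("bad circle init spec; expected circle:cx,cy,r", call. = FALSE)
    }
    return(circle_contour(vals[1L], vals[2L], vals[3L]))
  }
  if (is.character(init) && file.exists(init)) return(read_contour(init))
  stop("init must be a contour matrix, 'circle:cx,cy,r', or a contour file",
       call. = FALSE)
}

#' Run a full segmentation from a config
#'
#' Computes (or accepts) the external force field, evolves the snake from the
#' configured initial contour, and optionally writes the final contour and an
#' overlay PNG (initial contour dashed gray, final contour solid red).
#'
#' @param config A [run_config()]; `init` must be set.
#' @param image Optional image matrix overriding `config$input`.
#' @param field Optional precomputed `vector_field` (skips field
#'   computation).
#' @param overlay_path Optional path for an overlay PNG.
#' @return The `snake` fit, invisibly.
#' @export
run_segment <- function(config, image = NULL, field = NULL,
                        overlay_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(image)) {
    if (is.null(config$input)) stop("config$input is not set", call. = FALSE)
    image <- read_gray_image(config$input)
  }
  image <- normalize_intensity(image)
  if (is.null(field)) field <- compute_field(image, config)
  init <- parse_init(config$init)
  fit <- snake(field, init, alpha = config$alpha, beta = config$beta,
               tau = config$tau, max_iter = config$max_iter,
               tol = config$tol, force_mode = config$force_mode)
  if (fit$failed) {
    warning("snake failed to converge (contour collapse)", call. = FALSE)
  }
  if (!is.null(config$output)) write_contour(fit$points, config$output)
  if (!is.null(overlay_path)) {
    write_overlay(image, fit$init, fit$points, overlay_path)
  }
  invisible(fit)
}

#' Write an overlay PNG of initial and final contours on the image
#'
#' The initial contour is drawn as a dashed gray line and the final contour
#' as a solid red line, rasterized directly into an RGB copy of the image.
#'
#' @param image Image matrix in \[0,1\].
#' @param init,final Contour matrices.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, init, final, path) {
  h <- nrow(image); w <- ncol(image)
  rgb <- array(rep(image, 3L), dim = c(h, w, 3L))
  stamp <- function(pts, col, dashed = FALSE) {
    closed <- rbind(pts, pts[1L, , drop = FALSE])
    for (s in seq_len(nrow(closed) - 1L)) {
      if (dashed && s %% 2L == 0L) next
      a <- closed[s, ]; b <- closed[s + 1L, ]
      n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
      tpar <- seq(0, 1, length.out = n)
      xs <- round(a[1L] + tpar * (b[1L] - a[1L])) + 1L
      ys <- round(a[2L] + tpar * (b[2L] - a[2L])) + 1L
      ok <- xs >= 1L & xs <= w & ys >= 1L & ys <= h
      for (ch in 1:3) {
        rgb[cbind(ys[ok], xs[ok], ch)] <<- col[ch]
      }
    }
  }
  stamp(init, c(0.6, 0.6, 0.6), dashed = TRUE)
  stamp(final, c(1, 0, 0))
  png::writePNG(rgb, path)
  invisible(path)
}
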