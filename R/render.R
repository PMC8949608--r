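# Synthetic microscopy rendering: the stand-in for the camera.

#' Render a grayscale frame of the bead suspension
#'
#' Deterministic rendering of the field of view: uniform background, brighter
#' electrode stripes, beads drawn as dark filled disks of radius
#' `radius_um / um_per_px` pixels, followed by a mild Gaussian blur. Pixel
#' (0,0) is top-left, x grows rightward, intensities lie in \[0, 1\]. Beads
#' outside the field of view are silently clipped.
#'
#' @param pop Bead tibble ([init_beads()]).
#' @param geometry An [electrode_geometry()].
#' @param bg,electrode,bead Intensities of background, electrode stripes and
#'   bead disks.
#' @param blur_sigma Gaussian blur standard deviation (px).
#' @return A numeric matrix (`frame_h_px` x `frame_w_px`) in \[0, 1\].
#' @export
render_frame <- function(pop, geometry, bg = 0.40, electrode = 0.65,
                         bead = 0.05, blur_sigma = 0.7) {
  w <- geometry$frame_w_px
  h <- geometry$frame_h_px
  img <- matrix(bg, nrow = h, ncol = w)

  # electrode stripes: columns whose centre lies over a finger
  colc_um <- px_to_um_x(geometry, seq_len(w) - 1)
  over <- vapply(colc_um, function(x) {
    any(x >= geometry$fingers[, "xL"] & x <= geometry$fingers[, "xR"])
  }, logical(1))
  img[, over] <- electrode

  if (nrow(pop) > 0) {
    r_px <- pop$radius_um / geometry$um_per_px
    cx <- um_to_px_x(geometry, pop$x_um)
    cy <- um_to_px_y(geometry, pop$y_um)
    for (i in seq_len(nrow(pop))) {
      xs <- max(0, floor(cx[i] - r_px[i] - 1)):min(w - 1, ceiling(cx[i] + r_px[i] + 1))
      ys <- max(0, floor(cy[i] - r_px[i] - 1)):min(h - 1, ceiling(cy[i] + r_px[i] + 1))
      if (length(xs) == 0 || length(ys) == 0 || xs[1] > xs[length(xs)]) next
      dx <- outer(rep(1, length(ys)), xs - cx[i])
      dy <- outer(ys - cy[i], rep(1, length(xs)))
      disk <- sqrt(dx^2 + dy^2) <= r_px[i]
      sub <- img[ys + 1, xs + 1, drop = FALSE]
      sub[disk] <- bead
      img[ys + 1, xs + 1] <- sub
    }
  }
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  img
}

# separable Gaussian blur with edge-replicated borders
gaussian_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  img <- apply(img, 2, conv1_replicate, kern = k)      # down each column
  t(apply(img, 1, conv1_replicate, kern = k))          # along each row
}

conv1_replicate <- function(v, kern) {
  r <- (length(kern) - 1L) / 2L
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  out <- stats::filter(vp, kern, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Write frames as numbered PNG files
#'
#' @param frames List of grayscale matrices in \[0, 1\].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths (`frame_000001.png`, ...).
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[i]], 0), 1), paths[i])
  }
  invisible(paths)
}

#' Read a frame sequence
#'
#' Reads either a directory of numbered PNG frames (the dialect written by
#' [write_frames()]) or a single multi-page TIFF file.
#'
#' @param path Directory of PNGs, or a `.tif`/`.tiff` file.
#' @return List of grayscale matrices in \[0, 1\].
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", path, call. = FALSE)
    return(lapply(files, function(f) to_gray(png::readPNG(f))))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages) || (is.array(pages) && length(dim(pages)) <= 3)) {
      pages <- list(pages)
    }
    return(lapply(pages, to_gray))
  }
  stop("`path` must be a directory of PNGs or a TIFF file", call. = FALSE)
}

# luminance average for multi-channel images
to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    nc <- min(dim(img)[3], 3)  # ignore alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}
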