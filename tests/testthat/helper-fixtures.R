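# Shared fixtures, all generated in code.

# a small, fast geometry for loop tests (half-scale imaging so rendered beads
# span ~6 px)
small_geometry <- function(um_per_px = 0.5) {
  electrode_geometry(n_fingers = 4, gap_um = 70, finger_width_um = 20,
                     um_per_px = um_per_px, fov_h_um = 60)
}

# plain frame with dark disks at known centres (0-based pixel coordinates)
make_disk_frame <- function(centers, r = 5, size = 128, bg = 0.4,
                            fg = 0.05, blur = 0.7) {
  img <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(0, floor(cx - r - 1)):min(size - 1, ceiling(cx + r + 1))
    ys <- max(0, floor(cy - r - 1)):min(size - 1, ceiling(cy + r + 1))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    sub <- img[ys + 1, xs + 1, drop = FALSE]
    sub[sqrt(dx^2 + dy^2) <= r] <- fg
    img[ys + 1, xs + 1] <- sub
  }
  if (blur > 0) img <- depsweep:::gaussian_blur(img, blur)
  img
}

# n well-separated random centres inside [lo, hi]^2
separated_centers <- function(n, lo, hi, min_sep) {
  repeat {
    c0 <- cbind(stats::runif(n, lo, hi), stats::runif(n, lo, hi))
    if (n < 2 || min(stats::dist(c0)) >= min_sep) return(c0)
  }
}

# random material set guaranteed to possess a crossover
# (sigma_p > sigma_m, eps_p < eps_m)
random_crossover_materials <- function() {
  material_set(eps_p_rel = stats::runif(1, 2, 10),
               eps_m_rel = stats::runif(1, 50, 80),
               sigma_p = 10^stats::runif(1, -3, -2),
               sigma_m = 10^stats::runif(1, -4.7, -3.5))
}
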