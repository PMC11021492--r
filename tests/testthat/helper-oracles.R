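# analytically parameterised twisted plane: two leaflets of points whose
# cross-sections rotate by exactly `theta_total` degrees from end to end;
# closed-form oracle independent of build_ribbon()
twisted_plane <- function(n_seg = 15, n_col = 9, length_nm = 20,
                          theta_total = 80, gap = 1) {
  grid <- tidyr::expand_grid(leaflet = c("upper", "lower"),
                             column = seq_len(n_col),
                             segment = seq_len(n_seg))
  x <- (grid$segment - 1) / (n_seg - 1) * length_nm
  ang <- (x / length_nm) * theta_total * pi / 180
  y0 <- (grid$column - (n_col + 1) / 2) * 0.5
  z0 <- ifelse(grid$leaflet == "upper", gap / 2, -gap / 2)
  tibble::tibble(
    monomer_id = seq_len(nrow(grid)),
    leaflet = grid$leaflet, column = grid$column, segment = grid$segment,
    residue = 1L,
    x = x, y = y0 * cos(ang) - z0 * sin(ang),
    z = y0 * sin(ang) + z0 * cos(ang)
  )
}

# random proper rigid motion applied to labelled coordinates
rigid_motion <- function(coords, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- stats::rnorm(3, sd = 10)
  })
  p <- as.matrix(coords[, c("x", "y", "z")]) %*% t(q)
  coords$x <- p[, 1] + shift[1]
  coords$y <- p[, 2] + shift[2]
  coords$z <- p[, 3] + shift[3]
  coords
}
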