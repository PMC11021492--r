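#' Height-map container
#'
#' A raster of apparent heights (nm) on a square pixel grid, emulating an
#' AFM scan of a helix lying on a flat substrate. Rows index the lateral
#' (y) direction, columns the axial (x) direction before any in-plane
#' rotation.
#'
#' @param grid Numeric matrix of heights, nm (finite, >= 0).
#' @param pixel_size Edge length of a pixel, nm.
#' @param axis_angle In-plane orientation of the helix axis, degrees.
#' @return An object of class `"heightmap"`.
#' @export
heightmap <- function(grid, pixel_size, axis_angle = 0) {
  if (!is.matrix(grid) || !is.numeric(grid) || any(!is.finite(grid))) {
    abort_bad_arg("`grid` must be a finite numeric matrix.")
  }
  if (any(grid < 0)) abort_bad_arg("heights must be >= 0.")
  check_number(pixel_size, "pixel_size", lower = 0, allow_lower = FALSE)
  check_number(axis_angle, "axis_angle")
  structure(list(grid = grid, pixel_size = pixel_size,
                 axis_angle = axis_angle),
            class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d px at %.3g nm/px, axis at %.1f deg, max %.2f nm\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, x$axis_angle,
              max(x$grid)))
  invisible(x)
}

# upper envelope (max z as a function of y) of a W x T rectangle rotated by
# alpha radians and resting on the substrate plane z = 0, sampled at `ys`
rect_upper_envelope <- function(width, thickness, alpha, ys) {
  cy <- c(-width, width, width, -width) / 2
  cz <- c(-thickness, -thickness, thickness, thickness) / 2
  y <- cy * cos(alpha) - cz * sin(alpha)
  z <- cy * sin(alpha) + cz * cos(alpha)
  z <- z - min(z) # rest on the substrate
  # collapse duplicate y (axis-aligned angles), keep max z
  o <- order(y)
  y <- y[o]; z <- z[o]
  keep <- c(TRUE, diff(y) > 1e-12)
  for (k in which(!keep)) z[max(which(keep[seq_len(k)]))] <-
      max(z[max(which(keep[seq_len(k)]))], z[k])
  y <- y[keep]; z <- z[keep]
  if (length(y) == 1L) return(ifelse(abs(ys - y) < 1e-12, z, 0))
  # upper hull by monotone chain
  hy <- numeric(0); hz <- numeric(0)
  for (k in seq_along(y)) {
    while (length(hy) >= 2) {
      n <- length(hy)
      cross <- (hy[n] - hy[n - 1]) * (z[k] - hz[n - 1]) -
               (hz[n] - hz[n - 1]) * (y[k] - hy[n - 1])
      if (cross >= 0) { hy <- hy[-n]; hz <- hz[-n] } else break
    }
    hy <- c(hy, y[k]); hz <- c(hz, z[k])
  }
  out <- stats::approx(hy, hz, xout = ys, yleft = NA, yright = NA)$y
  out[is.na(out)] <- 0
  out
}

# separable Gaussian blur with zero (background) padding
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(numeric(r), v, numeric(r))
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Render an AFM-like height map of a rigid twisted ribbon
#'
#' The ribbon cross-section (a `width_nm` x `thickness_nm` rectangle)
#' rotates about the long axis by `360 * x / pitch_nm` degrees at axial
#' position x; the map records the upper envelope of the rotated rectangle
#' resting on the substrate, so the axial height profile oscillates between
#' the thickness (face-on) and about the width (edge-on) with period
#' `pitch_nm / 2` (two-fold ribbon symmetry). An optional apparent-height
#' value emulates what AFM actually reports (substrate flattening for low
#' apparent heights, multilayer stacking for large ones): the rigid relief
#' is rescaled so the apparent height sits at `plateau_frac` of the rigid
#' maximum and capped there, giving every half-turn a wide flat top at
#' exactly the apparent height. The map is then convolved with a Gaussian
#' tip of sd `tip_sigma_nm` and perturbed with seeded Gaussian noise.
#'
#' @param width_nm Ribbon width (> 0).
#' @param thickness_nm Ribbon thickness (> 0).
#' @param pitch_nm Pitch per full turn (> 0), or `NULL` for an untwisted
#'   flat stripe.
#' @param handedness `"right"` or `"left"`.
#' @param length_nm Axial extent of the rendered map.
#' @param pixel_size nm per pixel.
#' @param tip_sigma_nm Gaussian tip blur sd, nm (>= 0).
#' @param noise_sd Additive Gaussian height noise sd, nm (>= 0).
#' @param seed Integer seed for the noise.
#' @param apparent_height_nm Optional apparent height, nm (see above);
#'   `NULL` leaves the rigid envelope untouched.
#' @param plateau_frac Fraction of the rigid maximum at which the apparent
#'   height is pinned before capping (controls how wide the flat tops are).
#' @param axis_angle In-plane rotation applied to the finished map, degrees.
#' @param margin_nm Background margin around the footprint.
#' @return A [heightmap()].
#' @export
#' @examples
#' hm <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, length_nm = 220,
#'                        apparent_height_nm = 5.2, seed = 1)
render_heightmap <- function(width_nm, thickness_nm, pitch_nm = NULL,
                             handedness = c("right", "left"),
                             length_nm = if (is.null(pitch_nm)) 100 else 2.6 * pitch_nm,
                             pixel_size = 1, tip_sigma_nm = 0.5,
                             noise_sd = 0.1, seed = 1L,
                             apparent_height_nm = NULL, plateau_frac = 0.55,
                             axis_angle = 0, margin_nm = 6) {
  check_number(width_nm, "width_nm", lower = 0, allow_lower = FALSE)
  check_number(thickness_nm, "thickness_nm", lower = 0, allow_lower = FALSE)
  if (!is.null(pitch_nm)) check_number(pitch_nm, "pitch_nm", lower = 0,
                                       allow_lower = FALSE)
  handedness <- match.arg(handedness)
  check_number(length_nm, "length_nm", lower = 0, allow_lower = FALSE)
  check_number(pixel_size, "pixel_size", lower = 0, allow_lower = FALSE)
  check_number(tip_sigma_nm, "tip_sigma_nm", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(apparent_height_nm)) {
    check_number(apparent_height_nm, "apparent_height_nm",
                 lower = 0, allow_lower = FALSE)
  }
  check_number(plateau_frac, "plateau_frac", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)

  half_extent <- max(width_nm, thickness_nm) / 2 + margin_nm +
    3 * tip_sigma_nm
  ny <- ceiling(2 * half_extent / pixel_size)
  nx <- ceiling(length_nm / pixel_size)
  ys <- ((seq_len(ny)) - (ny + 1) / 2) * pixel_size
  xs <- (seq_len(nx) - 0.5) * pixel_size
  sgn <- if (handedness == "right") 1 else -1

  # a physical specimen is never registered to the pixel grid: draw a
  # sub-pixel lateral offset and an axial twist phase from the seed (these
  # also decorrelate pixel-coverage quantisation across a population)
  draws <- with_seed_or_not(seed, list(
    dy = stats::runif(1, -0.5, 0.5) * pixel_size,
    xph = stats::runif(1, 0, 1),
    noise = if (noise_sd > 0) stats::rnorm(ny * nx, 0, noise_sd)
  ))

  grid <- vapply(xs, function(x) {
    alpha <- if (is.null(pitch_nm)) 0 else
      sgn * 2 * pi * (x / pitch_nm + draws$xph)
    rect_upper_envelope(width_nm, thickness_nm, alpha, ys - draws$dy)
  }, numeric(ny))

  if (!is.null(apparent_height_nm)) {
    # apparent-height mapping: rescale the rigid relief so the requested
    # height sits at `plateau_frac` of the rigid maximum, then cap there.
    # Every period then presents a wide flat top at exactly the apparent
    # height (emulating substrate flattening / multilayer stacking), which
    # survives tip blur, while the face-on sections stay the profile minima.
    grid <- pmin(grid * apparent_height_nm / (plateau_frac * max(grid)),
                 apparent_height_nm)
  }

  grid <- gaussian_blur(grid, tip_sigma_nm / pixel_size)
  if (noise_sd > 0) {
    grid <- grid + matrix(draws$noise, nrow(grid))
  }
  grid <- pmax(grid, 0)
  hm <- heightmap(grid, pixel_size, axis_angle = 0)
  if (axis_angle != 0) hm <- rotate_heightmap(hm, axis_angle)
  hm
}

#' Mirror a height map laterally
#'
#' Parity operation (y -> -y) that flips the handedness of the imaged
#' helix without touching heights.
#' @param map A [heightmap()].
#' @return The mirrored map.
#' @export
mirror_heightmap <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  heightmap(map$grid[rev(seq_len(nrow(map$grid))), , drop = FALSE],
            map$pixel_size, -map$axis_angle)
}

#' Rotate a height map in plane
#'
#' Bilinear resampling onto an enlarged canvas; pixels falling outside the
#' source map take the background value 0.
#'
#' @param map A [heightmap()].
#' @param angle_deg Rotation angle, degrees (counter-clockwise).
#' @return A rotated [heightmap()]; `axis_angle` is updated accordingly.
#' @export
rotate_heightmap <- function(map, angle_deg) {
  stopifnot(inherits(map, "heightmap"))
  g <- map$grid
  a <- deg2rad(angle_deg)
  ny <- nrow(g); nx <- ncol(g)
  # output canvas large enough for the rotated bounding box
  ny2 <- ceiling(abs(ny * cos(a)) + abs(nx * sin(a)))
  nx2 <- ceiling(abs(nx * cos(a)) + abs(ny * sin(a)))
  ci <- (ny + 1) / 2; cj <- (nx + 1) / 2
  ci2 <- (ny2 + 1) / 2; cj2 <- (nx2 + 1) / 2
  out <- matrix(0, ny2, nx2)
  jj <- matrix(rep(seq_len(nx2), each = ny2), ny2) - cj2
  ii <- matrix(rep(seq_len(ny2), times = nx2), ny2) - ci2
  # inverse rotation into source coordinates (i ~ y, j ~ x)
  js <- cos(a) * jj + sin(a) * ii + cj
  is <- -sin(a) * jj + cos(a) * ii + ci
  j0 <- floor(js); i0 <- floor(is)
  fj <- js - j0; fi <- is - i0
  val <- function(i, j) {
    ok <- i >= 1 & i <= ny & j >= 1 & j <= nx
    v <- matrix(0, ny2, nx2)
    v[ok] <- g[cbind(i[ok], j[ok])]
    v
  }
  out <- val(i0, j0) * (1 - fi) * (1 - fj) +
         val(i0 + 1, j0) * fi * (1 - fj) +
         val(i0, j0 + 1) * (1 - fi) * fj +
         val(i0 + 1, j0 + 1) * fi * fj
  heightmap(pmax(out, 0), map$pixel_size, map$axis_angle + angle_deg)
}

#' Write / read a height map as plain text with a JSON sidecar
#'
#' The raster goes to a whitespace-separated text matrix (heights in nm);
#' pixel size, axis angle and provenance go to `<path>.json`.
#'
#' @param map A [heightmap()].
#' @param path Output path for the text matrix.
#' @param meta Optional named list merged into the sidecar (e.g. seed).
#' @return `path` (write) or a [heightmap()] (read).
#' @export
write_heightmap <- function(map, path, meta = list()) {
  stopifnot(inherits(map, "heightmap"))
  utils::write.table(map$grid, path, row.names = FALSE, col.names = FALSE)
  sidecar <- c(list(pixel_size = map$pixel_size,
                    axis_angle = map$axis_angle), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(path))
  dimnames(grid) <- NULL
  heightmap(grid, side$pixel_size, side$axis_angle %||% 0)
}

#' @export
autoplot.heightmap <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$grid)),
                           j = seq_len(ncol(object$grid)))
  df$h <- object$grid[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j * object$pixel_size,
                                   y = .data$i * object$pixel_size,
                                   fill = .data$h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
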