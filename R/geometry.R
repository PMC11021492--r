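#' Bilayer ribbon lattice constants
#'
#' The real-space repeat distances of the bilayer-like peptoid packing, as
#' inferred from the diffraction peaks: residues repeat at 0.29 nm along a
#' backbone chain, adjacent parallel chains sit 0.46 nm apart, the two
#' leaflets' backbone planes are 1.36 nm apart, and the full bilayer
#' (polar surface to polar surface) is 2.46 nm thick. Each molecule carries
#' `residues_per_chain` pseudo-residues: the hydrophobic units on the
#' backbone plane and one polar terminus on the outer surface.
#'
#' @param residue_spacing nm between adjacent residues along a chain.
#' @param chain_spacing nm between adjacent parallel chains (across width).
#' @param backbone_gap nm between the two leaflets' backbone planes.
#' @param bilayer_thickness nm, outer surface to outer surface.
#' @param residues_per_chain Residues per molecule (default 5: four
#'   hydrophobic units plus one polar terminus).
#' @return A list of class `"ribbon_lattice"`.
#' @export
ribbon_lattice <- function(residue_spacing = 0.29, chain_spacing = 0.46,
                           backbone_gap = 1.36, bilayer_thickness = 2.46,
                           residues_per_chain = 5L) {
  check_number(residue_spacing, "residue_spacing", lower = 0, allow_lower = FALSE)
  check_number(chain_spacing, "chain_spacing", lower = residue_spacing,
               allow_lower = FALSE)
  check_number(backbone_gap, "backbone_gap", lower = chain_spacing,
               allow_lower = FALSE)
  check_number(bilayer_thickness, "bilayer_thickness", lower = backbone_gap,
               allow_lower = FALSE)
  residues_per_chain <- check_count(residues_per_chain, "residues_per_chain",
                                    lower = 1L)
  structure(
    list(residue_spacing = residue_spacing, chain_spacing = chain_spacing,
         backbone_gap = backbone_gap, bilayer_thickness = bilayer_thickness,
         residues_per_chain = residues_per_chain),
    class = "ribbon_lattice"
  )
}

monomer_ids <- function(leaflet, column, segment, n_width, n_length) {
  (as.integer(leaflet == "lower")) * n_width * n_length +
    (column - 1L) * n_length + segment
}

#' Build labelled coordinates of a (possibly twisted) bilayer ribbon
#'
#' Places one pseudo-point per residue on a rectangular lattice: chains run
#' along the ribbon long axis (x), tiled end-to-end with the residue-spacing
#' period; adjacent chains are one `chain_spacing` apart across the width
#' (y); the two leaflets sit at z = +/- `backbone_gap`/2 with their polar
#' termini at z = +/- `bilayer_thickness`/2. A uniform twist rotates every
#' cross-section about the long axis by `360 * x / pitch_nm` degrees, signed
#' by the requested handedness; the builder refuses builds whose end-to-end
#' rotation exceeds a half turn, where the dihedral readout would alias.
#'
#' @param n_width Number of chain columns across the width (>= 2); physical
#'   width is `n_width * chain_spacing`.
#' @param n_length Number of chain segments along the length (>= 2).
#' @param lattice A [ribbon_lattice()].
#' @param pitch_nm Axial length per full 360-degree turn (nm), or `NULL`
#'   for a flat ribbon. Must be > 0 when given.
#' @param handedness `"right"` (positive rotation about +x with increasing
#'   x) or `"left"`.
#' @param noise_sd Gaussian positional noise sd, nm (>= 0).
#' @param seed Integer seed used when `noise_sd > 0`; `NULL` draws from the
#'   current RNG stream.
#' @return A tibble of class `"ribbon_coords"` with columns `monomer_id`,
#'   `leaflet`, `column`, `segment`, `residue`, `x`, `y`, `z` (nm).
#' @export
#' @examples
#' rb <- build_ribbon(8, 17, pitch_nm = 87)
#' twist_dihedral(rb)
build_ribbon <- function(n_width, n_length, lattice = ribbon_lattice(),
                         pitch_nm = NULL, handedness = c("right", "left"),
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lattice, "ribbon_lattice"))
  n_width <- check_count(n_width, "n_width", lower = 2L)
  n_length <- check_count(n_length, "n_length", lower = 2L)
  handedness <- match.arg(handedness)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(pitch_nm)) {
    check_number(pitch_nm, "pitch_nm", lower = 0, allow_lower = FALSE)
  }
  rpc <- lattice$residues_per_chain

  grid <- tidyr::expand_grid(
    leaflet = c("upper", "lower"),
    column = seq_len(n_width),
    segment = seq_len(n_length),
    residue = seq_len(rpc)
  )
  z_sign <- ifelse(grid$leaflet == "upper", 1, -1)
  is_polar <- grid$residue == rpc
  coords <- dplyr::mutate(
    grid,
    monomer_id = monomer_ids(.data$leaflet, .data$column, .data$segment,
                             n_width, n_length),
    x = ((.data$segment - 1L) * rpc + .data$residue - 1L) *
      lattice$residue_spacing,
    y = (.data$column - (n_width + 1) / 2) * lattice$chain_spacing,
    z = z_sign * ifelse(is_polar, lattice$bilayer_thickness / 2,
                        lattice$backbone_gap / 2)
  )

  if (!is.null(pitch_nm)) {
    span_deg <- 360 * (max(coords$x) - min(coords$x)) / pitch_nm
    if (span_deg > 180) {
      abort_bad_arg(sprintf(
        "end-to-end rotation %.1f deg exceeds a half turn; the dihedral readout would alias. Use a longer pitch or a shorter ribbon.",
        span_deg
      ))
    }
    sgn <- if (handedness == "right") 1 else -1
    alpha <- sgn * 2 * pi * coords$x / pitch_nm
    y0 <- coords$y
    z0 <- coords$z
    coords$y <- y0 * cos(alpha) - z0 * sin(alpha)
    coords$z <- y0 * sin(alpha) + z0 * cos(alpha)
  }

  if (noise_sd > 0) {
    noise <- with_seed_or_not(seed, stats::rnorm(3L * nrow(coords), 0, noise_sd))
    coords$x <- coords$x + noise[seq_len(nrow(coords))]
    coords$y <- coords$y + noise[nrow(coords) + seq_len(nrow(coords))]
    coords$z <- coords$z + noise[2L * nrow(coords) + seq_len(nrow(coords))]
  }

  out <- dplyr::select(coords, "monomer_id", "leaflet", "column", "segment",
                       "residue", "x", "y", "z")
  structure(out,
            class = c("ribbon_coords", class(out)),
            lattice = lattice, pitch_nm = pitch_nm,
            handedness = if (is.null(pitch_nm)) NA_character_ else handedness,
            n_width = n_width, n_length = n_length)
}

#' Mirror a ribbon through the xy plane
#'
#' Parity operation (`z -> -z`) used to flip the handedness of a structure.
#' @param coords A `ribbon_coords` tibble.
#' @return The mirrored coordinates.
#' @export
mirror_ribbon <- function(coords) {
  coords$z <- -coords$z
  coords
}

monomer_coms <- function(coords) {
  dplyr::summarise(
    dplyr::group_by(coords, .data$leaflet, .data$column, .data$segment),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop"
  )
}

# least-squares direction of position against an ordering covariate
# (slope of the regression of each coordinate on `ord`); sign follows
# increasing `ord`
fit_direction <- function(xyz, ord) {
  oc <- ord - mean(ord)
  denom <- sum(oc^2)
  if (denom == 0) return(c(NA_real_, NA_real_, NA_real_))
  drop(crossprod(oc, sweep(xyz, 2, colMeans(xyz)))) / denom
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-12) {
    rlang::abort("degenerate geometry: direction vector has (near-)zero length.",
                 class = "ribbonhelix_degenerate_error")
  }
  v / nv
}

#' Twist-dihedral order parameter of a ribbon
#'
#' The global twist dihedral \eqn{\theta} is defined through
#' \eqn{\vec v_u \cdot \vec v_l = |\vec v_u||\vec v_l|\cos\theta}, where
#' \eqn{\vec v_u} and \eqn{\vec v_l} are the best-fit vectors through the
#' centres of mass of the monomers forming the two end cross-sections of
#' the ribbon (ordered by column index), i.e. the signed angle by which the
#' ribbon cross-section rotates from one end to the other about the ribbon
#' long axis. Positive angles are right-handed (the sign is the sign of
#' \eqn{(\vec v_l \times \vec v_u)\cdot \hat a} with \eqn{\hat a} the
#' best-fit long axis oriented by increasing segment index).
#'
#' Beyond the two ends, the per-segment cross-section azimuth is regressed
#' against axial position, giving a twist *rate* (deg/nm) that uses every
#' segment; the extrapolated pitch is `360 * contour / |theta|`.
#'
#' @param coords A `ribbon_coords` tibble (at least 2 segments, 2 columns).
#' @param tolerance_deg Angles with `|theta|` at or below this value are
#'   reported as `"flat"` and carry no finite pitch. Default 1 degree.
#' @return A list of class `"twist_result"`: `theta_deg`, `v_u`, `v_l`,
#'   `axis`, `handedness`, `contour_nm` (axial extent between the end
#'   cross-section centres), `pitch_nm` (`NA` when flat),
#'   `twist_rate_deg_nm`.
#' @seealso [twist_at_contour()], [pitch_from_twist()]
#' @export
twist_dihedral <- function(coords, tolerance_deg = 1) {
  needed <- c("leaflet", "column", "segment", "x", "y", "z")
  if (!all(needed %in% names(coords))) {
    abort_bad_arg("`coords` must carry leaflet/column/segment labels and x, y, z.")
  }
  coms <- monomer_coms(coords)
  segs <- sort(unique(coms$segment))
  if (length(segs) < 2L) {
    rlang::abort("need at least 2 segments along the ribbon to define a twist.",
                 class = "ribbonhelix_insufficient_data_error")
  }
  if (length(unique(coms$column)) < 2L) {
    rlang::abort("need at least 2 columns across the ribbon to define edge vectors.",
                 class = "ribbonhelix_insufficient_data_error")
  }
  P <- as.matrix(coms[, c("x", "y", "z")])
  if (max(abs(sweep(P, 2, colMeans(P)))) < 1e-9) {
    rlang::abort("degenerate geometry: all centres of mass coincide.",
                 class = "ribbonhelix_degenerate_error")
  }

  # long axis: first principal direction of the monomer COMs, oriented so
  # the axial coordinate increases with segment index
  Pc <- sweep(P, 2, colMeans(P))
  axis <- svd(Pc, nu = 0, nv = 1)$v[, 1]
  if (sum(axis * fit_direction(P, coms$segment)) < 0) axis <- -axis
  axis <- unit(axis)
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])

  # per-segment cross-section direction (fit over column order) and azimuth
  sec <- purrr::map(segs, function(s) {
    rows <- coms$segment == s
    v <- fit_direction(P[rows, , drop = FALSE], coms$column[rows])
    t_ax <- mean(P[rows, , drop = FALSE] %*% axis)
    list(v = unit(v), t = t_ax)
  })
  t_ax <- vapply(sec, `[[`, numeric(1), "t")
  az <- vapply(sec, function(s) atan2(sum(s$v * e2), sum(s$v * e1)), numeric(1))
  az <- az[order(t_ax)]
  t_ord <- sort(t_ax)
  # unwrap the azimuth sequence
  daz <- diff(az)
  daz <- daz - 2 * pi * round(daz / (2 * pi))
  az_un <- cumsum(c(az[1], daz))
  rate <- if (stats::sd(t_ord) > 0) {
    stats::coef(stats::lm(az_un ~ t_ord))[[2]]
  } else NA_real_

  v_l <- sec[[which.min(t_ax)]]$v
  v_u <- sec[[which.max(t_ax)]]$v
  cross_lu <- c(v_l[2] * v_u[3] - v_l[3] * v_u[2],
                v_l[3] * v_u[1] - v_l[1] * v_u[3],
                v_l[1] * v_u[2] - v_l[2] * v_u[1])
  theta <- rad2deg(atan2(sum(cross_lu * axis), sum(v_l * v_u)))
  contour <- max(t_ax) - min(t_ax)

  hand <- if (theta > tolerance_deg) "right"
          else if (theta < -tolerance_deg) "left" else "flat"
  pitch <- if (hand == "flat") NA_real_ else 360 * contour / abs(theta)

  structure(
    list(theta_deg = theta, v_u = v_u, v_l = v_l, axis = axis,
         handedness = hand, contour_nm = contour, pitch_nm = pitch,
         twist_rate_deg_nm = rad2deg(rate)),
    class = "twist_result"
  )
}

#' @export
print.twist_result <- function(x, ...) {
  cat("<twist dihedral>\n")
  cat(sprintf("  theta = %.2f deg (%s), contour = %.2f nm\n",
              x$theta_deg, x$handedness, x$contour_nm))
  if (is.finite(x$pitch_nm)) {
    cat(sprintf("  pitch per full turn = %.1f nm (rate %.3f deg/nm)\n",
                x$pitch_nm, x$twist_rate_deg_nm))
  }
  invisible(x)
}

#' Twist dihedral across a reference contour length
#'
#' Rescales a measured twist to a stated contour length using the fitted
#' twist rate: `theta(L) = rate * L`. This is the same extrapolation that
#' turns a measured dihedral into a pitch per full turn, and lets a
#' discrete-lattice ribbon (whose realisable contour lengths are quantised
#' by the chain period) report the dihedral across any reference length.
#'
#' @param result A `twist_result` from [twist_dihedral()].
#' @param contour_nm Reference contour length, nm (> 0).
#' @return Signed twist dihedral in degrees across `contour_nm`.
#' @export
twist_at_contour <- function(result, contour_nm) {
  stopifnot(inherits(result, "twist_result"))
  check_number(contour_nm, "contour_nm", lower = 0, allow_lower = FALSE)
  result$twist_rate_deg_nm * contour_nm
}

#' Pitch per full helical turn from a twist dihedral
#'
#' @param theta_deg Global twist dihedral, degrees.
#' @param contour_nm Contour length over which the dihedral accrued, nm.
#' @param tolerance_deg Angles at or below this magnitude are flat and have
#'   no finite pitch.
#' @return Pitch in nm: `360 * contour_nm / |theta_deg|`.
#' @export
#' @examples
#' pitch_from_twist(98, 23.7) # ~87 nm
pitch_from_twist <- function(theta_deg, contour_nm, tolerance_deg = 1) {
  check_number(contour_nm, "contour_nm", lower = 0, allow_lower = FALSE)
  if (!is.numeric(theta_deg) || !is.finite(theta_deg)) {
    abort_bad_arg("`theta_deg` must be a finite number.")
  }
  if (abs(theta_deg) <= tolerance_deg) {
    rlang::abort("ribbon is flat within tolerance: no finite pitch.",
                 class = "ribbonhelix_flat_ribbon_error")
  }
  360 * contour_nm / abs(theta_deg)
}

#' Twist dihedral time profile over trajectory frames
#'
#' Computes the twist dihedral for every frame of a multi-run trajectory
#' and summarises the runs per time point (replicate mean and standard
#' deviation, as in multi-replicate relaxation analyses).
#'
#' @param frames A list of `ribbon_coords` frames, ordered run-major (all
#'   frames of run 1, then run 2, ...), or a single run's frames.
#' @param n_runs Number of independent runs; `length(frames)` must be a
#'   multiple of it.
#' @param times Optional numeric time stamps, one per frame within a run.
#' @return A tibble of class `"twist_profile"` with columns `run`, `frame`,
#'   `time`, `theta_deg`; the per-time replicate summary (mean, sd, n) is
#'   in `attr(, "summary")` (sd is `NA` for a single run).
#' @export
twist_profile <- function(frames, n_runs = 1, times = NULL) {
  n_runs <- check_count(n_runs, "n_runs", lower = 1L)
  if (!is.list(frames) || length(frames) == 0L) {
    abort_bad_arg("`frames` must be a non-empty list of coordinate frames.")
  }
  if (length(frames) %% n_runs != 0L) {
    rlang::abort(sprintf(
      "%d frames cannot be split into %d equal runs.", length(frames), n_runs),
      class = "ribbonhelix_shape_error")
  }
  per_run <- length(frames) %/% n_runs
  if (is.null(times)) times <- seq_len(per_run)
  if (length(times) != per_run) {
    rlang::abort("`times` must have one entry per frame within a run.",
                 class = "ribbonhelix_shape_error")
  }
  series <- tidyr::expand_grid(run = seq_len(n_runs), frame = seq_len(per_run))
  series$time <- times[series$frame]
  series$theta_deg <- vapply(seq_along(frames), function(i) {
    twist_dihedral(frames[[i]])$theta_deg
  }, numeric(1))
  summary <- dplyr::summarise(
    dplyr::group_by(series, .data$frame, .data$time),
    mean_theta = mean(.data$theta_deg),
    sd_theta = if (n_runs > 1) stats::sd(.data$theta_deg) else NA_real_,
    n_runs = n_runs,
    .groups = "drop"
  )
  structure(series, class = c("twist_profile", class(series)),
            summary = summary, single_run = n_runs == 1L)
}

#' @export
autoplot.twist_profile <- function(object, ...) {
  smry <- attr(object, "summary")
  p <- ggplot2::ggplot(smry, ggplot2::aes(x = .data$time, y = .data$mean_theta))
  if (any(is.finite(smry$sd_theta))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_theta - .data$sd_theta,
                   ymax = .data$mean_theta + .data$sd_theta),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "twist dihedral (deg)")
}
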