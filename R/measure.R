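# ---- internal image machinery ----------------------------------------------

# Otsu's threshold on a 256-bin histogram; splits background from footprint
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# height-weighted principal-axis angle of the footprint, degrees CCW from
# the column (x) direction
estimate_axis_angle <- function(map, min_relief = 0.1) {
  g <- map$grid
  thr <- otsu_threshold(g)
  idx <- which(g > thr, arr.ind = TRUE)
  if (max(g) - stats::median(g) < min_relief || nrow(idx) < 8L) {
    rlang::abort("no footprint detected above background.",
                 class = "ribbonhelix_detection_error")
  }
  w <- g[idx]
  jc <- idx[, 2] - sum(idx[, 2] * w) / sum(w)
  ic <- idx[, 1] - sum(idx[, 1] * w) / sum(w)
  sxx <- sum(w * jc * jc); syy <- sum(w * ic * ic); sxy <- sum(w * jc * ic)
  rad2deg(0.5 * atan2(2 * sxy, sxx - syy))
}

# rotate the map so the helix axis runs along the columns
align_heightmap <- function(map) {
  ang <- estimate_axis_angle(map)
  if (abs(ang) < 0.25) return(map)
  rotate_heightmap(map, -ang)
}

# per-column statistics of an aligned map: column max, background level,
# full width at half maximum (linear-interpolated crossings)
column_stats <- function(map) {
  g <- map$grid
  thr <- otsu_threshold(g)
  fg <- g > thr
  cols <- which(colSums(fg) > 0)
  if (!length(cols)) {
    rlang::abort("no footprint detected above background.",
                 class = "ribbonhelix_detection_error")
  }
  cols <- seq(min(cols), max(cols))
  bg <- stats::median(g[!fg])
  fwhm <- rep(NA_real_, length(cols))
  cmax <- rep(NA_real_, length(cols))
  for (k in seq_along(cols)) {
    v <- g[, cols[k]]
    m <- max(v)
    cmax[k] <- m
    half <- bg + (m - bg) / 2
    above <- which(v > half)
    if (!length(above)) next
    i1 <- min(above); i2 <- max(above)
    # subpixel edges by linear interpolation across the half-level
    lo <- if (i1 > 1) i1 - (v[i1] - half) / (v[i1] - v[i1 - 1]) else i1
    hi <- if (i2 < length(v)) i2 + (v[i2] - half) / (v[i2] - v[i2 + 1]) else i2
    fwhm[k] <- (hi - lo) * map$pixel_size
  }
  list(cols = cols, cmax = cmax, fwhm = fwhm, bg = bg,
       px = map$pixel_size, grid = g)
}

# equivalent-rectangle width of one column: integrated excess height over
# background divided by the plateau level. Unbiased under symmetric tip
# blur (which conserves the integral and the wide-plateau level), unlike a
# straight half-maximum crossing, which axial bleed pushes outward.
column_width <- function(cs, j) {
  v <- cs$grid[, cs$cols[j]] - cs$bg
  m <- max(v)
  if (m <= 0) return(NA_real_)
  above <- which(v > m / 2)
  i1 <- min(above); i2 <- max(above)
  interior <- if (i2 - i1 >= 8L) seq(i1 + 3L, i2 - 3L) else seq(i1, i2)
  h <- mean(v[interior])
  win <- seq(max(1L, i1 - 8L), min(length(v), i2 + 8L))
  sum(v[win]) * cs$px / h
}

running_mean <- function(v, k) {
  if (k <= 1) return(v)
  as.numeric(stats::filter(v, rep(1 / k, k), sides = 2, circular = FALSE)) ->
    out
  # fill the ends with the nearest defined value
  first <- which(!is.na(out))[1]
  last <- max(which(!is.na(out)))
  out[seq_len(first - 1)] <- out[first]
  out[seq(last + 1, length.out = length(out) - last)] <- out[last]
  out
}

# parabolic sub-sample refinement of an extremum at index k
refine_extremum <- function(v, k) {
  if (k <= 1 || k >= length(v)) return(k)
  denom <- v[k - 1] - 2 * v[k] + v[k + 1]
  if (abs(denom) < 1e-12) return(k)
  k + 0.5 * (v[k - 1] - v[k + 1]) / denom
}

# positions (fractional column index) of the face-on dips of the axial
# max-height profile, plus the initial autocorrelation period estimate
profile_dips <- function(cmax, min_amplitude_frac = 0.04) {
  prof <- running_mean(cmax, 3L)
  amp <- max(prof) - min(prof)
  if (amp < min_amplitude_frac * max(max(prof), 1e-12)) {
    rlang::abort("height profile shows no periodicity (flat within tolerance).",
                 class = "ribbonhelix_no_periodicity_error")
  }
  d <- prof - mean(prof)
  n <- length(d)
  ac <- stats::acf(d, lag.max = floor(n / 2), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # first local maximum of the autocorrelation beyond the zero-lag peak
  cand <- which(diff(sign(diff(ac))) < 0) + 1L
  cand <- cand[cand > 2L & ac[cand] > 0]
  if (!length(cand)) {
    rlang::abort("height profile shows no periodicity (no autocorrelation peak).",
                 class = "ribbonhelix_no_periodicity_error")
  }
  # the strongest peak marks the fundamental period; the first local peak
  # can sit on a secondary modulation (shallow edge-on sags)
  period0 <- cand[which.max(ac[cand])] - 1L
  # local minima separated by at least 0.6 * period0, below the midline
  mid <- (max(prof) + min(prof)) / 2
  is_min <- c(FALSE, diff(sign(diff(prof))) > 0, FALSE)
  dips <- which(is_min & prof < mid)
  if (length(dips) > 1) {
    keep <- dips[1]
    for (d2 in dips[-1]) {
      if (d2 - keep[length(keep)] >= 0.6 * period0) keep <- c(keep, d2)
      else if (prof[d2] < prof[keep[length(keep)]]) keep[length(keep)] <- d2
    }
    dips <- keep
  }
  # drop dips hugging the map ends, where the waveform is clipped
  dips <- dips[dips > 3L & dips < length(prof) - 2L]
  pos <- vapply(dips, refine_extremum, numeric(1), v = prof)
  list(dips = pos, period0 = period0, profile = prof)
}

# successive dip spacings with gross outliers (clipped or split periods)
# removed: keep spacings within 30% of the median
dip_spacings <- function(dips) {
  sp <- diff(dips)
  if (length(sp) > 2L) {
    med <- stats::median(sp)
    keep <- sp > 0.7 * med & sp < 1.3 * med
    if (any(keep)) sp <- sp[keep]
  }
  sp
}

# ---- estimators -------------------------------------------------------------

#' Estimate the helical pitch from a height map
#'
#' Extracts the axial maximum-height profile, finds its period through the
#' autocorrelation peak, refines it through the spacings of successive
#' face-on dips (sub-pixel, parabolic), and doubles the mean spacing: a
#' twisted ribbon's height profile repeats every *half* turn, so the pitch
#' per full turn is twice the profile period.
#'
#' @param map A [heightmap()].
#' @return A one-row tibble: `pitch_nm`, `pitch_sd_nm` (over spacings),
#'   `n_periods` (number of profile periods used).
#' @export
estimate_pitch <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  cs <- column_stats(align_heightmap(map))
  dp <- profile_dips(cs$cmax)
  if (length(dp$dips) < 3L) {
    rlang::abort("fewer than 2 profile periods visible: cannot estimate pitch.",
                 class = "ribbonhelix_insufficient_periods_error")
  }
  spacings <- dip_spacings(dp$dips) * cs$px
  tibble::tibble(
    pitch_nm = 2 * mean(spacings),
    pitch_sd_nm = 2 * stats::sd(spacings),
    n_periods = length(spacings)
  )
}

#' Estimate ribbon width from a height map
#'
#' Width is read at the face-on sections (the dips of the axial height
#' profile), where the ribbon lies flat and presents its full width: each
#' face-on column's lateral profile is reduced to its equivalent-rectangle
#' width (integrated excess height over the plateau level, which symmetric
#' tip blur leaves invariant), and the face-on values are averaged. For an
#' untwisted stripe (no periodicity) the median over sampled columns is
#' used instead.
#'
#' @param map A [heightmap()].
#' @return Width in nm.
#' @export
estimate_width <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  cs <- column_stats(align_heightmap(map))
  dips <- tryCatch(profile_dips(cs$cmax)$dips,
                   ribbonhelix_no_periodicity_error = function(e) NULL)
  if (is.null(dips) || length(dips) < 1L) {
    idx <- seq(1L, length(cs$cols), by = 5L)
    return(stats::median(vapply(idx, column_width, numeric(1), cs = cs),
                         na.rm = TRUE))
  }
  idx <- pmin(pmax(round(dips), 1L), length(cs$cols))
  mean(vapply(idx, column_width, numeric(1), cs = cs), na.rm = TRUE)
}

#' Estimate apparent helix height from a height map
#'
#' The mean, over profile periods (delimited by successive face-on dips),
#' of the per-period crest level: the median of all pixels within 7% of
#' the period's maximum, which reads the flat crest of each half-turn
#' robustly (the median is insensitive to noise spikes and to blur sag at
#' the crest edges, where a plain maximum is biased by both). For an
#' untwisted stripe, the median column maximum above background.
#'
#' @param map A [heightmap()].
#' @return Height in nm.
#' @export
estimate_height <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  cs <- column_stats(align_heightmap(map))
  dips <- tryCatch(profile_dips(cs$cmax)$dips,
                   ribbonhelix_no_periodicity_error = function(e) NULL)
  if (is.null(dips) || length(dips) < 2L) {
    return(stats::median(cs$cmax) - cs$bg)
  }
  bounds <- round(dips)
  crests <- vapply(seq_len(length(bounds) - 1L), function(k) {
    block <- cs$grid[, cs$cols[bounds[k]:bounds[k + 1]], drop = FALSE]
    top <- max(block)
    stats::median(block[block >= cs$bg + 0.93 * (top - cs$bg)])
  }, numeric(1))
  mean(crests) - cs$bg
}

# sign convention anchor (fixed against rendered reference pairs): a
# right-handed render (positive rotation about +x with increasing x)
# yields a positive structure-tensor off-diagonal sum on the aligned map
HANDEDNESS_SIGN <- 1

#' Classify the handedness of an imaged helix
#'
#' The screw sense shows up as a consistent oblique drift of the
#' edge-on ridge across the footprint. The classifier aligns the map,
#' computes central-difference gradients over the footprint, and reads the
#' sign of the structure-tensor off-diagonal (the net stripe obliquity
#' relative to the axis); the sign chain is anchored to the 3-D builder
#' convention through rendered references. The confidence is the relative
#' magnitude of the chiral component, `|2 S_xy| / (S_xx + S_yy)`, in
#' `[0, 1]`; mirroring the map flips the label and preserves it.
#'
#' @param map A [heightmap()].
#' @param min_confidence Labels with confidence below this are
#'   `"indeterminate"`.
#' @return A one-row tibble: `handedness`, `confidence`.
#' @export
classify_handedness <- function(map, min_confidence = 0.002) {
  stopifnot(inherits(map, "heightmap"))
  amap <- align_heightmap(map)
  g <- amap$grid
  if (nrow(g) < 3L || ncol(g) < 3L) {
    rlang::abort("map too small for gradient analysis.",
                 class = "ribbonhelix_detection_error")
  }
  thr <- otsu_threshold(g)
  gx <- (g[, c(2:ncol(g), ncol(g))] - g[, c(1, 1:(ncol(g) - 1))]) / 2
  gy <- (g[c(2:nrow(g), nrow(g)), ] - g[c(1, 1:(nrow(g) - 1)), ]) / 2
  mask <- g > thr
  sxx <- sum(gx[mask]^2); syy <- sum(gy[mask]^2)
  sxy <- sum(gx[mask] * gy[mask])
  conf <- abs(2 * sxy) / (sxx + syy)
  hand <- if (conf < min_confidence) "indeterminate"
          else if (HANDEDNESS_SIGN * sxy > 0) "right" else "left"
  tibble::tibble(handedness = hand, confidence = conf)
}

# ---- population-level wrappers ---------------------------------------------

#' Measure one helix: pitch, width, height, handedness
#'
#' @param map A [heightmap()].
#' @return A one-row tibble combining [estimate_pitch()],
#'   [estimate_width()], [estimate_height()] and [classify_handedness()].
#' @export
measure_helix <- function(map) {
  p <- estimate_pitch(map)
  h <- classify_handedness(map)
  tibble::tibble(
    pitch_nm = p$pitch_nm, pitch_sd_nm = p$pitch_sd_nm,
    n_periods = p$n_periods,
    width_nm = estimate_width(map),
    height_nm = estimate_height(map),
    handedness = h$handedness, confidence = h$confidence
  )
}

#' Measure every helix of a population
#'
#' @param maps A list of [heightmap()]s (e.g. from [generate_population()]).
#' @return A tibble with one row per helix (`helix_id` first).
#' @export
measure_population <- function(maps) {
  dplyr::bind_rows(purrr::imap(maps, function(m, i) {
    dplyr::bind_cols(tibble::tibble(helix_id = i), measure_helix(m))
  }))
}

#' Summarise per-helix measurements as a population
#'
#' Means, standard deviations (n - 1 denominator) and counts for pitch,
#' width and height, the right-handed fraction, and formatted
#' `"mean +/- sd nm (n = k)"` strings. Period-level pitch counts (total
#' periods across helices) are reported alongside helix-level counts.
#'
#' @param measurements A tibble from [measure_population()] (or at least
#'   one row of [measure_helix()] output).
#' @return A tibble of class `"population_summary"`: one row per quantity
#'   with `mean`, `sd`, `n`, `formatted`; handedness fraction and period
#'   counts as attributes (also shown by `print()`).
#' @export
summarize_population <- function(measurements) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L) {
    abort_bad_arg("`measurements` must contain at least one measurement.")
  }
  one <- function(name, v) {
    v <- v[is.finite(v)]
    s <- if (length(v) > 1L) stats::sd(v) else NA_real_
    tibble::tibble(
      quantity = name, mean = mean(v), sd = s, n = length(v),
      formatted = if (is.na(s)) {
        sprintf("%.1f nm (n = %d, sd not applicable)", mean(v), length(v))
      } else {
        sprintf("%.1f ± %.1f nm (n = %d)", mean(v), s, length(v))
      }
    )
  }
  out <- dplyr::bind_rows(
    one("pitch_nm", measurements$pitch_nm),
    one("width_nm", measurements$width_nm),
    one("height_nm", measurements$height_nm)
  )
  labelled <- measurements$handedness[measurements$handedness %in%
                                        c("left", "right")]
  frac <- if (length(labelled)) mean(labelled == "right") else NA_real_
  structure(out,
            class = c("population_summary", class(out)),
            fraction_right = frac,
            n_labelled = length(labelled),
            n_periods_total = sum(measurements$n_periods %||% NA_integer_))
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population summary>\n")
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %s\n", x$quantity[k], x$formatted[k]))
  }
  if (is.finite(attr(x, "fraction_right"))) {
    cat(sprintf("  right-handed fraction: %.2f (n = %d labelled)\n",
                attr(x, "fraction_right"), attr(x, "n_labelled")))
  }
  invisible(x)
}
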