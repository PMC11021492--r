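#' Specification of a synthetic helix population
#'
#' Per-helix geometric parameters are drawn from truncated-normal
#' distributions (truncated at zero) with the given means and sds, and
#' handedness from a Bernoulli draw; the drawn values form the ground-truth
#' table against which estimators are validated.
#'
#' @param n_helices Number of helices.
#' @param width_mean,width_sd Ribbon width distribution, nm.
#' @param height_mean,height_sd Apparent height distribution, nm.
#' @param pitch_mean,pitch_sd Pitch-per-turn distribution, nm.
#' @param handedness_fraction_right Probability that a helix is
#'   right-handed, in `[0, 1]`.
#' @param pixel_size nm per pixel of the rendered maps.
#' @param noise_sd Additive height-noise sd, nm.
#' @param tip_sigma Gaussian tip blur sd, nm.
#' @param bilayer_thickness Rendered ribbon cross-section thickness, nm.
#' @param seed Base integer seed; every helix derives its own stream.
#' @return A list of class `"population_spec"`.
#' @seealso [population_preset()], [generate_population()]
#' @export
population_spec <- function(n_helices = 50L,
                            width_mean = 10.7, width_sd = 1.7,
                            height_mean = 5.2, height_sd = 0.4,
                            pitch_mean = 86.4, pitch_sd = 6.7,
                            handedness_fraction_right = 0.5,
                            pixel_size = 1, noise_sd = 0.1,
                            tip_sigma = 0.5, bilayer_thickness = 2.46,
                            seed = 1L) {
  n_helices <- check_count(n_helices, "n_helices", lower = 1L)
  for (nm in c("width_mean", "height_mean", "pitch_mean")) {
    check_number(get(nm), nm, lower = 0, allow_lower = FALSE)
  }
  for (nm in c("width_sd", "height_sd", "pitch_sd", "noise_sd", "tip_sigma")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(handedness_fraction_right, "handedness_fraction_right",
               lower = 0, upper = 1)
  check_number(pixel_size, "pixel_size", lower = 0, allow_lower = FALSE)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(
    list(n_helices = n_helices, width_mean = width_mean, width_sd = width_sd,
         height_mean = height_mean, height_sd = height_sd,
         pitch_mean = pitch_mean, pitch_sd = pitch_sd,
         handedness_fraction_right = handedness_fraction_right,
         pixel_size = pixel_size, noise_sd = noise_sd,
         tip_sigma = tip_sigma, bilayer_thickness = bilayer_thickness,
         seed = seed),
    class = "population_spec"
  )
}

#' Measured population presets
#'
#' `"ph7"` carries the narrow-helix statistics (pitch 86.4 +/- 6.7 nm,
#' height 5.2 +/- 0.4 nm, width 10.7 +/- 1.7 nm, racemic); `"ph4"` the
#' wide/stacked statistics (pitch 110.1 +/- 20.3 nm, height
#' 15.6 +/- 2.4 nm, racemic).
#'
#' @param preset `"ph7"` or `"ph4"`.
#' @param ... Overrides passed to [population_spec()] (e.g. `n_helices`,
#'   `seed`).
#' @return A [population_spec()].
#' @export
population_preset <- function(preset = c("ph7", "ph4"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ph7 = list(pitch_mean = 86.4, pitch_sd = 6.7,
               height_mean = 5.2, height_sd = 0.4,
               width_mean = 10.7, width_sd = 1.7),
    ph4 = list(pitch_mean = 110.1, pitch_sd = 20.3,
               height_mean = 15.6, height_sd = 2.4,
               width_mean = 10.7, width_sd = 1.7)
  )
  do.call(population_spec, utils::modifyList(base, list(...)))
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic helix population with ground truth
#'
#' Draws per-helix width, apparent height, pitch and handedness from the
#' spec, renders one height map per helix, and returns the maps together
#' with the truth table. Fully reproducible from the spec's seed.
#'
#' @param spec A [population_spec()] or [population_preset()].
#' @param render Render the height maps (`TRUE`, default); `FALSE` returns
#'   only the truth table (e.g. for checking the drawn statistics).
#' @return A list with elements `maps` (list of [heightmap()]) and `truth`
#'   (a tibble with one row per helix: drawn `width_nm`, `height_nm`,
#'   `pitch_nm`, `handedness`, plus the rendered `length_nm` and the
#'   per-helix `seed`).
#' @export
#' @examples
#' pop <- generate_population(population_preset("ph7", n_helices = 3))
#' pop$truth
generate_population <- function(spec = population_spec(), render = TRUE) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_helices
  truth <- with_seed_or_not(spec$seed, tibble::tibble(
    helix_id = seq_len(n),
    width_nm = rtruncnorm_pos(n, spec$width_mean, spec$width_sd),
    height_nm = rtruncnorm_pos(n, spec$height_mean, spec$height_sd),
    pitch_nm = rtruncnorm_pos(n, spec$pitch_mean, spec$pitch_sd),
    handedness = ifelse(
      stats::runif(n) < spec$handedness_fraction_right, "right", "left"),
    seed = vapply(seq_len(n), derive_seed, integer(1), seed = spec$seed)
  ))
  truth$length_nm <- 2.6 * truth$pitch_nm
  if (!render) return(list(maps = list(), truth = truth))
  maps <- purrr::pmap(truth, function(helix_id, width_nm, height_nm, pitch_nm,
                                      handedness, seed, length_nm) {
    render_heightmap(
      width_nm = width_nm,
      thickness_nm = spec$bilayer_thickness,
      pitch_nm = pitch_nm, handedness = handedness,
      length_nm = length_nm, pixel_size = spec$pixel_size,
      tip_sigma_nm = spec$tip_sigma, noise_sd = spec$noise_sd,
      seed = seed, apparent_height_nm = height_nm
    )
  })
  list(maps = maps, truth = truth)
}
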