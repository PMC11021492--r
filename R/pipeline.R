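#' Pipeline configuration
#'
#' One object holding every tunable of the analysis pipeline: the global
#' seed, the width-model parameters, the pH mapping, the lattice constants,
#' the relaxation settings, the population presets to run, and the peak
#' list to assign. Round-trips through YAML unchanged.
#'
#' @param seed Global integer seed; every stochastic stage derives its
#'   stream from it.
#' @param model A [model_params()].
#' @param ph A [ph_map()].
#' @param lattice A [ribbon_lattice()].
#' @param relaxation A [relaxation_params()].
#' @param kappas Kappa values for the width-probability curves.
#' @param ph_grid pH values for the kappa-versus-pH table.
#' @param presets Population presets to generate (subset of `"ph7"`,
#'   `"ph4"`).
#' @param n_helices Helices per population.
#' @param ribbon List with `n_width`, `n_length`, `pitch_nm`, `handedness`
#'   for the demonstration ribbon build.
#' @param peaks_q_invA Peak list (inverse Angstrom) for assignment.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            model = model_params(),
                            ph = ph_map(),
                            lattice = ribbon_lattice(),
                            relaxation = relaxation_params(seed = seed),
                            kappas = c(0.1, 1, 10),
                            ph_grid = seq(2, 12, by = 0.5),
                            presets = c("ph7", "ph4"),
                            n_helices = 50L,
                            ribbon = list(n_width = 23L, n_length = 17L,
                                          pitch_nm = 87,
                                          handedness = "right"),
                            peaks_q_invA = c(0.2554, 0.4620, 1.3660, 2.1666)) {
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  stopifnot(inherits(model, "ribbon_model_params"), inherits(ph, "ph_map"),
            inherits(lattice, "ribbon_lattice"),
            inherits(relaxation, "relaxation_params"))
  bad <- setdiff(presets, c("ph7", "ph4"))
  if (length(bad)) {
    rlang::abort(sprintf("invalid config keys: unknown preset(s) %s",
                         paste(bad, collapse = ", ")),
                 class = "ribbonhelix_config_error")
  }
  need <- setdiff(c("n_width", "n_length", "pitch_nm", "handedness"),
                  names(ribbon))
  if (length(need)) {
    rlang::abort(sprintf("invalid config keys: ribbon lacks %s",
                         paste(need, collapse = ", ")),
                 class = "ribbonhelix_config_error")
  }
  structure(
    list(seed = seed, model = model, ph = ph, lattice = lattice,
         relaxation = relaxation, kappas = kappas, ph_grid = ph_grid,
         presets = presets, n_helices = check_count(n_helices, "n_helices"),
         ribbon = ribbon, peaks_q_invA = peaks_q_invA),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Field names in the file mirror the constructor arguments of
#' [pipeline_config()] and its component objects exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [pipeline_config()] (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 12)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    seed = raw$seed,
    model = do.call(model_params, raw$model),
    ph = do.call(ph_map, raw$ph),
    lattice = do.call(ribbon_lattice, raw$lattice),
    relaxation = do.call(relaxation_params, raw$relaxation),
    kappas = raw$kappas,
    ph_grid = raw$ph_grid,
    presets = raw$presets,
    n_helices = raw$n_helices,
    ribbon = raw$ribbon,
    peaks_q_invA = raw$peaks_q_invA
  )
}

#' Run the full analysis pipeline into an artifact directory
#'
#' Executes every stage with settings from the config and writes a
#' deterministic directory layout: model curves, the kappa-versus-pH
#' table, a built ribbon with its twist analysis, a relaxation trajectory,
#' one population per preset (height maps, truth table, per-helix
#' measurements, population summary), the assigned peak list, and a
#' manifest JSON listing every output with the seed and parameters that
#' generated it (plus content hashes, so two runs of the same config can
#' be compared byte for byte).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L) {
    rlang::abort("invalid config keys: `out_dir` must be a single path.",
                 class = "ribbonhelix_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  note <- function(p) { paths[length(paths) + 1L] <<- p; p }

  # 1. width-model curves and pH mapping
  curves <- width_curves(config$kappas, phi = config$model$phi,
                         beta_eps = config$model$beta_eps,
                         n_max = config$model$n_max,
                         delta = config$model$delta)
  write_result_csv(curves, note(file.path(out_dir, "model_curves.csv")))
  kap <- tibble::tibble(ph = config$ph_grid,
                        kappa = kappa_from_ph(config$ph_grid, config$ph))
  write_result_csv(kap, note(file.path(out_dir, "kappa_vs_ph.csv")))

  # 2. ribbon build and twist analysis
  rb <- build_ribbon(config$ribbon$n_width, config$ribbon$n_length,
                     lattice = config$lattice,
                     pitch_nm = config$ribbon$pitch_nm,
                     handedness = config$ribbon$handedness)
  write_xyz(rb, note(file.path(out_dir, "ribbon.xyz")))
  tw <- twist_dihedral(rb)
  write_result_csv(
    tibble::tibble(theta_deg = tw$theta_deg, handedness = tw$handedness,
                   contour_nm = tw$contour_nm, pitch_nm = tw$pitch_nm,
                   twist_rate_deg_nm = tw$twist_rate_deg_nm),
    note(file.path(out_dir, "twist.csv")))

  # 3. relaxation trajectory
  relax <- simulate_twist_relaxation(config$relaxation)
  write_result_csv(relax, note(file.path(out_dir, "relaxation.csv")))
  write_result_csv(attr(relax, "summary"),
                   note(file.path(out_dir, "relaxation_summary.csv")))

  # 4. populations, measurements, summaries
  for (preset in config$presets) {
    pdir <- file.path(out_dir, preset)
    dir.create(pdir, showWarnings = FALSE)
    spec <- population_preset(preset, n_helices = config$n_helices,
                              seed = derive_seed(config$seed,
                                                 match(preset, config$presets)))
    pop <- generate_population(spec)
    write_result_csv(pop$truth, note(file.path(pdir, "truth.csv")))
    for (i in seq_along(pop$maps)) {
      write_heightmap(pop$maps[[i]],
                      note(file.path(pdir, sprintf("helix_%03d.txt", i))),
                      meta = list(seed = pop$truth$seed[i]))
    }
    meas <- measure_population(pop$maps)
    write_result_csv(meas, note(file.path(pdir, "measurements.csv")))
    smry <- summarize_population(meas)
    write_result_csv(smry, note(file.path(pdir, "summary.csv")))
  }

  # 5. scattering peak assignment
  pk <- assign_peaks(config$peaks_q_invA, lattice = config$lattice)
  write_result_csv(pk, note(file.path(out_dir, "peaks_assigned.csv")))

  manifest <- list(
    seed = config$seed,
    parameters = unclass(write_config_plain(config)),
    outputs = lapply(paths, function(p) list(
      path = sub(paste0("^", out_dir, "/?"), "", p),
      md5 = unname(tools::md5sum(p))
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_config_plain <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Generate the small reference fixture set
#'
#' Writes, under `out_dir`: an ideal twisted ribbon (`ribbon.xyz`), a
#' four-run relaxation series (`relaxation.csv`), a left/right pair of
#' noise-free reference height maps (`reference_right.txt`,
#' `reference_left.txt` with JSON sidecars) anchoring the handedness sign
#' chain, and a reference scattering peak list (`peaks.csv`). Identical
#' across platforms for a given seed; everything is small enough for
#' version control.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Tibble of written files, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("cannot create fixture directory '%s'.", out_dir))
  }
  rb <- build_ribbon(23, 17, pitch_nm = 87, handedness = "right")
  write_xyz(rb, file.path(out_dir, "ribbon.xyz"))
  relax <- simulate_twist_relaxation(relaxation_params(seed = seed))
  write_result_csv(relax, file.path(out_dir, "relaxation.csv"))
  for (hand in c("right", "left")) {
    hm <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, handedness = hand,
                           length_nm = 225, tip_sigma_nm = 0.5, noise_sd = 0,
                           seed = seed, apparent_height_nm = 5.2)
    write_heightmap(hm, file.path(out_dir, sprintf("reference_%s.txt", hand)),
                    meta = list(seed = seed, handedness = hand))
  }
  utils::write.csv(
    data.frame(q_invA = q_from_d(c(24.6, 13.6, 4.6, 2.9))),
    file.path(out_dir, "peaks.csv"), row.names = FALSE)
  files <- list.files(out_dir, full.names = FALSE)
  invisible(tibble::tibble(file = files))
}
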