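#' Parameters of the twisted-ribbon width-selection model
#'
#' The model balances the interfacial free energy gained by burying
#' hydrophobic faces between adjacent peptoid columns against the dispersion
#' (stacking) penalty incurred by twist shear across the ribbon width. Its
#' single control parameter is the dimensionless ratio
#' \eqn{\kappa = \gamma l \delta / \varepsilon} of interfacial to dispersion
#' energy scales.
#'
#' The per-monomer free energy of a ribbon `n` columns wide, in units of the
#' dispersion energy \eqn{\varepsilon}, is
#' \deqn{e(N) = -\kappa (1 - 1/N) + \frac{\phi^2}{24}(N^2 - 1),}
#' where \eqn{\phi} is the twist shear angle accumulated per inter-column
#' spacing. The first term rewards wide ribbons (fewer unburied edges per
#' monomer), the second penalises them (stacking strain grows quadratically
#' towards the edges of a twisted ribbon).
#'
#' @param kappa Dimensionless balance parameter \eqn{\kappa \ge 0}.
#' @param phi Twist shear angle per inter-column spacing, radians (> 0).
#'   The default 0.0314 rad places the continuous optimum near 23 columns at
#'   `kappa = 1`, i.e. a physical width near the measured 10.7 nm.
#' @param beta_eps Dispersion energy depth in thermal units (> 0). Acts as
#'   the sharpness of the Boltzmann width distribution; default 50,
#'   interpreted as the cooperative segment size in monomers.
#' @param n_max Largest ribbon width (number of columns) evaluated, >= 2.
#' @param delta Inter-column spacing in nm used to convert a column count
#'   `N` into a physical width `D = N * delta`; default 0.46 nm, the
#'   inter-chain spacing seen by X-ray diffraction.
#'
#' @return A list of class `"ribbon_model_params"`.
#' @seealso [width_distribution()], [mode_width()], [kappa_from_ph()]
#' @export
#' @examples
#' p <- model_params(kappa = 1)
#' free_energy_per_monomer(1:5, p)
model_params <- function(kappa = 1, phi = 0.0314, beta_eps = 50,
                         n_max = 60L, delta = 0.46) {
  check_number(kappa, "kappa", lower = 0)
  check_number(phi, "phi", lower = 0, allow_lower = FALSE)
  check_number(beta_eps, "beta_eps", lower = 0, allow_lower = FALSE)
  n_max <- check_count(n_max, "n_max", lower = 2L)
  check_number(delta, "delta", lower = 0, allow_lower = FALSE)
  structure(
    list(kappa = kappa, phi = phi, beta_eps = beta_eps,
         n_max = n_max, delta = delta),
    class = "ribbon_model_params"
  )
}

#' @export
print.ribbon_model_params <- function(x, ...) {
  cat("<ribbon width model>\n")
  cat(sprintf("  kappa = %g, phi = %g rad, beta_eps = %g, n_max = %d, delta = %g nm\n",
              x$kappa, x$phi, x$beta_eps, x$n_max, x$delta))
  invisible(x)
}

#' Per-monomer free energy of an N-column twisted ribbon
#'
#' @param n Integer ribbon width(s) in columns, `n >= 1`. Vectorised.
#' @param params A [model_params()] object.
#' @return Free energy per monomer in units of \eqn{\varepsilon};
#'   `e(1) = 0` by construction.
#' @export
free_energy_per_monomer <- function(n, params = model_params()) {
  stopifnot(inherits(params, "ribbon_model_params"))
  if (length(n) == 0L || !is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    abort_bad_arg("`n` must contain finite widths >= 1.")
  }
  -params$kappa * (1 - 1 / n) + (params$phi^2 / 24) * (n^2 - 1)
}

#' Relative width probability curve, scaled to unit maximum
#'
#' Evaluates the Boltzmann weight \eqn{\tilde P(N) \propto
#' \exp(-\beta\varepsilon\, e(N))} on integer widths `N = 1..n_max` and
#' rescales so the maximum of each curve is exactly 1 (the conventional
#' presentation; only the shape and the mode carry information).
#'
#' @inheritParams free_energy_per_monomer
#' @return A tibble of class `"width_distribution"` with columns `n`
#'   (columns), `d_nm` (physical width `n * delta`), `energy` (per-monomer
#'   free energy) and `p_scaled`; attributes `mode_n` and `mode_d` give the
#'   most probable width (smallest `n` on exact ties).
#' @export
#' @examples
#' wd <- width_distribution(model_params(kappa = 10))
#' attr(wd, "mode_d") # most probable physical width, nm
width_distribution <- function(params = model_params()) {
  stopifnot(inherits(params, "ribbon_model_params"))
  n <- seq_len(params$n_max)
  e <- free_energy_per_monomer(n, params)
  # subtract the minimum before exponentiating for numerical range safety;
  # the subsequent unit-max rescale makes the shift irrelevant
  w <- exp(-params$beta_eps * (e - min(e)))
  p <- w / max(w)
  mode_n <- n[which.max(p)] # which.max takes the first (smallest) on ties
  out <- tibble::tibble(
    n = n,
    d_nm = n * params$delta,
    energy = e,
    p_scaled = p
  )
  structure(out,
            class = c("width_distribution", class(out)),
            mode_n = mode_n,
            mode_d = mode_n * params$delta,
            kappa = params$kappa)
}

#' Most probable ribbon width
#'
#' The continuous optimum of the free energy solves \eqn{e'(N) = 0}, giving
#' \eqn{N^* = (12\kappa/\phi^2)^{1/3}}; the integer mode is the better of
#' its floor/ceiling under `e(N)` (clamped to `[1, n_max]`).
#'
#' @inheritParams free_energy_per_monomer
#' @return A one-row tibble with `mode_n`, `mode_d` (nm) and
#'   `n_star_continuous` (`NA` when `kappa = 0`, where the mode is 1).
#' @export
mode_width <- function(params = model_params()) {
  stopifnot(inherits(params, "ribbon_model_params"))
  if (params$kappa == 0) {
    return(tibble::tibble(mode_n = 1L, mode_d = params$delta,
                          n_star_continuous = NA_real_))
  }
  n_star <- (12 * params$kappa / params$phi^2)^(1 / 3)
  cand <- unique(pmin(pmax(c(floor(n_star), ceiling(n_star)), 1), params$n_max))
  e <- free_energy_per_monomer(cand, params)
  mode_n <- as.integer(cand[which.min(e)])
  tibble::tibble(mode_n = mode_n, mode_d = mode_n * params$delta,
                 n_star_continuous = n_star)
}

#' pH to kappa mapping through the protonation equilibrium
#'
#' The polar terminus of the peptoid carries a carboxylic acid whose
#' protonation state sets the molecule's hydrophobicity: the protonated
#' (-COOH) form has a higher effective interfacial tension than the
#' deprotonated (-COO-) form. With protonated fraction
#' \eqn{f = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})}, the effective tension
#' is the population average \eqn{\gamma = f\gamma_{HA} + (1-f)\gamma_{A}},
#' and \eqn{\kappa = \gamma l \delta / \varepsilon}. Lower pH therefore
#' raises kappa and favours wider ribbons.
#'
#' @param pka_app Apparent pKa of the acid group inside the assembly. The
#'   aqueous value is ~3.5 but partial protonation is evident up to pH 7 in
#'   the assembled state, so the default apparent value is 5.5.
#' @param gamma_ha,gamma_a Interfacial tensions of the fully protonated and
#'   fully deprotonated forms, in units of \eqn{\varepsilon/(l\delta)};
#'   requires `gamma_ha > gamma_a >= 0`. Defaults place the saturation
#'   limits of kappa at 10 (acid) and 0.1 (base).
#' @param l Characteristic monomer length, nm (default 1.45, five residues
#'   at 0.29 nm).
#' @param delta Characteristic spacing between peptoid layers, nm.
#' @param epsilon Dispersion energy scale, thermal units.
#' @return A list of class `"ph_map"`.
#' @export
ph_map <- function(pka_app = 5.5,
                   gamma_ha = 10 / (1.45 * 0.46),
                   gamma_a = 0.1 / (1.45 * 0.46),
                   l = 1.45, delta = 0.46, epsilon = 1) {
  check_number(pka_app, "pka_app")
  check_number(gamma_a, "gamma_a", lower = 0)
  check_number(gamma_ha, "gamma_ha", lower = gamma_a, allow_lower = FALSE)
  check_number(l, "l", lower = 0, allow_lower = FALSE)
  check_number(delta, "delta", lower = 0, allow_lower = FALSE)
  check_number(epsilon, "epsilon", lower = 0, allow_lower = FALSE)
  structure(
    list(pka_app = pka_app, gamma_ha = gamma_ha, gamma_a = gamma_a,
         l = l, delta = delta, epsilon = epsilon),
    class = "ph_map"
  )
}

#' @describeIn ph_map Compute kappa at given pH value(s); vectorised and
#'   monotone non-increasing in pH.
#' @param ph Solution pH value(s).
#' @param map A [ph_map()] object.
#' @export
kappa_from_ph <- function(ph, map = ph_map()) {
  stopifnot(inherits(map, "ph_map"))
  if (!is.numeric(ph) || any(!is.finite(ph))) {
    abort_bad_arg("`ph` must be finite numeric.")
  }
  f <- 1 / (1 + 10^(ph - map$pka_app))
  gamma <- f * map$gamma_ha + (1 - f) * map$gamma_a
  gamma * map$l * map$delta / map$epsilon
}

#' Width-probability curves over several kappa values
#'
#' Convenience wrapper around [width_distribution()] that stacks curves for
#' a vector of kappa values into one tidy tibble, ready for plotting.
#'
#' @param kappas Numeric vector of kappa values.
#' @param ... Further arguments passed to [model_params()].
#' @return A tibble with columns `kappa`, `n`, `d_nm`, `p_scaled`.
#' @export
width_curves <- function(kappas = c(0.1, 1, 10), ...) {
  purrr::map_dfr(kappas, function(k) {
    wd <- width_distribution(model_params(kappa = k, ...))
    tibble::tibble(kappa = k, n = wd$n, d_nm = wd$d_nm, p_scaled = wd$p_scaled)
  })
}

#' @export
autoplot.width_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d_nm, y = .data$p_scaled)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "ribbon width D (nm)",
      y = expression(tilde(P)),
      title = sprintf("Width distribution, kappa = %g", attr(object, "kappa"))
    )
}

#' Plot width-probability curves for several kappa values
#'
#' @inheritParams width_curves
#' @return A ggplot object.
#' @export
plot_width_curves <- function(kappas = c(0.1, 1, 10), ...) {
  cv <- width_curves(kappas, ...)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$d_nm, y = .data$p_scaled,
                                   colour = factor(.data$kappa))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ribbon width D (nm)", y = expression(tilde(P)),
                  colour = expression(kappa))
}
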