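#' Lamellar spacing conversions
#'
#' First-order lamellar relation between the scattering vector magnitude
#' and the real-space repeat: `d = 2 * pi / q`.
#'
#' @param q Scattering vector magnitude(s), inverse Angstrom (> 0).
#' @param d Real-space spacing(s), Angstrom (> 0).
#' @return `d_from_q()`: spacing in Angstrom; `q_from_d()`: q in inverse
#'   Angstrom.
#' @export
#' @examples
#' d_from_q(1.36) # 4.62 A
d_from_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0)) {
    abort_bad_arg("`q` must be positive and finite.")
  }
  2 * pi / q
}

#' @rdname d_from_q
#' @export
q_from_d <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    abort_bad_arg("`d` must be positive and finite.")
  }
  2 * pi / d
}

lattice_reference_spacings <- function(lattice = ribbon_lattice()) {
  # reference spacings in Angstrom (internal unit for scattering)
  c(bilayer_thickness = lattice$bilayer_thickness * 10,
    inter_backbone = lattice$backbone_gap * 10,
    inter_chain = lattice$chain_spacing * 10,
    residue_repeat = lattice$residue_spacing * 10)
}

#' Assign scattering peaks to ribbon lattice features
#'
#' Converts each peak position to a real-space spacing and assigns it to
#' the nearest reference spacing of the bilayer lattice (bilayer
#' thickness, inter-backbone, inter-chain, residue repeat) when the
#' relative error is within `rel_tol`; otherwise the peak is left
#' unassigned. First-order features only (no harmonic indexing).
#'
#' @param q_invA Numeric vector of peak positions, inverse Angstrom.
#' @param lattice A [ribbon_lattice()] providing the reference spacings.
#' @param rel_tol Maximum relative error for an assignment (default 0.05).
#' @return A tibble with columns `q_invA`, `d_A`, `d_nm`, `label`,
#'   `relative_error` (`NA` for unassigned peaks).
#' @export
#' @examples
#' assign_peaks(c(0.2554, 0.462, 1.366, 2.167))
assign_peaks <- function(q_invA, lattice = ribbon_lattice(), rel_tol = 0.05) {
  if (length(q_invA) == 0L) {
    abort_bad_arg("`q_invA` must contain at least one peak.")
  }
  check_number(rel_tol, "rel_tol", lower = 0)
  d <- d_from_q(q_invA)
  refs <- lattice_reference_spacings(lattice)
  rel_err <- abs(outer(d, refs, function(x, r) x / r - 1))
  best <- apply(rel_err, 1, which.min)
  err <- rel_err[cbind(seq_along(d), best)]
  assigned <- err <= rel_tol
  tibble::tibble(
    q_invA = q_invA,
    d_A = d,
    d_nm = d / 10,
    label = ifelse(assigned, names(refs)[best], "unassigned"),
    relative_error = ifelse(assigned, err, NA_real_)
  )
}
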