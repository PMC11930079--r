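#' Theoretical scattering profile of a bead model via the Debye equation
#'
#' `I(q) = sum_ij f_i f_j sin(q r_ij) / (q r_ij)` with the `i = j` and
#' `q -> 0` limits taken as 1, so `I(0) = (sum f)^2`. Form factors are
#' q-independent constants (dummy-residue beads): only relative profile
#' shape is meaningful.
#'
#' @param coords Numeric matrix, n x 3, bead coordinates in Angstrom.
#' @param q_grid Numeric vector of momentum transfer values, 1/Angstrom,
#'   strictly increasing, >= 0.
#' @param form_factor Scalar or per-bead constant form factor (default 1).
#' @param label Profile label.
#' @return A [saxs_profile()] without uncertainties.
#' @export
debye_profile <- function(coords, q_grid, form_factor = 1, label = "debye") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || ncol(coords) != 3)
    abort("coords must be an n x 3 matrix with n >= 1")
  f <- rep_len(form_factor, nrow(coords))
  I <- cpp_debye(coords, as.numeric(q_grid), as.numeric(f))
  saxs_profile(q_grid, I, label = label)
}

#' Ensemble-averaged Debye profile
#'
#' Unweighted mean of the per-conformer Debye profiles, the forward model
#' for scattering from a flexible molecule in solution (all conformers
#' equally populated).
#'
#' @param conformers A conformer set (see [sample_conformers()]) or a list
#'   of n x 3 coordinate matrices.
#' @param q_grid Momentum transfer grid, 1/Angstrom.
#' @return A [saxs_profile()].
#' @export
ensemble_average_profile <- function(conformers, q_grid) {
  coords_list <- if (inherits(conformers, "conformer_set")) conformers$coords
                 else conformers
  if (length(coords_list) < 1) abort("empty conformer list")
  I <- purrr::map(coords_list, function(xyz) {
    cpp_debye(as.matrix(xyz), as.numeric(q_grid), rep(1, nrow(xyz)))
  })
  saxs_profile(q_grid, purrr::reduce(I, `+`) / length(I),
               label = sprintf("ensemble mean of %d conformers", length(I)))
}
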