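#' Mechanical and thermal parameters of the protofilament model
#'
#' Bundles the constants of the discrete worm-like-chain protofilament:
#' subunit length, subunit count, lateral-bond spring (rest length `l0`,
#' break length `lmax`, stiffness `ks`) and bending stiffness `kb` with the
#' preferred bond angles of GDP (`theta_D`) and GTP (`theta_T`) subunits.
#' Energies are in units of kBT at the reference temperature, lengths in nm,
#' angles in rad. `temperature_factor` scales the temperature: 1 is the
#' reference, values approaching 0 approach the zero-temperature limit.
#'
#' The derived bond-strength scales are `E_ms = ks*(lmax-l0)^2/2` (maximum
#' lateral-bond energy) and `E_mb = kb*(1-cos(theta_D))` (bending strain per
#' subunit of a straightened GDP bond); their difference
#' `delta_E = E_ms - E_mb` is the power-struggle parameter controlling
#' microtubule stability.
#'
#' @param b Subunit (tubulin dimer) length, nm.
#' @param N Number of subunits per protofilament.
#' @param l0 Lateral-bond rest length (tubulin dimer diameter), nm.
#' @param lmax Lateral-bond break length, nm.
#' @param ks Lateral spring constant, kBT/nm^2.
#' @param kb Bending stiffness, kBT.
#' @param theta_D Preferred bond angle between GDP subunits, rad.
#' @param theta_T Preferred bond angle between GTP subunits, rad.
#' @param temperature_factor Dimensionless temperature scaling.
#' @return An object of class `pf_params`.
#' @examples
#' p <- model_params(N = 32)
#' e_ms(p); e_mb(p); delta_e(p)
#' @export
model_params <- function(b = 8, N = 32, l0 = 6.5, lmax = 1.2 * l0,
                         ks = 2 * 8 / (lmax - l0)^2,
                         kb = 7 / (1 - cos(theta_D)),
                         theta_D = 0.4, theta_T = 0,
                         temperature_factor = 1) {
  stopifnot(b > 0, N >= 2, l0 > 0, lmax > l0, ks >= 0, kb >= 0,
            temperature_factor >= 0)
  structure(list(b = b, N = as.integer(N), l0 = l0, lmax = lmax, ks = ks,
                 kb = kb, theta_D = theta_D, theta_T = theta_T,
                 temperature_factor = temperature_factor),
            class = "pf_params")
}

#' @export
print.pf_params <- function(x, ...) {
  cat(sprintf("protofilament model: N = %d subunits of b = %g nm (L = %g nm)\n",
              x$N, x$b, x$N * x$b))
  cat(sprintf("  lateral bond: l0 = %g nm, lmax = %g nm, ks = %.4g kBT/nm^2 (E_ms = %.4g kBT)\n",
              x$l0, x$lmax, x$ks, e_ms(x)))
  cat(sprintf("  bending:      kb = %.4g kBT, theta_D = %g, theta_T = %g rad (E_mb = %.4g kBT)\n",
              x$kb, x$theta_D, x$theta_T, e_mb(x)))
  cat(sprintf("  delta_E = E_ms - E_mb = %.4g kBT, temperature factor %g\n",
              delta_e(x), x$temperature_factor))
  invisible(x)
}

#' Derived bond-strength scales
#'
#' `e_ms` is the maximum lateral-bond energy `ks*(lmax-l0)^2/2`, `e_mb` the
#' bending strain energy per subunit of a straightened GDP bond
#' `kb*(1-cos(theta_D))`, and `delta_e` their difference (the power-struggle
#' parameter). All in kBT.
#'
#' @param params A [model_params()] object.
#' @return Energy in kBT.
#' @export
e_ms <- function(params) 0.5 * params$ks * (params$lmax - params$l0)^2

#' @rdname e_ms
#' @export
e_mb <- function(params) params$kb * (1 - cos(params$theta_D))

#' @rdname e_ms
#' @export
delta_e <- function(params) e_ms(params) - e_mb(params)

#' Build parameters from target bond-strength scales
#'
#' Inverts the derived quantities: sets `ks = 2*E_ms/(lmax-l0)^2` and
#' `kb = E_mb/(1-cos(theta_D))` on top of a base parameter set, so that
#' [e_ms()] and [e_mb()] round-trip to the requested values.
#'
#' @param Ems Target maximum lateral-bond energy, kBT (>= 0).
#' @param Emb Target bending strain energy per subunit, kBT (>= 0).
#' @param base A [model_params()] object supplying all other fields.
#' @return A `pf_params` object.
#' @examples
#' p <- params_from_energies(8, 7, model_params())
#' c(e_ms(p), e_mb(p))
#' @export
params_from_energies <- function(Ems, Emb, base = model_params()) {
  stopifnot(Ems >= 0, Emb >= 0)
  if (Ems > 0 && base$lmax == base$l0)
    stop("lmax equals l0: cannot realize a nonzero lateral-bond energy")
  if (Emb > 0 && base$theta_D == 0)
    stop("theta_D is zero: cannot realize a nonzero bending strain energy")
  base$ks <- if (Ems == 0) 0 else 2 * Ems / (base$lmax - base$l0)^2
  base$kb <- if (Emb == 0) 0 else Emb / (1 - cos(base$theta_D))
  base
}

#' Nucleotide composition of a protofilament
#'
#' A per-subunit sequence of nucleotide states, each `"T"` (GTP, straight,
#' preferred bond angle `theta_T`) or `"D"` (GDP, curved, preferred angle
#' `theta_D`). The preferred angle of the bond proximal to subunit i is set
#' by subunit i's nucleotide; the clamp bond of subunit 1 follows subunit 1.
#'
#' @param nucleotide Character vector of `"T"`/`"D"` labels, length N.
#' @return An object of class `pf_composition`.
#' @export
composition <- function(nucleotide) {
  nucleotide <- as.character(nucleotide)
  if (!all(nucleotide %in% c("T", "D")))
    stop("nucleotide labels must be 'T' or 'D'")
  structure(list(nucleotide = nucleotide, N = length(nucleotide)),
            class = "pf_composition")
}

#' GTP-capped composition
#'
#' `m` GTP subunits at the plus end (tip) on top of `n_bulk` GDP subunits;
#' total length `m + n_bulk`.
#'
#' @param m Number of GTP cap subunits (>= 0).
#' @param n_bulk Number of GDP bulk subunits (>= 1).
#' @return A `pf_composition` of length `m + n_bulk`.
#' @examples
#' cap_composition(1, 19)  # one-subunit cap on a 19-subunit GDP bulk
#' @export
cap_composition <- function(m, n_bulk) {
  stopifnot(m >= 0, n_bulk >= 1)
  composition(c(rep("D", n_bulk), rep("T", m)))
}

#' Preferred bond angles of a composition
#'
#' @param comp A [composition()] object.
#' @param params A [model_params()] object supplying `theta_D`, `theta_T`.
#' @return Numeric vector of per-bond preferred angles, rad.
#' @export
preferred_angles <- function(comp, params) {
  ifelse(comp$nucleotide == "T", params$theta_T, params$theta_D)
}

check_sizes <- function(comp, params) {
  if (comp$N != params$N)
    stop(sprintf("composition length (%d) does not match params N (%d)",
                 comp$N, params$N))
  invisible(TRUE)
}
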