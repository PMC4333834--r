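#' Zero-temperature peel geometry
#'
#' The peeled segment of a GDP protofilament relaxes onto a circular arc of
#' radius `rc = b/theta_D` (20 nm at the default parameters). These helpers
#' hold that geometry.
#'
#' @param params A [model_params()] object, or NULL to give `rc`/`L`
#'   directly.
#' @param rc Intrinsic radius of curvature, nm.
#' @param L Protofilament length, nm.
#' @return An object of class `pf_geometry` with fields `rc` and `L`.
#' @export
geometry_params <- function(params = NULL, rc = params$b / params$theta_D,
                            L = params$N * params$b) {
  stopifnot(rc > 0, L > 0)
  structure(list(rc = rc, L = L), class = "pf_geometry")
}

#' Tip position of a peeled arc (zero-temperature relation)
#'
#' For a peeled length `Lc` relaxed onto the intrinsic arc,
#' `Rx0 = Lc - rc*sin(Lc/rc)`: non-decreasing in `Lc`, flat wherever the arc
#' completes full circles (Lc multiples of 2*pi*rc), which is what piles up
#' probability near Rx ~ 125 nm.
#'
#' @param Lc Peeled arc length(s), nm, in `[0, L]`.
#' @param geom A [geometry_params()] object.
#' @return Rx in nm (vectorized).
#' @examples
#' g <- geometry_params(rc = 20, L = 256)
#' rx_of_lc(2 * pi * 20, g)  # one full circle: Rx = Lc
#' @export
rx_of_lc <- function(Lc, geom) {
  stopifnot(all(Lc >= -1e-9), all(Lc <= geom$L + 1e-9))
  Lc - geom$rc * sin(Lc / geom$rc)
}

#' Zero-temperature two-state prediction
#'
#' Without thermal fluctuations the chain is fully bound (Rx = 0) when the
#' lateral bond strength wins (`delta_E > 0`) and fully peeled
#' (`Rx = L - rc*sin(L/rc)`) when bending wins (`delta_E < 0`). `delta_E = 0`
#' is degenerate and returns NA with a flag.
#'
#' @param deltaE Power-struggle parameter `E_ms - E_mb`, kBT.
#' @param geom A [geometry_params()] object.
#' @return Rx in nm; attribute `degenerate` is TRUE at `deltaE = 0`.
#' @export
zero_temperature_state <- function(deltaE, geom) {
  if (deltaE == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  rx <- if (deltaE > 0) 0 else rx_of_lc(geom$L, geom)
  structure(rx, degenerate = FALSE)
}

#' Semi-analytic multi-peak approximation of P(Rx)
#'
#' Mixture model for the tip-position distribution: peeling `Nc` subunits
#' costs `deltaE` per subunit and the free arc's tip distribution is
#' approximated by a Gaussian centered at the zero-temperature position
#' `Rx0(Nc*b)`, so
#' `P(Rx) = sum_Nc exp(-deltaE*Nc) * Normal(Rx; Rx0(Nc*b), sigma(Nc))`.
#' The folding of `Rx0` near multiples of `2*pi*rc` concentrates many `Nc`
#' values at nearly the same Rx, producing the multi-peak structure. The
#' width model `sigma(Nc) = sigma0*sqrt(Nc)` grows with peeled length; only
#' the peak positions (not widths) are quantitative.
#'
#' @param deltaE Peel cost per subunit, kBT.
#' @param geom A [geometry_params()] object.
#' @param N Number of subunits.
#' @param b Subunit length, nm.
#' @param sigma0 Width scale, nm (> 0).
#' @param bin_width Output bin width, nm.
#' @return An `rx_distribution` over `[0, L + 6*sigma(N)]`.
#' @export
semi_analytic_p <- function(deltaE, geom, N, b = 8, sigma0 = 2,
                            bin_width = 2) {
  stopifnot(N >= 1, sigma0 > 0)
  edges <- seq(0, geom$L + 6 * sigma0 * sqrt(N), by = bin_width)
  x <- (edges[-1] + edges[-length(edges)]) / 2
  p <- rep(0, length(x))
  for (nc in seq_len(N)) {
    mu <- rx_of_lc(min(nc * b, geom$L), geom)
    p <- p + exp(-deltaE * nc) * stats::dnorm(x, mu, sigma0 * sqrt(nc))
  }
  rx_distribution(edges, p / sum(p), NA_integer_)
}
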