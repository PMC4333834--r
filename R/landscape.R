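#' Free-energy landscape over the tip coordinate
#'
#' Tabulated free energy F(Rx) in kBT on an Rx grid, defined up to an
#' additive constant. Evaluation between grid points uses a natural cubic
#' spline that reproduces the tabulated values exactly; evaluation outside
#' the grid is an error (no silent extrapolation).
#'
#' @param grid Rx grid, nm (strictly increasing).
#' @param F Free energy at the grid points, kBT.
#' @param tilt_force Applied pulling force already folded into F, pN.
#' @return An object of class `pf_landscape`.
#' @export
landscape <- function(grid, F, tilt_force = 0) {
  stopifnot(length(grid) == length(F), length(grid) >= 4,
            all(diff(grid) > 0), all(is.finite(F)))
  structure(list(grid = grid, F = F, tilt_force = tilt_force),
            class = "pf_landscape")
}

#' Evaluate a landscape
#'
#' @param land A [landscape()].
#' @param x Positions, nm, inside the grid range.
#' @param deriv Derivative order (0 or 1).
#' @return F(x) in kBT (or dF/dx in kBT/nm).
#' @export
landscape_at <- function(land, x, deriv = 0) {
  rng <- range(land$grid)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9))
    stop(sprintf("evaluation outside the sampled landscape [%g, %g] nm",
                 rng[1], rng[2]))
  fn <- stats::splinefun(land$grid, land$F, method = "natural")
  fn(pmin(pmax(x, rng[1]), rng[2]), deriv = deriv)
}

#' Landscape from a sampled Rx distribution
#'
#' `F = -kBT ln P` on non-empty bins at the bin centers. Leading/trailing
#' empty bins are dropped; empty interior bins are filled by interpolation
#' with a warning. The minimum is shifted to 0.
#'
#' @param dist An `rx_distribution`.
#' @return A [landscape()] object.
#' @export
free_energy_from_distribution <- function(dist) {
  x <- bin_centers(dist)
  p <- dist$p
  pos <- which(p > 0)
  if (length(pos) == 0) stop("all-empty distribution")
  x <- x[pos[1]:pos[length(pos)]]
  p <- p[pos[1]:pos[length(pos)]]
  F <- ifelse(p > 0, -log(p), NA_real_)
  if (anyNA(F)) {
    warning(sprintf("%d empty interior bin(s) filled by interpolation", sum(is.na(F))))
    F <- stats::approx(x[!is.na(F)], F[!is.na(F)], xout = x)$y
  }
  landscape(x, F - min(F))
}

#' Tilt a landscape with a pulling force
#'
#' A force f applied at the tip adds `f*Rx` to the free energy:
#' `F(Rx, f) = F(Rx, 0) + f*Rx`, pointwise exactly, with f converted from pN
#' to kBT/nm (1 kBT/nm = 4.114 pN at 298 K).
#'
#' @param land A [landscape()].
#' @param f Pulling force, pN.
#' @param temperature_K Temperature for the unit conversion, K.
#' @return The tilted [landscape()].
#' @export
tilt <- function(land, f, temperature_K = 298) {
  f_kbt <- f / kbt_pn_nm(temperature_K)
  landscape(land$grid, land$F + f_kbt * land$grid,
            tilt_force = land$tilt_force + f)
}

kbt_pn_nm <- function(temperature_K = 298) {
  1.380649e-23 * temperature_K * 1e21   # kBT in pN*nm
}

#' Stokes-Einstein diffusion coefficient of the peeling tip
#'
#' `D = kBT / (6 pi eta a)` for a blob of radius `a` in a medium of
#' viscosity `eta`.
#'
#' @param a Effective blob size, nm (default 40 nm, the circle made by a
#'   peeled GDP protofilament).
#' @param eta Viscosity, Pa s (default water).
#' @param temperature_K Temperature, K.
#' @return D in nm^2/s.
#' @examples
#' diffusion_coefficient()  # ~5.46e6 nm^2/s
#' @export
diffusion_coefficient <- function(a = 40, eta = 0.001, temperature_K = 298) {
  stopifnot(a > 0, eta > 0, temperature_K > 0)
  kb <- 1.380649e-23
  (kb * temperature_K) / (6 * pi * eta * a * 1e-9) * 1e18   # m^2/s -> nm^2/s
}

#' Mean first-passage time across a landscape
#'
#' Kramers-type double integral for diffusion on F(Rx) with a reflecting
#' boundary at `A` and an absorbing boundary at `B`:
#' `tau = (1/D) int_A^B exp(-F(x)) int_x^B exp(F(u)) du dx` (F in kBT).
#' Evaluated on a dense grid over the spline interpolant with cumulative
#' trapezoids; invariant to an additive constant in F.
#'
#' @param land A [landscape()].
#' @param D Diffusion coefficient, nm^2/s.
#' @param A Start/reflecting position, nm.
#' @param B Absorbing position, nm (A < B, within the landscape support).
#' @param n_grid Quadrature grid size.
#' @param swap_order Evaluate the Fubini-swapped form instead (used as an
#'   internal consistency check).
#' @return Time in seconds.
#' @examples
#' flat <- landscape(seq(0, 130, 2), rep(0, 66))
#' mean_first_passage_time(flat, 5.46e6, 0, 125)  # ~B^2/(2D)
#' @export
mean_first_passage_time <- function(land, D, A, B, n_grid = 20001,
                                    swap_order = FALSE) {
  stopifnot(A < B, D > 0)
  rng <- range(land$grid)
  if (A < rng[1] - 1e-9 || B > rng[2] + 1e-9)
    stop(sprintf("[A, B] = [%g, %g] outside landscape support [%g, %g] nm",
                 A, B, rng[1], rng[2]))
  x <- seq(max(A, rng[1]), min(B, rng[2]), length.out = n_grid)
  F <- landscape_at(land, x)
  F <- F - mean(range(F))         # guard exp overflow; result is shift-invariant
  h <- x[2] - x[1]
  eF <- exp(F)
  emF <- exp(-F)
  if (!swap_order) {
    # inner integral G(x) = int_x^B exp(F) du, by reverse cumulative trapezoid
    G <- rev(cumtrapz_vec(rev(eF), h))
    trapz_vec(emF * G, h) / D
  } else {
    Hh <- cumtrapz_vec(emF, h)    # int_A^u exp(-F)
    trapz_vec(eF * Hh, h) / D
  }
}

cumtrapz_vec <- function(v, h) {
  n <- length(v)
  c(0, cumsum((v[-n] + v[-1]) / 2)) * h
}

trapz_vec <- function(v, h) sum((v[-length(v)] + v[-1]) / 2) * h

#' Unzippering velocities from the landscape
#'
#' Mean first-passage times from the tubular state A (Rx = `A`, reflecting)
#' to the one-circle ram's-horn state B (Rx = `B`) and the two-circle state C
#' (Rx = `C`), and the corresponding unzippering velocities
#' `v_AB = (B-A)/tau_AB`, `v_AC = (C-A)/tau_AC`.
#'
#' @param land A [landscape()] whose support reaches `C`.
#' @param D Diffusion coefficient, nm^2/s.
#' @param A,B,C State positions, nm (defaults 0, 125, 250).
#' @return List with `tau_AB_s`, `tau_AC_s`, `v_AB_nm_s`, `v_AC_nm_s`, `D_nm2_s`.
#' @export
unzippering_velocities <- function(land, D, A = 0, B = 125, C = 250) {
  A <- max(A, min(land$grid))
  tau_ab <- mean_first_passage_time(land, D, A, B)
  tau_ac <- mean_first_passage_time(land, D, A, C)
  list(tau_AB_s = tau_ab, tau_AC_s = tau_ac,
       v_AB_nm_s = (B - A) / tau_ab, v_AC_nm_s = (C - A) / tau_ac,
       D_nm2_s = D, A_nm = A, B_nm = B, C_nm = C)
}

#' Local minima of a landscape
#'
#' Smooths F with a Gaussian kernel (sd `sigma` nm), finds local minima of
#' the smoothed curve (grid interior plus boundary minima), and keeps those
#' whose depth relative to the lower flanking barrier is at least
#' `prominence`.
#'
#' @param land A [landscape()].
#' @param prominence Minimum depth, kBT (> 0).
#' @param sigma Gaussian smoothing width, nm (0 = none).
#' @return Data frame with columns `Rx_nm`, `F_kBT`, `prominence_kBT`,
#'   sorted by `Rx_nm`; zero rows if the landscape is monotone.
#' @export
find_minima <- function(land, prominence = 1, sigma = 4) {
  stopifnot(prominence > 0)
  x <- land$grid
  F <- land$F
  if (sigma > 0) {
    h <- stats::median(diff(x))
    half <- max(1L, ceiling(3 * sigma / h))
    k <- stats::dnorm(seq(-half, half) * h, sd = sigma)
    # reflect-pad so smoothing does not drag the boundaries
    Fp <- c(F[(half + 1):2], F, F[(length(F) - 1):(length(F) - half)])
    F <- as.vector(stats::filter(Fp, k / sum(k), sides = 2))[(half + 1):(half + length(x))]
  }
  n <- length(F)
  is_min <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) F[i - 1] else Inf
    r <- if (i < n) F[i + 1] else Inf
    F[i] < l && F[i] < r
  }, logical(1))
  idx <- which(is_min)
  # a landscape with no interior maximum (monotone) has no wells; otherwise
  # a well's depth is measured against the lower of the two barriers that
  # close it off, each barrier being the highest point on that side (a side
  # with no samples, i.e. a well at the very edge, does not constrain)
  has_interior_max <- any(vapply(2:(n - 1), function(i)
    F[i] > F[i - 1] && F[i] > F[i + 1], logical(1)))
  if (length(idx) == 0 || !has_interior_max)
    return(data.frame(Rx_nm = numeric(0), F_kBT = numeric(0),
                      prominence_kBT = numeric(0)))
  prom <- vapply(idx, function(i) {
    bl <- if (i > 1) max(F[1:(i - 1)]) else Inf
    br <- if (i < n) max(F[(i + 1):n]) else Inf
    min(bl, br) - F[i]
  }, numeric(1))
  keep <- is.finite(prom) & prom >= prominence
  out <- data.frame(Rx_nm = x[idx][keep], F_kBT = land$F[idx][keep],
                    prominence_kBT = prom[keep])
  out[order(out$Rx_nm), , drop = FALSE]
}

#' Read/write a landscape as TSV
#'
#' Columns `Rx_nm` and `F_kBT` (and `P` when written from a distribution).
#'
#' @param land A [landscape()].
#' @param path File path.
#' @return `write_landscape_tsv` returns the path invisibly;
#'   `read_landscape_tsv` returns a [landscape()].
#' @export
write_landscape_tsv <- function(land, path) {
  d <- attr(land, "dist")
  df <- data.frame(Rx_nm = land$grid, F_kBT = land$F)
  if (!is.null(d)) {
    p <- stats::approx(bin_centers(d), d$p, xout = land$grid)$y
    df$P <- p
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_tsv
#' @export
read_landscape_tsv <- function(path) {
  df <- utils::read.delim(path)
  landscape(df$Rx_nm, df$F_kBT)
}

#' Kinetics report
#'
#' Computes D, the first-passage times and unzippering velocities, and the
#' landscape minima, and returns them as one list ready for JSON export.
#'
#' @param land A [landscape()].
#' @param a,eta,temperature_K Diffusion-coefficient inputs (see
#'   [diffusion_coefficient()]).
#' @param A,B,C State positions, nm.
#' @param prominence Minima prominence threshold, kBT.
#' @return A list.
#' @export
kinetics_report <- function(land, a = 40, eta = 0.001, temperature_K = 298,
                            A = 0, B = 125, C = 250, prominence = 1) {
  D <- diffusion_coefficient(a, eta, temperature_K)
  kin <- unzippering_velocities(land, D, A, B, C)
  mins <- find_minima(land, prominence)
  c(kin, list(minima = mins,
              landscape_checksum = sum(land$F) + sum(land$grid)))
}
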