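#' Lateral-bond energy of a single breakable spring
#'
#' Hookean below the break length, constant plateau `E_ms` beyond it:
#' `ks*(li-l0)^2/2` for `li < lmax`, else `ks*(lmax-l0)^2/2`. Continuous at
#' `li = lmax`; the bond is history-free and re-forms whenever `li < lmax`.
#'
#' @param li Bond length(s), nm (>= 0).
#' @param params A [model_params()] object.
#' @return Energy in kBT (vectorized over `li`).
#' @examples
#' p <- model_params()
#' lateral_energy(p$l0, p)    # 0 at rest length
#' lateral_energy(p$lmax, p)  # the plateau E_ms
#' @export
lateral_energy <- function(li, params) {
  if (any(li < 0)) stop("invalid geometry: negative bond length")
  d <- pmin(li, params$lmax) - params$l0
  0.5 * params$ks * d^2
}

#' Bending energy of one longitudinal bond
#'
#' `kb*(1 - cos(theta - theta0))`: non-negative, smooth, zero iff the bond
#' sits at its preferred angle (mod 2*pi). For small deflections it reduces
#' to the quadratic `kb/2*(theta-theta0)^2`.
#'
#' @param theta Actual bond angle(s), rad.
#' @param theta0 Preferred bond angle(s), rad.
#' @param params A [model_params()] object.
#' @return Energy in kBT (vectorized).
#' @export
bending_energy <- function(theta, theta0, params) {
  params$kb * (1 - cos(theta - theta0))
}

#' Build the planar chain geometry from bond angles
#'
#' Reconstructs the rigid-rod chain deterministically from the angle vector:
#' subunit s points along the cumulative angle `Theta_s = sum(theta[1:s])`
#' (entry 1 is the clamp angle of subunit 1 against the microtubule body,
#' held at 0 during sampling) and node s sits at
#' `node[s-1] + b*(cos(Theta_s), sin(Theta_s))`. The rigid neighbor runs
#' parallel to x at offset `-l0`, so subunit s's lateral bond length is the
#' distance from its distal node to the fixed point `(s*b, -l0)`; the
#' preferred curl `+theta_D` therefore peels away from the neighbor.
#'
#' Derived state: tip coordinate `Rx = L - x_N` (L = N*b), the number `Nc`
#' of contiguous subunits from the tip whose lateral bond is broken
#' (`li >= lmax`), and the peeled length `Lc = Nc*b`.
#'
#' @param theta Numeric vector of N bond angles, rad (clamp first).
#' @param params A [model_params()] object with matching `N`.
#' @return An object of class `pf_chain` with fields `theta`, `nodes`
#'   ((N+1) x 2 matrix, nm), `li`, `Rx`, `Lc`, `Nc`.
#' @examples
#' p <- model_params(N = 16)
#' straight <- build_geometry(rep(0, 16), p)
#' straight$Rx            # 0
#' curled <- build_geometry(rep(p$theta_D, 16), p)
#' curled$Nc              # fully peeled
#' @export
build_geometry <- function(theta, params) {
  N <- params$N
  if (length(theta) != N)
    stop(sprintf("theta must have %d entries (clamp + %d relative angles)",
                 N, N - 1))
  ang <- cumsum(theta)
  x <- c(0, cumsum(params$b * cos(ang)))
  y <- c(0, cumsum(params$b * sin(ang)))
  s <- seq_len(N)
  li <- sqrt((x[s + 1] - s * params$b)^2 + (y[s + 1] + params$l0)^2)
  L <- N * params$b
  Rx <- L - x[N + 1]
  if (Rx < -1e-9 || Rx > 2 * L + 1e-9)
    stop("invalid geometry: tip coordinate outside [0, 2L]")
  broken <- rev(li) >= params$lmax           # from tip inward
  Nc <- if (broken[1]) which.min(c(broken, FALSE)) - 1L else 0L
  structure(list(theta = theta, nodes = cbind(x = x, y = y), li = li,
                 Rx = Rx, L = L, Lc = Nc * params$b, Nc = Nc),
            class = "pf_chain")
}

#' Total mechanical energy of a chain state
#'
#' Sum of all N bending terms (clamp bond included) and all N lateral-bond
#' terms; exactly additive over the per-bond calls.
#'
#' @param state A [build_geometry()] chain state.
#' @param comp A [composition()] of matching length.
#' @param params A [model_params()] object.
#' @return Energy in kBT.
#' @export
total_energy <- function(state, comp, params) {
  check_sizes(comp, params)
  if (length(state$theta) != params$N) stop("state/params size mismatch")
  theta0 <- preferred_angles(comp, params)
  sum(bending_energy(state$theta, theta0, params)) +
    sum(lateral_energy(state$li, params))
}

#' One Metropolis pivot move
#'
#' Perturbs one randomly chosen movable bond angle (the clamp is fixed) by a
#' uniform draw in `[-max_rotation, +max_rotation]`; subunits distal to the
#' pivot rotate rigidly. The move is accepted with probability
#' `min(1, exp(-beta * deltaE))` where `beta = 1/temperature_factor`; on
#' rejection the prior state is returned unchanged.
#'
#' This pure-R single step is the reference definition of the move; the
#' long-run samplers ([run_chain()], [umbrella_sample()]) use an equivalent
#' compiled kernel.
#'
#' @param state A `pf_chain` state.
#' @param comp A [composition()].
#' @param params A [model_params()] object.
#' @param max_rotation Proposal half-width, rad.
#' @return List with elements `state` (the new or unchanged chain),
#'   `accepted` (logical) and `delta_E` (the proposal's energy change, kBT).
#' @export
metropolis_step <- function(state, comp, params, max_rotation = 1.5) {
  check_sizes(comp, params)
  j <- sample.int(params$N - 1L, 1L) + 1L    # movable angle index (clamp excluded)
  delta <- stats::runif(1, -max_rotation, max_rotation)
  theta_new <- state$theta
  theta_new[j] <- theta_new[j] + delta
  cand <- build_geometry(theta_new, params)
  de <- total_energy(cand, comp, params) - total_energy(state, comp, params)
  beta <- 1 / params$temperature_factor
  accepted <- de <= 0 || stats::runif(1) < exp(-beta * de)
  list(state = if (accepted) cand else state, accepted = accepted,
       delta_E = de)
}

#' Export a chain conformation as XYZ-style text
#'
#' One node per line, `x y z` in nm (z = 0 for the planar single
#' protofilament), for quick visualization.
#'
#' @param state A `pf_chain` state.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(state, path) {
  nodes <- cbind(state$nodes, z = 0)
  utils::write.table(format(nodes, digits = 8), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Initial angles for a partially peeled chain
#'
#' Straight proximal segment with the distal `n_curl` bonds at the preferred
#' GDP angle; used to seed umbrella windows near their centers.
#'
#' @param n_curl Number of curled distal bonds.
#' @param params A [model_params()] object.
#' @return Angle vector of length N.
#' @keywords internal
peeled_init <- function(n_curl, params) {
  n_curl <- max(0L, min(as.integer(n_curl), params$N - 1L))
  c(rep(0, params$N - n_curl), rep(params$theta_D, n_curl))
}
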