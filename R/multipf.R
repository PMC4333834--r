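#' Three-protofilament state
#'
#' Three discrete protofilaments whose minus-end nodes form an equilateral
#' triangle of side `l0` (circumradius `rho = l0/sqrt(3)`) around the tube
#' axis. Protofilament `alpha` fluctuates only in the plane spanned by the
#' axis (x) and its own radial direction; the three planes are 120 degrees
#' apart. Subunit i of protofilament `alpha` bonds to subunit i of
#' protofilament `alpha+1` (cyclic, distal nodes), with the same breakable
#' spring as the single-protofilament model, so the straight configuration
#' has all inter-protofilament distances at `l0` and zero lateral energy.
#'
#' @param params A [model_params()] object.
#' @param theta N x 3 matrix of bond angles (clamp row first; default
#'   straight).
#' @param bendable Logical length-3 mask of which protofilaments may move.
#' @return An object of class `pf3_state` with per-PF in-plane node
#'   coordinates, 3-D coordinates, pairwise subunit distances `li` (N x 3,
#'   column alpha = distance to PF alpha+1), and per-PF tip coordinates `Rx`.
#' @export
build_3pf <- function(params, theta = matrix(0, params$N, 3),
                      bendable = rep(TRUE, 3)) {
  stopifnot(nrow(theta) == params$N, ncol(theta) == 3, length(bendable) == 3)
  rho <- params$l0 / sqrt(3)
  phi <- c(0, 2, 4) * pi / 3
  N <- params$N
  planar <- lapply(1:3, function(a) {
    ang <- cumsum(theta[, a])
    cbind(x = c(0, cumsum(params$b * cos(ang))),
          v = c(0, cumsum(params$b * sin(ang))))
  })
  nodes3d <- lapply(1:3, function(a) {
    r <- rho + planar[[a]][, "v"]
    cbind(x = planar[[a]][, "x"], y = r * cos(phi[a]), z = r * sin(phi[a]))
  })
  li <- sapply(1:3, function(a) {
    bnext <- a %% 3 + 1
    s <- seq_len(N) + 1
    sqrt(rowSums((nodes3d[[a]][s, , drop = FALSE] -
                  nodes3d[[bnext]][s, , drop = FALSE])^2))
  })
  Rx <- vapply(1:3, function(a) N * params$b - planar[[a]][N + 1, "x"],
               numeric(1))
  structure(list(theta = theta, planar = planar, nodes = nodes3d, li = li,
                 Rx = Rx, bendable = as.logical(bendable), rho = rho),
            class = "pf3_state")
}

#' Total energy of a three-protofilament state
#'
#' @param state A [build_3pf()] state.
#' @param comp A [composition()] applied to every protofilament.
#' @param params A [model_params()] object.
#' @return Energy in kBT.
#' @export
total_energy_3pf <- function(state, comp, params) {
  check_sizes(comp, params)
  theta0 <- preferred_angles(comp, params)
  bend <- sum(vapply(1:3, function(a)
    sum(bending_energy(state$theta[, a], theta0, params)), numeric(1)))
  bend + sum(lateral_energy(as.vector(state$li), params))
}

#' Metropolis sampling of the three-protofilament model
#'
#' Pivot moves within each bendable protofilament's plane; frozen
#' protofilaments stay exactly straight. Lateral energy uses the 3-D
#' inter-protofilament distances with the same plateau rule as the
#' single-protofilament model.
#'
#' @param comp A [composition()] applied to every protofilament.
#' @param params A [model_params()] object (its `ks` is the per-bond spring).
#' @param mc An [mc_config()].
#' @param bendable Logical length-3 mask (at least one TRUE).
#' @param theta_init Optional N x 3 initial angle matrix.
#' @return List with `mean_rx`, `sd_rx` (length 3, NA pattern irrelevant for
#'   frozen PFs whose Rx is 0), per-PF `dist` (list of `rx_distribution`),
#'   `acceptance_rate`, `theta_final`.
#' @export
run_3pf_mc <- function(comp, params, mc, bendable = rep(TRUE, 3),
                       theta_init = NULL) {
  check_sizes(comp, params)
  stopifnot(length(bendable) == 3, any(bendable))
  if (is.null(theta_init)) theta_init <- matrix(0, params$N, 3)
  pref <- matrix(preferred_angles(comp, params), params$N, 3)
  edges <- default_edges(params, mc)
  set.seed(mc$seed)
  raw <- .mc3_run_cpp(theta_init, pref,
                      params$b, params$l0, params$lmax, params$ks, params$kb,
                      1 / params$temperature_factor,
                      mc$n_steps, mc$burn_in, mc$record_every,
                      mc$max_rotation, as.logical(bendable),
                      edges[1], mc$bin_width, length(edges) - 1)
  dists <- lapply(1:3, function(a) {
    cnt <- raw$counts[, a]
    if (sum(cnt) == 0) NULL
    else rx_distribution(edges, cnt / sum(cnt), raw$n_samples)
  })
  list(mean_rx = raw$mean_rx, sd_rx = raw$sd_rx, dist = dists,
       acceptance_rate = raw$acc_rate, theta_final = raw$theta_final,
       bendable = bendable)
}

#' Effective lateral energy per bendable protofilament
#'
#' Accounting for how the three lateral bond capacities are shared among the
#' p bendable protofilaments: with one bendable PF both of its bonds pin it
#' (`2*per_bond`); with two, the three bonds split over two movers
#' (`3*per_bond/2`); with all three, one bond each (`per_bond`).
#'
#' @param p Number of bendable protofilaments (1, 2 or 3).
#' @param per_bond Interaction energy per lateral spring bond, kBT.
#' @return List with `p` and `Eeff_kBT`.
#' @examples
#' effective_lateral_energy(2, 4)  # 6 kBT
#' @export
effective_lateral_energy <- function(p, per_bond) {
  if (!p %in% 1:3) stop("p must be 1, 2 or 3")
  eeff <- if (p == 1) 2 * per_bond else 3 * per_bond / p
  list(p = p, Eeff_kBT = eeff)
}

#' Minimum bending strain that destabilizes the three-protofilament tube
#'
#' Bisection over the per-subunit bending strain `E_mb` (at fixed per-bond
#' lateral energy) for the smallest value at which the mean tip position of
#' the bendable protofilaments reaches `L/2`. `<Rx>` is monotone increasing
#' in `E_mb`, so the threshold is bracketed to `tol` kBT.
#'
#' @param p Number of bendable protofilaments (1, 2 or 3); the others are
#'   held rigid and straight.
#' @param params_base A [model_params()] object; its `ks` sets the per-bond
#'   lateral energy (default 4 kBT per bond at the standard geometry).
#' @param mc An [mc_config()] used for every bisection evaluation (seed
#'   advances per evaluation).
#' @param lower,upper Initial bracket on `E_mb`, kBT.
#' @param tol Bracket half-width at termination, kBT.
#' @return List with `Emb_threshold_kBT`, `bracket`, and the evaluation
#'   `history` data frame.
#' @export
destabilization_threshold <- function(p, params_base, mc, lower = 0.5,
                                      upper = 12, tol = 0.25) {
  stopifnot(p %in% 1:3)
  comp <- composition(rep("D", params_base$N))
  bendable <- c(rep(TRUE, p), rep(FALSE, 3 - p))
  half_L <- params_base$N * params_base$b / 2
  eval_count <- 0L
  hist <- list()
  mean_bendable <- function(emb) {
    eval_count <<- eval_count + 1L
    pars <- params_base
    pars$kb <- emb / (1 - cos(pars$theta_D))
    mci <- mc
    mci$seed <- mc$seed + eval_count
    r <- run_3pf_mc(comp, pars, mci, bendable)
    m <- mean(r$mean_rx[bendable])
    hist[[eval_count]] <<- data.frame(Emb_kBT = emb, mean_Rx_nm = m)
    m
  }
  flo <- mean_bendable(lower)
  fhi <- mean_bendable(upper)
  if (flo >= half_L || fhi < half_L)
    stop(sprintf("bracket [%g, %g] kBT does not straddle <Rx> = L/2 (got %.1f, %.1f nm)",
                 lower, upper, flo, fhi))
  while (upper - lower > 2 * tol) {
    mid <- (lower + upper) / 2
    if (mean_bendable(mid) >= half_L) upper <- mid else lower <- mid
  }
  list(Emb_threshold_kBT = (lower + upper) / 2,
       bracket = c(lower, upper),
       history = do.call(rbind, hist))
}
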