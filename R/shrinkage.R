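#' Langevin integration settings
#'
#' @param dt Time step, s.
#' @param t_total Total simulated time, s.
#' @param seed Integer RNG seed.
#' @param D Diffusion coefficient of the tip, nm^2/s.
#' @param record_every Record every this many steps.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(dt = 1e-7, t_total = 1, seed = 1,
                            D = diffusion_coefficient(), record_every = 1000) {
  stopifnot(dt > 0, t_total > dt, D > 0, record_every >= 1)
  structure(list(dt = dt, t_total = t_total, seed = as.integer(seed),
                 D = D, record_every = as.integer(record_every)),
            class = "langevin_config")
}

#' Subunit dissociation settings
#'
#' Dissociation is a Poisson process with rate `k_off` that is active only
#' while the tip is unzippered beyond `rx_gate` (subunits do not dissociate
#' from the tubular state). The default `k_off = 75/s` makes `b*k_off`
#' bracket the experimental GDP-microtubule shrinkage scale and is an
#' explicit tunable surfaced in every report.
#'
#' @param k_off Dissociation rate per exposed tip, 1/s (>= 0).
#' @param rx_gate No dissociation while Rx <= this, nm (default one subunit).
#' @return An object of class `dissociation_config`.
#' @export
dissociation_config <- function(k_off = 75, rx_gate = 8) {
  stopifnot(k_off >= 0, rx_gate >= 0)
  structure(list(k_off = k_off, rx_gate = rx_gate),
            class = "dissociation_config")
}

landscape_force_table <- function(land, dx = 0.25) {
  grid <- seq(min(land$grid), max(land$grid), by = dx)
  fn <- stats::splinefun(land$grid, land$F, method = "natural")
  list(lo = grid[1], dx = dx, force = -fn(grid, deriv = 1),
       xmin = grid[1], xmax = grid[length(grid)])
}

check_step_size <- function(ft, lcfg, bin = 2) {
  drift <- max(abs(ft$force)) * lcfg$D * lcfg$dt
  if (drift >= bin)
    stop(sprintf(paste0("Langevin drift per step (%.3g nm) exceeds the bin width; ",
                        "reduce dt below %.3g s"),
                 drift, lcfg$dt * bin / drift))
  invisible(TRUE)
}

#' Overdamped Langevin trajectory of the tip on a landscape
#'
#' Euler-Maruyama integration of
#' `dRx = -D F'(Rx) dt + sqrt(2 D dt) xi` (F in kBT) with mirror-reflecting
#' boundaries at both ends of the landscape support. Deterministic per seed.
#'
#' @param land A [landscape()].
#' @param lcfg A [langevin_config()].
#' @param x0 Initial tip position, nm.
#' @return A `shrinkage_trajectory`: data frame `t_s`, `Rx_nm`, `Nd`,
#'   `Lobs_nm` with attributes `mean_rx`, `sd_rx`, `max_rx`.
#' @export
langevin_trajectory <- function(land, lcfg, x0 = min(land$grid)) {
  simulate_shrinkage(land, lcfg, dissociation_config(k_off = 0), l_d = 0,
                     L0 = 1e15, x0 = x0)
}

#' Shrinkage simulation: Langevin unzippering plus stochastic dissociation
#'
#' Between dissociation events the tip diffuses on the landscape; while
#' `Rx > rx_gate` subunits dissociate as a Poisson process with rate `k_off`.
#' Each event removes the terminal subunit: the peeled arc shortens by `b`
#' and the tip is remapped through the zero-temperature peel geometry
#' (`Rx -> Rx0(Lc(Rx) - b)`), implementing the switch to a similar but
#' shorter landscape. The observable microtubule length obeys
#' `Lobs(t) = L0 - Rx(t)*l_d - b*Nd(t)` at every sample; the run ends
#' cleanly if it reaches 0.
#'
#' @param land A [landscape()].
#' @param lcfg A [langevin_config()].
#' @param dcfg A [dissociation_config()].
#' @param l_d Geometric factor relating Rx to observable length loss
#'   (dimensionless, default 1).
#' @param L0 Initial observable length, nm.
#' @param x0 Initial tip position, nm.
#' @param b Subunit length, nm.
#' @param geom Peel geometry for the post-dissociation remap (default from
#'   `b` and the standard GDP curl radius 20 nm, support matching the
#'   landscape).
#' @return A `shrinkage_trajectory` data frame (`t_s`, `Rx_nm`, `Nd`,
#'   `Lobs_nm`) with attributes `mean_rx`, `sd_rx`, `max_rx`, `nd_final`,
#'   `params`.
#' @export
simulate_shrinkage <- function(land, lcfg, dcfg, l_d = 1, L0 = 1000,
                               x0 = min(land$grid), b = 8, geom = NULL) {
  stopifnot(L0 > 0)
  ft <- landscape_force_table(land)
  check_step_size(ft, lcfg)
  remap_from <- numeric(0)
  remap_to <- numeric(0)
  if (dcfg$k_off > 0) {
    if (is.null(geom))
      geom <- geometry_params(rc = 20, L = max(land$grid) + 4 * b)
    lc <- seq(0, geom$L, by = 0.1)
    rx0 <- rx_of_lc(lc, geom)
    # strictly increasing pseudo-inverse of the (weakly monotone) arc relation
    rx0 <- cummax(rx0) + seq_along(rx0) * 1e-9
    rx_short <- rx_of_lc(pmax(lc - b, 0), geom)
    keep <- rx0 <= max(land$grid) + 1
    remap_from <- rx0[keep]
    remap_to <- pmax(rx_short[keep], min(land$grid))
  }
  set.seed(lcfg$seed)
  n_steps <- ceiling(lcfg$t_total / lcfg$dt)
  raw <- .langevin_cpp(ft$lo, ft$dx, ft$force, lcfg$D, lcfg$dt, n_steps,
                       lcfg$record_every, x0, ft$xmin, ft$xmax,
                       dcfg$k_off, dcfg$rx_gate, b,
                       remap_from, remap_to, L0, l_d)
  traj <- raw$trajectory
  structure(traj,
            class = c("shrinkage_trajectory", class(traj)),
            mean_rx = raw$mean_rx, sd_rx = raw$sd_rx, max_rx = raw$max_rx,
            nd_final = raw$nd_final,
            params = list(D = lcfg$D, dt = lcfg$dt, k_off = dcfg$k_off,
                          rx_gate = dcfg$rx_gate, l_d = l_d, b = b,
                          L0 = L0, seed = lcfg$seed))
}

#' Average shrinkage velocity of an ensemble
#'
#' Least-squares slope of the ensemble-averaged observable length over the
#' post-transient window: `v- = -d<Lobs>/dt`, with the standard error across
#' trajectories' individual slopes.
#'
#' @param trajs A `shrinkage_trajectory` or list of them (equal duration).
#' @param transient Fraction of the duration discarded at the start.
#' @return List with `v_minus_nm_s`, `sem_nm_s`, `n`.
#' @export
shrinkage_velocity <- function(trajs, transient = 0.1) {
  if (inherits(trajs, "shrinkage_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  slopes <- vapply(trajs, function(tr) {
    t <- tr$t_s
    keep <- t >= transient * max(t)
    if (sum(keep) < 3) stop("trajectory shorter than the transient window")
    -unname(stats::coef(stats::lm(tr$Lobs_nm[keep] ~ t[keep]))[2])
  }, numeric(1))
  list(v_minus_nm_s = mean(slopes),
       sem_nm_s = if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes)) else NA_real_,
       n = length(slopes))
}

#' Ram's-horn excursion statistics
#'
#' An unzippering event is a maximal contiguous interval with
#' `Rx > threshold`. Excursions or gaps shorter than `debounce` seconds are
#' merged to avoid counting integrator chatter. `Tu` is the mean event
#' lifetime, `Nu` the number of events per second of trajectory.
#'
#' @param traj A `shrinkage_trajectory` (or data frame with `t_s`, `Rx_nm`).
#' @param threshold Excursion threshold, nm (> 0; default 10 nm).
#' @param debounce Minimum event/gap duration, s (default 10 sample
#'   intervals).
#' @return List with `Tu_s` (NA when there are no events), `Nu_per_s`,
#'   `n_events`, `threshold_nm`.
#' @export
horn_statistics <- function(traj, threshold = 10, debounce = NULL) {
  stopifnot(threshold > 0)
  t <- traj$t_s
  up <- traj$Rx_nm > threshold
  dt <- stats::median(diff(t))
  if (is.null(debounce)) debounce <- 10 * dt
  r <- rle(up)
  # merge runs shorter than the debounce into their neighbors (a lone short
  # run at either edge is absorbed too)
  short <- r$lengths * dt < debounce & length(r$lengths) > 1
  r$values[short] <- !r$values[short]
  merged <- rle(inverse.rle(r))
  durations <- merged$lengths[merged$values] * dt
  total <- max(t) - min(t)
  if (length(durations) == 0)
    return(list(Tu_s = NA_real_, Nu_per_s = 0, n_events = 0L,
                threshold_nm = threshold))
  list(Tu_s = mean(durations), Nu_per_s = length(durations) / total,
       n_events = length(durations), threshold_nm = threshold)
}

#' Shrinkage velocity as a function of pulling force
#'
#' Tilts the landscape by each force (`F(Rx, f) = F(Rx, 0) + f*Rx`), reruns
#' the shrinkage ensemble and tabulates the velocity; reports whether the
#' response is monotone decreasing.
#'
#' @param land The untilted [landscape()].
#' @param f_grid Pulling forces, pN (>= 0).
#' @param lcfg A [langevin_config()].
#' @param dcfg A [dissociation_config()].
#' @param n_traj Trajectories per force.
#' @param l_d,L0 Passed to [simulate_shrinkage()].
#' @return Data frame `f_pN`, `v_minus_nm_s`, `sem_nm_s`; attribute
#'   `monotone_decreasing`.
#' @export
force_response <- function(land, f_grid, lcfg, dcfg, n_traj = 8,
                           l_d = 1, L0 = 5000) {
  stopifnot(all(f_grid >= 0))
  rows <- lapply(seq_along(f_grid), function(i) {
    tl <- tilt(land, f_grid[i])
    trajs <- lapply(seq_len(n_traj), function(k) {
      cfg <- lcfg
      cfg$seed <- lcfg$seed + 1000L * i + k
      simulate_shrinkage(tl, cfg, dcfg, l_d = l_d, L0 = L0)
    })
    v <- shrinkage_velocity(trajs)
    data.frame(f_pN = f_grid[i], v_minus_nm_s = v$v_minus_nm_s,
               sem_nm_s = v$sem_nm_s)
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_decreasing") <- !is.unsorted(rev(out$v_minus_nm_s))
  out
}

#' First-passage time of a Langevin walker (simulation cross-check)
#'
#' Simulates independent walkers from `A` (reflecting) until absorption at
#' `B` and returns their passage times; used to validate the mean
#' first-passage-time quadrature.
#'
#' @param land A [landscape()].
#' @param D Diffusion coefficient, nm^2/s.
#' @param A,B Reflecting start and absorbing target, nm.
#' @param n Number of walkers.
#' @param dt Time step, s.
#' @param seed RNG seed.
#' @param t_max Per-walker time cap, s.
#' @return Numeric vector of passage times (NA where capped).
#' @export
langevin_first_passage <- function(land, D, A, B, n = 1000, dt = 1e-7,
                                   seed = 1, t_max = 10) {
  ft <- landscape_force_table(land)
  set.seed(seed)
  vapply(seq_len(n), function(i)
    .langevin_fpt_cpp(ft$lo, ft$dx, ft$force, D, dt, A, ft$xmin, B, t_max),
    numeric(1))
}
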