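#' Monte Carlo sampling configuration
#'
#' @param n_steps Total Metropolis steps.
#' @param max_rotation Pivot proposal half-width, rad (the sampler draws a
#'   uniform increment in `[-max_rotation, +max_rotation]`).
#' @param seed Integer RNG seed.
#' @param record_every Record Rx into the histogram every this many steps.
#' @param burn_in Steps discarded before recording (default 10% of
#'   `n_steps`).
#' @param trace_every Thinning interval of the returned trace (0 = none).
#' @param bin_width Histogram bin width on Rx, nm.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_steps = 1e7, max_rotation = 1.5, seed = 1,
                      record_every = 100, burn_in = floor(n_steps / 10),
                      trace_every = 0, bin_width = 2) {
  stopifnot(n_steps > burn_in, burn_in >= 0, max_rotation > 0,
            record_every >= 1, bin_width > 0)
  structure(list(n_steps = n_steps, max_rotation = max_rotation,
                 seed = as.integer(seed), record_every = as.integer(record_every),
                 burn_in = burn_in, trace_every = as.integer(trace_every),
                 bin_width = bin_width),
            class = "mc_config")
}

#' Binned distribution of the tip coordinate Rx
#'
#' @param bin_edges Bin edges, nm.
#' @param p Probability per bin (sums to 1).
#' @param n_samples Number of recorded samples behind the histogram.
#' @return An object of class `rx_distribution`.
#' @export
rx_distribution <- function(bin_edges, p, n_samples) {
  stopifnot(length(p) == length(bin_edges) - 1, all(p >= -1e-12))
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) stop("empty distribution")
  structure(list(bin_edges = bin_edges, p = p / s,
                 n_samples = n_samples),
            class = "rx_distribution")
}

bin_centers <- function(dist) {
  e <- dist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Mean of an Rx distribution
#' @param dist An `rx_distribution`.
#' @return Mean Rx, nm.
#' @export
mean_rx <- function(dist) sum(bin_centers(dist) * dist$p)

default_edges <- function(params, mc) {
  seq(0, 2 * params$N * params$b, by = mc$bin_width)
}

run_sampler <- function(comp, params, mc, bias_k = 0, bias_center = 0,
                        theta_init = NULL) {
  check_sizes(comp, params)
  if (is.null(theta_init)) theta_init <- rep(0, params$N)
  edges <- default_edges(params, mc)
  set.seed(mc$seed)
  .mc_run_cpp(theta_init, preferred_angles(comp, params),
              params$b, params$l0, params$lmax, params$ks, params$kb,
              1 / params$temperature_factor,
              mc$n_steps, mc$burn_in, mc$record_every, mc$max_rotation,
              bias_k, bias_center,
              edges[1], mc$bin_width, length(edges) - 1,
              mc$trace_every)
}

#' Direct Metropolis sampling of a protofilament
#'
#' Runs the pivot-move Metropolis chain from the straight configuration and
#' returns the post-burn-in Rx histogram, summary statistics and (optionally)
#' a thinned trace. Deterministic for a fixed config.
#'
#' @param comp A [composition()].
#' @param params A [model_params()] object.
#' @param mc An [mc_config()].
#' @param theta_init Optional initial angle vector (default: straight).
#' @return List with `dist` (an `rx_distribution`), `mean_rx`, `sd_rx`,
#'   `acceptance_rate`, `trace` (data frame or NULL), `theta_final`.
#' @examples
#' \donttest{
#' p <- params_from_energies(8, 7, model_params(N = 8))
#' r <- run_chain(composition(rep("D", 8)), p, mc_config(n_steps = 2e5, seed = 1))
#' r$mean_rx
#' }
#' @export
run_chain <- function(comp, params, mc, theta_init = NULL) {
  raw <- run_sampler(comp, params, mc, theta_init = theta_init)
  edges <- default_edges(params, mc)
  counts <- raw$counts1 + raw$counts2
  list(dist = rx_distribution(edges, counts / sum(counts), raw$n_samples),
       counts = counts,
       mean_rx = raw$mean_rx, sd_rx = raw$sd_rx,
       acceptance_rate = raw$acc_rate,
       trace = raw$trace,
       theta_final = raw$theta_final)
}

#' Harmonic umbrella windows on Rx
#'
#' @param centers Window centers, nm.
#' @param k_bias Harmonic bias stiffness, kBT/nm^2 (recycled).
#' @return List of window descriptors.
#' @export
umbrella_windows <- function(centers, k_bias = 0.1) {
  k_bias <- rep_len(k_bias, length(centers))
  Map(function(c, k) list(center = c, k_bias = k), centers, k_bias)
}

#' Umbrella sampling over a set of windows
#'
#' Samples each window with its harmonic bias `k/2*(Rx - center)^2` added to
#' the physical energy; windows share bin edges so they can be recombined by
#' [wham_combine()]. Each window starts from a partially peeled configuration
#' near its center and uses seed `mc$seed + window index`.
#'
#' @param comp A [composition()].
#' @param params A [model_params()] object.
#' @param windows From [umbrella_windows()].
#' @param mc An [mc_config()] (`n_steps` is per window).
#' @return List of sampled windows, each with `center`, `k_bias`, `counts`,
#'   `counts1`/`counts2` (split halves), `n_samples`, `acceptance_rate`, and
#'   shared `bin_edges`. Empty windows are flagged with a warning.
#' @export
umbrella_sample <- function(comp, params, windows, mc) {
  check_sizes(comp, params)
  edges <- default_edges(params, mc)
  geom <- geometry_params(params)
  lc_grid <- seq(0, params$N * params$b, length.out = 512)
  rx0 <- rx_of_lc(lc_grid, geom)
  out <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    # seed the chain near the window center through the zero-T peel geometry
    lc <- lc_grid[which.min(abs(rx0 - win$center))]
    init <- peeled_init(round(lc / params$b), params)
    mcw <- mc
    mcw$seed <- mc$seed + w
    raw <- run_sampler(comp, params, mcw, bias_k = win$k_bias,
                       bias_center = win$center, theta_init = init)
    counts <- raw$counts1 + raw$counts2
    if (sum(counts) == 0)
      warning(sprintf("umbrella window at %g nm collected no samples; re-run with adjusted k_bias",
                      win$center))
    out[[w]] <- list(center = win$center, k_bias = win$k_bias,
                     counts = counts, counts1 = raw$counts1,
                     counts2 = raw$counts2, n_samples = raw$n_samples,
                     acceptance_rate = raw$acc_rate, bin_edges = edges)
  }
  out
}

#' WHAM recombination of umbrella windows
#'
#' Iterative histogram reweighting: solves the self-consistent equations
#' `P_j = sum_k h_kj / sum_k N_k exp(f_k) c_kj`,
#' `exp(-f_k) = sum_j c_kj P_j` with `c_kj = exp(-w_k(x_j))`, until the
#' window free-energy shifts change by less than `tol`.
#'
#' @param windows Sampled windows from [umbrella_sample()] (>= 1, shared bin
#'   edges).
#' @param tol Convergence tolerance on the shifts, kBT.
#' @param max_iter Iteration cap.
#' @return An `rx_distribution` of the unbiased P(Rx); attributes
#'   `wham_iterations` and `wham_converged` carry diagnostics.
#' @export
wham_combine <- function(windows, tol = 1e-8, max_iter = 100000) {
  stopifnot(length(windows) >= 1)
  edges <- windows[[1]]$bin_edges
  for (w in windows)
    if (!isTRUE(all.equal(w$bin_edges, edges)))
      stop("umbrella windows do not share bin edges")
  x <- (edges[-1] + edges[-length(edges)]) / 2
  H <- vapply(windows, function(w) w$counts, numeric(length(x)))
  occupied <- rowSums(H) > 0
  check_window_overlap(windows, occupied, x)
  Nk <- colSums(H)
  C <- vapply(windows, function(w) exp(-0.5 * w$k_bias * (x - w$center)^2),
              numeric(length(x)))
  h <- rowSums(H)
  f <- rep(0, length(windows))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- as.vector(C %*% (Nk * exp(f)))
    P <- ifelse(denom > 0, h / denom, 0)
    P <- P / sum(P)
    fnew <- -log(pmax(as.vector(crossprod(C, P)), 1e-300))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; converged <- TRUE; break }
    f <- fnew
  }
  dist <- rx_distribution(edges, P, sum(Nk))
  attr(dist, "wham_iterations") <- iter
  attr(dist, "wham_converged") <- converged
  dist
}

check_window_overlap <- function(windows, occupied, x) {
  if (length(windows) < 2) return(invisible(TRUE))
  occ <- lapply(windows, function(w) which(w$counts > 0))
  # windows sorted by center; each must share at least one occupied bin with
  # the union of those before it
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  seen <- occ[[ord[1]]]
  for (k in ord[-1]) {
    if (length(intersect(seen, occ[[k]])) == 0)
      stop(sprintf("umbrella windows are disconnected near Rx = %g nm: no histogram overlap",
                   windows[[k]]$center))
    seen <- union(seen, occ[[k]])
  }
  invisible(TRUE)
}

#' Mean tip position as a function of the power-struggle parameter
#'
#' Sweeps `delta_E = E_ms - E_mb` by varying the bending strain `E_mb` at
#' fixed lateral strength `E_ms` and reports the mean and standard deviation
#' of Rx from direct Metropolis sampling at each grid point.
#'
#' @param params_base A [model_params()] object (its [e_ms()] is held fixed).
#' @param deltaE_grid Values of delta_E, kBT.
#' @param comp A [composition()].
#' @param mc An [mc_config()] (seed advances by one per grid point).
#' @return Data frame with columns `deltaE_kBT`, `mean_Rx_nm`, `sd_Rx_nm`,
#'   `acceptance`.
#' @export
transition_curve <- function(params_base, deltaE_grid, comp, mc) {
  Ems <- e_ms(params_base)
  res <- lapply(seq_along(deltaE_grid), function(i) {
    de <- deltaE_grid[i]
    p <- params_from_energies(Ems, Ems - de, params_base)
    mci <- mc
    mci$seed <- mc$seed + i
    r <- run_chain(comp, p, mci)
    data.frame(deltaE_kBT = de, mean_Rx_nm = r$mean_rx, sd_Rx_nm = r$sd_rx,
               acceptance = r$acceptance_rate)
  })
  do.call(rbind, res)
}

#' Umbrella-sampled free-energy landscape, end to end
#'
#' Convenience wrapper: places harmonic windows `spacing` nm apart on
#' `[0, rx_max]`, samples each, recombines with WHAM and converts to a
#' free-energy landscape.
#'
#' @param comp A [composition()].
#' @param params A [model_params()] object.
#' @param mc An [mc_config()] (`n_steps` per window).
#' @param rx_max Upper end of the windowed range, nm (default: slightly past
#'   the fully peeled tip position).
#' @param spacing Window spacing, nm.
#' @param k_bias Window stiffness, kBT/nm^2.
#' @return A [landscape()] object; attribute `windows` keeps the per-window
#'   acceptance rates, attribute `dist` the recombined distribution.
#' @export
sample_landscape <- function(comp, params, mc, rx_max = NULL, spacing = 10,
                             k_bias = 0.1) {
  if (is.null(rx_max)) {
    full <- build_geometry(c(0, rep(params$theta_D, params$N - 1)), params)
    rx_max <- ceiling(full$Rx / spacing + 1) * spacing
  }
  wins <- umbrella_windows(seq(0, rx_max, by = spacing), k_bias)
  sampled <- umbrella_sample(comp, params, wins, mc)
  dist <- wham_combine(sampled)
  land <- free_energy_from_distribution(dist)
  attr(land, "windows") <- data.frame(
    center_nm = vapply(sampled, `[[`, numeric(1), "center"),
    acceptance = vapply(sampled, `[[`, numeric(1), "acceptance_rate"),
    n_samples = vapply(sampled, `[[`, numeric(1), "n_samples"))
  attr(land, "dist") <- dist
  land
}

#' Split-half convergence diagnostic for umbrella runs
#'
#' Recombines the first and second halves of each window's recording period
#' separately and reports the RMS difference of the two free-energy
#' estimates over their common support.
#'
#' @param sampled Output of [umbrella_sample()].
#' @return RMS difference in kBT.
#' @export
split_half_rms <- function(sampled) {
  halves <- lapply(c("counts1", "counts2"), function(fld) {
    ws <- lapply(sampled, function(w) { w$counts <- w[[fld]]; w })
    d <- wham_combine(ws)
    ifelse(d$p > 0, -log(d$p), NA_real_)
  })
  keep <- is.finite(halves[[1]]) & is.finite(halves[[2]])
  d <- halves[[1]][keep] - halves[[2]][keep]
  d <- d - mean(d)
  sqrt(mean(d^2))
}
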