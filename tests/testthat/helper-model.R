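# Shared small parameter sets and oracles for the tests.

# standard tubulin geometry with the lateral/bending strengths used throughout
std_params <- function(N = 32, Ems = 8, Emb = 7, temperature_factor = 1) {
  params_from_energies(Ems, Emb,
                       model_params(N = N, temperature_factor = temperature_factor))
}

all_gdp <- function(N) composition(rep("D", N))

# exact tip x-coordinate of the discrete chain with all bond angles equal
# (closed form of b * sum_{k=1}^N cos(k*theta)); oracle for the arc limit
discrete_arc_xn <- function(N, b, theta) {
  (b / (2 * sin(theta / 2))) * (sin(N * theta + theta / 2) - sin(theta / 2))
}

# Boltzmann quadrature oracle for the 2-subunit chain: the single movable
# angle theta2 has a 2*pi-periodic energy, so marginals follow from direct
# numerical integration over one period.
n2_quadrature <- function(params, comp, n_theta = 20001) {
  th <- seq(-pi, pi, length.out = n_theta)
  pref <- preferred_angles(comp, params)
  e <- vapply(th, function(t2)
    total_energy(build_geometry(c(0, t2), params), comp, params), numeric(1))
  w <- exp(-(e - min(e)) / params$temperature_factor)
  list(theta = th, w = w / sum(w),
       rx = params$b * (1 - cos(th)))
}

# synthetic umbrella windows over a known 1-D potential: multinomial counts
# from the exact biased densities (no chain involved), for WHAM oracles
synthetic_windows <- function(F_fun, centers, k_bias, edges, n_per_window,
                              seed = 1) {
  set.seed(seed)
  x <- (edges[-1] + edges[-length(edges)]) / 2
  lapply(centers, function(c0) {
    logw <- -F_fun(x) - 0.5 * k_bias * (x - c0)^2
    p <- exp(logw - max(logw))
    cnt <- as.numeric(stats::rmultinom(1, n_per_window, p / sum(p)))
    list(center = c0, k_bias = k_bias, counts = cnt, counts1 = cnt / 2,
         counts2 = cnt / 2, n_samples = n_per_window,
         acceptance_rate = NA_real_, bin_edges = edges)
  })
}
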