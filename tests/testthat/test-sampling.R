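test_that("metropolis acceptance follows the Boltzmann factor", {
  p <- std_params(N = 4)
  comp <- all_gdp(4)
  st <- build_geometry(rep(0, 4), p)
  set.seed(42)
  de <- acc <- numeric(20000)
  for (i in seq_along(de)) {        # frozen state: always propose from st
    mv <- metropolis_step(st, comp, p)
    de[i] <- mv$delta_E
    acc[i] <- mv$accepted
  }
  expect_true(all(acc[de <= 0] == 1))            # downhill always accepted
  band <- de > 0.8 & de < 1.2                    # uphill by ~1 kBT
  expect_gt(sum(band), 100)
  phat <- mean(acc[band])
  pexp <- mean(exp(-de[band]))
  se <- sqrt(pexp * (1 - pexp) / sum(band))
  expect_lt(abs(phat - pexp), 4 * se)
})

test_that("the sampler reproduces Boltzmann quadrature on the 2-subunit chain", {
  p <- params_from_energies(2, 1, model_params(N = 2))
  comp <- all_gdp(2)
  r <- run_chain(comp, p, mc_config(n_steps = 4e6, seed = 3, record_every = 20))
  q <- n2_quadrature(p, comp)
  # map the quadrature weights onto the sampler's Rx bins
  edges <- r$dist$bin_edges
  qp <- tapply(q$w, cut(q$rx, edges, include.lowest = TRUE), sum)
  qp[is.na(qp)] <- 0
  qp <- as.numeric(qp / sum(qp))
  keep <- qp > 1e-4
  n <- r$dist$n_samples
  # per-bin agreement within 5 sigma of multinomial error (correlated draws,
  # so allow a generous effective-sample-size reduction)
  n_eff <- n / 20
  sig <- sqrt(qp[keep] * (1 - qp[keep]) / n_eff)
  expect_lt(max(abs(r$dist$p[keep] - qp[keep]) / sig), 5)
  # and the mean tip position agrees closely
  expect_equal(r$mean_rx, sum(q$w * q$rx), tolerance = 0.02)
})

test_that("sampling is deterministic given the seed", {
  p <- std_params(N = 8)
  comp <- all_gdp(8)
  mc <- mc_config(n_steps = 1e5, seed = 11, trace_every = 100)
  r1 <- run_chain(comp, p, mc)
  r2 <- run_chain(comp, p, mc)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$counts, r2$counts)
  r3 <- run_chain(comp, p, mc_config(n_steps = 1e5, seed = 12, trace_every = 100))
  expect_false(identical(r1$trace$Rx_nm, r3$trace$Rx_nm))
})

test_that("bound and peeled regimes show up in the mean tip position", {
  N <- 19
  comp <- all_gdp(N)
  # deep tubular regime: lateral bonds dominate
  p_bound <- std_params(N = N, Ems = 8, Emb = 2)
  r_bound <- run_chain(comp, p_bound, mc_config(n_steps = 2e6, seed = 5))
  expect_lt(r_bound$mean_rx, 5)
  # slightly lateral-dominated is still peeled: entropy tips the balance
  p_peel <- std_params(N = N, Ems = 8, Emb = 7)
  r_peel <- run_chain(comp, p_peel, mc_config(n_steps = 8e6, seed = 5))
  expect_gt(r_peel$mean_rx, N * 8 / 2)
  # move acceptance sits in the expected few-percent band
  expect_gt(r_peel$acceptance_rate, 0.005)
  expect_lt(r_peel$acceptance_rate, 0.3)
})

test_that("a single unbiased umbrella window equals a direct run", {
  p <- std_params(N = 8)
  comp <- all_gdp(8)
  mc <- mc_config(n_steps = 5e5, seed = 2)
  win <- umbrella_sample(comp, p, umbrella_windows(0, k_bias = 0), mc)
  # umbrella seeds advance per window: window 1 uses seed + 1
  direct <- run_chain(comp, p, mc_config(n_steps = 5e5, seed = 3))
  expect_equal(win[[1]]$counts, direct$counts)
  d <- wham_combine(win)
  expect_equal(d$p, direct$dist$p, tolerance = 1e-12)
})

test_that("WHAM recovers synthetic potentials from overlapping windows", {
  edges <- seq(0, 300, 2)
  x <- (edges[-1] + edges[-length(edges)]) / 2

  # flat landscape, two harmonic windows: recovered P uniform within noise
  flat <- synthetic_windows(function(x) 0 * x, c(100, 200), 5e-4, edges,
                            2e5, seed = 4)
  pf <- wham_combine(flat)
  Ff <- -log(pf$p[pf$p > 0])
  expect_lt(diff(range(Ff)), 0.35)

  # double-well: well-depth difference recovered within 0.1 kBT
  F_true <- function(x) 2 * cos(2 * pi * x / 125.66) + 0.004 * x
  dw <- synthetic_windows(F_true, seq(20, 280, 20), 0.02, edges, 2e5, seed = 9)
  pd <- wham_combine(dw)
  Fd <- -log(pd$p)
  i1 <- which.min(abs(x - 62.8)); i2 <- which.min(abs(x - 188.5))
  true_diff <- F_true(x[i2]) - F_true(x[i1])
  expect_equal(Fd[i2] - Fd[i1], true_diff, tolerance = 0.1)
  expect_true(attr(pd, "wham_converged"))

  # disconnected windows are reported as such
  gap <- synthetic_windows(function(x) 0 * x, c(30, 270), 0.5, edges, 1e4)
  expect_error(wham_combine(gap), "disconnected")
})

test_that("umbrella-reweighted means agree with direct sampling where it mixes", {
  N <- 8
  p <- std_params(N = N, Ems = 8, Emb = 7)
  comp <- all_gdp(N)
  direct <- run_chain(comp, p, mc_config(n_steps = 4e6, seed = 21))
  land <- sample_landscape(comp, p, mc_config(n_steps = 1e6, seed = 31),
                           rx_max = 60, spacing = 10, k_bias = 0.1)
  d <- attr(land, "dist")
  m_umb <- mean_rx(d)
  # combined tolerance: direct SEM (correlated samples) plus umbrella noise
  expect_equal(m_umb, direct$mean_rx, tolerance = 0.1 * direct$mean_rx)
})

test_that("the transition curve sweeps deltaE by varying the bending strain", {
  N <- 8
  p <- std_params(N = N)
  comp <- all_gdp(N)
  tc <- transition_curve(p, c(-2, 6), comp, mc_config(n_steps = 1e6, seed = 17))
  expect_equal(names(tc), c("deltaE_kBT", "mean_Rx_nm", "sd_Rx_nm", "acceptance"))
  # deltaE = -2: fully peeled, near the zero-temperature arc position
  g <- geometry_params(p)
  expect_equal(tc$mean_Rx_nm[1], rx_of_lc(N * 8, g), tolerance = 0.25 * N * 8)
  expect_gt(tc$mean_Rx_nm[1], N * 8 / 2)
  # deltaE = +6: deeply tubular
  expect_lt(tc$mean_Rx_nm[2], 5)
})
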