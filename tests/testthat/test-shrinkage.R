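test_that("free diffusion and drift limits of the Langevin integrator", {
  D <- 5e6
  x <- seq(0, 4000, 2)
  flat <- landscape(x, rep(0, length(x)))
  # MSD = 2Dt from an ensemble of short runs started mid-support
  t_run <- 2e-4
  n <- 400
  disp <- vapply(seq_len(n), function(i) {
    tr <- langevin_trajectory(flat, langevin_config(dt = 1e-7, t_total = t_run,
                                                    seed = i, D = D,
                                                    record_every = 2000),
                              x0 = 2000)
    tr$Rx_nm[nrow(tr)] - 2000
  }, numeric(1))
  msd <- mean(disp^2)
  sem <- sd(disp^2) / sqrt(n)
  expect_lt(abs(msd - 2 * D * t_run), 3 * sem)

  # linear F = c*Rx: mean drift velocity -D*c
  cc <- 0.002
  ramp <- landscape(x, cc * x)
  drift <- vapply(seq_len(n), function(i) {
    tr <- langevin_trajectory(ramp, langevin_config(dt = 1e-7, t_total = t_run,
                                                    seed = 1000 + i, D = D,
                                                    record_every = 2000),
                              x0 = 2000)
    (tr$Rx_nm[nrow(tr)] - 2000) / t_run
  }, numeric(1))
  expect_lt(abs(mean(drift) - (-D * cc)), 3 * sd(drift) / sqrt(n))
})

test_that("long Langevin runs recover Boltzmann well occupancies", {
  D <- 5e6
  x <- seq(0, 200, 1)
  dF <- 1.2    # well asymmetry in kBT
  # double well with minima near 50 and 150
  F <- 2 * cos(2 * pi * x / 100) + dF * (x > 100)
  dw <- landscape(x, as.numeric(F))
  tr <- langevin_trajectory(dw, langevin_config(dt = 1e-7, t_total = 0.5,
                                                seed = 9, D = D,
                                                record_every = 50), x0 = 50)
  occ <- mean(tr$Rx_nm > 100)
  ratio_obs <- occ / (1 - occ)
  # expected occupancy ratio from the Boltzmann weights of the two halves
  w <- exp(-dw$F)
  ratio_exp <- sum(w[x > 100]) / sum(w[x <= 100])
  expect_equal(log(ratio_obs), log(ratio_exp), tolerance = 0.35)
})

test_that("Langevin first-passage times agree with the quadrature", {
  D <- diffusion_coefficient()
  x <- seq(0, 260, 1)
  land <- landscape(x, 1.5 * sin(x / 25) + 0.008 * x)
  tau_quad <- mean_first_passage_time(land, D, 0, 200)
  fpt <- langevin_first_passage(land, D, 0, 200, n = 600, dt = 1e-7, seed = 2)
  expect_false(anyNA(fpt))
  sem <- sd(fpt) / sqrt(length(fpt))
  expect_lt(abs(mean(fpt) - tau_quad), 3 * sem)
})

test_that("trajectories are deterministic per seed and conserve length exactly", {
  x <- seq(0, 260, 2)
  land <- landscape(x, 0.01 * x + sin(x / 20))
  lcfg <- langevin_config(dt = 1e-7, t_total = 0.02, seed = 5,
                          D = diffusion_coefficient(), record_every = 200)
  dcfg <- dissociation_config(k_off = 500, rx_gate = 8)
  tr1 <- simulate_shrinkage(land, lcfg, dcfg, l_d = 1, L0 = 4000)
  tr2 <- simulate_shrinkage(land, lcfg, dcfg, l_d = 1, L0 = 4000)
  expect_identical(tr1$Rx_nm, tr2$Rx_nm)
  expect_identical(tr1$Nd, tr2$Nd)
  # conservation: L0 - Lobs(t) = Rx(t)*l_d + b*Nd(t) at every sample
  expect_equal(4000 - tr1$Lobs_nm, tr1$Rx_nm * 1 + 8 * tr1$Nd,
               tolerance = 1e-12)
  expect_true(all(diff(tr1$Nd) >= 0))
  expect_equal(tr1$Lobs_nm[1], 4000 - tr1$Rx_nm[1])
})

test_that("dissociation is gated and fires at the Poisson rate when exposed", {
  x <- seq(0, 260, 2)
  # k_off = 0: no dissociation, pure unzippering
  land <- landscape(x, rep(0, length(x)))
  lcfg <- langevin_config(dt = 1e-7, t_total = 0.05, seed = 3,
                          D = diffusion_coefficient(), record_every = 100)
  tr0 <- simulate_shrinkage(land, lcfg, dissociation_config(k_off = 0),
                            l_d = 1, L0 = 5000)
  expect_true(all(tr0$Nd == 0))
  expect_equal(tr0$Lobs_nm, 5000 - tr0$Rx_nm)

  # an unreachable gate blocks all events
  trg <- simulate_shrinkage(land, lcfg, dissociation_config(k_off = 1e4,
                                                            rx_gate = 500),
                            l_d = 1, L0 = 5000)
  expect_true(all(trg$Nd == 0))

  # always-exposed regime: slope of b*Nd(t) equals b*k_off within 3 SEM
  steep <- landscape(x, -0.2 * x)  # strongly peel-biased: Rx stays high
  k_off <- 2000
  nds <- vapply(1:30, function(i) {
    cfg <- lcfg; cfg$seed <- 100 + i; cfg$t_total <- 0.1
    tr <- simulate_shrinkage(steep, cfg, dissociation_config(k_off, rx_gate = 0),
                             l_d = 0, L0 = 1e9, x0 = 200)
    tr$Nd[nrow(tr)] / tr$t_s[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(mean(nds) - k_off), 3 * sd(nds) / sqrt(length(nds)))
})

test_that("shrinkage velocity is the slope of the observable length", {
  # exactly linear synthetic trajectory
  t <- seq(0, 1, 0.01)
  tr <- structure(data.frame(t_s = t, Rx_nm = 0 * t, Nd = 0 * t,
                             Lobs_nm = 3000 - 42 * t),
                  class = c("shrinkage_trajectory", "data.frame"))
  v <- shrinkage_velocity(list(tr, tr))
  expect_equal(v$v_minus_nm_s, 42, tolerance = 1e-10)
  expect_error(shrinkage_velocity(list(structure(
    data.frame(t_s = 0:1, Rx_nm = 0:1, Nd = c(0, 0), Lobs_nm = c(1, 0)),
    class = c("shrinkage_trajectory", "data.frame")))), "transient")

  # dissociation-only regime: v- = b*k_off
  x <- seq(0, 260, 2)
  steep <- landscape(x, -0.2 * x)
  k_off <- 1500
  trajs <- lapply(1:20, function(i)
    simulate_shrinkage(steep,
                       langevin_config(dt = 1e-7, t_total = 0.1, seed = 200 + i,
                                       D = diffusion_coefficient(),
                                       record_every = 1000),
                       dissociation_config(k_off, rx_gate = 0),
                       l_d = 0, L0 = 1e9, x0 = 200))
  v2 <- shrinkage_velocity(trajs)
  expect_lt(abs(v2$v_minus_nm_s - 8 * k_off), 3 * v2$sem_nm_s)
})

test_that("ram's-horn statistics count threshold excursions", {
  # square wave, period 2 s, half the time above threshold
  t <- seq(0, 10, 0.01)
  rx <- ifelse(t %% 2 < 1, 50, 0)
  traj <- data.frame(t_s = t, Rx_nm = rx)
  h <- horn_statistics(traj, threshold = 10)
  expect_equal(h$Tu_s, 1, tolerance = 0.02)
  expect_equal(h$Nu_per_s, 0.5, tolerance = 0.02)

  # constant below threshold: no events, Tu reported missing (not zero)
  h0 <- horn_statistics(data.frame(t_s = t, Rx_nm = rep(1, length(t))), 10)
  expect_identical(h0$Nu_per_s, 0)
  expect_true(is.na(h0$Tu_s))

  # permanently peeled: one never-ending excursion
  h1 <- horn_statistics(data.frame(t_s = t, Rx_nm = rep(100, length(t))), 10)
  expect_equal(h1$n_events, 1L)
  expect_equal(h1$Tu_s, 10, tolerance = 0.01)
})

test_that("pulling force suppresses the shrinkage velocity", {
  x <- seq(0, 300, 2)
  land <- landscape(x, rep(0, length(x)))
  lcfg <- langevin_config(dt = 1e-7, t_total = 0.02, seed = 8,
                          D = diffusion_coefficient(), record_every = 500)
  dcfg <- dissociation_config(k_off = 300, rx_gate = 8)
  fr <- force_response(land, c(0, 10), lcfg, dcfg, n_traj = 6, L0 = 5000)
  expect_equal(nrow(fr), 2L)
  # f = 0 reproduces the untilted ensemble (same child seeds)
  trajs0 <- lapply(1:6, function(k) {
    cfg <- lcfg; cfg$seed <- lcfg$seed + 1000L + k
    simulate_shrinkage(land, cfg, dcfg, l_d = 1, L0 = 5000)
  })
  v0 <- shrinkage_velocity(trajs0)
  expect_equal(fr$v_minus_nm_s[1], v0$v_minus_nm_s, tolerance = 1e-10)
  # a strong tilt toward the tubular state slows shrinkage
  expect_lt(fr$v_minus_nm_s[2], fr$v_minus_nm_s[1])
})
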