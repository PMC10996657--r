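pc_params <- function() izh_params_of(ca3_example_config("full_scale"),
                                      "Pyramidal")

test_that("membrane equations match their closed forms", {
  p <- pc_params()
  # resting fixed point
  d0 <- izhikevich_derivatives(p$vr, 0, p, 0)
  expect_equal(d0$dv, 0)
  expect_equal(d0$du, 0)
  # at v = vr the quadratic term vanishes: dv/dt = I / C
  d1 <- izhikevich_derivatives(-63.12, 0, p, 100)
  expect_equal(d1$dv, 100 / 102)
  # random states against independently written expressions
  set.seed(4)
  for (r in 1:20) {
    v <- runif(1, -90, 30); u <- runif(1, -50, 300); I <- runif(1, -200, 500)
    d <- izhikevich_derivatives(v, u, p, I)
    expect_equal(d$dv, (p$k * (v - p$vr) * (v - p$vt) - u + I) / p$C)
    expect_equal(d$du, p$a * (p$b * (v - p$vr) - u))
  }
})

test_that("the RK4 step is exact at fixed points and 4th order accurate", {
  p <- pc_params()
  st <- izhikevich_step_rk4(p$vr, 0, p, 0, 0.2)
  expect_equal(st$v, p$vr)
  expect_equal(st$u, 0)
  # parameters reducing the system to dv/dt = -v: one step matches the
  # 4th-degree polynomial expansion of exp(-dt)
  lin <- list(C = 1, k = 1e-9, vr = 0, vt = 1e9, a = 0, b = 0)
  dt <- 0.3
  st <- izhikevich_step_rk4(1, 0, lin, 0, dt)
  expect_equal(st$v, 1 - dt + dt^2 / 2 - dt^3 / 6 + dt^4 / 24,
               tolerance = 1e-7)
  # order ~4 convergence on a smooth subthreshold segment
  integrate_to <- function(dt, t_end = 10, I = 200) {
    v <- p$vr; u <- 0
    for (i in seq_len(round(t_end / dt))) {
      s <- izhikevich_step_rk4(v, u, p, I, dt)
      v <- s$v; u <- s$u
    }
    v
  }
  ref <- integrate_to(0.005)
  e1 <- abs(integrate_to(0.2) - ref)
  e2 <- abs(integrate_to(0.1) - ref)
  expect_lt(e1, 1e-4)
  expect_gt(e1 / e2, 10)  # halving dt shrinks the error ~16x
  expect_lt(e1 / e2, 24)
})

test_that("spike detection resets the state per the cutoff rule", {
  p <- pc_params()
  hit <- detect_spike_and_reset(p$vpeak + 5, 10, p)
  expect_true(hit$spiked)
  expect_equal(hit$v, p$vmin)
  expect_equal(hit$u, 10 + p$d)
  miss <- detect_spike_and_reset(p$vpeak - 0.01, 10, p)
  expect_false(miss$spiked)
  expect_equal(miss$v, p$vpeak - 0.01)
  expect_equal(miss$u, 10)
})

test_that("Tsodyks-Markram event updates and relaxation match closed forms", {
  tm <- list(g = 0.55, tau_d = 7.55, tau_r = 318.51, tau_f = 21.45, U = 0.27)
  # from rest the conductance increment is w * g * U
  st <- tm_deliver(tm_rest_state(), tm, w = 0.625)
  expect_equal(st$g_syn, 0.625 * 0.55 * 0.27)
  expect_equal(st$u, 0.27)
  expect_equal(st$x, 1 - 0.27)
  # U = 1 consumes the whole resource pool in one event
  st1 <- tm_deliver(tm_rest_state(), list(g = 1, U = 1), w = 1)
  expect_equal(st1$x, 0)
  # relaxation identities
  s <- list(u = 0.4, x = 0.3, g_syn = 1)
  expect_equal(tm_relax(s, tm, 0), s)
  inf_ <- tm_relax(s, tm, 1e9)
  expect_equal(inf_$u, 0)
  expect_equal(inf_$x, 1)
  expect_equal(inf_$g_syn, 0)
  expect_equal(tm_relax(s, tm, tm$tau_d)$g_syn, exp(-1))
  # regular 20 Hz train against the independent scalar recursion
  times <- seq(0, 450, by = 50)
  inc_ref <- tm_recursion(times, tm$g, tm$U, tm$tau_f, tm$tau_r)
  st <- tm_rest_state(); t_prev <- NULL
  for (i in seq_along(times)) {
    if (!is.null(t_prev)) st <- tm_relax(st, tm, times[i] - t_prev)
    g0 <- st$g_syn
    st <- tm_deliver(st, tm, w = 1)
    expect_equal(st$g_syn - g0, inc_ref[i], tolerance = 1e-12)
    t_prev <- times[i]
  }
})

test_that("conductances convert to currents through the reversal potentials", {
  expect_equal(synaptic_current(-65, 0, 0), 0)
  expect_equal(synaptic_current(0, 2, 0, E_exc = 0), 0)  # at reversal
  expect_equal(synaptic_current(-65, 2, 0, E_exc = 0), 130)
  expect_equal(synaptic_current(-65, 0, 3, E_inh = -70), 3 * -5)
})

test_that("the simulator reproduces the single-neuron reference integrator", {
  net <- toy_pc_network(n = 1)
  p <- pc_params()
  # same dt: identical trajectory and spike times
  sim <- run_simulation(net, 300, dt = 0.2, record_v = 1,
                        stim = data.frame(neuron = 1, onset_ms = 0,
                                          duration_ms = 300,
                                          amplitude_pA = 700))
  ref <- ref_izhikevich(p, 700, 300, 0.2)
  expect_equal(sim$spikes$time_ms, ref$spikes, tolerance = 1e-9)
  # trajectory agrees except at the spike steps (records clamp to vpeak)
  off_spike <- !(seq_along(ref$v) %in% ref$spike_steps)
  expect_equal(sim$v[off_spike, 1], ref$v[off_spike], tolerance = 1e-8)
  # empty stimulation, no background: no spikes at all
  quiet <- run_simulation(net, 100)
  expect_equal(nrow(quiet$spikes), 0)
  # determinism of repeated runs
  again <- run_simulation(net, 300, dt = 0.2,
                          stim = data.frame(neuron = 1, onset_ms = 0,
                                            duration_ms = 300,
                                            amplitude_pA = 700))
  expect_identical(sim$spikes, again$spikes)
})

test_that("synaptic transmission through the core matches an R-side mirror", {
  cfg <- toy_config(counts = c("Pyramidal" = 2), probability = 1)
  net <- build_network(cfg, n_assemblies = 1, assembly_size = 2, seed = 1)
  expect_equal(nrow(net$synapses), 2)
  tm <- list(g = 0.55, tau_d = 7.55, tau_r = 318.51, tau_f = 21.45, U = 0.27)
  spike_ms <- c(10, 30, 45.4, 100, 101)
  dt <- 0.2
  sim <- run_simulation(net, 150, dt = dt, record_v = 2, plasticity = FALSE,
                        stim = data.frame(neuron = 1, onset_ms = spike_ms,
                                          duration_ms = 0, amplitude_pA = 0,
                                          force = TRUE))
  expect_equal(sim$spikes$neuron, rep(1L, 5))
  expect_equal(sim$spikes$time_ms, spike_ms)
  # TM state of the 1 -> 2 synapse equals the scalar recursion at arrivals
  s12 <- which(net$synapses$pre == 1 & net$synapses$post == 2)
  inc <- tm_recursion(spike_ms + 1, tm$g, tm$U, tm$tau_f, tm$tau_r)
  st <- tm_rest_state()
  for (i in seq_along(spike_ms)) {
    if (i > 1) st <- tm_relax(st, tm, diff(spike_ms)[i - 1])
    st <- tm_deliver(st, tm, w = 0.625)
  }
  expect_equal(sim$state$syn_u[s12], st$u, tolerance = 1e-12)
  expect_equal(sim$state$syn_x[s12], st$x, tolerance = 1e-12)
  # full postsynaptic trajectory against an R-side step-by-step mirror
  p <- pc_params()
  arrival_steps <- round(spike_ms / dt) + round(1 / dt)
  g <- 0; v <- p$vr; u <- 0
  decay <- exp(-dt / tm$tau_d)
  mirror <- numeric(round(150 / dt))
  k <- 1
  for (s in 0:(round(150 / dt) - 1)) {
    g <- g * decay
    if (s %in% arrival_steps) {
      g <- g + 0.625 * inc[k]
      k <- k + 1
    }
    I <- g * (0 - v)
    stp <- izhikevich_step_rk4(v, u, p, I, dt)
    v <- stp$v; u <- stp$u
    mirror[s + 1] <- v
  }
  expect_equal(sim$v[, 1], mirror, tolerance = 1e-9)
})

test_that("coincident firing potentiates both directions equally via STDP", {
  cfg <- toy_config(counts = c("Pyramidal" = 2), probability = 1)
  net <- build_network(cfg, n_assemblies = 1, assembly_size = 2, seed = 1)
  net$plasticity$A <- 0.05
  net$plasticity$w_max <- 1e6  # no clipping
  times <- c(10, 10.6, 30, 52.2)   # both neurons fire together
  stim <- rbind(
    data.frame(neuron = 1, onset_ms = times, duration_ms = 0,
               amplitude_pA = 0, force = TRUE),
    data.frame(neuron = 2, onset_ms = times + c(0, 0.2, 0, -0.2),
               duration_ms = 0, amplitude_pA = 0, force = TRUE))
  sim <- run_simulation(net, 100, stim = stim, plasticity = TRUE)
  dw <- sim$weights - 0.625
  expect_equal(dw[1], dw[2])
  oracle <- brute_stdp(times, times + c(0, 0.2, 0, -0.2), 0.05, tau = 20)
  expect_equal(dw[1], oracle, tolerance = 1e-10)
})

test_that("runs resume from saved state exactly", {
  cfg <- toy_config(counts = c("Pyramidal" = 25, "Basket" = 6),
                    probability = 0.4, anchor = 240)
  net <- build_network(cfg, n_assemblies = 1, assembly_size = 10, seed = 3)
  bg <- sample_network_background(net, seed = 8)
  whole <- run_simulation(net, 400, background = bg, plasticity = TRUE)
  first <- run_simulation(net, 150, background = bg, plasticity = TRUE)
  second <- run_simulation(net, 250, background = bg, plasticity = TRUE,
                           state = first$state, t0_ms = 150)
  expect_identical(rbind(first$spikes, second$spikes), whole$spikes)
  expect_identical(second$weights, whole$weights)
  expect_equal(second$state$v, whole$state$v)
})

test_that("divergent dynamics abort with the neuron identified", {
  net <- toy_pc_network(n = 1)
  expect_error(
    run_simulation(net, 10, stim = data.frame(neuron = 1, onset_ms = 0,
                                              duration_ms = 10,
                                              amplitude_pA = 1e308)),
    "non-finite dynamics")
})
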