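#' Izhikevich membrane equations
#'
#' Right-hand side of the two-variable quadratic integrate-and-fire model:
#' `dv/dt = (k (v - vr)(v - vt) - u + I) / C` and
#' `du/dt = a (b (v - vr) - u)`.
#'
#' @param v membrane potential (mV).
#' @param u recovery variable.
#' @param params list (or one-row data frame) with `C, k, vr, vt, a, b`.
#' @param I total input current (pA).
#' @return list with `dv` and `du` (per ms).
#' @export
izhikevich_derivatives <- function(v, u, params, I) {
  list(dv = (params$k * (v - params$vr) * (v - params$vt) - u + I) / params$C,
       du = params$a * (params$b * (v - params$vr) - u))
}

#' One classical 4th-order Runge-Kutta step of the Izhikevich system
#'
#' The input current is held constant across the step. Vectorized over
#' neurons when `v`, `u`, `I` (and the parameter fields) are vectors.
#'
#' @inheritParams izhikevich_derivatives
#' @param dt step size (ms).
#' @return list with updated `v`, `u` (no spike handling; see
#'   [detect_spike_and_reset()]).
#' @export
izhikevich_step_rk4 <- function(v, u, params, I, dt) {
  f <- function(v, u) izhikevich_derivatives(v, u, params, I)
  k1 <- f(v, u)
  k2 <- f(v + dt / 2 * k1$dv, u + dt / 2 * k1$du)
  k3 <- f(v + dt / 2 * k2$dv, u + dt / 2 * k2$du)
  k4 <- f(v + dt * k3$dv, u + dt * k3$du)
  list(v = v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv),
       u = u + dt / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du))
}

#' Spike detection and reset
#'
#' After integration, any neuron whose potential reached the cutoff `vpeak`
#' is marked as spiking, its potential reset to `vmin` and its recovery
#' variable incremented by `d`.
#'
#' @param v,u post-integration state (vectors allowed).
#' @param params list with `vpeak`, `vmin`, `d`.
#' @return list with `v`, `u`, logical `spiked`.
#' @export
detect_spike_and_reset <- function(v, u, params) {
  spiked <- v >= params$vpeak
  list(v = ifelse(spiked, params$vmin, v),
       u = ifelse(spiked, u + params$d, u),
       spiked = spiked)
}

#' Tsodyks-Markram event update at a spike arrival
#'
#' At each presynaptic spike arrival the utilization jumps toward 1, a
#' fraction of the available resources is consumed, and the synaptic
#' conductance increments by `w * g * u+ * x`:
#' `u+ = u + U (1 - u)`, `g <- g_syn + w g u+ x`, `x <- x - u+ x`, `u <- u+`.
#'
#' @param state list with `u`, `x`, `g_syn` (use `tm_rest_state()` for rest).
#' @param tm list with `g` (nS) and `U`.
#' @param w synaptic weight multiplier.
#' @return updated state list.
#' @export
tm_deliver <- function(state, tm, w = 1) {
  u_plus <- state$u + tm$U * (1 - state$u)
  list(u = u_plus,
       x = state$x - u_plus * state$x,
       g_syn = state$g_syn + w * tm$g * u_plus * state$x)
}

#' Exact exponential relaxation of Tsodyks-Markram state between events
#'
#' Conductance decays to 0 with `tau_d`, resources recover to 1 with
#' `tau_r`, utilization decays to 0 with `tau_f`.
#'
#' @param state list with `u`, `x`, `g_syn`.
#' @param tm list with `tau_d`, `tau_r`, `tau_f` (ms).
#' @param dt_ms elapsed time (>= 0).
#' @return relaxed state list.
#' @export
tm_relax <- function(state, tm, dt_ms) {
  stopifnot(dt_ms >= 0)
  list(u = state$u * exp(-dt_ms / tm$tau_f),
       x = 1 - (1 - state$x) * exp(-dt_ms / tm$tau_r),
       g_syn = state$g_syn * exp(-dt_ms / tm$tau_d))
}

#' @rdname tm_deliver
#' @export
tm_rest_state <- function() list(u = 0, x = 1, g_syn = 0)

#' Conductance-to-current closure
#'
#' `I = sum_class g_class (E_class - v)`, with one excitatory and one
#' inhibitory receptor class.
#'
#' @param v_post postsynaptic potential (mV).
#' @param g_exc,g_inh summed conductances (nS).
#' @param E_exc,E_inh reversal potentials (mV).
#' @return synaptic current (pA).
#' @export
synaptic_current <- function(v_post, g_exc, g_inh = 0, E_exc = 0,
                             E_inh = -70) {
  g_exc * (E_exc - v_post) + g_inh * (E_inh - v_post)
}

#' Run a clock-driven simulation of a network instance
#'
#' Integrates every neuron with fixed-step RK4 (default dt = 0.2 ms),
#' delivers spikes through Tsodyks-Markram synapses after the uniform 1 ms
#' conduction delay, and (optionally) applies the symmetric STDP rule to the
#' plastic synapses online. The run is fully deterministic given its inputs:
#' all randomness (background currents, stimulus construction) is sampled
#' before the call.
#'
#' @param network a `ca3_network` from [build_network()].
#' @param duration_ms simulated time in ms.
#' @param dt integration step in ms (default 0.2).
#' @param stim optional stimulus table: data frame with columns `neuron`,
#'   `onset_ms`, `duration_ms`, `amplitude_pA` and optional logical `force`;
#'   `force = TRUE` rows make the neuron spike at onset regardless of its
#'   state (hard forcing, used in unit tests), other rows inject a constant
#'   current pulse over `[onset, onset + duration)`.
#' @param presentation_windows optional data frame with `onset_ms`,
#'   `offset_ms`: inside these windows neurons use their presentation
#'   background current (distinct draw for types with a presentation
#'   override; identical otherwise).
#' @param background `NULL` for no background current, a numeric vector of
#'   per-neuron currents, or `list(base =, presentation =, redraw_ms =)`
#'   where `base`/`presentation` are per-neuron vectors (constant currents)
#'   or `n x K` matrices of `K` successive draws applied every `redraw_ms`
#'   (see [sample_network_background()]). The redraw clock runs on absolute
#'   simulation time, so resumed segments stay consistent.
#' @param plasticity logical; apply STDP to plastic synapses.
#' @param weights optional plastic/full weight vector overriding the
#'   network's current weights (length `nrow(network$synapses)`).
#' @param state opaque state from a previous call, to continue a run
#'   exactly where it stopped (checkpoint/resume); overrides `weights`.
#' @param record_v optional integer vector of neuron ids whose membrane
#'   potential is recorded each step (clamped to `vpeak` on spike steps).
#' @param t0_ms absolute start time; must equal the previous segment's end
#'   when resuming from `state`.
#' @return list of class `ca3_sim`: `spikes` (data frame `neuron`,
#'   `time_ms`), `weights`, `state`, `v` (matrix or NULL), `t0_ms`,
#'   `t1_ms`, `dt`.
#' @export
run_simulation <- function(network, duration_ms, dt = 0.2, stim = NULL,
                           presentation_windows = NULL, background = NULL,
                           plasticity = FALSE, weights = NULL, state = NULL,
                           record_v = NULL, t0_ms = 0) {
  stopifnot(inherits(network, "ca3_network"), duration_ms >= 0, dt > 0)
  cfg <- network$config
  neurons <- network$neurons
  syn <- network$synapses
  n <- nrow(neurons)
  cm <- connection_matrices(cfg)
  exc <- vapply(cfg$neuron_types, function(t) isTRUE(t$excitatory), TRUE)

  delay_steps <- max(1L, round_half_up(cfg$delay_ms / dt))
  if (!is.null(state)) {
    step_begin <- state$next_step
    if (abs(step_begin * dt - t0_ms) > dt / 2 && t0_ms != 0)
      stop("t0_ms does not match the resumed state's clock")
  } else {
    step_begin <- as.integer(round(t0_ms / dt))
  }
  n_steps <- as.integer(round(duration_ms / dt))
  step_end <- step_begin + n_steps

  # background currents: n x K matrices of draws plus a redraw interval
  as_bg_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  }
  redraw_ms <- Inf
  if (is.null(background)) {
    I_base <- I_pres <- matrix(0, n, 1)
  } else if (is.numeric(background)) {
    I_base <- I_pres <- as_bg_matrix(background)
  } else {
    I_base <- as_bg_matrix(background$base)
    I_pres <- as_bg_matrix(background$presentation %||% background$base)
    redraw_ms <- background$redraw_ms %||% Inf
  }
  stopifnot(nrow(I_base) == n, nrow(I_pres) == n,
            ncol(I_base) == ncol(I_pres))
  bg_interval_steps <- if (is.finite(redraw_ms))
    max(1L, round_half_up(redraw_ms / dt)) else .Machine$integer.max

  # stimulus tables -> step-indexed delta events / forced spikes
  stim_delta <- matrix(numeric(0), 0, 3)
  forced <- matrix(numeric(0), 0, 2)
  if (!is.null(stim) && nrow(stim)) {
    if (is.null(stim$force)) stim$force <- FALSE
    s0 <- round_half_up(stim$onset_ms / dt)
    hard <- which(stim$force)
    soft <- which(!stim$force)
    if (length(hard))
      forced <- cbind(s0[hard], stim$neuron[hard] - 1L)
    if (length(soft)) {
      s1 <- round_half_up((stim$onset_ms[soft] + stim$duration_ms[soft]) / dt)
      stim_delta <- rbind(
        cbind(s0[soft], stim$neuron[soft] - 1L, stim$amplitude_pA[soft]),
        cbind(s1, stim$neuron[soft] - 1L, -stim$amplitude_pA[soft]))
    }
    if (nrow(forced)) forced <- forced[order(forced[, 1]), , drop = FALSE]
    if (nrow(stim_delta))
      stim_delta <- stim_delta[order(stim_delta[, 1]), , drop = FALSE]
  }
  pres_delta <- matrix(numeric(0), 0, 2)
  if (!is.null(presentation_windows) && nrow(presentation_windows)) {
    pw <- presentation_windows
    pres_delta <- rbind(cbind(round_half_up(pw$onset_ms / dt), 1),
                        cbind(round_half_up(pw$offset_ms / dt), -1))
    pres_delta <- pres_delta[order(pres_delta[, 1]), , drop = FALSE]
  }

  w0 <- if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(syn))
    as.numeric(weights)
  } else if (!is.null(state)) {
    state$weights  # resumed runs continue from the segment's weights
  } else syn$weight

  rec_idx <- if (is.null(record_v)) integer(0) else as.integer(record_v - 1L)

  res <- sim_core(
    neurons$C, neurons$k, neurons$vr, neurons$vt, neurons$a, neurons$b,
    neurons$d, neurons$vpeak, neurons$vmin,
    as.integer(neurons$type_id - 1L), exc,
    as.integer(syn$pre - 1L), as.integer(syn$post - 1L),
    w0, syn$plastic,
    cm$g, cm$tau_d, cm$tau_r, cm$tau_f, cm$U,
    I_base, I_pres, bg_interval_steps,
    stim_delta, forced, pres_delta,
    step_begin, step_end, dt, delay_steps,
    isTRUE(plasticity), network$plasticity$A, network$plasticity$tau_ms,
    0, network$plasticity$w_max,
    cfg$reversal_mV$excitatory, cfg$reversal_mV$inhibitory,
    state, rec_idx)

  spikes <- data.frame(neuron = res$spike_neuron + 1L,
                       time_ms = res$spike_step * dt)
  v <- if (length(rec_idx)) {
    colnames(res$v_rec) <- as.character(record_v)
    res$v_rec
  } else NULL
  structure(list(spikes = spikes, weights = res$weights, state = res$state,
                 v = v, t0_ms = step_begin * dt, t1_ms = step_end * dt,
                 dt = dt),
            class = "ca3_sim")
}

#' @export
print.ca3_sim <- function(x, ...) {
  cat(sprintf("simulation segment [%g, %g) ms, dt = %g ms: %d spikes\n",
              x$t0_ms, x$t1_ms, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Write a spike raster as tab-separated text
#'
#' Events as `neuron_id  type_name  time_ms` with a commented manifest
#' header (duration, dt, config hash).
#'
#' @param sim a `ca3_sim` result.
#' @param network the network it came from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_raster <- function(sim, network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ca3assembly spike raster",
               sprintf("# t0_ms: %g", sim$t0_ms),
               sprintf("# t1_ms: %g", sim$t1_ms),
               sprintf("# dt_ms: %g", sim$dt),
               sprintf("# config_hash: %s", config_hash(network$config)),
               "neuron_id\ttype_name\ttime_ms"), con)
  df <- data.frame(neuron_id = sim$spikes$neuron,
                   type_name = network$neurons$type[sim$spikes$neuron],
                   time_ms = sim$spikes$time_ms)
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
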