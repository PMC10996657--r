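# Shared fixtures: small configurations built in code, and independent
# oracles (fine-step reference integrator, brute-force STDP sum, scalar
# Tsodyks-Markram recursion) used to cross-check the simulator.

# a reduced configuration with explicit counts/probabilities, reusing the
# shipped per-type physiology tables
toy_config <- function(counts = c("Pyramidal" = 20, "Basket" = 5),
                       probability = 0.5, anchor = 6000,
                       pairs = NULL) {
  base <- ca3_example_config("full_scale")
  keep <- vapply(base$neuron_types, `[[`, "", "name") %in% names(counts)
  cfg <- unclass(base)
  cfg$name <- "toy"
  cfg$neuron_types <- cfg$neuron_types[keep]
  cfg$neuron_types <- lapply(cfg$neuron_types, function(ty) {
    ty$count <- as.integer(counts[[ty$name]])
    ty
  })
  cfg$connections <- Filter(function(cn)
    cn$pre %in% names(counts) && cn$post %in% names(counts), cfg$connections)
  cfg$connections <- lapply(cfg$connections, function(cn) {
    key <- paste(cn$pre, cn$post, sep = "->")
    cn$probability <- if (!is.null(pairs)) {
      if (key %in% names(pairs)) pairs[[key]] else 0
    } else probability
    cn
  })
  cfg$plasticity$weight_anchor <- anchor
  ca3assembly:::as_ca3_config(cfg)
}

# a network of n unconnected (or fully connected) pyramidal cells
toy_pc_network <- function(n = 2, probability = 0, assembly_size = n,
                           anchor = 6000, seed = 1) {
  cfg <- toy_config(counts = c("Pyramidal" = n), probability = probability,
                    anchor = anchor)
  build_network(cfg, n_assemblies = 1, assembly_size = assembly_size,
                seed = seed)
}

izh_params_of <- function(config, type) {
  for (ty in config$neuron_types) if (ty$name == type) return(ty$izh)
  stop("no such type")
}

# independent fine-step reference: RK4 integration of one Izhikevich neuron
# under a constant current, with threshold/reset handling, written as a
# plain scalar loop
ref_izhikevich <- function(p, I, duration_ms, dt) {
  n <- round(duration_ms / dt)
  v <- p$vr; u <- 0
  vs <- numeric(n); spike_steps <- integer(0)
  f <- function(v, u) c((p$k * (v - p$vr) * (v - p$vt) - u + I) / p$C,
                        p$a * (p$b * (v - p$vr) - u))
  for (s in seq_len(n)) {
    k1 <- f(v, u)
    k2 <- f(v + dt / 2 * k1[1], u + dt / 2 * k1[2])
    k3 <- f(v + dt / 2 * k2[1], u + dt / 2 * k2[2])
    k4 <- f(v + dt * k3[1], u + dt * k3[2])
    v <- v + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    u <- u + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    if (v >= p$vpeak) {
      spike_steps <- c(spike_steps, s)
      v <- p$vmin
      u <- u + p$d
    }
    vs[s] <- v
  }
  # spikes timestamped at the start of the step in which the cutoff was
  # crossed, matching the simulator's convention
  list(v = vs, t = seq_len(n) * dt, spikes = (spike_steps - 1) * dt,
       spike_steps = spike_steps)
}

# brute-force all-pairs STDP sum (coincident pairs counted once)
brute_stdp <- function(pre_times, post_times, A, tau = 20) {
  if (!length(pre_times) || !length(post_times)) return(0)
  sum(A * exp(-abs(outer(post_times, pre_times, "-")) / tau))
}

# independent scalar Tsodyks-Markram recursion across a spike train:
# closed-form inter-spike relaxation followed by the event update, tracking
# the conductance increment of each event
tm_recursion <- function(spike_times, g, U, tau_f, tau_r) {
  u <- 0; x <- 1; t_prev <- NULL
  inc <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    if (!is.null(t_prev)) {
      el <- spike_times[i] - t_prev
      u <- u * exp(-el / tau_f)
      x <- 1 - (1 - x) * exp(-el / tau_r)
    }
    up <- u + U * (1 - u)
    inc[i] <- g * up * x
    x <- x - up * x
    u <- up
    t_prev <- spike_times[i]
  }
  inc
}

# assembly membership matrix helpers for brute-force metric recomputation
brute_group_means <- function(weights, synapses, members_list) {
  plast <- which(synapses$plastic)
  within <- rep(FALSE, length(plast))
  for (mem in members_list)
    within <- within | (synapses$pre[plast] %in% mem &
                        synapses$post[plast] %in% mem)
  list(signal = mean(weights[plast][within]),
       noise = mean(weights[plast][!within]))
}

# a network holding one neuron of the requested type (plus one pyramidal
# cell when needed to satisfy the assembly machinery), fully unconnected
single_type_network <- function(type) {
  counts <- setNames(1L, type)
  if (type != "Pyramidal") counts <- c(counts, "Pyramidal" = 1L)
  cfg <- toy_config(counts = counts, probability = 0)
  build_network(cfg, n_assemblies = 1, assembly_size = 1, seed = 1)
}

type_count_of <- function(config, name) {
  for (ty in config$neuron_types) if (ty$name == name) return(ty$count)
  stop("no such type")
}
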