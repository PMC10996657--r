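#' Generate a frozen gamma-window spike pattern for an assembly
#'
#' Each assembly member receives exactly `n_spikes` offsets drawn uniformly
#' in `[0, window_ms)` and snapped to the integration grid. The pattern is
#' generated once and reused identically at every presentation.
#'
#' @param members integer vector of member neuron ids.
#' @param assembly_id identifier carried into schedules and reports.
#' @param n_spikes spikes per member per presentation (default 4).
#' @param window_ms gamma window length in ms (default 20).
#' @param dt grid step for snapping (default 0.2 ms).
#' @param seed integer seed.
#' @return object of class `ca3_pattern`: `assembly_id`, `members`,
#'   `offsets_ms` (list parallel to `members`), `window_ms`.
#' @export
generate_pattern <- function(members, assembly_id = 1L, n_spikes = 4,
                             window_ms = 20, dt = 0.2, seed = 1L) {
  stopifnot(length(members) >= 1, n_spikes >= 0)
  set.seed(as.integer(seed))
  offsets <- lapply(seq_along(members), function(i) {
    if (n_spikes == 0) return(numeric(0))
    sort(floor(runif(n_spikes) * window_ms / dt) * dt)
  })
  structure(list(assembly_id = as.integer(assembly_id),
                 members = as.integer(members),
                 offsets_ms = offsets, window_ms = window_ms,
                 n_spikes = n_spikes, seed = as.integer(seed)),
            class = "ca3_pattern")
}

#' Build the theta-nested-gamma training schedule
#'
#' Patterns are presented round-robin, one per 200 ms theta cycle, each
#' occupying the first `gamma_ms` of its cycle, after an initial settling
#' period with background activity only.
#'
#' @param patterns list of `ca3_pattern` objects.
#' @param n_presentations presentations per pattern.
#' @param theta_ms theta cycle length (default 200).
#' @param gamma_ms gamma window length (default 20).
#' @param settle_ms settling prefix before the first presentation
#'   (default 1000).
#' @return object of class `ca3_schedule` with `entries` (data frame:
#'   `onset_ms`, `kind`, `assembly_id`, `item`, `presentation`), `items`
#'   (the pattern/cue list), `theta_ms`, `gamma_ms`, `duration_ms`.
#' @export
build_training_schedule <- function(patterns, n_presentations, theta_ms = 200,
                                    gamma_ms = 20, settle_ms = 1000) {
  stopifnot(length(patterns) >= 1, n_presentations >= 0)
  P <- length(patterns)
  n_cycles <- P * n_presentations
  cyc <- seq_len(n_cycles) - 1L
  entries <- data.frame(
    onset_ms = settle_ms + cyc * theta_ms,
    kind = rep("pattern", n_cycles),
    assembly_id = vapply(patterns, `[[`, 1L, "assembly_id")[(cyc %% P) + 1L],
    item = (cyc %% P) + 1L,
    presentation = (cyc %/% P) + 1L)
  structure(list(entries = entries, items = patterns, theta_ms = theta_ms,
                 gamma_ms = gamma_ms, settle_ms = settle_ms,
                 n_presentations = n_presentations,
                 duration_ms = settle_ms + n_cycles * theta_ms,
                 phase = "train"),
            class = "ca3_schedule")
}

#' Degrade a pattern into a test cue
#'
#' Selects `round_half_up((1 - degradation_pct/100) * size)` members of the
#' pattern. Without overlap awareness, members are sampled uniformly; with
#' `overlap_aware = TRUE`, members shared with other assemblies and unique
#' members are sampled in the same proportion as they occur in the assembly
#' (equal-proportion rule).
#'
#' @param pattern a `ca3_pattern`.
#' @param degradation_pct percentage of members withheld, in [0, 100).
#' @param overlap_aware logical; requires `assemblies`.
#' @param assemblies the `ca3_assemblies` object the pattern was built from.
#' @param seed integer seed for member selection.
#' @return object of class `ca3_cue`: the selected `members` with their
#'   `offsets_ms`, plus `assembly_id`, `degradation_pct`, and the
#'   shared/unique split when overlap-aware.
#' @export
degrade_pattern <- function(pattern, degradation_pct, overlap_aware = FALSE,
                            assemblies = NULL, seed = 1L) {
  stopifnot(inherits(pattern, "ca3_pattern"))
  if (degradation_pct < 0 || degradation_pct >= 100)
    stop("degradation_pct must be in [0, 100)")
  size <- length(pattern$members)
  m <- round_half_up((1 - degradation_pct / 100) * size)
  if (m == 0) stop("degenerate cue: no members left at ", degradation_pct,
                   "% degradation")
  set.seed(as.integer(seed))
  n_shared_sel <- NA_integer_
  if (overlap_aware) {
    if (is.null(assemblies))
      stop("overlap-aware degradation needs the assemblies object")
    shared_all <- unique(unlist(assemblies$shared[
      grepl(paste0("(^|-)", pattern$assembly_id, "(-|$)"),
            names(assemblies$shared))]))
    shared <- intersect(pattern$members, shared_all)
    unique_m <- setdiff(pattern$members, shared)
    n_shared_sel <- round_half_up(m * length(shared) / size)
    sel <- c(sample_ids(shared, n_shared_sel),
             sample_ids(unique_m, m - n_shared_sel))
  } else {
    sel <- sample_ids(pattern$members, m)
  }
  keep <- match(sel, pattern$members)
  structure(list(assembly_id = pattern$assembly_id,
                 members = pattern$members[keep],
                 offsets_ms = pattern$offsets_ms[keep],
                 window_ms = pattern$window_ms,
                 degradation_pct = degradation_pct,
                 n_shared_selected = n_shared_sel,
                 source_size = size, seed = as.integer(seed)),
            class = "ca3_cue")
}

# sample() without the length-1 surprise
sample_ids <- function(x, n) {
  if (n == 0) return(integer(0))
  x[sample.int(length(x), n)]
}

#' Build the degraded-cue testing schedule
#'
#' In `simultaneous` mode all cues are presented at the same onset (default
#' 500 ms into a 1 s run); in `sequential` mode one cue per theta cycle.
#' The readout window recorded for each cue is the first gamma window after
#' the cue offset, where retrieval is expected during the second half of the
#' theta cycle.
#'
#' @param cues list of `ca3_cue` objects.
#' @param onset_ms onset of the (first) cue presentation.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param duration_ms test phase duration (default 1000).
#' @param theta_ms,gamma_ms cycle lengths.
#' @return a `ca3_schedule` whose `entries` carry a `readout_t0`/`readout_t1`
#'   pair per cue.
#' @export
build_testing_schedule <- function(cues, onset_ms = 500,
                                   mode = c("simultaneous", "sequential"),
                                   duration_ms = 1000, theta_ms = 200,
                                   gamma_ms = 20) {
  mode <- match.arg(mode)
  n <- length(cues)
  onsets <- if (n == 0) numeric(0)
    else if (mode == "simultaneous") rep(onset_ms, n)
    else onset_ms + (seq_len(n) - 1L) * theta_ms
  if (length(onsets) && max(onsets) + 2 * gamma_ms > duration_ms)
    stop("cue onsets do not fit in the test duration")
  if (mode == "simultaneous" && n > 1) {
    all_members <- unlist(lapply(cues, `[[`, "members"))
    if (anyDuplicated(all_members))
      stop("schedule conflict: neuron cued by two simultaneous cues; ",
           "use sequential mode for overlapping cue sets")
  }
  entries <- data.frame(
    onset_ms = onsets,
    kind = rep("cue", n),
    assembly_id = vapply(cues, `[[`, 1L, "assembly_id"),
    item = seq_len(n),
    presentation = rep(1L, n),
    readout_t0 = onsets + gamma_ms,
    readout_t1 = onsets + 2 * gamma_ms)
  structure(list(entries = entries, items = cues, theta_ms = theta_ms,
                 gamma_ms = gamma_ms, settle_ms = onset_ms,
                 duration_ms = duration_ms, phase = "test"),
            class = "ca3_schedule")
}

#' @export
print.ca3_schedule <- function(x, ...) {
  cat(sprintf("%s schedule: %d entries over %g ms (theta %g ms, gamma %g ms)\n",
              x$phase, nrow(x$entries), x$duration_ms, x$theta_ms, x$gamma_ms))
  invisible(x)
}

#' Sample lognormal background currents for one neuron type
#'
#' Currents are lognormal with `(mu, sigma2)` interpreted as the location
#' and variance parameters of the underlying normal distribution of
#' `ln(I)`. Types with a presentation override (pyramidal cells) use the
#' override parameters when `presentation_window = TRUE`. One draw per
#' neuron per phase; currents are constant between redraws.
#'
#' @param type_spec one element of `config$neuron_types`.
#' @param n number of draws (>= 1).
#' @param presentation_window logical; use the presentation override if the
#'   type has one.
#' @param seed integer seed.
#' @return numeric vector of currents (pA), strictly positive.
#' @export
sample_background_currents <- function(type_spec, n, presentation_window = FALSE,
                                       seed = 1L) {
  stopifnot(n >= 1)
  bg <- type_spec$background
  mu <- bg$mu; s2 <- bg$sigma2
  if (presentation_window && !is.null(bg$sigma2_presentation)) {
    mu <- bg$mu_presentation %||% bg$mu
    s2 <- bg$sigma2_presentation
  }
  if (s2 < 0) stop("configuration error: sigma2 < 0")
  set.seed(as.integer(seed))
  exp(rnorm(n, mean = mu, sd = sqrt(s2)))
}

#' Sample one phase's background currents for a whole network
#'
#' With the default `redraw_ms = Inf`, one draw per neuron for the whole
#' phase (constant current). With a finite `redraw_ms`, each neuron receives
#' an independent draw for every successive `redraw_ms` interval of the
#' phase, emulating slowly fluctuating upstream drive; the constant-current
#' mode leaves the heavy tail of the lognormal pinned at the same neurons
#' for the entire phase, which under plasticity lets tonically coactive
#' pairs saturate their weights, so the stimulation protocols default to
#' redrawing (see [run_training()]).
#'
#' @param network a `ca3_network`.
#' @param seed integer seed.
#' @param duration_ms phase duration; required when `redraw_ms` is finite.
#' @param redraw_ms redraw interval in ms (default `Inf`: one draw/phase).
#' @return `list(base =, presentation =, redraw_ms =)`; `base` and
#'   `presentation` are per-neuron vectors (constant mode) or `n x K`
#'   matrices (redraw mode). The presentation entries differ from the base
#'   entries only for types with a presentation override.
#' @export
sample_network_background <- function(network, seed = 1L, duration_ms = NULL,
                                      redraw_ms = Inf) {
  neurons <- network$neurons
  K <- if (is.finite(redraw_ms)) {
    stopifnot(!is.null(duration_ms), redraw_ms > 0)
    max(1L, as.integer(ceiling(duration_ms / redraw_ms)))
  } else 1L
  base <- matrix(0, nrow(neurons), K)
  pres <- matrix(0, nrow(neurons), K)
  for (ti in seq_along(network$config$neuron_types)) {
    ty <- network$config$neuron_types[[ti]]
    idx <- which(neurons$type_id == ti)
    if (!length(idx)) next
    base[idx, ] <- sample_background_currents(
      ty, length(idx) * K, FALSE,
      seed = derive_seed(seed, paste0("bg_", ty$name)))
    pres[idx, ] <- if (is.null(ty$background$sigma2_presentation))
      base[idx, ] else sample_background_currents(
        ty, length(idx) * K, TRUE,
        seed = derive_seed(seed, paste0("bgpres_", ty$name)))
  }
  if (K == 1L) {
    base <- base[, 1]
    pres <- pres[, 1]
  }
  list(base = base, presentation = pres, redraw_ms = redraw_ms)
}

# expand schedule entries into the simulator's stimulus table
schedule_stimulus <- function(schedule, amplitude_pA = 5000, pulse_ms = 2,
                              force = FALSE) {
  ent <- schedule$entries
  rows <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    it <- schedule$items[[ent$item[i]]]
    n_sp <- lengths(it$offsets_ms)
    rows[[i]] <- data.frame(
      neuron = rep(it$members, n_sp),
      onset_ms = ent$onset_ms[i] + unlist(it$offsets_ms),
      duration_ms = pulse_ms,
      amplitude_pA = amplitude_pA,
      force = force)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(neuron = integer(0), onset_ms = numeric(0),
                                      duration_ms = numeric(0),
                                      amplitude_pA = numeric(0),
                                      force = logical(0))
  out
}

presentation_windows_of <- function(schedule) {
  data.frame(onset_ms = schedule$entries$onset_ms,
             offset_ms = schedule$entries$onset_ms + schedule$gamma_ms)
}

#' Train a network on a schedule, checkpointing the plastic weights
#'
#' Simulates the training schedule with plasticity enabled. Pattern spikes
#' are induced by brief suprathreshold current pulses (default 2 ms,
#' 5000 pA, calibrated to elicit one spike per pulse at pyramidal
#' parameters) at each member's frozen spike times; `force_spikes = TRUE`
#' replaces the pulses by hard spike forcing (unit-test mode). The plastic
#' weight vector is snapshotted after every `checkpoint_every` presentations
#' per pattern.
#'
#' @param network a `ca3_network`.
#' @param schedule a training `ca3_schedule`.
#' @param checkpoint_every checkpoint interval in presentations per pattern
#'   (default 5).
#' @param seed master seed for the phase's background currents.
#' @param dt integration step (ms).
#' @param stim_amplitude_pA,pulse_ms cue-pulse parameters.
#' @param force_spikes use hard forcing instead of current pulses.
#' @param background optional precomputed background (see
#'   [run_simulation()]); sampled from `seed` when `NULL`.
#' @param bg_redraw_ms background redraw interval used when sampling
#'   (default 100 ms; `Inf` for one constant draw per phase).
#' @return object of class `ca3_training`: `initial` and `checkpoints`
#'   (lists of `ca3_checkpoint`), `spikes` (full training raster),
#'   `final_state`, `background`, `schedule`, `dt`.
#' @export
run_training <- function(network, schedule, checkpoint_every = 5, seed = 1L,
                         dt = 0.2, stim_amplitude_pA = 5000, pulse_ms = 2,
                         force_spikes = FALSE, background = NULL,
                         bg_redraw_ms = 100) {
  stopifnot(inherits(network, "ca3_network"), inherits(schedule, "ca3_schedule"))
  if (is.null(background))
    background <- sample_network_background(
      network, seed = derive_seed(seed, "train_bg"),
      duration_ms = schedule$duration_ms, redraw_ms = bg_redraw_ms)
  stim <- schedule_stimulus(schedule, stim_amplitude_pA, pulse_ms,
                            force = force_spikes)
  pres_win <- presentation_windows_of(schedule)
  hash <- config_hash(network$config)
  mk_ckpt <- function(presentations, weights) {
    structure(list(presentations = as.integer(presentations), weights = weights,
                   config_hash = hash, checkpoint_every = checkpoint_every),
              class = "ca3_checkpoint")
  }
  initial <- mk_ckpt(0L, network$synapses$weight)
  P <- length(schedule$items)
  n_pres <- schedule$n_presentations
  bnds <- if (n_pres >= checkpoint_every)
    seq(checkpoint_every, n_pres, by = checkpoint_every) else integer(0)
  boundaries <- unique(c(bnds, n_pres))
  if (n_pres == 0) {
    warning("no presentations: empty checkpoint list")
    return(structure(list(initial = initial, checkpoints = list(),
                          spikes = data.frame(neuron = integer(0),
                                              time_ms = numeric(0)),
                          final_state = NULL, background = background,
                          schedule = schedule, dt = dt),
                     class = "ca3_training"))
  }
  seg_ends_ms <- schedule$settle_ms + boundaries * P * schedule$theta_ms
  state <- NULL
  t0 <- 0
  checkpoints <- vector("list", length(boundaries))
  spike_parts <- vector("list", length(boundaries))
  weights <- network$synapses$weight
  for (si in seq_along(seg_ends_ms)) {
    t1 <- seg_ends_ms[si]
    in_seg <- stim$onset_ms >= t0 & stim$onset_ms < t1
    in_win <- pres_win$onset_ms >= t0 & pres_win$onset_ms < t1
    sim <- run_simulation(network, duration_ms = t1 - t0, dt = dt,
                          stim = stim[in_seg, , drop = FALSE],
                          presentation_windows = pres_win[in_win, , drop = FALSE],
                          background = background, plasticity = TRUE,
                          weights = if (is.null(state)) weights else NULL,
                          state = state, t0_ms = t0)
    state <- sim$state
    weights <- sim$weights
    checkpoints[[si]] <- mk_ckpt(boundaries[si], weights)
    spike_parts[[si]] <- sim$spikes
    t0 <- t1
  }
  structure(list(initial = initial, checkpoints = checkpoints,
                 spikes = do.call(rbind, spike_parts), final_state = state,
                 background = background, schedule = schedule, dt = dt),
            class = "ca3_training")
}

#' @export
print.ca3_training <- function(x, ...) {
  cat(sprintf("training run: %d checkpoints (every %d presentations), %d spikes\n",
              length(x$checkpoints),
              if (length(x$checkpoints)) x$checkpoints[[1]]$checkpoint_every else NA,
              nrow(x$spikes)))
  invisible(x)
}

#' Test pattern completion from a training checkpoint
#'
#' Loads a checkpoint's plastic weights, applies divisive downscaling so the
#' mean plastic weight returns to `w_init` exactly, freezes plasticity, and
#' runs the degraded-cue testing schedule.
#'
#' @param network the `ca3_network` the checkpoint came from.
#' @param checkpoint a `ca3_checkpoint`.
#' @param cues list of `ca3_cue` objects (see [degrade_pattern()]).
#' @param duration_ms test duration (default 1000).
#' @param onset_ms cue onset (default 500).
#' @param mode cue placement, `"simultaneous"` (default) or `"sequential"`.
#' @param seed seed for the test phase's background currents.
#' @inheritParams run_training
#' @return list of class `ca3_test`: `sim` (the `ca3_sim`), `readout`
#'   (data frame `assembly_id`, `t0`, `t1`), `cues`, `weights`
#'   (downscaled), `downscale_factor`.
#' @export
run_test_from_checkpoint <- function(network, checkpoint, cues,
                                     duration_ms = 1000, onset_ms = 500,
                                     mode = "simultaneous", seed = 1L,
                                     dt = 0.2, stim_amplitude_pA = 5000,
                                     pulse_ms = 2, force_spikes = FALSE,
                                     background = NULL, bg_redraw_ms = 100) {
  stopifnot(inherits(checkpoint, "ca3_checkpoint"))
  if (!identical(checkpoint$config_hash, config_hash(network$config)))
    stop("checkpoint error: configuration hash mismatch")
  w <- checkpoint$weights
  plast <- network$synapses$plastic
  scaled <- downscale_weights(w[plast], w_init = network$plasticity$w_init)
  w[plast] <- scaled
  schedule <- build_testing_schedule(cues, onset_ms = onset_ms, mode = mode,
                                     duration_ms = duration_ms)
  if (is.null(background))
    background <- sample_network_background(
      network, seed = derive_seed(seed, "test_bg"),
      duration_ms = duration_ms, redraw_ms = bg_redraw_ms)
  stim <- schedule_stimulus(schedule, stim_amplitude_pA, pulse_ms,
                            force = force_spikes)
  sim <- run_simulation(network, duration_ms = duration_ms, dt = dt,
                        stim = stim,
                        presentation_windows = presentation_windows_of(schedule),
                        background = background, plasticity = FALSE,
                        weights = w)
  readout <- data.frame(assembly_id = schedule$entries$assembly_id,
                        t0 = schedule$entries$readout_t0,
                        t1 = schedule$entries$readout_t1)
  structure(list(sim = sim, readout = readout, cues = cues, weights = w,
                 downscale_factor = attr(scaled, "factor"),
                 schedule = schedule),
            class = "ca3_test")
}
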