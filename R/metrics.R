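#' Binary (or count) activity vector over a time window
#'
#' @param spikes a spike data frame (`neuron`, `time_ms`) or a `ca3_sim`.
#' @param window numeric `c(t0, t1)`; spikes with `t0 <= t < t1` count.
#' @param neuron_set integer vector of neuron ids defining the vector's
#'   support (typically all pyramidal cells).
#' @param mode `"binary"` (default; spiked at least once) or `"count"`.
#' @return named numeric vector over `neuron_set`.
#' @export
activity_vector <- function(spikes, window, neuron_set,
                            mode = c("binary", "count")) {
  mode <- match.arg(mode)
  if (inherits(spikes, "ca3_sim")) spikes <- spikes$spikes
  stopifnot(length(window) == 2, window[2] > window[1])
  if (!length(neuron_set)) stop("empty neuron set")
  sel <- spikes$time_ms >= window[1] & spikes$time_ms < window[2]
  counts <- table(factor(spikes$neuron[sel], levels = neuron_set))
  out <- as.numeric(counts)
  if (mode == "binary") out <- as.numeric(out > 0)
  names(out) <- as.character(neuron_set)
  out
}

#' Pattern reconstruction accuracy from Pearson correlations
#'
#' With `PCC_in = cor(train_in, test_in)` and
#' `PCC_out = cor(train_out, test_out)`, the accuracy is
#' `100 * (PCC_out - PCC_in) / (1 - PCC_in)`: 0 when the output resembles
#' the training pattern no more than the degraded cue already did, 100 when
#' the test output correlates perfectly with the training output, negative
#' when retrieval is worse than the cue.
#'
#' @param train_in,test_in,train_out,test_out activity vectors over the same
#'   neuron set (commanded inputs for `*_in`, observed outputs for `*_out`).
#' @return accuracy in percent (may be negative; at most 100).
#' @export
reconstruction_accuracy <- function(train_in, test_in, train_out, test_out) {
  n <- length(train_in)
  if (any(lengths(list(test_in, train_out, test_out)) != n))
    stop("all four activity vectors must have the same length")
  if (sd(train_in) == 0 || sd(test_in) == 0 || sd(train_out) == 0 ||
      sd(test_out) == 0)
    stop("correlation undefined: constant activity vector")
  pcc_in <- cor(train_in, test_in)
  pcc_out <- cor(train_out, test_out)
  if (pcc_in >= 1 - 1e-12)
    stop("undefined denominator: input correlation is 1 (undegraded cue)")
  100 * (pcc_out - pcc_in) / (1 - pcc_in)
}

# rows of the plastic synapse table whose pre AND post are in the same assembly
within_assembly_rows <- function(synapses, assemblies) {
  plast <- which(synapses$plastic)
  pre <- synapses$pre[plast]
  post <- synapses$post[plast]
  within <- logical(length(plast))
  for (mem in assemblies$members) {
    within <- within | (pre %in% mem & post %in% mem)
  }
  list(plastic_rows = plast, within = within)
}

#' Auto-association signal-to-noise ratio of the plastic weights
#'
#' Signal is the mean weight over plastic synapses whose pre- and
#' post-synaptic neurons belong to the same assembly; noise is the mean over
#' all other plastic synapses. The normalized percentage compares the ratio
#' against the ceiling reached if all within-assembly synapses sat at the
#' (downscaled) maximum weight and all others at the (downscaled) minimum;
#' with the default minimum of 0 that ceiling is infinite and the normalized
#' value is 0 unless the observed noise is itself 0 (reported as 100, the
#' infinite-SNR flag). Supply `w_min_norm > 0` for a finite ceiling.
#'
#' @param weights weight vector aligned with `synapses` rows.
#' @param synapses the network's synapse table.
#' @param assemblies a `ca3_assemblies`.
#' @param w_max maximum plastic weight (for the ceiling).
#' @param w_min_norm minimum weight used for the ceiling (default 0).
#' @return list: `ratio`, `normalized_pct`, `signal`, `noise`,
#'   `n_within`, `n_other`.
#' @export
autoassociation_snr <- function(weights, synapses, assemblies, w_max = NULL,
                                w_min_norm = 0) {
  wa <- within_assembly_rows(synapses, assemblies)
  if (!any(wa$within) || all(wa$within))
    stop("need at least one within-assembly and one other plastic synapse")
  w <- weights[wa$plastic_rows]
  signal <- mean(w[wa$within])
  noise <- mean(w[!wa$within])
  if (noise == 0) {
    return(list(ratio = Inf, normalized_pct = 100, signal = signal,
                noise = 0, n_within = sum(wa$within),
                n_other = sum(!wa$within)))
  }
  ratio <- signal / noise
  normalized <- if (is.null(w_max)) NA_real_ else {
    # the hypothetical saturated network is downscaled by the same divisive
    # rule, which cancels in the ratio
    ceiling_ <- if (w_min_norm > 0) w_max / w_min_norm else Inf
    if (is.finite(ceiling_)) 100 * ratio / ceiling_ else 0
  }
  list(ratio = ratio, normalized_pct = normalized, signal = signal,
       noise = noise, n_within = sum(wa$within), n_other = sum(!wa$within))
}

#' Fraction of within-assembly synapses at the maximum weight
#'
#' Computed on pre-downscaling weights: the percentage of within-assembly
#' plastic synapses with `w >= w_max - eps`.
#'
#' @inheritParams autoassociation_snr
#' @param w_max the plastic weight cap.
#' @param eps saturation tolerance (default `1e-6 * w_max`).
#' @return percentage in [0, 100].
#' @export
fraction_at_max <- function(weights, synapses, assemblies, w_max,
                            eps = 1e-6 * w_max) {
  stopifnot(eps >= 0)
  wa <- within_assembly_rows(synapses, assemblies)
  if (!any(wa$within)) stop("no within-assembly synapses")
  w <- weights[wa$plastic_rows][wa$within]
  100 * sum(w >= w_max - eps) / length(w)
}

#' Per-type firing rate summary
#'
#' Per-neuron rate = spike count / duration, optionally excluding stimulus
#' windows (both the spikes inside them and their total duration),
#' aggregated as mean and standard deviation by neuron type.
#'
#' @param spikes spike data frame or `ca3_sim`.
#' @param neurons the network's neuron table.
#' @param duration_ms total observed duration.
#' @param exclude_windows optional data frame `onset_ms`, `offset_ms`.
#' @return data frame: `type`, `n`, `rate_mean_hz`, `rate_sd_hz`.
#' @export
firing_rate_summary <- function(spikes, neurons, duration_ms,
                                exclude_windows = NULL) {
  stopifnot(duration_ms > 0)
  if (inherits(spikes, "ca3_sim")) spikes <- spikes$spikes
  eff_ms <- duration_ms
  if (!is.null(exclude_windows) && nrow(exclude_windows)) {
    keep <- rep(TRUE, nrow(spikes))
    for (i in seq_len(nrow(exclude_windows))) {
      keep <- keep & !(spikes$time_ms >= exclude_windows$onset_ms[i] &
                       spikes$time_ms < exclude_windows$offset_ms[i])
    }
    spikes <- spikes[keep, , drop = FALSE]
    eff_ms <- duration_ms - sum(exclude_windows$offset_ms -
                                exclude_windows$onset_ms)
    stopifnot(eff_ms > 0)
  }
  counts <- tabulate(spikes$neuron, nbins = nrow(neurons))
  rate <- counts / (eff_ms / 1000)
  types <- unique(neurons$type)
  out <- do.call(rbind, lapply(types, function(ty) {
    r <- rate[neurons$type == ty]
    data.frame(type = ty, n = length(r), rate_mean_hz = mean(r),
               rate_sd_hz = sd(r))
  }))
  rownames(out) <- NULL
  out
}

#' Most effective learning point of an accuracy curve
#'
#' Returns the abscissa with the largest discrete second difference of the
#' accuracy-versus-presentations curve (the point of steepest acceleration
#' of learning). Ties are broken toward fewer presentations; a curve with no
#' strict interior maximum (e.g. linear) returns the first interior point
#' with attribute `tie = TRUE`.
#'
#' @param presentations uniformly spaced abscissae (>= 4 values).
#' @param accuracy accuracy values (same length).
#' @return the selected presentations value, with attribute `tie`.
#' @export
learning_curve_inflection <- function(presentations, accuracy) {
  n <- length(presentations)
  if (n < 4 || length(accuracy) != n)
    stop("insufficient data: need >= 4 uniformly spaced checkpoints")
  gaps <- diff(presentations)
  if (any(abs(gaps - gaps[1]) > 1e-8 * abs(gaps[1])))
    stop("checkpoints must be uniformly spaced")
  d2 <- accuracy[3:n] - 2 * accuracy[2:(n - 1)] + accuracy[1:(n - 2)]
  best <- which.max(d2)  # first index wins ties
  tie <- sum(abs(d2 - d2[best]) < 1e-12) > 1
  structure(presentations[best + 1L], tie = tie)
}

#' Willshaw associative-memory capacity
#'
#' `P = c / gamma^2` for connection probability `c` and coding sparseness
#' `gamma` (assembly size / population size).
#'
#' @param c connection probability in (0, 1].
#' @param gamma sparseness ratio in (0, 1].
#' @return estimated number of storable patterns.
#' @export
willshaw_capacity <- function(c, gamma) {
  stopifnot(c > 0, c <= 1, gamma > 0, gamma <= 1)
  c / gamma^2
}

#' Treves-Rolls recurrent-collateral capacity (interpretation documented)
#'
#' Implemented as `P = k * C_RC / (gamma * log(1 / gamma))`, reading the
#' published expression as the number of recurrent-collateral inputs per
#' cell divided by `gamma ln(1/gamma)` and scaled by `k`. The placement of
#' `k` and the logarithm in the source expression is typographically
#' ambiguous; this function carries no validation weight and exists for
#' exploratory comparison only.
#'
#' @param c_rc recurrent-collateral connections per cell.
#' @param gamma sparseness ratio in (0, 1).
#' @param k information scaling factor (0.2-0.3 in the classical accounts).
#' @return estimated number of storable patterns.
#' @export
treves_rolls_capacity <- function(c_rc, gamma, k = 0.2) {
  stopifnot(gamma > 0, gamma < 1, c_rc > 0)
  k * c_rc / (gamma * log(1 / gamma))
}

#' Per-assembly pattern-completion report for a test run
#'
#' Builds the four activity vectors over all pyramidal cells — commanded
#' training input (all assembly members), commanded test input (the cue),
#' observed training output (spiking during the final training presentation
#' of the pattern), observed test output (spiking in the readout window) —
#' and computes [reconstruction_accuracy()] per assembly.
#'
#' @param network the `ca3_network`.
#' @param training a `ca3_training` result.
#' @param test a `ca3_test` result from the same network.
#' @param mode activity vectorization mode (default `"binary"`).
#' @return data frame: `assembly_id`, `pcc_in`, `pcc_out`, `accuracy_pct`;
#'   attribute `mean_accuracy`.
#' @export
pattern_completion_report <- function(network, training, test,
                                      mode = "binary") {
  pcs <- network$pc_ids
  sched <- training$schedule
  rows <- lapply(seq_len(nrow(test$readout)), function(i) {
    aid <- test$readout$assembly_id[i]
    cue <- test$cues[[i]]
    pat <- sched$items[[which(vapply(sched$items, `[[`, 1L,
                                     "assembly_id") == aid)]]
    ent <- sched$entries[sched$entries$assembly_id == aid, ]
    final_onset <- max(ent$onset_ms)
    train_in <- as.numeric(pcs %in% pat$members)
    test_in <- as.numeric(pcs %in% cue$members)
    train_out <- activity_vector(training$spikes,
                                 c(final_onset, final_onset + sched$gamma_ms),
                                 pcs, mode = mode)
    test_out <- activity_vector(test$sim$spikes,
                                c(test$readout$t0[i], test$readout$t1[i]),
                                pcs, mode = mode)
    pcc_in <- cor(train_in, test_in)
    pcc_out <- cor(train_out, test_out)
    data.frame(assembly_id = aid, pcc_in = pcc_in, pcc_out = pcc_out,
               accuracy_pct = reconstruction_accuracy(train_in, test_in,
                                                      train_out, test_out))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_accuracy") <- mean(out$accuracy_pct)
  out
}
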