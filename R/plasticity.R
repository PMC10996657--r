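#' Symmetric STDP kernel
#'
#' The weight change contributed by one pre/post spike pair at temporal
#' offset `dt_ms` (post minus pre): `A * exp(-|dt| / tau)`. The kernel is
#' strictly positive, symmetric in the spike order, and decreasing in |dt|.
#'
#' @param dt_ms spike-time difference(s) in ms.
#' @param A peak amplitude (weight units), from
#'   [derive_plasticity_constants()].
#' @param tau_ms decay time constant in ms (default 20).
#' @return weight change(s), same length as `dt_ms`.
#' @export
stdp_kernel <- function(dt_ms, A, tau_ms = 20) {
  stopifnot(tau_ms > 0, A >= 0)
  A * exp(-abs(dt_ms) / tau_ms)
}

#' Total STDP weight change for a pair of spike trains (online trace scheme)
#'
#' Computes the all-pairs sum `sum_ij A exp(-|t_post_j - t_pre_i| / tau)`
#' with the online exponential-trace algorithm the simulator uses: each side
#' keeps a trace that decays with `tau` and increments by 1 at its own
#' spikes; each spike credits `A` times the opposite trace. Exactly
#' coincident spikes are credited once per pair (at whichever side is
#' processed second), matching the simulator's grid tie-break.
#'
#' @param pre_times,post_times spike times in ms (any order; sorted
#'   internally).
#' @param A,tau_ms kernel parameters.
#' @return total weight change (unclipped).
#' @export
stdp_train_pair <- function(pre_times, post_times, A, tau_ms = 20) {
  ev <- data.frame(
    t = c(sort(pre_times), sort(post_times)),
    side = c(rep(1L, length(pre_times)), rep(2L, length(post_times))))
  if (nrow(ev) == 0) return(0)
  # within a time tie, order is irrelevant for the total: each coincident
  # pair is credited exactly once by whichever event runs second
  ev <- ev[order(ev$t), , drop = FALSE]
  trace <- c(0, 0)
  t_last <- c(-Inf, -Inf)
  dw <- 0
  for (i in seq_len(nrow(ev))) {
    s <- ev$side[i]; o <- 3L - s; t <- ev$t[i]
    if (is.finite(t_last[o])) {
      trace[o] <- trace[o] * exp(-(t - t_last[o]) / tau_ms)
      t_last[o] <- t
    }
    dw <- dw + A * trace[o]
    if (is.finite(t_last[s])) {
      trace[s] <- trace[s] * exp(-(t - t_last[s]) / tau_ms)
    }
    trace[s] <- trace[s] + 1
    t_last[s] <- t
  }
  dw
}

#' Clip a weight to the plasticity bounds
#'
#' @param w weight(s).
#' @param w_min,w_max bounds (defaults 0 and Inf).
#' @return clipped weight(s).
#' @export
clip_weight <- function(w, w_min = 0, w_max = Inf) {
  pmin(pmax(w, w_min), w_max)
}

#' Divisive synaptic downscaling
#'
#' Divides every plastic weight by the single factor `mean(w) / w_init`, so
#' the post-downscaling mean equals `w_init` exactly while all weight ratios
#' (hence the shape of the weight distribution and the auto-association
#' structure) are preserved. Applied once between training and testing,
#' emulating homeostatic renormalization during slow-wave sleep.
#'
#' @param w numeric vector of plastic weights, mean(w) > 0.
#' @param w_init target mean (default 0.625).
#' @return rescaled weights, with the scalar factor in attribute `factor`.
#' @export
downscale_weights <- function(w, w_init = 0.625) {
  m <- mean(w)
  if (!is.finite(m) || m <= 0)
    stop("degenerate weight state: mean weight must be positive")
  f <- m / w_init
  structure(w / f, factor = f)
}
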