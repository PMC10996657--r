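#' Load a network configuration from a YAML file
#'
#' A configuration declares the eight neuron types (population count,
#' Izhikevich parameters, lognormal background-current law), the 51
#' directional connection types (Bernoulli wiring probability, unitary
#' Tsodyks-Markram parameters, plasticity flag), the uniform conduction
#' delay, reversal potentials, and the plasticity constants' anchors.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `ca3_config` object.
#' @seealso [ca3_example_config()] for the shipped configurations,
#'   [scale_network()] for size reduction.
#' @export
load_network_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_ca3_config(cfg)
}

#' Shipped example configurations
#'
#' Two configurations ship with the package. `"full_scale"` matches the
#' published circuit totals (84,053 neurons across 8 types, ~176 million
#' expected synapses over 51 connection types); population counts other than
#' the Axo-axonic count and all connection probabilities are synthetic
#' estimates calibrated to those totals, as the per-type values are published
#' only in graphical form. `"desk_scale"` applies [scale_network()] with
#' factor 0.04 (~3,000 pyramidal cells), preserving expected in-degrees.
#'
#' @param name `"full_scale"` or `"desk_scale"`.
#' @return a `ca3_config` object.
#' @export
ca3_example_config <- function(name = c("desk_scale", "full_scale")) {
  name <- match.arg(name)
  fn <- paste0(name, "_synthetic.yaml")
  load_network_config(system.file("extdata", fn, package = "ca3assembly",
                                  mustWork = TRUE))
}

as_ca3_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$neuron_types), !is.null(cfg$connections))
  cfg$delay_ms <- as.numeric(cfg$delay_ms %||% 1)
  cfg$reversal_mV <- cfg$reversal_mV %||% list(excitatory = 0, inhibitory = -70)
  cfg$plasticity <- cfg$plasticity %||%
    list(w_init = 0.625, weight_anchor = 6000, tau_stdp_ms = 20)
  cfg$scale <- cfg$scale %||% 1
  cfg$neuron_types <- lapply(cfg$neuron_types, function(ty) {
    ty$count <- as.integer(round(ty$count))
    ty
  })
  class(cfg) <- "ca3_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  names_ <- vapply(cfg$neuron_types, `[[`, "", "name")
  if (anyDuplicated(names_))
    stop("configuration error: duplicated neuron type names")
  for (ty in cfg$neuron_types) {
    if (is.null(ty$count) || ty$count < 1)
      stop("configuration error: non-positive count for type '", ty$name, "'")
    p <- ty$izh
    req <- c("C", "k", "vr", "vt", "a", "b", "d", "vpeak", "vmin")
    miss <- setdiff(req, names(p))
    if (length(miss))
      stop("configuration error: type '", ty$name,
           "' missing Izhikevich parameter(s): ", paste(miss, collapse = ", "))
    if (p$C <= 0) stop("configuration error: C <= 0 for '", ty$name, "'")
    if (!(p$vr < p$vt && p$vt < p$vpeak))
      stop("configuration error: need vr < vt < vpeak for '", ty$name, "'")
    if (!(p$vmin < p$vpeak))
      stop("configuration error: need vmin < vpeak for '", ty$name, "'")
    if (is.null(ty$background) || ty$background$sigma2 < 0)
      stop("configuration error: invalid background spec for '", ty$name, "'")
  }
  keys <- vapply(cfg$connections, function(cn) paste(cn$pre, cn$post, sep = "->"), "")
  if (anyDuplicated(keys))
    stop("configuration error: duplicated connection spec: ",
         keys[duplicated(keys)][1])
  for (cn in cfg$connections) {
    if (!cn$pre %in% names_ || !cn$post %in% names_)
      stop("configuration error: connection references unknown type: ",
           cn$pre, "->", cn$post)
    if (cn$probability < 0 || cn$probability > 1)
      stop("configuration error: probability outside [0,1] for ",
           cn$pre, "->", cn$post)
    if (any(c(cn$tau_d, cn$tau_r, cn$tau_f) <= 0) || cn$g <= 0 ||
        cn$U <= 0 || cn$U >= 1)
      stop("configuration error: invalid Tsodyks-Markram parameters for ",
           cn$pre, "->", cn$post)
  }
  invisible(cfg)
}

#' @export
print.ca3_config <- function(x, ...) {
  counts <- vapply(x$neuron_types, `[[`, 0L, "count")
  cat("CA3 network configuration:", x$name %||% "<unnamed>", "\n")
  cat("  neuron types:", length(x$neuron_types),
      " total neurons:", format(sum(counts), big.mark = ","), "\n")
  cat("  connection types:", length(x$connections),
      " scale:", x$scale, "\n")
  invisible(x)
}

#' Rescale a network configuration
#'
#' Multiplies population counts by `factor` (rounded half up, minimum 1) and
#' divides connection probabilities by `factor` (capped at 1), so the
#' expected in-degree per connection type is preserved. A warning is issued
#' for every probability that caps; capped pairs no longer preserve their
#' expected in-degree.
#'
#' The plasticity weight anchor (assembly size times maximum weight) is
#' multiplied by `factor` as well: the maximum recurrent drive an assembly
#' member can receive scales as (within-assembly in-degree) x w_max, and the
#' in-degree per assembly member grows by 1/factor under probability
#' rescaling, so the anchor must shrink by `factor` to keep the potentiated
#' network in the same dynamical regime as at full scale.
#'
#' @param config a `ca3_config`.
#' @param factor scale factor in (0, 1].
#' @return a rescaled `ca3_config`.
#' @export
scale_network <- function(config, factor) {
  stopifnot(inherits(config, "ca3_config"))
  if (!(factor > 0 && factor <= 1)) stop("factor must be in (0, 1]")
  if (factor == 1) return(config)
  out <- config
  out$scale <- config$scale * factor
  out$neuron_types <- lapply(config$neuron_types, function(ty) {
    ty$count <- max(1L, round_half_up(ty$count * factor))
    ty
  })
  capped <- character(0)
  out$connections <- lapply(config$connections, function(cn) {
    p <- cn$probability / factor
    if (p > 1) {
      capped <<- c(capped, paste(cn$pre, cn$post, sep = "->"))
      p <- 1
    }
    cn$probability <- p
    cn
  })
  if (length(capped))
    warning("connection probabilities capped at 1 for: ",
            paste(capped, collapse = ", "))
  out$plasticity$weight_anchor <- config$plasticity$weight_anchor * factor
  out
}

#' Write a configuration back to YAML
#'
#' @param config a `ca3_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "ca3_config"))
  yaml::write_yaml(unclass(config), path, precision = 8)
  invisible(path)
}

type_names <- function(config) vapply(config$neuron_types, `[[`, "", "name")
type_counts <- function(config) {
  setNames(vapply(config$neuron_types, `[[`, 0L, "count"), type_names(config))
}

#' Tsodyks-Markram parameters as type-by-type matrices
#'
#' @param config a `ca3_config`.
#' @return list of 8x8 matrices (`g`, `tau_d`, `tau_r`, `tau_f`, `U`,
#'   `probability`, `wired`, `plastic`), rows = presynaptic type, columns =
#'   postsynaptic type; `NA` where a pair is not a potential connection.
#' @export
connection_matrices <- function(config) {
  tn <- type_names(config)
  k <- length(tn)
  mk <- function(fill) matrix(fill, k, k, dimnames = list(tn, tn))
  out <- list(g = mk(NA_real_), tau_d = mk(NA_real_), tau_r = mk(NA_real_),
              tau_f = mk(NA_real_), U = mk(NA_real_),
              probability = mk(0), wired = mk(FALSE), plastic = mk(FALSE))
  for (cn in config$connections) {
    i <- match(cn$pre, tn); j <- match(cn$post, tn)
    out$g[i, j] <- cn$g
    out$tau_d[i, j] <- cn$tau_d
    out$tau_r[i, j] <- cn$tau_r
    out$tau_f[i, j] <- cn$tau_f
    out$U[i, j] <- cn$U
    out$probability[i, j] <- cn$probability
    out$wired[i, j] <- TRUE
    out$plastic[i, j] <- isTRUE(cn$plastic)
  }
  out
}
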