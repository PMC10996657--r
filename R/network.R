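#' Instantiate the neuron populations of a configuration
#'
#' Assigns contiguous global indices grouped by type, in configuration order,
#' and copies each type's Izhikevich parameters onto its neurons.
#'
#' @param config a `ca3_config`.
#' @return a data frame with one row per neuron: `id`, `type`, `type_id`,
#'   and the nine Izhikevich parameters `C, k, vr, vt, a, b, d, vpeak, vmin`.
#' @export
build_populations <- function(config) {
  stopifnot(inherits(config, "ca3_config"))
  parts <- lapply(seq_along(config$neuron_types), function(ti) {
    ty <- config$neuron_types[[ti]]
    n <- ty$count
    cbind(data.frame(type = rep(ty$name, n), type_id = ti,
                     stringsAsFactors = FALSE),
          as.data.frame(ty$izh)[rep(1L, n), , drop = FALSE])
  })
  out <- do.call(rbind, parts)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Wire the network with independent Bernoulli trials
#'
#' Every ordered (pre, post) neuron pair whose type pair has a connection
#' spec is connected independently with that pair's probability. Autapses
#' are excluded, at most one synapse per ordered pair is created, all delays
#' are the configured uniform value, plastic synapses start at `w_init`, and
#' non-plastic weights are fixed at 1. Short-term plasticity state starts at
#' rest (u = 0, x = 1).
#'
#' @param neurons neuron table from [build_populations()].
#' @param config the `ca3_config` supplying connection specs.
#' @param seed integer seed for the wiring randomness.
#' @return a data frame of synapses, ordered by connection type then
#'   presynaptic index: `pre`, `post`, `weight`, `plastic`; attributes
#'   `delay_ms` and `seed`. Tsodyks-Markram state is implicit at rest and is
#'   materialized by the simulator.
#' @export
wire_connections <- function(neurons, config, seed = 1L) {
  stopifnot(inherits(config, "ca3_config"))
  cm <- connection_matrices(config)
  tn <- type_names(config)
  ids_by_type <- split(neurons$id, factor(neurons$type, levels = tn))
  w_init <- config$plasticity$w_init
  set.seed(as.integer(seed))
  pres <- vector("list", length(config$connections))
  posts <- vector("list", length(config$connections))
  plas <- logical(length(config$connections))
  for (ci in seq_along(config$connections)) {
    cn <- config$connections[[ci]]
    p <- cn$probability
    pre_ids <- ids_by_type[[cn$pre]]
    post_ids <- ids_by_type[[cn$post]]
    n_pre <- length(pre_ids); n_post <- length(post_ids)
    if (p <= 0 || n_pre == 0 || n_post == 0) next
    # one Bernoulli trial per ordered pair; pairs enumerated pre-major
    hits <- which(runif(n_pre * n_post) < p)
    if (!length(hits)) next
    pre_v <- pre_ids[((hits - 1L) %/% n_post) + 1L]
    post_v <- post_ids[((hits - 1L) %% n_post) + 1L]
    if (cn$pre == cn$post) {
      keep <- pre_v != post_v
      pre_v <- pre_v[keep]; post_v <- post_v[keep]
    }
    pres[[ci]] <- pre_v
    posts[[ci]] <- post_v
    plas[ci] <- isTRUE(cn$plastic)
  }
  n_each <- vapply(pres, length, 0L)
  syn <- data.frame(
    pre = unlist(pres) %||% integer(0),
    post = unlist(posts) %||% integer(0),
    weight = rep(ifelse(plas, w_init, 1), n_each),
    plastic = rep(plas, n_each)
  )
  attr(syn, "delay_ms") <- config$delay_ms
  attr(syn, "seed") <- as.integer(seed)
  syn
}

#' Plasticity constants for a given assembly size
#'
#' The maximum plastic weight multiplier is inversely proportional to the
#' assembly size, anchored at w_max = 20 for 300 members (anchor 6000); the
#' learning amplitude allows a weight to climb from `w_init` to the maximum
#' over 400 perfectly coincident spike pairs (100 presentations of 4-spike
#' trains):
#' \deqn{w_{max} = 6000 / size, \quad A = (w_{max} - w_{init}) / 400.}
#' Values are returned unrounded; rounding is applied only for display (see
#' [reproduce_table4()]).
#'
#' @param assembly_size number of pyramidal cells per assembly (>= 1).
#' @param w_init initial plastic weight multiplier (default 0.625).
#' @param g unitary conductance of the plastic connection type in nS
#'   (default 0.55, the recurrent pyramidal value); used for
#'   `g_max = w_max * g`.
#' @param anchor product of assembly size and maximum weight (default 6000).
#' @return list with `w_max`, `A`, `w_init`, `g_max`, `tau_ms`.
#' @export
derive_plasticity_constants <- function(assembly_size, w_init = 0.625,
                                        g = 0.55, anchor = 6000) {
  if (!is.numeric(assembly_size) || length(assembly_size) != 1 ||
      assembly_size <= 0)
    stop("assembly_size must be a positive number")
  w_max <- anchor / assembly_size
  A <- max(0, (w_max - w_init) / 400)
  list(w_max = w_max, A = A, w_init = w_init, g_max = w_max * g, tau_ms = 20)
}

#' Assign pyramidal cells to (possibly overlapping) assemblies
#'
#' With overlap fraction `f`, every unordered pair of assemblies shares
#' exactly `round_half_up(f * size)` cells; the pairwise shared sets are
#' mutually disjoint (no cell belongs to three assemblies) and remaining
#' members are unique to one assembly.
#'
#' @param pc_ids integer vector of pyramidal-cell global indices.
#' @param n_assemblies number of assemblies.
#' @param size members per assembly.
#' @param overlap pairwise overlap fraction in [0, 1).
#' @param seed integer seed for member selection.
#' @return an object of class `ca3_assemblies`: a list with `members` (list
#'   of integer vectors), `shared` (named list, "i-j" -> shared ids), `size`,
#'   `overlap`.
#' @export
assign_assemblies <- function(pc_ids, n_assemblies, size, overlap = 0,
                              seed = 1L) {
  stopifnot(n_assemblies >= 1, size >= 1, overlap >= 0, overlap < 1)
  k <- round_half_up(overlap * size)
  n_pairs_per <- n_assemblies - 1L
  n_unique <- size - n_pairs_per * k
  if (n_unique < 0)
    stop("configuration error: overlap ", overlap, " infeasible for size ",
         size, " with ", n_assemblies, " assemblies")
  pairs <- if (n_assemblies >= 2) utils::combn(n_assemblies, 2) else
    matrix(integer(0), 2, 0)
  need <- n_assemblies * n_unique + ncol(pairs) * k
  if (need > length(pc_ids))
    stop("configuration error: need ", need, " pyramidal cells, have ",
         length(pc_ids))
  set.seed(as.integer(seed))
  pool <- sample(pc_ids, need)
  shared <- list()
  members <- rep(list(integer(0)), n_assemblies)
  at <- 1L
  if (ncol(pairs) > 0 && k > 0) {
    for (pi in seq_len(ncol(pairs))) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      s <- pool[at:(at + k - 1L)]; at <- at + k
      shared[[paste(i, j, sep = "-")]] <- sort(s)
      members[[i]] <- c(members[[i]], s)
      members[[j]] <- c(members[[j]], s)
    }
  }
  for (i in seq_len(n_assemblies)) {
    u <- pool[at:(at + n_unique - 1L)]; at <- at + n_unique
    members[[i]] <- sort(c(members[[i]], u))
  }
  structure(list(members = members, shared = shared,
                 size = as.integer(size), overlap = overlap,
                 seed = as.integer(seed)),
            class = "ca3_assemblies")
}

#' @export
print.ca3_assemblies <- function(x, ...) {
  cat(length(x$members), "assemblies of size", x$size,
      "(pairwise overlap", paste0(100 * x$overlap, "%)"), "\n")
  invisible(x)
}

#' Build a complete network instance
#'
#' Runs [build_populations()], [wire_connections()], [assign_assemblies()]
#' and [derive_plasticity_constants()] from one configuration and returns a
#' simulable network object.
#'
#' @param config a `ca3_config`.
#' @param n_assemblies,assembly_size,overlap assembly layout; assemblies are
#'   drawn from the excitatory (pyramidal) population.
#' @param seed master seed; wiring and assembly selection use separate
#'   derived substreams.
#' @return an object of class `ca3_network`.
#' @export
build_network <- function(config, n_assemblies = 3, assembly_size = 50,
                          overlap = 0, seed = 1L) {
  stopifnot(inherits(config, "ca3_config"))
  neurons <- build_populations(config)
  synapses <- wire_connections(neurons, config, seed = derive_seed(seed, "wiring"))
  exc_type <- type_names(config)[vapply(config$neuron_types, function(t)
    isTRUE(t$excitatory), TRUE)]
  pc_ids <- neurons$id[neurons$type %in% exc_type]
  assemblies <- assign_assemblies(pc_ids, n_assemblies, assembly_size,
                                  overlap, seed = derive_seed(seed, "assembly"))
  plas <- derive_plasticity_constants(
    assembly_size,
    w_init = config$plasticity$w_init,
    g = connection_matrices(config)$g["Pyramidal", "Pyramidal"],
    anchor = config$plasticity$weight_anchor)
  plas$tau_ms <- config$plasticity$tau_stdp_ms
  structure(list(config = config, neurons = neurons, synapses = synapses,
                 assemblies = assemblies, plasticity = plas,
                 pc_ids = pc_ids, seed = as.integer(seed)),
            class = "ca3_network")
}

#' @export
print.ca3_network <- function(x, ...) {
  cat("CA3 network instance (seed ", x$seed, ")\n", sep = "")
  cat("  neurons:", format(nrow(x$neurons), big.mark = ","),
      " synapses:", format(nrow(x$synapses), big.mark = ","),
      sprintf(" (plastic: %s)\n",
              format(sum(x$synapses$plastic), big.mark = ",")))
  print(x$assemblies)
  cat(sprintf("  plasticity: w_init=%.3g w_max=%.4g A=%.4g tau=%g ms\n",
              x$plasticity$w_init, x$plasticity$w_max, x$plasticity$A,
              x$plasticity$tau_ms))
  invisible(x)
}

#' Write / read a sparse synapse snapshot
#'
#' Tab-separated triplets (pre, post, weight) with a commented header
#' carrying the wiring seed and configuration hash.
#'
#' @param network a `ca3_network`.
#' @param path output path.
#' @param weights optional weight vector overriding the table's weights
#'   (e.g. a checkpoint snapshot).
#' @return `path` invisibly (write); a data frame with attributes (read).
#' @export
write_synapse_snapshot <- function(network, path, weights = NULL) {
  syn <- network$synapses
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(syn))
    syn$weight <- weights
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ca3assembly synapse snapshot"),
    paste0("# seed: ", attr(network$synapses, "seed")),
    paste0("# config_hash: ", config_hash(network$config)),
    "pre\tpost\tweight"), con)
  write.table(syn[, c("pre", "post", "weight")], con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synapse_snapshot
#' @export
read_synapse_snapshot <- function(path) {
  hdr <- readLines(path, n = 3)
  out <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(out, "seed") <- as.integer(sub("# seed: ", "", hdr[2]))
  attr(out, "config_hash") <- sub("# config_hash: ", "", hdr[3])
  out
}
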