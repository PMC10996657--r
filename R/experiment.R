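#' Reproduce the plasticity-constants table
#'
#' Evaluates [derive_plasticity_constants()] for the 17 assembly sizes used
#' in the published parameter table and reports `g_max`, `w_max` and `A`
#' rounded to the printed precision (2, 2 and 3 decimals).
#'
#' @param sizes assembly sizes (default the 17 published ones).
#' @param g unitary recurrent-pyramidal conductance in nS used for `g_max`.
#'   Note the published `g_max` column implies an unrounded conductance of
#'   about 0.5531 nS, while the connection table prints 0.55; `g_max` here is
#'   derived from the configured value and may differ from the published
#'   column in the second decimal.
#' @return data frame: `size`, `g_max`, `w_max`, `A`.
#' @export
reproduce_table4 <- function(sizes = c(50, 75, 100, 150, 200, 225, 250, 270,
                                       275, 290, 300, 325, 375, 400, 425,
                                       500, 600),
                             g = 0.55) {
  rows <- lapply(sizes, function(s) {
    pc <- derive_plasticity_constants(s, g = g)
    data.frame(size = s, g_max = round(pc$g_max, 2),
               w_max = round(pc$w_max, 2), A = round(pc$A, 3))
  })
  do.call(rbind, rows)
}

write_manifest <- function(path, fields) {
  yaml::write_yaml(c(fields, list(package = "ca3assembly",
                                  version = as.character(
                                    utils::packageVersion("ca3assembly")),
                                  written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                   path)
  invisible(path)
}

#' Build a network and write it to disk
#'
#' @param config a `ca3_config` or path to a YAML configuration.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_assemblies,assembly_size,overlap assembly layout.
#' @return the built `ca3_network`, invisibly; writes `synapses.tsv`,
#'   `neurons.tsv`, `assemblies.tsv` and `manifest.yaml`.
#' @export
cmd_build <- function(config, out_dir, seed = 1L, n_assemblies = 3,
                      assembly_size = 50, overlap = 0) {
  if (is.character(config)) config <- load_network_config(config)
  net <- build_network(config, n_assemblies = n_assemblies,
                       assembly_size = assembly_size, overlap = overlap,
                       seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_synapse_snapshot(net, file.path(out_dir, "synapses.tsv"))
  write.table(net$neurons[, c("id", "type")],
              file.path(out_dir, "neurons.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  asm <- data.frame(
    assembly_id = rep(seq_along(net$assemblies$members),
                      lengths(net$assemblies$members)),
    neuron_id = unlist(net$assemblies$members))
  write.table(asm, file.path(out_dir, "assemblies.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"),
                 list(stage = "build", seed = seed,
                      config_hash = config_hash(config),
                      n_neurons = nrow(net$neurons),
                      n_synapses = nrow(net$synapses),
                      n_assemblies = n_assemblies,
                      assembly_size = assembly_size, overlap = overlap))
  invisible(net)
}

#' Train a network and write checkpoints to disk
#'
#' Runs [run_training()] and writes one directory per checkpoint
#' (`ckpt_<presentations>/weights.tsv`) plus a learning-curve table of
#' weight-based metrics (auto-association SNR and fraction of saturated
#' within-assembly synapses) at each checkpoint.
#'
#' @param network a `ca3_network`.
#' @param out_dir output directory.
#' @param n_presentations presentations per pattern.
#' @param checkpoint_every checkpoint interval.
#' @param seed master seed (patterns and background derive substreams).
#' @param ... passed to [run_training()].
#' @return the `ca3_training` object, invisibly.
#' @export
cmd_train <- function(network, out_dir, n_presentations = 30,
                      checkpoint_every = 5, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  patterns <- lapply(seq_along(network$assemblies$members), function(i)
    generate_pattern(network$assemblies$members[[i]], assembly_id = i,
                     seed = derive_seed(seed, paste0("pattern_", i))))
  schedule <- build_training_schedule(patterns, n_presentations)
  training <- run_training(network, schedule,
                           checkpoint_every = checkpoint_every,
                           seed = seed, ...)
  if (n_presentations == 0) {
    warning("0 presentations: writing no checkpoints")
    return(invisible(training))
  }
  curve <- lapply(training$checkpoints, function(ck) {
    dir_ck <- file.path(out_dir, paste0("ckpt_", ck$presentations))
    dir.create(dir_ck, showWarnings = FALSE)
    write_synapse_snapshot(network, file.path(dir_ck, "weights.tsv"),
                           weights = ck$weights)
    snr <- autoassociation_snr(ck$weights, network$synapses,
                               network$assemblies,
                               w_max = network$plasticity$w_max)
    data.frame(presentations = ck$presentations, snr = snr$ratio,
               pct_at_max = fraction_at_max(ck$weights, network$synapses,
                                            network$assemblies,
                                            network$plasticity$w_max))
  })
  write.table(do.call(rbind, curve), file.path(out_dir, "learning_curve.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"),
                 list(stage = "train", seed = seed,
                      config_hash = config_hash(network$config),
                      n_presentations = n_presentations,
                      checkpoint_every = checkpoint_every))
  training$patterns <- patterns
  invisible(training)
}

#' Test pattern completion over degradation levels and seeds
#'
#' For each degradation level and seed: select a cue from each trained
#' pattern, downscale the checkpoint's weights, run the test phase, and
#' compute the reconstruction report. A degradation of 0 makes the input
#' correlation 1 (undefined denominator) and is reported as skipped.
#'
#' @param network a `ca3_network`.
#' @param training a `ca3_training` (e.g. from [cmd_train()]).
#' @param checkpoint the `ca3_checkpoint` to test (default: final).
#' @param degradation_pcts vector of degradation percentages in [0, 100).
#' @param seeds one test run per seed.
#' @param out_dir optional directory for the metrics table.
#' @param overlap_aware pass-through to [degrade_pattern()].
#' @param ... passed to [run_test_from_checkpoint()].
#' @return data frame with one row per (degradation, seed, assembly) plus
#'   aggregate mean/sd rows (`assembly_id = NA`).
#' @export
cmd_test <- function(network, training, checkpoint = NULL,
                     degradation_pcts = 50, seeds = 1L, out_dir = NULL,
                     overlap_aware = FALSE, ...) {
  if (is.null(checkpoint))
    checkpoint <- training$checkpoints[[length(training$checkpoints)]]
  patterns <- training$schedule$items
  rows <- list()
  for (d in degradation_pcts) {
    if (d < 0 || d >= 100) stop("degradation must be in [0, 100)")
    for (s in seeds) {
      if (d == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          degradation_pct = d, seed = s, assembly_id = NA,
          accuracy_pct = NA, note = "skipped: undegraded cue (PCC_in = 1)")
        next
      }
      cues <- lapply(patterns, function(p)
        degrade_pattern(p, d, overlap_aware = overlap_aware,
                        assemblies = network$assemblies,
                        seed = derive_seed(s, paste0("cue", p$assembly_id, d))))
      tst <- run_test_from_checkpoint(network, checkpoint, cues, seed = s, ...)
      rep_ <- pattern_completion_report(network, training, tst)
      rows[[length(rows) + 1]] <- data.frame(
        degradation_pct = d, seed = s, assembly_id = rep_$assembly_id,
        accuracy_pct = rep_$accuracy_pct, note = "")
    }
    done <- do.call(rbind, rows)
    done <- done[done$degradation_pct == d & !is.na(done$accuracy_pct), ]
    if (nrow(done)) {
      rows[[length(rows) + 1]] <- data.frame(
        degradation_pct = d, seed = NA, assembly_id = NA,
        accuracy_pct = mean(done$accuracy_pct),
        note = sprintf("aggregate mean (sd %.3f) over %d rows",
                       sd(done$accuracy_pct), nrow(done)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(out, file.path(out_dir, "metrics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_manifest(file.path(out_dir, "manifest.yaml"),
                   list(stage = "test",
                        config_hash = config_hash(network$config),
                        checkpoint_presentations = checkpoint$presentations,
                        degradation_pcts = degradation_pcts,
                        seeds = seeds))
  }
  out
}
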