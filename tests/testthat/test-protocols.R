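test_that("patterns are frozen, grid-snapped, and deterministic", {
  pat <- generate_pattern(1:50, assembly_id = 1, seed = 7)
  expect_true(all(lengths(pat$offsets_ms) == 4))
  offs <- unlist(pat$offsets_ms)
  expect_true(all(offs >= 0 & offs < 20))
  expect_equal(offs, round(offs / 0.2) * 0.2)  # on the 0.2 ms grid
  expect_identical(generate_pattern(1:50, assembly_id = 1, seed = 7), pat)
  empty <- generate_pattern(1:5, n_spikes = 0, seed = 1)
  expect_true(all(lengths(empty$offsets_ms) == 0))
})

test_that("the training schedule is round-robin, theta-periodic, and sized", {
  pats <- lapply(1:3, function(i) generate_pattern((i * 100):(i * 100 + 9),
                                                   assembly_id = i, seed = i))
  sched <- build_training_schedule(pats, 65, settle_ms = 1000)
  expect_equal(nrow(sched$entries), 195)
  expect_equal(sched$duration_ms, 1000 + 195 * 200)  # 39 s patterned time
  expect_true(all(diff(sched$entries$onset_ms) == 200))
  expect_equal(sched$entries$assembly_id[1:6], c(1, 2, 3, 1, 2, 3))
  one <- build_training_schedule(pats[1], 1, settle_ms = 0)
  expect_equal(nrow(one$entries), 1)
  expect_equal(one$entries$onset_ms, 0)
  # pattern freezing: every presentation references the same frozen item
  stim <- ca3assembly:::schedule_stimulus(sched)
  s1 <- stim[stim$onset_ms < 1200, ]
  s2 <- stim[stim$onset_ms >= 1600 & stim$onset_ms < 1800, ]  # same pattern
  expect_equal(s2$onset_ms - 600, s1$onset_ms)
  expect_equal(s2$neuron, s1$neuron)
})

test_that("cue degradation sizes and overlap proportions follow the rules", {
  pat275 <- generate_pattern(1:275, assembly_id = 1, seed = 2)
  cue <- degrade_pattern(pat275, 50, seed = 3)
  expect_length(cue$members, 138)  # round-half-up of 137.5
  expect_true(all(cue$members %in% pat275$members))

  asm <- assign_assemblies(1:3000, 3, 300, overlap = 0.05, seed = 4)
  pat300 <- generate_pattern(asm$members[[1]], assembly_id = 1, seed = 5)
  cue300 <- degrade_pattern(pat300, 50, overlap_aware = TRUE,
                            assemblies = asm, seed = 6)
  expect_length(cue300$members, 150)
  expect_equal(cue300$n_shared_selected, 15L)  # 135 unique + 15 shared
  shared <- unlist(asm$shared[c("1-2", "1-3")])
  expect_equal(sum(cue300$members %in% shared), 15)

  full <- degrade_pattern(pat275, 0, seed = 1)
  expect_setequal(full$members, pat275$members)
  expect_error(degrade_pattern(pat275, 100), "degradation")
  tiny <- generate_pattern(1:2, assembly_id = 1, seed = 1)
  expect_error(degrade_pattern(tiny, 90), "degenerate cue")
})

test_that("testing schedules place cues and readout windows correctly", {
  pats <- lapply(1:3, function(i)
    generate_pattern(((i - 1) * 50 + 1):(i * 50), assembly_id = i, seed = i))
  cues <- lapply(pats, degrade_pattern, degradation_pct = 50, seed = 9)
  sim <- build_testing_schedule(cues, onset_ms = 500, mode = "simultaneous")
  expect_equal(sim$entries$onset_ms, rep(500, 3))
  expect_equal(sim$entries$readout_t0, rep(520, 3))
  expect_equal(sim$entries$readout_t1, rep(540, 3))
  seq_ <- build_testing_schedule(cues, onset_ms = 100, mode = "sequential")
  expect_equal(diff(seq_$entries$onset_ms), c(200, 200))
  empty <- build_testing_schedule(list())
  expect_equal(nrow(empty$entries), 0)
  # simultaneous cues sharing a neuron are a schedule conflict
  clash <- c(cues[1], cues[1])
  expect_error(build_testing_schedule(clash, mode = "simultaneous"),
               "schedule conflict")
})

test_that("background currents follow the configured lognormal law", {
  cfg <- ca3_example_config("full_scale")
  pc <- cfg$neuron_types[[1]]
  draws <- sample_background_currents(pc, 1e5, seed = 12)
  expect_true(all(draws > 0))
  # moment check on ln(I) under the location/variance parameterization
  se_m <- sqrt(1.5 / 1e5)
  se_v <- sqrt(2 * 1.5^2 / 1e5)
  expect_lt(abs(mean(log(draws)) - 4.0), 3 * se_m)
  expect_lt(abs(var(log(draws)) - 1.5), 3 * se_v)
  # presentation override uses the tighter variance
  pres <- sample_background_currents(pc, 1e5, presentation_window = TRUE,
                                     seed = 13)
  expect_lt(abs(var(log(pres)) - 1.0), 3 * sqrt(2 / 1e5))
  # degenerate variance pins every draw at exp(mu)
  degen <- pc
  degen$background$sigma2 <- 0
  expect_equal(sample_background_currents(degen, 10, seed = 1),
               rep(exp(4), 10))
  # whole-network sampling only re-draws types with an override
  net <- build_network(toy_config(c("Pyramidal" = 5, "Basket" = 4),
                                  probability = 0),
                       n_assemblies = 1, assembly_size = 2, seed = 1)
  bg <- sample_network_background(net, seed = 3)
  expect_false(any(bg$base[1:5] == bg$presentation[1:5]))
  expect_identical(bg$base[6:9], bg$presentation[6:9])
})

test_that("training checkpoints count presentations and are reproducible", {
  net <- toy_pc_network(n = 6, probability = 1, assembly_size = 3, seed = 2)
  pat <- generate_pattern(net$assemblies$members[[1]], assembly_id = 1,
                          seed = 4)
  sched <- build_training_schedule(list(pat), 65, settle_ms = 0)
  tr <- run_training(net, sched, checkpoint_every = 5, seed = 5,
                     force_spikes = TRUE, background = numeric(6))
  expect_length(tr$checkpoints, 13)
  expect_equal(vapply(tr$checkpoints, `[[`, 0L, "presentations"),
               seq(5, 65, by = 5))
  expect_equal(tr$initial$presentations, 0L)
  expect_true(all(tr$initial$weights == 0.625))
  tr2 <- run_training(net, sched, checkpoint_every = 5, seed = 5,
                      force_spikes = TRUE, background = numeric(6))
  expect_identical(tr$checkpoints[[13]]$weights,
                   tr2$checkpoints[[13]]$weights)
  expect_identical(tr$spikes, tr2$spikes)
  expect_warning(
    run_training(net, build_training_schedule(list(pat), 0, settle_ms = 0),
                 seed = 1, background = numeric(6)),
    "no presentations")
})

test_that("checkpoint segmentation does not alter the trajectory", {
  cfg <- toy_config(counts = c("Pyramidal" = 20, "Basket" = 5),
                    probability = 0.5, anchor = 240)
  net <- build_network(cfg, n_assemblies = 1, assembly_size = 8, seed = 6)
  pat <- generate_pattern(net$assemblies$members[[1]], assembly_id = 1,
                          seed = 7)
  sched <- build_training_schedule(list(pat), 10, settle_ms = 200)
  bg <- sample_network_background(net, seed = 8)
  fine <- run_training(net, sched, checkpoint_every = 2, seed = 9,
                       background = bg)
  coarse <- run_training(net, sched, checkpoint_every = 10, seed = 9,
                         background = bg)
  expect_identical(fine$checkpoints[[5]]$weights,
                   coarse$checkpoints[[1]]$weights)
  expect_identical(fine$spikes, coarse$spikes)
})

test_that("testing downscales to w_init exactly and validates the checkpoint", {
  cfg <- toy_config(counts = c("Pyramidal" = 20, "Basket" = 5),
                    probability = 0.5, anchor = 240)
  net <- build_network(cfg, n_assemblies = 1, assembly_size = 8, seed = 6)
  pat <- generate_pattern(net$assemblies$members[[1]], assembly_id = 1,
                          seed = 7)
  sched <- build_training_schedule(list(pat), 4, settle_ms = 200)
  bg <- sample_network_background(net, seed = 8)
  tr <- run_training(net, sched, checkpoint_every = 4, seed = 9,
                     background = bg)
  cue <- degrade_pattern(pat, 50, seed = 10)
  tst <- run_test_from_checkpoint(net, tr$checkpoints[[1]], list(cue),
                                  duration_ms = 600, onset_ms = 300, seed = 11)
  expect_equal(mean(tst$weights[net$synapses$plastic]), 0.625)
  expect_equal(tst$readout$t0, 320)
  # checkpoint at zero presentations: downscaling is a no-op
  t0 <- run_test_from_checkpoint(net, tr$initial, list(cue),
                                 duration_ms = 600, onset_ms = 300, seed = 11)
  expect_equal(t0$downscale_factor, 1)
  expect_identical(
    t0$sim$spikes,
    run_test_from_checkpoint(net, tr$initial, list(cue), duration_ms = 600,
                             onset_ms = 300, seed = 11)$sim$spikes)
  # config mismatch is rejected
  other <- build_network(toy_config(c("Pyramidal" = 9), probability = 0.5),
                         n_assemblies = 1, assembly_size = 3, seed = 1)
  expect_error(run_test_from_checkpoint(other, tr$initial, list(cue)),
               "hash mismatch")
})
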