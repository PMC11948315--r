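# Each block fixes a scripted loss table and asserts the full controller run
# against an independent hand execution of the switching algorithm (schedule,
# pruning, epochs trained, charged epochs). The tables are indexed by global
# epoch: a probe of candidate a from a checkpoint at epoch e reads row[e + 1],
# and training with a at epoch e reads row[e].

test_that("golden trace: mixed improvement and degradation with pruning", {
  tab <- list(A = c(0.50, 0.45, 0.50, 0.55, 0.40, 0.60, 0.70),
              B = c(0.60, 0.50, 0.42, 0.44, 0.43, 0.41, 0.45, 0.50),
              C = c(0.70, 0.80, 0.90, 1.00, 1.10, 1.20, 1.30, 1.40),
              D = c(0.80, 0.90, 1.00, 1.10, 1.20, 1.30, 1.40, 1.50))
  cfg <- quietConfig(c("A", "B", "C", "D"), p0 = 2, p1 = 1, afcsLoop = 3,
                     minAFCount = 2)
  tr <- scriptedTrainer(tab)
  run <- runAFCS(tr, cfg)
  # hand simulation: probes rank A,B,C,D; D pruned (initial); A trains e1-e4
  # (best e2 = 0.45), triggers; rollback to e2, probes at e3 rank B,A,C, C
  # pruned; B trains e3-e4 (best e3 = 0.42), triggers; rollback to e3, probes
  # at e4 rank B,A (floor blocks pruning); B triggers at e4.
  expect_identical(schedule(run),
                   data.frame(step = 1:3, epoch = c(1L, 2L, 3L), af = c("A", "B", "B")))
  expect_false(run@truncated)
  expect_identical(run@totalEpochs, 7L)
  expect_identical(run@chargedEpochs, 4L)
  expect_identical(run@finalState$bestLoss, 0.42)
  expect_identical(run@finalState$bestEpoch, 3L)
  expect_identical(run@trace$af, c(rep("A", 4), rep("B", 3)))
  expect_identical(run@trace$epoch, c(1L, 2L, 3L, 4L, 3L, 4L, 4L))
  # the trainer ends restored to the best checkpoint
  expect_identical(currentEpoch(tr), 3L)
  expect_identical(activeActivation(tr), "B")
})

test_that("golden trace: a dominant candidate is re-selected every cycle", {
  tab <- list(A = c(0.10, 0.12, 0.10, 0.13, 0.11, 0.14),
              B = c(0.20, 0.21, 0.22, 0.23, 0.24, 0.25),
              C = c(0.30, 0.31, 0.32, 0.33, 0.34, 0.35))
  cfg <- quietConfig(c("A", "B", "C"), p0 = 1, p1 = 1, afcsLoop = 3, minAFCount = 2)
  run <- runAFCS(scriptedTrainer(tab), cfg)
  # hand simulation: C pruned initially; A always probes best and always
  # worsens immediately at epoch 2, so every cycle records A at epoch 1
  expect_identical(schedule(run),
                   data.frame(step = 1:3, epoch = rep(1L, 3), af = rep("A", 3)))
  expect_identical(run@totalEpochs, 4L)
  expect_equal(run@chargedEpochs, extraEpochs(1, 1, 3))
  expect_identical(run@finalState$bestLoss, 0.10)
})

test_that("golden trace: probe ties break by candidate order, NaN ranks last", {
  tab <- list(A = c(0.90, 0.80, 0.85, 0.90, 0.70, 0.75, 0.80),
              B = c(0.50, 0.60, 0.65, 0.60, 0.62, 0.64),
              C = c(0.50, 0.55, 0.60, 0.58, 0.59, 0.60),
              D = c(NaN, NaN, NaN, NaN))
  cfg <- quietConfig(c("A", "B", "C", "D"), p0 = 2, p1 = 2, afcsLoop = 2,
                     minAFCount = 3)
  run <- runAFCS(scriptedTrainer(tab), cfg)
  # hand simulation: probes B=C=0.5 tie -> B first; D non-finite -> worst,
  # pruned initially. B trains e1-e3 (best e1), triggers; rollback to e1,
  # probes at e2 rank C,B,A; floor (3) blocks loop pruning; C triggers at e3.
  expect_identical(schedule(run),
                   data.frame(step = 1:2, epoch = c(1L, 1L), af = c("B", "C")))
  expect_identical(run@totalEpochs, 5L)
  expect_equal(run@chargedEpochs, extraEpochs(2, 2, 2))
  expect_identical(run@finalState$bestLoss, 0.50)
  # D was pruned, A survived the floor
  expect_false("D" %in% run@trace$af)
})

test_that("golden trace: NaN during training counts as an increase", {
  tab <- list(A = c(1.00, 0.90, 0.95, 0.85, NaN, 0.90, 0.95, 1.00),
              B = c(1.10, 1.00, 0.90, 0.80, 0.85, 0.90, 0.95),
              C = c(1.20, 1.10, 1.00, 0.90, 0.95, 1.00, 1.05))
  cfg <- afcsConfig(c("A", "B", "C"), p0 = 3, p1 = 2, afcsLoop = 2, minAFCount = 2)
  run <- runAFCS(scriptedTrainer(tab), cfg)
  # hand simulation: C pruned initially; A: e3 +1, e4 best 0.85, e5 NaN +1,
  # e6 0.90 +2, e7 0.95 +3 -> trigger; rollback to e4; probes at e5: A NaN
  # flagged, B=0.85 best; B: e5 0.85 not an increase (tie) and not a new
  # best; e6 +1, e7 +2 -> trigger.
  expect_identical(schedule(run),
                   data.frame(step = 1:2, epoch = c(1L, 4L), af = c("A", "B")))
  expect_identical(run@totalEpochs, 10L)
  expect_identical(run@chargedEpochs, 6L)
  expect_identical(run@finalState$bestLoss, 0.85)
  expect_identical(run@finalState$bestEpoch, 4L)
  expect_identical(sum(run@events$type == "nan_loss"), 1L)
})

test_that("golden trace: the epoch cap truncates a never-triggering run", {
  tab <- list(A = seq(1.0, by = -0.01, length.out = 10),
              B = seq(1.1, by = -0.01, length.out = 10),
              C = seq(1.2, by = -0.01, length.out = 10))
  cfg <- quietConfig(c("A", "B", "C"), p0 = 2, p1 = 1, afcsLoop = 3, minAFCount = 2)
  run <- runAFCS(scriptedTrainer(tab), cfg, epochCap = 5)
  expect_true(run@truncated)
  expect_identical(schedule(run),
                   data.frame(step = 1L, epoch = 1L, af = "A"))
  expect_identical(run@totalEpochs, 5L)
  expect_identical(run@chargedEpochs, 0L)
  expect_identical(run@trace$af, rep("A", 5))
})

test_that("a uniformly worsening table spends exactly the modelled extra epochs", {
  tab <- uniformWorseTable(6)
  cfg <- afcsConfig(names(tab), p0 = 3, p1 = 2, afcsLoop = 5, minAFCount = 3)
  run <- runAFCS(scriptedTrainer(tab), cfg)
  expect_equal(run@chargedEpochs, extraEpochs(3, 2, 5))   # 3 + 2*4 = 11
  expect_identical(nrow(schedule(run)), 5L)
  expect_true(all(schedule(run)$epoch == 1L))
})

test_that("when minAFCount = length(listAF) - 1 only the initial removal happens", {
  tab <- uniformWorseTable(4)
  cfg <- afcsConfig(names(tab), p0 = 2, p1 = 2, afcsLoop = 4, minAFCount = 3)
  run <- runAFCS(scriptedTrainer(tab), cfg)
  expect_identical(sum(run@events$type == "prune"), 1L)
})

test_that("published switch schedules satisfy the schedule invariants", {
  for (dsname in c("seedling", "aptos")) {
    ref <- referenceSwitchSchedules(dsname)
    for (mod in unique(ref$model)) {
      r <- ref[ref$model == mod, c("step", "epoch", "af")]
      rownames(r) <- NULL
      sch <- switchSchedule(r)           # validity: steps up, epochs non-dec
      expect_identical(nrow(sch@records), 5L)
      expect_identical(sch@records$epoch[1], 1L)
      expect_true(all(sch@records$af %in% defaultActivationNames()))
    }
  }
})

test_that("controller runs satisfy their structural invariants", {
  for (seed in c(11, 23, 37, 58)) {
    tab <- randomScriptedTable(seed)
    cfg <- afcsConfig(names(tab), p0 = 2, p1 = 2, afcsLoop = 3, minAFCount = 2,
                      seed = seed)
    run <- runAFCS(scriptedTrainer(tab), cfg, epochCap = 150)
    sch <- schedule(run)
    if (!run@truncated) expect_identical(nrow(sch), cfg@afcsLoop)
    expect_identical(sch$epoch[1], 1L)
    expect_true(all(diff(sch$step) > 0))
    expect_true(all(diff(sch$epoch) >= 0))
    expect_true(all(sch$af %in% cfg@listAF))
    expect_true(all(run@trace$af %in% cfg@listAF))
    # at most (length - minAFCount) prune events can ever occur
    expect_lte(sum(run@events$type == "prune"), length(cfg@listAF) - cfg@minAFCount)
    # reruns are bit-identical
    rerun <- runAFCS(scriptedTrainer(tab), cfg, epochCap = 150)
    expect_identical(schedule(rerun), sch)
    expect_identical(rerun@trace, run@trace)
  }
})
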