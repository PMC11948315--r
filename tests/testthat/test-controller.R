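feed <- function(losses, p, mode = "consecutive") {
  s <- controllerState(); out <- NULL
  dec <- character(0)
  for (i in seq_along(losses)) {
    out <- patienceStep(s, losses[i], p, epoch = i, mode = mode)
    s <- out$state
    dec <- c(dec, out$decision)
  }
  list(decisions = dec, state = s)
}

test_that("patience triggers on p strict consecutive increases", {
  r <- feed(c(1.0, 0.9, 0.95, 0.97, 0.99), p = 3)
  expect_identical(r$decisions, c(rep("continue", 4), "trigger"))
  # reset on any decrease: hand-simulated counter over a dip-and-rise stream
  r <- feed(c(1.0, 1.1, 1.2, 0.8, 0.9, 1.0, 1.1), p = 3)
  expect_identical(r$decisions, c(rep("continue", 6), "trigger"))
  expect_identical(r$state$bestEpoch, 4L)
  # strictly decreasing streams never trigger
  r <- feed(seq(2, 0.1, by = -0.05), p = 2)
  expect_false(any(r$decisions == "trigger"))
  # equal consecutive losses are not increases
  r <- feed(c(1, 1, 1, 1, 1), p = 2)
  expect_false(any(r$decisions == "trigger"))
})

test_that("NaN losses count as increases and never improve the best", {
  r <- feed(c(1.0, NaN, NaN), p = 2)
  expect_identical(r$decisions, c("continue", "continue", "trigger"))
  expect_identical(r$state$bestLoss, 1.0)
  # after a NaN, comparison resumes against the last finite loss
  r <- feed(c(1.0, NaN, 0.9), p = 3)
  expect_identical(r$state$count, 0L)
  expect_identical(r$state$bestLoss, 0.9)
})

test_that("no-improvement mode counts epochs since the best loss", {
  r <- feed(c(1.0, 0.99, 1.0, 1.0), p = 2, mode = "no_improvement")
  expect_identical(r$decisions, c("continue", "continue", "continue", "trigger"))
  # a later non-best decrease does not reset the counter in this mode
  r <- feed(c(1.0, 0.9, 1.2, 1.1), p = 2, mode = "no_improvement")
  expect_identical(r$decisions[4], "trigger")
})

test_that("pruneWorst honours the phase and the candidate floor", {
  expect_identical(pruneWorst(c("ReLU", "ELU", "SELU", "Mish"), "ELU", 3, "loop"),
                   c("ReLU", "SELU", "Mish"))
  expect_identical(pruneWorst(c("ReLU", "SELU", "Mish"), "Mish", 3, "loop"),
                   c("ReLU", "SELU", "Mish"))    # at the floor: no removal
  # initial phase removes unconditionally (7 candidates -> 6, Tanh out)
  seven <- c("Tanh", defaultActivationNames())
  expect_identical(pruneWorst(seven, "Tanh", 6, "initial"), defaultActivationNames())
  expect_identical(pruneWorst(c("A", "B"), "B", 3, "initial"), "A")
  expect_error(pruneWorst(c("A", "B"), "C", 2, "loop"), "not a remaining")
})

test_that("rankActivations sorts by probe loss with order tie-breaks", {
  tr <- scriptedTrainer(list(ReLU = 0.5, ELU = 0.7, SELU = 0.9))
  rk <- rankActivations(tr, c("ReLU", "ELU", "SELU"))
  expect_identical(rk$ranking, c("ReLU", "ELU", "SELU"))
  expect_identical(rk$best, "ReLU")
  expect_identical(rk$worst, "SELU")
  # tie between ELU and SELU keeps candidate order
  tr <- scriptedTrainer(list(ReLU = 0.9, ELU = 0.7, SELU = 0.7))
  expect_identical(rankActivations(tr, c("ReLU", "ELU", "SELU"))$ranking,
                   c("ELU", "SELU", "ReLU"))
  # the trainer is put back exactly as it was
  expect_identical(currentEpoch(tr), 0L)
  expect_identical(activeActivation(tr), NA_character_)
})

test_that("probe ranking on the printed first-repeat minima finds SELU, ReLU, Mish", {
  t3 <- referenceLossTraces()
  v1 <- t3[t3$model == "VGG16" & t3$experiment == "Exp1" & t3$af != "Tanh", ]
  mins <- tapply(v1$val_loss, v1$af, min)
  tr <- scriptedTrainer(lapply(stats::setNames(nm = names(mins)), function(a) mins[[a]]))
  rk <- rankActivations(tr, defaultActivationNames())
  expect_identical(rk$ranking[1:3], c("SELU", "ReLU", "Mish"))
})

test_that("non-finite probe losses rank last and are flagged", {
  tr <- scriptedTrainer(list(A = NaN, B = 0.4, C = 0.3))
  rk <- rankActivations(tr, c("A", "B", "C"))
  expect_identical(rk$ranking, c("C", "B", "A"))
  expect_identical(rk$flagged, "A")
  tr <- scriptedTrainer(list(A = NaN, B = NaN))
  expect_error(rankActivations(tr, c("A", "B")), "non-finite")
})

test_that("controller configurations are validated", {
  expect_error(afcsConfig(c("ReLU", "ELU")), "3 distinct")
  expect_error(afcsConfig(p0 = 0), ">= 1")
  expect_error(afcsConfig(afcsLoop = 1), ">= 2")
  expect_error(afcsConfig(minAFCount = 6), "length\\(listAF\\) - 1")
  expect_warning(afcsConfig(p0 = 1), "nominal domain")
  cfg <- afcsConfig()
  expect_identical(cfg@listAF, defaultActivationNames())
  expect_identical(c(cfg@p0, cfg@p1, cfg@afcsLoop, cfg@minAFCount), c(3L, 2L, 5L, 3L))
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- afcsConfig(p0 = 4, p1 = 3, afcsLoop = 6, minAFCount = 4, seed = 9)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    writeAFCSConfig(cfg, f)
    back <- readAFCSConfig(f)
    expect_identical(back@listAF, cfg@listAF)
    expect_identical(c(back@p0, back@p1, back@afcsLoop, back@minAFCount, back@seed),
                     c(4L, 3L, 6L, 4L, 9L))
  }
})
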