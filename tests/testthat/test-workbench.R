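test_that("a fixed-activation plan on a noiseless blob set is perfectly solvable", {
  plan <- experimentPlan(list(type = "synthetic", nClasses = 2, nPerClass = 10,
                              imageSize = 16, signalStrength = 90, noiseSd = 0,
                              seed = 3),
                         mode = "fixed", af = "ReLU", seed = 1, epochCap = 30,
                         patience = 5)
  b <- runExperiment(plan)
  expect_equal(b$metrics$accuracy, 1)
  expect_identical(b$label, "ReLU")
  expect_null(b$schedule)
  expect_true(all(c("epoch", "af", "val_loss") %in% names(b$trace)))
})

test_that("an AFCS plan yields a schedule with one row per completed cycle", {
  cfg <- quietConfig(c("ReLU", "ELU", "Mish"), p0 = 1, p1 = 1, afcsLoop = 2,
                     minAFCount = 2, seed = 1)
  plan <- experimentPlan(list(type = "synthetic", nClasses = 2, nPerClass = 10,
                              imageSize = 16, signalStrength = 15, noiseSd = 80,
                              seed = 4),
                         mode = "afcs", config = cfg, seed = 1, epochCap = 120)
  b <- runExperiment(plan)
  expect_false(is.null(b$schedule))
  if (!b$run@truncated) expect_identical(nrow(b$schedule), 2L)
  expect_identical(b$schedule$epoch[1], 1L)
  expect_true(all(b$schedule$af %in% cfg@listAF))
})

test_that("identical plans reproduce bit-identical bundles", {
  plan <- experimentPlan(list(type = "synthetic", nClasses = 2, nPerClass = 8,
                              imageSize = 16, seed = 5),
                         mode = "fixed", af = "ELU", seed = 2, epochCap = 4,
                         patience = 3)
  a <- runExperiment(plan)
  b <- runExperiment(plan)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$trace, b$trace)
  expect_identical(a$configHash, b$configHash)
})

test_that("plan validation enforces exactly one training mode", {
  ds <- list(type = "synthetic", nClasses = 2, nPerClass = 4, imageSize = 16)
  expect_error(experimentPlan(ds, mode = "fixed"), "needs 'af'")
  expect_error(experimentPlan(ds, mode = "afcs"), "needs 'config'")
  expect_error(experimentPlan(ds, mode = "afcs", af = "ReLU",
                              config = afcsConfig()), "not both")
})

test_that("compareRuns builds the comparison table and flags the best row", {
  mk <- function(label, acc) list(label = label, seed = 1L,
                                  metrics = list(accuracy = acc, loss = 1 - acc,
                                                 precision = acc, recall = acc,
                                                 f1 = acc))
  bundles <- list(mk("ReLU", 0.8), mk("ELU", 0.6), mk("AFCS", 0.9), mk("GELU", 0.7))
  tab <- compareRuns(bundles)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$label[tab$best], "AFCS")
  expect_identical(which(tab$best), which.max(tab$accuracy))   # independent argmax
  # identical bundles give identical rows
  same <- compareRuns(list(mk("A", 0.5), mk("A", 0.5)))
  expect_identical(same[1, 1:6], same[2, 1:6], ignore_attr = TRUE)
})

test_that("bundles written to disk carry their artifacts and metadata", {
  dir <- withr::local_tempdir()
  plan <- experimentPlan(list(type = "synthetic", nClasses = 2, nPerClass = 8,
                              imageSize = 16, seed = 5),
                         mode = "fixed", af = "ReLU", seed = 2, epochCap = 3,
                         patience = 3, outDir = dir)
  b <- runExperiment(plan)
  expect_true(all(file.exists(file.path(dir, c("metrics.csv", "trace.csv",
                                               "confusion.csv", "meta.json")))))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_identical(meta$configHash, b$configHash)
  expect_equal(meta$seed, 2L)
  m <- read.csv(file.path(dir, "metrics.csv"))
  expect_equal(m$accuracy, b$metrics$accuracy)
})

test_that("directory datasets round-trip through image files", {
  root <- withr::local_tempdir()
  ds <- makeBlobDataset(nClasses = 2, nPerClass = 3, imageSize = 16,
                        noiseSd = 0, seed = 9)
  for (i in seq_along(ds$labels)) {
    d <- file.path(root, paste0("class", ds$labels[i]))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    writeImageRaster(ds$images[i, , , ], file.path(d, paste0("img", i, ".png")))
  }
  plan <- experimentPlan(root, mode = "fixed", af = "ReLU", seed = 1,
                         epochCap = 2, patience = 2,
                         split = c(0.5, 0.25, 0.25))
  b <- runExperiment(plan)
  expect_true(is.finite(b$metrics$loss))
})
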