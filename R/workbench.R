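#' Describe one training experiment
#'
#' An experiment plan ties a dataset, a model, and a training mode (one fixed
#' activation for the whole run, or the switching controller) into a single
#' reproducible unit, mirroring the comparison protocol of the expansion
#' experiments: every candidate activation trained fixed, against one
#' controller run, on the same split.
#'
#' @param dataset a dataset list from [makeBlobDataset()], a directory of
#'   class-labelled images (one subdirectory per class, PNG/JPEG), or a list
#'   `list(type = "synthetic", ...)` of [makeBlobDataset()] arguments.
#' @param mode `"afcs"` (requires `config`) or `"fixed"` (requires `af`).
#' @param af fixed activation name (mode `"fixed"`).
#' @param config an [AFCSConfig-class] (mode `"afcs"`).
#' @param split fractions for [splitDataset()] (default 70/15/15, stratified).
#' @param seed integer seed for split, model init and batch order.
#' @param epochCap cap on trained epochs.
#' @param patience early-stopping patience for fixed-activation runs.
#' @param mask apply [colorRangeMask()] to every image before training.
#' @param resize resize images to `resize x resize` px first (`NULL` = keep).
#' @param outDir optional directory; when set, [runExperiment()] writes the
#'   result bundle there as CSV/JSON.
#' @return an `experimentPlan` list.
#' @export
experimentPlan <- function(dataset, mode = c("afcs", "fixed"), af = NULL,
                           config = NULL, split = c(0.7, 0.15, 0.15),
                           seed = 1L, epochCap = 400L, patience = 5L,
                           mask = FALSE, resize = NULL, outDir = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(af)) stop("fixed mode needs 'af'", call. = FALSE)
  if (mode == "afcs" && is.null(config)) stop("afcs mode needs 'config'", call. = FALSE)
  if (mode == "afcs" && !is.null(af)) stop("give either 'af' or 'config', not both", call. = FALSE)
  structure(list(dataset = dataset, mode = mode, af = af, config = config,
                 split = split, seed = as.integer(seed),
                 epochCap = as.integer(epochCap), patience = as.integer(patience),
                 mask = mask, resize = resize, outDir = outDir),
            class = "experimentPlan")
}

# FNV-1a over the deparsed plan: a dependency-free config fingerprint
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.resolveDataset <- function(dataset, plan) {
  if (is.character(dataset)) {
    classes <- list.dirs(dataset, recursive = FALSE)
    if (!length(classes)) stop("no class subdirectories in ", dataset, call. = FALSE)
    paths <- lapply(classes, list.files, pattern = "[.](png|jpe?g)$",
                    ignore.case = TRUE, full.names = TRUE)
    labels <- rep(seq_along(classes), lengths(paths))
    imgs <- lapply(unlist(paths), readImageRaster)
    if (!length(imgs)) stop("no images found in ", dataset, call. = FALSE)
    dataset <- list(images = NULL, labels = labels, files = unlist(paths))
    dataset$imagesList <- imgs
  } else if (!is.null(dataset$type) && identical(dataset$type, "synthetic")) {
    dataset <- do.call(makeBlobDataset, dataset[setdiff(names(dataset), "type")])
  }
  if (!is.null(dataset$imagesList)) {
    imgs <- dataset$imagesList
  } else {
    imgs <- lapply(seq_len(dim(dataset$images)[1]),
                   function(i) dataset$images[i, , , , drop = TRUE])
  }
  if (plan$mask) imgs <- lapply(imgs, function(im) {
    out <- colorRangeMask(im); attr(out, "mask") <- NULL; out
  })
  if (!is.null(plan$resize))
    imgs <- lapply(imgs, resizeImage, width = plan$resize, height = plan$resize)
  S <- dim(imgs[[1]])[1]
  arr <- array(0, c(length(imgs), S, S, 3))
  for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
  list(images = arr, labels = dataset$labels)
}

#' Run one experiment end to end
#'
#' Resolves the dataset (generating it if synthetic), applies the requested
#' preprocessing, splits it, trains — either one fixed activation under plain
#' early stopping, or the full switching controller — and evaluates on the
#' held-out test split. All artifacts carry the seed and a config fingerprint
#' so a bundle can be reproduced exactly.
#'
#' @param plan an [experimentPlan()].
#' @return a result bundle: list with `metrics` (test-set report including
#'   loss), `trace` (per-epoch losses), `schedule` (data frame, AFCS mode
#'   only), `confusion`, `mode`, `label`, `seed`, `configHash`, and `run` (the
#'   [AFCSRun-class], AFCS mode only).
#' @examples
#' plan <- experimentPlan(list(type = "synthetic", nClasses = 2, nPerClass = 10,
#'                             imageSize = 16, noiseSd = 0, seed = 3),
#'                        mode = "fixed", af = "ReLU", epochCap = 3)
#' bundle <- runExperiment(plan)
#' bundle$metrics$accuracy
#' @export
runExperiment <- function(plan) {
  stopifnot(inherits(plan, "experimentPlan"))
  data <- .resolveDataset(plan$dataset, plan)
  split <- splitDataset(data$labels, plan$split, seed = plan$seed, stratified = TRUE)
  trainer <- makeTinyCNN(data, split = split, seed = plan$seed,
                         activation = if (plan$mode == "fixed") plan$af else "ReLU")
  if (plan$mode == "fixed") {
    st <- controllerState(bestCheckpoint = snapshotModel(trainer))
    rows <- list()
    for (epoch in seq_len(plan$epochCap)) {
      loss <- trainOneEpoch(trainer)
      rows[[epoch]] <- data.frame(order = epoch, epoch = epoch, af = plan$af,
                                  val_loss = loss)
      out <- patienceStep(st, loss, plan$patience, epoch = epoch,
                          mode = "no_improvement")
      st <- out$state
      if (out$improved) st$bestCheckpoint <- snapshotModel(trainer)
      if (out$decision == "trigger") break
    }
    restoreModel(trainer, st$bestCheckpoint)
    trace <- do.call(rbind, rows)
    run <- NULL; sched <- NULL
    label <- plan$af
  } else {
    run <- runAFCS(trainer, plan$config, epochCap = plan$epochCap)
    trace <- run@trace
    sched <- schedule(run)
    label <- "AFCS"
  }
  metrics <- evaluateModel(trainer, "test")
  bundle <- list(metrics = metrics, trace = trace, schedule = sched,
                 confusion = metrics$confusion, mode = plan$mode, label = label,
                 seed = plan$seed,
                 configHash = .configHash(plan[setdiff(names(plan), "outDir")]),
                 run = run)
  if (!is.null(plan$outDir)) writeBundle(bundle, plan$outDir)
  bundle
}

#' Write a result bundle to disk
#'
#' Emits `metrics.csv` (one row), `trace.csv`, `schedule.csv` (AFCS runs),
#' `confusion.csv`, `events.log` and `meta.json` (seed + config fingerprint)
#' under `dir`.
#'
#' @param bundle a bundle from [runExperiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- bundle$metrics
  utils::write.csv(data.frame(label = bundle$label, accuracy = m$accuracy,
                              loss = m$loss, precision = m$precision,
                              recall = m$recall, f1 = m$f1,
                              averaging = m$averaging),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(bundle$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  if (!is.null(bundle$schedule))
    utils::write.csv(bundle$schedule, file.path(dir, "schedule.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(bundle$confusion)),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  if (!is.null(bundle$run))
    utils::write.csv(bundle$run@events, file.path(dir, "events.log"), row.names = FALSE)
  jsonlite::write_json(list(seed = bundle$seed, configHash = bundle$configHash,
                            label = bundle$label, mode = bundle$mode),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Compare result bundles
#'
#' Builds the comparison table of the experiment protocol: one row per run
#' (fixed activations and controller runs side by side) with accuracy, loss,
#' precision, recall and F1, and a flag on the best value per metric column
#' (max for scores, min for loss).
#'
#' @param bundles list of bundles from [runExperiment()] on the same dataset
#'   and split.
#' @return data frame, one row per bundle, with a logical `best` column
#'   marking the highest-accuracy row.
#' @export
compareRuns <- function(bundles) {
  stopifnot(length(bundles) >= 2L)
  hashes <- vapply(bundles, function(b) b$seed, integer(1))
  if (length(unique(hashes)) > 1L)
    warning("bundles use different seeds; comparison may not share a split")
  tab <- do.call(rbind, lapply(bundles, function(b)
    data.frame(label = b$label, accuracy = b$metrics$accuracy,
               loss = b$metrics$loss, precision = b$metrics$precision,
               recall = b$metrics$recall, f1 = b$metrics$f1)))
  tab$best <- seq_len(nrow(tab)) == which.max(tab$accuracy)
  tab
}
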