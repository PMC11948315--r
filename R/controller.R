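#' Configuration of the activation-switching controller
#'
#' The five controller hyperparameters plus run options. `listAF` is the
#' ordered candidate list; `p0` the patience of the first training segment and
#' `p1` the patience of every later cycle (consecutive validation-loss
#' increases tolerated before the controller acts); `afcsLoop` the number of
#' cycles a completed run performs; `minAFCount` the floor below which the
#' worst candidate is no longer pruned. Patience values of 1 are accepted with
#' a warning (the nominal domain is `>= 2`, but the cost model's own worked
#' example uses `p1 = 1`).
#'
#' @slot listAF ordered character vector of >= 3 distinct activation names.
#' @slot p0,p1 patience values in epochs, `>= 1`.
#' @slot afcsLoop number of cycles, `>= 2`.
#' @slot minAFCount candidate-list floor, in `[2, length(listAF) - 1]`.
#' @slot probeEpochs epochs each candidate is probed from the reference
#'   checkpoint when ranking (default 1).
#' @slot patienceMode `"consecutive"` (count strict epoch-over-epoch
#'   increases, reset on any non-increase; the default) or `"no_improvement"`
#'   (count epochs since the best loss improved, as in classical early
#'   stopping).
#' @slot seed integer seed forwarded to probe runs.
#' @export
setClass("AFCSConfig",
  representation(listAF = "character", p0 = "integer", p1 = "integer",
                 afcsLoop = "integer", minAFCount = "integer",
                 probeEpochs = "integer", patienceMode = "character",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@listAF) < 3L || anyDuplicated(object@listAF))
      return("listAF needs >= 3 distinct names")
    if (object@p0 < 1L || object@p1 < 1L) return("p0 and p1 must be >= 1")
    if (object@afcsLoop < 2L) return("afcsLoop must be >= 2")
    if (object@minAFCount < 2L) return("minAFCount must be >= 2")
    if (object@minAFCount > length(object@listAF) - 1L)
      return("minAFCount must be <= length(listAF) - 1")
    if (!object@patienceMode %in% c("consecutive", "no_improvement"))
      return("unknown patienceMode")
    TRUE
  })

#' @param listAF,p0,p1,afcsLoop,minAFCount,probeEpochs,patienceMode,seed see
#'   the class slots. Defaults are the calibrated values (`p0 = 3`, `p1 = 2`,
#'   `afcsLoop = 5`, `minAFCount = 3`) over the six default candidates.
#' @return an `AFCSConfig`.
#' @rdname AFCSConfig-class
#' @examples
#' afcsConfig()
#' @export
afcsConfig <- function(listAF = defaultActivationNames(), p0 = 3L, p1 = 2L,
                       afcsLoop = 5L, minAFCount = 3L, probeEpochs = 1L,
                       patienceMode = c("consecutive", "no_improvement"),
                       seed = 1L) {
  patienceMode <- match.arg(patienceMode)
  obj <- new("AFCSConfig", listAF = listAF, p0 = as.integer(p0), p1 = as.integer(p1),
             afcsLoop = as.integer(afcsLoop), minAFCount = as.integer(minAFCount),
             probeEpochs = as.integer(probeEpochs), patienceMode = patienceMode,
             seed = as.integer(seed))
  if (p0 < 2L || p1 < 2L)
    warning("patience below 2 is outside the nominal domain; accepted")
  obj
}

setMethod("show", "AFCSConfig", function(object) {
  cat("AFCSConfig: listAF = [", paste(object@listAF, collapse = ", "),
      "], p0 =", object@p0, ", p1 =", object@p1,
      ", loop =", object@afcsLoop, ", minAFCount =", object@minAFCount, "\n")
})

#' Read or write a controller configuration (YAML/JSON)
#'
#' Plain-text serialisation with keys `list_AF`, `p0`, `p1`, `AFCS_loop`,
#' `min_AF_count`, `probe_epochs`, `patience_mode`, `seed`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param config an [AFCSConfig-class].
#' @return `readAFCSConfig` an `AFCSConfig`; `writeAFCSConfig` the path,
#'   invisibly.
#' @export
readAFCSConfig <- function(path) {
  x <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  afcsConfig(listAF = as.character(x$list_AF),
             p0 = x$p0 %||% 3L, p1 = x$p1 %||% 2L,
             afcsLoop = x$AFCS_loop %||% 5L, minAFCount = x$min_AF_count %||% 3L,
             probeEpochs = x$probe_epochs %||% 1L,
             patienceMode = x$patience_mode %||% "consecutive",
             seed = x$seed %||% 1L)
}

#' @rdname readAFCSConfig
#' @export
writeAFCSConfig <- function(config, path) {
  x <- list(list_AF = as.list(config@listAF), p0 = config@p0, p1 = config@p1,
            AFCS_loop = config@afcsLoop, min_AF_count = config@minAFCount,
            probe_epochs = config@probeEpochs, patience_mode = config@patienceMode,
            seed = config@seed)
  if (grepl("[.]json$", path)) jsonlite::write_json(x, path, auto_unbox = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' Running state of the patience monitor
#'
#' A lightweight record threaded through [patienceStep()]: the consecutive
#' increase counter, the last (finite) loss seen, and the best loss with its
#' epoch and checkpoint token.
#'
#' @param bestCheckpoint opaque token of the best state (may be `NULL`).
#' @return a `controllerState` list with fields `count`, `prevLoss`,
#'   `lastFinite`, `bestLoss`, `bestEpoch`, `bestCheckpoint`, `sinceBest`.
#' @export
controllerState <- function(bestCheckpoint = NULL) {
  list(count = 0L, prevLoss = NA_real_, lastFinite = NA_real_,
       bestLoss = Inf, bestEpoch = 0L, bestCheckpoint = bestCheckpoint,
       sinceBest = 0L)
}

#' One step of the patience monitor
#'
#' Feeds one epoch's validation loss into the monitor. In `"consecutive"`
#' mode the counter increments on a strict increase over the previous epoch's
#' loss and resets to 0 on any non-increase; a trigger is returned exactly
#' when the counter reaches the patience `p`. A `NaN` loss is treated as an
#' increase. In `"no_improvement"` mode the counter counts epochs since the
#' best loss last improved. The best loss/epoch are tracked in either mode.
#'
#' @param state a [controllerState()].
#' @param valLoss this epoch's validation loss.
#' @param p patience threshold, `>= 1`.
#' @param epoch the epoch number being scored (for best-epoch bookkeeping).
#' @param mode `"consecutive"` or `"no_improvement"`.
#' @return list with `decision` (`"continue"` or `"trigger"`), `improved`
#'   (did `valLoss` beat the best loss) and the updated `state`.
#' @examples
#' s <- controllerState(); out <- NULL
#' for (l in c(1.0, 0.9, 0.95, 0.97, 0.99)) {
#'   out <- patienceStep(s, l, p = 3); s <- out$state
#' }
#' out$decision  # "trigger"
#' @export
patienceStep <- function(state, valLoss, p, epoch = NA_integer_,
                         mode = c("consecutive", "no_improvement")) {
  mode <- match.arg(mode)
  if (p < 1L) stop("patience must be >= 1", call. = FALSE)
  improved <- is.finite(valLoss) && valLoss < state$bestLoss
  if (improved) {
    state$bestLoss <- valLoss
    state$bestEpoch <- as.integer(epoch)
    state$sinceBest <- 0L
  } else state$sinceBest <- state$sinceBest + 1L
  if (mode == "consecutive") {
    increase <- if (is.nan(valLoss)) TRUE
                else if (is.na(state$lastFinite)) FALSE
                else valLoss > state$lastFinite
    state$count <- if (increase) state$count + 1L else 0L
  } else {
    state$count <- state$sinceBest
  }
  state$prevLoss <- valLoss
  if (is.finite(valLoss)) state$lastFinite <- valLoss
  list(decision = if (state$count >= p) "trigger" else "continue",
       improved = improved, state = state)
}

#' Rank candidate activations by short probe runs
#'
#' From the trainer's current state, for each candidate in order: restore the
#' reference checkpoint, set the candidate, train `probeEpochs` epochs and
#' record the final validation loss. Candidates are ranked ascending by probe
#' loss; ties keep candidate order; candidates with a non-finite probe loss
#' rank last and are flagged. The reference checkpoint is restored before
#' returning, so probing never perturbs the run.
#'
#' @param trainer a trainer-port object.
#' @param candidates ordered character vector of activation names.
#' @param probeEpochs probe length in epochs (default 1).
#' @param seed optional integer passed to [seedModel()] before probing so all
#'   probes share a data order.
#' @return list with `ranking` (names, best first), `best`, `worst` (the last
#'   ranked name different from `best`, `NA` if none), `probeLosses` (named)
#'   and `flagged` (non-finite candidates).
#' @examples
#' tr <- scriptedTrainer(list(ReLU = 0.5, ELU = 0.7, SELU = 0.9))
#' rankActivations(tr, c("ReLU", "ELU", "SELU"))$ranking
#' @export
rankActivations <- function(trainer, candidates, probeEpochs = 1L, seed = NULL) {
  stopifnot(length(candidates) >= 1L)
  ref <- snapshotModel(trainer)
  if (!is.null(seed)) seedModel(trainer, seed)
  losses <- vapply(candidates, function(af) {
    restoreModel(trainer, ref)
    setActivation(trainer, af)
    l <- NA_real_
    for (k in seq_len(probeEpochs)) l <- trainOneEpoch(trainer)
    as.numeric(l)
  }, numeric(1))
  restoreModel(trainer, ref)
  bad <- !is.finite(losses)
  if (all(bad)) stop("all candidate probe losses are non-finite", call. = FALSE)
  key <- ifelse(bad, Inf, losses)
  ord <- order(key)                       # stable: ties keep candidate order
  ranking <- candidates[ord]
  best <- ranking[1L]
  notBest <- ranking[ranking != best]
  list(ranking = ranking, best = best,
       worst = if (length(notBest)) notBest[length(notBest)] else NA_character_,
       probeLosses = losses, flagged = candidates[bad])
}

#' Remove the worst candidate from the list
#'
#' In the `"initial"` phase the worst candidate is removed unconditionally
#' (the switching algorithm removes it before any guard applies); in the
#' `"loop"` phase it is removed only while the list is above the
#' `minAFCount` floor. Survivor order is preserved.
#'
#' @param remaining ordered character vector of candidate names.
#' @param worst name to remove; must be present.
#' @param minAFCount list floor.
#' @param phase `"initial"` or `"loop"`.
#' @return the (possibly unchanged) candidate vector.
#' @examples
#' pruneWorst(c("ReLU", "ELU", "SELU", "Mish"), "ELU", 3, "loop")
#' pruneWorst(c("ReLU", "SELU", "Mish"), "Mish", 3, "loop")  # at the floor
#' @export
pruneWorst <- function(remaining, worst, minAFCount, phase = c("initial", "loop")) {
  phase <- match.arg(phase)
  if (!worst %in% remaining) stop("'", worst, "' is not a remaining candidate", call. = FALSE)
  if (phase == "loop" && length(remaining) <= minAFCount) return(remaining)
  remaining[remaining != worst]
}

#' The ordered switch schedule of a run
#'
#' One record per cycle: the cycle number (`step`), the epoch at which the
#' activation took effect (step 1 is always epoch 1; later steps carry the
#' epoch of the restored best checkpoint), and the activation name. On a
#' completed run there are exactly `afcsLoop` records, steps strictly
#' increasing and epochs non-decreasing.
#'
#' @slot records data frame with columns `step`, `epoch`, `af`.
#' @export
setClass("SwitchSchedule", representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    if (!all(c("step", "epoch", "af") %in% names(r)))
      return("records need columns step, epoch, af")
    if (nrow(r) > 1L) {
      if (any(diff(r$step) <= 0)) return("steps must be strictly increasing")
      if (any(diff(r$epoch) < 0)) return("epochs must be non-decreasing")
    }
    TRUE
  })

#' @rdname SwitchSchedule-class
#' @param records data frame with columns `step`, `epoch`, `af`.
#' @export
switchSchedule <- function(records) new("SwitchSchedule", records = records)

setMethod("show", "SwitchSchedule", function(object) {
  cat("SwitchSchedule (", nrow(object@records), " steps)\n", sep = "")
  print(object@records, row.names = FALSE)
})

#' @export
setMethod("as.data.frame", "SwitchSchedule", function(x, ...) x@records)

#' A completed (or truncated) switching run
#'
#' Returned by [runAFCS()].
#'
#' @slot schedule the [SwitchSchedule-class].
#' @slot trace data frame of every trained epoch in order: `order` (wall
#'   order), `cycle`, `epoch` (1-based, rewinding on rollback), `af`,
#'   `val_loss`.
#' @slot events data frame log of probe/switch/prune/trigger events.
#' @slot config the [AFCSConfig-class] used.
#' @slot truncated `TRUE` when the epoch cap ended the run before the last
#'   cycle triggered.
#' @slot chargedEpochs epochs trained beyond restored best checkpoints
#'   (discarded by rollback; the quantity modelled by [extraEpochs()]).
#' @slot totalEpochs total trained epochs, probes excluded.
#' @slot probeEpochsUsed epochs consumed by probe runs.
#' @slot finalState final [controllerState()] (list) with the best checkpoint.
#' @export
setClass("AFCSRun",
  representation(schedule = "SwitchSchedule", trace = "data.frame",
                 events = "data.frame", config = "AFCSConfig",
                 truncated = "logical", chargedEpochs = "integer",
                 totalEpochs = "integer", probeEpochsUsed = "integer",
                 finalState = "list"))

setMethod("show", "AFCSRun", function(object) {
  cat("AFCSRun:", nrow(object@schedule@records), "of", object@config@afcsLoop,
      "cycles;", object@totalEpochs, "epochs trained (",
      object@chargedEpochs, "charged beyond best checkpoints,",
      object@probeEpochsUsed, "probe epochs);",
      if (object@truncated) "TRUNCATED at epoch cap" else "completed", "\n")
  cat("best validation loss", object@finalState$bestLoss,
      "at epoch", object@finalState$bestEpoch, "\n")
  show(object@schedule)
})

#' @rdname AFCSRun-class
#' @param run an `AFCSRun`.
#' @return `schedule()` the schedule records as a data frame; `lossTrace()`
#'   the per-epoch trace.
#' @export
schedule <- function(run) run@schedule@records

#' @rdname AFCSRun-class
#' @export
lossTrace <- function(run) run@trace

#' Run the cyclic activation-switching controller
#'
#' Executes the full meta-training loop on any trainer-port object:
#'
#' 1. Rank all of `listAF` by probe runs, activate the best candidate, remove
#'    the worst (initial phase), and record schedule step 1 at epoch 1.
#' 2. Train under patience `p0` (see [patienceStep()]). Whenever the
#'    validation loss improves, the state is checkpointed.
#' 3. On each patience trigger, for cycles `i = 2 .. afcsLoop`: restore the
#'    best checkpoint (the epoch counter rewinds with it), re-rank the
#'    remaining candidates from that checkpoint, activate the best, remove the
#'    worst while above the `minAFCount` floor, record schedule step `i` at
#'    the checkpoint's epoch, and continue under patience `p1`.
#' 4. Stop after cycle `afcsLoop`'s trigger, or at `epochCap` (the run is then
#'    flagged truncated). The best checkpoint is restored before returning.
#'
#' With a scripted trainer the run is fully deterministic; with the tiny CNN
#' it is reproducible for a fixed seed.
#'
#' @param trainer a trainer-port object (see [scriptedTrainer()],
#'   [makeTinyCNN()]).
#' @param config an [AFCSConfig-class].
#' @param epochCap safety bound on total trained epochs (probes excluded).
#' @return an [AFCSRun-class].
#' @examples
#' tab <- list(A = seq(1.1, 2, by = 0.05), B = seq(1.2, 2.1, by = 0.05),
#'             C = seq(1.3, 2.2, by = 0.05))
#' run <- runAFCS(scriptedTrainer(tab),
#'                afcsConfig(c("A", "B", "C"), p0 = 2, p1 = 2, afcsLoop = 2,
#'                           minAFCount = 2))
#' schedule(run)
#' @export
runAFCS <- function(trainer, config, epochCap = 400L) {
  stopifnot(is(config, "AFCSConfig"), epochCap >= 1L)
  remaining <- config@listAF
  st <- controllerState(bestCheckpoint = snapshotModel(trainer))
  sched <- vector("list", config@afcsLoop)
  trace <- list(); events <- list()
  logEvent <- function(type, epoch, detail)
    events[[length(events) + 1L]] <<- data.frame(type = type, epoch = epoch,
                                                 detail = detail)
  charged <- 0L; total <- 0L; probesUsed <- 0L
  truncated <- FALSE
  for (i in seq_len(config@afcsLoop)) {
    phase <- if (i == 1L) "initial" else "loop"
    p <- if (i == 1L) config@p0 else config@p1
    if (i > 1L) restoreModel(trainer, st$bestCheckpoint)
    rk <- rankActivations(trainer, remaining, probeEpochs = config@probeEpochs,
                          seed = config@seed + i)
    probesUsed <- probesUsed + length(remaining) * config@probeEpochs
    logEvent("probe", currentEpoch(trainer),
             paste0(names(rk$probeLosses), "=", signif(rk$probeLosses, 4),
                    collapse = " "))
    setActivation(trainer, rk$best)
    schedEpoch <- if (i == 1L) 1L else max(1L, st$bestEpoch)
    sched[[i]] <- data.frame(step = i, epoch = schedEpoch, af = rk$best)
    logEvent("switch", schedEpoch, rk$best)
    if (!is.na(rk$worst)) {
      pruned <- pruneWorst(remaining, rk$worst, config@minAFCount, phase)
      if (length(pruned) < length(remaining)) logEvent("prune", schedEpoch, rk$worst)
      remaining <- pruned
    }
    # train this segment until the patience triggers
    st$count <- 0L
    st$prevLoss <- if (i == 1L) NA_real_ else st$bestLoss
    st$lastFinite <- st$prevLoss
    st$sinceBest <- 0L
    segStart <- st$bestEpoch
    repeat {
      if (total >= epochCap) { truncated <- TRUE; break }
      loss <- trainOneEpoch(trainer)
      total <- total + 1L
      ep <- currentEpoch(trainer)
      trace[[length(trace) + 1L]] <-
        data.frame(order = total, cycle = i, epoch = ep, af = rk$best,
                   val_loss = loss)
      if (is.nan(loss)) logEvent("nan_loss", ep, rk$best)
      out <- patienceStep(st, loss, p, epoch = ep, mode = config@patienceMode)
      st <- out$state
      if (out$improved) st$bestCheckpoint <- snapshotModel(trainer)
      if (out$decision == "trigger") {
        logEvent("trigger", ep, paste0("p=", p, " cycle=", i))
        charged <- charged + (ep - max(st$bestEpoch, segStart))
        break
      }
    }
    if (truncated) break
  }
  restoreModel(trainer, st$bestCheckpoint)
  records <- do.call(rbind, sched[!vapply(sched, is.null, TRUE)])
  rownames(records) <- NULL
  traceDf <- do.call(rbind, trace)
  rownames(traceDf) <- NULL
  new("AFCSRun",
      schedule = switchSchedule(records),
      trace = traceDf,
      events = if (length(events)) do.call(rbind, events)
               else data.frame(type = character(), epoch = integer(), detail = character()),
      config = config, truncated = truncated,
      chargedEpochs = as.integer(charged), totalEpochs = as.integer(total),
      probeEpochsUsed = as.integer(probesUsed),
      finalState = st)
}
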