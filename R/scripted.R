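#' A scripted-loss mock trainer
#'
#' A trainer-port conformant test double whose "training" replays a fixed
#' table of per-(activation, epoch) validation losses. `trainOneEpoch`
#' advances the epoch counter and returns `losses[[activeAF]][epoch]`;
#' snapshot/restore replay positions exactly, and `setActivation` switches the
#' lookup row. With a scripted trainer the whole switching controller is
#' deterministic, enabling exact golden-trace tests.
#'
#' Probe runs read the same table: a probe of candidate `a` from a checkpoint
#' at epoch `e` consumes `losses[[a]][e + 1]`, so the leading entries of each
#' row double as that activation's probe losses.
#'
#' @param losses named list mapping activation name to a numeric vector of
#'   per-epoch validation losses, or a data frame with columns `af`, `epoch`,
#'   `val_loss`. Consulting a missing cell is a scenario-coverage error.
#' @param metrics optional metrics report list returned verbatim by
#'   `evaluateModel` (a scripted trainer has nothing to evaluate otherwise).
#' @return a `ScriptedTrainer` object.
#' @examples
#' tr <- scriptedTrainer(list(ReLU = c(0.5, 0.4), ELU = c(0.7, 0.6)))
#' setActivation(tr, "ReLU")
#' trainOneEpoch(tr)  # 0.5
#' @export
scriptedTrainer <- function(losses, metrics = NULL) {
  if (is.data.frame(losses)) {
    stopifnot(all(c("af", "epoch", "val_loss") %in% names(losses)))
    losses <- lapply(split(losses, losses$af),
                     function(d) d$val_loss[order(d$epoch)])
  }
  stopifnot(is.list(losses), !is.null(names(losses)), all(nzchar(names(losses))))
  e <- new.env(parent = emptyenv())
  e$losses <- losses
  e$metrics <- metrics
  e$af <- NA_character_
  e$epoch <- 0L
  new("ScriptedTrainer", state = e)
}

#' @rdname scriptedTrainer
#' @export
setClass("ScriptedTrainer", representation(state = "environment"))

setMethod("show", "ScriptedTrainer", function(object) {
  e <- object@state
  cat("ScriptedTrainer:", length(e$losses), "activation rows; epoch",
      e$epoch, "; active:", e$af, "\n")
})

#' @rdname trainer-port
#' @export
setMethod("trainOneEpoch", "ScriptedTrainer", function(object, ...) {
  e <- object@state
  if (is.na(e$af)) stop("no activation set on scripted trainer", call. = FALSE)
  e$epoch <- e$epoch + 1L
  row <- e$losses[[e$af]]
  v <- if (e$epoch > length(row)) NA_real_ else row[e$epoch]
  if (is.na(v) && !is.nan(v))   # NaN is a legitimate scripted loss
    stop("scripted loss table has no entry for (", e$af, ", epoch ", e$epoch,
         "): scenario not covered", call. = FALSE)
  v
})

#' @rdname trainer-port
#' @export
setMethod("snapshotModel", "ScriptedTrainer", function(object, ...)
  list(af = object@state$af, epoch = object@state$epoch))

#' @rdname trainer-port
#' @export
setMethod("restoreModel", "ScriptedTrainer", function(object, token, ...) {
  object@state$af <- token$af
  object@state$epoch <- token$epoch
  invisible(object)
})

#' @rdname trainer-port
#' @export
setMethod("setActivation", "ScriptedTrainer", function(object, name, ...) {
  if (!name %in% names(object@state$losses))
    stop("activation '", name, "' not in scripted loss table", call. = FALSE)
  object@state$af <- name
  invisible(object)
})

#' @rdname trainer-port
#' @export
setMethod("currentEpoch", "ScriptedTrainer", function(object) object@state$epoch)

#' @rdname trainer-port
#' @export
setMethod("activeActivation", "ScriptedTrainer", function(object) object@state$af)

#' @rdname trainer-port
#' @export
setMethod("modelParameters", "ScriptedTrainer", function(object) list())

#' @rdname trainer-port
#' @export
setMethod("evaluateModel", "ScriptedTrainer", function(object, split = "test", ...) {
  if (is.null(object@state$metrics))
    stop("scripted trainer has no evaluation data", call. = FALSE)
  object@state$metrics
})

#' Read a scripted loss table from CSV
#'
#' Loads a CSV with columns `af`, `epoch`, `val_loss` into the list form
#' accepted by [scriptedTrainer()].
#'
#' @param path CSV file path.
#' @return named list of per-epoch loss vectors.
#' @export
readScriptedLosses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("af", "epoch", "val_loss") %in% names(d)))
  lapply(split(d, d$af), function(x) x$val_loss[order(x$epoch)])
}
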