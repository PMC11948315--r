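#' @title Trainer contract generics
#'
#' @description Any model that can be driven by the AFCS controller implements
#' this small set of generics (the "trainer port"): epoch-level training that
#' reports a validation loss, held-out evaluation, exact snapshot/restore of
#' the whole training state, and weight-preserving activation swaps. Both the
#' scripted mock trainer ([scriptedTrainer()]) and the trainable tiny CNN
#' ([makeTinyCNN()]) conform.
#'
#' @param object a trainer object.
#' @param ... passed to methods.
#' @return `trainOneEpoch` the epoch's validation loss (numeric scalar);
#'   `snapshotModel` an opaque checkpoint token; `restoreModel` the trainer,
#'   invisibly; `currentEpoch` the 1-based count of completed epochs;
#'   `activeActivation` the name of the activation currently in force;
#'   `evaluateModel` a metrics report (see [classificationMetrics()]);
#'   `modelParameters` the list of learnable parameter arrays.
#' @name trainer-port
NULL

#' @rdname trainer-port
#' @export
setGeneric("trainOneEpoch", function(object, ...) standardGeneric("trainOneEpoch"))

#' @rdname trainer-port
#' @param split which held-out split to evaluate (`"validation"` or `"test"`).
#' @export
setGeneric("evaluateModel", function(object, split = "test", ...) standardGeneric("evaluateModel"))

#' @rdname trainer-port
#' @export
setGeneric("snapshotModel", function(object, ...) standardGeneric("snapshotModel"))

#' @rdname trainer-port
#' @param token a checkpoint token previously returned by `snapshotModel`.
#' @export
setGeneric("restoreModel", function(object, token, ...) standardGeneric("restoreModel"))

#' @rdname trainer-port
#' @param name name of an activation function known to the trainer's catalog.
#' @export
setGeneric("setActivation", function(object, name, ...) standardGeneric("setActivation"))

#' @rdname trainer-port
#' @export
setGeneric("currentEpoch", function(object) standardGeneric("currentEpoch"))

#' @rdname trainer-port
#' @export
setGeneric("activeActivation", function(object) standardGeneric("activeActivation"))

#' @rdname trainer-port
#' @export
setGeneric("modelParameters", function(object) standardGeneric("modelParameters"))

#' @rdname trainer-port
#' @param seed integer used to re-seed the trainer's internal data-order
#'   stream; the default method is a no-op so purely scripted trainers ignore it.
#' @export
setGeneric("seedModel", function(object, seed) standardGeneric("seedModel"))

#' @export
#' @rdname trainer-port
setMethod("seedModel", "ANY", function(object, seed) invisible(object))
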